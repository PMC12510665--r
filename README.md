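# prot2rna

Design candidate binder RNAs for a target protein from its sequence alone,
and evaluate the designs. `prot2rna` is aimed at computational biologists
prototyping protein-conditional RNA design pipelines: it covers corpus
curation, model training, candidate generation, scoring, novelty and
stability analysis, molecular-dynamics trajectory statistics, and attention
interpretability, with synthetic-data generators that give every stage a
planted ground truth.

## The method

Protein-conditional design is cast as sequence-to-sequence translation.
For a protein p = (p1, ..., p_np) and RNA r = (r1, ..., r_nr), the model
learns

    p(r | p) = prod_i p(r_i | r_<i, p)

with a transformer encoder-decoder (relative position bias, tied
embeddings, BPE tokenization over a shared protein/RNA vocabulary) trained
by negative log-likelihood over an interaction corpus. Because corpora are
dominated by a few heavily-studied proteins, interactions are first grouped
into *complex clusters* — interactions sharing a protein cluster (40%
identity) and an RNA cluster (90% identity) — and each interaction is
weighted by 1/(cluster size): a cluster of 10 contributes weight 0.1 per
member, a cluster of 2 contributes 0.5, and every cluster carries equal
total mass for weighted up-sampling.

At inference the decoder is sampled stepwise (greedy, beam, top-k, nucleus;
production setting top-k = 30, temperature 1.5), the candidate pool is
scored by normalized minimum free energy, generation consistency
C/max(C), and a pluggable binding score, and candidates are ranked by the
equal-weighted composite. Novelty against known binders uses seeded
Smith-Waterman alignment with the four-way threshold conjunction
(identity >= 70%, alignment length >= 15 bp, coverage >= 50%, E-value
<= 0.1; seed word size 4 up to 50 nt, else 7). Trajectory analysis
computes dE = E_complex - (E_protein + E_RNA), interface hydrogen bonds
(4.5 A donor-acceptor, 150 degree D-H...A angle), 0.45 nm contacts,
RMSD/radius of gyration, and free-energy landscapes F = -kT ln P with the
minimum shifted to zero.

## Worked example

Train a small model on a synthetic planted-motif corpus and design RNAs
for a held-out protein:

```r
library(prot2rna)

code <- make_motif_code(n_motifs = 4, motif_len = 3, word_len = 5, seed = 11)
recs <- sample_interactions(code, 1200, seed = 12)
tok  <- train_bpe(recs, vocab_size = 64)
pairs <- tokenize_pairs(tok, recs)

cfg <- model_config(preset = "desk", vocab_size = vocab_size(tok), seed = 5)
model <- restrict_output_vocab(build_model(cfg), rna_token_ids(tok))
state <- train_model(model, pairs[1:1000], steps = 200, seed = 9)

round(c(first = state$loss_trace[1], last = tail(state$loss_trace, 1)), 2)
#> first  last
#>  7.34  1.22

pool <- generate_pool(state$model, tok, pairs[[1001]]$p,
                      specs = list(default_sampling_spec(max_new_tokens = 16)),
                      n_per_spec = 24, seed = 1)
register_binding_scorer("toy", toy_motif_scorer(code$words))
head(composite_rank(score_pool(pool, scorer = "toy")), 3)[, c("seq", "count", "composite")]
#>                       seq count composite
#> 12                  GUGGC     7 0.7192982
#> 2  CGAACGCGUGGCGUGGCUCGCA     1 0.7142857
#> 8    GGCCGUACGCGUGGCUACGC     1 0.7142857
```

Even after this short 200-step run the top-ranked candidate (`GUGGC`,
drawn 7 times out of 24) is exactly the RNA word the planted code maps this
protein's motif to. The loss falls as the model learns the code; after
full training (2000 steps on 5000 pairs, as the acceptance suite runs it)
held-out next-token accuracy exceeds 0.9 and the top-ranked candidate
contains the protein's true mapped RNA word for most held-out proteins.
`score_pool` adds per-candidate minimum free energy (kcal/mol, builtin
pair-energy model), its pool-normalized value in [0, 1], consistency and
binding scores; `composite_rank` orders candidates by their mean.

Folding and stability:

```r
fold_mfe("GGGAAACCC")$structure   #> "(((...)))"   (energy -9 kcal/mol)
gc_content("GAUC")                #> 0.5
ensemble_free_energy("GGGAAACCC") #> -9.041449 kcal/mol (<= MFE, always)
```

A thin CLI over the same functions ships in `inst/cli/prot2rna.R`
(`validate`, `curate`, `generate`, `score`, `novelty`, `trajmetrics`,
`simulate`).

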