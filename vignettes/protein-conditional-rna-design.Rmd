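---
title: "Protein-conditional RNA design: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-conditional RNA design: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prot2rna)
```

# The problem

RNA molecules that bind a chosen protein are promising therapeutic agents,
but the space of candidate sequences is astronomically large and classical
selection (SELEX and its relatives) is slow and expensive. `prot2rna` treats
protein-conditional RNA design as sequence-to-sequence translation: given a
protein sequence $p = (p_1, \dots, p_{n_p})$, learn the conditional
distribution of binder RNAs $r = (r_1, \dots, r_{n_r})$,

$$ p(r \mid p) \;=\; \prod_{i=1}^{n_r} p(r_i \mid r_{<i}, p), $$

with a transformer encoder-decoder trained to minimize the negative
log-likelihood of observed protein-RNA interactions. At inference, the
decoder is sampled token by token, conditioned only on the protein sequence,
so candidates can be designed for proteins with no known RNA interactions at
all. The package implements the full surrounding pipeline: corpus curation
and balancing, tokenization, training, decoding, candidate scoring, novelty
and stability analysis, molecular-dynamics trajectory statistics, and
cross-attention interpretability — plus synthetic-data generators that make
every stage testable against planted ground truth.

# Corpus curation and balancing

Interaction corpora are aggressively redundant: a handful of proteins can
account for most interactions (in public RNA-interaction databases, single
proteins reach over a million entries while others have fewer than a
hundred). The curation module addresses this in four steps:

1. **Length filter.** A record survives only if both sequences have length
   in $[10, 1024]$ (`filter_by_length`), removing outliers on both ends.
2. **Identity clustering.** RNAs are clustered at 90% identity and proteins
   at 40% (`greedy_cluster`), mirroring CD-HIT's greedy-incremental scheme:
   sequences are processed longest first and join the first cluster whose
   representative is at least as similar as the threshold. Identity is
   defined as matches in an optimal global alignment (match 1, mismatch 0,
   gaps contributing nothing) divided by the shorter length — the CD-HIT
   convention. At package scale (up to a few thousand sequences) exact
   alignments are affordable and no k-mer prefilter is used.
3. **Complex clusters and weights.** Interactions sharing both their
   protein cluster and their RNA cluster form one *complex cluster*; each
   interaction receives weight 1/(cluster size) (`compute_weights`), so a
   cluster of 10 interactions gives each member weight 0.1, a cluster of 2
   gives 0.5, and every cluster carries total mass exactly 1.
4. **Up-sampling.** `weighted_sample` draws with replacement proportional
   to these weights, equalizing expected representation across complex
   clusters. The target corpus size is a caller-chosen parameter (the
   balancing scheme itself does not prescribe one).

# Tokenization

Protein and RNA sequences are tokenized with byte-pair encoding
(`train_bpe`): starting from single residues, the most frequent adjacent
symbol pair is merged until the vocabulary budget (default 1000 non-special
tokens) is exhausted or no pair repeats. One shared model is trained on the
union corpus; RNA symbols are kept in a disjoint internal alphabet
(lowercased bases), so no merge can ever fuse protein and RNA symbols and a
single tied embedding table serves both sides. Four specials (PAD, EOS,
BOS, UNK) sit outside the budget at ids 0-3. Sequences are right-truncated
(keeping the N-terminus / 5' end) or right-padded to a fixed frame, EOS
preceding the padding; the encoder also records, per token, the residue
span it covers, which the attention analysis needs to map token scores back
onto residues.

# The sequence-to-sequence model

`build_model` constructs a pre-layer-norm transformer encoder-decoder with:

* **Relative position bias** in the self-attention scores (encoder:
  bidirectional buckets; decoder: causal buckets): a per-head learned
  scalar added to each query-key score that depends only on the bucketed
  distance $j - i$, never on absolute positions. Defaults are 32 buckets
  with exact small distances and log-spaced buckets up to a maximal
  distance of 128 — the standard bucketing for this mechanism, which the
  architecture family specifies only by name.
* **Tied embeddings**: the decoder's output projection is the transpose of
  the input embedding, consistent with the single shared vocabulary.
* **Masked decoding**: the decoder self-attention is causal, so the
  next-token distribution at step $i$ provably ignores positions $\ge i$
  (tested property).
* An optional **output-vocabulary restriction**
  (`restrict_output_vocab`): since the decoder targets RNA, its projection
  can be masked to RNA tokens plus EOS, matching a decoder whose output
  layer covers only the RNA vocabulary. The unrestricted model is retained
  as the default because several analytic test limits (uniform-logits NLL)
  are stated over the full vocabulary.

Two named configurations exist. `desk` (2 layers, 4 heads, $d=64$,
$d_{ff}=256$) is the configuration every experiment in this package runs
at; `paper` (6 layers, 12 heads, $d=512$, $d_{ff}=2048$, about 41M
parameters) approximates the full-scale setting whose exact widths are not
public, and is provided for completeness, never exercised by tests.

Training (`train_model`) minimizes the summed token NLL (padding excluded,
mean over the batch) with AdamW — decoupled weight decay 0.01 on linear and
embedding weights only — gradient accumulation (effective batch =
`batch_size` x `accum_steps`), global-norm clipping at 1.0, and a linear
warmup (100 steps) followed by cosine decay of the learning rate, the
recipe that reached the lowest desk-scale loss in our experiments. The
whole forward *and* backward pass is written directly on base-R matrices;
correctness is enforced by a finite-difference gradient check in the test
suite rather than trusted to an autodiff library. Dropout is configurable
but defaults to 0: desk-scale corpora are small enough that the planted
mapping is learned without regularization, and a zero rate keeps training
bit-reproducible for a fixed seed.

# Decoding and candidate pools

`sample_rna` implements greedy decoding, beam search (sum of log
probabilities, no length normalization; `B = 1` reduces to greedy), top-k
and nucleus sampling. Temperature divides the logits *before* any
truncation; the order matters and is fixed by that convention. Ties in
greedy/beam selection break toward the lowest token id so decoding is
deterministic. The production setting is top-k with $k = 30$ and
$T = 1.5$, the combination that scored best in the model-selection sweep;
`generate_pool` draws a pool per strategy (per-draw seeds derived from one
master seed via a counter), collapses duplicates, and records occurrence
counts $C$.

Candidates are scored by three normalized components:

* `mfe_norm` $= 1 - (\mathrm{MFE} - \min)/(\max - \min)$ over the pool
  (min-max scaling; an all-equal pool maps to all 1, since every member
  attains the pool optimum);
* `consistency_norm` $= C / \max(C)$;
* a pluggable `binding_score` in $[0,1]$. Affinity predictors are
  protein-specific external models, so the package defines a scorer
  *contract* (sequence in, self-normalized score out) with a toy motif
  scorer as reference implementation, rather than bundling any predictor.

The composite is their equal-weighted mean (weights configurable; absent
components re-mean over the rest) — the combination rule is a package
choice, as no canonical one exists.

# Secondary-structure thermodynamics

The builtin folding engine is a Nussinov-style dynamic program over
pseudoknot-free structures with pair energies GC $= -3$, AU $= -2$,
GU $= -1$ kcal/mol and hairpin loops of at least 3 unpaired bases. This
deliberately simplified energy model was chosen because it is *exactly*
testable: the test suite enumerates every legal structure of short
sequences and verifies both the MFE dynamic program and the
partition-function dynamic program ($\Delta G_{ens} = -kT \ln Z$ at 310 K,
$k = 0.0019872$ kcal mol$^{-1}$ K$^{-1}$) against brute force. A
full thermodynamic engine (ViennaRNA's `RNAfold`) is wired behind the same
interface (`engine = "vienna"`) for production use. Stability reporting
(`summarize_pool`) includes MFE, MFE/length (the length-normalized MFE,
distinct from the pool-relative `mfe_norm`), ensemble free energy, GC
content and length, with count-weighted medians and IQRs.

# Novelty classification

A designed RNA is *similar to known* only if a local alignment against the
known-binder database passes **all four** thresholds: identity $\ge 70\%$,
alignment length $\ge 15$ bp, query coverage $\ge 50\%$, E-value
$\le 0.1$; otherwise it is novel. Alignment is seeded (an exact shared
word of size 4 for queries up to 50 nt, 7 above — the boundary length 50
taking the smaller word) and scored by full affine-gap Smith-Waterman
(match +2, mismatch -3, gap open -5, gap extend -2, the classic nucleotide
defaults; the aligner this emulates does not publish its matrix in the
relevant sources). E-values use the Karlin-Altschul form
$E = K m n e^{-\lambda S}$ with $\lambda$ solved from the scoring system
under uniform base composition and $K = 0.3$; absolute E-values are
approximate — only the threshold behavior matters, and the thresholds are
configurable.

# Trajectory statistics

Given a multi-model PDB trajectory and per-frame component energies, the
package computes:

* **Binding energy** $\Delta E = E_{complex} - (E_{protein} + E_{RNA})$
  per frame;
* **Hydrogen bonds**: donor-acceptor (N/O heavy atom) pairs across the
  protein-RNA interface with $d(D, A) \le 4.5$ Å and D-H$\cdots$A angle
  $\ge 150°$. The angle's vertex is the hydrogen — the criterion's own
  name fixes that convention — and hydrogens are assigned to donors by a
  1.2 Å covalent-distance rule, so input structures must be protonated;
* **Contacts**: cross-chain atom pairs within 0.45 nm (converted once to
  4.5 Å — all internal coordinates are Å);
* **RMSD** against the first frame (optionally after optimal rigid-body
  superposition) and mass-weighted **radius of gyration**, over a
  configurable atom selection (default: protein atoms, since the
  reference procedure tracks a protein atom group without naming it);
* the **free-energy landscape** $F = -kT \ln P$ over a 2D histogram of
  RMSD x RG (default 50 x 50 bins over the observed ranges, Gaussian
  smoothing with $\sigma = 1$ bin — both package defaults, as the
  procedure states neither), minimum shifted to zero. Bins never visited
  are masked (NA) rather than set to $+\infty$: $-kT\ln P$ is undefined at
  $P = 0$, and masking keeps the basin depth (the largest finite $F$)
  well defined. Note that with $kT \approx 0.62$ kcal/mol at 310 K, a
  histogram over $n$ frames can only produce depths up to about
  $kT \ln n$; published basin depths in the 15-16 kcal/mol range imply a
  probability normalization that raw occupancy histograms cannot reach,
  so depths computed here are comparable to each other, not to such
  figures.

# Attention interpretability

Cross-attention maps from the decoder are aggregated **max over RNA
positions, then mean over heads, then mean over layers**, giving each
protein token the strongest attention it received; token scores are then
distributed equally over the residues in each token's span (mass
conserving; residues beyond a truncated prefix score 0 — the model never
attended them). The *attention ratio* is the maximum residue score inside
annotated binding domains divided by the maximum outside; ratios above 1
indicate domain-focused attention. Aggregation over up to 1000 samples per
protein reports both the per-sample ratio distribution and the ratio of
the mean profile (either could be meant by a per-protein ratio, so both
are emitted), with per-layer breakdowns.

# Synthetic data: what it emulates and what it does not

The generators provide planted ground truth for every analysis surface:

* `make_motif_code` / `sample_interactions`: a deterministic code mapping
  short protein motifs (length 3, drawn non-overlapping) to RNA words
  (length 5). Each synthetic protein (20-40 residues) carries 1-2 planted
  motifs; its RNA is the concatenation of the mapped words in motif order.
  Backgrounds are scrubbed of accidental motif occurrences so the mapping
  is exactly recoverable at zero noise. Motif lengths were chosen so a
  `desk` model learns the code in minutes of CPU time.
* `make_redundant_families`: founder sequences plus substitution-mutated
  copies at a target identity (realized within ±3%), exercising the
  90%/40% clustering thresholds in both recovery and anti-recovery
  directions.
* `make_toy_trajectory`: rigid bodies with interface geometry planted
  exactly at, inside, and outside the hydrogen-bond and contact cutoffs,
  plus a rigid drift schedule for RMSD and an exact $\Delta E$ schedule.
* `make_attention_fixture`: attention rows with in-domain columns enriched
  by a known factor, so the analysis recovers the factor exactly at zero
  noise.

These fixtures validate the *machinery*, not the biology: passing tests
show the algorithms compute what they claim on data whose truth is known.
Real corpora have motif grammar, structure-mediated binding, length and
composition biases, and noisy labels that no planted code emulates, so
desk-scale results say nothing about binding affinity of real designs.

# Desk-scale experiment sizes

The mapping-recovery experiment in the acceptance suite trains the `desk`
configuration for 2000 optimizer steps (batch 8) on 5000 planted-code
pairs, evaluates teacher-forced next-token accuracy on 200 held-out pairs,
and generates 48-draw top-k(30)/T=1.5 pools for 40 held-out proteins.
Exhaustive-oracle checks run at sequence length ≤ 12 (hundreds of
structures each) and 50-atom frames. These sizes keep each suite run
within a coffee break on one CPU while leaving the checked properties
non-trivial.

# Known limitations

* The builtin energy model ignores stacking, loop entropies and dangles;
  absolute energies are not comparable to full thermodynamic engines
  (which are available behind the `vienna` adapter).
* E-value calibration is approximate (fixed $K$, uniform composition).
* The trainer is single-device and CPU-bound; the `paper` configuration
  is provided but not trainable at desk scale.
* Binding scores are only as good as the plugged-in scorer; the toy motif
  scorer is a testing device, not an affinity predictor.
* Trajectory analysis assumes a fixed topology across frames and performs
  no periodic-boundary imaging.
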