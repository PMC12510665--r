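Package: prot2rna
Title: Protein-Conditional RNA Design, Scoring and Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing candidate binder RNAs from a protein
    sequence alone and for evaluating the designs. Curates protein-RNA
    interaction corpora (length filtering, greedy identity clustering,
    inverse complex-cluster-size weighting, up-sampling), trains a byte-pair
    tokenizer and an encoder-decoder transformer with relative position bias
    on paired sequences, decodes candidate RNAs with greedy, beam, top-k and
    nucleus sampling, and scores candidate pools by normalized minimum free
    energy, generation consistency and a pluggable binding scorer. Also
    provides novelty classification against known binders via seeded local
    alignment, secondary-structure thermodynamics (minimum free energy and
    ensemble free energy by dynamic programming), molecular-dynamics
    trajectory statistics (binding energy, hydrogen bonds, contacts, RMSD,
    radius of gyration, free-energy landscapes) and cross-attention
    interpretability against annotated protein domains, plus synthetic-data
    generators for all of the above.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
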