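# Independent oracles used across the suite. Each is a deliberately naive
# reimplementation (enumeration, brute force, direct formulas) kept separate
# from the package's algorithms.

# Longest-common-subsequence identity: matches under an optimal global
# alignment with match 1 / mismatch 0 / zero gap contribution equals the LCS
# length; divide by the shorter sequence length.
oracle_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n))
    for (j in seq_len(m))
      L[i + 1L, j + 1L] <- if (x[i] == y[j]) L[i, j] + 1L else
        max(L[i, j + 1L], L[i + 1L, j])
  L[n + 1L, m + 1L] / min(n, m)
}

# Greedy clustering re-run on top of the oracle identity.
oracle_greedy_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character()
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (oracle_identity(seqs[[i]], reps[[k]]) >= threshold) { hit <- k; break }
    }
    if (hit == 0L) { reps <- c(reps, seqs[[i]]); hit <- length(reps) }
    assign[i] <- hit
  }
  setNames(assign, names(seqs))
}

# Exhaustive enumeration of all pseudoknot-free structures (as lists of
# pairs) with hairpin loops of >= 3 unpaired bases.
oracle_enumerate_structures <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pairable <- function(i, j) {
    !is.na(c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1,
             UG = -1)[paste0(s[i], s[j])]) && (j - i - 1L) >= 3L
  }
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- lapply(rec(i + 1L, j), identity)  # i unpaired
    for (k in seq.int(i + 1L, j)) {
      if (!pairable(i, k)) next
      left <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (ls in left) for (rs in right)
        out[[length(out) + 1L]] <- c(list(c(i, k)), ls, rs)
    }
    out
  }
  rec(1L, length(s))
}

oracle_structure_energy <- function(seq, pairs) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  en <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  sum(vapply(pairs, function(p) en[[paste0(s[p[1L]], s[p[2L]])]], 0))
}

oracle_mfe <- function(seq) {
  structs <- oracle_enumerate_structures(seq)
  min(vapply(structs, function(p) oracle_structure_energy(seq, p), 0))
}

oracle_ensemble <- function(seq, temperature = 310) {
  kT <- 0.0019872 * temperature
  structs <- oracle_enumerate_structures(seq)
  Z <- sum(vapply(structs, function(p)
    exp(-oracle_structure_energy(seq, p) / kT), 0))
  -kT * log(Z)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

random_protein <- function(n) paste(sample(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE), collapse = "")

# Brute-force cross-chain contact count.
oracle_contacts <- function(xyz, chain_tag, cutoff = 4.5) {
  count <- 0L
  for (i in seq_len(nrow(xyz) - 1L))
    for (j in seq.int(i + 1L, nrow(xyz))) {
      if (chain_tag[i] == chain_tag[j]) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) count <- count + 1L
    }
  count
}

# Brute-force hydrogen-bond count mirroring the stated geometric criteria.
oracle_hbonds <- function(xyz, atoms) {
  ang <- function(v1, v2) {
    c <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    acos(min(max(c, -1), 1)) * 180 / pi
  }
  heavy <- which(atoms$element %in% c("N", "O"))
  count <- 0L
  for (d in heavy) for (a in heavy) {
    if (atoms$chain_tag[d] == atoms$chain_tag[a]) next
    if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) > 4.5) next
    hs <- which(atoms$element == "H" &
                  atoms$chain_tag == atoms$chain_tag[d])
    hs <- hs[vapply(hs, function(h)
      sqrt(sum((xyz[h, ] - xyz[d, ])^2)) <= 1.2, TRUE)]
    ok <- any(vapply(hs, function(h)
      ang(xyz[d, ] - xyz[h, ], xyz[a, ] - xyz[h, ]) >= 150, TRUE))
    if (ok) count <- count + 1L
  }
  count
}

softmax_vec_test <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# A tiny trained-free model whose step distributions are arbitrary but fixed.
tiny_model <- function(vocab_size = 8L, seed = 123L) {
  cfg <- model_config(n_layers = 1L, n_heads = 2L, d_model = 8L, d_ff = 16L,
                      vocab_size = vocab_size, max_len = 32L, seed = seed)
  build_model(cfg)
}
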