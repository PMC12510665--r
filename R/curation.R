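#' Filter interaction records by sequence length
#'
#' A record is kept only when BOTH its protein and its RNA length fall inside
#' `[min_len, max_len]` (bounds inclusive). The defaults are the corpus
#' filter used throughout the pipeline.
#'
#' @param records List of [interaction_record()] objects.
#' @param min_len,max_len Inclusive length bounds (defaults 10 and 1024).
#' @return The surviving records, in input order.
#' @export
filter_by_length <- function(records, min_len = 10L, max_len = 1024L) {
  keep <- vapply(records, function(r) {
    lp <- nchar(r$protein$seq); lr <- nchar(r$rna$seq)
    lp >= min_len && lp <= max_len && lr >= min_len && lr <= max_len
  }, TRUE)
  records[keep]
}

#' Global-alignment sequence identity
#'
#' Identity between two sequences is the number of matched positions in an
#' optimal global alignment (match 1, mismatch 0, gaps contribute 0 matches)
#' divided by the length of the shorter sequence (CD-HIT convention).
#'
#' @param a,b Sequence strings over a common character set.
#' @return Identity fraction in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  if (a == b) return(1)
  chars <- unique(strsplit(paste0(a, b), "", fixed = TRUE)[[1L]])
  mat <- diag(1, length(chars))
  dimnames(mat) <- list(chars, chars)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: sequences are processed longest-first (ties
#' broken by lexicographic id); each sequence joins the first existing
#' cluster whose representative has identity at least `identity_threshold`
#' with it, otherwise it founds a new cluster with itself as representative.
#'
#' @param seqs Named character vector of sequences (names are member ids).
#' @param identity_threshold Identity threshold in (0, 1].
#' @return data.frame with columns `member_id`, `cluster_id`,
#'   `is_representative`, `identity_to_representative`.
#' @export
greedy_cluster <- function(seqs, identity_threshold) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (length(seqs) == 0L)
    return(data.frame(member_id = character(), cluster_id = integer(),
                      is_representative = logical(),
                      identity_to_representative = numeric()))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("seqs must be a named character vector")
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  rep_seq <- character()
  out <- data.frame(member_id = names(seqs), cluster_id = NA_integer_,
                    is_representative = FALSE,
                    identity_to_representative = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    for (k in seq_along(rep_seq)) {
      idn <- seq_identity(seqs[[i]], rep_seq[[k]])
      if (idn >= identity_threshold) {
        out$cluster_id[i] <- k
        out$identity_to_representative[i] <- idn
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_seq <- c(rep_seq, seqs[[i]])
      k <- length(rep_seq)
      out$cluster_id[i] <- k
      out$is_representative[i] <- TRUE
      out$identity_to_representative[i] <- 1
    }
  }
  out
}

#' Assign complex-cluster ids to interaction records
#'
#' A complex cluster groups interactions that share the same protein cluster
#' and the same RNA cluster. The id is a stable integer key of the pair
#' (protein_cluster_id, rna_cluster_id), numbered in record order of first
#' appearance.
#'
#' @param records List of [interaction_record()] objects.
#' @param protein_clusters,rna_clusters Cluster assignments as returned by
#'   [greedy_cluster()] over the protein and RNA members.
#' @return The records with `complex_cluster_id` set.
#' @export
assign_complex_clusters <- function(records, protein_clusters, rna_clusters) {
  pmap <- setNames(protein_clusters$cluster_id, protein_clusters$member_id)
  rmap <- setNames(rna_clusters$cluster_id, rna_clusters$member_id)
  keys <- vapply(records, function(r) {
    pc <- pmap[r$protein$id]; rc <- rmap[r$rna$id]
    if (is.na(pc)) stop("protein '", r$protein$id, "' has no cluster")
    if (is.na(rc)) stop("rna '", r$rna$id, "' has no cluster")
    paste(pc, rc, sep = ":")
  }, "")
  ids <- match(keys, unique(keys))
  for (i in seq_along(records)) records[[i]]$complex_cluster_id <- ids[i]
  records
}

#' Inverse complex-cluster-size weighting
#'
#' Each interaction receives weight 1 / (size of its complex cluster), so a
#' cluster of 10 interactions gives each member weight 0.1 and a cluster of
#' 2 gives each member weight 0.5. The weights of a cluster's members sum to
#' exactly 1, giving every complex cluster equal total sampling mass.
#'
#' @param records List of [interaction_record()] objects with
#'   `complex_cluster_id` set (see [assign_complex_clusters()]).
#' @return A list of class `weighted_corpus` with fields `records` (weights
#'   set) and `cluster_sizes` (named integer vector keyed by cluster id).
#' @export
compute_weights <- function(records) {
  ids <- vapply(records, function(r) r$complex_cluster_id, 0L)
  if (anyNA(ids)) stop("complex_cluster_id must be set on all records")
  sizes <- table(ids)
  for (i in seq_along(records))
    records[[i]]$weight <- 1 / as.integer(sizes[as.character(ids[i])])
  structure(list(records = records,
                 cluster_sizes = setNames(as.integer(sizes), names(sizes))),
            class = "weighted_corpus")
}

#' Weighted up-sampling of a corpus
#'
#' Draws `n` records with replacement with probability proportional to the
#' inverse-cluster-size weights, so each complex cluster contributes the
#' same expected number of draws. Deterministic for a fixed seed.
#'
#' @param corpus A `weighted_corpus` from [compute_weights()].
#' @param n Number of draws (>= 1); the target corpus size is caller-chosen.
#' @param seed Integer RNG seed.
#' @return List of `n` interaction records.
#' @export
weighted_sample <- function(corpus, n, seed = 1L) {
  stopifnot(inherits(corpus, "weighted_corpus"), n >= 1L)
  w <- vapply(corpus$records, function(r) r$weight, 0)
  if (all(w == 0)) stop("all weights are zero")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  corpus$records[idx]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Derive a reproducible child seed from a master seed
#'
#' Used wherever the package needs several independent RNG streams from one
#' user-facing seed (per-fixture generators, per-draw sampling). The result
#' stays below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param i Non-negative stream counter.
#' @return Integer seed.
#' @export
child_seed <- function(master, i) {
  as.integer((as.double(master) * 69069 + as.double(i) * 1234567 + 1) %%
               2147483647)
}
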