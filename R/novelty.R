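# Novelty classification of designed RNAs against known binders: seeded
# Smith-Waterman local alignment with Karlin-Altschul E-values, applied with
# a fixed conjunction of thresholds; plus the stability metric suite.

NOVELTY_THRESHOLDS <- list(identity = 0.70, alignment_length = 15L,
                           coverage = 0.50, e_value = 0.1)
ALIGN_SCORING <- list(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2)
KA_K <- 0.3

#' Seed word size for local alignment
#'
#' Short sequences (length <= 50 nt) use word size 4; long ones use 7. The
#' boundary length 50 belongs to the short group.
#'
#' @param seq RNA sequence string (or its length as an integer).
#' @return Integer word size (4 or 7).
#' @export
choose_word_size <- function(seq) {
  len <- if (is.character(seq)) nchar(seq) else as.integer(seq)
  ifelse(len <= 50L, 4L, 7L)
}

karlin_lambda <- function(scoring = ALIGN_SCORING) {
  key <- paste(scoring$match, scoring$mismatch)
  cache <- getOption("prot2rna.lambda_cache", list())
  if (!is.null(cache[[key]])) return(cache[[key]])
  # uniform base composition: 4 matching pairs, 12 mismatching, each p=1/16
  f <- function(l) 0.25 * exp(l * scoring$match) +
    0.75 * exp(l * scoring$mismatch) - 1
  lam <- uniroot(f, c(1e-8, 10))$root
  cache[[key]] <- lam
  options(prot2rna.lambda_cache = cache)
  lam
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with K fixed at 0.3 and lambda solved
#' from the scoring system under uniform base composition. Absolute values
#' are approximate; the novelty thresholds are what matters and they are
#' configurable.
#'
#' @param score Raw alignment score.
#' @param m,n Query and subject lengths.
#' @param scoring Scoring list (match, mismatch, gap_open, gap_extend).
#' @return E-value (>= 0), strictly decreasing in `score` and strictly
#'   increasing in `m * n`.
#' @export
alignment_evalue <- function(score, m, n, scoring = ALIGN_SCORING) {
  KA_K * m * n * exp(-karlin_lambda(scoring) * score)
}

has_seed <- function(query, subject, word_size) {
  lq <- nchar(query)
  if (lq < word_size || nchar(subject) < word_size) return(FALSE)
  starts <- seq_len(lq - word_size + 1L)
  words <- unique(substring(query, starts, starts + word_size - 1L))
  any(vapply(words, function(w) grepl(w, subject, fixed = TRUE), TRUE))
}

smith_waterman <- function(query, subject, scoring = ALIGN_SCORING) {
  a <- strsplit(query, "", fixed = TRUE)[[1L]]
  b <- strsplit(subject, "", fixed = TRUE)[[1L]]
  n <- length(a); m <- length(b)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  NEG <- -1e9
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)  # subject residue against a query gap
  F <- matrix(NEG, n + 1L, m + 1L)  # query residue against a subject gap
  tbH <- matrix(0L, n + 1L, m + 1L)  # 0 stop, 1 diagonal, 2 E, 3 F
  tbE <- matrix(0L, n + 1L, m + 1L)  # 1 opened from H, 0 extended
  tbF <- matrix(0L, n + 1L, m + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      openE <- H[i + 1L, j] - go - ge
      extE <- E[i + 1L, j] - ge
      E[i + 1L, j + 1L] <- max(openE, extE)
      tbE[i + 1L, j + 1L] <- as.integer(openE >= extE)
      openF <- H[i, j + 1L] - go - ge
      extF <- F[i, j + 1L] - ge
      F[i + 1L, j + 1L] <- max(openF, extF)
      tbF[i + 1L, j + 1L] <- as.integer(openF >= extF)
      diag <- H[i, j] + if (a[i] == b[j]) scoring$match else scoring$mismatch
      h <- max(0, diag, E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      tbH[i + 1L, j + 1L] <- if (h == 0) 0L else if (h == diag) 1L else
        if (h == E[i + 1L, j + 1L]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)
  i <- bi; j <- bj
  matches <- 0L; columns <- 0L
  state <- "H"
  repeat {
    if (state == "H") {
      dir <- tbH[i + 1L, j + 1L]
      if (dir == 0L) break
      if (dir == 1L) {
        columns <- columns + 1L
        if (a[i] == b[j]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else state <- if (dir == 2L) "E" else "F"
    } else if (state == "E") {
      columns <- columns + 1L
      from_h <- tbE[i + 1L, j + 1L] == 1L
      j <- j - 1L
      if (from_h) state <- "H"
    } else {
      columns <- columns + 1L
      from_h <- tbF[i + 1L, j + 1L] == 1L
      i <- i - 1L
      if (from_h) state <- "H"
    }
  }
  list(score = best, matches = matches, alignment_length = columns)
}

#' Best seeded local alignment between a designed RNA and a known binder
#'
#' An exact shared word of the seed size is required to trigger alignment at
#' all (mirroring word-seeded search); when a seed exists, the optimal local
#' alignment is computed by full Smith-Waterman dynamic programming with
#' affine gaps (match +2, mismatch -3, gap open -5, gap extend -2 by
#' default). Identity is matches / alignment_length; coverage is
#' alignment_length / query length.
#'
#' @param query,subject RNA sequence strings.
#' @param scoring Scoring list (see [alignment_evalue()]).
#' @param word_size Seed word size; defaults to [choose_word_size()] on the
#'   query.
#' @return A list of class `alignment_hit` (see [alignment_hit()]), or
#'   `NULL` when no seed word is shared.
#' @export
local_align <- function(query, subject, scoring = ALIGN_SCORING,
                        word_size = NULL) {
  if (is.null(word_size)) word_size <- choose_word_size(query)
  if (!has_seed(query, subject, word_size)) return(NULL)
  sw <- smith_waterman(query, subject, scoring)
  if (is.null(sw)) return(NULL)
  alignment_hit(score = sw$score,
                identity = sw$matches / sw$alignment_length,
                alignment_length = sw$alignment_length,
                coverage = sw$alignment_length / nchar(query),
                e_value = alignment_evalue(sw$score, nchar(query),
                                           nchar(subject), scoring))
}

#' Construct an alignment hit record
#'
#' @param score Raw local alignment score.
#' @param identity Fraction of matched columns in \[0, 1\].
#' @param alignment_length Number of alignment columns (bp).
#' @param coverage Alignment length / query length.
#' @param e_value Karlin-Altschul E-value (>= 0).
#' @param query_id,subject_id Optional identifiers.
#' @return A list of class `alignment_hit`.
#' @export
alignment_hit <- function(score, identity, alignment_length, coverage,
                          e_value, query_id = NA_character_,
                          subject_id = NA_character_) {
  stopifnot(identity >= 0, identity <= 1, e_value >= 0)
  structure(list(query_id = query_id, subject_id = subject_id,
                 score = score, identity = identity,
                 alignment_length = as.integer(alignment_length),
                 coverage = coverage, e_value = e_value),
            class = "alignment_hit")
}

#' Does a hit pass the similar-to-known thresholds?
#'
#' The verdict is a pure conjunction: a hit marks a candidate as similar to
#' known only if identity >= 70% AND alignment length >= 15 bp AND query
#' coverage >= 50% AND E-value <= 0.1. Crossing any single boundary flips
#' the outcome.
#'
#' @param hit An `alignment_hit` (or `NULL`, which fails).
#' @param thresholds Named list overriding `identity`, `alignment_length`,
#'   `coverage`, `e_value`.
#' @return Logical.
#' @export
passes_novelty_thresholds <- function(hit, thresholds = NOVELTY_THRESHOLDS) {
  if (is.null(hit)) return(FALSE)
  th <- utils::modifyList(NOVELTY_THRESHOLDS, as.list(thresholds))
  hit$identity >= th$identity &&
    hit$alignment_length >= th$alignment_length &&
    hit$coverage >= th$coverage &&
    hit$e_value <= th$e_value
}

#' Classify a candidate as novel or similar to known
#'
#' Aligns the candidate against every known binder (seeded local alignment)
#' and applies [passes_novelty_thresholds()]; the candidate is
#' `similar_to_known` iff some hit passes all four criteria, else `novel`.
#' An empty database yields `novel` with no best hit.
#'
#' @param candidate RNA sequence string.
#' @param known_db Character vector (optionally named) of known binder RNAs.
#' @param thresholds See [passes_novelty_thresholds()].
#' @return List of class `novelty_verdict`: `label` (`"novel"` or
#'   `"similar_to_known"`) and `best_hit` (highest-scoring hit or `NULL`).
#' @export
classify_novelty <- function(candidate, known_db,
                             thresholds = NOVELTY_THRESHOLDS) {
  best <- NULL
  similar <- FALSE
  for (k in seq_along(known_db)) {
    hit <- local_align(candidate, known_db[[k]])
    if (is.null(hit)) next
    hit$subject_id <- if (!is.null(names(known_db))) names(known_db)[k]
                      else as.character(k)
    if (is.null(best) || hit$score > best$score) best <- hit
    if (passes_novelty_thresholds(hit, thresholds)) similar <- TRUE
  }
  structure(list(label = if (similar) "similar_to_known" else "novel",
                 best_hit = best),
            class = "novelty_verdict")
}

#' Fraction of novel candidates in a pool
#'
#' @param pool Character vector of candidate RNA sequences.
#' @param known_db Character vector of known binder RNAs.
#' @param thresholds See [passes_novelty_thresholds()].
#' @return Fraction in \[0, 1\].
#' @export
novelty_rate <- function(pool, known_db, thresholds = NOVELTY_THRESHOLDS) {
  if (length(pool) == 0L) stop("cannot compute a novelty rate on an empty pool")
  labels <- vapply(pool, function(s)
    classify_novelty(s, known_db, thresholds)$label, "")
  mean(labels == "novel")
}

#' GC content of a sequence
#' @param seq Non-empty sequence string.
#' @return (#G + #C) / length.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mean(chars %in% c("G", "C"))
}

#' Ensemble free energy of an RNA
#'
#' `-kT ln Z` over the Boltzmann ensemble of all pseudoknot-free secondary
#' structures under the same simplified pair-energy model and hairpin rule
#' as [fold_mfe()] (builtin engine), computed by partition-function dynamic
#' programming at T = 310 K by default. Always at most the MFE (the
#' ensemble is at least as favorable as its best structure). The `"vienna"`
#' engine delegates to `RNAfold -p`.
#'
#' @param seq RNA sequence string.
#' @param engine `"builtin"` or `"vienna"`.
#' @param temperature Temperature in Kelvin (builtin engine).
#' @return Free energy in kcal/mol.
#' @export
ensemble_free_energy <- function(seq, engine = c("builtin", "vienna"),
                                 temperature = 310) {
  engine <- match.arg(engine)
  if (!nzchar(seq)) stop("cannot fold an empty sequence")
  if (engine == "vienna") return(ensemble_vienna(seq))
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(s %in% RNA_ALPHABET)) stop("sequence is not RNA (A/C/G/U)")
  n <- length(s)
  kT <- BOLTZMANN_KCAL * temperature
  if (n < 2L) return(0)
  Z <- matrix(1, n + 1L, n)  # Z[i, j]: subsequence i..j; row n+1 pads i=j+1
  zat <- function(i, j) if (i > j) 1 else Z[i, j]
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      total <- zat(i + 1L, j)
      if (j >= i + MIN_HAIRPIN + 1L) {
        for (k in (i + MIN_HAIRPIN + 1L):j) {
          e <- pair_energy(s[i], s[k])
          if (is.na(e)) next
          total <- total + exp(-e / kT) * zat(i + 1L, k - 1L) * zat(k + 1L, j)
        }
      }
      Z[i, j] <- total
    }
  }
  -kT * log(Z[1L, n])
}

ensemble_vienna <- function(seq) {
  out <- tryCatch(
    system2("RNAfold", args = c("-p", "--noPS", "--noDP"), input = seq,
            stdout = TRUE),
    error = function(e) stop("RNAfold is not available: ",
                             conditionMessage(e)))
  # the ensemble free energy is printed in square brackets
  line <- grep("\\[\\s*-?[0-9.]+\\s*\\]", out, value = TRUE)
  if (!length(line)) stop("could not parse RNAfold -p output")
  as.numeric(sub(".*\\[\\s*(-?[0-9.]+)\\s*\\].*", "\\1", line[1L]))
}

#' Stability summary of a candidate pool
#'
#' Per sequence: MFE, length-normalized MFE (MFE/length; distinct from the
#' pool-relative min-max `mfe_norm` of [score_pool()]), ensemble free
#' energy, GC content and length; plus weighted distribution summaries
#' (median and IQR, weighting each sequence by its occurrence count).
#'
#' @param pool Character vector of RNA sequences, or a data.frame with
#'   columns `seq` and optionally `count`.
#' @param engine Folding engine.
#' @param temperature Temperature (K) for the ensemble free energy.
#' @return List with `table` (per-sequence data.frame) and `summary`
#'   (data.frame of median and IQR per metric).
#' @export
summarize_pool <- function(pool, engine = "builtin", temperature = 310) {
  if (is.character(pool)) pool <- data.frame(seq = pool, count = 1L,
                                             stringsAsFactors = FALSE)
  if (is.null(pool$count)) pool$count <- 1L
  stopifnot(nrow(pool) >= 1L)
  tab <- data.frame(
    seq = pool$seq,
    count = pool$count,
    length = nchar(pool$seq),
    mfe = vapply(pool$seq, function(s) fold_mfe(s, engine)$energy, 0),
    dg_ensemble = vapply(pool$seq, ensemble_free_energy, 0, engine = engine,
                         temperature = temperature),
    gc = vapply(pool$seq, gc_content, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$mfe_per_length <- tab$mfe / tab$length
  wq <- function(x, w, probs) {
    ord <- order(x)
    x <- x[ord]; w <- w[ord]
    cw <- cumsum(w) / sum(w)
    vapply(probs, function(p) x[which(cw >= p)[1L]], 0)
  }
  metrics <- c("length", "mfe", "mfe_per_length", "dg_ensemble", "gc")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    q <- wq(tab[[m]], tab$count, c(0.25, 0.5, 0.75))
    data.frame(metric = m, median = q[2L], iqr = q[3L] - q[1L])
  }))
  list(table = tab, summary = summ)
}
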