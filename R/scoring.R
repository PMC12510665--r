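# Candidate scoring: secondary-structure thermodynamics under a simplified
# pair-energy model (exactly testable by exhaustive enumeration), pool-level
# normalizations, and a pluggable binding scorer.

PAIR_ENERGIES <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
MIN_HAIRPIN <- 3L
BOLTZMANN_KCAL <- 0.0019872  # kcal / (mol K)

pair_energy <- function(a, b) {
  e <- PAIR_ENERGIES[paste0(a, b)]
  ifelse(is.na(e), NA_real_, e)
}

#' Fold an RNA into its minimum free energy structure
#'
#' The builtin engine minimizes the sum of base-pair energies (GC = -3,
#' AU = -2, GU = -1 kcal/mol) over all pseudoknot-free nested structures
#' with hairpin loops of at least 3 unpaired bases, by Nussinov-style
#' dynamic programming with traceback. The `"vienna"` engine delegates to a
#' full thermodynamic folding tool (`RNAfold`) conforming to the same
#' sequence-in, structure-plus-energy-out contract.
#'
#' @param seq RNA sequence string (A/C/G/U).
#' @param engine `"builtin"` (default) or `"vienna"`.
#' @return List of class `folding_result`: `structure` (dot-bracket),
#'   `energy` (kcal/mol), `engine`.
#' @export
fold_mfe <- function(seq, engine = c("builtin", "vienna")) {
  engine <- match.arg(engine)
  if (!nzchar(seq)) stop("cannot fold an empty sequence")
  if (engine == "vienna") return(fold_vienna(seq))
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(s %in% RNA_ALPHABET)) stop("sequence is not RNA (A/C/G/U)")
  n <- length(s)
  W <- matrix(0, n, n)
  pair_opts <- function(i, j) {
    # candidate partners k for position i within [i, j], hairpin rule applied
    if (j < i + MIN_HAIRPIN + 1L) return(integer())
    (i + MIN_HAIRPIN + 1L):j
  }
  for (span in seq_len(max(n - 1L, 0L))) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- W[i + 1L, j]
      for (k in pair_opts(i, j)) {
        e <- pair_energy(s[i], s[k])
        if (is.na(e)) next
        inner <- if (k - 1L >= i + 1L) W[i + 1L, k - 1L] else 0
        rest <- if (k + 1L <= j) W[k + 1L, j] else 0
        cand <- e + inner + rest
        if (cand < best) best <- cand
      }
      W[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      # tie-break: leave i unpaired whenever that attains the optimum
      if (abs(W[i, j] - W[i + 1L, j]) < 1e-9) {
        i <- i + 1L
        next
      }
      advanced <- FALSE
      for (k in pair_opts(i, j)) {
        e <- pair_energy(s[i], s[k])
        if (is.na(e)) next
        inner <- if (k - 1L >= i + 1L) W[i + 1L, k - 1L] else 0
        rest <- if (k + 1L <= j) W[k + 1L, j] else 0
        if (abs(W[i, j] - (e + inner + rest)) < 1e-9) {
          db[i] <<- "("; db[k] <<- ")"
          if (k - 1L >= i + 1L) trace(i + 1L, k - 1L)
          i <- k + 1L
          advanced <- TRUE
          break
        }
      }
      if (!advanced) i <- i + 1L
    }
  }
  if (n >= 2L) trace(1L, n)
  structure(list(structure = paste(db, collapse = ""),
                 energy = if (n >= 2L) W[1L, n] else 0,
                 engine = "builtin"),
            class = "folding_result")
}

fold_vienna <- function(seq) {
  out <- tryCatch(
    system2("RNAfold", args = "--noPS", input = seq, stdout = TRUE),
    error = function(e) stop("RNAfold is not available: ",
                             conditionMessage(e)))
  line <- out[2L]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1L]]
  if (length(m) != 3L) stop("could not parse RNAfold output: ", line)
  structure(list(structure = m[2L], energy = as.numeric(m[3L]),
                 engine = "vienna"),
            class = "folding_result")
}

#' Min-max normalized MFE over a candidate pool
#'
#' `MFE_norm = 1 - (MFE - min) / (max - min)`: the pool minimum (most
#' stable) maps to 1, the maximum to 0. A degenerate pool in which all
#' values coincide maps to all 1 (every member attains the pool minimum).
#' Adding a constant to every MFE leaves the output unchanged.
#'
#' @param pool_mfes Numeric vector of MFE values (>= 1 value).
#' @return Vector of normalized values in \[0, 1\].
#' @export
normalize_mfe <- function(pool_mfes) {
  stopifnot(length(pool_mfes) >= 1L)
  lo <- min(pool_mfes); hi <- max(pool_mfes)
  if (hi - lo < 1e-12) return(rep(1, length(pool_mfes)))
  1 - (pool_mfes - lo) / (hi - lo)
}

#' Consistency scores from occurrence counts
#'
#' A candidate's occurrence count across sampling runs divided by the
#' maximum count observed in the pool (`C_norm = C / max(C)`).
#'
#' @param counts Positive integer occurrence counts.
#' @return Values in (0, 1\], order-preserving.
#' @export
consistency_scores <- function(counts) {
  stopifnot(length(counts) >= 1L, all(counts >= 1L))
  counts / max(counts)
}

.scorer_registry <- new.env(parent = emptyenv())

#' Register a binding scorer plug-in
#'
#' Binding-affinity prediction is an external concern; the pipeline only
#' requires a function mapping an RNA sequence to a self-normalized score in
#' \[0, 1\]. Scorers are registered by name and retrieved at scoring time.
#'
#' @param name Scorer name.
#' @param fn Function `function(seq) -> numeric in [0, 1]`.
#' @export
register_binding_scorer <- function(name, fn) {
  stopifnot(is.function(fn))
  assign(name, fn, envir = .scorer_registry)
  invisible(name)
}

#' Retrieve a registered binding scorer
#' @param name Scorer name.
#' @return The scorer function.
#' @export
binding_scorer <- function(name) {
  if (!exists(name, envir = .scorer_registry, inherits = FALSE))
    stop("unknown binding scorer: '", name, "'")
  get(name, envir = .scorer_registry)
}

#' Toy motif binding scorer
#'
#' Returns (number of occurrences of the configured RNA motif words in the
#' sequence) / `max_occurrences`, clipped to \[0, 1\]. Occurrences of
#' different words are summed; overlapping occurrences of one word count
#' once per start position. Useful with synthetic planted-motif corpora and
#' as the reference implementation of the scorer contract.
#'
#' @param motifs Character vector of RNA motif words.
#' @param max_occurrences Denominator (maximum creditable occurrences).
#' @return A scorer function suitable for [register_binding_scorer()].
#' @export
toy_motif_scorer <- function(motifs, max_occurrences = 1L) {
  stopifnot(length(motifs) >= 1L, max_occurrences >= 1L)
  function(seq) {
    if (!nzchar(seq)) return(0)
    hits <- sum(vapply(motifs, function(m) {
      g <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1L]]
      if (g[1L] == -1L) 0L else length(g)
    }, 0L))
    min(1, hits / max_occurrences)
  }
}

#' Score a sequence with a registered binding scorer
#' @param seq RNA sequence string.
#' @param scorer Scorer name (see [register_binding_scorer()]).
#' @return Score in \[0, 1\].
#' @export
score_binding <- function(seq, scorer) {
  fn <- binding_scorer(scorer)
  val <- fn(seq)
  if (!is.numeric(val) || val < -1e-9 || val > 1 + 1e-9)
    stop("scorer '", scorer, "' returned a value outside [0, 1]")
  min(max(val, 0), 1)
}

#' Score a candidate pool
#'
#' Computes, per candidate: MFE and dot-bracket structure (builtin engine by
#' default), pool-normalized MFE, consistency, and (optionally) a binding
#' score from a registered scorer.
#'
#' @param pool A `candidate_pool` from [generate_pool()], or a data.frame
#'   with columns `seq` and `count`. Empty sequences (immediate-EOS draws
#'   from an undertrained model) are dropped before scoring.
#' @param scorer Optional scorer name; `NULL` skips the binding component.
#' @param engine Folding engine for [fold_mfe()].
#' @return data.frame with columns `seq`, `count`, `structure`, `mfe`,
#'   `mfe_norm`, `consistency_norm` and (if scored) `binding_score`.
#' @export
score_pool <- function(pool, scorer = NULL, engine = "builtin") {
  pool <- pool[nzchar(pool$seq), , drop = FALSE]
  if (nrow(pool) == 0L) stop("no non-empty candidates to score")
  folds <- lapply(pool$seq, fold_mfe, engine = engine)
  out <- data.frame(
    seq = pool$seq,
    count = pool$count,
    structure = vapply(folds, `[[`, "", "structure"),
    mfe = vapply(folds, `[[`, 0, "energy"),
    stringsAsFactors = FALSE)
  out$mfe_norm <- normalize_mfe(out$mfe)
  out$consistency_norm <- consistency_scores(out$count)
  if (!is.null(scorer))
    out$binding_score <- vapply(out$seq, score_binding, 0, scorer = scorer)
  out
}

#' Composite ranking of scored candidates
#'
#' The composite score is a weighted mean of the available normalized
#' components (`mfe_norm`, `consistency_norm`, `binding_score`), equal
#' weights by default; when a component is absent the mean is taken over
#' the remaining ones. Candidates are sorted by descending composite,
#' ties broken by lexicographic sequence order.
#'
#' @param scored data.frame from [score_pool()].
#' @param weights Optional named numeric weights per component.
#' @return The data.frame with a `composite` column, ranked.
#' @export
composite_rank <- function(scored, weights = NULL) {
  comps <- intersect(c("mfe_norm", "consistency_norm", "binding_score"),
                     names(scored))
  if (length(comps) == 0L) stop("no score components present")
  if (is.null(weights)) weights <- setNames(rep(1, length(comps)), comps)
  weights <- weights[comps]
  if (anyNA(weights)) stop("weights must cover all present components")
  mat <- as.matrix(scored[comps])
  scored$composite <- as.vector(mat %*% weights) / sum(weights)
  scored[order(-scored$composite, scored$seq), , drop = FALSE]
}
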