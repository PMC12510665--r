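#' Sampling specification for RNA generation
#'
#' @param strategy One of `"greedy"`, `"beam"`, `"top_k"`, `"nucleus"`.
#' @param k Top-k truncation (required for `top_k`).
#' @param p Cumulative-probability threshold in (0, 1\] (required for
#'   `nucleus`).
#' @param temperature Positive temperature; logits are divided by it before
#'   any truncation. Default 1.
#' @param beam_size Beam width B (required for `beam`).
#' @param max_new_tokens Cap on generated tokens (default 64).
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(strategy = c("greedy", "beam", "top_k", "nucleus"),
                          k = NULL, p = NULL, temperature = 1,
                          beam_size = NULL, max_new_tokens = 64L) {
  strategy <- match.arg(strategy)
  if (temperature <= 0) stop("temperature must be positive")
  if (strategy == "top_k" && (is.null(k) || k < 1L))
    stop("top_k sampling requires k >= 1")
  if (strategy == "nucleus" && (is.null(p) || p <= 0 || p > 1))
    stop("nucleus sampling requires p in (0, 1]")
  if (strategy == "beam" && (is.null(beam_size) || beam_size < 1L))
    stop("beam search requires beam_size >= 1")
  structure(list(strategy = strategy, k = k, p = p,
                 temperature = temperature, beam_size = beam_size,
                 max_new_tokens = as.integer(max_new_tokens)),
            class = "sampling_spec")
}

#' The setting used for all production generation runs
#'
#' Top-k sampling with k = 30 and temperature 1.5, the combination that
#' scored highest across strategies in the model-selection sweep.
#'
#' @param max_new_tokens Cap on generated tokens.
#' @return A `sampling_spec`.
#' @export
default_sampling_spec <- function(max_new_tokens = 64L)
  sampling_spec("top_k", k = 30L, temperature = 1.5,
                max_new_tokens = max_new_tokens)

#' Nucleus (top-p) filtering of a distribution
#'
#' Keeps the smallest prefix of probability-sorted tokens whose cumulative
#' mass reaches `p` (ties broken by token id) and renormalizes; all other
#' tokens get probability zero. `p = 1` is the identity.
#'
#' @param dist Probability vector.
#' @param p Threshold in (0, 1\].
#' @return Renormalized probability vector of the same length.
#' @export
nucleus_filter <- function(dist, p) {
  stopifnot(p > 0, p <= 1)
  ord <- order(-dist, seq_along(dist))
  cum <- cumsum(dist[ord])
  keep_n <- which(cum >= p - 1e-12)[1L]
  if (is.na(keep_n)) keep_n <- length(dist)
  out <- numeric(length(dist))
  kept <- ord[seq_len(keep_n)]
  out[kept] <- dist[kept] / sum(dist[kept])
  out
}

#' Top-k filtering of a distribution
#'
#' Zeroes all but the k most probable tokens (ties broken by token id) and
#' renormalizes.
#'
#' @param dist Probability vector.
#' @param k Number of tokens to keep.
#' @return Renormalized probability vector.
#' @export
top_k_filter <- function(dist, k) {
  stopifnot(k >= 1L)
  if (k >= length(dist)) return(dist / sum(dist))
  ord <- order(-dist, seq_along(dist))
  out <- numeric(length(dist))
  kept <- ord[seq_len(k)]
  out[kept] <- dist[kept] / sum(dist[kept])
  out
}

step_distribution <- function(model, H, prefix_ids, spec) {
  sl <- step_logits(model, NULL, prefix_ids, H = H)
  logits <- sl$logits / spec$temperature
  dist <- softmax_vec(logits)
  if (spec$strategy == "top_k") dist <- top_k_filter(dist, spec$k)
  if (spec$strategy == "nucleus") dist <- nucleus_filter(dist, spec$p)
  dist
}

#' Sample one RNA sequence for a protein
#'
#' Tokens are drawn stepwise from the (temperature-scaled, truncated,
#' renormalized) next-token distribution until EOS or `max_new_tokens`.
#' Greedy decoding takes the argmax at each step (ties broken by lowest
#' token id); beam search delegates to [beam_search()]. Stochastic
#' strategies are deterministic for a fixed seed.
#'
#' @param model A trained `seq2seq_model`.
#' @param p_ids Protein token ids, or `NULL` when `H` is given.
#' @param spec A [sampling_spec()].
#' @param seed RNG seed (used by `top_k`/`nucleus`).
#' @param H Optional precomputed encoder output.
#' @return List with `ids` (generated 0-based token ids, EOS excluded),
#'   `log_prob` (sum of unmodified model log-probabilities along the path)
#'   and `ended` (TRUE when EOS was produced).
#' @export
sample_rna <- function(model, p_ids, spec = default_sampling_spec(),
                       seed = 1L, H = NULL) {
  stopifnot(inherits(spec, "sampling_spec"))
  if (spec$strategy == "beam")
    return(beam_search(model, p_ids, B = spec$beam_size,
                       max_new_tokens = spec$max_new_tokens, H = H))
  if (is.null(H)) H <- encode_protein(model, p_ids)
  eos <- SPECIAL_TOKENS[["EOS"]]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- integer()
  log_prob <- 0
  ended <- FALSE
  for (step in seq_len(spec$max_new_tokens)) {
    sl <- step_logits(model, NULL, ids, H = H)
    base <- softmax_vec(sl$logits)
    if (spec$strategy == "greedy") {
      nxt <- which.max(base) - 1L
    } else {
      dist <- softmax_vec(sl$logits / spec$temperature)
      if (spec$strategy == "top_k") dist <- top_k_filter(dist, spec$k)
      if (spec$strategy == "nucleus") dist <- nucleus_filter(dist, spec$p)
      nxt <- sample.int(length(dist), 1L, prob = dist) - 1L
    }
    log_prob <- log_prob + log(base[nxt + 1L])
    if (nxt == eos) { ended <- TRUE; break }
    ids <- c(ids, nxt)
  }
  list(ids = ids, log_prob = log_prob, ended = ended)
}

#' Beam search decoding
#'
#' Maintains `B` live hypotheses, expanding each with its top `B` next
#' tokens per step, and returns the completed sequence with the highest
#' total log-probability (sum of log-probs, no length normalization).
#' Ties are broken deterministically by token ids. `B = 1` is greedy.
#'
#' @param model A trained `seq2seq_model`.
#' @param p_ids Protein token ids, or `NULL` when `H` is given.
#' @param B Beam size (>= 1).
#' @param max_new_tokens Cap on generated tokens.
#' @param H Optional precomputed encoder output.
#' @return As [sample_rna()].
#' @export
beam_search <- function(model, p_ids, B, max_new_tokens = 64L, H = NULL) {
  stopifnot(B >= 1L)
  if (is.null(H)) H <- encode_protein(model, p_ids)
  eos <- SPECIAL_TOKENS[["EOS"]]
  beams <- list(list(ids = integer(), lp = 0))
  done <- list()
  for (step in seq_len(max_new_tokens)) {
    cand <- list()
    for (b in beams) {
      sl <- step_logits(model, NULL, b$ids, H = H)
      logp <- sl$logits - log(sum(exp(sl$logits - max(sl$logits)))) -
        max(sl$logits)
      ord <- order(-logp, seq_along(logp))
      for (tkn in ord[seq_len(min(B, length(ord)))]) {
        cand[[length(cand) + 1L]] <-
          list(ids = c(b$ids, tkn - 1L), lp = b$lp + logp[tkn])
      }
    }
    scores <- vapply(cand, `[[`, 0, "lp")
    keys <- vapply(cand, function(x) paste(x$ids, collapse = ","), "")
    ord <- order(-scores, keys)
    cand <- cand[ord[seq_len(min(B, length(cand)))]]
    beams <- list()
    for (cn in cand) {
      last <- cn$ids[length(cn$ids)]
      if (last == eos) {
        cn$ids <- cn$ids[-length(cn$ids)]
        done[[length(done) + 1L]] <- cn
      } else beams[[length(beams) + 1L]] <- cn
    }
    if (length(beams) == 0L) break
  }
  for (b in beams) done[[length(done) + 1L]] <- b  # ran out of budget
  scores <- vapply(done, `[[`, 0, "lp")
  keys <- vapply(done, function(x) paste(x$ids, collapse = ","), "")
  best <- done[[order(-scores, keys)[1L]]]
  list(ids = best$ids, log_prob = best$lp, ended = TRUE)
}

#' Generate a candidate pool across sampling strategies
#'
#' Draws `n_per_spec` sequences per spec (per-draw seeds are derived from
#' the master seed via a counter, so pools are reproducible), decodes them
#' to RNA strings and collapses duplicates while accumulating occurrence
#' counts across specs.
#'
#' @param model A trained `seq2seq_model`.
#' @param tok The `bpe_tokenizer` used to decode token ids.
#' @param p_ids Protein token ids.
#' @param specs List of [sampling_spec()] objects.
#' @param n_per_spec Draws per spec (scalar or vector matching `specs`).
#' @param seed Master seed.
#' @return A data.frame of class `candidate_pool` with columns `seq`,
#'   `count`, `strategies` (comma-joined tags) and attribute `n_draws`.
#' @export
generate_pool <- function(model, tok, p_ids, specs = list(default_sampling_spec()),
                          n_per_spec = 10L, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  n_per_spec <- rep_len(n_per_spec, length(specs))
  draws <- list()
  counter <- 0L
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    for (j in seq_len(n_per_spec[si])) {
      counter <- counter + 1L
      res <- sample_rna(model, p_ids, spec, seed = child_seed(seed, counter))
      seq <- bpe_decode(tok, res$ids)
      draws[[counter]] <- list(seq = seq, tag = spec$strategy)
    }
  }
  seqs <- vapply(draws, `[[`, "", "seq")
  tags <- vapply(draws, `[[`, "", "tag")
  uniq <- sort(unique(seqs))
  pool <- data.frame(
    seq = uniq,
    count = vapply(uniq, function(s) sum(seqs == s), 0L),
    strategies = vapply(uniq, function(s)
      paste(sort(unique(tags[seqs == s])), collapse = ","), ""),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(pool, "n_draws") <- sum(n_per_spec)
  class(pool) <- c("candidate_pool", "data.frame")
  pool
}
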