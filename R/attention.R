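# Cross-attention interpretability: token- and residue-level attention
# profiles and the domain attention ratio. Tensors are consumed as plain
# arrays indexed (layer, head, rna_position, protein_token), so the analysis
# is decoupled from any model runtime.

#' Validate and tag a cross-attention tensor
#'
#' @param weights 4-d array indexed (layer, head, rna_position,
#'   protein_token); each (layer, head, rna_position) slice must be a
#'   probability distribution over protein tokens.
#' @return The array with class `attention_tensor`.
#' @export
attention_tensor <- function(weights) {
  stopifnot(is.array(weights), length(dim(weights)) == 4L)
  if (any(weights < -1e-9)) stop("attention weights must be nonnegative")
  sums <- apply(weights, c(1L, 2L, 3L), sum)
  if (any(abs(sums - 1) > 1e-5))
    stop("attention rows must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  structure(weights, class = "attention_tensor")
}

#' Token-level attention profile
#'
#' Aggregation is max over RNA positions (per head), then mean over heads
#' (per layer), then mean over layers (global): each protein token's score
#' is the strongest attention it received from any RNA position, averaged
#' across heads and layers.
#'
#' @param tensor An [attention_tensor()].
#' @return List with `per_layer` (layers x tokens matrix) and `global`
#'   (numeric vector over tokens).
#' @export
token_profile <- function(tensor) {
  d <- dim(tensor)
  per_layer <- matrix(0, d[1L], d[4L])
  for (l in seq_len(d[1L])) {
    head_scores <- matrix(0, d[2L], d[4L])
    for (h in seq_len(d[2L]))
      head_scores[h, ] <- apply(tensor[l, h, , , drop = FALSE], 4L, max)
    per_layer[l, ] <- colMeans(head_scores)
  }
  list(per_layer = per_layer, global = colMeans(per_layer))
}

#' Distribute token attention scores over residues
#'
#' Each residue covered by a token's span receives `token_score /
#' span_width`; residues beyond the encoded prefix (e.g. truncated tails)
#' receive 0. Total score mass is conserved.
#'
#' @param token_scores Numeric vector, one score per protein token.
#' @param spans k x 2 matrix of 1-based inclusive residue intervals (from
#'   [token_residue_spans()]).
#' @param protein_len Total protein length in residues.
#' @return Numeric vector of per-residue scores (length `protein_len`).
#' @export
residue_profile <- function(token_scores, spans, protein_len) {
  if (length(token_scores) != nrow(spans))
    stop("token_scores length (", length(token_scores),
         ") does not match span count (", nrow(spans), ")")
  if (nrow(spans) && max(spans[, 2L]) > protein_len)
    stop("spans exceed the stated protein length")
  prof <- numeric(protein_len)
  for (k in seq_len(nrow(spans))) {
    i <- spans[k, 1L]:spans[k, 2L]
    prof[i] <- prof[i] + token_scores[k] / length(i)
  }
  prof
}

domain_mask <- function(domains, protein_len) {
  inside <- rep(FALSE, protein_len)
  for (k in seq_len(nrow(domains))) {
    s <- domains$start[k]; e <- domains$end[k]
    if (s < 1L || e > protein_len || s > e)
      stop("domain interval [", s, ", ", e, "] invalid for protein length ",
           protein_len)
    inside[s:e] <- TRUE
  }
  inside
}

#' Domain attention ratio
#'
#' Maximum residue-level attention inside annotated binding domains divided
#' by the maximum outside them; > 1 indicates domain-focused attention.
#'
#' @param profile Per-residue attention scores.
#' @param domains data.frame with `start`, `end` columns (1-based
#'   inclusive), e.g. from [read_domains()].
#' @return Positive ratio.
#' @export
attention_ratio <- function(profile, domains) {
  stopifnot(nrow(domains) >= 1L)
  inside <- domain_mask(domains, length(profile))
  if (all(inside)) stop("no residues outside the domains; ratio undefined")
  out_max <- max(profile[!inside])
  if (out_max <= 0) stop("maximum attention outside domains is 0; ",
                         "ratio undefined")
  max(profile[inside]) / out_max
}

#' Aggregate residue attention profiles over interaction samples
#'
#' Averages per-residue profiles across up to `sample_cap` samples for one
#' protein and retains the per-sample attention-ratio distribution; a
#' per-layer ratio matrix is computed when per-layer profiles are supplied.
#'
#' @param profiles List of per-residue profiles (equal lengths).
#' @param domains Domain annotation data.frame.
#' @param layer_profiles Optional list of layers x residues matrices
#'   aligned with `profiles`.
#' @param sample_cap Maximum number of samples used (default 1000).
#' @return List with `mean_profile`, `ratios` (one per sample),
#'   `mean_ratio`, `ratio_of_mean` (ratio of the averaged profile),
#'   `per_layer_ratios` (samples x layers matrix or NULL), `n_samples`.
#' @export
aggregate_attention <- function(profiles, domains, layer_profiles = NULL,
                                sample_cap = 1000L) {
  stopifnot(length(profiles) >= 1L)
  keep <- seq_len(min(length(profiles), sample_cap))
  profiles <- profiles[keep]
  lens <- vapply(profiles, length, 0L)
  if (length(unique(lens)) != 1L)
    stop("profiles have mixed protein lengths: ",
         paste(unique(lens), collapse = ", "))
  mean_profile <- Reduce(`+`, profiles) / length(profiles)
  ratios <- vapply(profiles, attention_ratio, 0, domains = domains)
  per_layer <- NULL
  if (!is.null(layer_profiles)) {
    layer_profiles <- layer_profiles[keep]
    per_layer <- t(vapply(layer_profiles, function(m)
      apply(m, 1L, attention_ratio, domains = domains),
      numeric(nrow(layer_profiles[[1L]]))))
  }
  list(mean_profile = mean_profile, ratios = unname(ratios),
       mean_ratio = mean(ratios),
       ratio_of_mean = attention_ratio(mean_profile, domains),
       per_layer_ratios = per_layer, n_samples = length(profiles))
}
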