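# Encoder-decoder transformer with T5-style relative position bias,
# implemented directly on base-R matrices (forward + hand-derived backward).
# Pre-layer-norm residual blocks; tied input embedding / output projection;
# no biases on linear maps (layer norms carry scale and shift).

bcr <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Model configuration
#'
#' @param n_layers Number of encoder layers (the decoder uses the same count).
#' @param n_heads Attention heads; must divide `d_model`.
#' @param d_model Model width.
#' @param d_ff Feed-forward inner width.
#' @param vocab_size Total vocabulary size including special tokens.
#' @param max_len Maximum sequence length.
#' @param rel_buckets,rel_max_dist Relative-position bias bucketing: number
#'   of learned buckets per head and the distance beyond which positions
#'   share the farthest bucket.
#' @param dropout Dropout rate applied to sublayer outputs during training.
#' @param seed Seed for deterministic parameter initialization.
#' @param preset Optional named configuration: `"desk"` (2 layers, 4 heads,
#'   d_model 64, d_ff 256) for laptop-scale experiments, or `"paper"`
#'   (6 layers, 12 heads, d_model 512, d_ff 2048), an approximation of the
#'   full-scale setting. Explicit arguments override preset values.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_layers = 2L, n_heads = 4L, d_model = 64L,
                         d_ff = 256L, vocab_size = 1004L, max_len = 1024L,
                         rel_buckets = 32L, rel_max_dist = 128L,
                         dropout = 0, seed = 42L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    pv <- switch(preset,
                 desk = list(n_layers = 2L, n_heads = 4L, d_model = 64L,
                             d_ff = 256L),
                 paper = list(n_layers = 6L, n_heads = 12L, d_model = 512L,
                              d_ff = 2048L))
    call_names <- names(match.call())
    for (nm in names(pv))
      if (!nm %in% call_names) assign(nm, pv[[nm]])
  }
  if (d_model %% n_heads != 0L)
    stop("d_model (", d_model, ") must be divisible by n_heads (", n_heads, ")")
  if (vocab_size < 5L) stop("vocab_size too small")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_model = as.integer(d_model), d_ff = as.integer(d_ff),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 rel_buckets = as.integer(rel_buckets),
                 rel_max_dist = as.integer(rel_max_dist),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

# T5 relative-position bucketing: 0-based bucket for relative position
# rel = key_pos - query_pos. Bidirectional splits buckets between signs;
# the causal (decoder) variant uses only non-positive rel. Half of the
# per-sign budget is exact small distances, the rest log-spaced up to
# max_dist.
rel_bucket <- function(rel, bidirectional, num_buckets = 32L,
                       max_dist = 128L) {
  ret <- 0L
  nb <- num_buckets
  if (bidirectional) {
    nb <- nb %/% 2L
    ret <- as.integer(rel > 0L) * nb
    n <- abs(rel)
  } else {
    n <- pmax(-rel, 0L)
  }
  max_exact <- nb %/% 2L
  large <- max_exact +
    floor(log(pmax(n, 1L) / max_exact) / log(max_dist / max_exact) *
            (nb - max_exact))
  large <- pmin(large, nb - 1L)
  ret + ifelse(n < max_exact, n, large)
}

bucket_matrix <- function(nq, nk, bidirectional, num_buckets, max_dist) {
  rel <- outer(seq_len(nq), seq_len(nk), function(i, j) j - i)
  matrix(rel_bucket(rel, bidirectional, num_buckets, max_dist) + 1L, nq, nk)
}

#' Relative position bias between two absolute positions
#'
#' Exposes the learned per-head bias the self-attention layers add to their
#' scores; it depends only on the bucketed distance `j - i`, never on the
#' absolute positions.
#'
#' @param model A `seq2seq_model`.
#' @param i,j Query and key positions (1-based).
#' @param which `"encoder"` (bidirectional buckets) or `"decoder"` (causal).
#' @return Numeric vector, one bias per head.
#' @export
position_bias <- function(model, i, j, which = c("encoder", "decoder")) {
  which <- match.arg(which)
  cfg <- model$config
  b <- rel_bucket(j - i, which == "encoder", cfg$rel_buckets,
                  cfg$rel_max_dist) + 1L
  tab <- if (which == "encoder") model$params$enc_rel else model$params$dec_rel
  tab[b, ]
}

init_mat <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)

#' Build an encoder-decoder model
#'
#' Parameters are initialized deterministically from `config$seed`. The
#' output projection is tied to the input embedding.
#'
#' @param config A [model_config()].
#' @return A list of class `seq2seq_model` with `config`, `params` (named
#'   list of matrices/vectors) and `out_mask` (optional output-vocabulary
#'   restriction, `NULL` by default).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model; ff <- config$d_ff; V <- config$vocab_size
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  p <- list(emb = init_mat(V, d),
            enc_rel = init_mat(config$rel_buckets, config$n_heads),
            dec_rel = init_mat(config$rel_buckets, config$n_heads))
  add_layer <- function(prefix, cross) {
    p[[paste0(prefix, "_ln1_g")]] <<- rep(1, d)
    p[[paste0(prefix, "_ln1_b")]] <<- rep(0, d)
    for (w in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0(prefix, "_", w)]] <<- init_mat(d, d)
    p[[paste0(prefix, "_ln2_g")]] <<- rep(1, d)
    p[[paste0(prefix, "_ln2_b")]] <<- rep(0, d)
    if (cross) {
      for (w in c("Cq", "Ck", "Cv", "Co"))
        p[[paste0(prefix, "_", w)]] <<- init_mat(d, d)
      p[[paste0(prefix, "_ln3_g")]] <<- rep(1, d)
      p[[paste0(prefix, "_ln3_b")]] <<- rep(0, d)
    }
    p[[paste0(prefix, "_W1")]] <<- init_mat(d, ff)
    p[[paste0(prefix, "_W2")]] <<- init_mat(ff, d)
  }
  for (l in seq_len(config$n_layers)) add_layer(paste0("enc", l), FALSE)
  for (l in seq_len(config$n_layers)) add_layer(paste0("dec", l), TRUE)
  p$enc_lnf_g <- rep(1, d); p$enc_lnf_b <- rep(0, d)
  p$dec_lnf_g <- rep(1, d); p$dec_lnf_b <- rep(0, d)
  structure(list(config = config, params = p, out_mask = NULL),
            class = "seq2seq_model")
}

#' Total number of trainable parameters
#' @param model A `seq2seq_model`.
#' @return Integer parameter count.
#' @export
param_count <- function(model) sum(vapply(model$params, length, 0L))

#' Restrict the decoder output vocabulary
#'
#' Masks the output projection so that only `allowed_ids` (0-based token
#' ids, e.g. [rna_token_ids()]) can receive probability mass; all other
#' logits are set to -Inf before the softmax, in both training loss and
#' generation.
#'
#' @param model A `seq2seq_model`.
#' @param allowed_ids Integer vector of permitted 0-based token ids.
#' @return The model with `out_mask` set.
#' @export
restrict_output_vocab <- function(model, allowed_ids) {
  mask <- rep(FALSE, model$config$vocab_size)
  mask[allowed_ids + 1L] <- TRUE
  model$out_mask <- mask
  model
}

# ---- layer primitives -------------------------------------------------------

ln_fwd <- function(x, g, b) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- xc * inv
  y <- xhat * bcr(g, n) + bcr(b, n)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dxhat <- dy * bcr(cache$g, n)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

mha_fwd <- function(xq, xkv, Wq, Wk, Wv, Wo, n_heads, bias = NULL,
                    causal = FALSE) {
  d <- ncol(Wq); dh <- d %/% n_heads; scale <- 1 / sqrt(dh)
  Q <- xq %*% Wq; K <- xkv %*% Wk; V <- xkv %*% Wv
  nq <- nrow(Q); nk <- nrow(K)
  blocked <- if (causal) outer(seq_len(nq), seq_len(nk), `<`) else NULL
  A <- vector("list", n_heads)
  O <- matrix(0, nq, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) * scale
    if (!is.null(bias)) S <- S + bias[[h]]
    if (!is.null(blocked)) S[blocked] <- -Inf
    A[[h]] <- softmax_rows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  list(y = O %*% Wo,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, A = A, O = O,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo, n_heads = n_heads,
                    dh = dh, scale = scale, has_bias = !is.null(bias)))
}

mha_bwd <- function(dy, cache) {
  ch <- cache
  dWo <- t(ch$O) %*% dy
  dO <- dy %*% t(ch$Wo)
  nq <- nrow(dO); nk <- nrow(ch$K); d <- ncol(ch$Wq)
  dQ <- matrix(0, nq, d); dK <- matrix(0, nk, d); dV <- matrix(0, nk, d)
  dbias <- if (ch$has_bias) vector("list", ch$n_heads) else NULL
  for (h in seq_len(ch$n_heads)) {
    cols <- ((h - 1L) * ch$dh + 1L):(h * ch$dh)
    A <- ch$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- ch$V[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(A * dA))
    if (ch$has_bias) dbias[[h]] <- dS
    dQ[, cols] <- (dS %*% ch$K[, cols, drop = FALSE]) * ch$scale
    dK[, cols] <- (t(dS) %*% ch$Q[, cols, drop = FALSE]) * ch$scale
  }
  list(dxq = dQ %*% t(ch$Wq),
       dxkv = dK %*% t(ch$Wk) + dV %*% t(ch$Wv),
       dWq = t(ch$xq) %*% dQ, dWk = t(ch$xkv) %*% dK,
       dWv = t(ch$xkv) %*% dV, dWo = dWo, dbias = dbias)
}

ffn_fwd <- function(x, W1, W2) {
  z <- x %*% W1
  a <- pmax(z, 0)
  list(y = a %*% W2, cache = list(x = x, z = z, a = a, W1 = W1, W2 = W2))
}

ffn_bwd <- function(dy, cache) {
  dW2 <- t(cache$a) %*% dy
  da <- dy %*% t(cache$W2)
  dz <- da * (cache$z > 0)
  list(dx = dz %*% t(cache$W1), dW1 = t(cache$x) %*% dz, dW2 = dW2)
}

drop_mask <- function(dim1, dim2, rate) {
  if (rate <= 0) return(NULL)
  matrix(rbinom(dim1 * dim2, 1L, 1 - rate), dim1, dim2) / (1 - rate)
}

# ---- encoder / decoder forward & backward ----------------------------------

rel_bias_list <- function(table, bmat, n_heads) {
  lapply(seq_len(n_heads), function(h)
    matrix(table[bmat, h], nrow(bmat), ncol(bmat)))
}

enc_forward <- function(model, p_ids, training = FALSE) {
  cfg <- model$config; params <- model$params
  n <- length(p_ids)
  x <- params$emb[p_ids + 1L, , drop = FALSE]
  bmat <- bucket_matrix(n, n, TRUE, cfg$rel_buckets, cfg$rel_max_dist)
  bias <- rel_bias_list(params$enc_rel, bmat, cfg$n_heads)
  rate <- if (training) cfg$dropout else 0
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pf <- function(s) params[[paste0("enc", l, "_", s)]]
    ln1 <- ln_fwd(x, pf("ln1_g"), pf("ln1_b"))
    at <- mha_fwd(ln1$y, ln1$y, pf("Wq"), pf("Wk"), pf("Wv"), pf("Wo"),
                  cfg$n_heads, bias = bias)
    m1 <- drop_mask(n, cfg$d_model, rate)
    x1 <- x + if (is.null(m1)) at$y else at$y * m1
    ln2 <- ln_fwd(x1, pf("ln2_g"), pf("ln2_b"))
    ff <- ffn_fwd(ln2$y, pf("W1"), pf("W2"))
    m2 <- drop_mask(n, cfg$d_model, rate)
    x <- x1 + if (is.null(m2)) ff$y else ff$y * m2
    layers[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2, ff = ff,
                        m1 = m1, m2 = m2)
  }
  lnf <- ln_fwd(x, params$enc_lnf_g, params$enc_lnf_b)
  list(H = lnf$y, layers = layers, lnf = lnf, bmat = bmat, p_ids = p_ids)
}

acc_add <- function(acc, name, val) {
  cur <- acc$g[[name]]
  acc$g[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

acc_add_rel <- function(acc, name, bmat, dbias) {
  for (h in seq_along(dbias)) {
    rs <- rowsum(as.vector(dbias[[h]]), as.vector(bmat))
    idx <- as.integer(rownames(rs))
    cur <- acc$g[[name]]
    if (is.null(cur)) {
      cur <- matrix(0, acc$rel_dim, acc$rel_dim2)
    }
    cur[idx, h] <- cur[idx, h] + rs[, 1L]
    acc$g[[name]] <- cur
  }
  invisible(NULL)
}

enc_backward <- function(model, fw, dH, acc) {
  cfg <- model$config
  bk <- ln_bwd(dH, fw$lnf$cache)
  acc_add(acc, "enc_lnf_g", bk$dg); acc_add(acc, "enc_lnf_b", bk$db)
  dx <- bk$dx
  for (l in rev(seq_len(cfg$n_layers))) {
    ch <- fw$layers[[l]]
    nm <- function(s) paste0("enc", l, "_", s)
    dff_out <- if (is.null(ch$m2)) dx else dx * ch$m2
    fb <- ffn_bwd(dff_out, ch$ff$cache)
    acc_add(acc, nm("W1"), fb$dW1); acc_add(acc, nm("W2"), fb$dW2)
    l2 <- ln_bwd(fb$dx, ch$ln2$cache)
    acc_add(acc, nm("ln2_g"), l2$dg); acc_add(acc, nm("ln2_b"), l2$db)
    dx1 <- dx + l2$dx
    dat_out <- if (is.null(ch$m1)) dx1 else dx1 * ch$m1
    ab <- mha_bwd(dat_out, ch$at$cache)
    acc_add(acc, nm("Wq"), ab$dWq); acc_add(acc, nm("Wk"), ab$dWk)
    acc_add(acc, nm("Wv"), ab$dWv); acc_add(acc, nm("Wo"), ab$dWo)
    acc_add_rel(acc, "enc_rel", fw$bmat, ab$dbias)
    l1 <- ln_bwd(ab$dxq + ab$dxkv, ch$ln1$cache)
    acc_add(acc, nm("ln1_g"), l1$dg); acc_add(acc, nm("ln1_b"), l1$db)
    dx <- dx1 + l1$dx
  }
  demb <- rowsum(dx, fw$p_ids + 1L)
  idx <- as.integer(rownames(demb))
  cur <- acc$g[["emb"]]
  if (is.null(cur)) cur <- matrix(0, cfg$vocab_size, cfg$d_model)
  cur[idx, ] <- cur[idx, ] + demb
  acc$g[["emb"]] <- cur
  invisible(NULL)
}

dec_forward <- function(model, r_in_ids, H, training = FALSE) {
  cfg <- model$config; params <- model$params
  n <- length(r_in_ids)
  x <- params$emb[r_in_ids + 1L, , drop = FALSE]
  bmat <- bucket_matrix(n, n, FALSE, cfg$rel_buckets, cfg$rel_max_dist)
  bias <- rel_bias_list(params$dec_rel, bmat, cfg$n_heads)
  rate <- if (training) cfg$dropout else 0
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    pf <- function(s) params[[paste0("dec", l, "_", s)]]
    ln1 <- ln_fwd(x, pf("ln1_g"), pf("ln1_b"))
    at <- mha_fwd(ln1$y, ln1$y, pf("Wq"), pf("Wk"), pf("Wv"), pf("Wo"),
                  cfg$n_heads, bias = bias, causal = TRUE)
    m1 <- drop_mask(n, cfg$d_model, rate)
    x1 <- x + if (is.null(m1)) at$y else at$y * m1
    ln2 <- ln_fwd(x1, pf("ln2_g"), pf("ln2_b"))
    cr <- mha_fwd(ln2$y, H, pf("Cq"), pf("Ck"), pf("Cv"), pf("Co"),
                  cfg$n_heads)
    m2 <- drop_mask(n, cfg$d_model, rate)
    x2 <- x1 + if (is.null(m2)) cr$y else cr$y * m2
    ln3 <- ln_fwd(x2, pf("ln3_g"), pf("ln3_b"))
    ff <- ffn_fwd(ln3$y, pf("W1"), pf("W2"))
    m3 <- drop_mask(n, cfg$d_model, rate)
    x <- x2 + if (is.null(m3)) ff$y else ff$y * m3
    layers[[l]] <- list(ln1 = ln1, at = at, ln2 = ln2, cr = cr, ln3 = ln3,
                        ff = ff, m1 = m1, m2 = m2, m3 = m3)
  }
  lnf <- ln_fwd(x, params$dec_lnf_g, params$dec_lnf_b)
  list(D = lnf$y, layers = layers, lnf = lnf, bmat = bmat,
       r_in_ids = r_in_ids)
}

dec_backward <- function(model, fw, dD, acc) {
  cfg <- model$config
  bk <- ln_bwd(dD, fw$lnf$cache)
  acc_add(acc, "dec_lnf_g", bk$dg); acc_add(acc, "dec_lnf_b", bk$db)
  dx <- bk$dx
  dH <- NULL
  for (l in rev(seq_len(cfg$n_layers))) {
    ch <- fw$layers[[l]]
    nm <- function(s) paste0("dec", l, "_", s)
    dff_out <- if (is.null(ch$m3)) dx else dx * ch$m3
    fb <- ffn_bwd(dff_out, ch$ff$cache)
    acc_add(acc, nm("W1"), fb$dW1); acc_add(acc, nm("W2"), fb$dW2)
    l3 <- ln_bwd(fb$dx, ch$ln3$cache)
    acc_add(acc, nm("ln3_g"), l3$dg); acc_add(acc, nm("ln3_b"), l3$db)
    dx2 <- dx + l3$dx
    dcr_out <- if (is.null(ch$m2)) dx2 else dx2 * ch$m2
    cb <- mha_bwd(dcr_out, ch$cr$cache)
    acc_add(acc, nm("Cq"), cb$dWq); acc_add(acc, nm("Ck"), cb$dWk)
    acc_add(acc, nm("Cv"), cb$dWv); acc_add(acc, nm("Co"), cb$dWo)
    dH <- if (is.null(dH)) cb$dxkv else dH + cb$dxkv
    l2 <- ln_bwd(cb$dxq, ch$ln2$cache)
    acc_add(acc, nm("ln2_g"), l2$dg); acc_add(acc, nm("ln2_b"), l2$db)
    dx1 <- dx2 + l2$dx
    dat_out <- if (is.null(ch$m1)) dx1 else dx1 * ch$m1
    ab <- mha_bwd(dat_out, ch$at$cache)
    acc_add(acc, nm("Wq"), ab$dWq); acc_add(acc, nm("Wk"), ab$dWk)
    acc_add(acc, nm("Wv"), ab$dWv); acc_add(acc, nm("Wo"), ab$dWo)
    acc_add_rel(acc, "dec_rel", fw$bmat, ab$dbias)
    l1 <- ln_bwd(ab$dxq + ab$dxkv, ch$ln1$cache)
    acc_add(acc, nm("ln1_g"), l1$dg); acc_add(acc, nm("ln1_b"), l1$db)
    dx <- dx1 + l1$dx
  }
  demb <- rowsum(dx, fw$r_in_ids + 1L)
  idx <- as.integer(rownames(demb))
  cur <- acc$g[["emb"]]
  if (is.null(cur)) cur <- matrix(0, cfg$vocab_size, cfg$d_model)
  cur[idx, ] <- cur[idx, ] + demb
  acc$g[["emb"]] <- cur
  dH
}

project_logits <- function(model, D) {
  L <- D %*% t(model$params$emb)
  if (!is.null(model$out_mask)) L[, !model$out_mask] <- -Inf
  L
}

#' Negative log-likelihood from a logits matrix
#'
#' Sum over positions of -log softmax probability of the target token.
#' Exposed so analytic cases (uniform logits, certain predictions) can be
#' checked directly.
#'
#' @param logits n x V matrix of unnormalized scores.
#' @param targets Integer vector of n 0-based target token ids.
#' @return Scalar NLL (sum over the n positions).
#' @export
nll_from_logits <- function(logits, targets) {
  stopifnot(nrow(logits) == length(targets))
  P <- softmax_rows(logits)
  -sum(log(P[cbind(seq_along(targets), targets + 1L)]))
}

#' Teacher-forced next-token distributions for a pair
#'
#' Runs the full encoder-decoder on (protein, RNA) token ids and returns the
#' decoder's next-token logits at every step `i` (conditioning on the true
#' prefix `r_{<i}`). Row `i` predicts target `i`, where the target sequence
#' is the RNA ids followed by EOS.
#'
#' @param model A `seq2seq_model`.
#' @param p_ids Protein token ids (0-based, unpadded).
#' @param r_ids RNA token ids (0-based, unpadded; no BOS/EOS).
#' @return (length(r_ids) + 1) x V logits matrix.
#' @export
forward_logits <- function(model, p_ids, r_ids) {
  enc <- enc_forward(model, p_ids)
  r_in <- c(SPECIAL_TOKENS[["BOS"]], r_ids)
  dec <- dec_forward(model, r_in, enc$H)
  project_logits(model, dec$D)
}

#' Conditional NLL of a batch
#'
#' Sum of per-token negative log-likelihoods within each sequence (padding
#' never enters: pairs carry unpadded ids), averaged over the batch.
#'
#' @param model A `seq2seq_model`.
#' @param batch List of pairs, each `list(p = <protein ids>, r = <rna ids>)`
#'   (0-based, unpadded).
#' @return Scalar mean NLL per sequence.
#' @export
nll_loss <- function(model, batch) {
  losses <- vapply(batch, function(pair) {
    logits <- forward_logits(model, pair$p, pair$r)
    targets <- c(pair$r, SPECIAL_TOKENS[["EOS"]])
    nll_from_logits(logits, targets)
  }, 0)
  mean(losses)
}

#' Loss and parameter gradients for a batch
#'
#' Backpropagates the batch-mean NLL through the full encoder-decoder and
#' returns gradients for every parameter (names match `model$params`).
#'
#' @inheritParams nll_loss
#' @param training Apply dropout (when the config has a nonzero rate).
#' @return List with `loss` (mean NLL) and `grads` (named list).
#' @export
nll_grads <- function(model, batch, training = FALSE) {
  cfg <- model$config
  acc <- new.env(parent = emptyenv())
  acc$g <- list()
  acc$rel_dim <- cfg$rel_buckets; acc$rel_dim2 <- cfg$n_heads
  total <- 0
  B <- length(batch)
  for (pair in batch) {
    enc <- enc_forward(model, pair$p, training = training)
    r_in <- c(SPECIAL_TOKENS[["BOS"]], pair$r)
    dec <- dec_forward(model, r_in, enc$H, training = training)
    logits <- project_logits(model, dec$D)
    targets <- c(pair$r, SPECIAL_TOKENS[["EOS"]])
    P <- softmax_rows(logits)
    total <- total + -sum(log(P[cbind(seq_along(targets), targets + 1L)]))
    dlogits <- P / B
    dlogits[cbind(seq_along(targets), targets + 1L)] <-
      dlogits[cbind(seq_along(targets), targets + 1L)] - 1 / B
    # tied projection: logits = D %*% t(emb)
    dD <- dlogits %*% model$params$emb
    cur <- acc$g[["emb"]]
    if (is.null(cur)) cur <- matrix(0, cfg$vocab_size, cfg$d_model)
    acc$g[["emb"]] <- cur + t(dlogits) %*% dec$D
    dH <- dec_backward(model, dec, dD, acc)
    enc_backward(model, enc, dH, acc)
  }
  list(loss = total / B, grads = acc$g)
}

fix_rel_dims <- function(grads, model) {
  # rel tables may have been created lazily; ensure full dimension
  for (nm in c("enc_rel", "dec_rel"))
    if (is.null(grads[[nm]]))
      grads[[nm]] <- matrix(0, model$config$rel_buckets, model$config$n_heads)
  grads
}

#' Train a model with AdamW and gradient accumulation
#'
#' Runs a fixed number of optimizer steps. Each step draws `accum_steps`
#' micro-batches of `batch_size` pairs (sampled uniformly with replacement
#' from the corpus, deterministic for a fixed seed), averages their
#' gradients, clips the global gradient norm, and applies an Adam update
#' with decoupled weight decay (decay on linear and embedding weights, not
#' on layer-norm parameters or relative-bias tables). The effective batch is
#' `batch_size * accum_steps`. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model A `seq2seq_model`.
#' @param pairs List of `list(p = ids, r = ids)` tokenized pairs.
#' @param steps Number of optimizer steps.
#' @param batch_size Micro-batch size (default 8).
#' @param accum_steps Gradient accumulation factor (default 1).
#' @param lr Peak learning rate (default 1e-3).
#' @param lr_schedule `"cosine"` (default): linear warmup over
#'   `warmup_steps` then cosine decay to zero; or `"constant"`.
#' @param warmup_steps Warmup steps for the cosine schedule (default 100).
#' @param weight_decay Decoupled weight-decay coefficient (default 0.01).
#' @param clip Global gradient-norm clip (default 1.0).
#' @param seed RNG seed controlling batch order (and dropout, if enabled).
#' @param verbose Print running loss every 100 steps.
#' @return A list of class `train_state`: `model` (trained), `loss_trace`
#'   (per-step mean NLL), `steps`, `effective_batch`.
#' @export
train_model <- function(model, pairs, steps, batch_size = 8L,
                        accum_steps = 1L, lr = 1e-3,
                        lr_schedule = c("cosine", "constant"),
                        warmup_steps = 100L, weight_decay = 0.01,
                        clip = 1.0, seed = 1L, verbose = FALSE) {
  stopifnot(length(pairs) >= 1L, steps >= 1L)
  lr_schedule <- match.arg(lr_schedule)
  lr_at <- function(step) {
    if (lr_schedule == "constant") return(lr)
    if (step <= warmup_steps && warmup_steps > 0L)
      return(lr * step / warmup_steps)
    prog <- (step - warmup_steps) / max(1L, steps - warmup_steps)
    lr * 0.5 * (1 + cos(pi * min(prog, 1)))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- model$params
  m <- lapply(params, function(x) x * 0)
  v <- lapply(params, function(x) x * 0)
  decay_ok <- !grepl("ln|rel", names(params))
  names(decay_ok) <- names(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    gsum <- NULL
    loss_sum <- 0
    for (a in seq_len(accum_steps)) {
      idx <- sample.int(length(pairs), batch_size, replace = TRUE)
      gr <- nll_grads(model, pairs[idx], training = model$config$dropout > 0)
      loss_sum <- loss_sum + gr$loss
      g <- fix_rel_dims(gr$grads, model)
      gsum <- if (is.null(gsum)) g else
        setNames(lapply(names(g), function(n) gsum[[n]] + g[[n]]), names(g))
    }
    loss <- loss_sum / accum_steps
    if (!is.finite(loss))
      stop("training diverged at step ", step, " (non-finite loss); ",
           "reduce the learning rate")
    trace[step] <- loss
    g <- lapply(gsum, function(x) x / accum_steps)
    gnorm <- sqrt(sum(vapply(g, function(x) sum(x * x), 0)))
    if (is.finite(clip) && gnorm > clip)
      g <- lapply(g, function(x) x * (clip / gnorm))
    bc1 <- 1 - b1^step; bc2 <- 1 - b2^step
    for (nm in names(params)) {
      gi <- g[[nm]]
      if (is.null(gi)) next
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gi
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gi * gi
      upd <- (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + eps)
      if (decay_ok[[nm]] && weight_decay > 0)
        upd <- upd + weight_decay * params[[nm]]
      params[[nm]] <- params[[nm]] - lr_at(step) * upd
    }
    model$params <- params
    if (verbose && step %% 100L == 0L)
      message("step ", step, "  loss ", round(loss, 4))
  }
  structure(list(model = model, loss_trace = trace, steps = steps,
                 effective_batch = batch_size * accum_steps),
            class = "train_state")
}

#' Encode a protein once for repeated decoding
#' @param model A `seq2seq_model`.
#' @param p_ids Protein token ids (0-based, unpadded).
#' @return Encoder output matrix `H` (n_p x d).
#' @export
encode_protein <- function(model, p_ids) enc_forward(model, p_ids)$H

#' Next-token distribution given a generation prefix
#'
#' @param model A `seq2seq_model`.
#' @param p_ids Protein token ids, or `NULL` when `H` is supplied.
#' @param prefix_ids RNA token ids generated so far (possibly empty).
#' @param H Optional precomputed encoder output from [encode_protein()].
#' @return List with `logits` and `probs` (valid probability vector over
#'   the vocabulary).
#' @export
step_logits <- function(model, p_ids, prefix_ids = integer(), H = NULL) {
  if (is.null(H)) H <- encode_protein(model, p_ids)
  if (length(prefix_ids) + 1L >= model$config$max_len)
    stop("prefix length exceeds max_len")
  r_in <- c(SPECIAL_TOKENS[["BOS"]], prefix_ids)
  dec <- dec_forward(model, r_in, H)
  logits <- project_logits(model, dec$D)[length(r_in), ]
  list(logits = logits, probs = softmax_vec(logits))
}

softmax_vec <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}

#' Extract decoder cross-attention maps for one pair
#'
#' Runs a teacher-forced forward pass and returns the cross-attention
#' weights as an array indexed (layer, head, rna_position, protein_token);
#' each (layer, head, rna_position) row is a distribution over protein
#' tokens.
#'
#' @inheritParams forward_logits
#' @return 4-d array of attention weights.
#' @export
extract_cross_attention <- function(model, p_ids, r_ids) {
  enc <- enc_forward(model, p_ids)
  r_in <- c(SPECIAL_TOKENS[["BOS"]], r_ids)
  dec <- dec_forward(model, r_in, enc$H)
  cfg <- model$config
  out <- array(0, dim = c(cfg$n_layers, cfg$n_heads, length(r_in),
                          length(p_ids)))
  for (l in seq_len(cfg$n_layers))
    for (h in seq_len(cfg$n_heads))
      out[l, h, , ] <- dec$layers[[l]]$cr$cache$A[[h]]
  attention_tensor(out)
}

#' Serialize a model (config plus flat parameter archive) to JSON
#' @param model A `seq2seq_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              out_mask = model$out_mask,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = as.vector(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [save_model()]
#' @param path Path to the JSON checkpoint.
#' @return A `seq2seq_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1L], p$dim[2L])
    else as.numeric(p$data)
  })
  out_mask <- if (is.null(obj$out_mask) || !length(obj$out_mask)) NULL
              else as.logical(obj$out_mask)
  structure(list(config = cfg, params = params, out_mask = out_mask),
            class = "seq2seq_model")
}

#' Tokenize interaction records into model-ready id pairs
#'
#' Protein ids are the encoded tokens followed by EOS; RNA ids are the bare
#' token sequence (BOS/EOS framing is added internally by the loss and the
#' samplers). Padding is never included.
#'
#' @param tok A `bpe_tokenizer`.
#' @param records List of [interaction_record()] objects.
#' @param max_len Frame length for truncation.
#' @return List of `list(p = ids, r = ids)` pairs.
#' @export
tokenize_pairs <- function(tok, records, max_len = 1024L) {
  lapply(records, function(rec) {
    pe <- bpe_encode(tok, rec$protein$seq, "protein", max_len = max_len)
    re <- bpe_encode(tok, rec$rna$seq, "rna", max_len = max_len)
    p <- pe$ids[pe$mask == 1L]
    r <- re$ids[re$mask == 1L]
    r <- r[r != tok$specials[["EOS"]]]
    list(p = p, r = r)
  })
}

#' Held-out next-token accuracy under teacher forcing
#'
#' Fraction of target positions (RNA tokens plus EOS) where the model's
#' argmax next-token prediction equals the true token.
#'
#' @param model A `seq2seq_model`.
#' @param pairs List of tokenized pairs as in [nll_loss()].
#' @return Fraction in \[0, 1\].
#' @export
next_token_accuracy <- function(model, pairs) {
  hits <- 0L; total <- 0L
  for (pair in pairs) {
    logits <- forward_logits(model, pair$p, pair$r)
    targets <- c(pair$r, SPECIAL_TOKENS[["EOS"]])
    pred <- max.col(logits, ties.method = "first") - 1L
    hits <- hits + sum(pred == targets)
    total <- total + length(targets)
  }
  hits / total
}
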