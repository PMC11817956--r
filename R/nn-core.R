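# Minimal neural-network core used by the segmentation models.
#
# Tensors are plain R arrays with dim (X, Y, Z, C); token matrices are
# (n_tokens x channels).  Every layer is a pair of pure functions
# (<layer>_fwd, <layer>_bwd); the forward returns whatever cache its backward
# needs, so architectures compose layers explicitly and walk the caches in
# reverse for backpropagation.  All heavy convolution arithmetic lives in
# compiled code (src/nn_ops.cpp).

nn_rnorm <- function(dim, sd) array(stats::rnorm(prod(dim), 0, sd), dim = dim)

#' @noRd
init_conv <- function(k, ic, oc) {
  # He initialization for ReLU nets
  sd <- sqrt(2 / (k^3 * ic))
  list(w = nn_rnorm(c(k, k, k, ic, oc), sd), b = numeric(oc))
}

init_linear <- function(ic, oc, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(1 / ic)
  list(w = matrix(stats::rnorm(ic * oc, 0, sd), ic, oc), b = numeric(oc))
}

init_norm <- function(c) list(g = rep(1, c), b = numeric(c))

conv3d_fwd <- function(x, p, stride = 1L, pad = 1L) {
  cpp_conv3d_fwd(x, p$w, p$b, as.integer(stride), as.integer(pad))
}

conv3d_bwd <- function(x, p, dy, stride = 1L, pad = 1L) {
  cpp_conv3d_bwd(x, p$w, dy, as.integer(stride), as.integer(pad))
}

tconv3d_fwd <- function(x, p) cpp_tconv3d_fwd(x, p$w, p$b)

tconv3d_bwd <- function(x, p, dy) cpp_tconv3d_bwd(x, p$w, dy)

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(x, dy) {
  dy[x <= 0] <- 0
  dy
}

gelu_fwd <- function(x) x * stats::pnorm(x)

gelu_bwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

# Instance norm, inference-only path: channel-at-a-time, no cache, minimal
# copies (used by the full-resolution forward passes).
inorm_infer <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  for (ch in seq_len(d[4])) {
    v <- x[, , , ch]
    mu <- mean(v)
    sd2 <- mean((v - mu)^2)
    x[, , , ch] <- (v - mu) * (p$g[ch] / sqrt(sd2 + eps)) + p$b[ch]
  }
  x
}

# Instance norm: normalize each channel over its spatial extent.
inorm_fwd <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  s <- prod(d[1:3])
  xm <- matrix(x, s, d[4])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu, "-")
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  dim(y) <- d
  list(y = y, xhat = xhat, inv_sd = inv_sd, dim = d)
}

inorm_bwd <- function(cache, p, dy) {
  d <- cache$dim
  s <- prod(d[1:3])
  dym <- matrix(dy, s, d[4])
  xhat <- cache$xhat
  dg <- colSums(dym * xhat)
  db <- colSums(dym)
  dxh <- sweep(dym, 2, p$g, "*")
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * xhat)
  dx <- sweep(sweep(dxh, 2, m1, "-") - sweep(xhat, 2, m2, "*"),
              2, cache$inv_sd, "*")
  dim(dx) <- d
  list(dx = dx, dg = dg, db = db)
}

# Layer norm over the feature dimension of a (n x C) token matrix.
lnorm_fwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- sweep(sweep(xhat, 2, p$g, "*"), 2, p$b, "+")
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

lnorm_bwd <- function(cache, p, dy) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2, p$g, "*")
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) * cache$inv_sd
  list(dx = dx, dg = dg, db = db)
}

linear_fwd <- function(x, p) sweep(x %*% p$w, 2, p$b, "+")

linear_bwd <- function(x, p, dy) {
  list(dx = dy %*% t(p$w), dw = crossprod(x, dy), db = colSums(dy))
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- Adam ------------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update over a flat named list of parameter arrays.
#' `trainable` is a logical vector over names(params); frozen entries are
#' left bit-identical and their moments untouched.
#' @noRd
adam_step <- function(params, grads, state, trainable,
                      lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (!isTRUE(trainable[[nm]])) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Accumulate grads2 into grads1 (both flat named lists; NULL-safe).
acc_grads <- function(g1, g2) {
  for (nm in names(g2)) {
    if (is.null(g1[[nm]])) g1[[nm]] <- g2[[nm]] else g1[[nm]] <- g1[[nm]] + g2[[nm]]
  }
  g1
}
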