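# Windowed multi-head self-attention (W-MSA / SW-MSA) and the transformer
# block used by the Swin-style encoder.  Tokens are the voxels of a
# (X, Y, Z, C) feature array flattened in array order; attention is computed
# independently inside non-overlapping 3D windows.  The shifted variant
# cyclically rolls the volume by half a window before partitioning and rolls
# back afterwards.

# Flat token indices of each window: a (window_size x n_windows) matrix.
window_index <- function(dims, win) {
  stopifnot(all(dims %% win == 0))
  nb <- dims %/% win
  # offsets within a window, x fastest
  off <- as.matrix(expand.grid(x = 0:(win[1] - 1), y = 0:(win[2] - 1),
                               z = 0:(win[3] - 1)))
  base <- as.matrix(expand.grid(x = seq(0, dims[1] - win[1], by = win[1]),
                                y = seq(0, dims[2] - win[2], by = win[2]),
                                z = seq(0, dims[3] - win[3], by = win[3])))
  ws <- nrow(off)
  nw <- nrow(base)
  idx <- matrix(0L, ws, nw)
  for (j in seq_len(nw)) {
    xs <- base[j, 1] + off[, 1]
    ys <- base[j, 2] + off[, 2]
    zs <- base[j, 3] + off[, 3]
    idx[, j] <- as.integer(xs + dims[1] * (ys + dims[2] * zs) + 1)
  }
  idx
}

roll3 <- function(x4, shift) {
  d <- dim(x4)
  ix <- ((seq_len(d[1]) - 1 + shift[1]) %% d[1]) + 1
  iy <- ((seq_len(d[2]) - 1 + shift[2]) %% d[2]) + 1
  iz <- ((seq_len(d[3]) - 1 + shift[3]) %% d[3]) + 1
  x4[ix, iy, iz, , drop = FALSE]
}

msa_fwd <- function(tok, p, idx, heads, cache = TRUE) {
  n <- nrow(tok)
  c_ <- ncol(tok)
  dh <- c_ %/% heads
  scale <- 1 / sqrt(dh)
  q <- linear_fwd(tok, list(w = p$wq, b = p$bq))
  k <- linear_fwd(tok, list(w = p$wk, b = p$bk))
  v <- linear_fwd(tok, list(w = p$wv, b = p$bv))
  o <- matrix(0, n, c_)
  aws <- if (cache) vector("list", ncol(idx)) else NULL
  for (j in seq_len(ncol(idx))) {
    rows <- idx[, j]
    if (cache) aws[[j]] <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      qh <- q[rows, cols, drop = FALSE]
      kh <- k[rows, cols, drop = FALSE]
      a <- softmax_rows(tcrossprod(qh, kh) * scale)
      o[rows, cols] <- a %*% v[rows, cols, drop = FALSE]
      if (cache) aws[[j]][[h]] <- a
    }
  }
  y <- linear_fwd(o, list(w = p$wo, b = p$bo))
  list(y = y,
       cache = if (cache) list(tok = tok, q = q, k = k, v = v, o = o,
                               a = aws, scale = scale) else NULL)
}

msa_bwd <- function(cache, p, idx, heads, dy) {
  tok <- cache$tok
  c_ <- ncol(tok)
  dh <- c_ %/% heads
  lo <- linear_bwd(cache$o, list(w = p$wo, b = p$bo), dy)
  do_ <- lo$dx
  dq <- matrix(0, nrow(tok), c_)
  dk <- dq
  dv <- dq
  for (j in seq_len(ncol(idx))) {
    rows <- idx[, j]
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      a <- cache$a[[j]][[h]]
      doh <- do_[rows, cols, drop = FALSE]
      vh <- cache$v[rows, cols, drop = FALSE]
      da <- tcrossprod(doh, vh)
      dv[rows, cols] <- dv[rows, cols] + crossprod(a, doh)
      ds <- a * (da - rowSums(da * a)) * cache$scale
      dq[rows, cols] <- dq[rows, cols] +
        ds %*% cache$k[rows, cols, drop = FALSE]
      dk[rows, cols] <- dk[rows, cols] +
        crossprod(ds, cache$q[rows, cols, drop = FALSE])
    }
  }
  lq <- linear_bwd(tok, list(w = p$wq, b = p$bq), dq)
  lk <- linear_bwd(tok, list(w = p$wk, b = p$bk), dk)
  lv <- linear_bwd(tok, list(w = p$wv, b = p$bv), dv)
  list(dx = lq$dx + lk$dx + lv$dx,
       dwq = lq$dw, dbq = lq$db, dwk = lk$dw, dbk = lk$db,
       dwv = lv$dw, dbv = lv$db, dwo = lo$dw, dbo = lo$db)
}

init_msa <- function(c_) {
  sd <- 0.02
  list(wq = matrix(stats::rnorm(c_ * c_, 0, sd), c_, c_), bq = numeric(c_),
       wk = matrix(stats::rnorm(c_ * c_, 0, sd), c_, c_), bk = numeric(c_),
       wv = matrix(stats::rnorm(c_ * c_, 0, sd), c_, c_), bv = numeric(c_),
       wo = matrix(stats::rnorm(c_ * c_, 0, sd), c_, c_), bo = numeric(c_))
}

init_swin_block <- function(c_, mlp_ratio = 2) {
  hid <- c_ * mlp_ratio
  list(ln1 = init_norm(c_), attn = init_msa(c_), ln2 = init_norm(c_),
       fc1 = init_linear(c_, hid, sd = 0.02), fc2 = init_linear(hid, c_, sd = 0.02))
}

# One transformer sub-block: LN -> (S)W-MSA -> +res -> LN -> MLP -> +res.
swin_block_fwd <- function(x4, p, win, heads, shift, cache = TRUE) {
  d <- dim(x4)
  wff <- pmin(as.integer(win), d[1:3])
  if (any(d[1:3] %% wff != 0)) {
    stop("window size (", paste(wff, collapse = "x"),
         ") incompatible with stage resolution (",
         paste(d[1:3], collapse = "x"), ")")
  }
  sh <- if (shift) (wff %/% 2L) else c(0L, 0L, 0L)
  xs <- if (shift) roll3(x4, -sh) else x4
  tok <- matrix(xs, prod(d[1:3]), d[4])
  idx <- window_index(d[1:3], wff)
  l1 <- lnorm_fwd(tok, p$ln1)
  at <- msa_fwd(l1$y, p$attn, idx, heads, cache)
  r1 <- tok + at$y
  l2 <- lnorm_fwd(r1, p$ln2)
  h1 <- linear_fwd(l2$y, p$fc1)
  g1 <- gelu_fwd(h1)
  h2 <- linear_fwd(g1, p$fc2)
  y <- r1 + h2
  y4 <- array(y, d)
  if (shift) y4 <- roll3(y4, sh)
  list(y = y4,
       cache = if (cache) list(d = d, sh = sh, shift = shift, idx = idx,
                               tok = tok, l1 = l1, at = at$cache, r1 = r1,
                               l2 = l2, h1 = h1, g1 = g1) else NULL)
}

swin_block_bwd <- function(cache, p, heads, dy4) {
  d <- cache$d
  if (cache$shift) dy4 <- roll3(dy4, -cache$sh)
  dy <- matrix(dy4, prod(d[1:3]), d[4])
  lf2 <- linear_bwd(cache$g1, p$fc2, dy)
  dg1 <- gelu_bwd(cache$h1, lf2$dx)
  lf1 <- linear_bwd(cache$l2$y, p$fc1, dg1)
  ln2 <- lnorm_bwd(cache$l2, p$ln2, lf1$dx)
  dr1 <- dy + ln2$dx
  am <- msa_bwd(cache$at, p$attn, cache$idx, heads, dr1)
  ln1 <- lnorm_bwd(cache$l1, p$ln1, am$dx)
  dtok <- dr1 + ln1$dx
  dx4 <- array(dtok, d)
  if (cache$shift) dx4 <- roll3(dx4, cache$sh)
  # grads use the same leaf names as the parameters so they align for Adam
  grads <- list(ln1 = list(g = ln1$dg, b = ln1$db),
                attn = list(wq = am$dwq, bq = am$dbq, wk = am$dwk,
                            bk = am$dbk, wv = am$dwv, bv = am$dbv,
                            wo = am$dwo, bo = am$dbo),
                ln2 = list(g = ln2$dg, b = ln2$db),
                fc1 = list(w = lf1$dw, b = lf1$db),
                fc2 = list(w = lf2$dw, b = lf2$db))
  list(dx = dx4, grads = grads)
}
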