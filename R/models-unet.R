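#' U-net specification
#'
#' Describes the residual 3D U-net: a stride-1 stem convolution lifting the
#' input to `base_channels`, four stride-2 residual encoder blocks that each
#' double the channels and halve every spatial dimension (so five encoder
#' blocks in total, counting the stem), four decoder blocks mirroring them
#' with transposed convolutions and skip concatenations, and a final 1x1x1
#' convolution reducing to `out_channels`.  At the defaults
#' (`base_channels = 16`, input 128x128x64) the bottleneck activation is
#' 256x8x8x4 and the output is 2x128x128x64.
#'
#' `base_channels` and `input_shape` together form the scale knob: shrinking
#' both preserves the doubling/halving ladder proportionally so desk-scale
#' variants exercise the same structural contracts.
#'
#' @param base_channels Channels after the stem convolution (default 16).
#' @param input_shape Integer length-3 spatial shape; every dimension must be
#'   a multiple of 32.
#' @param in_channels,out_channels Input image channels and output classes.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(base_channels = 16L, input_shape = c(128L, 128L, 64L),
                      in_channels = 1L, out_channels = 2L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape %% 32 != 0)) {
    stop("input dimensions must be multiples of 32, got (",
         paste(input_shape, collapse = ", "), ")")
  }
  structure(list(base_channels = as.integer(base_channels),
                 input_shape = input_shape,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_encoder_blocks = 5L, n_decoder_blocks = 4L,
                 n_down = 4L),
            class = "unet_spec")
}

#' Closed-form shape ladder of a U-net spec
#'
#' Predicted activation shape after each encoder block (including the stem),
#' independent of any forward pass; used as the oracle against observed
#' shapes.
#'
#' @param spec A [unet_spec()].
#' @return A tibble with columns `stage`, `channels`, `x`, `y`, `z`.
#' @export
unet_ladder <- function(spec) {
  stages <- 0:spec$n_down
  tibble::tibble(
    stage = stages,
    channels = spec$base_channels * 2L^stages,
    x = spec$input_shape[1] %/% 2L^stages,
    y = spec$input_shape[2] %/% 2L^stages,
    z = spec$input_shape[3] %/% 2L^stages
  )
}

#' Build a residual 3D U-net
#'
#' Instantiates the network described by a [unet_spec()] with randomly
#' initialized weights.  Every trainable parameter is tagged with exactly one
#' group: `encoder` (stem + downsampling blocks), `decoder` (the two decoder
#' blocks nearest the bottleneck), `bottom_two` (the two decoder blocks
#' nearest the output) or `head` (the final channel-reducing convolution).
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `seg_model` handle usable with [model_forward()], [segment()],
#'   [set_trainable()].
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  set.seed(seed)
  bc <- spec$base_channels
  p <- list()
  p$stem <- list(conv = init_conv(3, spec$in_channels, bc), n = init_norm(bc))
  for (i in seq_len(spec$n_down)) {
    ic <- bc * 2L^(i - 1)
    oc <- bc * 2L^i
    p[[paste0("enc", i)]] <- list(
      conv1 = init_conv(3, ic, oc), n1 = init_norm(oc),
      conv2 = init_conv(3, oc, oc), n2 = init_norm(oc),
      proj = init_conv(1, ic, oc))
  }
  for (j in seq_len(spec$n_down)) {
    ic <- bc * 2L^(spec$n_down - j + 1)  # 256,128,64,32 at defaults
    oc <- ic %/% 2L
    p[[paste0("dec", j)]] <- list(
      up = list(w = nn_rnorm(c(2, 2, 2, ic, oc), sqrt(2 / (8 * ic))),
                b = numeric(oc)),
      conv1 = init_conv(3, 2 * oc, oc), n1 = init_norm(oc),
      proj = init_conv(1, 2 * oc, oc))
  }
  p$head <- list(conv = init_conv(1, bc, spec$out_channels))
  params <- nn_flatten(p)
  groups <- vapply(names(params), function(nm) {
    if (startsWith(nm, "stem") || startsWith(nm, "enc")) return("encoder")
    if (startsWith(nm, "head")) return("head")
    j <- as.integer(sub("^dec([0-9]+)\\..*$", "\\1", nm))
    if (j > spec$n_down - 2) "bottom_two" else "decoder"
  }, character(1))
  trainable <- stats::setNames(rep(TRUE, length(params)), names(params))
  structure(list(arch = "unet", spec = spec, params = params,
                 groups = groups, trainable = trainable),
            class = c("unet_model", "seg_model"))
}

unet_res_down_fwd <- function(params, prefix, x, stride, cache) {
  pc1 <- getp(params, paste0(prefix, ".conv1"))
  pn1 <- getp(params, paste0(prefix, ".n1"))
  pc2 <- getp(params, paste0(prefix, ".conv2"))
  pn2 <- getp(params, paste0(prefix, ".n2"))
  ppj <- getp(params, paste0(prefix, ".proj"))
  if (!cache) {
    # inference path: minimal live copies
    a <- relu_fwd(inorm_infer(conv3d_fwd(x, pc1, stride = stride, pad = 1L),
                              pn1))
    a <- relu_fwd(inorm_infer(conv3d_fwd(a, pc2, stride = 1L, pad = 1L),
                              pn2))
    y <- a + conv3d_fwd(x, ppj, stride = stride, pad = 0L)
    return(list(y = y, cache = NULL))
  }
  a <- conv3d_fwd(x, pc1, stride = stride, pad = 1L)
  n1 <- inorm_fwd(a, pn1)
  r1 <- relu_fwd(n1$y)
  c2 <- conv3d_fwd(r1, pc2, stride = 1L, pad = 1L)
  n2 <- inorm_fwd(c2, pn2)
  r2 <- relu_fwd(n2$y)
  sc <- conv3d_fwd(x, ppj, stride = stride, pad = 0L)
  y <- r2 + sc
  list(y = y, cache = if (cache) list(x = x, a = a, n1 = n1, r1 = r1,
                                      c2 = c2, n2 = n2) else NULL)
}

unet_res_down_bwd <- function(params, prefix, cache, dy, stride, grads) {
  pc1 <- getp(params, paste0(prefix, ".conv1"))
  pn1 <- getp(params, paste0(prefix, ".n1"))
  pc2 <- getp(params, paste0(prefix, ".conv2"))
  pn2 <- getp(params, paste0(prefix, ".n2"))
  ppj <- getp(params, paste0(prefix, ".proj"))
  bpj <- conv3d_bwd(cache$x, ppj, dy, stride = stride, pad = 0L)
  dr2 <- relu_bwd(cache$n2$y, dy)
  bn2 <- inorm_bwd(cache$n2, pn2, dr2)
  bc2 <- conv3d_bwd(cache$r1, pc2, bn2$dx, stride = 1L, pad = 1L)
  dr1 <- relu_bwd(cache$n1$y, bc2$dx)
  bn1 <- inorm_bwd(cache$n1, pn1, dr1)
  bc1 <- conv3d_bwd(cache$x, pc1, bn1$dx, stride = stride, pad = 1L)
  grads <- setg(grads, prefix, list(
    conv1 = list(w = bc1$dw, b = bc1$db), n1 = list(g = bn1$dg, b = bn1$db),
    conv2 = list(w = bc2$dw, b = bc2$db), n2 = list(g = bn2$dg, b = bn2$db),
    proj = list(w = bpj$dw, b = bpj$db)))
  list(dx = bc1$dx + bpj$dx, grads = grads)
}

concat4 <- function(a, b) {
  d <- dim(a)
  db <- dim(b)
  y <- array(0, c(d[1:3], d[4] + db[4]))
  y[, , , seq_len(d[4])] <- a
  y[, , , d[4] + seq_len(db[4])] <- b
  y
}

#' @noRd
unet_forward <- function(model, x, cache = FALSE) {
  params <- model$params
  spec <- model$spec
  shapes <- list()
  cc <- if (cache) list() else NULL
  ps <- getp(params, "stem.conv")
  pn <- getp(params, "stem.n")
  a0 <- conv3d_fwd(x, ps, stride = 1L, pad = 1L)
  n0 <- inorm_fwd(a0, pn)
  s0 <- relu_fwd(n0$y)
  if (cache) cc$stem <- list(x = x, a0 = a0, n0 = n0)
  shapes$stem <- dim(s0)
  skips <- list(s0)
  h <- s0
  for (i in seq_len(spec$n_down)) {
    blk <- unet_res_down_fwd(params, paste0("enc", i), h, 2L, cache)
    h <- blk$y
    shapes[[paste0("enc", i)]] <- dim(h)
    if (i < spec$n_down) skips[[i + 1]] <- h
    if (cache) cc[[paste0("enc", i)]] <- blk$cache
  }
  shapes$bottleneck <- dim(h)
  for (j in seq_len(spec$n_down)) {
    pre <- paste0("dec", j)
    pup <- getp(params, paste0(pre, ".up"))
    pc1 <- getp(params, paste0(pre, ".conv1"))
    pn1 <- getp(params, paste0(pre, ".n1"))
    ppj <- getp(params, paste0(pre, ".proj"))
    up <- tconv3d_fwd(h, pup)
    sk <- skips[[spec$n_down - j + 1]]
    ct <- concat4(up, sk)
    c1 <- conv3d_fwd(ct, pc1, stride = 1L, pad = 1L)
    n1 <- inorm_fwd(c1, pn1)
    r1 <- relu_fwd(n1$y)
    sc <- conv3d_fwd(ct, ppj, stride = 1L, pad = 0L)
    hnew <- r1 + sc
    if (cache) cc[[pre]] <- list(hin = h, ct = ct, c1 = c1, n1 = n1)
    h <- hnew
    shapes[[pre]] <- dim(h)
  }
  ph <- getp(params, "head.conv")
  y <- conv3d_fwd(h, ph, stride = 1L, pad = 0L)
  if (cache) cc$head <- list(hin = h)
  shapes$out <- dim(y)
  list(y = y, shapes = shapes, cache = cc)
}

#' @noRd
unet_backward <- function(model, cache, dy) {
  params <- model$params
  spec <- model$spec
  grads <- list()
  ph <- getp(params, "head.conv")
  bh <- conv3d_bwd(cache$head$hin, ph, dy, stride = 1L, pad = 0L)
  grads <- setg(grads, "head", list(conv = list(w = bh$dw, b = bh$db)))
  dh <- bh$dx
  dskips <- vector("list", spec$n_down)  # gradient w.r.t. each skip
  for (j in rev(seq_len(spec$n_down))) {
    pre <- paste0("dec", j)
    pup <- getp(params, paste0(pre, ".up"))
    pc1 <- getp(params, paste0(pre, ".conv1"))
    pn1 <- getp(params, paste0(pre, ".n1"))
    ppj <- getp(params, paste0(pre, ".proj"))
    cc <- cache[[pre]]
    bpj <- conv3d_bwd(cc$ct, ppj, dh, stride = 1L, pad = 0L)
    dr1 <- relu_bwd(cc$n1$y, dh)
    bn1 <- inorm_bwd(cc$n1, pn1, dr1)
    bc1 <- conv3d_bwd(cc$ct, pc1, bn1$dx, stride = 1L, pad = 1L)
    dct <- bc1$dx + bpj$dx
    ocu <- dim(cc$hin)[4] %/% 2L  # up channels
    dup <- dct[, , , seq_len(ocu), drop = FALSE]
    dsk <- dct[, , , ocu + seq_len(dim(dct)[4] - ocu), drop = FALSE]
    dskips[[spec$n_down - j + 1]] <- dsk
    bup <- tconv3d_bwd(cc$hin, pup, dup)
    grads <- setg(grads, pre, list(
      up = list(w = bup$dw, b = bup$db),
      conv1 = list(w = bc1$dw, b = bc1$db),
      n1 = list(g = bn1$dg, b = bn1$db),
      proj = list(w = bpj$dw, b = bpj$db)))
    dh <- bup$dx
  }
  for (i in rev(seq_len(spec$n_down))) {
    if (i < spec$n_down) dh <- dh + dskips[[i + 1]]
    blk <- unet_res_down_bwd(params, paste0("enc", i),
                             cache[[paste0("enc", i)]], dh, 2L, grads)
    grads <- blk$grads
    dh <- blk$dx
  }
  dh <- dh + dskips[[1]]
  ps <- getp(params, "stem.conv")
  pn <- getp(params, "stem.n")
  dr0 <- relu_bwd(cache$stem$n0$y, dh)
  bn0 <- inorm_bwd(cache$stem$n0, pn, dr0)
  bc0 <- conv3d_bwd(cache$stem$x, ps, bn0$dx, stride = 1L, pad = 1L)
  grads <- setg(grads, "stem", list(conv = list(w = bc0$dw, b = bc0$db),
                                    n = list(g = bn0$dg, b = bn0$db)))
  grads
}
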