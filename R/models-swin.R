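#' Swin-transformer segmentation model specification
#'
#' Describes the Swin-UNETR-style network: a stride-2 patch embedding to
#' `embed_dim` channels followed by four patch-merging stages (each doubling
#' channels and halving every spatial dimension), every stage carrying a
#' windowed-attention pair (W-MSA then SW-MSA, each wrapped in layer norm and
#' an MLP).  At the defaults (`embed_dim = 48`, input 128x128x64) the
#' bottleneck feature map is 768x4x4x2.  The decoder has five blocks of
#' {stride-2 transposed convolution; concatenation with the encoder feature
#' passed through a residual convolution sub-block; residual convolution
#' sub-block}, ending in a 48x128x128x64 feature and a final 1x1x1
#' convolution to `out_channels`.
#'
#' `embed_dim` is the scale knob; the channel ladder ends at
#' `embed_dim * 16`.
#'
#' @param embed_dim Channels after patch embedding (default 48; ladder ends
#'   at `16 * embed_dim`).
#' @param input_shape Integer length-3 spatial shape, multiples of 32.
#' @param window_size In-plane/through-plane attention window (clipped to the
#'   stage resolution where needed).
#' @param mlp_ratio Hidden width multiplier of the transformer MLPs.
#' @param in_channels,out_channels Input image channels and output classes.
#' @return An object of class `swin_spec`.
#' @export
swin_spec <- function(embed_dim = 48L, input_shape = c(128L, 128L, 64L),
                      window_size = 4L, mlp_ratio = 2L,
                      in_channels = 1L, out_channels = 2L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3 || any(input_shape %% 32 != 0)) {
    stop("input dimensions must be multiples of 32, got (",
         paste(input_shape, collapse = ", "), ")")
  }
  structure(list(embed_dim = as.integer(embed_dim),
                 input_shape = input_shape,
                 window_size = as.integer(window_size),
                 mlp_ratio = as.integer(mlp_ratio),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_encoder_blocks = 5L, n_decoder_blocks = 5L,
                 decoder_feature_channels = as.integer(embed_dim),
                 bottleneck_channels = as.integer(embed_dim) * 16L),
            class = "swin_spec")
}

#' Closed-form shape ladder of a Swin spec
#'
#' @param spec A [swin_spec()].
#' @return A tibble with one row per encoder stage (stage 0 is the patch
#'   embedding) giving channels and spatial shape.
#' @export
swin_ladder <- function(spec) {
  stages <- 0:4
  tibble::tibble(
    stage = stages,
    channels = spec$embed_dim * 2L^stages,
    x = spec$input_shape[1] %/% 2L^(stages + 1),
    y = spec$input_shape[2] %/% 2L^(stages + 1),
    z = spec$input_shape[3] %/% 2L^(stages + 1)
  )
}

space_to_depth <- function(x4, f = 2L) {
  d <- dim(x4)
  out <- array(0, c(d[1] %/% f, d[2] %/% f, d[3] %/% f, d[4] * f^3))
  o <- 0L
  for (dz in seq_len(f)) for (dy in seq_len(f)) for (dx in seq_len(f)) {
    out[, , , o * d[4] + seq_len(d[4])] <-
      x4[seq(dx, d[1], by = f), seq(dy, d[2], by = f),
         seq(dz, d[3], by = f), , drop = FALSE]
    o <- o + 1L
  }
  out
}

depth_to_space <- function(y4, f = 2L, c_in) {
  d <- dim(y4)
  out <- array(0, c(d[1] * f, d[2] * f, d[3] * f, c_in))
  o <- 0L
  for (dz in seq_len(f)) for (dy in seq_len(f)) for (dx in seq_len(f)) {
    out[seq(dx, d[1] * f, by = f), seq(dy, d[2] * f, by = f),
        seq(dz, d[3] * f, by = f), ] <-
      y4[, , , o * c_in + seq_len(c_in), drop = FALSE]
    o <- o + 1L
  }
  out
}

swin_heads <- function(c_) max(1L, c_ %/% 24L)

#' Build a Swin-transformer segmentation network
#'
#' Parameter groups: `encoder` is the transformer part (patch embedding +
#' attention stages) — the part frozen by the self-supervised downstream
#' protocol; `decoder` covers the full-resolution stem, the skip residual
#' sub-blocks and the three deepest decoder blocks; `bottom_two` the two
#' decoder blocks nearest the output; `head` the final convolution.
#'
#' @param spec A [swin_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `seg_model` handle.
#' @export
build_swin_unetr <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "swin_spec"))
  set.seed(seed)
  ed <- spec$embed_dim
  p <- list()
  # full-resolution residual stem (first skip)
  p$stem <- list(conv1 = init_conv(3, spec$in_channels, ed), n1 = init_norm(ed),
                 conv2 = init_conv(3, ed, ed), n2 = init_norm(ed),
                 proj = init_conv(1, spec$in_channels, ed))
  p$patch_embed <- init_linear(8 * spec$in_channels, ed, sd = 0.02)
  for (i in 0:4) {
    ci <- ed * 2L^i
    st <- list()
    if (i > 0) st$merge <- init_linear(8L * (ci %/% 2L), ci, sd = 0.02)
    st$b1 <- init_swin_block(ci, spec$mlp_ratio)
    st$b2 <- init_swin_block(ci, spec$mlp_ratio)
    p[[paste0("stage", i)]] <- st
  }
  for (i in 0:3) {
    ci <- ed * 2L^i
    p[[paste0("skip", i)]] <- list(
      conv1 = init_conv(3, ci, ci), n1 = init_norm(ci),
      conv2 = init_conv(3, ci, ci), n2 = init_norm(ci),
      proj = init_conv(1, ci, ci))
  }
  for (j in 1:5) {
    ic <- if (j == 5) ed else ed * 2L^(5 - j)     # 768,384,192,96,48
    oc <- if (j == 5) ed else ic %/% 2L
    p[[paste0("dec", j)]] <- list(
      up = list(w = nn_rnorm(c(2, 2, 2, ic, oc), sqrt(2 / (8 * ic))),
                b = numeric(oc)),
      conv1 = init_conv(3, 2 * oc, oc), n1 = init_norm(oc),
      conv2 = init_conv(3, oc, oc), n2 = init_norm(oc),
      proj = init_conv(1, 2 * oc, oc))
  }
  p$head <- list(conv = init_conv(1, ed, spec$out_channels))
  params <- nn_flatten(p)
  groups <- vapply(names(params), function(nm) {
    if (startsWith(nm, "patch_embed") || startsWith(nm, "stage")) {
      return("encoder")
    }
    if (startsWith(nm, "head")) return("head")
    if (startsWith(nm, "dec4") || startsWith(nm, "dec5")) return("bottom_two")
    "decoder"
  }, character(1))
  trainable <- stats::setNames(rep(TRUE, length(params)), names(params))
  structure(list(arch = "swin", spec = spec, params = params,
                 groups = groups, trainable = trainable),
            class = c("swin_model", "seg_model"))
}

# Residual convolution sub-block: conv-IN-ReLU-conv-IN-ReLU + 1x1 projection.
res_block_fwd <- function(params, prefix, x, cache) {
  unet_res_down_fwd(params, prefix, x, 1L, cache)
}

res_block_bwd <- function(params, prefix, cache, dy, grads) {
  unet_res_down_bwd(params, prefix, cache, dy, 1L, grads)
}

patch_embed_fwd <- function(params, x, ed, cache) {
  s2d <- space_to_depth(x, 2L)
  d <- dim(s2d)
  tok <- matrix(s2d, prod(d[1:3]), d[4])
  pe <- getp(params, "patch_embed")
  emb <- linear_fwd(tok, pe)
  y <- array(emb, c(d[1:3], ed))
  list(y = y, cache = if (cache) list(tok = tok, d = d) else NULL)
}

#' @noRd
swin_encoder_forward <- function(model, x, cache = FALSE) {
  spec <- model$spec
  params <- model$params
  win <- rep(spec$window_size, 3)
  cc <- if (cache) list() else NULL
  shapes <- list()
  pe <- patch_embed_fwd(params, x, spec$embed_dim, cache)
  h <- pe$y
  if (cache) cc$patch_embed <- pe$cache
  feats <- list()
  for (i in 0:4) {
    ci <- spec$embed_dim * 2L^i
    pre <- paste0("stage", i)
    if (i > 0) {
      s2d <- space_to_depth(h, 2L)
      d <- dim(s2d)
      tokm <- matrix(s2d, prod(d[1:3]), d[4])
      pm <- getp(params, paste0(pre, ".merge"))
      mg <- linear_fwd(tokm, pm)
      if (cache) cc[[paste0(pre, ".mergecache")]] <- list(tokm = tokm, d = d)
      h <- array(mg, c(d[1:3], ci))
    }
    heads <- swin_heads(ci)
    b1 <- swin_block_fwd(h, nn_sub(params, paste0(pre, ".b1")), win, heads,
                         shift = FALSE, cache = cache)
    b2 <- swin_block_fwd(b1$y, nn_sub(params, paste0(pre, ".b2")), win, heads,
                         shift = TRUE, cache = cache)
    if (cache) {
      cc[[paste0(pre, ".b1")]] <- b1$cache
      cc[[paste0(pre, ".b2")]] <- b2$cache
    }
    h <- b2$y
    feats[[i + 1]] <- h
    shapes[[pre]] <- dim(h)
  }
  list(bottleneck = h, feats = feats, shapes = shapes, cache = cc)
}

#' @noRd
swin_encoder_backward <- function(model, cache, dfeats) {
  # dfeats: list of gradients w.r.t. each stage output (stage0..stage4)
  spec <- model$spec
  params <- model$params
  grads <- list()
  dh <- dfeats[[5]]
  for (i in 4:0) {
    ci <- spec$embed_dim * 2L^i
    pre <- paste0("stage", i)
    heads <- swin_heads(ci)
    if (i < 4 && !is.null(dfeats[[i + 1]])) dh <- dh + dfeats[[i + 1]]
    b2 <- swin_block_bwd(cache[[paste0(pre, ".b2")]],
                         nn_sub(params, paste0(pre, ".b2")), heads, dh)
    grads <- setg(grads, paste0(pre, ".b2"), b2$grads)
    b1 <- swin_block_bwd(cache[[paste0(pre, ".b1")]],
                         nn_sub(params, paste0(pre, ".b1")), heads, b2$dx)
    grads <- setg(grads, paste0(pre, ".b1"), b1$grads)
    dh <- b1$dx
    if (i > 0) {
      mc <- cache[[paste0(pre, ".mergecache")]]
      pm <- getp(params, paste0(pre, ".merge"))
      dmg <- matrix(dh, prod(mc$d[1:3]), ci)
      lb <- linear_bwd(mc$tokm, pm, dmg)
      grads <- setg(grads, pre, list(merge = list(w = lb$dw, b = lb$db)))
      ds2d <- array(lb$dx, mc$d)
      dh <- depth_to_space(ds2d, 2L, mc$d[4] %/% 8L)
    }
  }
  # through patch embedding
  pc <- cache$patch_embed
  pe <- getp(params, "patch_embed")
  demb <- matrix(dh, prod(pc$d[1:3]), spec$embed_dim)
  lb <- linear_bwd(pc$tok, pe, demb)
  grads <- setg(grads, "", list(patch_embed = list(w = lb$dw, b = lb$db)))
  ds2d <- array(lb$dx, pc$d)
  dx <- depth_to_space(ds2d, 2L, pc$d[4] %/% 8L)
  list(dx = dx, grads = grads)
}

#' @noRd
swin_forward <- function(model, x, cache = FALSE) {
  spec <- model$spec
  params <- model$params
  cc <- if (cache) list() else NULL
  st <- res_block_fwd(params, "stem", x, cache)
  f0 <- st$y
  if (cache) cc$stem <- st$cache
  rm(st)
  enc <- swin_encoder_forward(model, x, cache)
  if (cache) cc$enc <- enc$cache
  shapes <- enc$shapes
  shapes$stem <- dim(f0)
  shapes$bottleneck <- dim(enc$bottleneck)
  h <- enc$bottleneck
  for (j in 1:5) {
    pre <- paste0("dec", j)
    pup <- getp(params, paste0(pre, ".up"))
    up <- tconv3d_fwd(h, pup)
    hin <- h
    if (!cache) hin <- NULL
    h <- NULL
    if (j < 5) {
      si <- 4 - j  # stage index of the skip
      sp <- res_block_fwd(params, paste0("skip", si), enc$feats[[si + 1]],
                          cache)
      skp <- sp$y
      if (cache) cc[[paste0("skipc", si)]] <- sp$cache
      if (!cache) enc$feats[si + 1] <- list(NULL)
    } else {
      skp <- f0
      if (!cache) f0 <- NULL
    }
    ct <- concat4(up, skp)
    rm(up, skp)
    rb <- res_block_fwd(params, pre, ct, cache)
    if (cache) cc[[pre]] <- list(hin = hin, ct = ct, rb = rb$cache)
    rm(ct)
    h <- rb$y
    rm(rb)
    shapes[[pre]] <- dim(h)
    if (!cache) gc(FALSE)
  }
  ph <- getp(params, "head.conv")
  y <- conv3d_fwd(h, ph, stride = 1L, pad = 0L)
  if (cache) cc$head <- list(hin = h)
  shapes$out <- dim(y)
  list(y = y, shapes = shapes, cache = cc)
}

#' @noRd
swin_backward <- function(model, cache, dy) {
  spec <- model$spec
  params <- model$params
  grads <- list()
  ph <- getp(params, "head.conv")
  bh <- conv3d_bwd(cache$head$hin, ph, dy, stride = 1L, pad = 0L)
  grads <- setg(grads, "head", list(conv = list(w = bh$dw, b = bh$db)))
  dh <- bh$dx
  dfeats <- vector("list", 5)
  dstem <- NULL
  for (j in 5:1) {
    pre <- paste0("dec", j)
    cc <- cache[[pre]]
    rb <- res_block_bwd(params, pre, cc$rb, dh, grads)
    grads <- rb$grads
    dct <- rb$dx
    ocu <- dim(cc$hin)[4]
    ocu <- if (j == 5) spec$embed_dim else ocu %/% 2L
    dup <- dct[, , , seq_len(ocu), drop = FALSE]
    dskp <- dct[, , , ocu + seq_len(dim(dct)[4] - ocu), drop = FALSE]
    if (j < 5) {
      si <- 4 - j
      sb <- res_block_bwd(params, paste0("skip", si),
                          cache[[paste0("skipc", si)]], dskp, grads)
      grads <- sb$grads
      dfeats[[si + 1]] <- sb$dx
    } else {
      dstem <- dskp
    }
    pup <- getp(params, paste0(pre, ".up"))
    bup <- tconv3d_bwd(cc$hin, pup, dup)
    grads <- setg(grads, pre, list(up = list(w = bup$dw, b = bup$db)))
    dh <- bup$dx
  }
  dfeats[[5]] <- dh
  eb <- swin_encoder_backward(model, cache$enc, dfeats)
  grads <- acc_grads(grads, eb$grads)
  sb <- res_block_bwd(params, "stem", cache$stem, dstem, grads)
  grads <- sb$grads
  dx <- eb$dx + sb$dx
  list(dx = dx, grads = grads)
}
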