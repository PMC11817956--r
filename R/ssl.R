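# Self-supervised pretext task: dual-view cutout corruption, contrastive +
# L1 reconstruction loss, and the frozen-encoder downstream protocol.
#
# Two corrupted views of each unlabeled volume are built by replacing
# rectangular regions with noise — view 1 cuts the image interior (6 crops,
# 5..32 px per side), view 2 the outer border band (6 crops, 20..64 px).
# Both views pass through the transformer encoder; spatially pooled
# bottleneck features go through a small projection head and a
# normalized-temperature contrastive loss ties the two views of the same
# volume together against in-batch negatives, while a light reconstruction
# head decodes view 2 back to the uncorrupted volume under an L1 penalty.

#' Cutout corruption specification
#'
#' @param mode `"inner"` (crops drawn from the central half of each slice
#'   extent) or `"outer"` (crops intersecting the border band, the outer
#'   quarter).
#' @param min_size,max_size Crop side range in pixels (defaults: inner 5-32,
#'   outer 20-64).
#' @param n_crops Number of rectangles per view (default 6).
#' @param seed Integer seed.
#' @return A list of class `cutout_spec`.
#' @export
cutout_spec <- function(mode = c("inner", "outer"), min_size = NULL,
                        max_size = NULL, n_crops = 6L, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(min_size)) min_size <- if (mode == "inner") 5L else 20L
  if (is.null(max_size)) max_size <- if (mode == "inner") 32L else 64L
  stopifnot(min_size <= max_size, n_crops >= 0)
  structure(list(mode = mode, min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 n_crops = as.integer(n_crops), seed = as.integer(seed)),
            class = "cutout_spec")
}

#' Corrupt a volume with rectangular cutouts
#'
#' Exactly `n_crops` rectangles are replaced by uniform noise over the
#' volume's observed intensity range; every voxel outside the rectangles is
#' bit-identical to the input.  Rectangle sides are uniform in
#' `[min_size, max_size]`; the same in-plane rectangle is replicated across
#' a randomly chosen contiguous slab of slices so the corruption is
#' three-dimensional.
#'
#' @param volume 3D numeric array.
#' @param spec A [cutout_spec()].
#' @return The corrupted volume.
#' @export
make_cutout_view <- function(volume, spec) {
  stopifnot(inherits(spec, "cutout_spec"))
  d <- dim(volume)
  if (any(d[1:2] < spec$max_size)) {
    stop("volume in-plane extent (", d[1], "x", d[2],
         ") is smaller than the maximum crop size ", spec$max_size)
  }
  if (spec$n_crops == 0L) return(volume)
  set.seed(spec$seed)
  rng <- range(volume)
  if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1
  for (cr in seq_len(spec$n_crops)) {
    sx <- sample(spec$min_size:spec$max_size, 1)
    sy <- sample(spec$min_size:spec$max_size, 1)
    if (spec$mode == "inner") {
      # fully inside the central half of each in-plane extent
      lo1 <- floor(d[1] / 4) + 1L; hi1 <- floor(3 * d[1] / 4)
      lo2 <- floor(d[2] / 4) + 1L; hi2 <- floor(3 * d[2] / 4)
      sx <- min(sx, hi1 - lo1 + 1L)
      sy <- min(sy, hi2 - lo2 + 1L)
      x0 <- if (hi1 - sx + 1L > lo1) sample(lo1:(hi1 - sx + 1L), 1) else lo1
      y0 <- if (hi2 - sy + 1L > lo2) sample(lo2:(hi2 - sy + 1L), 1) else lo2
    } else {
      # must intersect the border band (outer quarter)
      band <- function(x0, y0) {
        x1 <- x0 + sx - 1L; y1 <- y0 + sy - 1L
        x0 <= floor(d[1] / 4) || x1 > floor(3 * d[1] / 4) ||
          y0 <= floor(d[2] / 4) || y1 > floor(3 * d[2] / 4)
      }
      repeat {
        x0 <- sample(seq_len(d[1] - sx + 1L), 1)
        y0 <- sample(seq_len(d[2] - sy + 1L), 1)
        if (band(x0, y0)) break
      }
    }
    zlen <- sample(seq_len(max(1L, d[3] %/% 2L)), 1)
    z0 <- sample(seq_len(d[3] - zlen + 1L), 1)
    noise <- stats::runif(sx * sy * zlen, rng[1], rng[2])
    volume[x0:(x0 + sx - 1L), y0:(y0 + sy - 1L),
           z0:(z0 + zlen - 1L)] <- noise
  }
  volume
}

# Cutout size defaults are stated for the canonical 128x128 in-plane extent;
# for smaller (desk-scale) volumes they shrink proportionally.
scaled_cutout_spec <- function(mode, inplane, seed) {
  f <- min(inplane) / 128
  if (mode == "inner") {
    cutout_spec("inner", min_size = max(2L, round(5 * f)),
                max_size = max(3L, round(32 * f)), seed = seed)
  } else {
    cutout_spec("outer", min_size = max(3L, round(20 * f)),
                max_size = max(4L, min(round(64 * f), min(inplane))),
                seed = seed)
  }
}

# Row-normalize, compute the similarity matrix, and return loss + gradients.
contrastive_core <- function(z1, z2, temperature) {
  n <- nrow(z1)
  z <- rbind(z1, z2)
  nz <- sqrt(rowSums(z * z))
  nz[nz == 0] <- 1e-12
  u <- z / nz
  s <- tcrossprod(u) / temperature
  diag(s) <- -Inf
  pair <- c((n + 1):(2 * n), 1:n)
  p <- softmax_rows(s)
  loss <- -mean(log(p[cbind(seq_len(2 * n), pair)] + 1e-300))
  # dL/ds = (P - onehot(pair)) / 2N
  ds <- p / (2 * n)
  ds[cbind(seq_len(2 * n), pair)] <- ds[cbind(seq_len(2 * n), pair)] -
    1 / (2 * n)
  ds[!is.finite(ds)] <- 0
  du <- (ds + t(ds)) %*% u / temperature
  # back through row normalization
  dz <- (du - u * rowSums(du * u)) / nz
  list(loss = loss, dz1 = dz[seq_len(n), , drop = FALSE],
       dz2 = dz[(n + 1):(2 * n), , drop = FALSE])
}

#' Normalized-temperature contrastive loss over matched embedding batches
#'
#' Row `i` of `z1` and row `i` of `z2` are the two views of the same volume;
#' all other rows act as in-batch negatives.  Embeddings are L2-normalized,
#' similarities divided by `temperature`, and each view's matched partner is
#' scored against the other `2N - 2` candidates with a softmax
#' cross-entropy, averaged over all `2N` anchors.  When all embeddings are
#' identical the loss equals `log(2N - 1)`.
#'
#' @param z1,z2 Numeric matrices (N x d) with equal dimensions, N >= 2.
#' @param temperature Positive softmax temperature (default 0.5).
#' @return The scalar loss.
#' @export
contrastive_loss <- function(z1, z2, temperature = 0.5) {
  if (!is.matrix(z1)) z1 <- rbind(z1)
  if (!is.matrix(z2)) z2 <- rbind(z2)
  stopifnot(all(dim(z1) == dim(z2)), temperature > 0)
  if (nrow(z1) < 2) {
    stop("contrastive loss needs a batch of at least 2 (no negatives otherwise)")
  }
  contrastive_core(z1, z2, temperature)$loss
}

#' Mean absolute reconstruction error
#'
#' @param recon,original Arrays of identical shape.
#' @return Scalar mean |recon - original|; zero iff equal.
#' @export
reconstruction_l1 <- function(recon, original) {
  if (!identical(dim(recon), dim(original))) {
    stop("shape mismatch between reconstruction and original")
  }
  mean(abs(recon - original))
}

#' Combined pretext loss
#'
#' @param contrastive Contrastive term.
#' @param l1 Reconstruction term.
#' @param lambda Weight on the L1 term (default 1).
#' @return `contrastive + lambda * l1`.
#' @export
combined_loss <- function(contrastive, l1, lambda = 1) {
  contrastive + lambda * l1
}

# ---- pretext model ---------------------------------------------------------

#' Build the pretext model: transformer encoder + projection and
#' reconstruction heads
#'
#' @param spec A [swin_spec()] describing the encoder.
#' @param proj_dim Output dimension of the 2-layer projection head.
#' @param seed Integer seed.
#' @return A `pretext_model`.
#' @export
build_pretext_model <- function(spec, proj_dim = 32L, seed = 1L) {
  stopifnot(inherits(spec, "swin_spec"))
  full <- build_swin_unetr(spec, seed = seed)
  enc_names <- names(full$params)[full$groups == "encoder"]
  params <- full$params[enc_names]
  set.seed(derive_seed(seed, 99L))
  ed <- spec$embed_dim
  bc <- 16L * ed
  p <- list()
  p$proj <- list(fc1 = init_linear(bc, bc), fc2 = init_linear(bc, proj_dim))
  chans <- c(bc, bc %/% 2L, bc %/% 4L, bc %/% 8L, ed, ed)
  for (j in 1:5) {
    p[[paste0("recon_up", j)]] <- list(
      w = nn_rnorm(c(2, 2, 2, chans[j], chans[j + 1]),
                   sqrt(2 / (8 * chans[j]))),
      b = numeric(chans[j + 1]))
  }
  p$recon_out <- init_conv(1, ed, 1L)
  params <- c(params, nn_flatten(p))
  groups <- stats::setNames(
    ifelse(names(params) %in% enc_names, "encoder", "head"), names(params))
  structure(list(spec = spec, params = params, groups = groups,
                 proj_dim = as.integer(proj_dim)),
            class = "pretext_model")
}

pretext_encode <- function(model, volume, cache = FALSE) {
  x <- volume
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  enc <- swin_encoder_forward(model, x, cache = cache)
  b <- enc$bottleneck
  d <- dim(b)
  nvox <- prod(d[1:3])
  pooled <- colSums(matrix(b, nvox, d[4])) / nvox
  list(enc = enc, bottleneck = b, pooled = pooled, nvox = nvox, bdim = d)
}

pretext_project <- function(params, pooled, cache = FALSE) {
  p1 <- getp(params, "proj.fc1")
  p2 <- getp(params, "proj.fc2")
  h <- linear_fwd(rbind(pooled), p1)
  r <- relu_fwd(h)
  z <- linear_fwd(r, p2)
  list(z = drop(z), cache = if (cache) list(pooled = pooled, h = h, r = r)
       else NULL)
}

pretext_project_bwd <- function(params, cache, dz, grads) {
  p1 <- getp(params, "proj.fc1")
  p2 <- getp(params, "proj.fc2")
  l2 <- linear_bwd(cache$r, p2, rbind(dz))
  dr <- relu_bwd(cache$h, l2$dx)
  l1 <- linear_bwd(rbind(cache$pooled), p1, dr)
  grads <- setg(grads, "proj", list(fc1 = list(w = l1$dw, b = l1$db),
                                    fc2 = list(w = l2$dw, b = l2$db)))
  list(dpooled = drop(l1$dx), grads = grads)
}

pretext_recon <- function(params, bottleneck, cache = FALSE) {
  h <- bottleneck
  cc <- if (cache) list() else NULL
  for (j in 1:5) {
    pre <- paste0("recon_up", j)
    pup <- getp(params, pre)
    hin <- h
    h <- tconv3d_fwd(h, pup)
    hraw <- h
    h <- relu_fwd(h)
    if (cache) cc[[pre]] <- list(hin = hin, hraw = hraw)
  }
  po <- getp(params, "recon_out")
  y <- conv3d_fwd(h, po, stride = 1L, pad = 0L)
  if (cache) cc$out <- list(hin = h)
  list(y = y, cache = cc)
}

pretext_recon_bwd <- function(params, cache, dy, grads) {
  po <- getp(params, "recon_out")
  bo <- conv3d_bwd(cache$out$hin, po, dy, stride = 1L, pad = 0L)
  grads <- setg(grads, "recon_out", list(w = bo$dw, b = bo$db))
  dh <- bo$dx
  for (j in 5:1) {
    pre <- paste0("recon_up", j)
    pup <- getp(params, pre)
    cc <- cache[[pre]]
    dh <- relu_bwd(cc$hraw, dh)
    bu <- tconv3d_bwd(cc$hin, pup, dh)
    grads <- setg(grads, pre, list(w = bu$dw, b = bu$db))
    dh <- bu$dx
  }
  list(dbottleneck = dh, grads = grads)
}

#' Self-supervised pretraining on unlabeled volumes
#'
#' For every batch, each volume yields an interior-cutout view and an
#' outer-cutout view; pooled bottleneck embeddings of the two views are tied
#' by the contrastive term while the outer view is decoded back to the
#' uncorrupted volume under an L1 penalty.  The combined loss
#' `contrastive + lambda * L1` updates the encoder and both heads.
#' Deterministic for a fixed seed.
#'
#' @param model A `pretext_model` from [build_pretext_model()].
#' @param volumes List of 3D arrays (>= 2, the contrastive term needs
#'   in-batch negatives).
#' @param epochs Training epochs.
#' @param batch_size Volumes per batch (>= 2).
#' @param lr Adam learning rate.
#' @param temperature Contrastive temperature.
#' @param lambda L1 weight.
#' @param seed Master seed.
#' @return A list with the trained `model` and a `history` tibble of
#'   per-epoch mean losses.
#' @export
pretrain <- function(model, volumes, epochs = 5L, batch_size = 2L,
                     lr = 1e-3, temperature = 0.5, lambda = 1, seed = 1L) {
  stopifnot(inherits(model, "pretext_model"))
  if (length(volumes) < 2 || batch_size < 2) {
    stop("pretraining needs at least 2 volumes and batch_size >= 2 ",
         "(the contrastive loss has no negatives otherwise)")
  }
  state <- adam_init(model$params)
  trainable <- stats::setNames(rep(TRUE, length(model$params)),
                               names(model$params))
  history <- tibble::tibble(epoch = integer(), loss = numeric())
  step <- 0L
  for (ep in seq_len(epochs)) {
    set.seed(derive_seed(seed, ep))
    ord <- sample(seq_along(volumes))
    losses <- c()
    b0 <- 1L
    while (b0 + 1L <= length(ord)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      b0 <- b0 + batch_size
      if (length(idx) < 2) break
      step <- step + 1L
      n <- length(idx)
      encs1 <- vector("list", n)
      encs2 <- vector("list", n)
      projs1 <- vector("list", n)
      projs2 <- vector("list", n)
      recons <- vector("list", n)
      z1 <- NULL
      z2 <- NULL
      l1s <- numeric(n)
      for (q in seq_len(n)) {
        vol <- volumes[[idx[q]]]
        s1 <- scaled_cutout_spec("inner", dim(vol)[1:2],
                                 seed = derive_seed(seed, step * 1000L + q))
        s2 <- scaled_cutout_spec("outer", dim(vol)[1:2],
                                 seed = derive_seed(seed,
                                                    step * 1000L + 500L + q))
        a1 <- make_cutout_view(vol, s1)
        a2 <- make_cutout_view(vol, s2)
        e1 <- pretext_encode(model, a1, cache = TRUE)
        e2 <- pretext_encode(model, a2, cache = TRUE)
        p1 <- pretext_project(model$params, e1$pooled, cache = TRUE)
        p2 <- pretext_project(model$params, e2$pooled, cache = TRUE)
        rc <- pretext_recon(model$params, e2$bottleneck, cache = TRUE)
        encs1[[q]] <- e1
        encs2[[q]] <- e2
        projs1[[q]] <- p1
        projs2[[q]] <- p2
        recons[[q]] <- rc
        z1 <- rbind(z1, p1$z)
        z2 <- rbind(z2, p2$z)
        l1s[q] <- reconstruction_l1(drop(rc$y), vol)
      }
      con <- contrastive_core(z1, z2, temperature)
      loss <- combined_loss(con$loss, mean(l1s), lambda)
      losses <- c(losses, loss)
      grads <- list()
      for (q in seq_len(n)) {
        vol <- volumes[[idx[q]]]
        # branch 1: contrastive only
        pb1 <- pretext_project_bwd(model$params, projs1[[q]]$cache,
                                   con$dz1[q, ], grads)
        grads <- pb1$grads
        db1 <- array(rep(pb1$dpooled, each = encs1[[q]]$nvox) /
                       encs1[[q]]$nvox, encs1[[q]]$bdim)
        eb1 <- swin_encoder_backward(model, encs1[[q]]$enc$cache,
                                     c(vector("list", 4), list(db1)))
        grads <- acc_grads(grads, eb1$grads)
        # branch 2: contrastive + reconstruction
        pb2 <- pretext_project_bwd(model$params, projs2[[q]]$cache,
                                   con$dz2[q, ], grads)
        grads <- pb2$grads
        drecon <- sign(drop(recons[[q]]$y) - vol) * lambda /
          (length(vol) * n)
        dim(drecon) <- dim(recons[[q]]$y)
        rb <- pretext_recon_bwd(model$params, recons[[q]]$cache, drecon,
                                grads)
        grads <- rb$grads
        db2 <- array(rep(pb2$dpooled, each = encs2[[q]]$nvox) /
                       encs2[[q]]$nvox, encs2[[q]]$bdim) + rb$dbottleneck
        eb2 <- swin_encoder_backward(model, encs2[[q]]$enc$cache,
                                     c(vector("list", 4), list(db2)))
        grads <- acc_grads(grads, eb2$grads)
      }
      upd <- adam_step(model$params, grads, state, trainable, lr = lr)
      model$params <- upd$params
      state <- upd$state
    }
    history <- dplyr::bind_rows(history,
                                tibble::tibble(epoch = ep,
                                               loss = mean(losses)))
  }
  list(model = model, history = history)
}

#' Downstream segmentation training with a frozen pretrained encoder
#'
#' Transplants the pretext encoder weights into a full segmentation network,
#' freezes the encoder (`decoder_only` policy) and trains the decoding path
#' with the soft-Dice segmentation loss on the labeled (typically augmented)
#' cases.
#'
#' @param pretrained A trained `pretext_model` (or the `model` element of a
#'   [pretrain()] result).
#' @param cases Non-empty list of labeled `canonical_case` objects.
#' @param epochs,lr,seed Training schedule.
#' @return The trained `seg_model` (encoder bit-identical to the pretrained
#'   one).
#' @export
downstream_train <- function(pretrained, cases, epochs = 5L, lr = 1e-3,
                             seed = 1L) {
  if (inherits(pretrained, "list") && !is.null(pretrained$model)) {
    pretrained <- pretrained$model
  }
  stopifnot(inherits(pretrained, "pretext_model"))
  if (!length(cases)) stop("downstream training needs a non-empty dataset")
  model <- build_swin_unetr(pretrained$spec, seed = derive_seed(seed, 7L))
  enc_names <- names(model$params)[model$groups == "encoder"]
  model$params[enc_names] <- pretrained$params[enc_names]
  model <- set_trainable(model, "decoder_only")
  fit <- train_model(model, cases, epochs = epochs, lr = lr, seed = seed)
  fit$model
}
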