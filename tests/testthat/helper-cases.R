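# Shared fixtures, built in code: small canonical-style cases with bright
# ellipsoidal lesions on a noisy textured background, mirroring what the
# phantom generator produces at desk scale.

make_lesion_case <- function(seed, shape = c(32L, 32L, 32L), radius = 6,
                             size_class = "large", spacing = 1) {
  set.seed(seed)
  img <- array(stats::runif(prod(shape), 0, 0.3), shape)
  center <- stats::runif(3, -0.15, 0.15) * shape * spacing
  r <- radius * stats::runif(1, 0.8, 1.2)
  d2 <- neuroseg:::ellipsoid_dist2(shape, rep(spacing, 3), center,
                                   c(r, r, r))
  lab <- (d2 <= 1) * 1L
  dim(lab) <- shape
  img[d2 <= 1] <- img[d2 <= 1] + 0.6
  area <- max_slice_area_cm2(lab, spacing)
  neuroseg:::new_canonical_case(img, lab, paste0("case", seed), size_class,
                                area, shape)
}

make_blob_cases <- function(n, seed0 = 100, shape = c(32L, 32L, 32L),
                            radius = 6) {
  lapply(seq_len(n), function(i) make_lesion_case(seed0 + i, shape, radius))
}

tiny_unet_spec <- function(shape = c(32L, 32L, 32L)) {
  unet_spec(base_channels = 4L, input_shape = shape)
}

tiny_swin_spec <- function(shape = c(32L, 32L, 32L)) {
  swin_spec(embed_dim = 6L, input_shape = shape, window_size = 4L)
}

num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
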