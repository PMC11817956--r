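# Geometric training-set augmentation: the four in-plane transforms
# (rotation by +/-20..50 degrees, scaling by 0.6..0.9 or 1.1..1.5, both
# combined, and a fixed 0.4 shear), applied slice-wise with one shared
# parameter draw per case.  Images use bilinear interpolation, labels
# nearest neighbor; out-of-field regions are zero-filled.  Evaluation data
# are never augmented.

augment_kinds <- c("rotate", "scale", "rotate_scale", "shear")

#' Augmentation specification
#'
#' @param kind One of `"rotate"`, `"scale"`, `"rotate_scale"`, `"shear"`.
#' @param seed Integer seed for the parameter draw.
#' @return A list of class `augment_spec`.
#' @export
augment_spec <- function(kind = augment_kinds, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rotate_range_deg = c(20, 50),
                 scale_ranges = rbind(c(0.6, 0.9), c(1.1, 1.5)),
                 shear_amount = 0.4, seed = as.integer(seed)),
            class = "augment_spec")
}

#' Draw transform parameters for an augmentation kind
#'
#' Angles are uniform in magnitude over [20, 50] degrees with a fair-coin
#' sign; scales uniform over [0.6, 0.9] or [1.1, 1.5] with a fair-coin
#' branch (so near-identity scales in (0.9, 1.1) never occur); shear is
#' fixed at 0.4.
#'
#' @param spec An [augment_spec()].
#' @return A list with `kind`, `angle_deg`, `scale`, `shear`.
#' @export
sample_augment_params <- function(spec) {
  stopifnot(inherits(spec, "augment_spec"))
  set.seed(spec$seed)
  angle <- 0
  scale <- 1
  shear <- 0
  if (spec$kind %in% c("rotate", "rotate_scale")) {
    angle <- sample(c(-1, 1), 1) * stats::runif(1, spec$rotate_range_deg[1],
                                                spec$rotate_range_deg[2])
  }
  if (spec$kind %in% c("scale", "rotate_scale")) {
    br <- sample(1:2, 1)
    scale <- stats::runif(1, spec$scale_ranges[br, 1],
                          spec$scale_ranges[br, 2])
  }
  if (spec$kind == "shear") shear <- spec$shear_amount
  list(kind = spec$kind, angle_deg = angle, scale = scale, shear = shear)
}

augment_matrix <- function(params) {
  th <- params$angle_deg * pi / 180
  r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- diag(c(params$scale, params$scale))
  sh <- matrix(c(1, 0, params$shear, 1), 2, 2)
  r %*% s %*% sh
}

# Apply the in-plane affine map (about the slice center) to every slice.
apply_affine_slicewise <- function(image, label, params) {
  d <- dim(image)
  a <- augment_matrix(params)
  ai <- solve(a)
  ci <- (d[1] + 1) / 2
  cj <- (d[2] + 1) / 2
  gi <- matrix(seq_len(d[1]) - ci, d[1], d[2])
  gj <- matrix(seq_len(d[2]) - cj, d[1], d[2], byrow = TRUE)
  qx <- ai[1, 1] * gi + ai[1, 2] * gj + ci
  qy <- ai[2, 1] * gi + ai[2, 2] * gj + cj
  x0 <- floor(qx); y0 <- floor(qy)
  wx <- qx - x0; wy <- qy - y0
  gather <- function(m, ix, iy) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
    out <- numeric(length(ix))
    out[ok] <- m[cbind(ix[ok], iy[ok])]
    out
  }
  img_out <- array(0, d)
  lab_out <- array(0L, d)
  ixn <- round(qx); iyn <- round(qy)
  for (k in seq_len(d[3])) {
    m <- image[, , k]
    v <- gather(m, x0, y0) * (1 - wx) * (1 - wy) +
      gather(m, x0 + 1, y0) * wx * (1 - wy) +
      gather(m, x0, y0 + 1) * (1 - wx) * wy +
      gather(m, x0 + 1, y0 + 1) * wx * wy
    img_out[, , k] <- v
    if (!is.null(label)) {
      lab_out[, , k] <- as.integer(gather(label[, , k], ixn, iyn) >= 0.5)
    }
  }
  list(image = img_out, label = if (is.null(label)) NULL else lab_out)
}

#' Apply one augmentation to a canonical case
#'
#' The same sampled in-plane transform is applied to every slice of the
#' image (bilinear) and label (nearest); the label stays binary and the
#' canonical shape is preserved.
#'
#' @param case A `canonical_case`.
#' @param spec An [augment_spec()]; parameters are drawn from its seed.
#' @return A new `canonical_case` flagged as augmented.
#' @export
apply_augment <- function(case, spec) {
  stopifnot(inherits(case, "canonical_case"))
  if (!inherits(spec, "augment_spec")) stop("unknown augmentation kind")
  params <- sample_augment_params(spec)
  tr <- apply_affine_slicewise(case$image, case$label, params)
  out <- case
  out$image <- tr$image
  out$label <- tr$label
  out$augmented <- TRUE
  out$augment_params <- params
  out
}

#' Expand a training set by augmentation
#'
#' Returns `rate x length(cases)` cases: each original once plus
#' `rate - 1` augmented variants per original, cycling uniformly over the
#' four transform kinds.  Augmented variants inherit their source id so
#' cross-validation can keep them on the training side with their source.
#'
#' @param cases List of `canonical_case` objects.
#' @param rate Integer augmentation rate (>= 1; the studied rates are 1, 4,
#'   8, 16, 32).
#' @param seed Master seed; each variant draws its own derived seed.
#' @return A list of `canonical_case` objects.
#' @export
expand_training_set <- function(cases, rate, seed = 1L) {
  rate <- as.integer(rate)
  if (rate < 1) stop("augmentation rate must be >= 1, got ", rate)
  if (rate == 1L) return(cases)
  out <- vector("list", length(cases) * rate)
  pos <- 1L
  for (i in seq_along(cases)) {
    out[[pos]] <- cases[[i]]
    pos <- pos + 1L
    for (r in seq_len(rate - 1L)) {
      kind <- augment_kinds[((r - 1L) %% 4L) + 1L]
      sp <- augment_spec(kind, seed = derive_seed(seed, i * 1000L + r))
      out[[pos]] <- apply_augment(cases[[i]], sp)
      pos <- pos + 1L
    }
  }
  out
}
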