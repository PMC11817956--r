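# Synthetic brain-phantom generator.
#
# Emulates the two kinds of raw material the pipeline consumes: (a) clinical
# axial T2-FLAIR series with DICOM-style grayscale metadata, polygon tumor
# annotations and optional white-matter-hyperintensity confounders, and (b)
# public-challenge-style labeled volumes with multi-label lesions.  Lesions
# are axis-aligned ellipsoids so the per-slice area (and hence the
# small/large class, threshold 3.5 cm^2) is controlled analytically; the
# background is an ellipsoidal "brain" with low-frequency multiplicative
# texture plus Gaussian noise, enough structure that naive thresholding does
# not solve the segmentation task.

#' Lesion specification
#'
#' @param center_mm Numeric length-3 lesion center, in mm relative to the
#'   volume center.
#' @param radii_mm Positive length-3 ellipsoid semi-axes in mm
#'   (in-plane x, in-plane y, through-plane z).
#' @param intensity_boost Multiplier (> 1) applied to background tissue
#'   intensity inside the lesion.
#' @param size_class `"small"` or `"large"`: small lesions have a maximum
#'   per-slice area below 3.5 cm^2, large ones at or above it.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm = c(0, 0, 0), radii_mm = c(6, 6, 6),
                        intensity_boost = 1.8,
                        size_class = c("small", "large")) {
  size_class <- match.arg(size_class)
  stopifnot(length(radii_mm) == 3, all(radii_mm > 0), intensity_boost > 1)
  structure(list(center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 intensity_boost = intensity_boost,
                 size_class = size_class),
            class = "lesion_spec")
}

phantom_slice_set <- c(24L, 25L, 47L, 48L, 49L, 50L, 51L)

#' Phantom specification
#'
#' Defines one synthetic clinical-style case.  Defaults mirror the emulated
#' acquisition: 256x256 in-plane matrix at 0.9 mm pixel spacing (a realistic
#' head-MRI value that puts a ~1.1 cm^2 lesion at roughly 13 pixels across),
#' slice counts drawn from {47..51} with a minority of thin stacks at 24-25,
#' and 12-bit stored pixel values related to physical intensity through a
#' rescale slope/intercept pair, windowed by a center/width pair.
#'
#' @param in_plane Square in-plane matrix size in pixels.
#' @param n_slices Number of axial slices; one of 24, 25, 47..51.
#' @param pixel_spacing_mm,slice_thickness_mm Voxel geometry in mm.
#' @param lesions List of [lesion_spec()] objects (possibly empty).
#' @param hyperintensity_count Number of bright non-tumor speckles to add.
#' @param noise_sd Additive Gaussian noise, in physical intensity units
#'   (background tissue is ~600 units).
#' @param rescale_slope,rescale_intercept Stored-value to physical-value
#'   affine map: physical = slope * stored + intercept.
#' @param window_center,window_width Display window in physical units.
#' @param seed Integer seed; equal seeds give bit-identical cases.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(in_plane = 256L, n_slices = 48L,
                         pixel_spacing_mm = 0.9, slice_thickness_mm = 3.0,
                         lesions = list(), hyperintensity_count = 0L,
                         noise_sd = 20, rescale_slope = 2,
                         rescale_intercept = -100, window_center = 600,
                         window_width = 1200, seed = 1L) {
  n_slices <- as.integer(n_slices)
  if (!n_slices %in% phantom_slice_set) {
    stop("n_slices must be one of {", paste(phantom_slice_set, collapse = ", "),
         "}, got ", n_slices)
  }
  stopifnot(pixel_spacing_mm > 0, slice_thickness_mm > 0, window_width > 0,
            rescale_slope > 0, noise_sd >= 0, hyperintensity_count >= 0)
  structure(list(in_plane = as.integer(in_plane), n_slices = n_slices,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm, lesions = lesions,
                 hyperintensity_count = as.integer(hyperintensity_count),
                 noise_sd = noise_sd, rescale_slope = rescale_slope,
                 rescale_intercept = rescale_intercept,
                 window_center = window_center, window_width = window_width,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized ellipsoid distance on the voxel grid (mm coordinates
# relative to the volume center).
ellipsoid_dist2 <- function(dims, spacing, center_mm, radii_mm) {
  cx <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * spacing[1]
  cy <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * spacing[2]
  cz <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / radii_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / radii_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / radii_mm[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}

# Low-frequency multiplicative texture: a few random plane waves.
phantom_texture <- function(dims, n_waves = 4, amp = 0.05) {
  tex <- array(0, dims)
  ii <- seq_len(dims[1]) / dims[1]
  jj <- seq_len(dims[2]) / dims[2]
  kk <- seq_len(dims[3]) / dims[3]
  for (m in seq_len(n_waves)) {
    f <- stats::runif(3, 0.5, 2.5)
    ph <- stats::runif(1, 0, 2 * pi)
    phase <- outer(outer(2 * pi * f[1] * ii, 2 * pi * f[2] * jj, "+"),
                   2 * pi * f[3] * kk, "+") + ph
    tex <- tex + amp * sin(phase)
  }
  tex
}

lesion_soft_boost <- function(dist2, boost) {
  fall <- pmin(1, pmax(0, (1 - dist2) / 0.3))
  1 + (boost - 1) * fall
}

#' Generate one synthetic clinical-style case
#'
#' Builds the physical-intensity volume (brain ellipsoid + texture + lesions
#' + noise), quantizes it to 12-bit stored values through the spec's rescale
#' slope/intercept, derives per-slice metadata, the binary truth mask and
#' per-slice closed-polygon annotations (only on slices where the mask has
#' foreground).  Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `synthetic_case`: list with `series`
#'   (a `raw_series`), `annotations` (an `annotation_set`), `truth_mask`
#'   (binary array), `group` and the originating `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  np <- spec$in_plane
  nz <- spec$n_slices
  dims <- c(np, np, nz)
  spacing <- c(spec$pixel_spacing_mm, spec$pixel_spacing_mm,
               spec$slice_thickness_mm)
  brain_r <- c(0.42 * np * spacing[1], 0.46 * np * spacing[2],
               0.48 * nz * spacing[3])
  bd2 <- ellipsoid_dist2(dims, spacing, c(0, 0, 0), brain_r)
  edge <- pmin(1, pmax(0, (1 - bd2) * 4))
  tex <- phantom_texture(dims)
  physical <- 600 * (1 + tex) * edge
  mask <- array(0L, dims)
  for (les in spec$lesions) {
    ld2 <- ellipsoid_dist2(dims, spacing, les$center_mm, les$radii_mm)
    physical <- physical * lesion_soft_boost(ld2, les$intensity_boost)
    mask[ld2 <= 1] <- 1L
  }
  if (spec$noise_sd > 0) {
    physical <- physical + stats::rnorm(length(physical), 0, spec$noise_sd)
  }
  raw <- round((physical - spec$rescale_intercept) / spec$rescale_slope)
  raw <- pmin(pmax(raw, 0), 4095)
  dim(raw) <- dims

  series_uid <- sprintf("1.2.826.0.1.synthetic.%d", spec$seed)
  slices <- vector("list", nz)
  for (k in seq_len(nz)) {
    slices[[k]] <- list(
      pixels = matrix(as.integer(raw[, , k]), np, np),
      meta = slice_meta(rescale_slope = spec$rescale_slope,
                        rescale_intercept = spec$rescale_intercept,
                        window_center = spec$window_center,
                        window_width = spec$window_width,
                        pixel_spacing = spec$pixel_spacing_mm,
                        sop_uid = sprintf("%s.%03d", series_uid, k)))
  }
  series <- structure(list(slices = slices, plane = "axial",
                           modality_tag = "T2-FLAIR",
                           series_uid = series_uid),
                      class = "raw_series")
  annotations <- lesion_annotations(spec, mask, series)
  group <- if (any(mask > 0)) {
    cls <- classify_tumor_size(mask, spec$pixel_spacing_mm)
    paste0(cls, "_tumor")
  } else {
    "normal_plain"
  }
  case <- structure(list(series = series, annotations = annotations,
                         truth_mask = mask, group = group, spec = spec),
                    class = "synthetic_case")
  if (spec$hyperintensity_count > 0) {
    case <- add_hyperintensity_speckles(case, spec$hyperintensity_count,
                                        seed = spec$seed + 1L)
  }
  case
}

# Analytic per-slice ellipse contours re-encoded as closed polygon lists,
# so the JSON/rasterization path is exercised against a known mask.
lesion_annotations <- function(spec, mask, series) {
  np <- spec$in_plane
  nz <- spec$n_slices
  sp <- spec$pixel_spacing_mm
  entries <- list()
  for (k in seq_len(nz)) {
    if (!any(mask[, , k] > 0)) next
    polys <- list()
    zk <- (k - (nz + 1) / 2) * spec$slice_thickness_mm
    for (les in spec$lesions) {
      rz2 <- 1 - ((zk - les$center_mm[3]) / les$radii_mm[3])^2
      if (rz2 <= 0) next
      ri <- les$radii_mm[1] * sqrt(rz2) / sp
      rj <- les$radii_mm[2] * sqrt(rz2) / sp
      ci <- les$center_mm[1] / sp + (np + 1) / 2
      cj <- les$center_mm[2] / sp + (np + 1) / 2
      if (ri < 0.5 || rj < 0.5) {
        coords <- cbind(ci + c(-0.5, 0.5, 0.5, -0.5, -0.5),
                        cj + c(-0.5, -0.5, 0.5, 0.5, -0.5))
      } else {
        th <- seq(0, 2 * pi, length.out = 41)
        coords <- cbind(ci + ri * cos(th), cj + rj * sin(th))
      }
      polys[[length(polys) + 1]] <- list(coords = coords, width = 1)
    }
    if (length(polys)) {
      entries[[series$slices[[k]]$meta$sop_uid]] <- polys
    }
  }
  structure(list(entries = entries), class = "annotation_set")
}

#' Add white-matter-hyperintensity-like speckles to a normal case
#'
#' Inserts `count` small bright blobs (each under 0.3 cm^2 per slice) into
#' the image of a tumor-free case.  The truth mask is untouched — the
#' speckles are confounders, not lesions — and the group becomes
#' `normal_hyperintense` when `count > 0`.
#'
#' @param case A `synthetic_case` with an empty truth mask.
#' @param count Non-negative number of speckles.
#' @param seed Integer seed.
#' @return The modified `synthetic_case`.
#' @export
add_hyperintensity_speckles <- function(case, count, seed = 1L) {
  stopifnot(inherits(case, "synthetic_case"))
  if (any(case$truth_mask > 0)) {
    stop("hyperintensity speckles can only be added to normal (tumor-free) cases")
  }
  count <- as.integer(count)
  stopifnot(count >= 0)
  if (count == 0) return(case)
  spec <- case$spec
  set.seed(seed)
  np <- spec$in_plane
  nz <- spec$n_slices
  sp <- spec$pixel_spacing_mm
  centers <- matrix(0, 0, 3)
  radii <- numeric(0)
  tries <- 0
  while (nrow(centers) < count && tries < 2000) {
    tries <- tries + 1
    r_mm <- stats::runif(1, max(1.4, 1.6 * sp), 2.6)
    cand <- c(stats::runif(2, -0.28, 0.28) * np * sp,
              stats::runif(1, -0.3, 0.3) * nz * spec$slice_thickness_mm)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt(rowSums(sweep(centers[, 1:2, drop = FALSE], 2,
                              cand[1:2], "-")^2) +
                  (centers[, 3] - cand[3])^2)
      if (any(d < (radii + r_mm + 4 * sp))) ok <- FALSE
    }
    if (ok) {
      centers <- rbind(centers, cand)
      radii <- c(radii, r_mm)
    }
  }
  if (nrow(centers) < count) stop("could not place the requested speckles")
  dims <- c(np, np, nz)
  spacing <- c(sp, sp, spec$slice_thickness_mm)
  boost <- array(1, dims)
  for (s in seq_len(count)) {
    rz <- max(spec$slice_thickness_mm * 0.8, radii[s])
    d2 <- ellipsoid_dist2(dims, spacing, centers[s, ],
                          c(radii[s], radii[s], rz))
    boost <- boost * lesion_soft_boost(d2, 2.2)
  }
  for (k in seq_len(nz)) {
    px <- case$series$slices[[k]]$pixels
    newpx <- as.integer(pmin(round(px * boost[, , k]), 4095L))
    case$series$slices[[k]]$pixels <- matrix(newpx, np, np)
  }
  case$group <- "normal_hyperintense"
  case
}

#' Generate a challenge-style labeled volume
#'
#' A 3D image with one large multi-label lesion; label values are drawn only
#' from {0, 1, 2, 4} (background, necrotic core, peritumoral edema,
#' enhancing tumor).  When `n_slices = 155` the first 15 slices are
#' all-background, mirroring the blank leading slices of the emulated
#' public dataset.
#'
#' @param size In-plane matrix size (default 240).
#' @param n_slices Number of slices (>= 33; default 155).
#' @param seed Integer seed.
#' @return A list of class `brats_case` with `image` (numeric array) and
#'   `label` (integer array over {0,1,2,4}).
#' @export
generate_brats_like_case <- function(size = 240L, n_slices = 155L, seed = 1L) {
  size <- as.integer(size)
  n_slices <- as.integer(n_slices)
  if (n_slices < 33) stop("n_slices must be at least 33, got ", n_slices)
  set.seed(seed)
  dims <- c(size, size, n_slices)
  blank_lead <- as.integer(round(15 * n_slices / 155))
  spacing <- c(1, 1, 1)
  # brain confined to slices after the blank lead
  z0 <- blank_lead + 1
  zc <- (z0 + n_slices * 0.92) / 2 - (n_slices + 1) / 2
  zr <- (n_slices * 0.92 - z0) / 2
  bd2 <- ellipsoid_dist2(dims, spacing, c(0, 0, zc),
                         c(0.42 * size, 0.46 * size, zr))
  edge <- pmin(1, pmax(0, (1 - bd2) * 4))
  tex <- phantom_texture(dims)
  image <- 600 * (1 + tex) * edge
  # one large lesion with nested sub-labels
  cen <- c(stats::runif(2, -0.15, 0.15) * size, zc + stats::runif(1, -0.2, 0.2) * zr)
  rad <- c(stats::runif(2, 0.10, 0.16) * size, stats::runif(1, 0.15, 0.25) * zr)
  ld2 <- ellipsoid_dist2(dims, spacing, cen, rad)
  label <- array(0L, dims)
  label[ld2 <= 1] <- 2L    # edema envelope
  label[ld2 <= 0.7] <- 4L  # enhancing shell
  label[ld2 <= 0.4] <- 1L  # necrotic core
  label[, , seq_len(blank_lead)] <- 0L
  image <- image * lesion_soft_boost(ld2, 1.8)
  image <- image + stats::rnorm(length(image), 0, 15)
  image[image < 0] <- 0
  image[, , seq_len(blank_lead)] <- 0
  structure(list(image = image, label = label, seed = seed),
            class = "brats_case")
}

# Draw a lesion spec of the requested class.  Target maximum slice areas:
# small — log-normal with median 1.1 cm^2, truncated; large — uniform
# 4.5..12 cm^2.
sample_lesion_spec <- function(size_class, np, nz, spacing_mm, thickness_mm) {
  if (size_class == "small") {
    # clamp well below 3.5 cm^2: the rasterized annotation adds a boundary
    # stroke of roughly half a pixel, which must not flip the class
    area <- min(2.8, max(0.3, 1.1 * exp(stats::rnorm(1, 0, 0.45))))
  } else {
    area <- stats::runif(1, 4.5, 12)
  }
  r_mm <- sqrt(area / pi) * 10  # cm^2 -> equivalent circular radius in mm
  aspect <- stats::runif(1, 0.8, 1.25)
  rx <- r_mm * aspect
  ry <- r_mm / aspect
  rz <- max(thickness_mm * 1.2, r_mm * stats::runif(1, 0.7, 1.2))
  center <- c(stats::runif(2, -0.2, 0.2) * np * spacing_mm,
              stats::runif(1, -0.25, 0.25) * nz * thickness_mm)
  lesion_spec(center_mm = center, radii_mm = c(rx, ry, rz),
              intensity_boost = stats::runif(1, 1.6, 2.0),
              size_class = size_class)
}

#' Generate a full synthetic cohort
#'
#' Draws the requested number of large-tumor, small-tumor, plain-normal and
#' hyperintensity-normal cases.  Small/large lesions satisfy the 3.5 cm^2
#' maximum-slice-area rule by construction (radii are shrunk/grown and the
#' pixel-counted area re-checked).  Per-case seeds derive deterministically
#' from the cohort seed.
#'
#' @param n_large,n_small,n_normal_plain,n_normal_hyper Group sizes.
#' @param seed Master seed.
#' @param in_plane,pixel_spacing_mm,slice_thickness_mm Acquisition geometry.
#' @return A list of `synthetic_case` objects, in group order.
#' @export
generate_cohort <- function(n_large = 18L, n_small = 15L,
                            n_normal_plain = 15L, n_normal_hyper = 7L,
                            seed = 1L, in_plane = 256L,
                            pixel_spacing_mm = 0.9,
                            slice_thickness_mm = 3.0) {
  stopifnot(n_large >= 0, n_small >= 0, n_normal_plain >= 0,
            n_normal_hyper >= 0)
  groups <- c(rep("large_tumor", n_large), rep("small_tumor", n_small),
              rep("normal_plain", n_normal_plain),
              rep("normal_hyperintense", n_normal_hyper))
  cases <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    cseed <- derive_seed(seed, i)
    set.seed(cseed)
    n_slices <- if (stats::runif(1) < 0.15) sample(c(24L, 25L), 1) else
      sample(47:51, 1)
    g <- groups[i]
    lesions <- list()
    if (g %in% c("large_tumor", "small_tumor")) {
      cls <- if (g == "large_tumor") "large" else "small"
      lesions <- list(sample_lesion_spec(cls, in_plane, n_slices,
                                         pixel_spacing_mm,
                                         slice_thickness_mm))
    }
    hyper <- if (g == "normal_hyperintense") sample(3:8, 1) else 0L
    spec <- phantom_spec(in_plane = in_plane, n_slices = n_slices,
                         pixel_spacing_mm = pixel_spacing_mm,
                         slice_thickness_mm = slice_thickness_mm,
                         lesions = lesions, hyperintensity_count = hyper,
                         seed = cseed)
    case <- generate_phantom(spec)
    # enforce the size class by construction: adjust radii until the
    # pixel-counted maximum slice area lands on the right side of 3.5 cm^2
    if (g %in% c("large_tumor", "small_tumor")) {
      want <- sub("_tumor", "", g)
      tries <- 0
      while (classify_tumor_size(case$truth_mask, pixel_spacing_mm) != want &&
               tries < 5) {
        tries <- tries + 1
        fac <- if (want == "small") 0.85 else 1.2
        les <- spec$lesions[[1]]
        les$radii_mm[1:2] <- les$radii_mm[1:2] * fac
        spec$lesions[[1]] <- les
        case <- generate_phantom(spec)
      }
      if (classify_tumor_size(case$truth_mask, pixel_spacing_mm) != want) {
        stop("failed to construct a ", want, " lesion for case ", i)
      }
    }
    cases[[i]] <- case
  }
  cases
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat("<synthetic_case>", x$group, "\n")
  cat("  slices:", x$spec$n_slices, " in-plane:", x$spec$in_plane, "x",
      x$spec$in_plane, "@", x$spec$pixel_spacing_mm, "mm\n")
  cat("  foreground voxels:", sum(x$truth_mask), "\n")
  invisible(x)
}
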