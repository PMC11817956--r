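# DICOM-style grayscale standardization and geometry canonicalization.
#
# Raw clinical-style series go through the grayscale LUT chain (modality
# rescale -> value-of-interest window -> 12-bit presentation normalization),
# polygon annotations are rasterized to binary masks, thin stacks (24-25
# slices) are interpolated to 47-48, stacks are zero-padded to 64 slices and
# resampled in-plane to 128x128.  Challenge-style volumes are decimated from
# 155 to 64 slices (every other slice starting at index 16), their labels
# merged to binary, and resampled the same way.  The small/large size class
# is always decided at the native in-plane resolution, before resampling.

#' Per-slice DICOM-style metadata
#'
#' @param rescale_slope,rescale_intercept Modality LUT affine coefficients
#'   (physical = slope * stored + intercept); slope must be positive.
#' @param window_center,window_width Display window (width > 0).
#' @param display_max Maximum display value (default 4095, 12-bit).
#' @param pixel_spacing In-plane pixel spacing in mm.
#' @param sop_uid Slice instance identifier.
#' @return A list of class `slice_meta`.
#' @export
slice_meta <- function(rescale_slope = 1, rescale_intercept = 0,
                       window_center = 2048, window_width = 4096,
                       display_max = 4095L, pixel_spacing = 1,
                       sop_uid = "") {
  stopifnot(rescale_slope > 0, window_width > 0, display_max >= 1,
            pixel_spacing > 0)
  structure(list(rescale_slope = rescale_slope,
                 rescale_intercept = rescale_intercept,
                 window_center = window_center, window_width = window_width,
                 display_max = as.integer(display_max),
                 pixel_spacing = pixel_spacing, sop_uid = sop_uid),
            class = "slice_meta")
}

#' Modality LUT: stored values to standardized physical values
#'
#' The affine map `v = m * v_org + b0` defined by the rescale slope and
#' intercept attributes.
#'
#' @param v_org Stored pixel value(s).
#' @param m Rescale slope.
#' @param b0 Rescale intercept.
#' @return Standardized value(s), same shape as `v_org`.
#' @export
modality_lut <- function(v_org, m = 1, b0 = 0) m * v_org + b0

#' Value-of-interest LUT: windowed contrast mapping
#'
#' Piecewise-linear window: 0 below `c - w/2`, `gm` above `c + w/2`, and
#' linear with slope `gm / w` inside, i.e. `G(v) = (gm / w) (v + w/2 - c)`.
#' Values exactly at the window edges take the linear branch, which meets
#' the flat branches continuously.
#'
#' @param v Standardized value(s) from [modality_lut()].
#' @param c Window center (level).
#' @param w Window width (> 0).
#' @param gm Maximum display value.
#' @return Windowed value(s) in `[0, gm]`.
#' @export
voi_lut <- function(v, c, w, gm = 4095) {
  if (w <= 0) stop("window width must be positive, got ", w)
  out <- gm / w * (v + w / 2 - c)
  out[v < c - w / 2] <- 0
  out[v > c + w / 2] <- gm
  out
}

#' Presentation LUT: per-case normalization to 12-bit grayscale
#'
#' Linear min-max rescale of the whole case to integers in `[0, 4095]`;
#' a constant input maps to all zeros.
#'
#' @param values Numeric array.
#' @param gm Maximum output value (default 4095).
#' @return Integer-valued array of the same shape.
#' @export
presentation_normalize <- function(values, gm = 4095L) {
  rng <- range(values)
  if (rng[2] <= rng[1]) {
    out <- values * 0
  } else {
    out <- round((values - rng[1]) / (rng[2] - rng[1]) * gm)
  }
  out
}

#' Decimate slices: every other slice from a start index
#'
#' Output slice `i` (0-based) equals input slice `start + 2 i` (0-based).
#' With the defaults (`start = 16`, `count = 64`) a 155-slice stack maps to
#' 64 slices covering input indices 16..142.
#'
#' @param volume 3D array (x, y, slice).
#' @param start 0-based first slice index.
#' @param count Number of output slices.
#' @return 3D array with `count` slices.
#' @export
decimate_slices <- function(volume, start = 16L, count = 64L) {
  s <- dim(volume)[3]
  last <- start + 2 * (count - 1)
  if (start < 0 || last >= s) {
    stop("decimation needs start + 2*(count-1) < n_slices: ",
         start, " + 2*(", count, "-1) = ", last, " but n_slices = ", s)
  }
  idx <- start + 2 * seq(0, count - 1) + 1  # to 1-based
  volume[, , idx, drop = FALSE]
}

#' Merge multi-label tumor annotation into a binary mask
#'
#' Labels 1, 2 and 4 (necrotic core, edema, enhancing tumor) all map to 1;
#' 0 stays 0.
#'
#' @param label Array with values in {0, 1, 2, 4}.
#' @return Integer array over {0, 1} of the same shape.
#' @export
merge_brats_labels <- function(label) {
  vals <- unique(as.vector(label))
  bad <- setdiff(vals, c(0, 1, 2, 4))
  if (length(bad)) {
    stop("unexpected label value(s): ", paste(sort(bad), collapse = ", "),
         " (expected subset of {0, 1, 2, 4})")
  }
  out <- (label != 0) * 1L
  if (!is.null(dim(label))) dim(out) <- dim(label)
  out
}

# Even-odd point-in-polygon fill plus a boundary stroke of the annotation's
# segment width.  Coordinates are pixel-center positions in matrix index
# space: coords[, 1] is the row (x), coords[, 2] the column (y).
fill_polygon <- function(mask, coords, width = 1) {
  nx <- nrow(mask)
  ny <- ncol(mask)
  cl <- coords
  if (!all(cl[1, ] == cl[nrow(cl), ])) cl <- rbind(cl, cl[1, ])
  i0 <- max(1L, floor(min(cl[, 1]) - width))
  i1 <- min(nx, ceiling(max(cl[, 1]) + width))
  j0 <- max(1L, floor(min(cl[, 2]) - width))
  j1 <- min(ny, ceiling(max(cl[, 2]) + width))
  if (i0 > i1 || j0 > j1) return(mask)
  ii <- i0:i1
  jj <- j0:j1
  gi <- matrix(ii, length(ii), length(jj))
  gj <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  inside <- matrix(FALSE, length(ii), length(jj))
  stroke <- matrix(FALSE, length(ii), length(jj))
  hw <- max(width, 1) / 2
  for (k in seq_len(nrow(cl) - 1)) {
    x1 <- cl[k, 1]; y1 <- cl[k, 2]
    x2 <- cl[k + 1, 1]; y2 <- cl[k + 1, 2]
    # even-odd crossing test on the column coordinate
    if (y1 != y2) {
      cross <- ((gj >= pmin(y1, y2)) & (gj < pmax(y1, y2))) &
        (gi < x1 + (gj - y1) * (x2 - x1) / (y2 - y1))
      inside <- xor(inside, cross)
    }
    # boundary stroke: distance to the segment
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx * vx + vy * vy
    t <- if (L2 > 0) pmin(1, pmax(0, ((gi - x1) * vx + (gj - y1) * vy) / L2))
         else 0
    dx <- gi - (x1 + t * vx)
    dy <- gj - (y1 + t * vy)
    stroke <- stroke | (dx * dx + dy * dy <= hw * hw)
  }
  mask[ii, jj] <- mask[ii, jj] | inside | stroke
  mask
}

#' Rasterize closed polygon annotations to a binary mask
#'
#' Each polyline is a closed contour (first vertex equal to the last, or
#' closed implicitly); the mask is the union of the filled interiors
#' (even-odd rule) and the boundary strokes of the stated segment width.
#' Polylines with fewer than 3 distinct vertices are skipped with a warning.
#'
#' @param polylines List of `list(coords = <n x 2 matrix>, width = <pixels>)`.
#' @param canvas Integer length-2 mask size (rows, columns).
#' @return An integer 0/1 matrix of dimension `canvas`.
#' @export
rasterize_annotations <- function(polylines, canvas) {
  mask <- matrix(FALSE, canvas[1], canvas[2])
  for (pl in polylines) {
    coords <- pl$coords
    distinct <- unique(round(coords, 9))
    if (nrow(distinct) < 3) {
      warning("skipping polyline with fewer than 3 distinct vertices")
      next
    }
    mask <- fill_polygon(mask, coords, pl$width %||% 1)
  }
  mode(mask) <- "integer"
  mask
}

# Keys cubic-convolution midpoint along the slice axis.
cubic_midpoints <- function(volume) {
  s <- dim(volume)[3]
  mids <- array(0, c(dim(volume)[1:2], s - 1))
  for (i in seq_len(s - 1)) {
    if (i == 1 || i == s - 1) {
      mids[, , i] <- (volume[, , i] + volume[, , i + 1]) / 2
    } else {
      mids[, , i] <- (-volume[, , i - 1] + 9 * volume[, , i] +
                        9 * volume[, , i + 1] - volume[, , i + 2]) / 16
    }
  }
  mids
}

#' Interpolate thin slice stacks to roughly double the slice count
#'
#' Stacks of 24 or 25 slices are interpolated along the slice axis so every
#' original slice is reproduced exactly at even output indices and a new
#' slice is synthesized between each adjacent pair (24 -> 47, 25 -> 48; for
#' 25 slices the 2S-1 = 49 arithmetic is reconciled with the expected 47-48
#' range by dropping the final slice).  Stacks outside 24-25 slices pass
#' through unchanged.  Labels are interpolated the same way and re-binarized
#' at 0.5.
#'
#' @param volume 3D image array.
#' @param label Optional matching binary 3D array.
#' @param method `"cubic"` (Keys cubic convolution, the default stand-in for
#'   high-order slice interpolation) or `"linear"`.
#' @return A list with `volume` and (if given) `label`.
#' @export
interpolate_slices <- function(volume, label = NULL, method = c("cubic",
                                                                "linear")) {
  method <- match.arg(method)
  s <- dim(volume)[3]
  if (!s %in% c(24L, 25L)) {
    return(list(volume = volume, label = label))
  }
  interp1 <- function(v) {
    mids <- if (method == "cubic") cubic_midpoints(v) else
      (v[, , -dim(v)[3], drop = FALSE] + v[, , -1, drop = FALSE]) / 2
    out <- array(0, c(dim(v)[1:2], 2 * s - 1))
    out[, , seq(1, 2 * s - 1, by = 2)] <- v
    out[, , seq(2, 2 * s - 2, by = 2)] <- mids
    if (s == 25L) out <- out[, , seq_len(48), drop = FALSE]
    out
  }
  vol2 <- interp1(volume)
  lab2 <- NULL
  if (!is.null(label)) {
    lab2 <- (interp1(label) >= 0.5) * 1L
    dim(lab2) <- dim(vol2)
  }
  list(volume = vol2, label = lab2)
}

#' Pad a stack with trailing black slices
#'
#' @param volume 3D array with at most `target` slices.
#' @param target Target depth (default 64).
#' @return 3D array with exactly `target` slices; appended slices all zero.
#' @export
pad_to_depth <- function(volume, target = 64L) {
  s <- dim(volume)[3]
  if (s > target) stop("depth ", s, " exceeds the target of ", target)
  if (s == target) return(volume)
  out <- array(0, c(dim(volume)[1:2], target))
  out[, , seq_len(s)] <- volume
  storage.mode(out) <- storage.mode(volume)
  out
}

bilinear_2d <- function(m, target) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- (seq_len(target[1]) - 0.5) * nx / target[1] + 0.5
  sy <- (seq_len(target[2]) - 0.5) * ny / target[2] + 0.5
  x0 <- pmin(pmax(floor(sx), 1), nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(pmax(floor(sy), 1), ny); y1 <- pmin(y0 + 1, ny)
  wx <- pmin(pmax(sx - x0, 0), 1)
  wy <- pmin(pmax(sy - y0, 0), 1)
  a <- m[x0, y0, drop = FALSE]; b <- m[x1, y0, drop = FALSE]
  cc <- m[x0, y1, drop = FALSE]; d <- m[x1, y1, drop = FALSE]
  t1 <- a * (1 - wx) + b * wx
  t2 <- cc * (1 - wx) + d * wx
  sweep(t1, 2, 1 - wy, "*") + sweep(t2, 2, wy, "*")
}

nearest_2d <- function(m, target) {
  nx <- nrow(m); ny <- ncol(m)
  ix <- pmin(pmax(round((seq_len(target[1]) - 0.5) * nx / target[1] + 0.5), 1), nx)
  iy <- pmin(pmax(round((seq_len(target[2]) - 0.5) * ny / target[2] + 0.5), 1), ny)
  m[ix, iy, drop = FALSE]
}

#' Resample in-plane to a target matrix size
#'
#' Images are resampled with bilinear interpolation, labels with nearest
#' neighbor (values stay in {0, 1}).
#'
#' @param image 2D matrix or 3D array.
#' @param label Optional matching binary array.
#' @param target Length-2 target in-plane size (default 128x128).
#' @return A list with `image` and (if given) `label`.
#' @export
resample_inplane <- function(image, label = NULL, target = c(128L, 128L)) {
  res3 <- function(v, fun) {
    if (length(dim(v)) == 2) return(fun(v, target))
    out <- array(0, c(target, dim(v)[3]))
    for (k in seq_len(dim(v)[3])) out[, , k] <- fun(v[, , k], target)
    out
  }
  img2 <- res3(image, bilinear_2d)
  lab2 <- NULL
  if (!is.null(label)) {
    lab2 <- res3(label, nearest_2d)
    storage.mode(lab2) <- "integer"
  }
  list(image = img2, label = lab2)
}

#' Classify a lesion as small or large by its maximum slice area
#'
#' A case is `small` when the largest per-slice foreground area across all
#' slices is below 3.5 cm^2, `large` otherwise, and `none` when the label is
#' empty.  Areas are foreground pixel counts times the squared pixel
#' spacing, evaluated at the resolution of the supplied label (callers
#' should classify before any resampling).
#'
#' @param label Binary 3D array.
#' @param pixel_spacing_mm In-plane pixel spacing in mm.
#' @return `"small"`, `"large"` or `"none"`.
#' @export
classify_tumor_size <- function(label, pixel_spacing_mm) {
  a <- max_slice_area_cm2(label, pixel_spacing_mm)
  if (a == 0) return("none")
  if (a < 3.5) "small" else "large"
}

#' @rdname classify_tumor_size
#' @export
max_slice_area_cm2 <- function(label, pixel_spacing_mm) {
  counts <- apply(label > 0, 3, sum)
  max(counts) * pixel_spacing_mm^2 / 100
}

new_canonical_case <- function(image, label, source_id, size_class,
                               native_area, target_shape) {
  stopifnot(all(dim(image) == target_shape), all(dim(label) == target_shape),
            all(label %in% c(0L, 1L)))
  structure(list(image = image, label = label, source_id = source_id,
                 size_class = size_class,
                 native_max_slice_area_cm2 = native_area),
            class = "canonical_case")
}

#' Preprocess a clinical-style case to the canonical tensor
#'
#' Applies the full conversion chain: per-slice modality LUT and VOI LUT,
#' per-case 12-bit presentation normalization, polygon rasterization,
#' slice interpolation for 24-25-slice stacks, zero-padding to the target
#' depth and in-plane resampling.  The maximum slice area (and hence the
#' size class) is recorded at native resolution before any resampling.
#' Intensities in the canonical tensor are scaled to [0, 1].
#'
#' @param series A `raw_series`.
#' @param annotations An `annotation_set` (polylines keyed by slice UID).
#' @param target_shape Canonical shape (default 128x128x64).
#' @param gm Display maximum for the VOI LUT.
#' @param interp_method Passed to [interpolate_slices()].
#' @return A `canonical_case`.
#' @export
preprocess_clinical_case <- function(series, annotations,
                                 target_shape = c(128L, 128L, 64L),
                                 gm = 4095, interp_method = "cubic") {
  stopifnot(inherits(series, "raw_series"))
  uids <- vapply(series$slices, function(s) s$meta$sop_uid, character(1))
  ann_uids <- names(annotations$entries)
  orphans <- setdiff(ann_uids, uids)
  if (length(orphans)) {
    stop("annotation UID(s) with no matching slice: ",
         paste(orphans, collapse = ", "))
  }
  np <- dim(series$slices[[1]]$pixels)
  s <- length(series$slices)
  vol <- array(0, c(np, s))
  lab <- array(0L, c(np, s))
  for (k in seq_len(s)) {
    sl <- series$slices[[k]]
    v <- modality_lut(sl$pixels, sl$meta$rescale_slope,
                      sl$meta$rescale_intercept)
    vol[, , k] <- voi_lut(v, sl$meta$window_center, sl$meta$window_width, gm)
    if (uids[k] %in% ann_uids) {
      lab[, , k] <- rasterize_annotations(annotations$entries[[uids[k]]], np)
    }
  }
  vol <- presentation_normalize(vol, gm)
  spacing <- series$slices[[1]]$meta$pixel_spacing
  native_area <- max_slice_area_cm2(lab, spacing)
  size_class <- classify_tumor_size(lab, spacing)
  ip <- interpolate_slices(vol, lab, method = interp_method)
  vol <- pad_to_depth(ip$volume, target_shape[3])
  lab <- pad_to_depth(ip$label, target_shape[3])
  rs <- resample_inplane(vol, lab, target_shape[1:2])
  new_canonical_case(rs$image / gm, rs$label, series$series_uid %||% "case",
                     size_class, native_area, target_shape)
}

#' Preprocess a challenge-style labeled volume to the canonical tensor
#'
#' Decimates slices (every other slice from `start`), merges the multi-label
#' annotation to binary, resamples in-plane and min-max normalizes the
#' image to [0, 1].
#'
#' @param image 3D image array.
#' @param label Matching array with values in {0, 1, 2, 4}.
#' @param target_shape Canonical shape (default 128x128x64).
#' @param start 0-based decimation start index (default 16).
#' @param pixel_spacing_mm Native in-plane spacing used for the size class.
#' @param source_id Identifier carried into the output.
#' @return A `canonical_case`.
#' @export
preprocess_brats_case <- function(image, label,
                                  target_shape = c(128L, 128L, 64L),
                                  start = 16L, pixel_spacing_mm = 1,
                                  source_id = "brats_case") {
  img <- decimate_slices(image, start = start, count = target_shape[3])
  lab <- decimate_slices(label, start = start, count = target_shape[3])
  lab <- merge_brats_labels(lab)
  native_area <- max_slice_area_cm2(lab, pixel_spacing_mm)
  size_class <- classify_tumor_size(lab, pixel_spacing_mm)
  rs <- resample_inplane(img, lab, target_shape[1:2])
  img <- presentation_normalize(rs$image) / 4095
  new_canonical_case(img, rs$label, source_id, size_class, native_area,
                     target_shape)
}

#' @export
print.canonical_case <- function(x, ...) {
  cat("<canonical_case>", x$source_id, "\n")
  cat("  shape:", paste(dim(x$image), collapse = "x"),
      " size_class:", x$size_class,
      sprintf(" native max slice area: %.2f cm^2\n",
              x$native_max_slice_area_cm2))
  invisible(x)
}
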