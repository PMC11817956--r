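test_that("modality LUT is the exact affine map", {
  expect_identical(modality_lut(7, 1, 0), 7)
  expect_identical(modality_lut(0, 3, -2), -2)
  expect_identical(modality_lut(100, 2, 10), 210)
  v <- matrix(1:6, 2)
  expect_equal(modality_lut(v, 0.5, -3), 0.5 * v - 3)
})

test_that("VOI LUT hits its boundary values and rejects bad widths", {
  c0 <- 100; w <- 40; gm <- 4095
  expect_equal(voi_lut(c0 - w, c0, w, gm), 0)
  expect_equal(voi_lut(c0, c0, w, gm), gm / 2)
  expect_equal(voi_lut(c0 + w, c0, w, gm), gm)
  # window edges take the linear branch and meet the flats continuously
  expect_equal(voi_lut(c0 - w / 2, c0, w, gm), 0)
  expect_equal(voi_lut(c0 + w / 2, c0, w, gm), gm)
  expect_error(voi_lut(1, c0, 0, gm), "positive")
})

test_that("VOI LUT matches a per-element piecewise oracle on a dense grid", {
  gm <- 4095
  oracle <- function(v, c0, w) {
    if (v < c0 - w / 2) return(0)
    if (v > c0 + w / 2) return(gm)
    gm / w * (v + w / 2 - c0)
  }
  set.seed(11)
  for (rep in 1:20) {
    c0 <- stats::runif(1, -100, 100)
    w <- stats::runif(1, 1, 200)
    v <- seq(c0 - w, c0 + w, length.out = 101)
    got <- voi_lut(v, c0, w, gm)
    want <- vapply(v, oracle, numeric(1), c0 = c0, w = w)
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(diff(got) >= -1e-9))
  }
})

test_that("raw-to-12-bit composite map is non-decreasing", {
  set.seed(5)
  raw <- sort(stats::runif(200, 0, 4095))
  v <- modality_lut(raw, 2, -100)
  g <- voi_lut(v, 600, 1200)
  out <- presentation_normalize(g)
  expect_true(all(diff(out) >= 0))
})

test_that("presentation normalization spans the 12-bit range", {
  expect_equal(presentation_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(presentation_normalize(c(0, 1)), c(0, 4095))
  set.seed(2)
  x <- stats::runif(100, -5, 5)
  out <- presentation_normalize(x)
  expect_true(all(out >= 0 & out <= 4095))
  expect_equal(max(out), 4095)
  expect_equal(min(out), 0)
})

test_that("slice decimation picks every other slice from the start index", {
  v <- array(seq_len(4 * 4 * 155), c(4, 4, 155))
  d <- decimate_slices(v)
  expect_equal(dim(d)[3], 64)
  expect_identical(d[, , 1], v[, , 17])   # 0-based input index 16
  expect_identical(d[, , 64], v[, , 143]) # 0-based input index 142
  one <- decimate_slices(v, start = 5L, count = 1L)
  expect_identical(one[, , 1], v[, , 6])
  v10 <- array(seq_len(2 * 2 * 10), c(2, 2, 10))
  d10 <- decimate_slices(v10, start = 0L, count = 5L)
  expect_identical(d10, v10[, , c(1, 3, 5, 7, 9), drop = FALSE])
  expect_error(decimate_slices(v10, start = 0L, count = 6L), "n_slices")
})

test_that("label merging maps 1/2/4 to 1 and rejects other values", {
  expect_equal(merge_brats_labels(c(0, 1, 2, 4)), c(0, 1, 1, 1))
  z <- array(0L, c(3, 3, 2))
  expect_equal(merge_brats_labels(z), z * 0L)
  set.seed(3)
  lab <- array(sample(c(0, 1, 2, 4), 200, replace = TRUE), c(10, 10, 2))
  out <- merge_brats_labels(lab)
  expect_equal(sum(out == 1), sum(lab %in% c(1, 2, 4)))
  expect_error(merge_brats_labels(c(0, 3)), "3")
})

test_that("polygon rasterization fills squares and matches a brute-force oracle", {
  sq <- list(list(coords = cbind(c(3, 12, 12, 3, 3), c(3, 3, 12, 12, 3)),
                  width = 1))
  mask <- rasterize_annotations(sq, c(20, 20))
  expect_gte(sum(mask), 100)
  expect_lte(sum(mask), 144)
  # independent per-pixel even-odd crossing oracle (interior only)
  crossing <- function(px, py, xs, ys) {
    n <- length(xs) - 1
    inside <- FALSE
    for (k in seq_len(n)) {
      if ((ys[k] > py) != (ys[k + 1] > py)) {
        xint <- xs[k] + (py - ys[k]) * (xs[k + 1] - xs[k]) /
          (ys[k + 1] - ys[k])
        if (px < xint) inside <- !inside
      }
    }
    inside
  }
  interior <- outer(1:20, 1:20, Vectorize(function(i, j) {
    crossing(i, j, c(3, 12, 12, 3, 3), c(3, 3, 12, 12, 3))
  }))
  expect_true(all(mask[interior] == 1))
  expect_equal(rasterize_annotations(list(), c(5, 5)), matrix(0L, 5, 5))
  degen <- list(list(coords = cbind(c(1, 1), c(1, 1)), width = 1))
  expect_warning(m2 <- rasterize_annotations(degen, c(5, 5)), "3 distinct")
  expect_equal(sum(m2), 0)
})

test_that("slice interpolation doubles thin stacks and reproduces originals", {
  set.seed(7)
  v24 <- array(stats::runif(6 * 6 * 24), c(6, 6, 24))
  out <- interpolate_slices(v24)
  expect_equal(dim(out$volume)[3], 47)
  expect_equal(out$volume[, , seq(1, 47, 2)], v24, tolerance = 1e-12)
  v25 <- array(stats::runif(6 * 6 * 25), c(6, 6, 25))
  out25 <- interpolate_slices(v25)
  expect_equal(dim(out25$volume)[3], 48)
  const <- array(3, c(4, 4, 24))
  expect_equal(unique(as.vector(interpolate_slices(const)$volume)), 3)
  v48 <- array(stats::runif(4 * 4 * 48), c(4, 4, 48))
  expect_identical(interpolate_slices(v48)$volume, v48)
  lab <- array(rbinom(6 * 6 * 24, 1, 0.4), c(6, 6, 24))
  outl <- interpolate_slices(v24, lab)
  expect_true(all(outl$label %in% c(0L, 1L)))
})

test_that("depth padding appends zeros and preserves content", {
  set.seed(9)
  v <- array(stats::runif(4 * 4 * 47), c(4, 4, 47))
  p <- pad_to_depth(v, 64L)
  expect_equal(dim(p)[3], 64)
  expect_equal(p[, , 1:47], v)
  expect_true(all(p[, , 48:64] == 0))
  expect_identical(pad_to_depth(p, 64L), p)
  expect_equal(sum(p > 0.5), sum(v > 0.5))
  expect_error(pad_to_depth(array(0, c(2, 2, 70)), 64L), "exceeds")
})

test_that("in-plane resampling honors the shape and label contracts", {
  set.seed(13)
  checker <- outer(1:256, 1:256, function(i, j) (i + j) %% 2)
  out <- resample_inplane(checker)
  expect_equal(dim(out$image), c(128, 128))
  const <- matrix(2.5, 64, 64)
  expect_equal(unique(as.vector(resample_inplane(const)$image)), 2.5)
  # native lesions >= 2x2 pixels survive 256 -> 128 nearest resampling
  for (pos in c(10, 65, 127, 200)) {
    lab <- array(0L, c(256, 256, 1))
    lab[pos:(pos + 1), pos:(pos + 1), 1] <- 1L
    rs <- resample_inplane(array(0, c(256, 256, 1)), lab)
    expect_gt(sum(rs$label), 0)
    expect_true(all(rs$label %in% c(0L, 1L)))
  }
})

test_that("tumor size classification follows the 3.5 cm^2 max-slice rule", {
  empty <- array(0L, c(10, 10, 3))
  expect_equal(classify_tumor_size(empty, 1), "none")
  lab <- array(0L, c(20, 20, 3))
  lab[1:10, 1:10, 2] <- 1L  # 100 px at 1 mm = 1.0 cm^2
  expect_equal(classify_tumor_size(lab, 1), "small")
  lab2 <- array(0L, c(25, 25, 3))
  lab2[1:20, 1:20, 1] <- 1L  # 400 px = 4.0 cm^2
  lab2[1:5, 1:5, 2] <- 1L
  expect_equal(classify_tumor_size(lab2, 1), "large")
  expect_equal(max_slice_area_cm2(lab2, 1), 4.0)
})

test_that("clinical-style preprocessing yields canonical 128x128x64 cases", {
  co <- generate_cohort(0, 1, 1, 0, seed = 21, in_plane = 128)
  tumor <- co[[1]]
  cc <- preprocess_clinical_case(tumor$series, tumor$annotations)
  expect_equal(dim(cc$image), c(128, 128, 64))
  expect_equal(dim(cc$label), c(128, 128, 64))
  expect_true(all(cc$label %in% c(0L, 1L)))
  expect_equal(cc$size_class, "small")
  expect_gt(sum(cc$label), 0)
  normal <- co[[2]]
  cn <- preprocess_clinical_case(normal$series, normal$annotations)
  expect_equal(sum(cn$label), 0)
  expect_equal(cn$size_class, "none")
  # full-chain determinism: identical voxel payloads across two runs
  cc2 <- preprocess_clinical_case(tumor$series, tumor$annotations)
  expect_identical(cc$image, cc2$image)
  expect_identical(cc$label, cc2$label)
})

test_that("orphan annotation UIDs are rejected by name", {
  co <- generate_cohort(0, 1, 0, 0, seed = 22, in_plane = 128)
  cs <- co[[1]]
  bad <- cs$annotations
  bad$entries[["9.9.9.bogus"]] <- bad$entries[[1]]
  expect_error(preprocess_clinical_case(cs$series, bad), "9.9.9.bogus")
})

test_that("challenge-style preprocessing decimates, merges and resizes", {
  b <- generate_brats_like_case(size = 96, n_slices = 155, seed = 31)
  cc <- preprocess_brats_case(b$image, b$label,
                              target_shape = c(128L, 128L, 64L))
  expect_equal(dim(cc$image), c(128, 128, 64))
  expect_true(all(cc$label %in% c(0L, 1L)))
  expect_gt(sum(cc$label), 0)
  # all-background case
  empty <- preprocess_brats_case(b$image, b$label * 0L,
                                 target_shape = c(128L, 128L, 64L))
  expect_equal(sum(empty$label), 0)
  expect_equal(empty$size_class, "none")
})

test_that("case directories round-trip through the sidecar format", {
  co <- generate_cohort(0, 1, 0, 0, seed = 41, in_plane = 96)
  cs <- co[[1]]
  d <- withr::local_tempdir()
  write_clinical_case(cs, d)
  rt <- read_clinical_case(d)
  c1 <- preprocess_clinical_case(cs$series, cs$annotations)
  c2 <- preprocess_clinical_case(rt$series, rt$annotations)
  expect_identical(c1$image, c2$image)
  expect_identical(c1$label, c2$label)
  expect_equal(c1$size_class, c2$size_class)
  # NIfTI pair writing
  paths <- write_canonical_case(c1, d)
  expect_true(all(file.exists(paths)))
  img <- RNifti::readNifti(paths[["image"]])
  expect_equal(dim(img), c(128, 128, 64))
})
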