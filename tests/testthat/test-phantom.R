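test_that("phantoms are deterministic in the seed and lesion-free when asked", {
  sp <- phantom_spec(in_plane = 64, n_slices = 24, seed = 7)
  c1 <- generate_phantom(sp)
  c2 <- generate_phantom(sp)
  expect_identical(c1, c2)
  expect_equal(sum(c1$truth_mask), 0)
  expect_equal(c1$group, "normal_plain")
  expect_equal(length(c1$annotations$entries), 0)
  c3 <- generate_phantom(phantom_spec(in_plane = 64, n_slices = 24, seed = 8))
  expect_false(identical(c1$series$slices[[1]]$pixels,
                         c3$series$slices[[1]]$pixels))
  expect_error(phantom_spec(n_slices = 30), "n_slices")
})

test_that("a lesion with ~1.1 cm^2 max slice area classifies as small", {
  r <- sqrt(1.1 / pi) * 10  # mm
  sp <- phantom_spec(in_plane = 128, n_slices = 48, seed = 3,
                     lesions = list(lesion_spec(radii_mm = c(r, r, r),
                                                size_class = "small")))
  cs <- generate_phantom(sp)
  expect_equal(classify_tumor_size(cs$truth_mask, sp$pixel_spacing_mm),
               "small")
  expect_equal(cs$group, "small_tumor")
  a <- max_slice_area_cm2(cs$truth_mask, sp$pixel_spacing_mm)
  expect_gt(a, 0.6)
  expect_lt(a, 1.7)
})

test_that("annotations appear exactly on slices with mask foreground", {
  co <- generate_cohort(1, 1, 0, 0, seed = 17, in_plane = 96)
  for (cs in co) {
    uids <- vapply(cs$series$slices, function(s) s$meta$sop_uid,
                   character(1))
    fg <- apply(cs$truth_mask > 0, 3, any)
    expect_setequal(names(cs$annotations$entries), uids[fg])
  }
})

test_that("annotation polygons rasterize back onto the generating mask", {
  co <- generate_cohort(1, 1, 0, 0, seed = 19, in_plane = 128)
  for (cs in co) {
    d <- dim(cs$truth_mask)
    uids <- vapply(cs$series$slices, function(s) s$meta$sop_uid,
                   character(1))
    lab <- array(0L, d)
    for (k in seq_len(d[3])) {
      if (uids[k] %in% names(cs$annotations$entries)) {
        lab[, , k] <- rasterize_annotations(cs$annotations$entries[[uids[k]]],
                                            d[1:2])
      }
    }
    expect_gte(dice(lab, cs$truth_mask)$dice, 0.9)
  }
})

test_that("hyperintensity speckles add bright components but never touch the mask", {
  sp <- phantom_spec(in_plane = 96, n_slices = 47, seed = 5)
  base <- generate_phantom(sp)
  spk <- add_hyperintensity_speckles(base, 3, seed = 11)
  expect_equal(spk$group, "normal_hyperintense")
  expect_equal(sum(spk$truth_mask), 0)
  diff <- array(0L, c(96, 96, 47))
  for (k in 1:47) {
    diff[, , k] <- (spk$series$slices[[k]]$pixels >
                      base$series$slices[[k]]$pixels) * 1L
  }
  comp <- label_components(diff)
  expect_equal(comp$n, 3)
  # each speckle stays under 0.3 cm^2 per slice
  for (k in 1:47) {
    sl <- diff[, , k]
    if (!any(sl > 0)) next
    cc2 <- label_components(array(sl, c(96, 96, 1)))
    expect_true(all(cc2$sizes * sp$pixel_spacing_mm^2 / 100 < 0.3))
  }
  expect_identical(add_hyperintensity_speckles(base, 0, seed = 1), base)
  tumor <- generate_cohort(1, 0, 0, 0, seed = 23, in_plane = 96)[[1]]
  expect_error(add_hyperintensity_speckles(tumor, 2), "normal")
})

test_that("challenge-style volumes have the expected label support and blanks", {
  b <- generate_brats_like_case(size = 64, n_slices = 155, seed = 2)
  expect_true(all(unique(as.vector(b$label)) %in% c(0, 1, 2, 4)))
  expect_true(all(c(1, 2, 4) %in% b$label))
  expect_true(all(b$label[, , 1:15] == 0))
  expect_true(all(b$image[, , 1:15] == 0))
  b2 <- generate_brats_like_case(size = 64, n_slices = 155, seed = 2)
  expect_identical(b, b2)
  expect_error(generate_brats_like_case(n_slices = 20), "33")
})

test_that("cohorts have the requested composition and class guarantees", {
  co <- generate_cohort(2, 2, 1, 1, seed = 29, in_plane = 96)
  groups <- vapply(co, function(x) x$group, character(1))
  expect_equal(as.integer(table(factor(groups,
                                       c("large_tumor", "small_tumor",
                                         "normal_plain",
                                         "normal_hyperintense")))),
               c(2L, 2L, 1L, 1L))
  for (cs in co) {
    if (cs$group %in% c("large_tumor", "small_tumor")) {
      expect_gt(sum(cs$truth_mask), 0)
      want <- sub("_tumor", "", cs$group)
      expect_equal(classify_tumor_size(cs$truth_mask,
                                       cs$spec$pixel_spacing_mm), want)
    } else {
      expect_equal(sum(cs$truth_mask), 0)
    }
    expect_true(cs$spec$n_slices %in% c(24L, 25L, 47:51))
  }
  expect_length(generate_cohort(0, 0, 0, 0, seed = 1), 0)
})

test_that("random lesion draws respect the 3.5 cm^2 size-class boundary", {
  set.seed(37)
  np <- 128L
  for (cls in c("small", "large")) {
    for (i in 1:100) {
      les <- neuroseg:::sample_lesion_spec(cls, np, 48, 0.9, 3.0)
      d2 <- neuroseg:::ellipsoid_dist2(c(np, np, 48), c(0.9, 0.9, 3.0),
                                       les$center_mm, les$radii_mm)
      mask <- (d2 <= 1) * 1L
      dim(mask) <- c(np, np, 48)
      a <- max_slice_area_cm2(mask, 0.9)
      if (cls == "small") expect_lt(a, 3.5) else expect_gte(a, 3.5)
    }
  }
})

test_that("stored pixel values recover physical intensities through the modality LUT", {
  # same seed, two different slope/intercept encodings of the same physical
  # field: after Eq.-2 style rescaling they agree to quantization accuracy
  mk <- function(slope, intercept) {
    generate_phantom(phantom_spec(in_plane = 64, n_slices = 24, seed = 13,
                                  rescale_slope = slope,
                                  rescale_intercept = intercept))
  }
  a <- mk(1, 0)
  b <- mk(2, -100)
  pa <- a$series$slices[[12]]$pixels
  pb <- b$series$slices[[12]]$pixels
  va <- modality_lut(pa, 1, 0)
  vb <- modality_lut(pb, 2, -100)
  # compare only where neither encoding clipped at the 12-bit range
  ok <- pa > 0 & pa < 4095 & pb > 0 & pb < 4095
  expect_gt(sum(ok), 1000)
  expect_lt(max(abs(va[ok] - vb[ok])), (1 + 2) / 2 + 1e-9)
})
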