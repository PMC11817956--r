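test_that("Dice reproduces the offset-square worked examples", {
  mk <- function(s, off) {
    n <- s + off + 2
    truth <- matrix(0L, n, n)
    truth[2:(s + 1), 2:(s + 1)] <- 1L
    pred <- matrix(0L, n, n)
    pred[(2 + off):(s + 1 + off), (2 + off):(s + 1 + off)] <- 1L
    list(pred = pred, truth = truth)
  }
  m3 <- mk(3, 1)
  sc3 <- dice(m3$pred, m3$truth)
  expect_equal(sc3$tp, 4)
  expect_equal(sc3$fp, 5)
  expect_equal(sc3$fn, 5)
  expect_equal(round(sc3$dice, 2), 0.44)
  m5 <- mk(5, 1)
  sc5 <- dice(m5$pred, m5$truth)
  expect_equal(sc5$dice, 2 * 16 / (2 * 16 + 9 + 9))
  expect_equal(round(sc5$dice, 2), 0.64)
})

test_that("Dice edge cases and symmetry hold", {
  a <- array(c(1, 1, 0, 0), c(2, 2, 1))
  expect_equal(dice(a, a)$dice, 1)
  z <- array(0L, c(2, 2, 1))
  expect_equal(dice(z, z)$dice, 1)  # both-empty convention
  expect_equal(dice(z, a)$dice, 0)
  expect_error(dice(a, array(0, c(3, 3, 1))), "mismatch")
  set.seed(4)
  p <- array(stats::rbinom(60, 1, 0.4), c(5, 4, 3))
  t <- array(stats::rbinom(60, 1, 0.4), c(5, 4, 3))
  expect_equal(dice(p, t)$dice, dice(t, p)$dice)
  # brute-force per-voxel confusion oracle
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(p)) {
    if (p[i] == 1 && t[i] == 1) tp <- tp + 1
    if (p[i] == 1 && t[i] == 0) fp <- fp + 1
    if (p[i] == 0 && t[i] == 1) fn <- fn + 1
  }
  sc <- dice(p, t)
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(tp, fp, fn))
  expect_equal(sc$dice, 2 * tp / (2 * tp + fp + fn))
})

test_that("detection applies the minimum-component rule over 26-connected blobs", {
  z <- array(0L, c(6, 6, 3))
  expect_false(detect(z))
  one <- z; one[3, 3, 2] <- 1L
  expect_true(detect(one, detection_rule(1)))
  expect_false(detect(one, detection_rule(2)))
  two <- z
  two[1:3, 1, 1] <- 1L              # size 3
  two[4:6, 4:6, 3] <- 1L            # size 9
  expect_true(detect(two, detection_rule(5)))
  expect_false(detect(two, detection_rule(10)))
  # diagonal voxels are one component under 26-connectivity
  diagm <- z; diagm[1, 1, 1] <- 1L; diagm[2, 2, 2] <- 1L
  expect_equal(label_components(diagm)$n, 1)
  # component sizes match an independent brute-force flood fill
  set.seed(6)
  m <- array(stats::rbinom(125, 1, 0.25), c(5, 5, 5))
  cc <- label_components(m)
  visited <- array(FALSE, dim(m))
  sizes <- integer(0)
  for (i in which(m == 1)) {
    if (visited[i]) next
    queue <- i; visited[i] <- TRUE; n <- 0
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]; n <- n + 1
      idx <- arrayInd(cur, dim(m))
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        ni <- idx + c(dx, dy, dz)
        if (any(ni < 1) || any(ni > dim(m))) next
        flat <- ni[1] + 5 * (ni[2] - 1) + 25 * (ni[3] - 1)
        if (m[flat] == 1 && !visited[flat]) {
          visited[flat] <- TRUE
          queue <- c(queue, flat)
        }
      }
    }
    sizes <- c(sizes, n)
  }
  expect_equal(sort(cc$sizes), sort(sizes))
})

test_that("detection metrics reproduce the printed cohort summary", {
  tab <- detection_table_from_counts(
    detected = c(small_tumor = 15, normal_hyperintense = 7,
                 normal_plain = 3),
    not_detected = c(small_tumor = 0, normal_hyperintense = 0,
                     normal_plain = 12))
  m <- detection_metrics(tab)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity_all, 54.5)
  expect_equal(m$specificity_excl_hyper, 80.0)
})

test_that("detection metrics equal independent ratio arithmetic", {
  clean <- detection_table_from_counts(
    detected = c(small_tumor = 5, normal_hyperintense = 0,
                 normal_plain = 0),
    not_detected = c(small_tumor = 0, normal_hyperintense = 4,
                     normal_plain = 6))
  m <- detection_metrics(clean)
  expect_equal(m$specificity_all, 100)
  expect_equal(m$specificity_excl_hyper, 100)
  set.seed(10)
  for (i in 1:100) {
    ds <- sample(0:9, 1); ns <- sample(0:9, 1)
    dh <- sample(0:9, 1); nh <- sample(0:9, 1)
    dp <- sample(0:9, 1); np <- sample(0:9, 1)
    if (ds + ns == 0) ds <- 1
    tab <- detection_table_from_counts(
      detected = c(small_tumor = ds, normal_hyperintense = dh,
                   normal_plain = dp),
      not_detected = c(small_tumor = ns, normal_hyperintense = nh,
                       normal_plain = np))
    m <- detection_metrics(tab)
    expect_equal(m$sensitivity, floor(1000 * ds / (ds + ns) + 0.5) / 10)
    tot_n <- dh + nh + dp + np
    if (tot_n > 0) {
      expect_equal(m$specificity_all,
                   floor(1000 * (nh + np) / tot_n + 0.5) / 10)
    } else {
      expect_true(is.na(m$specificity_all))
    }
    if (dp + np > 0) {
      expect_equal(m$specificity_excl_hyper,
                   floor(1000 * np / (dp + np) + 0.5) / 10)
    } else {
      expect_true(is.na(m$specificity_excl_hyper))
    }
  }
})

test_that("the size bias of Dice under a fixed offset is strictly monotone", {
  st <- dice_offset_study(c(3, 5), 1)
  expect_equal(round(st$dice, 2), c(0.44, 0.64))
  expect_true(all(dice_offset_study(3:6, 0)$dice == 1))
  seq_ <- dice_offset_study(3:20, 1)$dice
  expect_true(all(diff(seq_) > 0))
  s <- 3:20
  closed <- 2 * (s - 1)^2 / (2 * (s - 1)^2 + 2 * (2 * s - 1))
  expect_equal(seq_, closed, tolerance = 1e-12)
  expect_error(dice_offset_study(1, 1), ">=")
})

test_that("case reports are written as CSV plus JSON summary", {
  scores <- tibble::tibble(case = c("a", "b"), group = "small_tumor",
                           dice = c(0.4, 0.6), detected = c(TRUE, TRUE))
  csvp <- withr::local_tempfile(fileext = ".csv")
  jsonp <- withr::local_tempfile(fileext = ".json")
  s <- write_case_report(scores, csvp, jsonp)
  expect_equal(s$mean_dice, 0.5)
  back <- utils::read.csv(csvp)
  expect_equal(nrow(back), 2)
  js <- jsonlite::read_json(jsonp)
  expect_equal(js$n_detected, 2)
})
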