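# Evaluation: voxel-wise Dice overlap, case-level detection decisions
# (connected components), the cohort sensitivity/specificity summary
# (including the hyperintensity-excluded specificity), and the Dice
# size-bias study for offset squares.

#' Dice overlap between two binary masks
#'
#' Counts voxel-wise true positives, false positives and false negatives and
#' returns `2TP / (2TP + FP + FN)`.  When both masks are empty the score is
#' 1 by convention: a correct all-negative segmentation is not penalized
#' (tumor-free cases are scored by detection, not Dice).
#'
#' @param pred,truth Binary arrays of identical shape.
#' @return A list of class `seg_score` with `tp`, `fp`, `fn`, `dice`.
#' @export
dice <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("shape mismatch between prediction and truth")
  }
  p <- pred > 0
  t <- truth > 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  d <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp = tp, fp = fp, fn = fn, dice = d), class = "seg_score")
}

#' Case-level detection rule
#'
#' A case counts as "tumor detected" when some 26-connected foreground
#' component of the predicted mask has at least `min_component_voxels`
#' voxels.  The default of 1 means any predicted voxel triggers a
#' detection; larger values trade sensitivity for specificity.
#'
#' @param min_component_voxels Positive integer (default 1).
#' @return A list of class `detection_rule`.
#' @export
detection_rule <- function(min_component_voxels = 1L) {
  min_component_voxels <- as.integer(min_component_voxels)
  stopifnot(min_component_voxels >= 1)
  structure(list(min_component_voxels = min_component_voxels),
            class = "detection_rule")
}

#' Apply the detection rule to a predicted mask
#'
#' @param pred Binary 3D array (2D inputs are treated as a single slice).
#' @param rule A [detection_rule()].
#' @return Logical: was a tumor detected?
#' @export
detect <- function(pred, rule = detection_rule()) {
  stopifnot(inherits(rule, "detection_rule"))
  m <- pred
  if (is.null(dim(m))) dim(m) <- c(length(m), 1L, 1L)
  if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1L)
  storage.mode(m) <- "integer"
  cc <- cpp_label_components(m)
  any(cc$sizes >= rule$min_component_voxels)
}

#' Connected components of a binary mask (26-connectivity)
#'
#' @param mask Binary 3D array.
#' @return A list with `labels` (integer array), `n` and `sizes`.
#' @export
label_components <- function(mask) {
  m <- mask
  if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1L)
  storage.mode(m) <- "integer"
  cpp_label_components(m)
}

#' Per-group detection table
#'
#' Tabulates detected / not-detected counts per cohort group from a
#' per-case score table (columns `group` and `detected`).
#'
#' @param scores A data frame with one row per case.
#' @return A `detection_table` tibble with columns `group`, `detected`,
#'   `not_detected`, `total`.
#' @export
detection_table <- function(scores) {
  tab <- dplyr::summarise(dplyr::group_by(scores, group),
                          detected = sum(detected),
                          not_detected = sum(!detected),
                          .groups = "drop")
  tab <- dplyr::mutate(tab, total = detected + not_detected)
  structure(tab, class = c("detection_table", class(tab)))
}

#' @rdname detection_table
#' @param detected,not_detected Named integer vectors (names are groups,
#'   e.g. `small_tumor`, `normal_hyperintense`, `normal_plain`).
#' @export
detection_table_from_counts <- function(detected, not_detected) {
  stopifnot(identical(sort(names(detected)), sort(names(not_detected))))
  g <- names(detected)
  det <- as.integer(detected[g])
  nodet <- as.integer(not_detected[g])
  tab <- tibble::tibble(group = g, detected = det, not_detected = nodet,
                        total = det + nodet)
  structure(tab, class = c("detection_table", class(tab)))
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Sensitivity and specificity from a detection table
#'
#' Sensitivity is the fraction of tumor cases detected; specificity the
#' fraction of normal cases (both plain and hyperintense) with no detection;
#' the hyperintensity-excluded specificity restricts the denominator to
#' plain normals.  All three are percentages rounded half-up to one
#' decimal; a zero denominator yields `NA` (undefined), never 0.
#'
#' @param table A [detection_table()].
#' @return A one-row tibble with `sensitivity`, `specificity_all`,
#'   `specificity_excl_hyper` (in percent).
#' @export
detection_metrics <- function(table) {
  stopifnot(inherits(table, "detection_table"))
  tumor <- dplyr::filter(table, grepl("_tumor$", group))
  if (sum(tumor$total) == 0) stop("the tumor group must be non-empty")
  normals <- dplyr::filter(table, grepl("^normal", group))
  plain <- dplyr::filter(normals, group == "normal_plain")
  pct <- function(num, den) {
    if (den == 0) return(NA_real_)
    round_half_up(100 * num / den, 1)
  }
  tibble::tibble(
    sensitivity = pct(sum(tumor$detected), sum(tumor$total)),
    specificity_all = pct(sum(normals$not_detected), sum(normals$total)),
    specificity_excl_hyper = pct(sum(plain$not_detected), sum(plain$total))
  )
}

#' Dice under a fixed segmentation offset for different object sizes
#'
#' Builds, for each square side, a ground-truth square and a prediction
#' shifted by `offset` pixels in both axes, and scores them with [dice()].
#' Under a fixed offset the score increases strictly with object size —
#' the size bias that makes small-lesion Dice systematically low.
#'
#' @param sizes Integer vector of square sides.
#' @param offset Shift in pixels (applied to both axes); sides must exceed
#'   the offset.
#' @return A tibble with `size` and `dice`.
#' @export
dice_offset_study <- function(sizes, offset = 1L) {
  stopifnot(all(sizes >= offset + 1))
  purrr::map_dfr(sizes, function(s) {
    n <- s + offset + 2L
    truth <- matrix(0L, n, n)
    truth[2:(s + 1), 2:(s + 1)] <- 1L
    pred <- matrix(0L, n, n)
    pred[(2 + offset):(s + 1 + offset), (2 + offset):(s + 1 + offset)] <- 1L
    tibble::tibble(size = s, dice = dice(pred, truth)$dice)
  })
}

#' Write a per-case evaluation report
#'
#' @param scores Per-case tibble (case, group, dice, detected).
#' @param csv_path,json_path Output files (CSV per case, JSON summary).
#' @return The summary list, invisibly.
#' @export
write_case_report <- function(scores, csv_path, json_path = NULL) {
  utils::write.csv(scores, csv_path, row.names = FALSE)
  summary <- list(n_cases = nrow(scores),
                  mean_dice = mean(scores$dice),
                  n_detected = sum(scores$detected))
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}

#' @export
print.seg_score <- function(x, ...) {
  cat(sprintf("<seg_score> dice=%.4f (TP=%d FP=%d FN=%d)\n",
              x$dice, x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
tidy.seg_score <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, dice = x$dice)
}
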