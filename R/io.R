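# On-disk formats.
#
# Clinical-style cases are written one directory per case in a documented
# sidecar format that carries the standard DICOM attribute names: per slice,
# a JSON metadata file (RescaleSlope, RescaleIntercept, WindowCenter,
# WindowWidth, PixelSpacing, SOPInstanceUID, Rows, Columns, InstanceNumber,
# SeriesDescription) plus a plain-text pixel file of stored 12-bit values;
# per annotated slice, one JSON polygon file named by SOPInstanceUID.
# Challenge-style and canonical cases are written as NIfTI (.nii.gz)
# image/label pairs.

#' Write / read a clinical-style case directory
#'
#' @param case A `synthetic_case`.
#' @param dir Output directory (created if missing).
#' @return `write_clinical_case` returns `dir`; `read_clinical_case` returns a list
#'   with `series` and `annotations` ready for [preprocess_clinical_case()].
#' @export
write_clinical_case <- function(case, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(case$series$slices)) {
    sl <- case$series$slices[[k]]
    meta <- list(RescaleSlope = sl$meta$rescale_slope,
                 RescaleIntercept = sl$meta$rescale_intercept,
                 WindowCenter = sl$meta$window_center,
                 WindowWidth = sl$meta$window_width,
                 PixelSpacing = sl$meta$pixel_spacing,
                 SOPInstanceUID = sl$meta$sop_uid,
                 Rows = nrow(sl$pixels), Columns = ncol(sl$pixels),
                 InstanceNumber = k,
                 SeriesDescription = case$series$modality_tag)
    jsonlite::write_json(meta, file.path(dir, sprintf("slice_%03d.json", k)),
                         auto_unbox = TRUE, digits = NA)
    writeLines(paste(as.integer(sl$pixels), collapse = " "),
               file.path(dir, sprintf("slice_%03d.txt", k)))
  }
  for (uid in names(case$annotations$entries)) {
    polys <- lapply(case$annotations$entries[[uid]], function(pl) {
      list(coords = unname(pl$coords), width = pl$width)
    })
    jsonlite::write_json(polys, file.path(dir, paste0("ann_", uid, ".json")),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_clinical_case
#' @export
read_clinical_case <- function(dir) {
  metas <- sort(list.files(dir, pattern = "^slice_[0-9]+\\.json$",
                           full.names = TRUE))
  if (!length(metas)) stop("no slice metadata found in ", dir)
  slices <- vector("list", length(metas))
  order_key <- integer(length(metas))
  for (i in seq_along(metas)) {
    m <- jsonlite::read_json(metas[i], simplifyVector = TRUE)
    px <- scan(sub("\\.json$", ".txt", metas[i]), what = integer(),
               quiet = TRUE)
    slices[[i]] <- list(
      pixels = matrix(px, m$Rows, m$Columns),
      meta = slice_meta(rescale_slope = m$RescaleSlope,
                        rescale_intercept = m$RescaleIntercept,
                        window_center = m$WindowCenter,
                        window_width = m$WindowWidth,
                        pixel_spacing = m$PixelSpacing,
                        sop_uid = m$SOPInstanceUID))
    order_key[i] <- m$InstanceNumber
  }
  slices <- slices[order(order_key)]
  uid0 <- slices[[1]]$meta$sop_uid
  series <- structure(list(slices = slices, plane = "axial",
                           modality_tag = "T2-FLAIR",
                           series_uid = sub("\\.[0-9]+$", "", uid0)),
                      class = "raw_series")
  anns <- list()
  for (f in list.files(dir, pattern = "^ann_.*\\.json$", full.names = TRUE)) {
    uid <- sub("^ann_(.*)\\.json$", "\\1", basename(f))
    raw <- jsonlite::read_json(f, simplifyVector = TRUE)
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    anns[[uid]] <- lapply(raw, function(pl) {
      list(coords = matrix(unlist(pl$coords), ncol = 2, byrow = FALSE),
           width = pl$width)
    })
  }
  list(series = series,
       annotations = structure(list(entries = anns),
                               class = "annotation_set"))
}

#' Write / read a challenge-style labeled volume as NIfTI
#'
#' @param case A `brats_case` from [generate_brats_like_case()].
#' @param dir Output directory.
#' @param id Case identifier used in the file names.
#' @return `write_brats_case` returns the two file paths; `read_brats_case`
#'   a list with `image` and `label` arrays.
#' @export
write_brats_case <- function(case, dir, id = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pi_ <- file.path(dir, paste0(id, "_image.nii.gz"))
  pl_ <- file.path(dir, paste0(id, "_label.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(case$image), pi_)
  RNifti::writeNifti(RNifti::asNifti(case$label * 1), pl_)
  invisible(c(image = pi_, label = pl_))
}

#' @rdname write_brats_case
#' @export
read_brats_case <- function(dir, id = "case") {
  img <- RNifti::readNifti(file.path(dir, paste0(id, "_image.nii.gz")))
  lab <- RNifti::readNifti(file.path(dir, paste0(id, "_label.nii.gz")))
  list(image = array(as.numeric(img), dim(img)),
       label = array(as.integer(round(as.numeric(lab))), dim(lab)))
}

#' Write a canonical case as a NIfTI image/label pair
#'
#' @param case A `canonical_case`.
#' @param dir Output directory.
#' @return The two file paths, invisibly.
#' @export
write_canonical_case <- function(case, dir) {
  stopifnot(inherits(case, "canonical_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pi_ <- file.path(dir, paste0(case$source_id, "_image.nii.gz"))
  pl_ <- file.path(dir, paste0(case$source_id, "_label.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(case$image), pi_)
  RNifti::writeNifti(RNifti::asNifti(case$label * 1), pl_)
  invisible(c(image = pi_, label = pl_))
}
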