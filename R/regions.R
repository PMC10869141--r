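#' Construct a region set
#'
#' A region set holds the R binary 3D masks over which histopathology
#' supervision is defined: lesion regions (targeted biopsies), sextant regions
#' (systematic biopsies) and/or the whole gland (exam-level findings). Lesion
#' masks may overlap sextant masks.
#'
#' @param masks List of binary 3D arrays on the exam grid; may be empty.
#' @param kinds Character vector, one of `"lesion"`, `"sextant"`, `"gland"` per region.
#' @param region_ids Optional identifier strings (defaults to `kind_i`).
#' @return An object of class `fl_region_set`.
#' @export
region_set <- function(masks = list(), kinds = character(0), region_ids = NULL) {
  if (length(masks) != length(kinds))
    stop_fl("got %d masks but %d kinds", length(masks), length(kinds),
            class = "fl_precondition_error")
  if (!all(kinds %in% c("lesion", "sextant", "gland")))
    stop_fl("region kinds must be lesion/sextant/gland", class = "fl_precondition_error")
  for (i in seq_along(masks)) {
    if (!all(masks[[i]] %in% c(0, 1)))
      stop_fl("region mask %d is not binary", i, class = "fl_precondition_error")
    if (sum(masks[[i]]) < 1)
      stop_fl("region mask %d is empty", i, class = "fl_empty_region_error")
  }
  if (is.null(region_ids))
    region_ids <- if (length(masks)) paste0(kinds, "_", seq_along(masks)) else character(0)
  structure(list(masks = masks, kinds = as.character(kinds),
                 region_ids = as.character(region_ids)),
            class = "fl_region_set")
}

n_regions <- function(rs) length(rs$masks)

#' @export
print.fl_region_set <- function(x, ...) {
  cat(sprintf("<fl_region_set: %d regions (%s)>\n", n_regions(x),
              paste(sprintf("%d %s", table(factor(x$kinds, c("lesion", "sextant", "gland"))),
                            c("lesion", "sextant", "gland")), collapse = ", ")))
  invisible(x)
}

#' Construct a per-region supervision record
#'
#' Each region carries a supervision signal (0 = ignore, 1 = strong, 2 = weak)
#' and a maximum ISUP grade group (0 = negative finding, 1-5). The signal
#' dynamically selects which loss terms the region feeds; signal-0 regions are
#' excluded from every term.
#'
#' @param signal Integer vector in `{0, 1, 2}`, one per region.
#' @param max_grade_group Integer vector in `{0, ..., 5}`, one per region.
#' @return An object of class `fl_supervision`.
#' @export
supervision_record <- function(signal = integer(0), max_grade_group = integer(0)) {
  if (length(signal) != length(max_grade_group))
    stop_fl("signal and max_grade_group lengths differ", class = "fl_precondition_error")
  if (length(signal) && !all(signal %in% 0:2))
    stop_fl("supervision signal must be 0, 1 or 2", class = "fl_precondition_error")
  if (length(max_grade_group) && !all(max_grade_group %in% 0:5))
    stop_fl("max_grade_group must be in 0..5", class = "fl_precondition_error")
  structure(list(signal = as.integer(signal),
                 max_grade_group = as.integer(max_grade_group)),
            class = "fl_supervision")
}

#' Binarize ISUP grade groups for the K = 2 task
#'
#' Grade group >= 2 defines clinically significant prostate cancer (the
#' positive class); grade groups 0-1 map to the negative class.
#'
#' @param gg Integer vector of ISUP grade groups (0-5).
#' @return Integer vector of 0-based class bins (0 or 1).
#' @export
binarize_grade <- function(gg) as.integer(gg >= 2L)

# One-hot rows (R x K) from 0-based class bins.
onehot_rows <- function(bins, K = 2L) {
  m <- matrix(0, nrow = length(bins), ncol = K)
  if (length(bins)) m[cbind(seq_along(bins), bins + 1L)] <- 1
  m
}

#' Construct ground-truth labels for one exam
#'
#' @param seg_mask Binary 3D array: union of annotated lesion masks (may be empty).
#' @param region_onehot Numeric matrix (R x K) of one-hot region class labels;
#'   for K = 2 these are the binarized maximum grade groups. Rows must sum to 1.
#' @return An object of class `fl_labels`.
#' @export
groundtruth_labels <- function(seg_mask, region_onehot = matrix(0, 0, 2)) {
  if (!all(seg_mask %in% c(0, 1)))
    stop_fl("seg_mask must be binary", class = "fl_precondition_error")
  region_onehot <- as.matrix(region_onehot)
  if (nrow(region_onehot) && any(abs(rowSums(region_onehot) - 1) > 1e-9))
    stop_fl("region_onehot rows must sum to 1", class = "fl_precondition_error")
  structure(list(seg_mask = seg_mask, region_onehot = region_onehot),
            class = "fl_labels")
}

#' Loss weights and numerical options of the multi-task objective
#'
#' The composite objective is
#' `alpha1*lambda1*L_region_classifier + alpha2*lambda2*L_ggmap_hist +
#'  alpha3*lambda3*L_ggmap + alpha4*lambda4*L_segmentation`.
#' Alpha and lambda enter only as products; both default to 1.
#'
#' @param alpha,lambda Non-negative length-4 weight vectors, term order
#'   (region_classifier, ggmap_hist, ggmap, segmentation).
#' @param dice_epsilon Small positive stabilizer in the dice denominator.
#' @param dice_variant `"as_printed"` (no factor 2 in the numerator; perfect
#'   overlap scores 0.5) or `"standard"` (conventional soft dice).
#' @param hist_high_variant `"suppress"` (binary cross-entropy toward zero on
#'   histogram bins above the labelled grade bin) or `"as_printed"` (the
#'   literal form, which is identically zero for one-hot labels; returns 0
#'   with a warning).
#' @param delta Stability floor applied inside every logarithm.
#' @return An object of class `fl_loss_weights`.
#' @export
loss_weights <- function(alpha = c(1, 1, 1, 1), lambda = c(1, 1, 1, 1),
                         dice_epsilon = 1e-6,
                         dice_variant = c("as_printed", "standard"),
                         hist_high_variant = c("suppress", "as_printed"),
                         delta = 1e-6) {
  if (length(alpha) != 4L || length(lambda) != 4L || any(alpha < 0) || any(lambda < 0))
    stop_fl("alpha and lambda must be non-negative length-4 vectors",
            class = "fl_precondition_error")
  if (dice_epsilon <= 0 || delta <= 0)
    stop_fl("dice_epsilon and delta must be positive", class = "fl_precondition_error")
  structure(list(alpha = as.numeric(alpha), lambda = as.numeric(lambda),
                 dice_epsilon = dice_epsilon,
                 dice_variant = match.arg(dice_variant),
                 hist_high_variant = match.arg(hist_high_variant),
                 delta = delta),
            class = "fl_loss_weights")
}

# ---- supervision sidecar + region mask IO ------------------------------------

#' Write regions and supervision to disk
#'
#' Region masks are stored as one 4D NIfTI (`<exam_id>_regions.nii.gz`,
#' regions along the first axis); the supervision sidecar
#' `<exam_id>_supervision.json` lists `{region_id, kind, signal,
#' max_grade_group}` per region. The ground-truth lesion segmentation union is
#' written as `<exam_id>_seg.nii.gz`.
#'
#' @param regions An `fl_region_set`.
#' @param record An `fl_supervision`.
#' @param labels An `fl_labels`.
#' @param spacing Voxel spacing in mm.
#' @param dir Output directory.
#' @param exam_id Exam identifier.
#' @return The sidecar path, invisibly.
#' @export
write_supervision <- function(regions, record, labels, spacing, dir, exam_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  R <- n_regions(regions)
  if (R > 0) {
    arr <- array(0, dim = c(R, dim(regions$masks[[1L]])))
    for (r in seq_len(R)) arr[r, , , ] <- regions$masks[[r]]
    nifti_write(arr, c(1, spacing), file.path(dir, sprintf("%s_regions.nii.gz", exam_id)))
  }
  nifti_write(labels$seg_mask, spacing, file.path(dir, sprintf("%s_seg.nii.gz", exam_id)))
  recs <- lapply(seq_len(R), function(r)
    list(region_id = regions$region_ids[r], kind = regions$kinds[r],
         signal = record$signal[r], max_grade_group = record$max_grade_group[r]))
  sp <- file.path(dir, sprintf("%s_supervision.json", exam_id))
  jsonlite::write_json(recs, sp, auto_unbox = TRUE, digits = NA)
  invisible(sp)
}

#' Read regions and supervision written by [write_supervision()]
#'
#' Both on-disk dialects are understood: one 4D NIfTI
#' (`<exam_id>_regions.nii.gz`) or per-region 3D files
#' (`<exam_id>_region_<region_id>.nii.gz`).
#'
#' @param dir Directory holding the files.
#' @param exam_id Exam identifier.
#' @param K Number of classes for the one-hot labels (default 2).
#' @return A list with elements `regions`, `record`, `labels`.
#' @export
read_supervision <- function(dir, exam_id, K = 2L) {
  sp <- file.path(dir, sprintf("%s_supervision.json", exam_id))
  recs <- jsonlite::read_json(sp, simplifyVector = FALSE)
  R <- length(recs)
  kinds <- vapply(recs, `[[`, "", "kind")
  ids <- vapply(recs, `[[`, "", "region_id")
  signal <- vapply(recs, function(r) as.integer(r$signal), 0L)
  max_gg <- vapply(recs, function(r) as.integer(r$max_grade_group), 0L)
  masks <- list()
  f4 <- file.path(dir, sprintf("%s_regions.nii.gz", exam_id))
  if (R > 0 && file.exists(f4)) {
    arr <- nifti_read(f4)$data
    masks <- lapply(seq_len(R), function(r) round(arr[r, , , ]))
  } else if (R > 0) {
    masks <- lapply(ids, function(id)
      round(nifti_read(file.path(dir, sprintf("%s_region_%s.nii.gz", exam_id, id)))$data))
  }
  seg <- round(nifti_read(file.path(dir, sprintf("%s_seg.nii.gz", exam_id)))$data)
  list(regions = region_set(masks, kinds, ids),
       record = supervision_record(signal, max_gg),
       labels = groundtruth_labels(seg, onehot_rows(binarize_grade(max_gg), K)))
}
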