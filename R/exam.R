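#' Construct a multi-parametric MRI exam
#'
#' An exam bundles a registered 3-channel 3D volume (T2-weighted, diffusion-weighted
#' and ADC map), a binary prostate-gland mask on the same grid, and the voxel
#' spacing in millimetres. All intensity statistics used by the normalization
#' steps are computed inside the gland mask.
#'
#' @param image Numeric 4D array, `dim = c(3, X, Y, Z)`, channel order
#'   T2WI, DWI, ADC (arbitrary units before normalization).
#' @param gland_mask Binary 3D array `dim = c(X, Y, Z)` with at least one
#'   foreground voxel.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm, axis
#'   order (x, y, z).
#' @param exam_id,site_id Opaque identifier strings.
#' @param channels Channel role names; defaults to `c("T2WI", "DWI", "ADC")`.
#' @return An object of class `fl_exam`.
#' @export
exam <- function(image, gland_mask, spacing, exam_id = "exam", site_id = "site",
                 channels = c("T2WI", "DWI", "ADC")) {
  if (length(dim(image)) != 4L)
    stop_fl("image must be a 4D array (channels, X, Y, Z)", class = "fl_shape_error")
  if (dim(image)[1L] != length(channels))
    stop_fl("image has %d channels but %d channel names were given",
            dim(image)[1L], length(channels), class = "fl_shape_error")
  if (!identical(dim(gland_mask), dim(image)[-1L]))
    stop_fl("gland_mask grid %s does not match image grid %s",
            paste(dim(gland_mask), collapse = "x"),
            paste(dim(image)[-1L], collapse = "x"), class = "fl_shape_error")
  if (!all(gland_mask %in% c(0, 1)))
    stop_fl("gland_mask must be binary", class = "fl_precondition_error")
  if (sum(gland_mask) < 1)
    stop_fl("gland_mask has no foreground voxels", class = "fl_precondition_error")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_fl("spacing must be 3 positive voxel edge lengths in mm",
            class = "fl_precondition_error")
  structure(list(image = image, gland_mask = gland_mask,
                 spacing = as.numeric(spacing),
                 exam_id = as.character(exam_id), site_id = as.character(site_id),
                 channels = channels),
            class = "fl_exam")
}

#' @export
print.fl_exam <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<fl_exam %s/%s: %d channels (%s), grid %dx%dx%d, spacing [%s] mm, gland %d vox>\n",
              x$site_id, x$exam_id, d[1L], paste(x$channels, collapse = ","),
              d[2L], d[3L], d[4L], paste(format(x$spacing, trim = TRUE), collapse = ", "),
              sum(x$gland_mask)))
  invisible(x)
}

grid_dim <- function(ex) dim(ex$image)[-1L]

#' Normalization report of an exam
#'
#' Returns the per-channel report attached by [iqr99_normalize()] (the 1st and
#' 99th gland percentiles used and the post-transform gland mean/sd), or `NULL`
#' if the exam has not been normalized.
#'
#' @param ex An `fl_exam`.
#' @return A data frame with columns `channel`, `p1`, `p99`, `post_mean`,
#'   `post_std`, or `NULL`.
#' @export
norm_report <- function(ex) attr(ex, "norm_report", exact = TRUE)

# ---- on-disk layout: NIfTI channels/masks + JSON sidecar ----------------------

nifti_write <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr, internal = FALSE)
  RNifti::pixdim(img) <- spacing[seq_along(dim(arr))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path, internal = FALSE)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a)) # drop the NIfTI header attributes
  list(data = a, spacing = as.numeric(RNifti::pixdim(img)))
}

#' Write an exam to a directory as NIfTI volumes plus a JSON sidecar
#'
#' Each channel and the gland mask are written as separate `.nii.gz` files; a
#' sidecar `<exam_id>.json` records the exam id, site id and channel roles.
#'
#' @param ex An `fl_exam`.
#' @param dir Output directory (created if missing).
#' @return The sidecar path, invisibly.
#' @export
write_exam <- function(ex, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_along(ex$channels)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", ex$exam_id, ex$channels[i]))
    nifti_write(ex$image[i, , , ], ex$spacing, f)
    files[ex$channels[i]] <- basename(f)
  }
  fg <- file.path(dir, sprintf("%s_gland.nii.gz", ex$exam_id))
  nifti_write(ex$gland_mask, ex$spacing, fg)
  sidecar <- list(exam_id = ex$exam_id, site_id = ex$site_id,
                  channels = as.list(files), gland_mask = basename(fg),
                  spacing = ex$spacing)
  sp <- file.path(dir, sprintf("%s.json", ex$exam_id))
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA)
  invisible(sp)
}

#' Read an exam written by [write_exam()]
#'
#' @param dir Directory holding the NIfTI files and sidecar.
#' @param exam_id Exam identifier (basename of the sidecar).
#' @return An `fl_exam`.
#' @export
read_exam <- function(dir, exam_id) {
  sp <- file.path(dir, sprintf("%s.json", exam_id))
  if (!file.exists(sp))
    stop_fl("no sidecar %s", sp, class = "fl_io_error")
  sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
  chans <- names(sc$channels)
  vols <- lapply(chans, function(ch) nifti_read(file.path(dir, sc$channels[[ch]]))$data)
  g <- nifti_read(file.path(dir, sc$gland_mask))
  img <- array(0, dim = c(length(chans), dim(vols[[1L]])))
  for (i in seq_along(vols)) img[i, , , ] <- vols[[i]]
  exam(img, round(g$data), as.numeric(sc$spacing), sc$exam_id, sc$site_id, chans)
}
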