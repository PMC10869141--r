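#' IQR99 intensity normalization referenced to the prostate gland
#'
#' MR image amplitudes are relative, so each channel is rescaled by the
#' robust intensity range between the 1st and 99th percentile, with both
#' percentiles computed over gland voxels only:
#' `I_norm = (I - p1) / (p99 - p1)`.
#' The same affine map is applied to out-of-gland voxels. With `clip = TRUE`
#' (the default) the result is clamped to `[0, 1]`, which removes outlying
#' values created by imaging artifacts; the un-clipped reading is kept behind
#' the flag because clamping changes gland statistics slightly.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param ex An [exam()].
#' @param clip Clamp the output to `[0, 1]`?
#' @return The normalized `fl_exam`, with a per-channel [norm_report()]
#'   attached (percentiles used, post-transform gland mean and sd).
#' @export
iqr99_normalize <- function(ex, clip = TRUE) {
  stopifnot(inherits(ex, "fl_exam"))
  gidx <- which(ex$gland_mask > 0)
  if (length(gidx) == 0L)
    stop_fl("gland mask is empty", class = "fl_precondition_error")
  nch <- dim(ex$image)[1L]
  rep_rows <- vector("list", nch)
  for (c in seq_len(nch)) {
    vol <- ex$image[c, , , ]
    p <- quantile(vol[gidx], c(0.01, 0.99), type = 7, names = FALSE)
    if (p[2L] <= p[1L])
      stop_fl("degenerate intensity in channel %s: p1 == p99 == %g",
              ex$channels[c], p[1L], class = "fl_degenerate_intensity_error")
    vol <- (vol - p[1L]) / (p[2L] - p[1L])
    if (clip) vol <- clamp(vol, 0, 1)
    ex$image[c, , , ] <- vol
    rep_rows[[c]] <- data.frame(channel = ex$channels[c], p1 = p[1L], p99 = p[2L],
                                post_mean = mean(vol[gidx]), post_std = sd(vol[gidx]))
  }
  attr(ex, "norm_report") <- do.call(rbind, rep_rows)
  ex
}

#' Z-score normalization referenced to the prostate gland
#'
#' Shifts and scales each channel so that gland voxels have zero mean and unit
#' standard deviation, addressing residual cross-patient variability after
#' [iqr99_normalize()]. Out-of-gland voxels receive the same affine map.
#'
#' @param ex An [exam()].
#' @param channels Channel names to transform; default all. The narrower
#'   reading (T2WI and DWI only) is available as
#'   `channels = c("T2WI", "DWI")`.
#' @return The normalized `fl_exam`.
#' @export
zscore_normalize <- function(ex, channels = NULL) {
  stopifnot(inherits(ex, "fl_exam"))
  gidx <- which(ex$gland_mask > 0)
  if (length(gidx) == 0L)
    stop_fl("gland mask is empty", class = "fl_precondition_error")
  channels <- channels %||% ex$channels
  for (ch in channels) {
    c <- match(ch, ex$channels)
    if (is.na(c)) stop_fl("unknown channel %s", ch, class = "fl_precondition_error")
    vol <- ex$image[c, , , ]
    mu <- mean(vol[gidx])
    s <- sd(vol[gidx])
    if (!is.finite(s) || s <= 0)
      stop_fl("degenerate intensity in channel %s: zero variance over gland voxels",
              ch, class = "fl_degenerate_intensity_error")
    ex$image[c, , , ] <- (vol - mu) / s
  }
  ex
}

#' Resample an exam to a target voxel spacing
#'
#' Continuous channels are interpolated trilinearly; the gland mask uses
#' nearest-neighbour interpolation so it stays binary. Output grid dimensions
#' are `round(dim * spacing / target_spacing)` (at least 1), with the
#' voxel-center coordinate convention.
#'
#' @param ex An [exam()].
#' @param target_spacing Numeric length-3 target spacing in mm, e.g.
#'   `c(0.66, 0.66, 2.24)`.
#' @return The resampled `fl_exam`.
#' @export
resample_to_grid <- function(ex, target_spacing) {
  stopifnot(inherits(ex, "fl_exam"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0) || any(ex$spacing <= 0))
    stop_fl("spacings must be positive length-3 mm vectors", class = "fl_precondition_error")
  if (isTRUE(all.equal(target_spacing, ex$spacing))) return(ex)
  d <- grid_dim(ex)
  out_dim <- pmax(1L, as.integer(round(d * ex$spacing / target_spacing)))
  img <- array(0, dim = c(dim(ex$image)[1L], out_dim))
  for (c in seq_len(dim(ex$image)[1L]))
    img[c, , , ] <- .resample3d(ex$image[c, , , ], ex$spacing, target_spacing, out_dim, 0L)
  mask <- .resample3d(ex$gland_mask, ex$spacing, target_spacing, out_dim, 1L)
  ex$image <- img
  ex$gland_mask <- mask
  ex$spacing <- target_spacing
  ex
}

#' Resample a single 3D mask or volume between spacings
#'
#' Convenience wrapper used for region masks and labels when an exam is
#' resampled; masks should use `method = "nearest"`.
#'
#' @param vol 3D array.
#' @param spacing,target_spacing Current and target spacing (mm).
#' @param method `"trilinear"` or `"nearest"`.
#' @return The resampled array.
#' @export
resample_volume <- function(vol, spacing, target_spacing, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  out_dim <- pmax(1L, as.integer(round(dim(vol) * spacing / target_spacing)))
  .resample3d(vol, as.numeric(spacing), as.numeric(target_spacing), out_dim,
              if (method == "nearest") 1L else 0L)
}

#' Full preprocessing pipeline for one exam
#'
#' Resamples to the target grid (if given), then applies IQR99 and Z-score
#' normalization in that order (the order is configurable).
#'
#' @param ex An [exam()].
#' @param target_spacing Optional target spacing in mm; `NULL` keeps the grid.
#' @param clip Passed to [iqr99_normalize()].
#' @param zscore Apply the Z-score step?
#' @param order Order of the two normalization steps.
#' @param zscore_channels Passed to [zscore_normalize()].
#' @return The preprocessed `fl_exam`.
#' @export
preprocess_exam <- function(ex, target_spacing = NULL, clip = TRUE, zscore = TRUE,
                            order = c("iqr99", "zscore"), zscore_channels = NULL) {
  if (!is.null(target_spacing)) ex <- resample_to_grid(ex, target_spacing)
  for (step in order) {
    if (step == "iqr99") ex <- iqr99_normalize(ex, clip = clip)
    else if (step == "zscore" && zscore) ex <- zscore_normalize(ex, channels = zscore_channels)
  }
  ex
}
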