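#' TMS slice-artifact removal and smoothing
#'
#' Pulses delivered during acquisition corrupt exactly one slice per pulse.
#' The repair strategy relies on the schedule guaranteeing that no slice is
#' targeted in two consecutive volumes: each targeted plane is replaced by
#' the mean of the same slice in the neighbouring volumes. A 4-SD rule over
#' each slice's run time course catches residual outliers, which are
#' repaired from the nearest clean volumes. Smoothing comes last.
#'
#' @name cleanup
NULL

new_slice_flag_table <- function(n_volumes, n_slices, z_threshold = NA_real_) {
  structure(list(status = matrix("clean", n_volumes, n_slices),
                 z_threshold = z_threshold),
            class = "slice_flag_table")
}

#' Interpolate TMS-targeted slices
#'
#' Replaces each targeted (volume, slice) plane with the element-wise mean
#' of the same slice in the previous and next volumes (first-order
#' interpolation). Targets in the first or last volume use the single
#' available neighbour. Errors if a slice is targeted in two consecutive
#' volumes, since both interpolation sources would then be corrupted.
#'
#' @param series a `volume_series`
#' @param targets data.frame with columns volume (0-based), slice (1-based)
#' @return list(series, flags): the repaired series and a `slice_flag_table`
#'   marking targeted planes as "interpolated"
#' @export
interpolate_targeted <- function(series, targets) {
  d <- dim(series$data)
  flags <- new_slice_flag_table(d[4], d[3])
  planes <- unique(targets[, c("volume", "slice")])
  planes <- planes[order(planes$slice, planes$volume), , drop = FALSE]
  if (nrow(planes) > 1) {
    bad <- which(diff(planes$volume) == 1 & diff(planes$slice) == 0)
    if (length(bad))
      stop(sprintf("slice %d targeted in consecutive volumes %d and %d",
                   planes$slice[bad[1]], planes$volume[bad[1]],
                   planes$volume[bad[1] + 1]))
  }
  for (r in seq_len(nrow(planes))) {
    v <- planes$volume[r] + 1L                 # 1-based array index
    z <- slice_to_z(series, planes$slice[r])
    lo <- if (v > 1) series$data[, , z, v - 1] else NULL
    hi <- if (v < d[4]) series$data[, , z, v + 1] else NULL
    series$data[, , z, v] <-
      if (is.null(lo)) hi else if (is.null(hi)) lo else (lo + hi) / 2
    flags$status[v, planes$slice[r]] <- "interpolated"
  }
  list(series = series, flags = flags)
}

#' Mask an entire slice out of all downstream analyses
#'
#' Used for slices corrupted in every condition (in Experiment 1 the deepest
#' slice, number 25 of the descending sequence, carries every 1-Hz pulse
#' artifact and is removed outright). Idempotent.
#'
#' @param series a `volume_series`
#' @param slice_index 1-based acquisition-order slice index
#' @return the series with the slice recorded in `dropped_slices`
#' @export
drop_slice <- function(series, slice_index) {
  nz <- dim(series$data)[3]
  if (slice_index < 1 || slice_index > nz)
    stop(sprintf("slice index %d out of range 1..%d", slice_index, nz))
  series$dropped_slices <- sort(unique(c(series$dropped_slices,
                                         as.integer(slice_index))))
  series
}

#' Flag outlier slices by the 4-SD rule
#'
#' For each slice, the time series of within-plane mean signal is screened:
#' volumes deviating from that slice's run mean by more than `z` SDs are
#' flagged. Mean and SD are computed excluding planes already marked
#' targeted/interpolated (they were replaced before this step, matching the
#' prescribed order). A constant time course (zero SD) yields no flags.
#'
#' @param series a `volume_series`
#' @param z threshold in SD units (default 4)
#' @param flags optional `slice_flag_table` from [interpolate_targeted()];
#'   flagged planes keep their "interpolated" status
#' @return a `slice_flag_table` with "outlier" entries
#' @export
detect_outlier_slices <- function(series, z = 4, flags = NULL) {
  d <- dim(series$data)
  if (is.null(flags)) flags <- new_slice_flag_table(d[4], d[3])
  flags$z_threshold <- z
  if (!is.finite(z)) return(flags)
  nv <- prod(d[1:2])
  for (s in seq_len(d[3])) {
    if (s %in% series$dropped_slices) next
    zz <- slice_to_z(series, s)
    means <- colMeans(matrix(series$data[, , zz, ], nv, d[4]))
    keep <- flags$status[, s] == "clean"
    mu <- mean(means[keep]); sdv <- stats::sd(means[keep])
    if (!is.finite(sdv) || sdv == 0) next
    out <- keep & abs(means - mu) > z * sdv
    flags$status[out, s] <- "outlier"
  }
  flags
}

#' Repair flagged outlier slices
#'
#' Each flagged plane is replaced by the mean of the nearest non-flagged
#' planes of the same slice before and after it; a contiguous flagged
#' stretch is bridged by the nearest clean pair spanning it. At the run
#' edges the single available clean neighbour is used. Errors if a slice is
#' flagged in every volume. Running the repair twice changes nothing.
#'
#' @param series a `volume_series`
#' @param flags a `slice_flag_table` from [detect_outlier_slices()]
#' @return the repaired `volume_series`
#' @export
repair_outliers <- function(series, flags) {
  d <- dim(series$data)
  for (s in seq_len(d[3])) {
    bad <- which(flags$status[, s] == "outlier")
    if (!length(bad)) next
    if (length(bad) == d[4])
      stop(sprintf("slice %d flagged as outlier in every volume", s))
    zz <- slice_to_z(series, s)
    good <- setdiff(seq_len(d[4]), bad)
    for (v in bad) {
      lo <- suppressWarnings(max(good[good < v]))
      hi <- suppressWarnings(min(good[good > v]))
      if (!is.finite(lo)) {
        series$data[, , zz, v] <- series$data[, , zz, hi]
      } else if (!is.finite(hi)) {
        series$data[, , zz, v] <- series$data[, , zz, lo]
      } else {
        series$data[, , zz, v] <-
          (series$data[, , zz, lo] + series$data[, , zz, hi]) / 2
      }
    }
  }
  series
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3-D Gaussian smoothing with
#' sigma = fwhm / (2 sqrt(2 ln 2)) per axis, expressed in voxel units of the
#' (possibly anisotropic) voxel sizes. Planes masked by [drop_slice()] are
#' excluded from the kernel support and the kernel is renormalised over the
#' remaining support, so masked data neither leak in nor drag means down.
#' `fwhm_mm = 0` is the identity.
#'
#' @param series a `volume_series`
#' @param fwhm_mm full width at half maximum in mm (default 6)
#' @return the smoothed `volume_series`
#' @export
smooth_gaussian <- function(series, fwhm_mm = 6) {
  if (fwhm_mm == 0) return(series)
  vx <- abs(diag(series$affine)[1:3])
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vx
  weights <- valid_plane_mask(series) + 0
  series$data <- separable_smooth(series$data, sigma_vox, weights)
  series
}

#' Framewise displacement (Power convention)
#'
#' FD_t = sum of absolute volume-to-volume differences of the three
#' translations (mm) plus 50 mm times the sum over the three rotations
#' (radians), the rotational arc on a 50-mm-radius sphere. FD of the first
#' volume is 0.
#'
#' @param motion matrix or data.frame with 6 columns: 3 translations (mm)
#'   then 3 rotations (radians)
#' @return numeric vector of per-volume FD in mm
#' @export
framewise_displacement <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion must have 6 columns (3 translations, 3 rotations)")
  d <- abs(apply(motion, 2, function(x) c(0, diff(x))))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  rowSums(d[, 1:3, drop = FALSE]) + 50 * rowSums(d[, 4:6, drop = FALSE])
}

#' Full cleanup pipeline for one run
#'
#' Targeted-slice interpolation, outlier detection and repair, optional
#' whole-slice drop, then spatial smoothing — in the prescribed order.
#'
#' @param series a `volume_series`
#' @param pulses pulse targets for this run (volume, slice)
#' @param drop integer slice indices to mask entirely (e.g. 25 for
#'   Experiment 1)
#' @param z outlier threshold in SDs
#' @param fwhm_mm smoothing kernel FWHM
#' @return list(series, flags)
#' @export
cleanup_run <- function(series, pulses, drop = integer(), z = 4, fwhm_mm = 6) {
  st <- interpolate_targeted(series, pulses)
  flags <- detect_outlier_slices(st$series, z = z, flags = st$flags)
  series <- repair_outliers(st$series, flags)
  for (s in drop) series <- drop_slice(series, s)
  series <- smooth_gaussian(series, fwhm_mm)
  list(series = series, flags = flags)
}

#' Export a slice flag table as TSV
#' @param flags a `slice_flag_table`
#' @param path output file
#' @param run run id written into the first column
#' @return invisibly, the path
#' @export
write_flag_table <- function(flags, path, run = 1L) {
  idx <- which(flags$status != "clean", arr.ind = TRUE)
  out <- data.frame(run = run, volume = idx[, 1] - 1L, slice = idx[, 2],
                    status = flags$status[idx])
  out <- out[order(out$volume, out$slice), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
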