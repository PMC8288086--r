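#' Configuration for the synthetic TMS-fMRI generator
#'
#' The generator emulates the acquisitions of the two slice-locked TMS-fMRI
#' experiments: a head phantom with seven bright fiducial capsules on a
#' simulated coil plane, and 4-D BOLD runs in which stimulation conditions
#' differ in their multivoxel pattern but, by construction, not in mean
#' activity over the pattern support.
#'
#' Defaults describe the Experiment-2 acquisition (31 slices of 40 ms, TR
#' 1240 ms, 3.0 x 3.0 x 3.5 mm voxels) with a baseline of 1000 a.u., noise
#' SD 10 a.u. (temporal SNR 100), AR(1) coefficient 0.3, a per-voxel pattern
#' amplitude of 10 a.u. (1% signal change) at the entry point decaying with
#' depth over `depth_lambda` = 15 mm, and a dominant shared
#' (frequency-ordered) pattern axis (weight 0.8) with condition-unique
#' residual axes - the monotone-pattern account of the frequency effect,
#' which is what lets a 5-vs-25 Hz decoder generalize to 8.33-vs-12.5 Hz. The
#' amplitude was fixed by a forward power calculation: after the 6-mm
#' analysis smoothing it leaves a per-voxel pattern RMS near 0.08 x
#' amplitude against a smoothed noise SD near 2.8 a.u., i.e. an aggregate
#' multivoxel separation d' of about 3-4 in the 20-mm ROI - decodable well
#' above chance from 60 trials while contributing nothing to ROI means.
#'
#' @param grid length-3 voxel counts (default 24 x 24 x 31)
#' @param voxel_mm voxel edge lengths in mm (default 3, 3, 3.5)
#' @param tr_ms repetition time in ms
#' @param slice_ms per-slice acquisition time in ms
#' @param baseline baseline signal in a.u.
#' @param noise_sd stationary SD of the temporal noise in a.u.
#' @param ar1 AR(1) coefficient of the temporal noise, in [0, 1)
#' @param pattern_amp per-voxel pattern RMS amplitude at the entry point, a.u.
#' @param depth_lambda e-folding depth of the pattern amplitude in mm
#' @param shared_axis_weight weight w in [0, 1] of the shared pattern axis
#'   (w = 1: all conditions collinear along one axis, scaled by g(condition);
#'   w = 0: mutually orthogonal condition-unique patterns)
#' @param artifact_gain multiplicative factor applied to TMS-corrupted slices
#' @param motion_sd SD of simulated motion parameters (mm; default 0)
#' @param noise_smooth_fwhm FWHM (mm) of optional spatial smoothing of the
#'   noise field; 0 disables
#' @param seed integer seed; every stochastic step derives from it
#' @return an object of class `synth_config`
#' @export
synth_config <- function(grid = c(24, 24, 31), voxel_mm = c(3, 3, 3.5),
                         tr_ms = 1240, slice_ms = 40, baseline = 1000,
                         noise_sd = 10, ar1 = 0.3, pattern_amp = 10,
                         depth_lambda = 15, shared_axis_weight = 0.8,
                         artifact_gain = 2, motion_sd = 0,
                         noise_smooth_fwhm = 0, seed = 1L) {
  stopifnot(length(grid) == 3, all(grid >= 4),
            ar1 >= 0, ar1 < 1, pattern_amp >= 0,
            shared_axis_weight >= 0, shared_axis_weight <= 1)
  structure(list(grid = as.integer(grid), voxel_mm = voxel_mm, tr_ms = tr_ms,
                 slice_ms = slice_ms, baseline = baseline, noise_sd = noise_sd,
                 ar1 = ar1, pattern_amp = pattern_amp,
                 depth_lambda = depth_lambda,
                 shared_axis_weight = shared_axis_weight,
                 artifact_gain = artifact_gain, motion_sd = motion_sd,
                 noise_smooth_fwhm = noise_smooth_fwhm,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Synthesize an anatomical phantom with fiducial capsules
#'
#' Builds an ellipsoidal head/brain, places six bright capsules in a regular
#' hexagon on a plane tangent to the scalp above the stimulation target and a
#' seventh capsule displaced along the outward plane normal from the hexagon
#' centre (the coil's upper-surface capsule). The true entry line is the
#' inward normal through that seventh (apex) capsule. Capsule intensity far
#' exceeds the brain's 99.9th percentile, as required by the fiducial
#' detector.
#'
#' @param config a `synth_config`
#' @param hexagon_radius_mm radius of the capsule hexagon (default 20)
#' @param standoff_mm gap between scalp and coil plane (default 6)
#' @param apex_height_mm height of the apex capsule above the coil plane
#' @param capsule_radius_mm capsule radius (default 3.2)
#' @return list with `anat` (3-D array), `brain_mask` (logical array),
#'   `affine`, and `truth` (fiducials 7x3 mm, entry apex/direction,
#'   hexagon centre, brain centre/semi-axes)
#' @export
make_anatomy <- function(config, hexagon_radius_mm = 20, standoff_mm = 6,
                         apex_height_mm = 10, capsule_radius_mm = 3.2) {
  d <- config$grid; vx <- config$voxel_mm
  affine <- make_affine(vx)
  extent <- (d - 1) * vx
  # snap the target column to a voxel centre so the noiseless entry line
  # runs through voxel centres (keeps the round-trip error sub-voxel)
  centre_xy <- vx[1:2] * round(extent[1:2] / 2 / vx[1:2])
  z_max <- extent[3]
  brain_top <- z_max - (standoff_mm + apex_height_mm + capsule_radius_mm + 3)
  semi_z <- min(40, brain_top / 2)
  semi_xy <- min(0.44 * extent[1:2])
  centre <- c(centre_xy, brain_top - semi_z)
  semi <- c(semi_xy, semi_xy, semi_z)

  xyz <- grid_world_coords(d, affine)
  q <- ((xyz[, 1] - centre[1]) / semi[1])^2 +
       ((xyz[, 2] - centre[2]) / semi[2])^2 +
       ((xyz[, 3] - centre[3]) / semi[3])^2
  brain_mask <- array(q <= 1, d)

  # smooth intensity variation inside the brain so the 99.9th percentile is
  # well defined and below the capsule intensity
  set.seed(config$seed + 101L)
  anat <- array(10 + stats::rnorm(prod(d), 0, 2), d)
  anat[brain_mask] <- 600 + 50 * sin(xyz[brain_mask, 1] / 11) *
    cos(xyz[brain_mask, 2] / 13) + stats::rnorm(sum(brain_mask), 0, 10)

  # coil plane tangent to the scalp above the target: horizontal plane at
  # brain_top + standoff, hexagon centred above the brain centre
  plane_z <- brain_top + standoff_mm
  if (plane_z <= brain_top)
    stop("hexagon plane intersects the brain mask; configuration rejected")
  # keep the hexagon inside the field of view on small grids
  hexagon_radius_mm <- min(hexagon_radius_mm, 0.45 * min(extent[1:2]))
  ang <- seq(0, 2 * pi, length.out = 7)[1:6] + pi / 6
  hexagon <- cbind(centre[1] + hexagon_radius_mm * cos(ang),
                   centre[2] + hexagon_radius_mm * sin(ang),
                   plane_z)
  apex <- c(centre[1:2], plane_z + apex_height_mm)
  fiducials <- rbind(hexagon, apex)
  if (max(fiducials[, 3]) + capsule_radius_mm > z_max + vx[3] / 2)
    stop("fiducial capsules fall outside the field of view")
  # any capsule inside the brain would invalidate the geometry
  qf <- ((fiducials[, 1] - centre[1]) / semi[1])^2 +
        ((fiducials[, 2] - centre[2]) / semi[2])^2 +
        ((fiducials[, 3] - centre[3]) / semi[3])^2
  if (any(qf <= 1))
    stop("hexagon plane intersects the brain mask; configuration rejected")

  # soft-edged bright capsules (partial-volume weighting keeps the
  # intensity-weighted centroid close to the true centre on a coarse grid)
  for (r in seq_len(nrow(fiducials))) {
    dist <- sqrt(colSums((t(xyz) - fiducials[r, ])^2))
    w <- stats::pnorm((capsule_radius_mm - dist) / 1.2)
    sel <- w > 0.01
    anat[sel] <- anat[sel] + 3000 * w[sel]
  }

  entry_direction <- c(0, 0, -1)   # inward plane normal
  list(anat = anat, brain_mask = brain_mask, affine = affine,
       truth = list(fiducials = fiducials, apex = apex,
                    entry_direction = entry_direction,
                    hexagon_centre = c(centre[1:2], plane_z),
                    entry_point = c(centre[1:2], brain_top),
                    brain_centre = centre, brain_semi_axes = semi))
}

#' Condition-specific zero-mean voxel patterns with depth decay
#'
#' For condition c with ordinal value g(c), the pattern is
#' amp * decay(d) * (w * g(c) * U + (1 - w) * V_c), where d is distance from
#' the brain entry point, decay = exp(-d / depth_lambda), U is a fixed
#' zero-mean unit-RMS spatial map shared by all conditions and the V_c are
#' condition-unique zero-mean unit-RMS maps, mutually orthogonal and
#' orthogonal to U. Every pattern is re-centred to exact zero mean over its
#' support, so conditions share identical spatial-mean responses by
#' construction: the decodable signal carries no univariate footprint.
#'
#' Two properties make the patterns decodable yet invisible to univariate
#' analysis. First, the component maps are drawn spatially correlated at
#' the analysis smoothing scale (`pattern_fwhm_mm`), so the decodable
#' structure survives the 6-mm preprocessing smoothing instead of being
#' averaged away. Second, each final pattern is projected orthogonal to the
#' smoothed ROI-mean functionals of the analysis spheres placed on the true
#' entry line (`mean_match_radii`): after preprocessing smoothing, the mean
#' of every condition's pattern over each analysis ROI is exactly zero, so
#' conditions are mean-matched at the scales the univariate tests look at
#' while the fine-grained multivoxel structure remains. Every pattern also
#' has exact zero mean over its whole support.
#'
#' @param config a `synth_config`
#' @param entry_point mm coordinates of the brain entry point
#' @param brain_mask logical 3-D array (the pattern support)
#' @param conditions character vector of condition labels (>= 2)
#' @param g ordinal value per condition; default: centred log frequency for
#'   the Experiment-2 labels, otherwise a centred 1..K ramp
#' @param affine 4x4 affine of the grid (default from config voxel sizes)
#' @param entry_direction unit vector of the stimulation axis (into the
#'   brain; default straight down)
#' @param pattern_fwhm_mm spatial correlation scale of the component maps
#'   (default 6, the preprocessing smoothing kernel)
#' @param mean_match_radii radii (mm) of the analysis ROIs whose smoothed
#'   means are projected out (default 8, 12, 16, 20; NULL disables)
#' @param data_fwhm_mm the preprocessing smoothing the projection accounts
#'   for (default 6)
#' @return list with `patterns` (named list of 3-D arrays), `support`
#'   (logical array), `g`, and the maps `U`, `V`
#' @export
make_patterns <- function(config, entry_point, brain_mask, conditions,
                          g = NULL, affine = make_affine(config$voxel_mm),
                          entry_direction = c(0, 0, -1),
                          pattern_fwhm_mm = 6,
                          mean_match_radii = c(8, 12, 16, 20),
                          data_fwhm_mm = 6) {
  stopifnot(length(conditions) >= 2)
  support <- which(brain_mask)
  if (length(support) < 10) stop("pattern support smaller than 10 voxels")
  n <- length(support)
  if (is.null(g)) {
    freqs <- exp2_frequencies()
    g <- if (all(conditions %in% names(freqs))) log(freqs[conditions])
         else seq_along(conditions)
    g <- as.numeric(g - mean(g))
    names(g) <- conditions
  }
  d <- dim(brain_mask)
  xyz <- grid_world_coords(d, affine)[support, , drop = FALSE]
  dist <- sqrt(colSums((t(xyz) - entry_point)^2))
  decay <- exp(-dist / config$depth_lambda)

  set.seed(config$seed + 202L)
  K <- length(conditions)
  raw <- matrix(stats::rnorm(n * (K + 1)), n, K + 1)
  if (pattern_fwhm_mm > 0) {
    sig_vox <- pattern_fwhm_mm / (2 * sqrt(2 * log(2))) / config$voxel_mm
    w3 <- brain_mask + 0
    for (j in seq_len(K + 1)) {
      f <- array(0, d); f[support] <- raw[, j]
      sm <- separable_smooth(array(f, c(d, 1)), sig_vox, w3)
      raw[, j] <- sm[cbind(arrayInd(support, d), 1)]
    }
  }
  raw <- sweep(raw, 2, colMeans(raw))          # zero-mean columns
  basis <- qr.Q(qr(raw))                       # orthonormal, still ~zero-mean
  basis <- sweep(basis, 2, colMeans(basis))    # re-centre exactly
  basis <- sweep(basis, 2, sqrt(colMeans(basis^2)), "/")  # unit RMS
  U <- basis[, 1]
  V <- basis[, -1, drop = FALSE]

  # constraint matrix: intercept + smoothed ROI-mean functionals, so that
  # after the analysis smoothing every pattern has zero mean over each
  # analysis sphere on the entry line
  W <- matrix(1, n, 1)
  if (!is.null(mean_match_radii) && length(mean_match_radii)) {
    Wr <- tryCatch(
      roi_mean_functionals(brain_mask, affine, entry_point, entry_direction,
                           mean_match_radii, data_fwhm_mm)[support, ,
                                                           drop = FALSE],
      error = function(e) NULL)
    if (!is.null(Wr)) W <- cbind(W, Wr)
  }
  # drop collinear constraint columns (coarse grids can voxelize two radii
  # to the same sphere)
  qw <- qr(W)
  W <- W[, qw$pivot[seq_len(qw$rank)], drop = FALSE]
  WtWi <- solve(crossprod(W))

  w <- config$shared_axis_weight
  patterns <- list()
  for (i in seq_along(conditions)) {
    vals <- config$pattern_amp * decay * (w * g[i] * U + (1 - w) * V[, i])
    vals <- vals - W %*% (WtWi %*% crossprod(W, vals))   # mean-matching
    p <- array(0, d); p[support] <- vals
    patterns[[conditions[i]]] <- p
  }
  sup <- array(FALSE, d); sup[support] <- TRUE
  list(patterns = patterns, support = sup, g = g, U = U, V = V,
       decay = decay, entry_point = entry_point)
}

# Adjoint-smoothed ROI-mean functionals: column r satisfies
# <column_r, p> = mean over ROI_r of the smoothed pattern p, for the
# renormalised separable smoothing S(x) = sm(x) / sm(1) used in
# preprocessing. The adjoint is sm(b / sm(1)) for ROI indicator b.
roi_mean_functionals <- function(brain_mask, affine, entry_point,
                                 entry_direction, radii, fwhm_mm) {
  d <- dim(brain_mask)
  vx <- abs(diag(affine)[1:3])
  sig_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vx
  Ks <- lapply(1:3, function(a) gauss_conv_matrix(d[a], sig_vox[a]))
  sm <- function(x) {
    for (a in 1:3) x <- apply_along_axis(x, Ks[[a]], a)
    x
  }
  den <- sm(array(1, d))
  line <- structure(list(apex = entry_point - 15 * entry_direction,
                         direction = entry_direction),
                    class = "entry_line")
  cols <- lapply(radii, function(r) {
    roi <- place_roi(line, brain_mask, affine, r)
    b <- array(0, d); b[roi$voxels] <- 1 / nrow(roi$voxels)
    as.vector(sm(b / den))
  })
  do.call(cbind, cols)
}

# Condition regressors sampled at volume times: boxcar over each trial's
# full stimulation window convolved with the canonical HRF.
condition_regressors <- function(events, conditions, n_volumes, tr_s,
                                 hrf = hrf_spec(), dt = 0.1) {
  t_hi <- seq(0, n_volumes * tr_s + hrf$length, by = dt)
  kern <- canonical_hrf(hrf, dt = dt)
  X <- matrix(0, n_volumes, length(conditions),
              dimnames = list(NULL, conditions))
  frame_times <- (seq_len(n_volumes) - 1) * tr_s
  for (ci in seq_along(conditions)) {
    box <- numeric(length(t_hi))
    ev <- events[events$trial_type == conditions[ci], , drop = FALSE]
    for (r in seq_len(nrow(ev)))
      box[t_hi >= ev$onset[r] & t_hi < ev$onset[r] + ev$duration[r]] <- 1
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(t_hi)] * dt
    X[, ci] <- stats::approx(t_hi, conv, xout = frame_times, rule = 2)$y
  }
  X
}

#' Simulate one clean BOLD run
#'
#' signal(v, t) = baseline + sum over conditions of pattern_c(v) times the
#' HRF-convolved boxcar of that condition's trials, plus AR(1) noise with
#' stationary SD `noise_sd`, optionally spatially smoothed. Deterministic
#' given `config$seed` and `run`.
#'
#' @param schedule a `session_schedule`
#' @param run run number within the schedule
#' @param patterns result of [make_patterns()] (or a named list of 3-D
#'   arrays matching the schedule's condition labels)
#' @param config a `synth_config`
#' @return a `volume_series`
#' @export
simulate_run <- function(schedule, run, patterns, config) {
  pats <- if (!is.null(patterns$patterns)) patterns$patterns else patterns
  d <- config$grid
  stopifnot(all(vapply(pats, function(p) identical(dim(p), d), logical(1))))
  nt <- schedule$n_volumes_per_run
  tr_s <- schedule$tr_ms / 1000
  ev <- schedule$events[schedule$events$run == run, , drop = FALSE]
  conds <- names(pats)
  X <- condition_regressors(ev, conds, nt, tr_s)

  P <- vapply(pats, as.vector, numeric(prod(d)))    # voxels x conditions
  signal <- tcrossprod(P, X)                        # voxels x time

  set.seed(config$seed + 1000L * run)
  innov_sd <- config$noise_sd * sqrt(1 - config$ar1^2)
  E <- matrix(stats::rnorm(prod(d) * nt, 0, innov_sd), prod(d), nt)
  if (config$ar1 > 0) {
    E[, 1] <- E[, 1] / sqrt(1 - config$ar1^2)       # stationary start
    for (t in 2:nt) E[, t] <- config$ar1 * E[, t - 1] + E[, t]
  }
  arr <- array(config$baseline + signal + E, c(d, nt))
  if (config$noise_smooth_fwhm > 0) {
    # smooth the noise field only, preserving the pattern term
    sig_vox <- config$noise_smooth_fwhm / (2 * sqrt(2 * log(2))) / config$voxel_mm
    En <- separable_smooth(array(E, c(d, nt)), sig_vox)
    sc <- config$noise_sd / stats::sd(as.vector(En[, , , min(nt, 5)]))
    arr <- array(config$baseline + signal, c(d, nt)) + En * sc
  }
  volume_series(arr, make_affine(config$voxel_mm), schedule$tr_ms,
                schedule$slice_ms)
}

#' Multiply TMS-targeted slices by the artifact gain
#'
#' Every (volume, slice) plane named by the pulse targets is multiplied by
#' `gain`; all other voxels are untouched. Duplicate targets (several pulses
#' in one slice of one volume) are collapsed with a warning so the gain is
#' applied once per plane.
#'
#' @param series a `volume_series`
#' @param pulses data.frame with columns volume (0-based) and slice (1-based
#'   acquisition order), e.g. the run-subset of `schedule$pulses`
#' @param gain multiplicative artifact factor
#' @return the corrupted `volume_series`, with attribute "corrupted" holding
#'   the unique (volume, slice) pairs
#' @export
inject_artifacts <- function(series, pulses, gain) {
  d <- dim(series$data)
  stopifnot(all(pulses$volume >= 0), all(pulses$volume < d[4]),
            all(pulses$slice >= 1), all(pulses$slice <= d[3]))
  planes <- unique(pulses[, c("volume", "slice")])
  if (nrow(planes) < nrow(pulses))
    warning(sprintf("%d duplicate (volume, slice) targets collapsed",
                    nrow(pulses) - nrow(planes)))
  if (gain != 1) {
    for (r in seq_len(nrow(planes))) {
      z <- slice_to_z(series, planes$slice[r])
      tt <- planes$volume[r] + 1L
      series$data[, , z, tt] <- series$data[, , z, tt] * gain
    }
  }
  attr(series, "corrupted") <- planes[order(planes$volume, planes$slice), ]
  series
}

#' Write a full synthetic dataset to disk
#'
#' Emits NIfTI functional runs (with artifacts if `gain != 1`), the
#' anatomical phantom and brain mask, per-run events and a pulses table,
#' zero (or simulated) motion parameters, per-condition ground-truth pattern
#' NIfTIs and a `truth.json` bundle. Re-runnable byte-identically for a
#' given seed.
#'
#' @param out_dir output directory
#' @param schedule a `session_schedule`
#' @param config a `synth_config`
#' @param with_artifacts logical; inject slice artifacts (default TRUE)
#' @return invisibly, the dataset manifest (also stored in truth.json)
#' @export
write_dataset <- function(out_dir, schedule, config, with_artifacts = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anat <- make_anatomy(config)
  pats <- make_patterns(config, anat$truth$entry_point, anat$brain_mask,
                        names(schedule$conditions))
  write_nifti_vol(anat$anat, anat$affine, file.path(out_dir, "anat.nii.gz"))
  write_nifti_vol(anat$brain_mask + 0, anat$affine,
                  file.path(out_dir, "mask.nii.gz"))
  runs <- sort(unique(schedule$events$run))
  func_paths <- character()
  for (r in runs) {
    series <- simulate_run(schedule, r, pats, config)
    if (with_artifacts)
      series <- inject_artifacts(series,
                                 schedule$pulses[schedule$pulses$run == r, ],
                                 config$artifact_gain)
    p <- file.path(out_dir, sprintf("func_run-%02d.nii.gz", r))
    write_nifti_vol(series$data, series$affine, p)
    func_paths <- c(func_paths, p)
    set.seed(config$seed + 3000L + r)
    mot <- matrix(stats::rnorm(schedule$n_volumes_per_run * 6,
                               0, config$motion_sd),
                  schedule$n_volumes_per_run, 6)
    colnames(mot) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
    utils::write.table(round(mot, 6),
                       file.path(out_dir, sprintf("motion_run-%02d.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_events(schedule, out_dir)
  pat_paths <- character()
  for (nm in names(pats$patterns)) {
    p <- file.path(out_dir, sprintf("truth_pattern_%s.nii.gz", nm))
    write_nifti_vol(pats$patterns[[nm]], anat$affine, p)
    pat_paths <- c(pat_paths, p)
  }
  manifest <- list(
    seed = config$seed, experiment = schedule$experiment,
    conditions = names(schedule$conditions),
    config = unclass(config),
    entry_point = anat$truth$entry_point, apex = anat$truth$apex,
    entry_direction = anat$truth$entry_direction,
    fiducials = anat$truth$fiducials,
    func = basename(func_paths), anat = "anat.nii.gz", mask = "mask.nii.gz",
    pattern_files = basename(pat_paths))
  jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
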