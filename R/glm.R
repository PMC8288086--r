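#' HRF specification (double-gamma)
#'
#' The canonical haemodynamic response: a gamma density peaking ~5 s after
#' onset minus a ratio-scaled undershoot gamma peaking ~15 s, normalised to
#' peak 1. Defaults are the standard 6/16 s delays, unit dispersions and
#' undershoot ratio 6.
#'
#' @param peak_delay,undershoot_delay gamma shape parameters in s
#' @param peak_disp,undershoot_disp gamma dispersions (scales) in s
#' @param ratio undershoot attenuation (peak / ratio)
#' @param length kernel length in s (>= 24)
#' @return an `hrf_spec`
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
                     undershoot_disp = 1, ratio = 6, length = 32) {
  stopifnot(length >= 24)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length = length),
            class = "hrf_spec")
}

#' Sample the canonical HRF
#'
#' @param spec an `hrf_spec`
#' @param dt sample step in s (> 0)
#' @return numeric kernel sampled at 0, dt, 2 dt, ...; kernel(0) = 0 and the
#'   peak value is 1
#' @export
canonical_hrf <- function(spec = hrf_spec(), dt = 0.1) {
  stopifnot(dt > 0)
  t <- seq(0, spec$length, by = dt)
  h <- stats::dgamma(t, shape = spec$peak_delay / spec$peak_disp,
                     scale = spec$peak_disp)
  if (spec$ratio > 0)
    h <- h - stats::dgamma(t, shape = spec$undershoot_delay / spec$undershoot_disp,
                           scale = spec$undershoot_disp) / spec$ratio
  h / max(h)
}

#' Build a design matrix for one run
#'
#' Three modes. "condition": one boxcar per condition spanning each trial's
#' full stimulation window (individual pulses are not modelled), convolved
#' with the canonical HRF and sampled at volume times — with 6 motion
#' regressors and a constant this gives 10 columns per run in Experiment 1
#' and 11 in Experiment 2. "trial": one such regressor per trial (the
#' decoding GLM). "fir": one indicator column per post-onset TR bin per
#' condition, no HRF assumption. Motion and constant are appended in all
#' modes.
#'
#' @param schedule a `session_schedule`
#' @param run run number
#' @param motion n_volumes x 6 matrix (or NULL for zeros)
#' @param mode "condition", "trial" or "fir"
#' @param hrf an `hrf_spec`
#' @param fir_window FIR window length in s (default 24)
#' @return a `design_matrix`: list(values, names, frame_times, trial_info)
#' @export
build_design <- function(schedule, run, motion = NULL,
                         mode = c("condition", "trial", "fir"),
                         hrf = hrf_spec(), fir_window = 24) {
  mode <- match.arg(mode)
  run <- as.integer(run)
  nt <- schedule$n_volumes_per_run
  tr_s <- schedule$tr_ms / 1000
  ev <- schedule$events[schedule$events$run == run, , drop = FALSE]
  frame_times <- (seq_len(nt) - 1) * tr_s
  conds <- names(schedule$conditions)
  trial_info <- NULL
  if (mode == "condition") {
    X <- condition_regressors(ev, conds, nt, tr_s, hrf)
    task_names <- conds
  } else if (mode == "trial") {
    if (nrow(ev) > 1) {
      o <- order(ev$onset)
      if (any(diff(ev$onset[o]) < ev$duration[o][-nrow(ev)] - 1e-9))
        stop("overlapping trials cannot be modelled in trial mode")
    }
    cols <- lapply(seq_len(nrow(ev)), function(i) {
      one <- ev[i, , drop = FALSE]
      condition_regressors(one, one$trial_type, nt, tr_s, hrf)
    })
    X <- do.call(cbind, cols)
    task_names <- sprintf("trial%03d_%s", seq_len(nrow(ev)), ev$trial_type)
    trial_info <- data.frame(name = task_names, condition = ev$trial_type,
                             run = run, onset = ev$onset,
                             stringsAsFactors = FALSE)
  } else {
    if (fir_window <= 0) stop("FIR window must be positive")
    nbins <- ceiling(fir_window / tr_s)
    X <- matrix(0, nt, 0)
    task_names <- character()
    for (cn in conds) {
      on <- ev$onset[ev$trial_type == cn]
      B <- matrix(0, nt, nbins)
      for (o in on) {
        v0 <- floor(o / tr_s + 1e-9)
        for (b in seq_len(nbins)) {
          v <- v0 + b
          if (v >= 1 && v <= nt) B[v, b] <- B[v, b] + 1
        }
      }
      X <- cbind(X, B)
      task_names <- c(task_names, sprintf("%s_bin%02d", cn, seq_len(nbins)))
    }
  }
  if (is.null(motion)) motion <- matrix(0, nt, 6)
  motion <- as.matrix(motion)
  stopifnot(nrow(motion) == nt, ncol(motion) == 6)
  keep_mot <- apply(motion, 2, function(x) stats::sd(x) > 0)
  Xfull <- cbind(X, motion, 1)
  colnames(Xfull) <- c(task_names,
                       paste0("motion", 1:6), "constant")
  # zero-variance motion columns are kept out of the fit to preserve rank
  drop <- which(!keep_mot) + length(task_names)
  structure(list(values = Xfull, names = colnames(Xfull),
                 frame_times = frame_times, trial_info = trial_info,
                 task_cols = seq_along(task_names), null_cols = drop,
                 mode = mode, run = run, row_runs = rep(run, nt)),
            class = "design_matrix")
}

#' Stack per-run designs block-diagonally
#'
#' Task, motion and constant regressors all stay run-specific (session-wise
#' modelling); the returned design spans the concatenated runs.
#'
#' @param designs list of `design_matrix` objects, one per run
#' @return a `design_matrix` with run-prefixed column names
#' @export
combine_designs <- function(designs) {
  nts <- vapply(designs, function(d) nrow(d$values), integer(1))
  total <- sum(nts)
  ncols <- vapply(designs, function(d) ncol(d$values), integer(1))
  X <- matrix(0, total, sum(ncols))
  nm <- character(sum(ncols)); null_cols <- integer()
  r0 <- 0L; c0 <- 0L
  trial_info <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    X[r0 + seq_len(nts[i]), c0 + seq_len(ncols[i])] <- d$values
    nm[c0 + seq_len(ncols[i])] <- sprintf("run%d_%s", d$run, d$names)
    null_cols <- c(null_cols, c0 + d$null_cols)
    if (!is.null(d$trial_info)) trial_info[[i]] <- d$trial_info
    r0 <- r0 + nts[i]; c0 <- c0 + ncols[i]
  }
  colnames(X) <- nm
  structure(list(values = X, names = nm,
                 frame_times = unlist(lapply(designs, `[[`, "frame_times")),
                 trial_info = if (length(trial_info)) do.call(rbind, trial_info) else NULL,
                 null_cols = null_cols, mode = designs[[1]]$mode,
                 runs = vapply(designs, `[[`, integer(1) , "run"),
                 row_runs = unlist(lapply(designs, `[[`, "row_runs"))),
            class = "design_matrix")
}

#' Ordinary least squares fit per voxel
#'
#' Solves the GLM by QR decomposition for every voxel in the mask. Columns
#' flagged as identically zero (e.g. all-zero motion parameters) are
#' excluded from the solve and reported with beta 0. Errors on a
#' rank-deficient design, naming the collinear columns.
#'
#' With `whiten = TRUE` the fit is repeated after AR(1) prewhitening
#' (Cochrane-Orcutt): the lag-1 autocorrelation of the pooled OLS residuals
#' is estimated per fit and both data and design are quasi-differenced
#' within each run block before the final solve, so t statistics are
#' calibrated under temporally autocorrelated noise.
#'
#' @param series a `volume_series`, a list of them (concatenated runs), or
#'   a scans x voxels matrix
#' @param design a `design_matrix`
#' @param mask logical 3-D array or voxel-index vector selecting voxels
#'   (required for a `volume_series`; ignored for a matrix)
#' @param whiten logical; AR(1) prewhitening (default FALSE)
#' @return a `beta_maps`: list(betas regressors x voxels, sigma2, dof,
#'   xtx_inv, names, voxel_index, rho)
#' @export
fit_ols <- function(series, design, mask = NULL, whiten = FALSE) {
  grid_dim <- NULL
  if (inherits(series, "volume_series")) {
    d <- dim(series$data)
    grid_dim <- d[1:3]
    if (is.null(mask)) mask <- valid_plane_mask(series)
    vox <- if (is.logical(mask)) which(mask & valid_plane_mask(series)) else as.integer(mask)
    if (!length(vox)) stop("empty mask")
    Y <- matrix(series$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
    Y <- t(Y)
  } else if (is.list(series) && all(vapply(series, inherits, logical(1), "volume_series"))) {
    d <- dim(series[[1]]$data)
    grid_dim <- d[1:3]
    if (is.null(mask)) mask <- valid_plane_mask(series[[1]])
    vox <- if (is.logical(mask)) which(mask & valid_plane_mask(series[[1]])) else as.integer(mask)
    if (!length(vox)) stop("empty mask")
    Y <- do.call(rbind, lapply(series, function(s)
      t(matrix(s$data, prod(d[1:3]), dim(s$data)[4])[vox, , drop = FALSE])))
  } else {
    Y <- as.matrix(series)
    vox <- seq_len(ncol(Y))
  }
  X <- design$values
  stopifnot(nrow(X) == nrow(Y))
  use <- setdiff(seq_len(ncol(X)), design$null_cols)
  Xu <- X[, use, drop = FALSE]
  qrx <- qr(Xu)
  if (qrx$rank < ncol(Xu)) {
    bad <- colnames(Xu)[qrx$pivot[(qrx$rank + 1):ncol(Xu)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  beta_u <- qr.coef(qrx, Y)
  resid <- Y - Xu %*% beta_u
  rho <- 0
  if (whiten) {
    rr <- design$row_runs
    if (is.null(rr)) rr <- rep(1L, nrow(Y))
    lag1 <- function(e) {
      num <- 0; den <- 0
      for (r in unique(rr)) {
        idx <- which(rr == r)
        er <- e[idx, , drop = FALSE]
        num <- num + sum(er[-1, , drop = FALSE] * er[-length(idx), , drop = FALSE])
        den <- den + sum(er^2)
      }
      num / den
    }
    wtrans <- function(M, r1) {
      for (r in unique(rr)) {
        idx <- which(rr == r)
        first <- idx[1]
        M[idx[-1], ] <- M[idx[-1], , drop = FALSE] -
          r1 * M[idx[-length(idx)], , drop = FALSE]
        M[first, ] <- sqrt(1 - r1^2) * M[first, , drop = FALSE]
      }
      M
    }
    # iterate the quasi-differencing until the residuals are white
    for (it in 1:4) {
      r1 <- max(min(lag1(resid), 0.95), -0.5)
      if (abs(r1) < 0.01) break
      Y <- wtrans(Y, r1)
      Xu <- wtrans(Xu, r1)
      qrx <- qr(Xu)
      beta_u <- qr.coef(qrx, Y)
      resid <- Y - Xu %*% beta_u
      if (it == 1) rho <- r1 else rho <- rho + r1 * (1 - rho)
    }
  }
  dof <- nrow(Y) - qrx$rank
  sigma2 <- colSums(resid^2) / dof
  betas <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), NULL))
  betas[use, ] <- beta_u
  piv <- qrx$pivot
  xtx_inv_u <- matrix(0, ncol(Xu), ncol(Xu))
  xtx_inv_u[piv, piv] <- chol2inv(qr.R(qrx))
  xtx_inv <- matrix(0, ncol(X), ncol(X))
  xtx_inv[use, use] <- xtx_inv_u
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 xtx_inv = xtx_inv, names = colnames(X),
                 voxel_index = vox, grid_dim = grid_dim, rho = rho),
            class = "beta_maps")
}

#' Linear contrast of GLM betas
#'
#' effect = c'beta per voxel; t = effect / sqrt(sigma2 * c'(X'X)^-1 c).
#'
#' @param fit a `beta_maps`
#' @param cvec contrast vector, either full length or named by regressor
#' @return a `contrast_result`: list(effect, t, se, dof, cvec)
#' @export
contrast <- function(fit, cvec) {
  if (!is.null(names(cvec))) {
    full <- numeric(length(fit$names)); names(full) <- fit$names
    miss <- setdiff(names(cvec), fit$names)
    if (length(miss)) stop("unknown regressors: ", paste(miss, collapse = ", "))
    full[names(cvec)] <- cvec
    cvec <- full
  }
  stopifnot(length(cvec) == nrow(fit$betas))
  if (all(cvec == 0)) stop("zero contrast vector")
  effect <- as.vector(t(cvec) %*% fit$betas)
  var_c <- as.numeric(t(cvec) %*% fit$xtx_inv %*% cvec)
  se <- sqrt(fit$sigma2 * var_c)
  structure(list(effect = effect, se = se,
                 t = ifelse(se > 0, effect / se, 0),
                 dof = fit$dof, cvec = cvec),
            class = "contrast_result")
}

#' Pairwise condition contrast across runs
#'
#' Builds the contrast vector (a - b), replicated over each run's condition
#' column and divided by the number of runs, for a combined
#' (block-diagonal) condition-mode fit.
#'
#' @param fit a `beta_maps` from a combined condition-mode design
#' @param a,b condition labels (contrast is a minus b)
#' @return a `contrast_result`
#' @export
condition_contrast <- function(fit, a, b) {
  ca <- grep(sprintf("^run[0-9]+_%s$", a), fit$names, value = TRUE)
  cb <- grep(sprintf("^run[0-9]+_%s$", b), fit$names, value = TRUE)
  if (!length(ca) || !length(cb)) stop("conditions not found in design")
  cv <- c(stats::setNames(rep(1 / length(ca), length(ca)), ca),
          stats::setNames(rep(-1 / length(cb), length(cb)), cb))
  contrast(fit, cv)
}

#' ROI-mean parameter estimate
#'
#' Mean of a beta or contrast-effect map over the ROI voxels (planes dropped
#' by [drop_slice()] are already excluded from the ROI mask). Significance
#' of an ROI contrast is assessed exactly by fitting the ROI-mean time
#' series via [fit_roi_mean()] and applying [contrast()] to that fit.
#'
#' @param result a `contrast_result`, or a numeric vector of per-voxel
#'   values aligned with `fit$voxel_index`
#' @param roi a `spherical_roi`
#' @param fit the `beta_maps` the result came from (for voxel indexing)
#' @return scalar mean over the ROI voxels (a.u.)
#' @export
roi_parameter_estimate <- function(result, roi, fit) {
  vals <- if (inherits(result, "contrast_result")) result$effect else result
  sel <- match(roi_linear_index(roi, fit), fit$voxel_index)
  sel <- sel[!is.na(sel)]
  if (!length(sel)) stop("empty ROI mask after intersection with fitted voxels")
  mean(vals[sel])
}

roi_linear_index <- function(roi, fit) {
  d <- fit$grid_dim
  if (is.null(d)) stop("fit carries no grid dimensions; use fit_ols on a volume_series")
  as.integer(roi$voxels[, 1] + (roi$voxels[, 2] - 1) * d[1] +
               (roi$voxels[, 3] - 1) * d[1] * d[2])
}

#' Fit the GLM to the ROI-mean time series
#'
#' Averages the series over the ROI voxels first, then fits the design —
#' the exact ROI-level inference used for the univariate null checks.
#'
#' @param series_list list of `volume_series`, one per run
#' @param design combined `design_matrix` matching the concatenation
#' @param roi a `spherical_roi`
#' @param whiten AR(1) prewhitening (default TRUE: ROI-level inference is
#'   the calibrated path)
#' @return a `beta_maps` with a single "voxel" (the ROI mean)
#' @export
fit_roi_mean <- function(series_list, design, roi, whiten = TRUE) {
  ys <- lapply(series_list, function(s) {
    d <- dim(s$data)
    lin <- roi$voxels[, 1] + (roi$voxels[, 2] - 1) * d[1] +
      (roi$voxels[, 3] - 1) * d[1] * d[2]
    colMeans(matrix(s$data, prod(d[1:3]), d[4])[lin, , drop = FALSE])
  })
  y <- matrix(unlist(ys), ncol = 1)
  fit_ols(y, design, whiten = whiten)
}

#' FIR time courses in an ROI
#'
#' Fits the FIR design to the ROI-mean series and converts the per-bin
#' betas to percent signal change against the run constant. Returns one
#' curve per condition with the OLS standard error of each bin.
#'
#' @param series_list list of `volume_series`, one per run
#' @param schedule the `session_schedule`
#' @param roi a `spherical_roi`
#' @param motion list of motion matrices (or NULL)
#' @param fir_window window length in s (default 24; must cover the longest
#'   trial plus 10 s)
#' @return data.frame(bin_s, condition, psc, se)
#' @export
fir_timecourse <- function(series_list, schedule, roi, motion = NULL,
                           fir_window = 24) {
  if (fir_window <= 0) stop("FIR window must be positive")
  longest <- max(schedule$events$duration)
  if (fir_window < longest + 10)
    stop(sprintf("FIR window must cover the longest trial plus 10 s (>= %g s)",
                 longest + 10))
  runs <- sort(unique(schedule$events$run))
  designs <- lapply(seq_along(runs), function(i)
    build_design(schedule, runs[i],
                 motion = if (is.null(motion)) NULL else motion[[i]],
                 mode = "fir", fir_window = fir_window))
  design <- combine_designs(designs)
  fit <- fit_roi_mean(series_list, design, roi)
  tr_s <- schedule$tr_ms / 1000
  nbins <- ceiling(fir_window / tr_s)
  const_cols <- grep("_constant$", fit$names)
  baseline <- mean(fit$betas[const_cols, 1])
  out <- list()
  for (cn in names(schedule$conditions)) {
    for (b in seq_len(nbins)) {
      cols <- grep(sprintf("^run[0-9]+_%s_bin%02d$", cn, b), fit$names)
      cv <- numeric(length(fit$names))
      cv[cols] <- 1 / length(cols)
      cr <- contrast(fit, stats::setNames(cv, fit$names)[cv != 0])
      out[[length(out) + 1L]] <- data.frame(
        bin_s = b * tr_s, condition = cn,
        psc = 100 * cr$effect / baseline,
        se = 100 * cr$se / baseline)
    }
  }
  do.call(rbind, out)
}
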