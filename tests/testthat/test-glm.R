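test_that("the canonical HRF has the standard double-gamma shape", {
  h <- canonical_hrf(hrf_spec(), dt = 0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak_t <- t[which.max(h)]
  expect_gte(peak_t, 4.5); expect_lte(peak_t, 6)
  # undershoot present around 15 s
  expect_lt(min(h[t > 10 & t < 25]), 0)
  # ratio 0: single gamma, strictly positive after onset
  h0 <- canonical_hrf(hrf_spec(ratio = 0), dt = 0.1)
  expect_true(all(h0[-1] > 0))
})

test_that("design matrices carry the published regressor counts", {
  s1 <- build_exp1_session(0)
  d1 <- build_design(s1, run = 1, mode = "condition")
  expect_equal(ncol(d1$values), 10)            # 3 condition + 6 motion + constant
  s2 <- build_exp2_session(0)
  d2 <- build_design(s2, run = 1, mode = "condition")
  expect_equal(ncol(d2$values), 11)            # 4 condition + 6 motion + constant
  # trial mode: 90 trial regressors over the 3 Experiment-1 runs
  trial_cols <- vapply(1:3, function(r)
    length(grep("^trial", build_design(s1, r, mode = "trial")$names)),
    integer(1))
  expect_equal(sum(trial_cols), 90)
  # zero-event schedule: motion + constant only
  s0 <- s1; s0$events <- s1$events[0, ]
  d0 <- build_design(s0, run = 1, mode = "condition")
  task <- setdiff(seq_len(ncol(d0$values)), d0$null_cols)
  expect_equal(d0$names[task], c("low1Hz", "high1Hz", "burst", "constant"))
  expect_true(all(d0$values[, 1:3] == 0))
})

test_that("OLS equals the brute-force normal-equations solution", {
  set.seed(21)
  n <- 20
  X <- cbind(stats::rnorm(n), stats::rnorm(n), 1)
  colnames(X) <- c("a", "b", "constant")
  des <- structure(list(values = X, names = colnames(X),
                        null_cols = integer(), row_runs = rep(1L, n)),
                   class = "design_matrix")
  Y <- matrix(stats::rnorm(n * 3), n, 3)
  fit <- fit_ols(Y, des)
  # independent oracle: solve the normal equations directly
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% Y
  expect_lt(max(abs(fit$betas - beta_oracle)), 1e-10)
  resid <- Y - X %*% beta_oracle
  expect_equal(fit$sigma2, colSums(resid^2) / (n - 3), tolerance = 1e-12)
  expect_equal(fit$dof, n - 3)
  # noiseless recovery to machine precision
  truth <- matrix(c(2, -1, 5), 3, 1)
  fitn <- fit_ols(X %*% truth, des)
  expect_lt(max(abs(fitn$betas - truth)), 1e-8)
  # design = constant only: beta is the time mean
  desc <- structure(list(values = matrix(1, n, 1, dimnames = list(NULL, "constant")),
                         names = "constant", null_cols = integer(),
                         row_runs = rep(1L, n)),
                    class = "design_matrix")
  expect_equal(as.vector(fit_ols(Y, desc)$betas), colMeans(Y))
  # rank deficiency is refused with the offending columns named
  Xbad <- cbind(X, dup = X[, 1])
  desb <- structure(list(values = Xbad, names = colnames(Xbad),
                         null_cols = integer(), row_runs = rep(1L, n)),
                    class = "design_matrix")
  expect_error(fit_ols(Y, desb), "collinear")
})

test_that("contrasts, their SEs and ROI estimates are exact", {
  set.seed(22)
  n <- 40
  X <- cbind(a = stats::rnorm(n), b = stats::rnorm(n), constant = 1)
  des <- structure(list(values = X, names = colnames(X),
                        null_cols = integer(), row_runs = rep(1L, n)),
                   class = "design_matrix")
  y <- X %*% c(1.5, 0.5, 10) + stats::rnorm(n)
  fit <- fit_ols(matrix(y, ncol = 1), des)
  # oracle via lm
  lmf <- stats::lm(y ~ 0 + X)
  cr <- contrast(fit, c(a = 1, b = -1))
  cv <- c(1, -1, 0)
  expect_equal(cr$effect, sum(cv * stats::coef(lmf)), tolerance = 1e-10)
  expect_equal(cr$se, sqrt(as.numeric(t(cv) %*% stats::vcov(lmf) %*% cv)),
               tolerance = 1e-10)
  # the zero contrast (e_a - e_a) is refused
  expect_error(contrast(fit, c(a = 0)), "zero")
  expect_error(contrast(fit, c(1, -1, 0) - c(1, -1, 0)), "zero")
  expect_error(contrast(fit, c(nope = 1)), "unknown")
})

test_that("ROI parameter estimates average the requested voxels only", {
  ser <- toy_series(dim = c(5, 5, 5), nt = 12)
  set.seed(23)
  ser$data <- array(stats::rnorm(length(ser$data)), dim(ser$data))
  des <- structure(list(values = matrix(1, 12, 1,
                                        dimnames = list(NULL, "constant")),
                        names = "constant", null_cols = integer(),
                        row_runs = rep(1L, 12)),
                   class = "design_matrix")
  fit <- fit_ols(ser, des, mask = array(TRUE, c(5, 5, 5)))
  roi <- structure(list(voxels = rbind(c(2, 2, 2), c(3, 3, 3)),
                        coords_mm = rbind(c(3, 3, 3.5), c(6, 6, 7))),
                   class = "spherical_roi")
  est <- roi_parameter_estimate(fit$betas["constant", ], roi, fit)
  expect_equal(est, mean(c(mean(ser$data[2, 2, 2, ]),
                           mean(ser$data[3, 3, 3, ]))))
  # constant map k -> k
  est2 <- roi_parameter_estimate(rep(7.7, length(fit$voxel_index)), roi, fit)
  expect_equal(est2, 7.7)
  # empty intersection is an error
  roi_out <- structure(list(voxels = matrix(c(99, 99, 99), 1)),
                       class = "spherical_roi")
  expect_error(roi_parameter_estimate(fit$betas["constant", ], roi_out, fit))
})

test_that("FIR recovers the noiseless HRF-convolved boxcar", {
  sched <- tiny_exp2_schedule()
  # single hz5 trial so every FIR bin is identified without overlap
  sched$conditions <- sched$conditions["hz5"]
  sched$events <- sched$events[sched$events$trial_type == "hz5", ][1, ]
  sched$pulses <- sched$pulses[sched$pulses$condition == "hz5", ]
  cfg <- synth_config(grid = c(6, 6, 6), noise_sd = 0, seed = 30)
  flat <- list(hz5 = array(5, cfg$grid))    # uniform 5 a.u. response
  run <- simulate_run(sched, 1, flat, cfg)
  roi <- structure(list(voxels = as.matrix(expand.grid(2:4, 2:4, 2:4))),
                   class = "spherical_roi")
  fir <- fir_timecourse(list(run), sched, roi, fir_window = 40)
  tr_s <- sched$tr_ms / 1000
  # oracle: the convolved boxcar at lags 0, TR, 2 TR, ... as percent change
  ev <- sched$events[1, ]; ev$onset <- 0
  nbins <- ceiling(40 / tr_s)
  X <- tmspattern:::condition_regressors(ev, "hz5", nbins, tr_s)
  expected <- 100 * 5 * X[, 1] / cfg$baseline
  got <- fir$psc[fir$condition == "hz5"]
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
  # the curve rises to a clear peak a few seconds after onset
  expect_gt(max(got), 0.5)
  expect_equal(got[1], 0, tolerance = 1e-8)
  expect_error(fir_timecourse(list(run), sched, roi, fir_window = 0),
               "positive")
})

test_that("an injected univariate effect is recovered by the ROI contrast", {
  sched <- tiny_exp2_schedule()
  cfg <- synth_config(grid = c(6, 6, 6), noise_sd = 2, seed = 31)
  pats <- lapply(stats::setNames(nm = names(sched$conditions)),
                 function(nm) array(0, cfg$grid))
  pats[["hz25"]] <- array(0.8, cfg$grid)        # Delta = 0.8 a.u. everywhere
  run <- simulate_run(sched, 1, pats, cfg)
  des <- combine_designs(list(build_design(sched, 1, mode = "condition")))
  roi <- structure(list(voxels = as.matrix(expand.grid(1:6, 1:6, 1:6))),
                   class = "spherical_roi")
  rf <- fit_roi_mean(list(run), des, roi)
  cr <- condition_contrast(rf, "hz25", "hz5")
  expect_equal(cr$effect[1], 0.8, tolerance = 0.15)
  expect_lt(2 * stats::pt(-abs(cr$t[1]), cr$dof), 0.01)
})
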