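test_that("GNB parameters match the hand-worked example", {
  fm <- feature_matrix(matrix(c(-1, 0, 1, 2), 4, 1),
                       labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  m <- gnb_fit(fm)
  expect_equal(as.vector(m$means), c(-0.5, 1.5))
  expect_equal(as.vector(m$vars), c(0.25, 0.25))   # ML variance, denominator n
  expect_equal(m$priors, c(0.5, 0.5))
  pr <- gnb_predict(m, matrix(0, 1, 1))
  expect_equal(pr$labels, "A")
  # identical classes give identical parameters
  fm2 <- feature_matrix(matrix(c(1, 2, 1, 2), 4, 1),
                        labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  m2 <- gnb_fit(fm2)
  expect_equal(m2$means[1, ], m2$means[2, ])
  expect_equal(m2$vars[1, ], m2$vars[2, ])
  # constant feature hits the variance floor without blowing up
  fmc <- feature_matrix(matrix(c(5, 5, 5, 5, 1, 2, 1, 2), 4, 2),
                        labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  mc <- gnb_fit(fmc)
  expect_true(all(mc$vars >= mc$floor))
  expect_true(all(is.finite(gnb_predict(mc, matrix(c(5, 1.5), 1, 2))$log_posterior)))
  expect_error(gnb_fit(feature_matrix(matrix(1:3, 3, 1),
                                      labels = c("A", "B", "B"),
                                      runs = c(1, 1, 2))), ">= 2 samples")
})

test_that("GNB posteriors equal an independent brute-force Bayes computation", {
  set.seed(31)
  X <- matrix(stats::rnorm(8), 4, 2)
  fm <- feature_matrix(X, labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  m <- gnb_fit(fm)
  test <- matrix(stats::rnorm(6), 3, 2)
  pr <- gnb_predict(m, test)
  # oracle: explicit products of Gaussian densities per class, with the
  # model's pooled (equal-n) variances computed from first principles
  ml_var <- function(rows) apply(X[rows, ], 2, function(x) mean(x^2) - mean(x)^2)
  v_pooled <- pmax((ml_var(1:2) + ml_var(3:4)) / 2, m$floor)
  for (i in 1:3) for (k in 1:2) {
    mu <- colMeans(X[(2 * k - 1):(2 * k), ])
    lp <- log(0.5) + sum(stats::dnorm(test[i, ], mu, sqrt(v_pooled), log = TRUE))
    expect_equal(pr$log_posterior[i, k], lp, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # with class-specific variances the densities use each class's own ML
  # variance
  m_cl <- gnb_fit(fm, pooled_variance = FALSE)
  pr_cl <- gnb_predict(m_cl, test)
  for (k in 1:2) {
    mu <- colMeans(X[(2 * k - 1):(2 * k), ])
    v <- pmax(ml_var((2 * k - 1):(2 * k)), m_cl$floor)
    lp <- log(0.5) + sum(stats::dnorm(test[1, ], mu, sqrt(v), log = TRUE))
    expect_equal(pr_cl$log_posterior[1, k], lp, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # model applied to its own class means classifies perfectly
  self <- gnb_predict(m, m$means)
  expect_equal(self$labels, m$classes)
  # exact posterior ties break to the first class and are flagged
  sym <- feature_matrix(matrix(c(-1, -2, 1, 2), 4, 1),
                        labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  ms <- gnb_fit(sym)
  tie <- gnb_predict(ms, matrix(0, 1, 1))
  expect_true(tie$tie)
  expect_equal(tie$labels, "A")
  expect_error(gnb_predict(m, matrix(0, 1, 5)), "mismatch")
})

test_that("leave-one-run-out CV partitions by run and scores correctly", {
  set.seed(32)
  # perfectly separated classes: accuracy 1
  n <- 24
  labels <- rep(c("A", "B"), each = 12)
  runs <- rep(rep(1:3, each = 4), 2)
  X <- matrix(stats::rnorm(n * 5, ifelse(labels == "A", -3, 3)), n, 5)
  fm <- feature_matrix(X, labels, runs)
  cv <- cross_validate_loro(fm)
  expect_equal(cv$accuracy, 1)
  expect_length(cv$fold_accuracy, 3)
  expect_equal(mean(cv$correct), cv$accuracy)
  # shuffled labels: near chance (permutation oracle)
  set.seed(33)
  accs <- replicate(30, {
    sh <- fm
    for (r in 1:3) {
      idx <- which(sh$runs == r)
      sh$labels[idx] <- sample(sh$labels[idx])
    }
    cross_validate_loro(sh)$accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 2 * stats::sd(accs) / sqrt(30) + 0.05)
  # a run missing a class is refused
  bad <- feature_matrix(X[runs != 1 | labels != "A", ],
                        labels[runs != 1 | labels != "A"],
                        runs[runs != 1 | labels != "A"])
  expect_error(cross_validate_loro(bad), "missing a class")
})

test_that("cross-pair generalization transfers along the shared axis only", {
  # shared axis (w = 1): 5/25-trained decoder transfers to 8.33/12.5
  fm1 <- feature_session(w = 1, amp = 2, beta_noise_sd = 1, seed = 41,
                         trials_per_run = 8)
  g1 <- cross_pair_generalization(fm1, c("hz5", "hz25"), c("hz8.33", "hz12.5"))
  expect_gt(g1$accuracy, 0.7)
  expect_gt(g1$train_accuracy, 0.9)
  # orthogonal unique patterns (w = 0): transfer collapses to chance on
  # average (a single session is bimodal: the unique test patterns project
  # onto an arbitrary side of the trained boundary)
  acc0 <- mean(vapply(41:52, function(s) {
    fm0 <- feature_session(w = 0, amp = 2, beta_noise_sd = 1, seed = s,
                           trials_per_run = 8)
    cross_pair_generalization(fm0, c("hz5", "hz25"),
                              c("hz8.33", "hz12.5"))$accuracy
  }, numeric(1)))
  expect_lt(abs(acc0 - 0.5), 0.2)
  # the label mapping follows frequency order
  expect_equal(unname(g1$mapping["hz8.33"]), "hz5")
  expect_equal(unname(g1$mapping["hz12.5"]), "hz25")
  # train = test reduces to resubstitution
  gr <- cross_pair_generalization(fm1, c("hz5", "hz25"), c("hz5", "hz25"))
  expect_equal(gr$accuracy, gr$train_accuracy)
  expect_error(cross_pair_generalization(fm1, c("hz5", "hz25"),
                                         c("hz25", "hz12.5")), "overlap")
})

test_that("Gini information gain scores the textbook separator and selects stably", {
  # a voxel perfectly separating 2+2 labels at the median: gain 0.5
  fm <- feature_matrix(matrix(c(1, 2, 10, 11, 5, 5, 5, 5), 4, 2),
                       labels = c("A", "A", "B", "B"), runs = c(1, 2, 1, 2))
  rk <- gini_information_gain(fm)
  expect_equal(unname(rk$gain[1]), 0.5)
  # a constant voxel carries no information
  expect_equal(unname(rk$gain[2]), 0)
  # label-independent voxels score near zero on average
  set.seed(34)
  Xn <- matrix(stats::rnorm(40 * 30), 40, 30)
  fmn <- feature_matrix(Xn, labels = rep(c("A", "B"), 20),
                        runs = rep(1:2, each = 20))
  rkn <- gini_information_gain(fmn)
  expect_lt(mean(rkn$gain), 0.1)       # small-sample bias bound
  # deterministic: same input, same ranking
  expect_identical(rkn$gain, gini_information_gain(fmn)$gain)
  # top-N selection honours N
  rk2 <- gini_information_gain(fmn, top_n = 5)
  expect_equal(sum(rk2$selected), 5)
})

test_that("informative voxels concentrate in the upper hemisphere under depth decay", {
  fm <- feature_session(w = 0.5, amp = 3, beta_noise_sd = 1, seed = 42,
                        trials_per_run = 8)
  rk <- gini_information_gain(fm)
  enr <- hemisphere_enrichment(rk, fm$upper)
  expect_gt(enr$prop_upper, 0.5)
  expect_lt(enr$p_vs_share, 0.05)
  # uniform selection tracks the upper-half share
  all_sel <- rk; all_sel$selected <- rep(TRUE, length(rk$selected))
  enr_all <- hemisphere_enrichment(all_sel, fm$upper)
  expect_equal(enr_all$prop_upper, enr_all$upper_share)
  # degenerate cases
  one_sided <- rk
  one_sided$selected <- fm$upper
  expect_equal(hemisphere_enrichment(one_sided, fm$upper)$prop_upper, 1)
  none <- rk; none$selected <- rep(FALSE, length(rk$selected))
  expect_error(hemisphere_enrichment(none, fm$upper), "empty")
})

test_that("chance testing handles normal, degenerate and null cases", {
  cv <- structure(list(correct = rep(TRUE, 20), chance = 0.25),
                  class = "cv_result")
  ts <- test_vs_chance(cv)
  expect_true(is.na(ts$t))                        # zero variance: binomial only
  expect_lt(ts$p_binom, 1e-10)
  cv2 <- structure(list(correct = rep(c(TRUE, FALSE), 10), chance = 0.5),
                   class = "cv_result")
  ts2 <- test_vs_chance(cv2)
  expect_equal(ts2$t, 0)
  expect_equal(ts2$accuracy, 0.5)
})

test_that("permutation chance floors sit at 1/k for balanced designs", {
  set.seed(35)
  for (k in c(2, 4)) {
    labels <- rep(letters[1:k], times = 3 * 4)
    runs <- rep(1:3, each = 4 * k)
    X <- matrix(stats::rnorm(length(labels) * 10), length(labels), 10)
    fm <- feature_matrix(X, labels, runs)
    pc <- permutation_chance(fm, n_perm = 100, seed = 36)
    se <- stats::sd(pc$accuracies) / sqrt(length(pc$accuracies))
    expect_lt(abs(pc$mean - 1 / k), 2 * se + 0.02)
  }
  expect_error(permutation_chance(feature_matrix(matrix(stats::rnorm(24), 12),
                                                 rep(c("a", "b"), 6),
                                                 rep(1:2, each = 6)),
                                  n_perm = 10), ">= 100")
})

test_that("feature extraction returns one row per trial and survives 1-voxel ROIs", {
  sched <- tiny_exp2_schedule()
  cfg <- synth_config(grid = c(8, 8, 8), seed = 43, noise_sd = 3)
  pats <- lapply(stats::setNames(nm = names(sched$conditions)),
                 function(nm) array(stats::rnorm(512, 0, 0.5), c(8, 8, 8)))
  # three shortened runs so LORO is possible
  sched3 <- tiny_exp2_schedule(n_runs = 3)
  runs <- lapply(1:3, function(r) simulate_run(sched3, r, pats, cfg))
  des <- combine_designs(lapply(1:3, function(r)
    build_design(sched3, r, mode = "trial")))
  fit <- fit_ols(runs, des, mask = array(TRUE, c(8, 8, 8)))
  roi <- structure(list(voxels = as.matrix(expand.grid(3:6, 3:6, 3:6)),
                        coords_mm = matrix(0, 64, 3)),
                   class = "spherical_roi")
  fm <- extract_features(fit, roi)
  expect_equal(dim(fm$values), c(12, 64))        # 3 runs x 4 trials
  expect_equal(sort(unique(fm$runs)), 1:3)
  expect_setequal(unique(fm$labels), names(sched$conditions))
  roi1 <- structure(list(voxels = matrix(c(4, 4, 4), 1),
                         coords_mm = matrix(0, 1, 3)),
                    class = "spherical_roi")
  fm1 <- extract_features(fit, roi1)
  expect_equal(ncol(fm1$values), 1)
})
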