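#' Trial-wise multivoxel decoding
#'
#' Gaussian naive Bayes over trial-wise GLM beta patterns, with
#' leave-one-run-out cross-validation, cross-pair generalization, Gini
#' information-gain voxel ranking and chance-level testing.
#'
#' @name decode
NULL

#' Assemble the trial x voxel feature matrix
#'
#' Rows are trials (from a trial-mode GLM fit), columns are ROI voxels;
#' dropped planes were excluded when the ROI was built.
#'
#' By default each trial's betas are noise-normalised: divided by the
#' design-based standard-error factor sqrt((X'X)^-1_jj) of that trial's
#' regressor (the t-map convention common in MVPA). Conditions of unequal
#' stimulation duration yield trial betas of unequal estimation variance;
#' without normalisation a prototype classifier picks up that nuisance
#' (class prototypes of quiet conditions are estimated more tightly), so a
#' signal-free pipeline would sit above chance. Normalisation restores a
#' calibrated chance level. The cost is that class means are rescaled per
#' condition; analyses that depend on a common pattern scale across
#' conditions (cross-pair generalization) should use raw betas
#' (`noise_normalise = FALSE`).
#'
#' @param fit a `beta_maps` from a trial-mode design
#' @param roi a `spherical_roi`
#' @param noise_normalise divide each trial's betas by its design SE factor
#'   (default TRUE)
#' @return a `feature_matrix`: list(values trials x voxels, labels, runs,
#'   voxel_coords mm, upper logical per voxel if the ROI was split)
#' @export
extract_features <- function(fit, roi, noise_normalise = TRUE) {
  info <- fit_trial_info(fit)
  sel <- match(roi_linear_index(roi, fit), fit$voxel_index)
  keep <- !is.na(sel)
  if (!any(keep)) stop("empty ROI")
  rows <- grep("^run[0-9]+_trial[0-9]+_", fit$names)
  vals <- fit$betas[rows, sel[keep], drop = FALSE]   # trials x voxels
  if (noise_normalise) {
    se_fac <- sqrt(diag(fit$xtx_inv)[rows])
    vals <- vals / se_fac
  }
  feature_matrix(vals, labels = info$condition, runs = info$run,
                 voxel_coords = roi$coords_mm[keep, , drop = FALSE],
                 upper = if (!is.null(roi$upper)) roi$upper[keep] else NULL)
}

fit_trial_info <- function(fit) {
  rows <- grep("^run[0-9]+_trial[0-9]+_", fit$names, value = TRUE)
  if (!length(rows)) stop("fit does not come from a trial-mode design")
  data.frame(
    run = as.integer(sub("^run([0-9]+)_.*$", "\\1", rows)),
    condition = sub("^run[0-9]+_trial[0-9]+_(.*)$", "\\1", rows),
    stringsAsFactors = FALSE)
}

#' Construct a feature matrix
#' @param values trials x voxels numeric matrix
#' @param labels condition label per trial
#' @param runs run id per trial
#' @param voxel_coords optional voxels x 3 mm coordinates
#' @param upper optional logical per voxel (upper-hemisphere flag)
#' @return a `feature_matrix`
#' @export
feature_matrix <- function(values, labels, runs, voxel_coords = NULL,
                           upper = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(labels), length(labels) == length(runs),
            !anyNA(values), length(unique(labels)) >= 2)
  structure(list(values = values, labels = as.character(labels),
                 runs = as.integer(runs), voxel_coords = voxel_coords,
                 upper = upper),
            class = "feature_matrix")
}

subset_trials <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], fm$labels[idx], fm$runs[idx],
                 fm$voxel_coords, fm$upper)
}

#' Fit a Gaussian naive Bayes model
#'
#' Per class and voxel: the sample mean and maximum-likelihood variance
#' (denominator n), floored at `floor_frac` times the largest feature
#' variance so constant features cannot blow up the likelihood. Priors are
#' uniform (the designs are balanced).
#'
#' By default the per-voxel variances are pooled across classes (the
#' sample-size-weighted mean of the class ML variances). Stimulation
#' conditions of unequal duration yield trial betas with unequal estimation
#' variance, and class-specific variances would let the classifier decode
#' that nuisance — a signal-free dataset would leave chance. Pooling keeps
#' the classifier a mean-pattern decoder; set `pooled_variance = FALSE` for
#' fully class-specific Gaussians.
#'
#' @param train a `feature_matrix`
#' @param floor_frac variance floor as a fraction of the maximum
#'   per-class/voxel variance (default 1e-9)
#' @param pooled_variance share variances across classes (default TRUE)
#' @return a `gnb_model`: list(classes, priors, means, vars K x voxels)
#' @export
gnb_fit <- function(train, floor_frac = 1e-9, pooled_variance = TRUE) {
  classes <- sort(unique(train$labels))
  if (any(table(train$labels) < 2)) stop("every class needs >= 2 samples")
  K <- length(classes); V <- ncol(train$values)
  means <- matrix(0, K, V); vars <- matrix(0, K, V)
  nk <- numeric(K)
  for (k in seq_len(K)) {
    Xk <- train$values[train$labels == classes[k], , drop = FALSE]
    nk[k] <- nrow(Xk)
    means[k, ] <- colMeans(Xk)
    vars[k, ] <- colMeans(Xk^2) - colMeans(Xk)^2       # ML variance
  }
  if (pooled_variance) {
    pooled <- colSums(vars * nk) / sum(nk)
    vars <- matrix(pooled, K, V, byrow = TRUE)
  }
  floor_val <- max(floor_frac * max(vars), .Machine$double.xmin)
  vars <- pmax(vars, floor_val)
  structure(list(classes = classes, priors = rep(1 / K, K),
                 means = means, vars = vars, floor = floor_val,
                 pooled_variance = pooled_variance),
            class = "gnb_model")
}

#' Predict with a Gaussian naive Bayes model
#'
#' argmax over classes of log prior + sum over voxels of the Gaussian log
#' density. Exact posterior ties break to the lowest (first) class label
#' and are flagged.
#'
#' @param model a `gnb_model`
#' @param test a `feature_matrix` or trials x voxels matrix
#' @return list(labels, log_posterior trials x classes, tie logical)
#' @export
gnb_predict <- function(model, test) {
  X <- if (inherits(test, "feature_matrix")) test$values else as.matrix(test)
  if (ncol(X) != ncol(model$means))
    stop(sprintf("feature dimension mismatch: model has %d voxels, test has %d",
                 ncol(model$means), ncol(X)))
  K <- length(model$classes)
  lp <- matrix(0, nrow(X), K, dimnames = list(NULL, model$classes))
  for (k in seq_len(K)) {
    mu <- model$means[k, ]; v <- model$vars[k, ]
    d2 <- sweep(X, 2, mu)^2
    lp[, k] <- log(model$priors[k]) - 0.5 * sum(log(2 * pi * v)) -
      0.5 * as.vector(d2 %*% (1 / v))
  }
  best <- max.col(lp, ties.method = "first")
  tie <- apply(lp, 1, function(r) sum(r == max(r)) > 1)
  list(labels = model$classes[best], log_posterior = lp, tie = tie)
}

#' Leave-one-run-out cross-validation
#'
#' For each run: train on all other runs, predict that run's trials. Mean
#' accuracy is reported both per fold and over all trials (equal per-trial
#' weighting; with balanced runs the two coincide).
#'
#' @param features a `feature_matrix` spanning >= 2 runs
#' @param classes optional subset of labels to decode (default all)
#' @return a `cv_result`: list(predicted, correct, accuracy,
#'   fold_accuracy, chance, n_classes)
#' @export
cross_validate_loro <- function(features, classes = NULL) {
  fm <- features
  if (!is.null(classes)) fm <- subset_trials(fm, fm$labels %in% classes)
  runs <- sort(unique(fm$runs))
  if (length(runs) < 2) stop("need >= 2 runs for leave-one-run-out CV")
  labs <- sort(unique(fm$labels))
  for (r in runs)
    if (!all(labs %in% fm$labels[fm$runs == r]))
      stop(sprintf("run %d is missing a class", r))
  predicted <- character(length(fm$labels))
  tie <- logical(length(fm$labels))
  fold_acc <- numeric(length(runs))
  for (i in seq_along(runs)) {
    test_idx <- which(fm$runs == runs[i])
    model <- gnb_fit(subset_trials(fm, -test_idx))
    pr <- gnb_predict(model, fm$values[test_idx, , drop = FALSE])
    predicted[test_idx] <- pr$labels
    tie[test_idx] <- pr$tie
    fold_acc[i] <- mean(pr$labels == fm$labels[test_idx])
  }
  correct <- predicted == fm$labels
  structure(list(predicted = predicted, labels = fm$labels, runs = fm$runs,
                 correct = correct, accuracy = mean(correct),
                 fold_accuracy = fold_acc, tie = tie,
                 n_classes = length(labs), chance = 1 / length(labs)),
            class = "cv_result")
}

#' Train on one frequency pair, test on another
#'
#' Trains a two-class GNB on all trials of `train_pair` and tests on all
#' trials of `test_pair`, mapping test labels to training labels by ordinal
#' (frequency) correspondence: lower to lower, higher to higher.
#'
#' @param features a `feature_matrix` containing all four labels
#' @param train_pair,test_pair length-2 character vectors of disjoint labels
#' @param order_by named numeric vector giving each label's ordinal value
#'   (default: the Experiment-2 frequencies)
#' @return list(accuracy, mapping, train_accuracy (resubstitution), n_test)
#' @export
cross_pair_generalization <- function(features, train_pair, test_pair,
                                      order_by = exp2_frequencies()) {
  if (length(intersect(train_pair, test_pair)) &&
      !identical(sort(train_pair), sort(test_pair)))
    stop("train and test pairs overlap")
  stopifnot(all(c(train_pair, test_pair) %in% features$labels))
  train_pair <- train_pair[order(order_by[train_pair])]
  test_pair <- test_pair[order(order_by[test_pair])]
  mapping <- stats::setNames(train_pair, test_pair)
  tr <- subset_trials(features, features$labels %in% train_pair)
  model <- gnb_fit(tr)
  te <- subset_trials(features, features$labels %in% test_pair)
  pr <- gnb_predict(model, te$values)
  expected <- mapping[te$labels]
  tr_pr <- gnb_predict(model, tr$values)
  list(accuracy = mean(pr$labels == expected), mapping = mapping,
       train_accuracy = mean(tr_pr$labels == tr$labels), n_test = length(expected))
}

gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Gini information-gain voxel ranking
#'
#' Per voxel: discretize the feature (default: median split) and score the
#' reduction in Gini impurity of the class labels,
#' gain = Gini(labels) - sum over bins of p(bin) Gini(labels | bin).
#' Selection keeps voxels whose gain exceeds the mean gain (or the top N).
#'
#' @param features a `feature_matrix` (or trials x voxels matrix with
#'   `labels`)
#' @param labels class labels (taken from `features` if absent)
#' @param n_bins number of equal-frequency bins (default 2 = median split)
#' @param top_n optional: select exactly the top N voxels instead of the
#'   mean-gain rule
#' @return a `feature_ranking`: list(gain per voxel, selected logical,
#'   threshold)
#' @export
gini_information_gain <- function(features, labels = NULL, n_bins = 2,
                                  top_n = NULL) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  if (is.null(labels)) labels <- features$labels
  stopifnot(length(unique(labels)) >= 2, nrow(X) == length(labels))
  base <- gini_impurity(labels)
  gain <- apply(X, 2, function(x) {
    br <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
    bins <- cut(x, breaks = unique(br), include.lowest = TRUE)
    if (length(levels(bins)) < 2) return(0)
    g <- 0
    for (lv in levels(bins)) {
      in_bin <- bins == lv
      g <- g + mean(in_bin) * gini_impurity(labels[in_bin])
    }
    base - g
  })
  gain <- pmax(gain, 0)
  if (is.null(top_n)) {
    threshold <- mean(gain)
    selected <- gain > threshold
  } else {
    top_n <- min(top_n, length(gain))
    ord <- order(gain, decreasing = TRUE)     # ties broken by voxel order
    threshold <- gain[ord[top_n]]
    selected <- logical(length(gain))
    selected[ord[seq_len(top_n)]] <- TRUE
  }
  structure(list(gain = gain, selected = selected, threshold = threshold),
            class = "feature_ranking")
}

#' Upper-hemisphere enrichment of informative voxels
#'
#' Proportion of selected voxels falling in the upper (coil-side) half of
#' the ROI, with exact binomial tests against 0.5 and against the upper
#' half's share of all ROI voxels (the fairer null when the halves hold
#' unequal numbers of voxels).
#'
#' @param ranking a `feature_ranking`
#' @param upper logical per voxel: TRUE if in the upper half
#' @return list(prop_upper, n_selected, p_vs_half, p_vs_share, upper_share)
#' @export
hemisphere_enrichment <- function(ranking, upper) {
  sel <- ranking$selected
  if (!any(sel)) stop("empty selection")
  stopifnot(length(upper) == length(sel))
  k <- sum(upper[sel]); n <- sum(sel)
  share <- mean(upper)
  list(prop_upper = k / n, n_selected = n,
       p_vs_half = stats::binom.test(k, n, 0.5, alternative = "greater")$p.value,
       p_vs_share = stats::binom.test(k, n, share, alternative = "greater")$p.value,
       upper_share = share)
}

#' Test decoding accuracy against chance
#'
#' One-sample t test of the per-trial correctness against the chance
#' proportion, plus the exact binomial test. When correctness has zero
#' variance (all right or all wrong) only the binomial test is returned.
#'
#' @param cv a `cv_result`
#' @param chance chance proportion (default `cv$chance`)
#' @return list(accuracy, chance, t, df, p_t, p_binom, n)
#' @export
test_vs_chance <- function(cv, chance = cv$chance) {
  x <- as.numeric(cv$correct)
  n <- length(x); k <- sum(x)
  p_binom <- stats::binom.test(k, n, chance, alternative = "greater")$p.value
  if (stats::sd(x) == 0) {
    return(list(accuracy = mean(x), chance = chance, t = NA_real_,
                df = NA_integer_, p_t = NA_real_, p_binom = p_binom, n = n))
  }
  tt <- stats::t.test(x, mu = chance, alternative = "greater")
  list(accuracy = mean(x), chance = chance, t = unname(tt$statistic),
       df = unname(tt$parameter), p_t = tt$p.value, p_binom = p_binom, n = n)
}

#' Empirical chance distribution by label permutation
#'
#' Permutes labels within run (preserving the balanced fold structure) and
#' re-runs the full leave-one-run-out CV each time.
#'
#' @param features a `feature_matrix`
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @return list(accuracies, mean, q95)
#' @export
permutation_chance <- function(features, n_perm = 100, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  acc <- vapply(seq_len(n_perm), function(i) {
    fm <- features
    for (r in unique(fm$runs)) {
      idx <- which(fm$runs == r)
      fm$labels[idx] <- sample(fm$labels[idx])
    }
    cross_validate_loro(fm)$accuracy
  }, numeric(1))
  list(accuracies = acc, mean = mean(acc),
       q95 = unname(stats::quantile(acc, 0.95)))
}

#' Simulate trial-wise beta patterns directly
#'
#' Feature-level shortcut used for decoder calibration: trial betas equal
#' the condition's ROI pattern plus i.i.d. Gaussian estimation noise. This
#' bypasses the BOLD forward model but preserves the pattern geometry
#' (shared axis vs orthogonal unique axes), which is what the
#' generalization analyses probe.
#'
#' @param patterns result of [make_patterns()]
#' @param roi_index linear voxel indices of the ROI within the grid
#' @param trials_per_run trials per condition per run
#' @param n_runs number of runs
#' @param beta_noise_sd SD of the additive noise on each trial beta (a.u.)
#' @param seed RNG seed
#' @return a `feature_matrix`
#' @export
simulate_trial_betas <- function(patterns, roi_index, trials_per_run = 5,
                                 n_runs = 3, beta_noise_sd = 1, seed = 1L,
                                 voxel_coords = NULL, upper = NULL) {
  conds <- names(patterns$patterns)
  P <- vapply(patterns$patterns, function(p) as.vector(p)[roi_index],
              numeric(length(roi_index)))
  set.seed(seed)
  rows <- list(); labels <- character(); runs <- integer()
  for (r in seq_len(n_runs)) for (cn in conds) for (i in seq_len(trials_per_run)) {
    rows[[length(rows) + 1L]] <- P[, cn] +
      stats::rnorm(length(roi_index), 0, beta_noise_sd)
    labels <- c(labels, cn); runs <- c(runs, r)
  }
  feature_matrix(do.call(rbind, rows), labels, runs,
                 voxel_coords = voxel_coords, upper = upper)
}
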