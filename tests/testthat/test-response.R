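# CSP/LDA accuracy response.

make_cov_trials <- function(n_per_class = 20, fs = 160, seed = 9) {
  # 2-channel toy: class left concentrates variance on channel 1,
  # class right on channel 2
  set.seed(seed)
  n <- fs
  arr <- array(0, dim = c(2 * n_per_class, 2, n),
               dimnames = list(NULL, c("C3", "C4"), NULL))
  labels <- factor(rep(c("left", "right"), n_per_class),
                   levels = c("left", "right"))
  for (i in seq_len(2 * n_per_class)) {
    hot <- if (labels[i] == "left") 1 else 2
    arr[i, hot, ] <- rnorm(n, sd = 3)
    arr[i, 3 - hot, ] <- rnorm(n, sd = 1)
  }
  new("TrialSet", trials = arr, labels = labels, fs = fs,
      timing = miTiming(), montage = sensorimotorMontage())
}

test_that("CSP filters whiten the composite covariance and split classes", {
  ts <- make_cov_trials()
  csp <- fitCsp(ts, n_per_class = 3, shrinkage = 0.05)
  # 2 channels cap the selection at one filter per class
  expect_equal(nrow(csp@filters), 2L)
  # whitening identity on the shrunk class covariances
  covs <- bciability:::.trial_covs(trialArray(ts))$norm
  lab <- trialLabels(ts)
  S_l <- Reduce(`+`, covs[lab == "left"]) / sum(lab == "left")
  S_r <- Reduce(`+`, covs[lab == "right"]) / sum(lab == "right")
  sh <- bciability:::.shrink
  W <- csp@filters
  I2 <- W %*% (sh(S_l, 0.05) + sh(S_r, 0.05)) %*% t(W)
  expect_lt(max(abs(I2 - diag(2))), 1e-6)
  # top filter separates the class variances by a clear ratio
  feats <- cspFeatures(ts, csp)
  v1 <- exp(feats[lab == "left", 1])
  v2 <- exp(feats[lab == "right", 1])
  expect_gt(mean(v1) / mean(v2), 2)
  # identical class covariances: eigenvalues near 1/2
  ts_same <- make_cov_trials()
  ts_same@labels <- factor(rep(c("left", "right"), 20)[sample(40)],
                           levels = c("left", "right"))
  csp_same <- fitCsp(ts_same)
  expect_lt(max(abs(csp_same@eigenvalues - 0.5)), 0.15)
})

test_that("CSP features are scale-invariant log variance ratios", {
  ts <- make_cov_trials()
  csp <- fitCsp(ts)
  f1 <- cspFeatures(ts, csp)
  ts10 <- ts
  ts10@trials <- ts10@trials * 10
  expect_equal(cspFeatures(ts10, csp), f1, tolerance = 1e-10)
  expect_equal(ncol(f1), 2L * csp@n_per_class)
  # six channels give the full 6-filter, 6-feature layout
  prof <- fixed_profile(erd_depth = 0.6)
  ts6 <- selectChannels(simulateTrialSet(prof, n_trials = 10, fs = 160),
                        channelConfig("6Ch"))
  csp6 <- fitCsp(ts6, n_per_class = 3)
  expect_equal(nrow(csp6@filters), 6L)
  expect_equal(ncol(cspFeatures(ts6, csp6)), 6L)
})

test_that("the internal LDA matches MASS::lda when shrinkage is off", {
  set.seed(19)
  X <- matrix(rnorm(60 * 4), 60)
  X[31:60, ] <- X[31:60, ] + 1
  y <- factor(rep(c("left", "right"), each = 30),
              levels = c("left", "right"))
  fit <- bciability:::.rlda_fit(X, y, gamma = 0)
  mine <- bciability:::.rlda_predict(fit, X)
  ref <- predict(MASS::lda(X, grouping = y), X)$class
  expect_equal(as.character(mine), as.character(ref))
})

test_that("window arithmetic matches the 50% overlap rule", {
  prof <- fixed_profile(erd_depth = 0.7)
  ts <- simulateTrialSet(prof, n_trials = 12, fs = 160)
  ar <- accuracyResponse(ts, config = "2Ch", delta_taus = c(0.5),
                         n_rep = 1, n_folds = 4, seed = 1)
  expect_equal(nrow(ar@curves[["0.5"]]), 7L)
  expect_error(accuracyResponse(ts, delta_taus = 3), "longer than")
})

test_that("accuracy tracks ERD depth and collapses to chance under nulls", {
  # high separation: near-perfect at the longest window
  prof <- fixed_profile(erd_depth = 0.8, mu_amp = 4)
  ts <- simulateTrialSet(prof, n_trials = 50, fs = 160)
  ar <- accuracyResponse(ts, config = "2Ch", delta_taus = c(2.0),
                         n_rep = 3, n_folds = 10, seed = 2)
  expect_gte(ar@summary[["2"]], 0.85)
  expect_true(all(ar@summary >= 0 & ar@summary <= 1))
  # no ERD: all windows near chance
  prof0 <- fixed_profile(erd_depth = 0)
  ts0 <- simulateTrialSet(prof0, n_trials = 50, fs = 160)
  ar0 <- accuracyResponse(ts0, config = "2Ch", delta_taus = c(1.0, 2.0),
                          n_rep = 3, n_folds = 10, seed = 2)
  expect_true(all(ar0@summary >= 0.4 & ar0@summary <= 0.65))
  # label permutation: mean accuracy at chance
  set.seed(11)
  accs <- replicate(5, {
    tsp <- ts
    tsp@labels <- sample(tsp@labels)
    mean(accuracyResponse(tsp, config = "2Ch", delta_taus = c(2.0),
                          n_rep = 2, n_folds = 10,
                          seed = sample.int(1e6, 1))@summary_mean)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.07)
})

test_that("summary accuracy increases with erd_depth across a cohort", {
  accs <- vapply(c(0.1, 0.45, 0.8), function(d) {
    prof <- fixed_profile(erd_depth = d)
    ts <- simulateTrialSet(prof, n_trials = 25, fs = 160)
    accuracyResponse(ts, config = "2Ch", delta_taus = c(2.0),
                     n_rep = 2, n_folds = 10, seed = 3)@summary[["2"]]
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))
  expect_gt(accs[3], accs[1])
})

test_that("preconditions are enforced", {
  prof <- fixed_profile()
  ts <- simulateTrialSet(prof, n_trials = 5, fs = 160)
  expect_error(accuracyResponse(ts), "20 trials")
})
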