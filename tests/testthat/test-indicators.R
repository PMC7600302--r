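test_that("Welch PSD locates tones and conserves white-noise power", {
  fs <- 160
  t <- seq(0, 20, by = 1 / fs)
  psd <- welchPsd(sin(2 * pi * 10 * t), fs)
  expect_equal(psd@freq[which.max(psd@power)], 10)
  set.seed(3)
  x <- rnorm(fs * 60, sd = 2)
  psd2 <- welchPsd(x, fs)
  total <- sum(psd2@power) * diff(psd2@freq[1:2])
  expect_lt(abs(total / var(x) - 1), 0.1)
  # constant signal: detrended windows carry no band power
  psd3 <- welchPsd(rep(5, fs * 4), fs)
  expect_lt(max(psd3@power[psd3@freq >= 4 & psd3@freq <= 40]), 1e-20)
  expect_error(welchPsd(rnorm(10), fs), "shorter")
})

test_that("spectral model fit recovers constructed peak parameters", {
  psd <- constructed_psd()
  fit <- fitPsdModel(psd)
  expect_true(fit@converged)
  expect_lt(abs(fit@peaks["mu", "m"] - 10), 0.5)
  expect_lt(abs(fit@peaks["beta", "m"] - 22), 1.0)
  expect_lt(fit@residual / sqrt(sum(psd@power^2)), 1e-3)
  # null peaks: pure noise floor fits with zero weights
  f <- seq(4, 40, by = 1)
  noise_only <- new("PSDEstimate", freq = f, power = 0.5 + 10 / f,
                    channel = "x", meta = list())
  fit0 <- fitPsdModel(noise_only)
  expect_lt(fit0@peaks["mu", "k"], 1e-3)
  expect_lt(fit0@peaks["beta", "k"], 1e-3)
  expect_lt(fit0@residual, 1e-6)
})

test_that("fit scales homogeneously and improves with more starts", {
  psd <- constructed_psd()
  fit1 <- fitPsdModel(psd)
  psd3 <- new("PSDEstimate", freq = psd@freq, power = 3 * psd@power,
              channel = "x", meta = list())
  fit3 <- fitPsdModel(psd3)
  expect_equal(fit3@peaks["mu", "k"] / fit1@peaks["mu", "k"], 3,
               tolerance = 1e-3)
  expect_equal(fit3@noise[["kappa2"]] / fit1@noise[["kappa2"]], 3,
               tolerance = 1e-3)
  expect_equal(fit3@peaks["mu", "m"], fit1@peaks["mu", "m"],
               tolerance = 1e-4)
  # best-of-k residual is monotone in the number of starts
  r_k <- vapply(1:5, function(k) fitPsdModel(psd, n_starts = k)@residual,
                numeric(1))
  expect_true(all(diff(r_k) <= 1e-12))
})

test_that("xi1 is the channel-mean excess over the fitted noise floor", {
  f <- seq(4, 40, by = 1)
  noise <- c(kappa1 = 0.5, kappa2 = 10, eta = 1)
  eps_curve <- noiseCurve(f, noise)
  mk_psd <- function(p) new("PSDEstimate", freq = f, power = p,
                            channel = "x", meta = list())
  mk_fit <- function() new("PSDFitModel",
                           peaks = matrix(0, 2, 3,
                                          dimnames = list(c("mu", "beta"),
                                                          c("k", "m", "sigma"))),
                           noise = noise, residual = 0, converged = TRUE)
  # s == noise floor: zero indicator
  expect_equal(xi1(list(mk_psd(eps_curve)), list(mk_fit())), 0)
  # unit Gaussian bump on the floor: excess max equals the bump height
  bump <- exp(-(f - 10)^2 / (2 * 1.5^2))
  expect_equal(xi1(list(mk_psd(eps_curve + bump)), list(mk_fit())),
               max(bump))
  # doubling the bump strictly increases xi1; channel order irrelevant
  x_small <- xi1(list(mk_psd(eps_curve + bump)), list(mk_fit()))
  x_big <- xi1(list(mk_psd(eps_curve + 2 * bump)), list(mk_fit()))
  expect_gt(x_big, x_small)
  two_a <- xi1(list(mk_psd(eps_curve + bump), mk_psd(eps_curve + 2 * bump)),
               list(mk_fit(), mk_fit()))
  two_b <- xi1(list(mk_psd(eps_curve + 2 * bump), mk_psd(eps_curve + bump)),
               list(mk_fit(), mk_fit()))
  expect_equal(two_a, two_b)
  shifted <- mk_psd(eps_curve)
  shifted@freq <- f + 0.5
  expect_error(xi1(list(mk_psd(eps_curve), shifted),
                   list(mk_fit(), mk_fit())), "grids")
})

test_that("ERD/ERS time courses recover imposed power changes", {
  # exactly constant per-sample power: zhat identically zero
  ts_const <- alpha_trials(1, n_per_class = 3)
  set.seed(12)
  ts_const@trials[] <- sample(c(-1, 1), length(ts_const@trials),
                              replace = TRUE)
  e_const <- suppressWarnings(computeErds(ts_const, band = "none",
                                          channel = "C3"))
  expect_equal(max(abs(e_const$left@zhat)), 0)
  # stationary noise: the MI-interval mean stays near zero
  ts0 <- alpha_trials(1, n_per_class = 20)
  e0 <- computeErds(ts0, band = "none", channel = "C3")
  mi0 <- e0$left@time >= 2.7 & e0$left@time < 4.5
  expect_lt(abs(mean(e0$left@zhat[mi0])), 0.1)
  expect_true(all(e0$left@zhat >= -1))
  # doubled MI power: ERS of +100% on the scaled channel
  ts2 <- alpha_trials(2, n_per_class = 50)
  e2 <- computeErds(ts2, band = "none", channel = "C3")
  mi <- e2$left@time >= 2.7 & e2$left@time < 4.5
  expect_lt(abs(mean(e2$left@zhat[mi]) - 1), 0.15)
  # generator with erd_depth = 0.5: about -50% on the contralateral side
  prof <- fixed_profile(erd_depth = 0.5, mu_amp = 3, k2 = 0.2)
  ts <- simulateTrialSet(prof, n_trials = 50, fs = 160)
  er <- computeErds(ts, band = "mu", channel = "C3")
  mi2 <- er$right@time >= 2.7 & er$right@time < 4.5
  expect_lt(abs(mean(er$right@zhat[mi2]) + 0.5), 0.12)
  # degenerate reference errors
  z <- alpha_trials(1, n_per_class = 2)
  z@trials[] <- 0
  expect_error(suppressWarnings(computeErds(z, band = "none",
                                            channel = "C3")),
               "degenerate")
})

test_that("xi2 satisfies its algebraic identities", {
  a <- toy_erds(c(1, 0))
  b <- toy_erds(c(0, 1), class_label = "right")
  # printed 2-sample toy: squared distance 2 over unit norms
  expect_equal(erdsDistance(a, b, mi = c(0, 2)), 2)
  # identical curves: zero
  expect_equal(erdsDistance(a, toy_erds(c(1, 0)), mi = c(0, 2)), 0)
  # common positive scaling cancels
  set.seed(4)
  u <- rnorm(50); v <- rnorm(50)
  expect_equal(erdsDistance(u, v), erdsDistance(3.7 * u, 3.7 * v))
  # class swap symmetry
  expect_equal(erdsDistance(u, v), erdsDistance(v, u))
  # brute-force oracle identity on stored curves
  brute <- sum((u - v)^2) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  expect_equal(erdsDistance(u, v), brute)
  expect_error(erdsDistance(u, v[-1]), "length")
  # degenerate pairs are skipped; all degenerate gives 0
  zero <- toy_erds(rep(0, 2))
  res <- suppressWarnings(xi2(list(list(left = zero, right = zero)),
                              mi = c(0, 2)))
  expect_equal(res$xi2, 0)
  mixed <- suppressWarnings(xi2(list(
    list(left = zero, right = zero),
    list(left = a, right = b)), mi = c(0, 2)))
  expect_equal(mixed$xi2, 2)
})

test_that("run-wise xi2 declines when class separation decays", {
  mk_subject <- function(seed) {
    prof <- fixed_profile(mu_amp = 4, k2 = 0.2)
    parts <- lapply(c(0.9, 0.5, 0.15), function(d) {
      p <- prof; p$erd_depth <- d; p$seed <- seed + round(100 * d)
      simulateTrialSet(p, n_trials = 15, fs = 160)
    })
    do.call(abind_trials, parts)
  }
  abind_trials <- function(...) {
    sets <- list(...)
    arr <- do.call(rbind, lapply(sets, function(s) {
      dim(s@trials) <- c(dim(s@trials)[1], prod(dim(s@trials)[2:3]))
      s@trials
    }))
    d3 <- dim(sets[[1]]@trials)
    out <- sets[[1]]
    out@trials <- array(arr, dim = c(nrow(arr), d3[2], d3[3]),
                        dimnames = list(NULL,
                                        dimnames(sets[[1]]@trials)[[2]],
                                        NULL))
    out@labels <- factor(unlist(lapply(sets, function(s)
      as.character(s@labels))), levels = c("left", "right"))
    out
  }
  subjects <- lapply(1:4, mk_subject)
  res <- suppressWarnings(
    runTrendTest(subjects, run_size = 30, channels = c("C3", "C4")))
  expect_equal(ncol(res$xi2_runs), 3L)
  expect_true(all(diff(res$run_means) < 0))
  expect_error(runTrendTest(subjects, run_size = 90), "2 complete runs")
  # identically generated runs: the paired test stays non-significant
  null_subjects <- lapply(11:15, function(s) {
    p <- fixed_profile(); p$seed <- s
    simulateTrialSet(p, n_trials = 20, fs = 160)
  })
  null_res <- runTrendTest(null_subjects, run_size = 20,
                           channels = c("C3", "C4"))
  expect_gt(min(null_res$p_values), 0.05)
})
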