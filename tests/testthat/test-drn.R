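test_that("moment features follow the window arithmetic and hand values", {
  # degenerate constant window
  expect_equal(as.numeric(momentFeatures(rep(3, 8), fs = 8, win_s = 1)),
               c(3, 3, 0, 3, 3))
  # 2 s at any rate: 3 windows, 15 values
  f <- momentFeatures(rnorm(320), fs = 160, win_s = 1)
  expect_equal(attr(f, "n_windows"), 3L)
  expect_equal(length(f), 15L)
  # hand arithmetic with population variance
  expect_equal(as.numeric(momentFeatures(c(1, 2, 3, 4), fs = 4, win_s = 1)),
               c(2.5, 2.5, 1.25, 1, 4))
  expect_error(momentFeatures(numeric(0), fs = 8), "empty")
})

test_that("input stacks respect source and channel order", {
  prof <- fixed_profile()
  ts <- simulateTrialSet(prof, n_trials = 5, fs = 160)
  rest <- trimResting(simulateResting(prof, fs = 160, duration_s = 15), 5)
  b <- buildInputs(trials = ts, source = "baseline",
                   channels = c("C3", "C4"))
  # 5 trials x 2 s baseline each = 20 s: 39 windows, 195 per channel
  expect_equal(attr(b, "d"), 195L)
  expect_equal(attr(b, "n_channels"), 2L)
  r <- buildInputs(resting = rest, source = "resting",
                   channels = c("C3", "C4"))
  expect_equal(attr(r, "d"), 5L * 19L)   # 10 s trimmed record
  e <- buildInputs(trials = ts, source = "erds", channels = c("C3", "C4"))
  # mu and beta, two classes, 2 s each: 8 s concatenation per channel
  expect_equal(attr(e, "d"), 5L * 15L)
  # order is part of the contract
  r_swap <- buildInputs(resting = rest, source = "resting",
                        channels = c("C4", "C3"))
  expect_false(isTRUE(all.equal(as.numeric(r), as.numeric(r_swap))))
  expect_equal(as.numeric(r)[1:attr(r, "d")],
               as.numeric(r_swap)[(attr(r, "d") + 1):(2 * attr(r, "d"))])
  expect_error(buildInputs(source = "resting"), "resting source")
})

test_that("architecture sizes obey the ceiling formulas", {
  m <- buildDrn(15, 2)
  expect_equal(c(m@h, m@h * m@n_channels, m@p), c(23L, 46L, 23L))
  m6 <- buildDrn(15, 6)
  expect_equal(c(m6@h, m6@h * m6@n_channels, m6@p), c(23L, 138L, 69L))
  sc <- buildDrn(99, 9, scalar_variant = TRUE)
  expect_equal(c(sc@d, sc@h, sc@p), c(1L, 2L, 1L))
  # property over a grid
  for (d in c(1, 7, 33, 128)) for (cc in c(1, 2, 6)) {
    mm <- buildDrn(d, cc)
    expect_equal(mm@h, as.integer(ceiling(1.5 * d)))
    expect_equal(mm@p, as.integer(ceiling(0.5 * mm@h * cc)))
    expect_equal(dim(mm@params$W2), c(mm@h * cc, mm@p))
    expect_equal(dim(mm@params$w3), c(mm@p, 1L))
  }
})

test_that("training fits constants, linear maps, and is deterministic", {
  set.seed(21)
  X <- matrix(rnorm(20 * 10), 20)
  attr(X, "d") <- 5; attr(X, "n_channels") <- 2
  m <- trainDrn(buildDrn(5, 2, seed = 1), X, rep(0.7, 20))
  expect_lt(max(abs(extractXiStar(m, X) - 0.7)), 0.02)
  # linear target recovery
  X2 <- matrix(rnorm(50 * 20), 50)
  attr(X2, "d") <- 10; attr(X2, "n_channels") <- 2
  y2 <- 2 * rowMeans(X2) + 1
  r <- drnEvaluate(X2, y2, seed = 2, epochs = 800)
  expect_gte(r@spearman, 0.95)
  # bit-identical refits under the same seed, whatever the global RNG
  y3 <- rnorm(20)
  ma <- trainDrn(buildDrn(5, 2, seed = 5), X, y3, epochs = 50)
  set.seed(99)
  mb <- trainDrn(buildDrn(5, 2, seed = 5), X, y3, epochs = 50)
  expect_identical(ma@params, mb@params)
  expect_error(trainDrn(buildDrn(5, 2), X[1:2, ], rnorm(2)), "3 subjects")
})

test_that("xi* extraction is a plain forward pass over subjects", {
  set.seed(31)
  X <- matrix(rnorm(12 * 6), 12)
  attr(X, "d") <- 3; attr(X, "n_channels") <- 2
  y <- rnorm(12)
  m <- trainDrn(buildDrn(3, 2, seed = 1), X, y, epochs = 100)
  xs <- extractXiStar(m, X)
  expect_length(xs, 12)
  perm <- sample(12)
  expect_equal(extractXiStar(m, X[perm, ]), xs[perm])
  expect_error(extractXiStar(buildDrn(3, 2), X), "untrained")
  # scalar variant preserves the rank order of a monotone input
  xi_in <- sort(rnorm(30))
  y_mono <- plogis(xi_in)
  ms <- trainDrn(buildDrn(1, 1, scalar_variant = TRUE, seed = 2),
                 matrix(xi_in), y_mono, epochs = 400)
  out <- extractXiStar(ms, matrix(xi_in))
  expect_gte(cor(out, xi_in, method = "spearman"), 0.99)
})

test_that("psi mappings reduce accuracy vectors as specified", {
  set.seed(41)
  V <- matrix(runif(40, 0.5, 1), 10, 4)
  # all columns identical: mean mode returns the column
  V_same <- matrix(rep(V[, 1], 4), 10, 4)
  expect_equal(psiMap(V_same, "mean"), V[, 1])
  # inverse-variance weights: a column with 4x the variance gets 1/4 weight
  base <- runif(10, 0.6, 0.8)
  V2 <- cbind(base + rnorm(10, sd = 0.1),
              base + rnorm(10, sd = 0.2), base, base)
  v_col <- apply(V2, 2, var)
  w <- (1 / v_col) / sum(1 / v_col)
  expect_equal(psiMap(V2, "mean"), as.numeric(V2 %*% w))
  expect_equal(w[1] / w[2], v_col[2] / v_col[1])
  # rank-one matrix: PCA1 is an affine function of the plain mean
  s <- runif(10)
  V3 <- s %o% c(1, 1.2, 0.8, 1.1)
  expect_equal(cor(psiMap(V3, "PCA1"), rowMeans(V3), method = "spearman"), 1)
  # sign alignment: positively correlated with the plain mean
  expect_gt(cor(psiMap(V, "PCA1"), rowMeans(V)), 0)
  # degenerate: zero variance everywhere falls back to the mean
  V4 <- matrix(0.7, 5, 4)
  expect_warning(out <- psiMap(V4, "mean"), "variance")
  expect_equal(out, rep(0.7, 5))
})

test_that("evaluation handles monotone, reversed and tied inputs", {
  expect_equal(evaluateIndicator(1:5, c(2, 4, 6, 8, 10))@spearman, 1)
  expect_equal(evaluateIndicator(1:5, 5:1)@spearman, -1)
  expect_equal(evaluateIndicator(1:5, c(1, 2, 3, 5, 4))@spearman, 0.9)
  flagged <- evaluateIndicator(rep(1, 5), rnorm(5))
  expect_true(is.na(flagged@spearman))
  expect_true(flagged@diagnostics$constant_input)
  # linear baseline is the same statistic with its own mode label
  lb <- linearBaseline(1:5, c(2, 4, 6, 8, 10))
  expect_equal(lb@spearman, 1)
  expect_equal(lb@mode, "linear")
  # independent noise stays weakly correlated
  set.seed(51)
  rs <- replicate(200, linearBaseline(rnorm(50), rnorm(50))@spearman)
  expect_gte(mean(abs(rs) < 0.3), 0.95)
})

test_that("leave-one-out never sees the held-out subject", {
  set.seed(61)
  M <- 12
  X <- matrix(rnorm(M * 4), M)
  attr(X, "d") <- 2; attr(X, "n_channels") <- 2
  y <- rowMeans(X) + rnorm(M, sd = 0.05)
  loo <- looEvaluate(X, y, seed = 1, epochs = 150)
  expect_equal(loo@mode, "LOO")
  expect_equal(loo@diagnostics$n_fits, M)
  expect_length(loo@xi_star, M)
  # leakage probe: add a duplicate of subject 1's features carrying an
  # unrelated (offset) target. With a leak-free LOO the duplicate can
  # only mislead, so subject 1's held-out prediction must not improve.
  target_m <- 1
  X_dup <- rbind(X, X[target_m, ])
  attr(X_dup, "d") <- 2; attr(X_dup, "n_channels") <- 2
  y_dup <- c(y, y[target_m] + 2)
  loo_dup <- looEvaluate(X_dup, y_dup, seed = 1, epochs = 150)
  err_orig <- abs(loo@xi_star[target_m] - y[target_m])
  err_dup <- abs(loo_dup@xi_star[target_m] - y[target_m])
  expect_lt(err_orig, 0.5)        # clean prediction is decent
  expect_gte(err_dup, err_orig - 0.05)
  expect_error(looEvaluate(X[1:3, ], y[1:3]), "at least 4")
})
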