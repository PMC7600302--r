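test_that("band-pass keeps in-band and rejects out-of-band tones", {
  fs <- 160
  t <- seq(0, 10, by = 1 / fs)
  rec_of <- function(x) new("EEGRecording",
                            samples = matrix(x, nrow = 1), fs = fs,
                            channels = "C3")
  lowtone <- rec_of(sin(2 * pi * 2 * t))
  out <- bandpassFilter(lowtone, 4, 40)
  expect_lt(mean(out@samples^2), 0.01 * mean(lowtone@samples^2))
  intone <- rec_of(sin(2 * pi * 10 * t))
  out2 <- bandpassFilter(intone, 4, 40)
  expect_gt(mean(out2@samples^2), 0.95 * mean(intone@samples^2))
  zeros <- rec_of(rep(0, length(t)))
  expect_equal(bandpassFilter(zeros)@samples, zeros@samples)
  expect_error(bandpassFilter(intone, 4, 90), "Nyquist")
})

test_that("the Laplacian rejects common-mode and preserves focal signals", {
  mont <- sensorimotorMontage()
  fs <- 160
  n <- 160
  common <- matrix(rep(sin(2 * pi * 10 * seq_len(n) / fs),
                       each = length(mont@channels)),
                   nrow = length(mont@channels))
  rec <- new("EEGRecording", samples = common, fs = fs,
             channels = mont@channels)
  out <- suppressWarnings(laplacianFilter(rec, mont))
  # channels with enough neighbors see pure common mode: output is zero
  interior <- setdiff(mont@channels, "Oz")
  expect_lt(max(abs(out@samples[match(interior, mont@channels), ])), 1e-10)
  # the one-neighbor channel is passed through with a warning
  expect_warning(laplacianFilter(rec, mont), "Oz")
  expect_equal(out@samples[match("Oz", mont@channels), ],
               common[match("Oz", mont@channels), ])
  # focal signal on C3 with silent neighbors passes through unchanged
  focal <- matrix(0, length(mont@channels), n)
  focal[match("C3", mont@channels), ] <- rnorm(n)
  rec2 <- new("EEGRecording", samples = focal, fs = fs,
              channels = mont@channels)
  out2 <- suppressWarnings(laplacianFilter(rec2, mont))
  expect_equal(out2@samples[match("C3", mont@channels), ],
               focal[match("C3", mont@channels), ])
  # missing channel errors
  rec3 <- new("EEGRecording", samples = matrix(0, 1, n), fs = fs,
              channels = "XX")
  expect_error(laplacianFilter(rec3, mont), "missing channel")
})

test_that("the Laplacian equals the direct neighbor-mean formula", {
  mont <- sensorimotorMontage()
  n <- 64
  set.seed(1)
  m <- matrix(rnorm(length(mont@channels) * n), ncol = n)
  rec <- new("EEGRecording", samples = m, fs = 160,
             channels = mont@channels)
  out <- suppressWarnings(laplacianFilter(rec, mont))
  # Cz has the 4 neighbors C3, C4, Fz, Pz: small-Laplacian arithmetic
  i <- match("Cz", mont@channels)
  nb <- match(c("C3", "C4", "Fz", "Pz"), mont@channels)
  expect_equal(out@samples[i, ], m[i, ] - colMeans(m[nb, ]))
})

test_that("segmentation uses half-open intervals with exact sample counts", {
  prof <- fixed_profile()
  ts <- simulateTrialSet(prof, n_trials = 2, fs = 512)
  expect_equal(dim(trialArray(segmentTrials(ts, "mi")))[3], 1024L)
  expect_equal(dim(trialArray(segmentTrials(ts, "baseline")))[3], 1024L)
  expect_equal(dim(trialArray(segmentTrials(ts, c(0, 7))))[3], 3584L)
  # idempotent for the same nested interval
  seg <- segmentTrials(ts, c(0, 2))
  expect_equal(trialArray(segmentTrials(seg, c(0, 2))), trialArray(seg))
  expect_error(segmentTrials(ts, c(3, 3)), "increasing")
  expect_error(segmentTrials(ts, c(6, 8)), "outside")
})

test_that("resting trim removes exactly the requested head", {
  prof <- fixed_profile()
  rec <- simulateResting(prof, fs = 160, duration_s = 60)
  out <- trimResting(rec, 5)
  expect_equal(ncol(out@samples), 55L * 160L)
  expect_equal(out@samples[, 1], rec@samples[, 5 * 160 + 1])
  expect_equal(trimResting(rec, 0)@samples, rec@samples)
  short <- new("EEGRecording", samples = matrix(0, 1, 160), fs = 160,
               channels = "C3")
  expect_error(trimResting(short, 5), "shorter")
})

test_that("filtering commutes with trial concatenation away from edges", {
  fs <- 160
  set.seed(2)
  x <- rnorm(6 * fs)
  bf_whole <- bandpassFilter(new("EEGRecording",
                                 samples = matrix(x, 1), fs = fs,
                                 channels = "C3"), 8, 13)@samples[1, ]
  half <- bandpassFilter(new("EEGRecording",
                             samples = matrix(x[1:(3 * fs)], 1), fs = fs,
                             channels = "C3"), 8, 13)@samples[1, ]
  interior <- (fs + 1):(2 * fs)
  expect_lt(max(abs(bf_whole[interior] - half[interior])),
            0.05 * sd(half))
})
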