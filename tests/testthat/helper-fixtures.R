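# Shared fixtures, built in code at test time.

# a small profile with fixed fields (no randomness in the parameters)
fixed_profile <- function(efficiency = 0.5, erd_depth = 0.5,
                          mu_peak = 10, beta_peak = 20,
                          mu_amp = 3, beta_amp = 0.8,
                          k1 = 0.02, k2 = 0.5, eta = 1, seed = 42) {
  data.frame(subject_id = 1L, efficiency = efficiency,
             mu_peak_hz = mu_peak, beta_peak_hz = beta_peak,
             mu_amp = mu_amp, beta_amp = beta_amp,
             noise_k1 = k1, noise_k2 = k2, noise_eta = eta,
             erd_depth = erd_depth, seed = seed)
}

# trials of band-limited (or white) noise whose MI-interval amplitude is
# scaled by sqrt(alpha) on one channel for every trial; used for ERD/ERS
# arithmetic checks where alpha > 1 (ERS) must be expressible
alpha_trials <- function(alpha, n_per_class = 50, fs = 160, band = NULL,
                         seed = 7) {
  timing <- miTiming()
  montage <- sensorimotorMontage()
  n <- round(timing@trial_length_s * fs)
  mi_idx <- (round(timing@mi[1] * fs) + 1):(round(timing@mi[2] * fs))
  ch <- montage@channels
  n_tot <- 2L * n_per_class
  set.seed(seed)
  bf <- if (!is.null(band))
    signal::butter(4, band / (fs / 2), "pass")
  arr <- array(0, dim = c(n_tot, length(ch), n),
               dimnames = list(NULL, ch, NULL))
  for (i in seq_len(n_tot)) {
    for (j in seq_along(ch)) {
      x <- if (is.null(band)) rnorm(n) else {
        pad <- 2 * fs
        v <- signal::filtfilt(bf, rnorm(n + 2 * pad))
        v[(pad + 1):(pad + n)]
      }
      if (ch[j] == "C3") x[mi_idx] <- x[mi_idx] * sqrt(alpha)
      arr[i, j, ] <- x
    }
  }
  new("TrialSet", trials = arr,
      labels = factor(rep(c("left", "right"), n_per_class),
                      levels = c("left", "right")),
      fs = fs, timing = timing, montage = montage)
}

# constructed PSD: two Gaussian peaks plus hyperbolic noise floor
constructed_psd <- function(kmu = 2, mmu = 10, smu = 1.5,
                            kb = 1, mb = 22, sb = 3,
                            k1 = 0.5, k2 = 10, eta = 1,
                            f = seq(4, 40, by = 1)) {
  s <- kmu * exp(-(f - mmu)^2 / (2 * smu^2)) +
    kb * exp(-(f - mb)^2 / (2 * sb^2)) + k1 + k2 / f^eta
  new("PSDEstimate", freq = f, power = s, channel = "synthetic",
      meta = list())
}

# wrap a plain numeric curve in an ERDSTimeCourse (for xi2 identities)
toy_erds <- function(zhat, fs = 1, band = "mu", channel = "C3",
                     class_label = "left") {
  new("ERDSTimeCourse", zhat = zhat, zhat_masked = zhat,
      time = (seq_along(zhat) - 1) / fs, band = band, channel = channel,
      class_label = class_label, ref_interval = c(0, 1), ref_power = 1)
}
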