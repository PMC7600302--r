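# Synthetic motor-imagery EEG cohorts with known latent efficiency.
#
# Each subject owns a latent efficiency in [0, 1] that drives both the
# prominence of the mu/beta spectral peaks and the depth of the
# event-related desynchronization (ERD) during the MI interval, so every
# downstream stage (indicators, CSP/LDA response, regression, clustering)
# can be tested against known ground truth.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default trial timing
#'
#' The cue-paced MI paradigm: fixation/baseline 0--2 s, cue at 2 s, motor
#' imagery 2.6--4.6 s, 7 s trials.
#'
#' @return a \linkS4class{TrialTiming}.
#' @export
miTiming <- function() {
  new("TrialTiming", baseline = c(0, 2), cue_onset_s = 2,
      mi = c(2.6, 4.6), trial_length_s = 7)
}

#' Synthetic sensorimotor montage
#'
#' Ten electrodes on a unit grid: the six-channel sensorimotor set (C3,
#' Cz, C4, P3, Pz, P4) plus four surround channels (F3, Fz, F4, Oz) that
#' supply Laplacian neighbors. Adjacency links electrodes at unit grid
#' distance.
#'
#' @return a \linkS4class{Montage}.
#' @export
sensorimotorMontage <- function() {
  coords <- rbind(
    F3 = c(-1,  1), Fz = c(0,  1), F4 = c(1,  1),
    C3 = c(-1,  0), Cz = c(0,  0), C4 = c(1,  0),
    P3 = c(-1, -1), Pz = c(0, -1), P4 = c(1, -1),
    Oz = c(0, -2))
  ch <- rownames(coords)
  adj <- lapply(ch, function(a) {
    d <- sqrt(rowSums((coords - matrix(coords[a, ], nrow(coords), 2,
                                       byrow = TRUE))^2))
    ch[d > 0 & abs(d - 1) < 1e-9]
  })
  names(adj) <- ch
  new("Montage", channels = ch, coords = coords, adjacency = adj)
}

#' Standard channel configurations
#'
#' The two sensorimotor electrode arrangements used throughout: the
#' narrow two-channel set and the wide six-channel set.
#'
#' @param name \code{"2Ch"} or \code{"6Ch"}.
#' @return character vector of channel labels.
#' @examples
#' channelConfig("2Ch")
#' @export
channelConfig <- function(name = c("2Ch", "6Ch")) {
  name <- match.arg(name)
  switch(name,
         "2Ch" = c("C3", "C4"),
         "6Ch" = c("C3", "P3", "Cz", "Pz", "C4", "P4"))
}

# gain of the rhythm amplitude per electrode: full over the hand areas,
# reduced over midline/parietal, residual elsewhere
.osc_gain <- c(C3 = 1, C4 = 1, Cz = 0.6, Pz = 0.6, P3 = 0.6, P4 = 0.6)

.profile_cols <- c("subject_id", "efficiency", "mu_peak_hz", "beta_peak_hz",
                   "mu_amp", "beta_amp", "noise_k1", "noise_k2", "noise_eta",
                   "erd_depth", "seed")

validateProfile <- function(profile) {
  profile <- as.list(profile)
  missing <- setdiff(.profile_cols, names(profile))
  if (length(missing))
    stop("subject profile is missing fields: ", paste(missing, collapse = ", "))
  if (profile$efficiency < 0 || profile$efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  if (profile$erd_depth < 0 || profile$erd_depth > 1)
    stop("erd_depth must lie in [0, 1]")
  if (profile$mu_peak_hz < 8 || profile$mu_peak_hz > 13)
    stop("mu_peak_hz must lie in [8, 13]")
  if (profile$beta_peak_hz < 14 || profile$beta_peak_hz > 30)
    stop("beta_peak_hz must lie in [14, 30]")
  profile
}

#' Generate a synthetic subject cohort
#'
#' Draws per-subject latent efficiencies and maps them to physiological
#' generator parameters. Both the ERD depth and the mu-peak amplitude are
#' non-decreasing in efficiency (the generator's contract): subjects with
#' high efficiency have prominent sensorimotor rhythms and deep,
#' class-lateralized power suppression during motor imagery; low
#' efficiency approaches the 15--30% of users who never attain usable
#' BCI control.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the cohort is fully reproducible.
#' @param efficiency either \code{"uniform"} (default: efficiencies drawn
#'   uniformly on \code{[0, 1]}) or a numeric vector of fixed efficiencies
#'   (length 1 recycled, or length \code{n_subjects}).
#' @return a data.frame with one row per subject: latent efficiency,
#'   spectral-peak positions/amplitudes, hyperbolic-noise parameters
#'   (kappa1, kappa2, eta), ERD depth, and a per-subject simulation seed.
#' @examples
#' cohort <- makeCohort(5, seed = 7)
#' cohort$erd_depth
#' @export
makeCohort <- function(n_subjects, seed, efficiency = "uniform") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  with_seed(seed, {
    if (identical(efficiency, "uniform")) {
      e <- runif(n_subjects)
    } else if (is.numeric(efficiency)) {
      if (any(efficiency < 0 | efficiency > 1))
        stop("fixed efficiencies must lie in [0, 1]")
      if (length(efficiency) == 1) e <- rep(efficiency, n_subjects)
      else if (length(efficiency) == n_subjects) e <- efficiency
      else stop("efficiency vector must have length 1 or n_subjects")
    } else {
      stop("efficiency must be \"uniform\" or a numeric vector")
    }
    data.frame(
      subject_id = seq_len(n_subjects),
      efficiency = e,
      mu_peak_hz = runif(n_subjects, 8.5, 12.5),
      beta_peak_hz = runif(n_subjects, 16, 24),
      mu_amp = 1 + 4 * e,
      beta_amp = 0.3 + 1.2 * e,
      noise_k1 = runif(n_subjects, 0.01, 0.03),
      noise_k2 = runif(n_subjects, 0.4, 0.6),
      noise_eta = runif(n_subjects, 0.8, 1.3),
      erd_depth = 0.15 + 0.75 * e,
      seed = sample.int(.Machine$integer.max %/% 2, n_subjects)
    )
  })
}

#' Expected accuracy of a synthetic subject
#'
#' Ground-truth monotone map from latent efficiency to the accuracy a
#' well-calibrated classifier should approach: chance (0.5) at zero
#' efficiency up to 0.95 at full efficiency. Used by parameter-recovery
#' tests only.
#'
#' @param profile a subject profile row (or anything with an
#'   \code{efficiency} field).
#' @return expected accuracy fraction in \code{[0.5, 0.95]}.
#' @export
trueResponse <- function(profile) {
  e <- as.list(profile)$efficiency
  if (is.null(e)) stop("profile has no efficiency field")
  0.5 + 0.45 * e
}

# Gaussian noise with one-sided PSD kappa1 + kappa2 / f^eta, realized by
# shaping white noise in the frequency domain (frequencies below 1 Hz are
# clamped to the 1 Hz level to keep the spectrum integrable).
shapedNoise <- function(n, fs, kappa1, kappa2, eta) {
  f <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(f, fs - f)           # fold to [0, fs/2]
  s1 <- kappa1 + kappa2 / pmax(f_fold, 1)^eta
  amp <- sqrt(s1 / 2 * fs)            # two-sided density times fs
  x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * amp, inverse = TRUE)) / n
  x
}

# band-limited oscillation: 4th-order Butterworth band-pass on white
# noise, normalized so the realized variance equals `power`. The noise
# is padded by 2 s on both sides before filtering and trimmed after, so
# the filter's edge transient never reaches the trial.
bandOscillation <- function(n, fs, low, high, power, bf = NULL) {
  if (is.null(bf)) bf <- signal::butter(4, c(low, high) / (fs / 2), "pass")
  pad <- round(2 * fs)
  s <- signal::filtfilt(bf, stats::rnorm(n + 2 * pad))
  s <- s[(pad + 1):(pad + n)]
  s / stats::sd(s) * sqrt(power)
}

# amplitude envelope implementing ERD: unity outside the MI interval,
# `scale` inside, joined with 100 ms raised-cosine ramps
erdEnvelope <- function(n, fs, mi, scale, ramp_s = 0.1) {
  t <- (seq_len(n) - 1) / fs
  env <- rep(1, n)
  ramp <- ramp_s
  inside <- t >= mi[1] & t < mi[2]
  env[inside] <- scale
  on_ramp <- t >= mi[1] & t < mi[1] + ramp
  env[on_ramp] <- 1 + (scale - 1) * (1 - cos(pi * (t[on_ramp] - mi[1]) / ramp)) / 2
  off_ramp <- t >= mi[2] - ramp & t < mi[2]
  env[off_ramp] <- scale + (1 - scale) *
    (1 - cos(pi * (t[off_ramp] - (mi[2] - ramp)) / ramp)) / 2
  env
}

#' Simulate a labeled motor-imagery trial set
#'
#' Each trial is 1/f-shaped Gaussian background noise plus band-limited
#' mu and beta oscillations over the sensorimotor electrodes. During the
#' MI interval the oscillation amplitude on the contralateral hand-area
#' channel (C3 for right-hand trials, C4 for left-hand) is scaled by
#' \code{sqrt(1 - erd_depth)} with 100 ms cosine ramps, so the Welch band
#' power during MI is \code{(1 - erd_depth)} times the baseline band
#' power on that channel. Labels are balanced and the output is
#' bit-reproducible given the profile's seed.
#'
#' @param profile one subject profile row from \code{\link{makeCohort}}.
#' @param n_trials trials per class (>= 2).
#' @param fs sampling rate in Hz (>= 128 and above twice the beta band
#'   edge).
#' @param timing a \linkS4class{TrialTiming}.
#' @param montage a \linkS4class{Montage}.
#' @return a \linkS4class{TrialSet}.
#' @examples
#' prof <- makeCohort(1, seed = 3, efficiency = 0.8)[1, ]
#' ts <- simulateTrialSet(prof, n_trials = 4, fs = 160)
#' nTrials(ts)
#' @export
simulateTrialSet <- function(profile, n_trials = 50, fs = 160,
                             timing = miTiming(),
                             montage = sensorimotorMontage()) {
  profile <- validateProfile(profile)
  if (n_trials < 2) stop("need at least 2 trials per class")
  if (fs < 128) stop("fs must be >= 128 Hz")
  beta_high <- min(profile$beta_peak_hz + 2.5, 30)
  if (fs < 2 * beta_high)
    stop("fs below twice the beta band upper edge")
  ch <- montage@channels
  n <- round(timing@trial_length_s * fs)
  n_tot <- 2L * n_trials
  labels <- factor(rep(c("left", "right"), n_trials),
                   levels = c("left", "right"))
  mu_band <- c(profile$mu_peak_hz - 1.5, profile$mu_peak_hz + 1.5)
  beta_band <- c(profile$beta_peak_hz - 2.5, beta_high)
  bf_mu <- signal::butter(4, mu_band / (fs / 2), "pass")
  bf_beta <- signal::butter(4, beta_band / (fs / 2), "pass")
  env <- erdEnvelope(n, fs, timing@mi, sqrt(1 - profile$erd_depth))
  arr <- with_seed(profile$seed, {
    a <- array(0, dim = c(n_tot, length(ch), n),
               dimnames = list(NULL, ch, NULL))
    for (i in seq_len(n_tot)) {
      # C3 overlies the left motor cortex controlling the right hand
      contra <- if (labels[i] == "right") "C3" else "C4"
      for (j in seq_along(ch)) {
        g <- .osc_gain[ch[j]]
        if (is.na(g)) g <- 0.25
        x <- shapedNoise(n, fs, profile$noise_k1, profile$noise_k2,
                         profile$noise_eta)
        osc <- bandOscillation(n, fs, mu_band[1], mu_band[2],
                               profile$mu_amp * g, bf_mu) +
               bandOscillation(n, fs, beta_band[1], beta_band[2],
                               profile$beta_amp * g, bf_beta)
        if (ch[j] == contra) osc <- osc * env
        a[i, j, ] <- x + osc
      }
    }
    a
  })
  new("TrialSet", trials = arr, labels = labels, fs = fs,
      timing = timing, montage = montage)
}

#' Simulate a resting-state recording
#'
#' Same spectral model as the trial baseline (1/f noise plus mu/beta
#' oscillations), with no event-related modulation. The 60 s default
#' emulates the single resting record acquired per subject.
#'
#' @param profile one subject profile row from \code{\link{makeCohort}}.
#' @param fs sampling rate in Hz.
#' @param duration_s record length in seconds (>= 10).
#' @param montage a \linkS4class{Montage}.
#' @return an \linkS4class{EEGRecording}.
#' @export
simulateResting <- function(profile, fs = 160, duration_s = 60,
                            montage = sensorimotorMontage()) {
  profile <- validateProfile(profile)
  if (duration_s < 10) stop("duration_s must be >= 10")
  if (fs < 128) stop("fs must be >= 128 Hz")
  beta_high <- min(profile$beta_peak_hz + 2.5, 30)
  if (fs < 2 * beta_high) stop("fs below twice the beta band upper edge")
  ch <- montage@channels
  n <- round(duration_s * fs)
  mu_band <- c(profile$mu_peak_hz - 1.5, profile$mu_peak_hz + 1.5)
  beta_band <- c(profile$beta_peak_hz - 2.5, beta_high)
  bf_mu <- signal::butter(4, mu_band / (fs / 2), "pass")
  bf_beta <- signal::butter(4, beta_band / (fs / 2), "pass")
  samples <- with_seed(profile$seed + 1L, {
    m <- matrix(0, length(ch), n)
    for (j in seq_along(ch)) {
      g <- .osc_gain[ch[j]]
      if (is.na(g)) g <- 0.25
      x <- shapedNoise(n, fs, profile$noise_k1, profile$noise_k2,
                       profile$noise_eta)
      osc <- if (profile$mu_amp * g > 0)
        bandOscillation(n, fs, mu_band[1], mu_band[2],
                        profile$mu_amp * g, bf_mu)
      else 0
      osc_b <- if (profile$beta_amp * g > 0)
        bandOscillation(n, fs, beta_band[1], beta_band[2],
                        profile$beta_amp * g, bf_beta)
      else 0
      m[j, ] <- x + osc + osc_b
    }
    m
  })
  new("EEGRecording", samples = samples, fs = fs, channels = ch)
}

#' Nonlinear-monotone regression cohort
#'
#' A purpose-built study cohort for contrasting the wide-and-deep
#' regressor with a scalar linear baseline. Each subject's response is a
#' steep logistic function of the latent efficiency (monotone but
#' strongly nonlinear), while the available scalar indicator is the
#' latent passed through a hard saturating transform (clipped at 0.15)
#' plus observation noise (sd 0.1) -- above the saturation point the
#' scalar carries essentially no rank information. The full feature set,
#' in contrast, is extracted from simulated resting EEG whose rhythm
#' amplitudes scale with the latent efficiency, so a regressor that can
#' exploit the rich input recovers the response ranking.
#'
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param fs sampling rate for the simulated resting records.
#' @param duration_s resting record length per subject (trimming the
#'   first 5 s still applies downstream).
#' @return list with elements \code{profiles} (cohort data.frame),
#'   \code{latent}, \code{response}, \code{scalar} and
#'   \code{recordings} (list of \linkS4class{EEGRecording}).
#' @export
makeNonlinearCohort <- function(n_subjects = 50, seed = 1, fs = 160,
                                duration_s = 20) {
  profiles <- makeCohort(n_subjects, seed)
  latent <- profiles$efficiency
  scalar <- with_seed(seed + 1L,
                      pmin(latent, 0.15) + stats::rnorm(n_subjects, 0, 0.1))
  response <- stats::plogis(10 * (latent - 0.5))
  recordings <- lapply(seq_len(n_subjects), function(i)
    simulateResting(profiles[i, ], fs = fs, duration_s = duration_s))
  list(profiles = profiles, latent = latent, response = response,
       scalar = scalar, recordings = recordings)
}

#' Save / load a simulated cohort
#'
#' Persists trial sets and resting records per subject as an RDS
#' container with a JSON sidecar holding the generating configuration,
#' so pipeline stages can be re-run independently.
#'
#' @param cohort_data list with \code{profiles}, \code{trial_sets} and
#'   optionally \code{restings}.
#' @param dir output directory (created if absent).
#' @param config list stored in the JSON sidecar.
#' @return \code{saveCohortData} returns \code{dir} invisibly;
#'   \code{loadCohortData} returns the stored list.
#' @export
saveCohortData <- function(cohort_data, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(cohort_data, file.path(dir, "cohort.rds"))
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveCohortData
#' @export
loadCohortData <- function(dir) {
  path <- file.path(dir, "cohort.rds")
  if (!file.exists(path)) stop("no cohort container found in ", dir)
  readRDS(path)
}
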