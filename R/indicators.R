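# Neurophysiological indicators of MI ability.
#
# xi1 (pre-training): maximal excess of the resting power spectrum over
# its fitted aperiodic (hyperbolic) noise floor, after decomposing the
# 4-40 Hz spectrum into two Gaussian rhythm peaks plus noise.
# xi2 (initial training): normalized squared distance between the two
# classes' ERD/ERS time courses, maximized over rhythm bands and
# channels.

#' Welch power spectral density
#'
#' Averaged modified periodogram over Hamming-tapered sliding windows
#' (default 1 s length, 50% overlap). Segments are mean-detrended; the
#' one-sided density integrates to the signal variance.
#'
#' @param x single-channel sample vector.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param overlap fractional overlap in \code{[0, 1)}.
#' @param channel optional channel label stored in the estimate.
#' @return a \linkS4class{PSDEstimate}.
#' @examples
#' psd <- welchPsd(sin(2 * pi * 10 * seq(0, 10, by = 1/160)), fs = 160)
#' psd@freq[which.max(psd@power)]
#' @export
welchPsd <- function(x, fs, win_s = 1.0, overlap = 0.5, channel = "") {
  nwin <- round(win_s * fs)
  if (length(x) < nwin) stop("signal shorter than one window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nwin + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq.int(0L, nwin - 1L) / (nwin - 1L))
  u <- sum(w^2)
  nf <- nwin %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  pw <- acc / length(starts)
  # one-sided: double everything except DC and (for even nwin) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nf] <- 1
  pw <- pw * dbl
  new("PSDEstimate", freq = (seq_len(nf) - 1) * fs / nwin, power = pw,
      channel = channel,
      meta = list(win_s = win_s, overlap = overlap, fs = fs))
}

#' Aperiodic noise-floor curve
#'
#' Evaluates \eqn{\epsilon(f) = \kappa_1 + \kappa_2 / f^\eta}.
#'
#' @param f frequencies in Hz.
#' @param noise named numeric with \code{kappa1}, \code{kappa2},
#'   \code{eta} (e.g. the \code{noise} slot of a
#'   \linkS4class{PSDFitModel}).
#' @return noise-floor density at each frequency.
#' @export
noiseCurve <- function(f, noise) {
  unname(noise["kappa1"] + noise["kappa2"] / f^noise["eta"])
}

# full model curve of a PSDFitModel on a grid
.psd_model_curve <- function(f, peaks, noise) {
  g <- function(k, m, s) k * exp(-(f - m)^2 / (2 * s^2))
  g(peaks["mu", "k"], peaks["mu", "m"], peaks["mu", "sigma"]) +
    g(peaks["beta", "k"], peaks["beta", "m"], peaks["beta", "sigma"]) +
    noiseCurve(f, noise)
}

#' Evaluate a fitted spectral model
#'
#' @param fit a \linkS4class{PSDFitModel}.
#' @param f frequencies in Hz.
#' @return modeled density (peaks + noise floor) at each frequency.
#' @export
psdModelCurve <- function(fit, f) .psd_model_curve(f, fit@peaks, fit@noise)

#' Fit the two-peak spectral model
#'
#' Bounded nonlinear least squares decomposing a 4--40 Hz power spectrum
#' into two Gaussian rhythm peaks (amplitude form
#' \eqn{k \exp(-(f-m)^2 / 2\sigma^2)}, centers box-constrained to the mu
#' band 8--13 Hz and the beta band 14--30 Hz, all parameters nonnegative)
#' plus the aperiodic floor \eqn{\kappa_1 + \kappa_2 / f^\eta}. A
#' deterministic multistart (default 5 starts spanning peak positions and
#' slopes) keeps the lowest-residual solution; if no start converges the
#' best attempt is returned flagged as non-converged.
#'
#' All Welch grid frequencies inside the fitting range are weighted
#' equally on the linear power scale.
#'
#' @param psd a \linkS4class{PSDEstimate} covering at least 4--40 Hz.
#' @param f_range fitting range in Hz.
#' @param n_starts number of multistart initializations.
#' @return a \linkS4class{PSDFitModel}.
#' @export
fitPsdModel <- function(psd, f_range = c(4, 40), n_starts = 5) {
  keep <- psd@freq >= f_range[1] & psd@freq <= f_range[2]
  if (sum(keep) < 10) stop("PSD must cover the 4-40 Hz fitting range")
  f <- psd@freq[keep]
  s <- psd@power[keep]
  model <- function(p) {
    p["kmu"] * exp(-(f - p["mmu"])^2 / (2 * p["smu"]^2)) +
      p["kb"] * exp(-(f - p["mb"])^2 / (2 * p["sb"]^2)) +
      p["k1"] + p["k2"] / f^p["eta"]
  }
  resid_fn <- function(p) s - model(p)
  lower <- c(kmu = 0, mmu = 8, smu = 0.3, kb = 0, mb = 14, sb = 0.3,
             k1 = 0, k2 = 0, eta = 0)
  upper <- c(kmu = Inf, mmu = 13, smu = 5, kb = Inf, mb = 30, sb = 8,
             k1 = Inf, k2 = Inf, eta = 5)
  floor_guess <- max(min(s), 1e-12)
  height <- function(m0) {
    max(max(s[abs(f - m0) <= 1.5]) - floor_guess, 1e-6)
  }
  # deterministic start grid over plausible peak positions and slopes
  start_grid <- list(
    c(mmu = 10, mb = 20, eta = 1),
    c(mmu = 9, mb = 17, eta = 0.8),
    c(mmu = 11.5, mb = 24, eta = 1.2),
    c(mmu = 12.5, mb = 28, eta = 1.5),
    c(mmu = 8.5, mb = 15, eta = 0.5))
  start_grid <- start_grid[seq_len(min(n_starts, length(start_grid)))]
  best <- NULL
  for (sg in start_grid) {
    p0 <- c(kmu = height(sg[["mmu"]]), mmu = sg[["mmu"]], smu = 1.5,
            kb = height(sg[["mb"]]), mb = sg[["mb"]], sb = 2.5,
            k1 = floor_guess, k2 = max(s[1] * f[1], 1e-6),
            eta = sg[["eta"]])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    res <- sqrt(sum(resid_fn(unlist(fit$par))^2))
    conv <- fit$info %in% 1:4
    if (is.null(best) || res < best$res) {
      best <- list(par = unlist(fit$par), res = res, conv = conv)
    }
  }
  if (is.null(best)) {
    warning("spectral fit failed on all starts; returning the initial guess")
    p0 <- c(kmu = height(10), mmu = 10, smu = 1.5, kb = height(20),
            mb = 20, sb = 2.5, k1 = floor_guess,
            k2 = max(s[1] * f[1], 1e-6), eta = 1)
    best <- list(par = p0, res = sqrt(sum(resid_fn(p0)^2)), conv = FALSE)
  }
  p <- best$par
  peaks <- rbind(mu = c(k = p[["kmu"]], m = p[["mmu"]], sigma = p[["smu"]]),
                 beta = c(k = p[["kb"]], m = p[["mb"]], sigma = p[["sb"]]))
  colnames(peaks) <- c("k", "m", "sigma")
  if (!best$conv) warning("spectral fit did not converge")
  new("PSDFitModel", peaks = peaks,
      noise = c(kappa1 = p[["k1"]], kappa2 = p[["k2"]], eta = p[["eta"]]),
      residual = best$res, converged = best$conv)
}

#' Pre-training desynchronization indicator
#'
#' For each channel, the maximal excess of the measured spectrum over the
#' fitted aperiodic noise floor, floored at zero; the subject-level
#' indicator is the mean over the channel configuration. Large values
#' mean prominent sensorimotor rhythms standing clear of the 1/f
#' background -- the classic spectral predictor of MI aptitude.
#'
#' @param psds list of \linkS4class{PSDEstimate}, one per channel, on a
#'   common frequency grid.
#' @param fits list of \linkS4class{PSDFitModel}, one per channel.
#' @param f_range frequency range over which the excess is evaluated.
#' @return single nonnegative indicator value.
#' @export
xi1 <- function(psds, fits, f_range = c(4, 40)) {
  if (length(psds) != length(fits))
    stop("need one fit per channel")
  grid <- psds[[1]]@freq
  per_channel <- vapply(seq_along(psds), function(i) {
    if (!isTRUE(all.equal(psds[[i]]@freq, grid)))
      stop("PSD frequency grids differ between channels")
    keep <- grid >= f_range[1] & grid <= f_range[2]
    excess <- psds[[i]]@power[keep] -
      noiseCurve(grid[keep], fits[[i]]@noise)
    max(max(excess), 0)
  }, numeric(1))
  mean(per_channel)
}

#' Subject-level xi1 from a recording
#'
#' Convenience wrapper: Welch PSD and spectral-model fit per channel of
#' the configuration, then the channel-averaged indicator.
#'
#' @param rec an \linkS4class{EEGRecording} (e.g. trimmed resting data or
#'   concatenated baseline segments).
#' @param channels channel labels to use.
#' @param win_s,overlap Welch parameters.
#' @return list with \code{xi1}, \code{psds} and \code{fits}.
#' @export
computeXi1 <- function(rec, channels = channelConfig("2Ch"),
                       win_s = 1.0, overlap = 0.5) {
  idx <- match(channels, rec@channels)
  if (anyNA(idx))
    stop("recording is missing channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  psds <- lapply(idx, function(i)
    welchPsd(rec@samples[i, ], rec@fs, win_s, overlap,
             channel = rec@channels[i]))
  fits <- lapply(psds, fitPsdModel)
  list(xi1 = xi1(psds, fits), psds = psds, fits = fits)
}

#' ERD/ERS time course per class
#'
#' Relative band-power series: per class, squared samples averaged over
#' trials (\eqn{\zeta_t}), referenced to the mean over the reference
#' interval (\eqn{\bar\zeta}) as \eqn{\hat\zeta_t = (\zeta_t -
#' \bar\zeta)/\bar\zeta}. Samples whose z-score against the
#' reference-interval distribution is non-significant (two-sided, level
#' \code{alpha}) are masked to zero in \code{zhat_masked}. The time base
#' is one value per sample.
#'
#' @param trials a \linkS4class{TrialSet} with full-length trials.
#' @param band \code{"mu"}, \code{"beta"} (band-pass applied here) or
#'   \code{"none"} if the trials are already band-filtered.
#' @param channel channel label.
#' @param ref_interval reference interval in seconds (within the
#'   baseline; default 0.5--1.5 s).
#' @param alpha two-sided significance level of the z-score mask.
#' @return named list with one \linkS4class{ERDSTimeCourse} per class
#'   (\code{left}, \code{right}).
#' @export
computeErds <- function(trials, band = c("mu", "beta", "none"), channel,
                        ref_interval = c(0.5, 1.5), alpha = 0.01) {
  band <- match.arg(band)
  ch <- channelNames(trials)
  j <- match(channel, ch)
  if (is.na(j)) stop("channel ", channel, " not in the trial set")
  fs <- trials@fs
  x <- trials@trials[, j, , drop = TRUE]       # trials x samples
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (band != "none") {
    edges <- rhythmBand(band)
    bf <- signal::butter(4, edges / (fs / 2), "pass")
    x <- t(apply(x, 1, function(v) .filtfilt_padded(bf, v)))
  }
  n <- ncol(x)
  tvec <- (seq_len(n) - 1) / fs
  ref_idx <- .interval_samples(ref_interval[1], ref_interval[2], fs)
  if (max(ref_idx) > n) stop("reference interval outside the trial")
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- lapply(c(left = "left", right = "right"), function(lab) {
    sel <- trials@labels == lab
    if (sum(sel) < 2) stop("need at least 2 trials of class ", lab)
    zeta <- colMeans(x[sel, , drop = FALSE]^2)
    zbar <- mean(zeta[ref_idx])
    if (zbar == 0) stop("degenerate reference: zero power in ", lab)
    if (stats::var(zeta) <= stats::var(zeta[ref_idx]))
      warning("power variance over the trial does not exceed the ",
              "reference variance (class ", lab, ")")
    zhat <- (zeta - zbar) / zbar
    mu_ref <- mean(zhat[ref_idx])
    sd_ref <- stats::sd(zhat[ref_idx])
    masked <- zhat
    if (sd_ref > 0) {
      z <- (zhat - mu_ref) / sd_ref
      masked[abs(z) < zcrit] <- 0
    }
    new("ERDSTimeCourse", zhat = zhat, zhat_masked = masked, time = tvec,
        band = band, channel = channel, class_label = lab,
        ref_interval = ref_interval, ref_power = zbar)
  })
  out
}

#' Distance between two class ERD/ERS curves
#'
#' The squared euclidean distance between the two class curves divided by
#' the product of their norms:
#' \eqn{d = \|a - b\|_2^2 / (\|a\|_2 \|b\|_2)}. Invariant under common
#' positive scaling of both curves; zero for identical curves.
#'
#' @param left,right \linkS4class{ERDSTimeCourse} of each class, or plain
#'   numeric curves.
#' @param mi optional interval in seconds to restrict the curves to
#'   (used with ERDS objects; the masked series is evaluated).
#' @return nonnegative distance, or \code{NA} if either curve has zero
#'   norm.
#' @export
erdsDistance <- function(left, right, mi = NULL) {
  pick <- function(obj) {
    if (is(obj, "ERDSTimeCourse")) {
      v <- obj@zhat_masked
      if (!is.null(mi)) v <- v[obj@time >= mi[1] & obj@time < mi[2]]
      v
    } else as.numeric(obj)
  }
  a <- pick(left); b <- pick(right)
  if (length(a) != length(b)) stop("class curves differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum((a - b)^2) / (na * nb)
}

#' Initial-training synchronization indicator
#'
#' Maximum of the normalized class-distance \code{\link{erdsDistance}}
#' over the supplied (band, channel) ERD/ERS pairs: a single rhythm and
#' electrode with clearly separated class dynamics is enough to witness
#' an adequate neural response. Pairs where either class curve has zero
#' norm are skipped with a warning; if every pair is skipped the
#' indicator is 0.
#'
#' @param erds_pairs list of per-(band, channel) entries, each a list
#'   with elements \code{left} and \code{right}
#'   (\linkS4class{ERDSTimeCourse}).
#' @param mi interval in seconds the distance is evaluated on (default
#'   the MI interval 2.6--4.6 s).
#' @return list with \code{xi2} (the max), \code{per_pair} distances.
#' @export
xi2 <- function(erds_pairs, mi = c(2.6, 4.6)) {
  d <- vapply(erds_pairs, function(p)
    erdsDistance(p$left, p$right, mi = mi), numeric(1))
  if (all(is.na(d))) {
    warning("all (band, channel) pairs degenerate; xi2 set to 0")
    return(list(xi2 = 0, per_pair = d))
  }
  if (anyNA(d))
    warning("skipping ", sum(is.na(d)), " degenerate (band, channel) pair(s)")
  list(xi2 = max(d, na.rm = TRUE), per_pair = d)
}

#' Subject-level xi2 from a trial set
#'
#' Computes ERD/ERS per requested band and channel and returns the
#' maximized class distance. For the combined \code{mu + beta} setting
#' the maximum simply ranges over both bands' (band, channel) pairs.
#'
#' @param trials a \linkS4class{TrialSet} (full-length, broad-band
#'   filtered or raw).
#' @param bands subset of \code{c("mu", "beta")}.
#' @param channels channel labels (e.g. \code{channelConfig("2Ch")}).
#' @param ref_interval,alpha passed to \code{\link{computeErds}}.
#' @param mi evaluation interval; defaults to the trial set's MI
#'   interval.
#' @return list with \code{xi2}, \code{per_pair} and the pair grid.
#' @export
computeXi2 <- function(trials, bands = c("mu", "beta"),
                       channels = channelConfig("2Ch"),
                       ref_interval = c(0.5, 1.5), alpha = 0.01,
                       mi = NULL) {
  if (is.null(mi)) mi <- trials@timing@mi
  grid <- expand.grid(band = bands, channel = channels,
                      stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(grid)), function(i)
    computeErds(trials, band = grid$band[i], channel = grid$channel[i],
                ref_interval = ref_interval, alpha = alpha))
  res <- xi2(pairs, mi = mi)
  res$pairs <- grid
  res
}

#' Subset trials of a trial set
#'
#' @param x a \linkS4class{TrialSet}.
#' @param idx trial indices to keep.
#' @return a \linkS4class{TrialSet} with those trials.
#' @export
subsetTrials <- function(x, idx) {
  x@trials <- x@trials[idx, , , drop = FALSE]
  x@labels <- x@labels[idx]
  x
}

#' Run-wise xi2 trend test
#'
#' Splits each subject's time-ordered trials into consecutive runs of
#' \code{run_size} trials, computes xi2 per run, and tests consecutive
#' runs against each other across subjects with the paired Wilcoxon
#' signed-rank test. A decreasing run mean indicates that the measured
#' synchronization distance shrinks as training progresses.
#'
#' @param trial_sets list of \linkS4class{TrialSet}, one per subject,
#'   trials ordered in time.
#' @param run_size trials per run (default 30).
#' @param max_runs cap on the number of runs compared (default 3).
#' @param alpha test level.
#' @param bands,channels,ref_interval passed to \code{\link{computeXi2}}.
#' @return list with \code{xi2_runs} (subjects x runs matrix),
#'   \code{run_means}, \code{p_values} (consecutive-run comparisons) and
#'   \code{significant} at \code{alpha}.
#' @export
runTrendTest <- function(trial_sets, run_size = 30, max_runs = 3,
                         alpha = 0.05, bands = c("mu", "beta"),
                         channels = channelConfig("2Ch"),
                         ref_interval = c(0.5, 1.5)) {
  n_runs <- min(vapply(trial_sets, function(ts)
    as.integer(nTrials(ts) %/% run_size), integer(1)))
  n_runs <- min(n_runs, max_runs)
  if (n_runs < 2) stop("need at least 2 complete runs per subject")
  xi2_runs <- t(vapply(trial_sets, function(ts) {
    vapply(seq_len(n_runs), function(r) {
      idx <- ((r - 1) * run_size + 1):(r * run_size)
      computeXi2(subsetTrials(ts, idx), bands = bands,
                 channels = channels, ref_interval = ref_interval)$xi2
    }, numeric(1))
  }, numeric(n_runs)))
  colnames(xi2_runs) <- paste0("run", seq_len(n_runs))
  pvals <- vapply(seq_len(n_runs - 1), function(r)
    stats::wilcox.test(xi2_runs[, r], xi2_runs[, r + 1],
                       paired = TRUE, exact = FALSE)$p.value,
    numeric(1))
  names(pvals) <- paste0("run", seq_len(n_runs - 1), "_vs_run",
                         2:n_runs)
  list(xi2_runs = xi2_runs, run_means = colMeans(xi2_runs),
       p_values = pvals, significant = pvals < alpha)
}
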