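# Bi-class accuracy response: sliding-window CSP + regularized LDA under
# repeated stratified cross-validation. The per-subject accuracy at each
# window length delta-tau is the response variable the indicators are
# regressed on.

# trial covariances for one segmented window:
#   raw  : X X' per trial (for feature variances)
#   norm : trace-normalized (for CSP class means)
.trial_covs <- function(arr) {
  n <- dim(arr)[1]
  raw <- vector("list", n)
  norm <- vector("list", n)
  for (i in seq_len(n)) {
    X <- arr[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    R <- tcrossprod(X)
    raw[[i]] <- R
    norm[[i]] <- R / sum(diag(R))
  }
  list(raw = raw, norm = norm)
}

.shrink <- function(S, gamma) {
  p <- nrow(S)
  (1 - gamma) * S + gamma * (sum(diag(S)) / p) * diag(p)
}

# CSP core on two class-mean covariances
.csp_core <- function(S_l, S_r, n_per_class, shrinkage, channels) {
  C <- nrow(S_l)
  S_l <- .shrink(S_l, shrinkage)
  S_r <- .shrink(S_r, shrinkage)
  Sc <- S_l + S_r
  ec <- eigen(Sc, symmetric = TRUE)
  if (min(ec$values) < 1e-12 * max(ec$values))
    stop("singular composite covariance after shrinkage")
  W0 <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S <- W0 %*% S_l %*% t(W0)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)        # values descending in [0, 1]
  k <- min(n_per_class, C %/% 2)
  if (k < 1) stop("not enough channels for even one filter per class")
  sel <- c(seq_len(k), seq.int(C - k + 1, C))
  W <- t(es$vectors[, sel, drop = FALSE]) %*% W0
  new("CSPModel", filters = W, eigenvalues = es$values[sel],
      n_per_class = as.integer(k), shrinkage = shrinkage,
      channels = channels)
}

#' Fit common spatial patterns
#'
#' Per-trial covariances are trace-normalized, averaged per class and
#' shrunk toward a scaled identity; the filters come from the
#' generalized eigendecomposition of (class-l covariance, composite
#' covariance). The \code{n_per_class} filters with the largest and the
#' smallest class-l variance share are retained (capped at
#' \code{floor(channels / 2)} per class, so the two-channel configuration
#' yields one filter per class).
#'
#' @param trials a \linkS4class{TrialSet}, already windowed and filtered
#'   to the analysis band, with the chosen channels.
#' @param n_per_class filters per class (default 3).
#' @param shrinkage covariance shrinkage level in \code{[0, 1]}.
#' @return a \linkS4class{CSPModel}; its filters whiten the composite
#'   covariance (\code{W (S_l + S_r) W' = I} on the selected subspace).
#' @export
fitCsp <- function(trials, n_per_class = 3, shrinkage = 0.05) {
  lab <- trials@labels
  if (min(table(lab)) < 2) stop("need at least 2 trials per class")
  covs <- .trial_covs(trials@trials)$norm
  S_l <- Reduce(`+`, covs[lab == "left"]) / sum(lab == "left")
  S_r <- Reduce(`+`, covs[lab == "right"]) / sum(lab == "right")
  .csp_core(S_l, S_r, n_per_class, shrinkage, channelNames(trials))
}

#' CSP log-variance features
#'
#' Per trial: the variance of each spatially filtered signal, normalized
#' by the sum over filters, on a log scale. Scale-invariant by
#' construction.
#'
#' @param trials a \linkS4class{TrialSet} matching the fitted model's
#'   channels.
#' @param csp a \linkS4class{CSPModel}.
#' @return numeric matrix, trials x (2 * filters per class).
#' @export
cspFeatures <- function(trials, csp) {
  W <- csp@filters
  arr <- trials@trials
  n <- dim(arr)[1]
  out <- matrix(0, n, nrow(W))
  for (i in seq_len(n)) {
    X <- arr[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    v <- diag(W %*% tcrossprod(X) %*% t(W))
    if (any(v <= 0)) stop("zero-variance projection in trial ", i)
    out[i, ] <- log(v / sum(v))
  }
  out
}

# features from precomputed raw covariances (internal fast path)
.csp_features_from_covs <- function(raw_covs, W) {
  t(vapply(raw_covs, function(R) {
    v <- diag(W %*% R %*% t(W))
    v <- pmax(v, .Machine$double.xmin)
    log(v / sum(v))
  }, numeric(nrow(W))))
}

# two-class LDA with shrinkage of the pooled covariance
.rlda_fit <- function(X, y, gamma = 0.05) {
  X0 <- X[y == "left", , drop = FALSE]
  X1 <- X[y == "right", , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  Sp <- (crossprod(sweep(X0, 2, m0)) + crossprod(sweep(X1, 2, m1))) /
    (nrow(X) - 2)
  Sp <- .shrink(Sp, gamma)
  w <- solve(Sp, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2
  list(w = w, b = b)
}

.rlda_predict <- function(fit, X) {
  score <- as.numeric(X %*% fit$w) + fit$b
  factor(ifelse(score > 0, "right", "left"), levels = c("left", "right"))
}

# stratified fold assignment: a permutation-balanced fold id per trial
.stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds)
      stop("class ", cl, " has fewer trials than folds")
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Sliding-window CSP/LDA accuracy response
#'
#' For each window length \code{delta_tau}, windows slide across the MI
#' interval with 50% overlap. Per window position, CSP and regularized
#' LDA are fitted inside each training fold of a repeated stratified
#' cross-validation (default 10 repetitions of 10 folds) and scored on
#' the held-out fold. The time-varying curve is the mean CV accuracy per
#' position; the per-delta-tau summary is the maximum over positions
#' (the subject's best extraction window), with the mean over positions
#' stored for sensitivity and the CV standard deviation at the
#' maximizing window as dispersion.
#'
#' @param trials a full-length \linkS4class{TrialSet} (raw; the 4--40 Hz
#'   band-pass and channel selection are applied here).
#' @param config \code{"2Ch"}, \code{"6Ch"} or a character vector of
#'   channel labels.
#' @param delta_taus window lengths in seconds.
#' @param n_rep,n_folds cross-validation scheme.
#' @param n_per_class,shrinkage CSP settings.
#' @param lda_shrinkage LDA covariance shrinkage.
#' @param seed integer seed for fold assignment.
#' @return an \linkS4class{AccuracyResponse}.
#' @export
accuracyResponse <- function(trials, config = "2Ch",
                             delta_taus = c(0.5, 1.0, 1.5, 2.0),
                             n_rep = 10, n_folds = 10,
                             n_per_class = 3, shrinkage = 0.05,
                             lda_shrinkage = 0.05, seed = 1) {
  if (nTrials(trials) < 20)
    stop("need at least 20 trials for the accuracy response")
  channels <- if (length(config) == 1 && config %in% c("2Ch", "6Ch"))
    channelConfig(config) else config
  mi <- trials@timing@mi
  if (any(delta_taus > diff(mi) + 1e-9))
    stop("delta_tau longer than the MI interval")
  x <- selectChannels(bandpassFilter(trials, 4, 40), channels)
  y <- x@labels
  summary_max <- summary_mean <- dispersion <-
    setNames(numeric(length(delta_taus)), format(delta_taus))
  curves <- list()
  with_seed(seed, {
    for (di in seq_along(delta_taus)) {
      dt <- delta_taus[di]
      starts <- seq(mi[1], mi[2] - dt + 1e-9, by = dt / 2)
      acc_pos <- numeric(length(starts))
      sd_pos <- numeric(length(starts))
      for (pi in seq_along(starts)) {
        seg <- segmentTrials(x, c(starts[pi], starts[pi] + dt))
        covs <- .trial_covs(seg@trials)
        fold_acc <- numeric(0)
        for (rep_i in seq_len(n_rep)) {
          folds <- .stratified_folds(y, n_folds)
          for (k in seq_len(n_folds)) {
            tr <- folds != k
            S_l <- Reduce(`+`, covs$norm[tr & y == "left"]) /
              sum(tr & y == "left")
            S_r <- Reduce(`+`, covs$norm[tr & y == "right"]) /
              sum(tr & y == "right")
            csp <- .csp_core(S_l, S_r, n_per_class, shrinkage, channels)
            feats <- .csp_features_from_covs(covs$raw, csp@filters)
            lda <- .rlda_fit(feats[tr, , drop = FALSE], y[tr],
                             lda_shrinkage)
            pred <- .rlda_predict(lda, feats[!tr, , drop = FALSE])
            fold_acc <- c(fold_acc, mean(pred == y[!tr]))
          }
        }
        acc_pos[pi] <- mean(fold_acc)
        sd_pos[pi] <- stats::sd(fold_acc)
      }
      best <- which.max(acc_pos)
      summary_max[di] <- acc_pos[best]
      summary_mean[di] <- mean(acc_pos)
      dispersion[di] <- sd_pos[best]
      curves[[format(dt)]] <- data.frame(window_start = starts,
                                         accuracy = acc_pos,
                                         cv_sd = sd_pos)
    }
  })
  new("AccuracyResponse", summary = summary_max,
      summary_mean = summary_mean, dispersion = dispersion,
      curves = curves)
}
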