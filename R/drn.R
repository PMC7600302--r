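# The wide-and-deep regression network (DRN): joint extraction of a
# data-driven subject indicator from short-time moment features and
# regression of that indicator on the bi-class accuracy response.
#
# Architecture: per-channel dense branches (tanh, h = ceiling(1.5 d)
# units, separate weights per electrode), a concatenation stage of size
# h*C', a dense tanh layer of ceiling(0.5 h C') units, a one-neuron
# linear output, and a wide shortcut connecting the standardized input
# features directly to the output. Trained full-batch with Adam on the
# mean absolute error plus an elastic-net penalty on all weights.

#' Short-time moment features
#'
#' Time-varying statistical moments of one channel's signal: per sliding
#' window (default 1 s, 50% overlap) the mean, median, population
#' variance, minimum and maximum, concatenated in time order into a
#' single vector of length \code{5 * n_windows}.
#'
#' @param x single-channel sample vector.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds.
#' @param overlap fractional overlap in \code{[0, 1)}.
#' @return numeric feature vector with attribute \code{n_windows}.
#' @examples
#' momentFeatures(rep(3, 8), fs = 8, win_s = 1)   # one window
#' @export
momentFeatures <- function(x, fs, win_s = 1.0, overlap = 0.5) {
  if (length(x) == 0) stop("empty signal")
  nwin <- round(win_s * fs)
  if (length(x) < nwin) stop("signal shorter than one window")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nwin + 1L, by = step)
  feats <- vapply(starts, function(s) {
    w <- x[s:(s + nwin - 1L)]
    m <- mean(w)
    c(m, stats::median(w), mean((w - m)^2), min(w), max(w))
  }, numeric(5))
  out <- as.numeric(feats)          # window-major: 5 stats per window
  attr(out, "n_windows") <- length(starts)
  out
}

#' Build per-subject DRN input stacks
#'
#' Assembles the network input from one of three sources, channel by
#' channel in the order of the configuration:
#' \describe{
#'   \item{baseline}{per channel, the baseline-interval segments of all
#'     trials concatenated in trial order, then moment features;}
#'   \item{resting}{the (already trimmed) resting record per channel,
#'     then moment features;}
#'   \item{erds}{per channel, the masked class ERD/ERS curves over the
#'     MI interval, concatenated left then right for each requested
#'     band, then moment features.}
#' }
#'
#' @param trials a \linkS4class{TrialSet} (required for the baseline and
#'   erds sources).
#' @param resting an \linkS4class{EEGRecording} (required for the
#'   resting source).
#' @param source \code{"baseline"}, \code{"resting"} or \code{"erds"}.
#' @param channels channel labels in the configuration order.
#' @param bands bands used by the erds source.
#' @param win_s,overlap moment-feature window settings.
#' @param ref_interval,alpha ERD/ERS settings for the erds source.
#' @return numeric vector of length \code{d * length(channels)} (the
#'   per-channel stacks concatenated), with attributes \code{d} and
#'   \code{n_channels}.
#' @export
buildInputs <- function(trials = NULL, resting = NULL,
                        source = c("baseline", "resting", "erds"),
                        channels = channelConfig("2Ch"),
                        bands = c("mu", "beta"),
                        win_s = 1.0, overlap = 0.5,
                        ref_interval = c(0.5, 1.5), alpha = 0.01) {
  source <- match.arg(source)
  per_channel <- switch(source,
    baseline = {
      if (is.null(trials)) stop("baseline source needs a trial set")
      seg <- segmentTrials(trials, "baseline")
      fs <- seg@fs
      lapply(channels, function(ch) {
        j <- match(ch, channelNames(seg))
        if (is.na(j)) stop("trial set is missing channel ", ch)
        momentFeatures(as.numeric(t(seg@trials[, j, ])), fs,
                       win_s, overlap)
      })
    },
    resting = {
      if (is.null(resting)) stop("resting source needs a resting record")
      lapply(channels, function(ch) {
        j <- match(ch, resting@channels)
        if (is.na(j)) stop("resting record is missing channel ", ch)
        momentFeatures(resting@samples[j, ], resting@fs, win_s, overlap)
      })
    },
    erds = {
      if (is.null(trials)) stop("erds source needs a trial set")
      fs <- trials@fs
      mi <- trials@timing@mi
      lapply(channels, function(ch) {
        curves <- unlist(lapply(bands, function(b) {
          e <- computeErds(trials, band = b, channel = ch,
                           ref_interval = ref_interval, alpha = alpha)
          keep <- e$left@time >= mi[1] & e$left@time < mi[2]
          c(e$left@zhat_masked[keep], e$right@zhat_masked[keep])
        }))
        momentFeatures(curves, fs, win_s, overlap)
      })
    })
  d <- unique(vapply(per_channel, length, integer(1)))
  if (length(d) != 1) stop("per-channel feature lengths differ")
  out <- unlist(per_channel, use.names = FALSE)
  attr(out, "d") <- d
  attr(out, "n_channels") <- length(channels)
  out
}

#' Stack per-subject inputs into a feature matrix
#'
#' @param input_list list of vectors from \code{\link{buildInputs}} (one
#'   per subject, identical layout).
#' @return subjects x features matrix with attributes \code{d} and
#'   \code{n_channels}.
#' @export
stackInputs <- function(input_list) {
  d <- attr(input_list[[1]], "d")
  nc <- attr(input_list[[1]], "n_channels")
  X <- do.call(rbind, lapply(input_list, as.numeric))
  attr(X, "d") <- d
  attr(X, "n_channels") <- nc
  X
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build a wide-and-deep regression network
#'
#' Layer sizes follow the ceiling formulas exactly: branch width
#' \code{h = ceiling(1.5 d)}, concatenation size \code{h * C'}, second
#' layer \code{ceiling(0.5 h C')}, one linear output neuron. The scalar
#' variant (the ablation fed by a raw scalar indicator) drops the
#' concatenation stage: a single input of size 1, \code{h = 2},
#' second layer of 1 unit. Both variants keep the wide linear shortcut
#' from the standardized inputs to the output. Hidden layers are
#' Glorot-initialized under the given seed; the output head (the deep
#' readout and the wide shortcut) starts at zero, so the untrained
#' network is the flat function and the fitted function is built up
#' entirely by training -- the wide linear path first, the deep
#' refinement after -- instead of correcting a large random initial
#' function that would persist on unseen subjects.
#'
#' @param d per-channel input feature length.
#' @param n_channels number of channels C'.
#' @param scalar_variant logical; build the ablated scalar-input model.
#' @param seed integer seed for parameter initialization.
#' @return an untrained \linkS4class{DRNModel}.
#' @examples
#' m <- buildDrn(d = 15, n_channels = 2)
#' c(m@h, m@h * m@n_channels, m@p)    # 23, 46, 23
#' @export
buildDrn <- function(d, n_channels, scalar_variant = FALSE, seed = 1) {
  if (scalar_variant) { d <- 1L; n_channels <- 1L }
  if (d < 1 || n_channels < 1) stop("d and n_channels must be >= 1")
  d <- as.integer(d); n_channels <- as.integer(n_channels)
  h <- as.integer(ceiling(1.5 * d))
  p <- if (scalar_variant) as.integer(ceiling(0.5 * h))
       else as.integer(ceiling(0.5 * h * n_channels))
  ct <- if (scalar_variant) h else h * n_channels
  params <- with_seed(seed, {
    pr <- list()
    for (c_i in seq_len(n_channels)) {
      pr[[paste0("W1_", c_i)]] <- .glorot(d, h)
      pr[[paste0("b1_", c_i)]] <- numeric(h)
    }
    pr$W2 <- .glorot(ct, p)
    pr$b2 <- numeric(p)
    pr$w3 <- matrix(0, p, 1)
    pr$b3 <- 0
    pr$wwide <- matrix(0, d * n_channels, 1)
    pr
  })
  new("DRNModel", d = d, n_channels = n_channels, h = h, p = p,
      scalar_variant = scalar_variant, params = params,
      scaling = list(), trained = FALSE,
      config = list(seed = seed), history = numeric(0))
}

# forward pass; returns prediction and intermediates for backprop
.drn_forward <- function(model, X) {
  pr <- model@params
  d <- model@d; nc <- model@n_channels
  H <- vector("list", nc)
  for (c_i in seq_len(nc)) {
    cols <- ((c_i - 1) * d + 1):(c_i * d)
    A <- X[, cols, drop = FALSE] %*% pr[[paste0("W1_", c_i)]]
    A <- sweep(A, 2, pr[[paste0("b1_", c_i)]], `+`)
    H[[c_i]] <- tanh(A)
  }
  CT <- do.call(cbind, H)
  Z <- tanh(sweep(CT %*% pr$W2, 2, pr$b2, `+`))
  yhat <- as.numeric(Z %*% pr$w3 + X %*% pr$wwide + pr$b3)
  list(yhat = yhat, H = H, CT = CT, Z = Z)
}

# gradient of MAE + elastic net wrt all parameters
.drn_grad <- function(model, X, y, fwd, l1, l2) {
  pr <- model@params
  d <- model@d; nc <- model@n_channels
  M <- length(y)
  g <- sign(fwd$yhat - y) / M
  gr <- list()
  gr$wwide <- crossprod(X, g)
  gr$w3 <- crossprod(fwd$Z, g)
  gr$b3 <- sum(g)
  dZ <- matrix(g, ncol = 1) %*% t(pr$w3)   # M x p
  dA2 <- dZ * (1 - fwd$Z^2)
  gr$W2 <- crossprod(fwd$CT, dA2)
  gr$b2 <- colSums(dA2)
  dCT <- dA2 %*% t(pr$W2)
  h <- model@h
  for (c_i in seq_len(nc)) {
    hcols <- ((c_i - 1) * h + 1):(c_i * h)
    xcols <- ((c_i - 1) * d + 1):(c_i * d)
    dA1 <- dCT[, hcols, drop = FALSE] * (1 - fwd$H[[c_i]]^2)
    gr[[paste0("W1_", c_i)]] <- crossprod(X[, xcols, drop = FALSE], dA1)
    gr[[paste0("b1_", c_i)]] <- colSums(dA1)
  }
  # elastic net on weights only (biases free)
  for (nm in names(pr)) {
    if (grepl("^b", nm)) next
    gr[[nm]] <- gr[[nm]] + l1 * sign(pr[[nm]]) + 2 * l2 * pr[[nm]]
  }
  gr
}

.drn_penalty <- function(params, l1, l2) {
  s <- 0
  for (nm in names(params)) {
    if (grepl("^b", nm)) next
    s <- s + l1 * sum(abs(params[[nm]])) + l2 * sum(params[[nm]]^2)
  }
  s
}

#' Train a DRN
#'
#' Adam on the mean absolute error plus an elastic-net penalty (l1 and
#' l2 coefficients both 1e-3 by default) over all weights, learning
#' rate 1e-3. Training uses small shuffled mini-batches (default 10
#' subjects); the batch-to-batch gradient noise makes Adam's
#' second-moment normalization damp coordinates whose gradients flip
#' sign across batches, which strongly favors the reproducible
#' between-subject signal over per-subject noise. Set
#' \code{batch_size = NULL} for full-batch training. Inputs are
#' standardized per dimension using the training set's statistics
#' (stored in the model for later prediction). Training runs for at
#' most \code{epochs} epochs and stops early when the epoch loss has
#' not improved by more than \code{tol} for \code{patience} consecutive
#' epochs. Deterministic given the model's initialization seed (batch
#' shuffling is seeded from it).
#'
#' @param model an untrained (or re-trainable) \linkS4class{DRNModel}.
#' @param X subjects x features matrix (see \code{\link{stackInputs}});
#'   for the scalar variant a one-column matrix or plain vector.
#' @param y per-subject regression targets.
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param l1,l2 elastic-net coefficients.
#' @param batch_size mini-batch size (\code{NULL} for full batch).
#' @param tol,patience plateau early-stopping rule on the epoch loss.
#' @return the trained \linkS4class{DRNModel} (loss history in
#'   \code{@history}).
#' @export
trainDrn <- function(model, X, y, epochs = 2000, lr = 1e-3,
                     l1 = 1e-3, l2 = 1e-3, batch_size = 10,
                     tol = 1e-5, patience = 100) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (nrow(X) != length(y)) stop("one target per subject required")
  if (length(y) < 3) stop("need at least 3 subjects to train")
  if (ncol(X) != model@d * model@n_channels)
    stop("feature width does not match the model architecture")
  M <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  pr <- model@params
  m_state <- lapply(pr, function(p) p * 0)
  v_state <- lapply(pr, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(epochs)
  best <- Inf; wait <- 0; t_adam <- 0
  seed <- if (is.null(model@config$seed)) 1L else model@config$seed
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      batches <- if (is.null(batch_size) || batch_size >= M)
        list(seq_len(M))
      else split(sample.int(M), ceiling(seq_len(M) / batch_size))
      ep_loss <- 0
      for (b in batches) {
        t_adam <- t_adam + 1
        model@params <- pr
        fwd <- .drn_forward(model, Xs[b, , drop = FALSE])
        loss <- mean(abs(fwd$yhat - y[b])) + .drn_penalty(pr, l1, l2)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep,
               " (last finite epoch loss: ",
               if (ep > 1) signif(history[ep - 1], 6) else "none", ")")
        ep_loss <- ep_loss + loss * length(b)
        gr <- .drn_grad(model, Xs[b, , drop = FALSE], y[b], fwd, l1, l2)
        for (nm in names(pr)) {
          m_state[[nm]] <- b1 * m_state[[nm]] + (1 - b1) * gr[[nm]]
          v_state[[nm]] <- b2 * v_state[[nm]] + (1 - b2) * gr[[nm]]^2
          mhat <- m_state[[nm]] / (1 - b1^t_adam)
          vhat <- v_state[[nm]] / (1 - b2^t_adam)
          pr[[nm]] <- pr[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      history[ep] <- ep_loss / M
      if (history[ep] < best - tol) { best <- history[ep]; wait <- 0 }
      else wait <- wait + 1
      if (wait >= patience) { history <- history[seq_len(ep)]; break }
    }
  })
  model@params <- pr
  model@scaling <- list(center = ctr, scale = scl)
  model@trained <- TRUE
  model@config <- utils::modifyList(model@config,
    list(epochs = epochs, lr = lr, l1 = l1, l2 = l2,
         batch_size = batch_size, tol = tol, patience = patience))
  model@history <- history
  model
}

#' Extract the data-driven subject indicator
#'
#' The network's scalar output per subject -- the extracted indicator
#' that is correlated with (and predicts) the accuracy response.
#'
#' @param model a trained \linkS4class{DRNModel}.
#' @param X feature matrix (same layout as in training).
#' @return numeric vector, one indicator value per subject.
#' @export
extractXiStar <- function(model, X) {
  if (!model@trained) stop("model is untrained")
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  Xs <- sweep(sweep(X, 2, model@scaling$center), 2,
              model@scaling$scale, `/`)
  .drn_forward(model, Xs)$yhat
}

#' Map accuracy vectors to scalar regression targets
#'
#' Reduces each subject's accuracy vector across window lengths to a
#' single response: either the inverse-variance weighted mean (weights
#' proportional to 1 over the across-subject variance of the accuracy at
#' each window length, normalized to sum 1; optionally 1 over the
#' subject's own CV variance per cell) or the first
#' principal-component score of the centered accuracy matrix,
#' sign-aligned to correlate positively with the plain mean.
#'
#' @param V subjects x window-lengths accuracy matrix.
#' @param mode \code{"mean"} or \code{"PCA1"}.
#' @param weighting \code{"across"} (across-subject inverse variance,
#'   default) or \code{"cv"} (per-subject CV-variance weights).
#' @param cv_disp subjects x window-lengths CV standard deviations,
#'   required for \code{weighting = "cv"}.
#' @return numeric vector of per-subject targets.
#' @export
psiMap <- function(V, mode = c("mean", "PCA1"),
                   weighting = c("across", "cv"), cv_disp = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  V <- as.matrix(V)
  if (mode == "mean") {
    if (weighting == "cv") {
      if (is.null(cv_disp)) stop("cv weighting needs cv_disp")
      w <- 1 / pmax(cv_disp^2, 1e-12)
      return(rowSums(V * w) / rowSums(w))
    }
    v <- apply(V, 2, stats::var)
    if (all(v == 0)) {
      warning("zero across-subject variance at every window length; ",
              "falling back to the unweighted mean")
      return(rowMeans(V))
    }
    w <- 1 / pmax(v, 1e-12)
    w <- w / sum(w)
    return(as.numeric(V %*% w))
  }
  if (nrow(V) < 3) stop("PCA1 needs at least 3 subjects")
  pc <- stats::prcomp(V, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  if (stats::cor(score, rowMeans(V)) < 0) score <- -score
  as.numeric(score)
}

#' Spearman evaluation of an indicator
#'
#' Rank correlation between per-subject indicator values and the
#' response, with average ranks for ties. A constant indicator yields an
#' undefined correlation, returned as \code{NA} with a diagnostic flag.
#'
#' @param xi per-subject indicator values.
#' @param targets per-subject responses.
#' @param mode evaluation label stored in the result.
#' @return a \linkS4class{RegressionResult}.
#' @export
evaluateIndicator <- function(xi, targets, mode = "in-sample") {
  if (length(xi) != length(targets)) stop("length mismatch")
  if (length(xi) < 3) stop("need at least 3 subjects")
  flagged <- stats::sd(xi) == 0 || stats::sd(targets) == 0
  r <- if (flagged) NA_real_
       else stats::cor(xi, targets, method = "spearman")
  new("RegressionResult", xi_star = as.numeric(xi),
      targets = as.numeric(targets), spearman = r, mode = mode,
      diagnostics = list(constant_input = flagged))
}

#' Linear-correlation baseline
#'
#' The LC comparator: Spearman correlation of a raw scalar indicator
#' (xi1 or xi2) against the response, with no network in between.
#'
#' @param xi_scalar per-subject scalar indicator values.
#' @param targets per-subject responses.
#' @return a \linkS4class{RegressionResult} with mode \code{"linear"}.
#' @export
linearBaseline <- function(xi_scalar, targets) {
  evaluateIndicator(xi_scalar, targets, mode = "linear")
}

#' In-sample DRN evaluation
#'
#' Builds, trains and evaluates a DRN on the full cohort; the extracted
#' indicator is correlated with the targets in-sample.
#'
#' @param X feature matrix (or vector for the scalar variant).
#' @param targets per-subject responses.
#' @param scalar_variant logical.
#' @param seed initialization seed.
#' @param ... passed to \code{\link{trainDrn}}.
#' @return a \linkS4class{RegressionResult} (the trained model in
#'   \code{diagnostics$model}).
#' @export
drnEvaluate <- function(X, targets, scalar_variant = FALSE, seed = 1, ...) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  d <- attr(X, "d"); nc <- attr(X, "n_channels")
  if (is.null(d)) { d <- ncol(X); nc <- 1L }
  model <- buildDrn(d, nc, scalar_variant = scalar_variant, seed = seed)
  model <- trainDrn(model, X, targets, ...)
  res <- evaluateIndicator(extractXiStar(model, X), targets,
                           mode = "in-sample")
  res@diagnostics$model <- model
  res
}

#' Leave-one-out DRN evaluation
#'
#' For each subject, a fresh network is trained on the remaining
#' subjects (standardization statistics from the training subjects only)
#' and the held-out subject's indicator is predicted; the Spearman
#' correlation is computed over the held-out predictions. One model fit
#' per subject.
#'
#' @param X feature matrix (or vector for the scalar variant).
#' @param targets per-subject responses.
#' @param scalar_variant logical.
#' @param seed base seed (each fold derives its own).
#' @param ... passed to \code{\link{trainDrn}}.
#' @return a \linkS4class{RegressionResult} with mode \code{"LOO"}.
#' @export
looEvaluate <- function(X, targets, scalar_variant = FALSE, seed = 1, ...) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  M <- nrow(X)
  if (M < 4) stop("leave-one-out needs at least 4 subjects")
  d <- attr(X, "d"); nc <- attr(X, "n_channels")
  if (is.null(d)) { d <- ncol(X); nc <- 1L }
  preds <- numeric(M)
  for (m in seq_len(M)) {
    model <- buildDrn(d, nc, scalar_variant = scalar_variant,
                      seed = seed + m)
    model <- trainDrn(model, X[-m, , drop = FALSE], targets[-m], ...)
    preds[m] <- extractXiStar(model, X[m, , drop = FALSE])
  }
  res <- evaluateIndicator(preds, targets, mode = "LOO")
  res@diagnostics$n_fits <- M
  res
}
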