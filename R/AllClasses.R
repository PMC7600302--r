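#' @import methods
#' @importFrom stats approx cor kmeans median p.adjust prcomp qnorm quantile
#'   rnorm runif sd setNames var wilcox.test fft
NULL

#' Electrode montage
#'
#' A set of scalp electrodes with 2-D layout coordinates and a symmetric
#' neighbor map used by the surface Laplacian. Coordinates live on an
#' arbitrary planar grid; adjacency is what matters.
#'
#' @slot channels character vector of unique electrode labels.
#' @slot coords numeric matrix (channels x 2) of planar positions, rows
#'   named by channel.
#' @slot adjacency named list mapping each channel to its neighbor labels.
#' @export
setClass("Montage", representation(
  channels = "character",
  coords = "matrix",
  adjacency = "list"
))

setValidity("Montage", function(object) {
  msg <- character()
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@coords) != length(object@channels))
    msg <- c(msg, "coords must have one row per channel")
  if (!setequal(names(object@adjacency), object@channels))
    msg <- c(msg, "adjacency names must match channels")
  # adjacency must be symmetric
  for (ch in names(object@adjacency)) {
    for (nb in object@adjacency[[ch]]) {
      if (!nb %in% object@channels) {
        msg <- c(msg, sprintf("neighbor '%s' of '%s' is not a channel", nb, ch))
      } else if (!ch %in% object@adjacency[[nb]]) {
        msg <- c(msg, sprintf("adjacency not symmetric: %s->%s", ch, nb))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Continuous EEG recording
#'
#' A single multichannel record (channels x samples), e.g. a resting-state
#' measurement, with its sampling rate and channel labels.
#'
#' @slot samples numeric matrix, channels x time (microvolt scale,
#'   arbitrary units for synthetic data).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels, one per row.
#' @export
setClass("EEGRecording", representation(
  samples = "matrix",
  fs = "numeric",
  channels = "character"
))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) != length(object@channels))
    msg <- c(msg, "one channel label per sample row required")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Trial timing of the motor-imagery paradigm
#'
#' Timing of one trial: a fixation/baseline interval, the cue onset, the
#' motor-imagery interval and the total trial length, all in seconds from
#' trial start. Defaults follow the standard cue-paced paradigm: baseline
#' 0--2 s, cue at 2 s, MI interval 2.6--4.6 s, 7 s trials.
#'
#' @slot baseline numeric length-2, the baseline (fixation) interval.
#' @slot cue_onset_s cue onset time.
#' @slot mi numeric length-2, the motor-imagery interval.
#' @slot trial_length_s total trial duration.
#' @export
setClass("TrialTiming", representation(
  baseline = "numeric",
  cue_onset_s = "numeric",
  mi = "numeric",
  trial_length_s = "numeric"
))

setValidity("TrialTiming", function(object) {
  msg <- character()
  ok_iv <- function(iv) length(iv) == 2 && iv[1] < iv[2]
  if (!ok_iv(object@baseline) || !ok_iv(object@mi))
    msg <- c(msg, "baseline and mi must be increasing length-2 intervals")
  else {
    if (object@baseline[1] < 0 || object@mi[2] > object@trial_length_s)
      msg <- c(msg, "intervals must nest inside [0, trial_length_s]")
    if (object@mi[1] < object@cue_onset_s)
      msg <- c(msg, "MI interval must start after the cue onset")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled motor-imagery trial set
#'
#' The unit of all per-subject computation: an n_trials x channels x time
#' array of EEG trials with left/right-hand labels, sampling rate, trial
#' timing and the montage the channels come from.
#'
#' @slot trials numeric array, trials x channels x samples.
#' @slot labels factor with levels \code{"left"} and \code{"right"}.
#' @slot fs sampling rate in Hz.
#' @slot timing a \linkS4class{TrialTiming}.
#' @slot montage a \linkS4class{Montage}.
#' @export
setClass("TrialSet", representation(
  trials = "array",
  labels = "factor",
  fs = "numeric",
  timing = "TrialTiming",
  montage = "Montage"
))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@trials)
  if (length(d) != 3)
    msg <- c(msg, "trials must be a 3-d array (trials x channels x samples)")
  else {
    if (d[1] != length(object@labels))
      msg <- c(msg, "one label per trial required")
    cn <- dimnames(object@trials)[[2]]
    if (is.null(cn))
      msg <- c(msg, "trial array needs channel dimnames")
    else if (!all(cn %in% object@montage@channels))
      msg <- c(msg, "trial channels must exist in the montage")
  }
  if (!identical(levels(object@labels), c("left", "right")))
    msg <- c(msg, "labels must be a factor with levels left/right")
  if (length(msg)) msg else TRUE
})

#' Power spectral density estimate
#'
#' One channel's Welch PSD: a strictly increasing frequency grid and
#' nonnegative power densities, with estimation metadata.
#'
#' @slot freq frequency grid in Hz.
#' @slot power spectral density at each frequency (power per Hz).
#' @slot channel channel label.
#' @slot meta list with window length, overlap and sampling rate.
#' @export
setClass("PSDEstimate", representation(
  freq = "numeric",
  power = "numeric",
  channel = "character",
  meta = "list"
))

setValidity("PSDEstimate", function(object) {
  msg <- character()
  if (length(object@freq) != length(object@power))
    msg <- c(msg, "freq and power must have equal length")
  if (any(diff(object@freq) <= 0))
    msg <- c(msg, "freq must be strictly increasing")
  if (any(object@power < 0))
    msg <- c(msg, "power must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Fitted spectral-peak model
#'
#' Parameters of the two-Gaussian-plus-hyperbolic-noise decomposition of a
#' 4--40 Hz power spectrum: for each sensorimotor rhythm a Gaussian peak
#' (weight, center, width) and the aperiodic noise floor
#' \eqn{\epsilon(f) = \kappa_1 + \kappa_2 / f^\eta}.
#'
#' @slot peaks numeric matrix 2 x 3 (rows mu, beta; columns k, m, sigma).
#' @slot noise named numeric: kappa1, kappa2, eta.
#' @slot residual l2 norm of the misfit on the fitting grid.
#' @slot converged logical convergence flag (any multistart converged).
#' @export
setClass("PSDFitModel", representation(
  peaks = "matrix",
  noise = "numeric",
  residual = "numeric",
  converged = "logical"
))

setValidity("PSDFitModel", function(object) {
  msg <- character()
  if (!identical(dim(object@peaks), c(2L, 3L)))
    msg <- c(msg, "peaks must be 2 x 3 (mu/beta x k,m,sigma)")
  if (object@residual < 0) msg <- c(msg, "residual must be >= 0")
  if (any(object@peaks[, "k"] < 0) || any(object@noise < 0))
    msg <- c(msg, "weights and noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ERD/ERS relative-power time course
#'
#' Per-sample relative band power of one channel, band and class:
#' \eqn{\hat\zeta_t = (\zeta_t - \bar\zeta)/\bar\zeta} where
#' \eqn{\zeta_t} is the trial-averaged squared sample and \eqn{\bar\zeta}
#' its mean over the reference interval. Negative values are event-related
#' desynchronization, positive values synchronization.
#'
#' @slot zhat unmasked relative-power series.
#' @slot zhat_masked series with z-score-nonsignificant samples set to 0.
#' @slot time sample times in seconds from trial start.
#' @slot band band name, \code{"mu"} or \code{"beta"}.
#' @slot channel channel label.
#' @slot class_label trial class the curve belongs to.
#' @slot ref_interval reference interval (seconds).
#' @slot ref_power mean reference power \eqn{\bar\zeta}.
#' @export
setClass("ERDSTimeCourse", representation(
  zhat = "numeric",
  zhat_masked = "numeric",
  time = "numeric",
  band = "character",
  channel = "character",
  class_label = "character",
  ref_interval = "numeric",
  ref_power = "numeric"
))

setValidity("ERDSTimeCourse", function(object) {
  msg <- character()
  if (length(object@zhat) != length(object@time))
    msg <- c(msg, "zhat and time must align")
  if (object@ref_power <= 0)
    msg <- c(msg, "reference power must be positive")
  if (any(object@zhat < -1 - 1e-9))
    msg <- c(msg, "relative power cannot fall below -1")
  if (length(msg)) msg else TRUE
})

#' Common spatial patterns model
#'
#' Spatial filters maximizing the variance ratio between the two classes,
#' obtained from the generalized eigendecomposition of the shrunk class
#' covariances. The filters jointly diagonalize the class covariances and
#' whiten their sum.
#'
#' @slot filters filter matrix, selected filters x channels (rows are
#'   spatial filters).
#' @slot eigenvalues generalized eigenvalues (class-l variance share) of
#'   the selected filters.
#' @slot n_per_class filters retained per class.
#' @slot shrinkage covariance shrinkage level used.
#' @slot channels channel labels the filters apply to.
#' @export
setClass("CSPModel", representation(
  filters = "matrix",
  eigenvalues = "numeric",
  n_per_class = "integer",
  shrinkage = "numeric",
  channels = "character"
))

#' Wide-and-deep regression network
#'
#' The joint indicator-extraction / regression model: per-channel dense
#' branches with tanh activation, a concatenation stage, a second dense
#' tanh layer, a one-neuron linear output, and a wide linear shortcut from
#' the standardized input features to the output. The scalar variant drops
#' the concatenation stage and takes a single scalar input per subject.
#'
#' @slot d per-channel input feature length.
#' @slot n_channels number of per-channel branches (C').
#' @slot h branch width, \code{ceiling(1.5 * d)}.
#' @slot p second-layer width, \code{ceiling(0.5 * h * n_channels)}.
#' @slot scalar_variant logical flag for the ablated scalar-input model.
#' @slot params list of weight matrices and bias vectors.
#' @slot scaling list of per-dimension center/scale used to standardize
#'   inputs (set at training time).
#' @slot trained logical.
#' @slot config list of training hyperparameters.
#' @slot history numeric vector of per-epoch loss (set at training time).
#' @export
setClass("DRNModel", representation(
  d = "integer",
  n_channels = "integer",
  h = "integer",
  p = "integer",
  scalar_variant = "logical",
  params = "list",
  scaling = "list",
  trained = "logical",
  config = "list",
  history = "numeric"
))

setValidity("DRNModel", function(object) {
  msg <- character()
  if (object@h != ceiling(1.5 * object@d))
    msg <- c(msg, "branch width must equal ceiling(1.5 * d)")
  p_expect <- if (object@scalar_variant) ceiling(0.5 * object@h)
              else ceiling(0.5 * object@h * object@n_channels)
  if (object@p != p_expect)
    msg <- c(msg, "second-layer width violates the ceiling formula")
  if (length(msg)) msg else TRUE
})

#' Per-subject accuracy response
#'
#' CSP/LDA cross-validated accuracy of one subject at each sliding-window
#' length delta-tau, plus the time-varying accuracy over window positions.
#'
#' @slot summary named numeric, max-over-window-positions accuracy per
#'   delta-tau.
#' @slot summary_mean named numeric, mean-over-positions accuracy (stored
#'   for sensitivity).
#' @slot dispersion named numeric, CV standard deviation at the maximizing
#'   window per delta-tau.
#' @slot curves list per delta-tau of data.frames (window start, accuracy).
#' @export
setClass("AccuracyResponse", representation(
  summary = "numeric",
  summary_mean = "numeric",
  dispersion = "numeric",
  curves = "list"
))

setValidity("AccuracyResponse", function(object) {
  msg <- character()
  if (any(object@summary < 0 | object@summary > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Regression evaluation result
#'
#' Spearman evaluation of an indicator (scalar or network-extracted)
#' against a response, in-sample or leave-one-out.
#'
#' @slot xi_star per-subject indicator values (network output or raw
#'   scalar).
#' @slot targets per-subject response values.
#' @slot spearman Spearman rank correlation (NA and flagged when the
#'   indicator is constant).
#' @slot mode one of \code{"in-sample"}, \code{"LOO"}, \code{"linear"}.
#' @slot diagnostics list (training histories, flags).
#' @export
setClass("RegressionResult", representation(
  xi_star = "numeric",
  targets = "numeric",
  spearman = "numeric",
  mode = "character",
  diagnostics = "list"
))

#' Subject clustering result
#'
#' k-means partition of subjects by their accuracy profiles, with the
#' silhouette-selected number of groups, groups relabeled I, II, III by
#' decreasing mean accuracy, and an optional outlier group IV.
#'
#' @slot groups factor of group labels per subject.
#' @slot base_groups factor of the pre-outlier labels (equal to
#'   \code{groups} until \code{flagOutliers} is applied).
#' @slot k chosen number of clusters.
#' @slot silhouette named numeric, mean silhouette per candidate k.
#' @slot inertia named numeric, total within-cluster sum of squares per
#'   candidate k (elbow diagnostic).
#' @slot provenance character description of the inputs.
#' @export
setClass("ClusterResult", representation(
  groups = "factor",
  base_groups = "factor",
  k = "integer",
  silhouette = "numeric",
  inertia = "numeric",
  provenance = "character"
))
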