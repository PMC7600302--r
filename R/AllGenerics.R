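#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("trialArray", function(x) standardGeneric("trialArray"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("trialTiming", function(x) standardGeneric("trialTiming"))

#' Accessors for EEG containers
#'
#' Slot accessors for \linkS4class{EEGRecording} and
#' \linkS4class{TrialSet}: sampling rate, channel labels, the trial
#' array, trial labels, trial count and timing.
#'
#' @param x an \linkS4class{EEGRecording} or \linkS4class{TrialSet}.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases samplingRate channelNames trialArray trialLabels nTrials
#'   trialTiming
NULL

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "TrialSet", function(x) dimnames(x@trials)[[2]])
#' @rdname accessors
#' @export
setMethod("channelNames", "Montage", function(x) x@channels)
#' @rdname accessors
#' @export
setMethod("trialArray", "TrialSet", function(x) x@trials)
#' @rdname accessors
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@trials)[1])
#' @rdname accessors
#' @export
setMethod("trialTiming", "TrialSet", function(x) x@timing)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channel(s) x %d samples (%.1f s at %g Hz)\n",
              nrow(object@samples), ncol(object@samples),
              ncol(object@samples) / object@fs, object@fs))
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@trials)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples at %g Hz\n",
              d[1], d[2], d[3], object@fs))
  tb <- table(object@labels)
  cat(sprintf("  labels: left=%d right=%d\n", tb[["left"]], tb[["right"]]))
  cat(sprintf("  timing: baseline [%g, %g] s, MI [%g, %g] s, trial %g s\n",
              object@timing@baseline[1], object@timing@baseline[2],
              object@timing@mi[1], object@timing@mi[2],
              object@timing@trial_length_s))
})

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage: %d channels (%s)\n", length(object@channels),
              paste(object@channels, collapse = ", ")))
})

setMethod("show", "PSDFitModel", function(object) {
  cat("PSDFitModel (two Gaussian peaks + hyperbolic noise)\n")
  cat(sprintf("  mu:   k=%.3f m=%.2f Hz sigma=%.2f Hz\n",
              object@peaks["mu", "k"], object@peaks["mu", "m"],
              object@peaks["mu", "sigma"]))
  cat(sprintf("  beta: k=%.3f m=%.2f Hz sigma=%.2f Hz\n",
              object@peaks["beta", "k"], object@peaks["beta", "m"],
              object@peaks["beta", "sigma"]))
  cat(sprintf("  noise: kappa1=%.3f kappa2=%.3f eta=%.2f | residual %.4g%s\n",
              object@noise["kappa1"], object@noise["kappa2"],
              object@noise["eta"], object@residual,
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "DRNModel", function(object) {
  cat(sprintf("DRNModel (%s): d=%d, C'=%d, h=%d, theta2=%d, theta3=1%s\n",
              if (object@scalar_variant) "scalar variant" else "wide & deep",
              object@d, object@n_channels, object@h, object@p,
              if (object@trained) " [trained]" else " [untrained]"))
})

setMethod("show", "AccuracyResponse", function(object) {
  cat("AccuracyResponse (max over window positions):\n")
  print(round(object@summary, 3))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult [%s]: Spearman r = %s over %d subjects\n",
              object@mode,
              ifelse(is.na(object@spearman), "NA (constant input)",
                     sprintf("%.3f", object@spearman)),
              length(object@xi_star)))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k=%d, groups: %s\n", object@k,
              paste(sprintf("%s=%d", levels(object@groups),
                            tabulate(object@groups, nbins = nlevels(object@groups))),
                    collapse = " ")))
})
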