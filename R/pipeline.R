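# End-to-end pipeline: simulate (or load) a cohort, preprocess,
# compute indicators, the accuracy response, the regression comparison
# (linear baseline, scalar-variant DRN, full DRN, optional LOO) and the
# subject clustering, persisting tidy CSV tables and a JSON manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable field:
#' cohort size and seed, sampling rate, trials per class, channel
#' configuration, window lengths, bands, DRN hyperparameters and output
#' directory. Override any field via \code{...}.
#'
#' @param ... named overrides of the default fields.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    n_subjects = 12,
    seed = 1,
    fs = 160,
    n_trials = 20,                  # per class
    config = "2Ch",
    delta_taus = c(0.5, 1.0, 1.5, 2.0),
    bands = c("mu", "beta"),
    source = "resting",             # DRN input source
    resting_duration_s = 20,
    psi_modes = c("mean", "PCA1"),
    cv_reps = 3,
    cv_folds = 10,
    drn_epochs = 600,
    drn_lr = 1e-3,
    drn_l1 = 1e-3,
    drn_l2 = 1e-3,
    run_loo = FALSE,
    outlier_threshold = 2.0,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

.write_csv <- function(df, dir, name) {
  if (!is.null(dir))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  df
}

#' Run the full analysis pipeline
#'
#' Simulates a seeded cohort, preprocesses it (4--40 Hz band-pass,
#' surface Laplacian, resting trim), computes the pre-training (xi1) and
#' initial-training (xi2) indicators, the CSP/LDA accuracy response at
#' every window length, the regression comparison (linear baseline,
#' scalar-variant DRN, full DRN; optional leave-one-out), the psi
#' response mappings and the subject clustering with outlier flagging
#' (when LOO is enabled). All stages are deterministic given the
#' manifest. When \code{out_dir} is set, indicator/response tables, the
#' regression table, the cluster assignments and a JSON run manifest are
#' written there.
#'
#' @param cfg configuration list from \code{\link{pipelineConfig}}.
#' @return list with the cohort, indicator and response tables, the
#'   regression table, the cluster result and the manifest.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  if (!cfg$config %in% c("2Ch", "6Ch"))
    stop("config must be 2Ch or 6Ch")
  channels <- channelConfig(cfg$config)
  montage <- sensorimotorMontage()
  if (!all(channels %in% montage@channels))
    stop("channel configuration not covered by the montage")
  dir <- cfg$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- makeCohort(cfg$n_subjects, cfg$seed)
  M <- nrow(cohort)

  indicator_rows <- list()
  resp_summary <- matrix(NA_real_, M, length(cfg$delta_taus))
  resp_disp <- matrix(NA_real_, M, length(cfg$delta_taus))
  curve_rows <- list()
  inputs <- vector("list", M)
  xi1_vals <- numeric(M)
  xi2_vals <- numeric(M)

  for (m in seq_len(M)) {
    prof <- cohort[m, ]
    ts <- simulateTrialSet(prof, n_trials = cfg$n_trials, fs = cfg$fs,
                           montage = montage)
    ts_pp <- laplacianFilter(bandpassFilter(ts, 4, 40))
    rest <- simulateResting(prof, fs = cfg$fs,
                            duration_s = cfg$resting_duration_s,
                            montage = montage)
    rest_pp <- trimResting(
      laplacianFilter(bandpassFilter(rest, 4, 40), montage), 5)

    x1 <- computeXi1(rest_pp, channels = channels)$xi1
    x2 <- computeXi2(ts_pp, bands = cfg$bands, channels = channels)$xi2
    xi1_vals[m] <- x1
    xi2_vals[m] <- x2
    indicator_rows[[m]] <- data.frame(
      subject = m,
      xi1_resting = x1, xi2 = x2,
      config = cfg$config,
      bands = paste(cfg$bands, collapse = "+"))

    ar <- accuracyResponse(ts, config = cfg$config,
                           delta_taus = cfg$delta_taus,
                           n_rep = cfg$cv_reps, n_folds = cfg$cv_folds,
                           seed = cfg$seed + m)
    resp_summary[m, ] <- ar@summary
    resp_disp[m, ] <- ar@dispersion
    for (dt in names(ar@curves)) {
      cv <- ar@curves[[dt]]
      curve_rows[[paste(m, dt)]] <- data.frame(
        subject = m, delta_tau = as.numeric(dt),
        window_start = cv$window_start, accuracy = cv$accuracy)
    }

    inputs[[m]] <- switch(cfg$source,
      baseline = buildInputs(trials = ts_pp, source = "baseline",
                             channels = channels),
      resting = buildInputs(resting = rest_pp, source = "resting",
                            channels = channels),
      erds = buildInputs(trials = ts_pp, source = "erds",
                         channels = channels, bands = cfg$bands),
      stop("unknown source: ", cfg$source))
  }
  colnames(resp_summary) <- format(cfg$delta_taus)
  X <- stackInputs(inputs)

  # regression targets: each delta-tau column plus the psi mappings
  targets <- as.data.frame(resp_summary)
  for (pm in cfg$psi_modes)
    targets[[pm]] <- psiMap(resp_summary, mode = pm)

  reg_rows <- list()
  loo_results <- list()
  for (tn in names(targets)) {
    y <- targets[[tn]]
    lc1 <- linearBaseline(xi1_vals, y)
    lc2 <- linearBaseline(xi2_vals, y)
    sd1 <- drnEvaluate(xi1_vals, y, scalar_variant = TRUE,
                       seed = cfg$seed, epochs = cfg$drn_epochs,
                       lr = cfg$drn_lr, l1 = cfg$drn_l1, l2 = cfg$drn_l2)
    full <- drnEvaluate(X, y, seed = cfg$seed, epochs = cfg$drn_epochs,
                        lr = cfg$drn_lr, l1 = cfg$drn_l1, l2 = cfg$drn_l2)
    row <- data.frame(target = tn,
                      lc_xi1 = lc1@spearman, lc_xi2 = lc2@spearman,
                      drn_scalar_xi1 = sd1@spearman,
                      drn_full = full@spearman)
    if (isTRUE(cfg$run_loo)) {
      loo <- looEvaluate(X, y, seed = cfg$seed, epochs = cfg$drn_epochs,
                         lr = cfg$drn_lr, l1 = cfg$drn_l1,
                         l2 = cfg$drn_l2)
      row$drn_full_loo <- loo@spearman
      loo_results[[tn]] <- loo
    }
    reg_rows[[tn]] <- row
  }

  cl <- clusterSubjects(resp_summary, seed = cfg$seed)
  if (length(loo_results))
    cl <- flagOutliers(cl, loo_results[[1]], cfg$outlier_threshold)

  indicators <- do.call(rbind, indicator_rows)
  responses <- data.frame(subject = seq_len(M), resp_summary,
                          check.names = FALSE)
  curves <- do.call(rbind, curve_rows)
  regression <- do.call(rbind, reg_rows)
  assignments <- data.frame(subject = seq_len(M),
                            group = as.character(cl@groups))
  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   package_version = as.character(
                     utils::packageVersion("bciability")),
                   n_subjects = M)

  .write_csv(indicators, dir, "indicators.csv")
  .write_csv(responses, dir, "responses.csv")
  .write_csv(curves, dir, "accuracy_curves.csv")
  .write_csv(regression, dir, "regression.csv")
  .write_csv(assignments, dir, "cluster_assignments.csv")
  if (!is.null(dir))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  list(cohort = cohort, indicators = indicators, responses = responses,
       curves = curves, regression = regression, clusters = cl,
       loo = loo_results, manifest = manifest)
}
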