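# Clustering of subjects into efficiency groups from their accuracy
# profiles across window lengths, selection of the group number by
# silhouette, flagging of the non-predictable outlier group, and
# comparison of assignments between runs.

.roman_labels <- c("I", "II", "III", "IV", "V", "VI")

#' Cluster subjects by accuracy profile
#'
#' Seeded k-means (multiple restarts, best inertia kept) over the
#' subjects x window-lengths accuracy matrix for each candidate group
#' number; the chosen k maximizes the mean silhouette width, with the
#' inertia (total within-cluster sum of squares) curve reported as the
#' elbow diagnostic. Groups are relabeled I, II, III, ... by decreasing
#' group-mean accuracy, so group I always holds the best performers.
#' If all subjects are identical the silhouette is undefined and the
#' result falls back to a single group with a warning.
#'
#' @param accuracy_matrix subjects x window-lengths accuracy matrix
#'   (one row per subject, e.g. the four delta-tau summaries).
#' @param k_candidates candidate group numbers (default 2..6).
#' @param seed integer seed for the k-means restarts.
#' @param n_restarts random restarts per candidate k.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterSubjects <- function(accuracy_matrix, k_candidates = 2:6, seed = 1,
                            n_restarts = 10) {
  X <- as.matrix(accuracy_matrix)
  M <- nrow(X)
  if (M <= max(k_candidates))
    stop("need more subjects than the largest candidate k")
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("all subjects identical; silhouette undefined, using k = 1")
    g <- factor(rep("I", M), levels = "I")
    return(new("ClusterResult", groups = g, base_groups = g, k = 1L,
               silhouette = setNames(numeric(0), character(0)),
               inertia = setNames(numeric(0), character(0)),
               provenance = "accuracy profiles (degenerate)"))
  }
  n_distinct <- nrow(unique(X))
  k_candidates <- k_candidates[k_candidates <= n_distinct]
  if (length(k_candidates) == 0) {
    warning("not enough distinct accuracy profiles; using k = 1")
    g <- factor(rep("I", M), levels = "I")
    return(new("ClusterResult", groups = g, base_groups = g, k = 1L,
               silhouette = setNames(numeric(0), character(0)),
               inertia = setNames(numeric(0), character(0)),
               provenance = "accuracy profiles (degenerate)"))
  }
  sil <- setNames(numeric(length(k_candidates)), k_candidates)
  inert <- setNames(numeric(length(k_candidates)), k_candidates)
  fits <- vector("list", length(k_candidates))
  dmat <- stats::dist(X)
  with_seed(seed, {
    for (i in seq_along(k_candidates)) {
      k <- k_candidates[i]
      km <- stats::kmeans(X, centers = k, nstart = n_restarts,
                          iter.max = 50)
      fits[[i]] <- km
      inert[i] <- km$tot.withinss
      sw <- cluster::silhouette(km$cluster, dmat)
      sil[i] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
    }
  })
  best_i <- which.max(sil)
  km <- fits[[best_i]]
  k <- k_candidates[best_i]
  # relabel by decreasing group-mean accuracy
  means <- vapply(seq_len(k), function(g)
    mean(X[km$cluster == g, , drop = FALSE]), numeric(1))
  ord <- order(means, decreasing = TRUE)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  g <- factor(.roman_labels[relabel[km$cluster]],
              levels = .roman_labels[seq_len(k)])
  new("ClusterResult", groups = g, base_groups = g, k = as.integer(k),
      silhouette = sil, inertia = inert,
      provenance = "accuracy profiles")
}

#' Flag non-predictable subjects as group IV
#'
#' Subjects whose absolute leave-one-out residual exceeds
#' \code{threshold} times the median absolute residual are moved to the
#' outlier group IV -- the subjects for which the regression cannot
#' infer any predictive ability. The pre-outlier label is retained in
#' \code{base_groups}.
#'
#' @param cl a \linkS4class{ClusterResult}.
#' @param loo_result a \linkS4class{RegressionResult} with mode
#'   \code{"LOO"} (held-out predictions for every subject).
#' @param threshold residual multiple (default 2); \code{Inf} leaves the
#'   clustering untouched.
#' @return the \linkS4class{ClusterResult} with group IV added.
#' @export
flagOutliers <- function(cl, loo_result, threshold = 2.0) {
  if (length(loo_result@xi_star) != length(cl@groups))
    stop("LOO predictions must cover every clustered subject")
  resid <- abs(loo_result@targets - loo_result@xi_star)
  med <- stats::median(resid)
  out <- resid > threshold * med
  out[!is.finite(out)] <- FALSE
  labs <- as.character(cl@groups)
  labs[out] <- "IV"
  lev <- c(.roman_labels[seq_len(max(cl@k, 3))], "IV")
  lev <- unique(lev)
  cl@base_groups <- cl@groups
  cl@groups <- factor(labs, levels = lev[lev %in% c(labs, levels(cl@groups))])
  cl
}

#' Assignment matrix across clustering runs
#'
#' Collates the group labels of several clustering results over the same
#' subjects (e.g. different indicator sources, or the trial-ablation
#' stability runs) and counts, for every pair of runs, how many subjects
#' exchange groups between them.
#'
#' @param results list of \linkS4class{ClusterResult} over the same
#'   subject set.
#' @param labels run names (default \code{run1}, \code{run2}, ...).
#' @return list with \code{assignments} (subjects x runs character
#'   matrix) and \code{exchanges} (symmetric runs x runs count matrix).
#' @export
assignmentMatrix <- function(results, labels = NULL) {
  if (is.null(labels)) labels <- paste0("run", seq_along(results))
  n <- unique(vapply(results, function(r) length(r@groups), integer(1)))
  if (length(n) != 1)
    stop("all results must cover the same subject set")
  A <- vapply(results, function(r) as.character(r@groups), character(n))
  colnames(A) <- labels
  R <- length(results)
  ex <- matrix(0L, R, R, dimnames = list(labels, labels))
  for (i in seq_len(R))
    for (j in seq_len(R))
      ex[i, j] <- sum(A[, i] != A[, j])
  list(assignments = A, exchanges = ex)
}
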