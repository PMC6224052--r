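#' Vectorize variable-length series by zero padding
#'
#' PAM, CLARA, FCM and the validity indexes need fixed-length vectors: each
#' series is right-padded with zeros to the maximum length in the set.
#' Padding with zero is a modeling assumption (absence of observation is
#' treated as absence of utilization); the companion distance is plain
#' Euclidean unless another `method` is requested.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @return Numeric matrix, one row per series, with claim ids as row names.
#' @export
pad_series <- function(series) {
  stopifnot(length(series) > 0L)
  vals <- lapply(series, function(s)
    if (inherits(s, "utilization_series")) as.numeric(s$counts) else as.numeric(s))
  L <- max(lengths(vals))
  mat <- t(vapply(vals, function(v) c(v, rep(0, L - length(v))), numeric(L)))
  rownames(mat) <- series_ids(series)
  mat
}

#' Pairwise distances between padded series
#'
#' @param x matrix from [pad_series()] (or a series list, padded first).
#' @param method distance method passed to [stats::dist()]; default
#'   `"euclidean"`.
#' @return A `dist` object.
#' @export
series_dist <- function(x, method = "euclidean") {
  if (!is.matrix(x)) x <- pad_series(x)
  stats::dist(x, method = method)
}

#' Partitioning around medoids on a series distance matrix
#'
#' Thin wrapper over [cluster::pam()] (build and swap iterations) returning
#' labels and medoid indexes.
#'
#' @param d a `dist` object (or matrix from [pad_series()]).
#' @param M number of clusters.
#' @return List with `labels` (integer vector) and `medoids` (row indexes).
#' @export
pam_series <- function(d, M) {
  if (!inherits(d, "dist")) d <- series_dist(d)
  n <- attr(d, "Size")
  if (M >= n)  # saturated: every point is its own medoid at zero cost
    return(list(labels = seq_len(n), medoids = seq_len(n)))
  fit <- cluster::pam(d, k = M, diss = TRUE)
  list(labels = as.integer(fit$clustering), medoids = as.integer(fit$id.med))
}

#' CLARA: PAM on subsamples, best full-data cost kept
#'
#' Runs [cluster::clara()] on the padded data matrix with `sample_size`
#' series per draw (default 50) and `n_samples` draws (default 5); the
#' sample size is clamped to the number of series.
#'
#' @param x padded matrix (or series list).
#' @param M number of clusters.
#' @param sample_size series per subsample.
#' @param n_samples number of subsamples.
#' @param seed integer seed for the subsampling.
#' @return List with `labels` and `medoids` (row indexes).
#' @export
clara_series <- function(x, M, sample_size = 50L, n_samples = 5L, seed = 1L) {
  if (!is.matrix(x)) x <- pad_series(x)
  n <- nrow(x)
  sample_size <- min(sample_size, n)
  set.seed(seed)
  fit <- cluster::clara(x, k = M, metric = "euclidean",
                        samples = n_samples, sampsize = sample_size,
                        rngR = TRUE, pamLike = TRUE)
  list(labels = as.integer(fit$clustering),
       medoids = as.integer(fit$i.med))
}

#' Fuzzy c-means on padded series
#'
#' Wrapper over [e1071::cmeans()] with fuzzifier `m = 2` by default; hard
#' labels are the argmax memberships.
#'
#' @param x padded matrix (or series list).
#' @param M number of clusters.
#' @param fuzzifier fuzziness exponent, greater than 1 (default 2).
#' @param tol convergence tolerance on the objective.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initialization.
#' @return List with `membership` (n x M, rows summing to 1), `labels`
#'   (argmax), `centers`, and the `objective` trace.
#' @export
fcm_series <- function(x, M, fuzzifier = 2, tol = 1e-9, max_iter = 200L,
                       seed = 1L) {
  stopifnot(fuzzifier > 1)
  if (!is.matrix(x)) x <- pad_series(x)
  set.seed(seed)
  centers <- x[sample.int(nrow(x), M), , drop = FALSE]
  centers <- centers + stats::rnorm(length(centers), sd = 1e-4)  # break ties
  objective <- numeric(0)
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- e1071::cmeans(x, centers = centers, m = fuzzifier,
                         iter.max = 1L, verbose = FALSE, method = "cmeans")
    objective <- c(objective, fit$withinerror)
    centers <- fit$centers
    if (it > 1L && abs(objective[it - 1L] - objective[it]) <=
          tol * max(1, abs(objective[it - 1L]))) break
  }
  list(membership = fit$membership,
       labels = as.integer(apply(fit$membership, 1L, which.max)),
       centers = fit$centers, objective = objective)
}

#' Six-number silhouette summary
#'
#' Per-point silhouette widths `s(i) = (b - a) / max(a, b)` (mean
#' intra-cluster distance `a`, smallest mean distance to another cluster
#' `b`; singleton clusters score 0) computed with [cluster::silhouette()],
#' summarized as min, first quartile, median, mean, third quartile, max.
#'
#' @param d a `dist` object.
#' @param labels integer cluster labels.
#' @return Named numeric vector `min`, `q1`, `median`, `mean`, `q3`, `max`,
#'   with the per-point widths as attribute `"widths"`.
#' @export
silhouette_summary <- function(d, labels) {
  stopifnot(inherits(d, "dist"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least two clusters")
  sil <- cluster::silhouette(labels, d)
  w <- sil[, "sil_width"]
  q <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
  structure(c(min = min(w), q1 = q[1L], median = q[2L], mean = mean(w),
              q3 = q[3L], max = max(w)),
            widths = w)
}

#' Dunn index
#'
#' Smallest between-cluster point-to-point distance divided by the largest
#' within-cluster diameter. Larger is better; `Inf` (with a warning) when
#' every cluster has zero diameter.
#'
#' @param d a `dist` object.
#' @param labels integer cluster labels.
#' @return A single non-negative value.
#' @export
dunn_index <- function(d, labels) {
  stopifnot(inherits(d, "dist"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("Dunn index requires at least two clusters")
  dm <- as.matrix(d)
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  inter <- min(dm[!same & !is.na(same)])
  intra <- max(dm[same & !is.na(same)])
  if (intra == 0) {
    warning("all clusters have zero diameter; Dunn index is infinite")
    return(Inf)
  }
  inter / intra
}

#' Classical (Torgerson) two-dimensional MDS embedding
#'
#' Eigendecomposition of the double-centered squared distance matrix, top
#' two axes scaled by the square root of their eigenvalues
#' ([stats::cmdscale()]). Axis signs are canonicalized so the largest-
#' magnitude loading on each axis is positive, making the embedding
#' deterministic.
#'
#' @param d a `dist` object.
#' @return n x 2 coordinate matrix (second column zero when the
#'   configuration is essentially one-dimensional).
#' @export
mds_2d <- function(d) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  xy <- suppressWarnings(stats::cmdscale(d, k = min(2L, n - 1L)))
  # degenerate configurations (zero or rank-1 distances) return fewer axes
  while (ncol(xy) < 2L) xy <- cbind(xy, rep(0, n))
  for (j in 1:2) {
    i <- which.max(abs(xy[, j]))
    if (length(i) && xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  xy
}

#' Compare MHMM clustering with PAM, CLARA and FCM
#'
#' Runs the three baseline algorithms on the zero-padded series with the
#' same number of clusters as the mixture fit, relabels every partition in
#' decreasing size order, and reports cluster sizes, silhouette summaries,
#' Dunn indexes and a shared 2-D MDS projection.
#'
#' @param series list of count vectors or [utilization_series()] objects.
#' @param mhmm_labels hard cluster labels from [assign_clusters()].
#' @param M number of clusters (defaults to the number of distinct MHMM
#'   labels).
#' @param sample_size,n_samples CLARA subsampling controls.
#' @param fuzzifier FCM fuzziness exponent.
#' @param seed integer seed shared by the stochastic baselines.
#' @return Object of class `cluster_validation`: list with `sizes` (method
#'   x cluster), `silhouette` (method x six summaries), `dunn` (named
#'   vector), `labels` (per-method), `mds` (n x 2 coordinates).
#' @export
compare_clusterings <- function(series, mhmm_labels,
                                M = length(unique(mhmm_labels)),
                                sample_size = 50L, n_samples = 5L,
                                fuzzifier = 2, seed = 1L) {
  x <- pad_series(series)
  d <- series_dist(x)
  relabel_by_size <- function(l) {
    sizes <- tabulate(l, max(l))
    ord <- order(-sizes, seq_along(sizes))
    match(l, ord)
  }
  labels <- list(
    MHMM = as.integer(mhmm_labels),  # already size-ordered by fit_mhmm
    PAM = relabel_by_size(pam_series(d, M)$labels),
    CLARA = relabel_by_size(clara_series(x, M, sample_size, n_samples,
                                         seed = seed)$labels),
    FCM = relabel_by_size(fcm_series(x, M, fuzzifier, seed = seed)$labels))
  sizes <- t(vapply(labels, function(l) tabulate(l, M), integer(M)))
  colnames(sizes) <- paste0("cluster_", seq_len(M))
  sil <- t(vapply(labels, function(l) unclass(silhouette_summary(d, l)),
                  numeric(6)))
  dunn <- vapply(labels, function(l) dunn_index(d, l), numeric(1))
  structure(list(sizes = sizes, silhouette = sil, dunn = dunn,
                 labels = labels, mds = mds_2d(d)),
            class = "cluster_validation")
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat("Cluster sizes:\n"); print(x$sizes)
  cat("\nSilhouette summary:\n"); print(round(x$silhouette, 3))
  cat("\nDunn index:\n"); print(round(x$dunn, 4))
  invisible(x)
}
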