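#' Average silhouette width of a partition
#'
#' Mean over samples of (b - a)/max(a, b) with a the mean intra-cluster
#' distance and b the smallest mean distance to another cluster; singleton
#' clusters contribute 0 (the convention of \code{cluster::silhouette}).
#'
#' @param labels integer cluster labels (>= 2 distinct values).
#' @param data numeric matrix, rows = samples, Euclidean metric.
#' @return Scalar ASW in [-1, 1].
#' @export
silhouette_width <- function(labels, data) {
  if (length(unique(labels)) < 2) stop("ASW needs at least two clusters")
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(data))
  s <- sil[, "sil_width"]
  s[!is.finite(s)] <- 0          # coincident points: a = b = 0
  mean(s)
}

#' Dunn index of a partition
#'
#' Minimum distance between points of different clusters divided by the
#' maximum intra-cluster diameter.
#'
#' @param labels integer cluster labels (>= 2 distinct values).
#' @param data numeric matrix, Euclidean metric.
#' @return Scalar Dunn index (>= 0).
#' @export
dunn_index <- function(labels, data) {
  if (length(unique(labels)) < 2) stop("Dunn index needs at least two clusters")
  dm <- as.matrix(stats::dist(data))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  diam <- max(dm[same & !is.na(same)], 0)
  if (diam <= 0) stop("all intra-cluster diameters are zero")
  sep <- min(dm[!same & !is.na(same)])
  sep / diam
}

# k-means++ seeding for Lloyd's algorithm
.kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in seq_len(K - 1) + 1) {
    probs <- d2 / sum(d2)
    centers[k, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

.fit_kmeans <- function(X, K, restarts = 10L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- .kmeanspp_centers(X, K)
    km <- tryCatch(
      stats::kmeans(X, centers = cen, iter.max = 50, algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(km)) {
      km <- stats::kmeans(X, centers = K, nstart = 1, iter.max = 50)
    }
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best$cluster
}

.fit_gmm <- function(X, K) {
  fit <- tryCatch(
    mclust::Mclust(X, G = K,
                   modelNames = c("EII", "VII", "EEI", "VVI"),
                   verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit$classification
}

#' Comparative non-functional clustering of the raw grid points
#'
#' Runs a conventional clustering method on the profile values treated as
#' plain points in R^L (not as curves): k-means (Lloyd with k-means++
#' seeding and 10 restarts), k-medoids (PAM), or a Gaussian mixture over
#' diagonal/spherical covariance families chosen by BIC. The number of
#' clusters is the one maximizing the average silhouette width over the
#' range; the Dunn index is reported at the chosen K.
#'
#' @param x a \code{\link{profile_set}} (normalized or raw) or matrix.
#' @param method "kmeans", "kmedoids" or "gmm".
#' @param K_range candidate cluster counts; default 2:10.
#' @param seed integer seed.
#' @return Object of class \code{baseline_run}: \code{method},
#'   \code{K_range}, \code{asw} (named per K), \code{chosen_K},
#'   \code{labels} (at the chosen K), \code{labels_by_K}, \code{dunn}.
#' @export
cluster_points <- function(x, method = c("kmeans", "kmedoids", "gmm"),
                           K_range = 2:10, seed = 1L) {
  method <- match.arg(method)
  X <- if (inherits(x, "profile_set")) x$values else as.matrix(x)
  if (nrow(X) <= max(K_range)) stop("need more samples than the largest K")
  set.seed(seed)
  labels_by_K <- list()
  asw <- stats::setNames(numeric(length(K_range)), K_range)
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    labels <- switch(method,
                     kmeans = .fit_kmeans(X, K),
                     kmedoids = cluster::pam(X, k = K,
                                             cluster.only = TRUE),
                     gmm = .fit_gmm(X, K))
    if (is.null(labels) || length(unique(labels)) < 2) {
      warning(method, " produced no usable partition for K = ", K,
              "; skipped")
      asw[i] <- NA_real_
      next
    }
    labels_by_K[[as.character(K)]] <- labels
    asw[i] <- silhouette_width(labels, X)
  }
  if (all(is.na(asw))) stop("no K in the range could be fit by ", method)
  chosen <- K_range[which.max(asw)]
  labels <- labels_by_K[[as.character(chosen)]]
  structure(list(method = method, K_range = K_range, asw = asw,
                 chosen_K = as.integer(chosen), labels = labels,
                 labels_by_K = labels_by_K,
                 dunn = dunn_index(labels, X)),
            class = "baseline_run")
}

#' @export
print.baseline_run <- function(x, ...) {
  cat("baseline_run:", x$method, "chose K =", x$chosen_K,
      "by ASW (", format(max(x$asw), digits = 3), "), Dunn",
      format(x$dunn, digits = 3), "\n")
  invisible(x)
}
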