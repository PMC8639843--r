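#' Per-cluster mean covariate matrix
#'
#' One row per functional cluster, one column per requested covariate;
#' entries are the mean of the covariate over the cluster's samples
#' (missing values excluded pairwise with a warning).
#'
#' @param labels named vector of cluster labels, names = sample ids (or an
#'   unnamed vector aligned with \code{sample_id}).
#' @param covs covariate data.frame with \code{sample_id} column (see
#'   \code{\link{read_covariates}}).
#' @param covariate_list covariate columns to use; defaults to all
#'   recognized columns present.
#' @param sample_id sample ids aligned with \code{labels} when the latter is
#'   unnamed.
#' @return Object of class \code{cluster_covariate_matrix}: list with
#'   \code{M} (k x q matrix, rownames = cluster labels), \code{sizes}.
#' @export
cluster_covariate_means <- function(labels, covs,
                                    covariate_list = intersect(covariate_names(), names(covs)),
                                    sample_id = names(labels)) {
  if (is.null(sample_id)) stop("labels must be named by sample id (or supply sample_id)")
  covariate_list <- intersect(covariate_list, names(covs))
  if (!length(covariate_list)) stop("none of the requested covariates are present")
  idx <- match(sample_id, covs$sample_id)
  if (anyNA(idx)) {
    stop("no covariate row for sample(s): ",
         paste(utils::head(sample_id[is.na(idx)], 5), collapse = ", "))
  }
  dat <- covs[idx, covariate_list, drop = FALSE]
  if (anyNA(dat)) warning("missing covariate values excluded pairwise")
  labs <- sort(unique(labels))
  M <- matrix(NA_real_, length(labs), length(covariate_list),
              dimnames = list(as.character(labs), covariate_list))
  sizes <- integer(length(labs))
  ss <- numeric(length(covariate_list)); df <- 0
  for (i in seq_along(labs)) {
    rows <- labels == labs[i]
    sizes[i] <- sum(rows)
    cm <- colMeans(dat[rows, , drop = FALSE], na.rm = TRUE)
    if (any(!is.finite(cm))) {
      stop("cluster ", labs[i], " has no covariate coverage for: ",
           paste(covariate_list[!is.finite(cm)], collapse = ", "))
    }
    M[i, ] <- cm
    if (sizes[i] > 1) {
      dev <- sweep(as.matrix(dat[rows, , drop = FALSE]), 2, cm)
      ss <- ss + colSums(dev^2, na.rm = TRUE)
      df <- df + sizes[i] - 1
    }
  }
  within_sd <- if (df > 0) sqrt(ss / df) else NULL
  if (!is.null(within_sd)) names(within_sd) <- covariate_list
  structure(list(M = M, sizes = sizes, within_sd = within_sd),
            class = "cluster_covariate_matrix")
}

# squared per-feature differences for all row pairs: npairs x q
.pairwise_sq <- function(M) {
  k <- nrow(M)
  pairs <- utils::combn(k, 2)
  D <- (M[pairs[1, ], , drop = FALSE] - M[pairs[2, ], , drop = FALSE])^2
  attr(D, "pairs") <- pairs
  D
}

.soft_threshold <- function(a, delta) pmax(a - delta, 0)

# w = normalized soft-threshold of a with ||w||_1 <= wbound, by binary search
.l1_project <- function(a, wbound) {
  l2 <- sqrt(sum(a^2))
  if (l2 == 0) return(a)
  w <- a / l2
  if (sum(w) <= wbound) return(w)
  l1_at <- function(delta) {
    w <- .soft_threshold(a, delta)
    s <- sqrt(sum(w^2))
    if (s > 0) sum(w) / s else 0
  }
  lo <- 0; hi <- max(a)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (l1_at(mid) > wbound) lo <- mid else hi <- mid
  }
  w <- .soft_threshold(a, hi)
  s <- sqrt(sum(w^2))
  if (s == 0) {                 # degenerate: keep the single largest feature
    w <- as.numeric(seq_along(a) == which.max(a))
    s <- 1
  }
  w / s
}

#' Sparse complete-linkage hierarchical clustering of cluster covariate means
#'
#' Alternates between (i) the leading dissimilarity factor
#' u = D w / ||D w|| over row pairs and (ii) nonnegative feature weights
#' w maximizing sum_j w_j (D' u)_j subject to ||w||_2 <= 1 and
#' ||w||_1 <= wbound (soft-thresholding with the threshold chosen by binary
#' search), where D holds the squared per-feature differences of all row
#' pairs. The final tree is complete-linkage agglomeration of the weighted
#' dissimilarity sum_j w_j d_pair,j.
#'
#' Covariates carry incommensurate units (mmHg, um, mm^3, ratios), so
#' columns are centered and rescaled before dissimilarities are computed.
#' When the input is a \code{cluster_covariate_matrix}, the scale is the
#' pooled within-cluster standard deviation of each covariate: a covariate
#' is informative when its cluster means differ by more than its spread
#' among the samples of a cluster. For a plain matrix the across-row sd is
#' used instead.
#'
#' @param M a \code{cluster_covariate_matrix} (or plain matrix).
#' @param wbound L1 bound on the weights, in [1, sqrt(q)]; smaller is
#'   sparser.
#' @param standardize center and rescale columns first (see Details).
#' @param max_iter,tol weight-iteration controls (relative L1 change).
#' @return Object of class \code{metacluster_result}: \code{weights}
#'   (named, decreasing order preserved in \code{ranking}), \code{tree}
#'   (an \code{hclust}), \code{dist} (weighted dissimilarity),
#'   \code{wbound}, \code{objective}, \code{sizes}.
#' @export
sparse_hclust <- function(M, wbound = 2, standardize = TRUE,
                          max_iter = 25L, tol = 1e-4) {
  sizes <- NULL; scale_sd <- NULL
  if (inherits(M, "cluster_covariate_matrix")) {
    sizes <- M$sizes
    scale_sd <- M$within_sd
    M <- M$M
  }
  M <- as.matrix(M)
  q <- ncol(M)
  if (q < 2) stop("need at least two covariates")
  if (nrow(M) < 2) stop("need at least two cluster rows")
  if (wbound < 1) stop("wbound must be at least 1")
  if (standardize) {
    sdv <- if (is.null(scale_sd)) apply(M, 2, stats::sd) else scale_sd
    M <- sweep(M, 2, colMeans(M))
    pos <- sdv > 0
    M[, pos] <- sweep(M[, pos, drop = FALSE], 2, sdv[pos], "/")
    # zero-scale columns stay identically zero and get zero weight
    M[, !pos] <- 0
  }
  D <- .pairwise_sq(M)
  if (all(D == 0)) stop("all pairwise dissimilarities are zero")
  w <- rep(1 / sqrt(q), q)
  obj <- -Inf
  for (it in seq_len(max_iter)) {
    u <- drop(D %*% w)
    u <- u / sqrt(sum(u^2))
    a <- drop(crossprod(D, u))
    w_new <- .l1_project(a, wbound)
    delta <- sum(abs(w_new - w)) / max(sum(abs(w)), 1e-12)
    w <- w_new
    obj <- sum(a * w)
    if (delta < tol) break
  }
  names(w) <- colnames(M)
  dw <- drop(D %*% w)
  k <- nrow(M)
  dm <- matrix(0, k, k, dimnames = list(rownames(M), rownames(M)))
  pairs <- attr(D, "pairs")
  dm[t(pairs)] <- dw
  dm[t(pairs[2:1, , drop = FALSE])] <- dw
  dst <- stats::as.dist(dm)
  tree <- stats::hclust(dst, method = "complete")
  structure(list(weights = w,
                 ranking = names(sort(w, decreasing = TRUE)),
                 tree = tree, dist = dst, wbound = wbound,
                 objective = obj, sizes = sizes),
            class = "metacluster_result")
}

#' @export
print.metacluster_result <- function(x, ...) {
  nz <- sum(x$weights > 1e-8)
  cat("metacluster_result: wbound", x$wbound, ",", nz,
      "covariates with nonzero weight; top:",
      paste(utils::head(x$ranking, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Flat cut of the metacluster dendrogram
#'
#' Merge heights are rescaled so the root merge sits at 1 before cutting
#' (the covariate-mean matrices of different strata live on different raw
#' scales, so a common threshold is only meaningful after normalization).
#'
#' @param result a \code{metacluster_result}.
#' @param height cut threshold on the rescaled tree; default 0.1.
#' @param rescale rescale merge heights so the root is at 1.
#' @return Named integer metacluster labels, one per functional cluster.
#' @export
cut_metaclusters <- function(result, height = 0.1, rescale = TRUE) {
  tree <- result$tree
  h <- if (rescale) height * max(tree$height) else height
  stats::cutree(tree, h = h)
}

#' Permutation-gap choice of the sparsity bound
#'
#' For each candidate wbound the gap statistic is the log objective on the
#' observed matrix minus the mean log objective over matrices with each
#' column independently permuted; the wbound with the largest gap wins.
#'
#' @param M a \code{cluster_covariate_matrix} or matrix.
#' @param wbounds candidate bounds; default 2:5.
#' @param n_perm permutations per candidate.
#' @param seed integer seed for the permutations.
#' @return Chosen wbound with attribute \code{gaps}.
#' @export
select_wbound <- function(M, wbounds = 2:5, n_perm = 25L, seed = 1L) {
  if (inherits(M, "cluster_covariate_matrix")) M <- M$M
  M <- as.matrix(M)
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(i) apply(M, 2, sample))
  gaps <- vapply(wbounds, function(wb) {
    obs <- log(sparse_hclust(M, wbound = wb)$objective)
    ref <- vapply(perms, function(P) {
      log(sparse_hclust(P, wbound = wb)$objective)
    }, numeric(1))
    obs - mean(ref)
  }, numeric(1))
  structure(wbounds[which.max(gaps)], gaps = stats::setNames(gaps, wbounds))
}

#' Match metaclusters across age strata
#'
#' Metacluster centroids are the size-weighted means of their member
#' clusters' rows on the key covariates; metaclusters of each stratum are
#' matched greedily (ascending centroid distance) to those of the first
#' stratum, and metaclusters left over beyond the smaller count are labeled
#' distinct.
#'
#' @param results named list of \code{metacluster_result} per stratum.
#' @param labels_list named list of metacluster label vectors (from
#'   \code{\link{cut_metaclusters}}) per stratum.
#' @param M_list named list of \code{cluster_covariate_matrix} per stratum.
#' @param key_covariates covariate names used for matching (default the
#'   top-2 by weight in the first stratum).
#' @return data.frame with stratum, metacluster, matched_to (reference
#'   metacluster id or NA when distinct).
#' @export
correspond_metaclusters <- function(results, labels_list, M_list,
                                    key_covariates = NULL) {
  strata <- names(results)
  if (length(strata) < 2) stop("need at least two strata to correspond")
  if (is.null(key_covariates)) {
    key_covariates <- utils::head(results[[1]]$ranking, 2)
  }
  centroid <- function(M, labels) {
    sizes <- M$sizes
    X <- M$M[, key_covariates, drop = FALSE]
    t(vapply(sort(unique(labels)), function(g) {
      rows <- labels == g
      colSums(X[rows, , drop = FALSE] * sizes[rows]) / sum(sizes[rows])
    }, numeric(length(key_covariates))))
  }
  cents <- lapply(strata, function(s) centroid(M_list[[s]], labels_list[[s]]))
  names(cents) <- strata
  ref <- cents[[1]]
  out <- data.frame(stratum = strata[1],
                    metacluster = seq_len(nrow(ref)),
                    matched_to = seq_len(nrow(ref)))
  for (s in strata[-1]) {
    C <- cents[[s]]
    dmat <- as.matrix(stats::dist(rbind(ref, C)))[seq_len(nrow(ref)),
                                                  nrow(ref) + seq_len(nrow(C)),
                                                  drop = FALSE]
    match_s <- rep(NA_integer_, nrow(C))
    taken_r <- logical(nrow(ref)); taken_c <- logical(nrow(C))
    for (step in seq_len(min(nrow(ref), nrow(C)))) {
      d2 <- dmat
      d2[taken_r, ] <- Inf; d2[, taken_c] <- Inf
      ij <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      match_s[ij[2]] <- ij[1]
      taken_r[ij[1]] <- TRUE; taken_c[ij[2]] <- TRUE
    }
    out <- rbind(out, data.frame(stratum = s,
                                 metacluster = seq_len(nrow(C)),
                                 matched_to = match_s))
  }
  out
}
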