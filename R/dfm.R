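#' The twelve covariance-constraint variants of the discriminative
#' functional mixture model
#'
#' The latent (within-subspace) covariance can be full, diagonal or
#' isotropic, each either cluster-specific or common across clusters; the
#' residual noise variance outside the subspace is either cluster-specific
#' or common. The crossing gives twelve model variants.
#'
#' @return data.frame with columns \code{id}, \code{latent}
#'   ("full"/"diagonal"/"isotropic"), \code{latent_common},
#'   \code{noise_common}.
#' @export
dfm_variants <- function() {
  g <- expand.grid(latent = c("full", "diagonal", "isotropic"),
                   latent_common = c(FALSE, TRUE),
                   noise_common = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  g$id <- paste0(substr(g$latent, 1, 1),
                 ifelse(g$latent_common, "C", "K"),
                 "_n", ifelse(g$noise_common, "C", "K"))
  g[, c("id", "latent", "latent_common", "noise_common")]
}

.variant_row <- function(variant) {
  v <- dfm_variants()
  if (is.character(variant)) {
    row <- v[v$id == variant, ]
    if (!nrow(row)) stop("unknown DFM variant id: ", variant)
    return(row)
  }
  variant
}

#' Free-parameter count of a DFM variant
#'
#' m = (K - 1) mixing proportions + K d latent means
#'   + (p d - d(d+1)/2) for the orthonormal subspace basis
#'   + latent covariance parameters (d(d+1)/2, d or 1, times K when
#'     cluster-specific)
#'   + noise parameters (K or 1).
#'
#' @param variant variant id string or a row of \code{\link{dfm_variants}}.
#' @param K number of clusters.
#' @param p number of basis coefficients.
#' @param d latent subspace dimension.
#' @return Integer parameter count.
#' @export
count_params <- function(variant, K, p, d) {
  v <- .variant_row(variant)
  lat_per <- switch(v$latent,
                    full = d * (d + 1) / 2,
                    diagonal = d,
                    isotropic = 1)
  lat <- if (v$latent_common) lat_per else K * lat_per
  noise <- if (v$noise_common) 1 else K
  (K - 1) + K * d + (p * d - d * (d + 1) / 2) + lat + noise
}

# ---- internal EM machinery ------------------------------------------------

# log density of each row of X under each component, via the subspace
# decomposition: cost = Mahalanobis inside span(U) + isotropic residual
# energy outside, matching covariance U Sigma_k U' + beta_k (I - U U')
.dfm_logdens <- function(X, U, theta) {
  n <- nrow(X); p <- ncol(X)
  K <- length(theta$pi)
  d <- ncol(U)
  Z <- X %*% U                      # n x d latent scores
  R2 <- rowSums(X^2) - rowSums(Z^2) # squared residual norm outside span(U)
  R2 <- pmax(R2, 0)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    S <- theta$Sigma[[k]]
    ch <- chol(S)
    Zi <- sweep(Z, 2, theta$mu[[k]])
    maha <- colSums(backsolve(ch, t(Zi), transpose = TRUE)^2)
    beta <- theta$beta[k]
    out[, k] <- log(theta$pi[k]) - 0.5 * (
      maha + 2 * sum(log(diag(ch))) +
        R2 / beta + (p - d) * log(beta) + p * log(2 * pi))
  }
  out
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

.dfm_estep <- function(X, U, theta) {
  ld <- .dfm_logdens(X, U, theta)
  lse <- .logsumexp_rows(ld)
  list(t = exp(ld - lse), loglik = sum(lse))
}

# F-step: top-d generalized eigenvectors of the soft between-cluster scatter
# against the (ridge-regularized) total scatter, orthonormalized
.dfm_fstep <- function(X, t, d, ridge = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  S <- crossprod(Xc) / n
  nk <- colSums(t)
  Mk <- sweep(crossprod(t, X), 1, nk, "/")   # K x p soft cluster means
  Mc <- sweep(Mk, 2, xbar)
  B <- crossprod(Mc * sqrt(nk / n))          # between-cluster scatter
  A <- solve(S + ridge * mean(diag(S)) * diag(p), B)
  e <- eigen(A)
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(d)]
  V <- Re(e$vectors[, ord, drop = FALSE])
  qr.Q(qr(V))[, seq_len(d), drop = FALSE]
}

# M-step under the variant's constraints. Latent means/covariances are the
# responsibility-weighted moments of the subspace scores; the residual
# variance is the weighted mean squared residual energy outside the
# subspace per dimension (the exact maximizer, so the fixed-U EM step is an
# ascent step).
.dfm_mstep <- function(X, t, U, variant, min_var = 1e-8) {
  v <- .variant_row(variant)
  n <- nrow(X); p <- ncol(X); d <- ncol(U)
  K <- ncol(t)
  nk <- colSums(t)
  if (any(nk < 1e-6)) return(NULL)           # empty cluster -> caller restarts
  pi_k <- nk / n
  Z <- X %*% U
  r2 <- pmax(rowSums(X^2) - rowSums(Z^2), 0) # residual energy outside span(U)
  mu <- vector("list", K)
  Sigma_raw <- vector("list", K)
  beta_raw <- numeric(K)
  for (k in seq_len(K)) {
    w <- t[, k]
    mu[[k]] <- colSums(Z * w) / nk[k]
    Zc <- sweep(Z, 2, mu[[k]])
    Sk <- crossprod(Zc * sqrt(w)) / nk[k]
    Sigma_raw[[k]] <- (Sk + t(Sk)) / 2
    beta_raw[k] <- sum(w * r2) / (nk[k] * (p - d))
  }
  pool <- function(lst) Reduce(`+`, Map(`*`, lst, pi_k))
  Sigma <- Sigma_raw
  if (v$latent_common) {
    Sc <- pool(Sigma_raw)
    Sigma <- rep(list(Sc), K)
  }
  Sigma <- lapply(Sigma, function(S) {
    S <- switch(v$latent,
                full = S,
                diagonal = diag(diag(S), nrow = d),
                isotropic = diag(rep(mean(diag(S)), d), nrow = d))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < min_var) S <- S + (min_var - min(ev)) * diag(d)
    S
  })
  beta <- if (v$noise_common) rep(sum(pi_k * beta_raw), K) else beta_raw
  beta <- pmax(beta, min_var)
  list(pi = pi_k, mu = mu, Sigma = Sigma, beta = beta)
}

.one_hot <- function(labels, K) {
  t <- matrix(0, length(labels), K)
  t[cbind(seq_along(labels), labels)] <- 1
  t
}

# whitened coordinates for initialization: shared high-variance modes are
# rescaled to unit variance so they cannot dominate the seeding
.whiten <- function(X, ridge = 1e-8) {
  e <- eigen(stats::cov(X) + ridge * diag(ncol(X)), symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-10)
  X %*% e$vectors %*% diag(1 / sqrt(vals), length(vals))
}

.dfm_fit_once <- function(X, K, variant, d, init, seed, max_iter, tol) {
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  labels0 <- if (init == "kmeans") {
    stats::kmeans(.whiten(X), centers = K, nstart = 3, iter.max = 30)$cluster
  } else {
    sample(rep_len(seq_len(K), n))
  }
  t <- .one_hot(labels0, K)
  # mild smoothing so no component starts empty-ish with zero covariance mass
  t <- (t + 1e-3) / (1 + K * 1e-3)
  U <- .dfm_fstep(X, t, d)
  theta <- .dfm_mstep(X, t, U, variant)
  if (is.null(theta)) return(NULL)
  es <- .dfm_estep(X, U, theta)
  ll <- es$loglik
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    t <- es$t
    U_new <- .dfm_fstep(X, t, d)
    theta_new <- .dfm_mstep(X, t, U_new, variant)
    if (is.null(theta_new)) return(NULL)
    es_new <- .dfm_estep(X, U_new, theta_new)
    if (es_new$loglik < ll - 1e-9) {
      # the subspace update is not guaranteed to ascend; fall back to a
      # plain M-step with the previous subspace, which is
      theta_new <- .dfm_mstep(X, t, U, variant)
      if (is.null(theta_new)) return(NULL)
      es_new <- .dfm_estep(X, U, theta_new)
    } else {
      U <- U_new
    }
    theta <- theta_new
    gain <- es_new$loglik - ll
    ll <- es_new$loglik
    ll_trace <- c(ll_trace, ll)
    es <- es_new
    if (abs(gain) < tol) { converged <- TRUE; break }
  }
  list(U = U, theta = theta, t = es$t, loglik = ll, loglik_trace = ll_trace,
       converged = converged, n_iter = iter)
}

#' Fit a discriminative functional mixture model by EM
#'
#' Models basis coefficients gamma_i as a K-component Gaussian mixture whose
#' cluster structure lives in a d-dimensional discriminative subspace
#' spanned by the orthonormal columns of U: component k has mean U mu_k and
#' covariance U Sigma_k U' + beta_k (I - U U'). The fit alternates an
#' E-step (responsibilities via the subspace decomposition of the
#' densities), an F-step (U from the generalized eigenproblem of the soft
#' between-cluster scatter against the total scatter), and an M-step
#' (moment updates under the variant's constraints, with the residual
#' variance beta_k = (tr C_k - tr U'C_k U)/(p - d)). The log-likelihood is
#' nondecreasing: if a subspace update would lower it the previous subspace
#' is kept for that iteration.
#'
#' @param coeffs a \code{coefficient_set} (or plain n x p matrix).
#' @param K number of clusters (>= 2).
#' @param variant variant id from \code{\link{dfm_variants}}.
#' @param d latent dimension, 1 <= d <= min(p - 1, K - 1); default K - 1.
#' @param init "kmeans" or "random" initialization.
#' @param seed integer seed; restarts use seed, seed + 1, ...
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood gain at which to stop.
#' @param n_restarts number of restarts; the best log-likelihood is kept.
#' @return Object of class \code{dfm_model}: \code{K}, \code{d}, \code{U},
#'   \code{pi}, \code{mu}, \code{Sigma}, \code{beta}, \code{t}
#'   (responsibilities), \code{labels}, \code{loglik}, \code{loglik_trace},
#'   \code{variant}, \code{m} (free parameters), \code{converged},
#'   \code{n_iter}, \code{n}.
#' @export
em_fit <- function(coeffs, K, variant = "fK_nK", d = K - 1L,
                   init = c("kmeans", "random"), seed = 1L,
                   max_iter = 200L, tol = 1e-6, n_restarts = 5L) {
  init <- match.arg(init)
  X <- if (inherits(coeffs, "coefficient_set")) coeffs$gamma else as.matrix(coeffs)
  # the subspace models deviations from the overall mean coefficient vector
  # (component means are U mu_k, which live in span(U)); center once here
  center <- colMeans(X)
  X <- sweep(X, 2, center)
  n <- nrow(X); p <- ncol(X)
  if (K < 2) stop("K must be at least 2")
  if (n <= K) stop("need more samples than clusters")
  d <- as.integer(d)
  if (d < 1 || d > min(p - 1, K - 1)) {
    stop("d must lie in 1..min(p - 1, K - 1)")
  }
  best <- NULL
  attempts <- 0L
  r <- 0L
  while (r < n_restarts && attempts < 4L * n_restarts) {
    attempts <- attempts + 1L
    fit <- .dfm_fit_once(X, K, variant, d, init, seed + attempts - 1L,
                         max_iter, tol)
    if (is.null(fit)) next                   # empty cluster; try a new seed
    r <- r + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts collapsed to an empty cluster (K = ", K, ")")
  }
  labels <- max.col(best$t)
  structure(
    list(K = as.integer(K), d = d, center = center, U = best$U,
         pi = best$theta$pi,
         mu = best$theta$mu, Sigma = best$theta$Sigma,
         beta = best$theta$beta, t = best$t, labels = labels,
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         variant = if (is.character(variant)) variant else variant$id,
         m = count_params(variant, K, p, d),
         converged = best$converged, n_iter = best$n_iter, n = n),
    class = "dfm_model")
}

#' @export
print.dfm_model <- function(x, ...) {
  cat("dfm_model: K =", x$K, ", d =", x$d, ", variant", x$variant,
      ", loglik", format(x$loglik), if (x$converged) "(converged)" else
        "(max iterations)", "\n")
  invisible(x)
}

#' Posterior responsibilities of data under a fitted DFM model
#'
#' @param coeffs a \code{coefficient_set} or n x p matrix.
#' @param model a \code{dfm_model}.
#' @return n x K matrix of responsibilities (rows sum to one).
#' @export
dfm_posterior <- function(coeffs, model) {
  X <- if (inherits(coeffs, "coefficient_set")) coeffs$gamma else as.matrix(coeffs)
  if (!is.null(model$center)) X <- sweep(X, 2, model$center)
  .dfm_estep(X, model$U,
             list(pi = model$pi, mu = model$mu, Sigma = model$Sigma,
                  beta = model$beta))$t
}

#' Information criteria of a fitted DFM model
#'
#' All three are on the maximize orientation:
#' AIC = loglik - m; BIC = loglik - (m/2) log n;
#' ICL = BIC + sum_i sum_k t_ik log t_ik (BIC minus the responsibilities'
#' entropy, so ICL <= BIC with equality for hard assignments).
#'
#' @param model a \code{dfm_model}.
#' @param n sample size; defaults to the fitted size.
#' @return Named numeric vector (AIC, BIC, ICL).
#' @export
dfm_criteria <- function(model, n = model$n) {
  ll <- model$loglik
  m <- model$m
  bic <- ll - (m / 2) * log(n)
  tl <- model$t * log(pmax(model$t, .Machine$double.xmin))
  c(AIC = ll - m, BIC = bic, ICL = bic + sum(tl))
}

# elbow of a criterion trace (maximize orientation): the K with the largest
# discrete curvature; the first K competes with curvature -(first gain) so a
# monotone-decreasing trace elects the smallest K; ties go to the smaller K
.elbow <- function(K_values, crit) {
  J <- length(crit)
  if (J == 1) return(K_values[1])
  curv <- rep(-Inf, J)
  curv[1] <- crit[1] - crit[2]
  if (J > 2) {
    for (j in 2:(J - 1)) curv[j] <- crit[j] - (crit[j - 1] + crit[j + 1]) / 2
  }
  K_values[which.max(curv)]
}

#' Fit DFM models over a range of K and select the number of clusters
#'
#' For each K all requested variants are fit (each best-of-restarts) and the
#' variant with the best BIC is retained; the number of clusters is then the
#' elbow of the retained BIC trace (largest second difference, ties to the
#' smaller K), mirroring a "no significant further gain" reading of the
#' criterion curves. Full AIC/BIC/ICL traces for every (K, variant) pair are
#' returned for inspection or manual override.
#'
#' @param coeffs a \code{coefficient_set} or n x p matrix.
#' @param K_range integer vector of candidate cluster counts.
#' @param variants character vector of variant ids (default all twelve).
#' @param d latent dimension; NULL means K - 1 per fit (capped at p - 1).
#' @param seed integer seed.
#' @param n_restarts,max_iter,tol forwarded to \code{\link{em_fit}}.
#' @return Object of class \code{cluster_solution}: \code{K} (chosen),
#'   \code{labels}, \code{model} (the chosen fit), \code{trace}
#'   (data.frame over K and variant with loglik, m, AIC, BIC, ICL),
#'   \code{best_per_K} (data.frame of the retained variant per K).
#' @export
select_K <- function(coeffs, K_range = 2:12, variants = dfm_variants()$id,
                     d = NULL, seed = 1L, n_restarts = 5L,
                     max_iter = 200L, tol = 1e-6) {
  X <- if (inherits(coeffs, "coefficient_set")) coeffs$gamma else as.matrix(coeffs)
  p <- ncol(X)
  rows <- list(); fits <- list()
  for (K in K_range) {
    dk <- if (is.null(d)) min(K - 1L, p - 1L) else min(d, K - 1L, p - 1L)
    for (v in variants) {
      fit <- tryCatch(
        em_fit(X, K = K, variant = v, d = dk, seed = seed,
               n_restarts = n_restarts, max_iter = max_iter, tol = tol),
        error = function(e) NULL)
      if (is.null(fit)) next
      cr <- dfm_criteria(fit)
      key <- paste0("K", K, "_", v)
      fits[[key]] <- fit
      rows[[key]] <- data.frame(K = K, variant = v, d = dk,
                                loglik = fit$loglik, m = fit$m,
                                AIC = cr[["AIC"]], BIC = cr[["BIC"]],
                                ICL = cr[["ICL"]],
                                converged = fit$converged)
    }
  }
  if (!length(rows)) stop("no (K, variant) fit converged")
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  best_per_K <- do.call(rbind, lapply(split(trace, trace$K), function(df) {
    df[which.max(df$BIC), ]
  }))
  best_per_K <- best_per_K[order(best_per_K$K), ]
  K_chosen <- .elbow(best_per_K$K, best_per_K$BIC)
  row <- best_per_K[best_per_K$K == K_chosen, ]
  model <- fits[[paste0("K", K_chosen, "_", row$variant)]]
  structure(list(K = as.integer(K_chosen), labels = model$labels,
                 model = model, trace = trace, best_per_K = best_per_K),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: chose K =", x$K, "(variant", x$model$variant,
      ") by the BIC elbow over K in {",
      paste(x$best_per_K$K, collapse = ", "), "}\n")
  invisible(x)
}
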