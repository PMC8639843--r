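# small in-code fixtures shared across test files

# constant curves at the given levels on the default 180-point grid
const_profiles <- function(levels, grid = angular_grid(), age = NULL) {
  profile_set(matrix(rep(levels, each = grid$L), nrow = length(levels),
                     byrow = TRUE),
              grid = grid, age = age)
}

# band-limited curves: level + sum of harmonic terms given as a list of
# (m, sin_amp, cos_amp) triplets, one row per curve
harmonic_profiles <- function(coef_list, grid = angular_grid()) {
  t <- grid$angles
  vals <- t(vapply(coef_list, function(co) {
    y <- rep(co$level, grid$L)
    if (!is.null(co$harm)) {
      for (h in co$harm) {
        w <- 2 * pi * h[1] * t / 360
        y <- y + h[2] * sin(w) + h[3] * cos(w)
      }
    }
    y
  }, numeric(grid$L)))
  profile_set(vals, grid = grid)
}

# brute-force average silhouette width (direct definition)
brute_asw <- function(labels, data) {
  dm <- as.matrix(stats::dist(data))
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(dm[i, labels == g])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# brute-force Dunn index (direct definition)
brute_dunn <- function(labels, data) {
  dm <- as.matrix(stats::dist(data))
  n <- nrow(dm)
  inter <- Inf; intra <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) intra <- max(intra, dm[i, j])
    else inter <- min(inter, dm[i, j])
  }
  inter / intra
}

# dense-covariance log-density of the subspace mixture model, for checking
# the decomposed E-step: N(x; U mu_k, U Sigma_k U' + beta_k (I - U U'))
dense_logdens <- function(X, U, pi_k, mu, Sigma, beta) {
  p <- ncol(X); K <- length(pi_k)
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    Cov <- U %*% Sigma[[k]] %*% t(U) + beta[k] * (diag(p) - U %*% t(U))
    ch <- chol(Cov)
    Xc <- sweep(X, 2, drop(U %*% mu[[k]]))
    maha <- colSums(backsolve(ch, t(Xc), transpose = TRUE)^2)
    out[, k] <- log(pi_k[k]) -
      0.5 * (maha + 2 * sum(log(diag(ch))) + p * log(2 * pi))
  }
  out
}

# a fabricated dfm_model object for testing posterior/criteria arithmetic
fake_dfm_model <- function(loglik, m, t, n = nrow(t)) {
  structure(list(loglik = loglik, m = m, t = t, n = n), class = "dfm_model")
}
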