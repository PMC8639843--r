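test_that("the variant family and its parameter counts are correct", {
  v <- dfm_variants()
  expect_equal(nrow(v), 12)
  expect_false(anyDuplicated(v$id) > 0)
  # enumerated examples: cluster-specific full + cluster-specific noise,
  # and common isotropic + common noise
  expect_equal(count_params("fK_nK", K = 3, p = 11, d = 2), 39)
  expect_equal(count_params("iC_nC", K = 2, p = 11, d = 1), 15)
  # m grows strictly with K (d = K - 1 alongside)
  for (id in v$id) {
    m <- vapply(2:6, function(K) count_params(id, K, p = 11, d = K - 1),
                numeric(1))
    expect_true(all(diff(m) > 0))
  }
})

test_that("information criteria follow their stated forms", {
  # hard responsibilities: zero entropy, ICL = BIC
  t_hard <- matrix(0, 100, 3); t_hard[cbind(1:100, rep(1:3, length.out = 100))] <- 1
  mod <- fake_dfm_model(loglik = -100, m = 39, t = t_hard, n = 100)
  cr <- dfm_criteria(mod)
  expect_equal(cr[["AIC"]], -139)
  expect_equal(cr[["BIC"]], -100 - 19.5 * log(100))
  expect_equal(cr[["ICL"]], cr[["BIC"]])
  # maximal entropy: ICL = BIC - n log K
  t_flat <- matrix(1 / 3, 100, 3)
  cr2 <- dfm_criteria(fake_dfm_model(-100, 39, t_flat))
  expect_equal(cr2[["ICL"]], cr2[["BIC"]] - 100 * log(3))
  expect_lte(cr2[["ICL"]], cr2[["BIC"]])
})

test_that("subspace-decomposed densities match direct dense evaluation", {
  set.seed(17)
  p <- 4; d <- 2; K <- 3; n <- 50
  U <- qr.Q(qr(matrix(rnorm(p * d), p)))[, 1:d]
  Sigma <- lapply(1:K, function(k) {
    A <- matrix(rnorm(d * d), d); crossprod(A) + diag(d)
  })
  mu <- lapply(1:K, function(k) rnorm(d, 0, 3))
  beta <- runif(K, 0.5, 2)
  pi_k <- c(0.2, 0.3, 0.5)
  X <- matrix(rnorm(n * p, 0, 2), n)
  got <- circlust:::.dfm_logdens(X, U, list(pi = pi_k, mu = mu,
                                            Sigma = Sigma, beta = beta))
  want <- dense_logdens(X, U, pi_k, mu, Sigma, beta)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("a point equidistant between symmetric components splits 50/50", {
  p <- 3
  U <- diag(p)[, 1, drop = FALSE]
  model <- structure(list(center = rep(0, p), U = U, pi = c(0.5, 0.5),
                          mu = list(-4, 4),
                          Sigma = list(matrix(1), matrix(1)),
                          beta = c(1, 1)), class = "dfm_model")
  post <- dfm_posterior(matrix(0, 1, p), model)
  expect_equal(drop(post), c(0.5, 0.5))
})

test_that("EM separates planted spherical clouds and ascends monotonically", {
  set.seed(23)
  n <- 200; p <- 5
  mu <- rbind(c(10, 0, 0, 0, 0), c(-10, 0, 0, 0, 0))
  z <- rep(1:2, each = n / 2)
  X <- mu[z, ] + matrix(rnorm(n * p, 0, 0.1), n)
  fit <- em_fit(X, K = 2, d = 1, seed = 1, n_restarts = 2)
  # oracle: nearest planted mean
  oracle <- apply(X, 1, function(x) {
    which.min(c(sum((x - mu[1, ])^2), sum((x - mu[2, ])^2)))
  })
  expect_equal(mclust::adjustedRandIndex(fit$labels, oracle), 1)
  expect_equal(mclust::adjustedRandIndex(fit$labels, z), 1)
  # EM ascent, simplex responsibilities, orthonormal subspace
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_equal(unname(rowSums(fit$t)), rep(1, n), tolerance = 1e-12)
  expect_lt(max(abs(crossprod(fit$U) - diag(fit$d))), 1e-8)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)
})

test_that("EM ascent holds across variants on a harder mixture", {
  set.seed(31)
  n <- 150; p <- 6
  z <- sample(1:3, n, replace = TRUE)
  mu <- matrix(rnorm(18, 0, 3), 3)
  X <- mu[z, ] + matrix(rnorm(n * p), n)
  for (id in c("fK_nK", "dC_nK", "iK_nC", "fC_nC")) {
    fit <- em_fit(X, K = 3, variant = id, d = 2, seed = 2, n_restarts = 2,
                  max_iter = 80)
    expect_true(all(diff(fit$loglik_trace) > -1e-6), label = id)
  }
})

test_that("relabeling clusters leaves likelihood and criteria unchanged", {
  set.seed(29)
  X <- rbind(matrix(rnorm(80, 5), 40, 2), matrix(rnorm(80, -5), 40, 2))
  X <- cbind(X, matrix(rnorm(160, 0, 0.5), 80, 2))
  fit <- em_fit(X, K = 2, d = 1, seed = 3, n_restarts = 2)
  perm <- fit
  perm$pi <- fit$pi[2:1]; perm$mu <- fit$mu[2:1]
  perm$Sigma <- fit$Sigma[2:1]; perm$beta <- fit$beta[2:1]
  perm$t <- fit$t[, 2:1]
  post <- dfm_posterior(X, perm)
  ld <- circlust:::.dfm_logdens(sweep(X, 2, perm$center), perm$U,
                                list(pi = perm$pi, mu = perm$mu,
                                     Sigma = perm$Sigma, beta = perm$beta))
  ll_perm <- sum(circlust:::.logsumexp_rows(ld))
  expect_equal(ll_perm, fit$loglik, tolerance = 1e-8)
  expect_equal(dfm_criteria(perm), dfm_criteria(fit), tolerance = 1e-8)
})

test_that("planted one-dimensional mixture parameters are recovered at n = 2000", {
  set.seed(41)
  n <- 2000; p <- 3
  pi_true <- c(0.4, 0.6); mu_true <- c(-5, 5)
  sig_true <- 1.5; beta_true <- 0.5
  z <- sample(1:2, n, replace = TRUE, prob = pi_true)
  latent <- mu_true[z] + rnorm(n, 0, sqrt(sig_true))
  X <- cbind(latent, matrix(rnorm(n * (p - 1), 0, sqrt(beta_true)), n))
  fit <- em_fit(X, K = 2, variant = "fK_nC", d = 1, seed = 4, n_restarts = 3)
  ord <- order(vapply(fit$mu, function(m) m[1] * sign(fit$U[1, 1]), numeric(1)))
  expect_equal(sort(fit$pi), sort(pi_true), tolerance = 0.1)
  mu_hat <- sort(vapply(fit$mu, function(m) m[1], numeric(1)) * sign(fit$U[1, 1]))
  # the fitted subspace centers the data, so compare gaps not locations
  expect_equal(diff(mu_hat), diff(mu_true), tolerance = 0.1 * diff(mu_true))
  expect_equal(mean(vapply(fit$Sigma, function(S) S[1, 1], numeric(1))),
               sig_true, tolerance = 0.1 * sig_true + 0.1)
  expect_equal(fit$beta[1], beta_true, tolerance = 0.1 * beta_true)
})

test_that("cluster-count selection finds planted structure and collapses on noise", {
  set.seed(37)
  # three well-separated planted clusters in a 6-dim coefficient space
  n <- 150
  mu <- rbind(c(8, 0, 0, 0, 0, 0), c(-4, 7, 0, 0, 0, 0), c(-4, -7, 0, 0, 0, 0))
  z <- rep(1:3, each = n / 3)
  X <- mu[z, ] + matrix(rnorm(n * 6, 0, 0.8), n)
  sol <- select_K(X, K_range = 2:5, variants = c("fK_nK", "iC_nC"), d = 2,
                  seed = 5, n_restarts = 2, max_iter = 80)
  expect_equal(sol$K, 3L)
  expect_gte(mclust::adjustedRandIndex(sol$labels, z), 0.95)
  expect_true(all(c("AIC", "BIC", "ICL") %in% names(sol$trace)))
  # traces retained for every fitted (K, variant) pair
  expect_equal(nrow(sol$trace), length(2:5) * 2)
  # a single Gaussian cloud gives a decreasing trace and the smallest K
  X0 <- matrix(rnorm(120 * 4), 120)
  sol0 <- select_K(X0, K_range = 2:4, variants = "iC_nC", d = 1,
                   seed = 6, n_restarts = 2, max_iter = 60)
  expect_equal(sol0$K, 2L)
})
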