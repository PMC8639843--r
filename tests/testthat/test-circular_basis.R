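test_that("the Fourier design is orthogonal on the uniform grid", {
  grid <- angular_grid()
  # constant function value
  expect_equal(unique(round(fourier_design(grid, 1)[, 1], 10)),
               round(1 / sqrt(360), 10))
  for (p in c(3L, 11L, 21L)) {
    Psi <- fourier_design(grid, p)
    expect_lt(max(abs(crossprod(Psi) - (grid$L / 360) * diag(p))), 1e-10)
  }
  expect_error(fourier_design(grid, 2), "odd")
})

test_that("least-squares coefficients reproduce band-limited curves", {
  # constant curve: the single coefficient is level * sqrt(360)
  ps <- const_profiles(90)
  co <- fit_coefficients(ps, 1)
  expect_equal(unname(co$gamma[1, 1]), 90 * sqrt(360), tolerance = 1e-10)
  expect_equal(unname(reconstruct(co)$values), unname(ps$values),
               tolerance = 1e-10)

  # one-harmonic curve is exact at p = 3
  ps2 <- harmonic_profiles(list(list(level = 5, harm = list(c(1, 0, 2)))))
  rec2 <- reconstruct(fit_coefficients(ps2, 3))
  expect_lt(max(abs(rec2$values - ps2$values)), 1e-8)

  # generic band-limited curves: reconstruct(fit) is the identity
  set.seed(7)
  cl <- lapply(1:4, function(i) {
    list(level = runif(1, 80, 100),
         harm = lapply(1:5, function(m) c(m, rnorm(1, 0, 5), rnorm(1, 0, 5))))
  })
  ps3 <- harmonic_profiles(cl)
  rec3 <- reconstruct(fit_coefficients(ps3, 11))
  expect_lt(max(abs(rec3$values - ps3$values)), 1e-8)

  # zero coefficients give zero curves
  co0 <- fit_coefficients(ps3, 11)
  co0$gamma[] <- 0
  expect_true(all(reconstruct(co0)$values == 0))
})

test_that("curve statistics follow their defining arithmetic", {
  ps <- const_profiles(c(80, 100))
  st <- curve_stats(ps)
  expect_equal(unique(st$mean_curve), 90)
  expect_equal(unique(st$sd_curve), sqrt(200))
  expect_equal(st$tv, 72000)                 # 2 * 100 * 360 deviations
  # identical curves: zero spread
  st2 <- curve_stats(const_profiles(c(90, 90)))
  expect_true(all(st2$sd_curve == 0))
  expect_equal(st2$tv, 0)
  expect_error(curve_stats(const_profiles(90)), "two curves")
  # TV equals step * trace of the pointwise sample covariance
  set.seed(11)
  X <- matrix(rnorm(5 * 180, 90, 4), 5)
  ps3 <- profile_set(abs(X))
  expect_equal(curve_stats(ps3)$tv,
               ps3$grid$step * sum(diag(stats::cov(ps3$values))),
               tolerance = 1e-8)
})

test_that("FVE is 1 for band-limited curves and nondecreasing in p", {
  set.seed(3)
  cl <- lapply(1:5, function(i) {
    list(level = runif(1, 80, 100),
         harm = lapply(1:3, function(m) c(m, rnorm(1, 0, 4), rnorm(1, 0, 4))))
  })
  ps <- harmonic_profiles(cl)
  expect_equal(fve(ps, 7), 1, tolerance = 1e-8)
  # rough curves: FVE climbs monotonically over nested bases
  psr <- profile_set(matrix(runif(6 * 180, 60, 120), 6))
  fves <- vapply(seq(1, 21, 2), function(p) fve(psr, p), numeric(1))
  expect_true(all(diff(fves) >= -1e-12))
  expect_error(fve(const_profiles(c(90, 90)), 3), "undefined")
})

test_that("basis-order selection returns the smallest adequate order", {
  set.seed(5)
  # five harmonics with real energy at the top one, plus tiny noise
  cl <- lapply(1:8, function(i) {
    list(level = 90,
         harm = lapply(1:5, function(m) c(m, rnorm(1, 0, 4),
                                          rnorm(1, if (m == 5) 6 else 0, 4))))
  })
  ps <- harmonic_profiles(cl)
  ps$values <- ps$values + matrix(rnorm(length(ps$values), 0, 1e-6),
                                  nrow(ps$values))
  ps <- profile_set(ps$values)
  expect_identical(as.integer(select_p(ps)), 11L)
  expect_lt(attr(select_p(ps), "fve")[["9"]], 0.99)

  # constant plus one harmonic needs p = 3
  cl2 <- lapply(1:4, function(i) list(level = 90 + i,
                                      harm = list(c(1, i, 2 * i))))
  expect_identical(as.integer(select_p(harmonic_profiles(cl2))), 3L)

  # threshold ~0: first candidate that explains anything wins
  expect_identical(as.integer(select_p(const_profiles(c(80, 100)),
                                       threshold = 1e-12)), 1L)
  expect_error(select_p(ps, candidates = integer(0)), "candidate")
  # when nothing qualifies the largest candidate is returned flagged
  psr <- profile_set(matrix(runif(4 * 180, 60, 120), 4))
  expect_warning(pw <- select_p(psr, candidates = c(1L, 3L)), "largest")
  expect_identical(as.integer(pw), 3L)
  expect_false(attr(pw, "converged"))
})

test_that("cluster templates carry mean curves, sizes and within-cluster TV", {
  ps <- const_profiles(c(80, 80, 100, 100))
  tp <- cluster_templates(ps, c(1, 1, 2, 2), p = 1)
  expect_equal(unique(tp[["1"]]$mean_curve), 80)
  expect_equal(unique(tp[["2"]]$mean_curve), 100)
  expect_equal(tp[["1"]]$size, 2)
  # single cluster template is the global mean
  tp1 <- cluster_templates(ps, rep(1, 4), p = 1)
  expect_equal(tp1[["1"]]$mean_curve, curve_stats(ps)$mean_curve)
  # within-cluster TV equals step * trace of within covariance
  set.seed(13)
  psr <- profile_set(matrix(runif(6 * 180, 60, 120), 6))
  labs <- c(1, 1, 1, 2, 2, 2)
  tpr <- cluster_templates(psr, labs, p = 11)
  expect_equal(tpr[["2"]]$tv,
               psr$grid$step * sum(diag(stats::cov(psr$values[4:6, ]))),
               tolerance = 1e-8)
  # flat export table
  tab <- templates_table(tpr)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("cluster", "size", "gamma_1", "total_variation")
                  %in% names(tab)))
})
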