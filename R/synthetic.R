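#' Default per-cluster covariate effect table
#'
#' Cluster means for the nine clinical covariates. By default only the
#' average cup-to-disc ratio and cup volume vary across clusters (spanning
#' roughly 0.44-0.62 and 0.10-0.30 respectively, the ranges seen across
#' healthy metaclusters); the remaining covariates sit at cohort-typical
#' values, so the planted metacluster signal lives in exactly those two
#' covariates.
#'
#' @param K number of clusters.
#' @return K x 9 matrix, columns \code{\link{covariate_names}}.
#' @export
default_covariate_effects <- function(K) {
  nm <- covariate_names()
  M <- matrix(rep(c(iop = 12.6, cct = 525, axial_length = 22.6,
                    rim_area = 1.36, disc_area = 1.96, disc_diameter = 1.49,
                    vertical_cdr = 0.49, average_cdr = 0.52,
                    cup_volume = 0.18), each = K),
              nrow = K, dimnames = list(NULL, nm))
  M[, "average_cdr"] <- seq(0.44, 0.62, length.out = K)
  M[, "cup_volume"] <- seq(0.10, 0.30, length.out = K)
  M
}

# per-sample noise sd for each covariate, on the scale of healthy-eye spreads
.default_covariate_sd <- function() {
  c(iop = 2.3, cct = 32, axial_length = 0.74, rim_area = 0.22,
    disc_area = 0.35, disc_diameter = 0.15, vertical_cdr = 0.14,
    average_cdr = 0.14, cup_volume = 0.16)
}

# default within-cluster latent directions: coordinate axes of the
# harmonic-1 sine (an overall tilt of the rim profile toward the nasal or
# temporal side) and the harmonic-4 sine — shape modes shared by all
# clusters and orthogonal to the coordinates the default templates use to
# differ, mimicking strong common anatomical variation on top of subtler
# cluster-specific shape
.default_latent_basis <- function(p_star, d) {
  free <- c(2L, 8L, 9L)                      # sin1, sin4, cos4 coordinates
  if (d > length(free)) {
    stop("default latent basis supports d <= ", length(free),
         "; supply latent_basis explicitly for larger d")
  }
  diag(p_star)[, free[seq_len(d)], drop = FALSE]
}

# default cluster templates as Fourier coefficients (orthonormal basis,
# p* columns: constant, then sin/cos pairs). All clusters share the mean
# level (about 90 um) and a pronounced temporal dip at 0 degrees (the
# harmonic-1 cosine term); they differ in higher-harmonic shape features,
# with deliberate energy at the top harmonic so the generating order is
# identifiable from data.
.default_templates <- function(K, p_star = 11L, mean_level = 90,
                               dip_um = 27) {
  amp <- function(um) um / sqrt(2 / 360)     # um amplitude -> coefficient
  Tm <- matrix(0, K, p_star)
  Tm[, 1] <- mean_level * sqrt(360)
  Tm[, 3] <- -amp(dip_um)                    # cos(t): minimum at 0 degrees
  H <- (p_star - 1) %/% 2
  # shape features: per-cluster signatures in harmonics 2..H
  set_coef <- function(k, m, sin_um, cos_um) {
    if (m <= H) {
      Tm[k, 2 * m] <<- Tm[k, 2 * m] + amp(sin_um)
      Tm[k, 2 * m + 1] <<- Tm[k, 2 * m + 1] + amp(cos_um)
    }
  }
  for (k in seq_len(K)) {
    phase <- 2 * pi * (k - 1) / K
    set_coef(k, 2, 7 * cos(phase), -7 * sin(phase))
    set_coef(k, 3, 5 * sin(phase), 5 * cos(phase))
    set_coef(k, H, 6 * cos(phase + pi / 4), 6 * sin(phase + pi / 4))
  }
  Tm
}

#' Specification of a synthetic circular-profile cohort
#'
#' Defines K cluster templates (band-limited circular curves around 90 um
#' with a 27 um temporal dip at 0 degrees), within-cluster variation
#' concentrated in a d-dimensional subspace of the basis coefficients plus
#' isotropic coefficient noise, optional rare spike outliers, and
#' cluster-linked clinical covariates.
#'
#' @param K number of clusters.
#' @param n_per_cluster samples per cluster.
#' @param p_star generating Fourier basis order (odd).
#' @param d latent subspace dimension.
#' @param latent_sd standard deviations of the d latent directions
#'   (recycled). The defaults make the shared shape modes the dominant
#'   source of pointwise variation, as in real rim profiles where common
#'   anatomical variation dwarfs the subtler cluster-specific shape.
#' @param latent_basis p_star x d orthonormal matrix of within-cluster
#'   latent directions; default fixed shape modes (harmonic-1 and
#'   harmonic-4 sines) orthogonal to the default templates' differences.
#' @param noise_sd isotropic coefficient noise sd.
#' @param level_sd per-sample overall thickness level sd in micrometers
#'   (spread of the constant Fourier coordinate); removed by
#'   normalization.
#' @param templates K x p_star coefficient matrix; default
#'   shape-differentiated templates.
#' @param n_outliers number of spike outliers to inject downstream.
#' @param outlier_magnitude spike size in units of the max pointwise sd.
#' @param covariate_effects K x 9 cluster-mean covariate table.
#' @param covariate_sd per-covariate noise sd (named, recycled).
#' @param grid the shared \code{\link{angular_grid}}.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(K = 3L, n_per_cluster = 200L, p_star = 11L,
                           d = 2L, latent_sd = c(250, 180),
                           latent_basis = .default_latent_basis(p_star, d),
                           noise_sd = 15, level_sd = 9,
                           templates = .default_templates(K, p_star),
                           n_outliers = 0L, outlier_magnitude = 6,
                           covariate_effects = default_covariate_effects(K),
                           covariate_sd = .default_covariate_sd(),
                           grid = angular_grid()) {
  if (K < 1) stop("K must be at least 1")
  if (p_star %% 2 == 0) stop("p_star must be odd")
  if (nrow(templates) != K || ncol(templates) != p_star) {
    stop("templates must be K x p_star")
  }
  Psi <- fourier_design(grid, p_star)
  tmpl_curves <- templates %*% t(Psi)
  if (any(tmpl_curves <= 0)) stop("templates must be strictly positive on the grid")
  if (nrow(latent_basis) != p_star || ncol(latent_basis) != d) {
    stop("latent_basis must be p_star x d")
  }
  structure(list(K = as.integer(K), n_per_cluster = as.integer(n_per_cluster),
                 p_star = as.integer(p_star), d = as.integer(d),
                 latent_sd = rep_len(latent_sd, d),
                 latent_basis = latent_basis,
                 noise_sd = noise_sd, level_sd = level_sd,
                 templates = templates,
                 n_outliers = as.integer(n_outliers),
                 outlier_magnitude = outlier_magnitude,
                 covariate_effects = covariate_effects,
                 covariate_sd = covariate_sd, grid = grid),
            class = "synthetic_spec")
}

#' Simulate a cohort of circular profiles from the mixture model
#'
#' Per sample: draw a cluster z, latent eta ~ N(0, diag(latent_sd^2)),
#' coefficient perturbation gamma = U eta + eps with eps ~
#' N(0, noise_sd^2 I) (U the spec's orthonormal latent basis), plus a
#' per-sample overall thickness level shift of sd \code{level_sd}
#' micrometers on the constant coordinate; the curve is
#' template_z + sum_j gamma_j psi_j on the grid. Ages are drawn uniformly
#' in \code{age_range}; eyes alternate OD/OS. Negative values (a
#' pathological parameterization) are clipped at zero with a warning.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param age_range uniform age range, default [40, 50) (one stratum).
#' @return List: \code{profiles} (a \code{profile_set}), \code{labels}
#'   (true cluster per sample, named), \code{gamma} (true coefficients),
#'   \code{U} (the latent subspace used).
#' @export
simulate_profiles <- function(spec, seed = 1L, age_range = c(40, 50)) {
  set.seed(seed)
  n <- spec$K * spec$n_per_cluster
  z <- rep(seq_len(spec$K), each = spec$n_per_cluster)
  U <- spec$latent_basis
  eta <- matrix(stats::rnorm(n * spec$d), n) %*% diag(spec$latent_sd, spec$d)
  eps <- matrix(stats::rnorm(n * spec$p_star, sd = spec$noise_sd), n)
  gamma <- spec$templates[z, , drop = FALSE] + eta %*% t(U) + eps
  gamma[, 1] <- gamma[, 1] + stats::rnorm(n, sd = spec$level_sd * sqrt(360))
  Psi <- fourier_design(spec$grid, spec$p_star)
  vals <- gamma %*% t(Psi)
  if (any(vals < 0)) {
    warning(sum(vals < 0), " negative values clipped at zero")
    vals[vals < 0] <- 0
  }
  ids <- sprintf("S%04d", seq_len(n))
  prof <- profile_set(vals, grid = spec$grid, sample_id = ids,
                      eye = rep_len(c("OD", "OS"), n),
                      age = stats::runif(n, age_range[1], age_range[2]))
  list(profiles = prof, labels = stats::setNames(z, ids), gamma = gamma, U = U)
}

#' Inject single-angle spike outliers
#'
#' Each chosen sample gets one angular position raised to
#' max_l mean + magnitude * max_l sd (pointwise statistics of the input
#' set), so the spike exceeds the outlier threshold exactly when
#' magnitude > factor (default detection factor 3.5).
#'
#' @param x a \code{profile_set}.
#' @param count number of samples to spike.
#' @param magnitude spike height in units of the maximal pointwise sd.
#' @param seed integer seed for the choice of samples and angles.
#' @return List: \code{profiles} (modified set), \code{outlier_ids}
#'   (character sample ids; empty when count = 0).
#' @export
inject_outliers <- function(x, count, magnitude = 6, seed = 1L) {
  if (count > nrow(x$values)) stop("count exceeds the number of samples")
  if (count == 0) return(list(profiles = x, outlier_ids = character(0)))
  set.seed(seed)
  st <- curve_stats(x)
  spike <- max(st$mean_curve) + magnitude * max(st$sd_curve)
  idx <- sample.int(nrow(x$values), count)
  vals <- x$values
  for (i in idx) {
    vals[i, sample.int(ncol(vals), 1)] <- spike
  }
  prof <- profile_set(vals, grid = x$grid, sample_id = x$sample_id,
                      eye = x$eye, age = x$age, normalized = x$normalized)
  list(profiles = prof, outlier_ids = x$sample_id[idx])
}

#' Simulate cluster-linked clinical covariates
#'
#' Each sample's covariate is its cluster's mean (from the effect table)
#' plus independent Gaussian noise.
#'
#' @param labels named vector of cluster labels (names = sample ids).
#' @param effects K x 9 cluster-mean table (rows indexed by cluster).
#' @param sd per-covariate noise sd (named vector, recycled over columns).
#' @param seed integer seed.
#' @return data.frame with \code{sample_id} and the nine covariates.
#' @export
simulate_covariates <- function(labels,
                                effects = default_covariate_effects(max(labels)),
                                sd = .default_covariate_sd(), seed = 1L) {
  if (max(labels) > nrow(effects)) {
    stop("effect table has no row for cluster ", max(labels))
  }
  set.seed(seed)
  n <- length(labels)
  nm <- colnames(effects)
  sd <- rep_len(sd, length(nm))
  vals <- effects[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * length(nm)), n) %*% diag(sd, length(nm))
  out <- data.frame(sample_id = names(labels), check.names = FALSE)
  out[nm] <- as.data.frame(vals)
  rownames(out) <- NULL
  out
}

#' Truth table for a simulated cohort
#'
#' @param labels named true-cluster vector from
#'   \code{\link{simulate_profiles}}.
#' @param outlier_ids ids spiked by \code{\link{inject_outliers}}.
#' @return data.frame: sample_id, true_cluster, is_outlier.
#' @export
truth_table <- function(labels, outlier_ids = character(0)) {
  data.frame(sample_id = names(labels),
             true_cluster = unname(labels),
             is_outlier = names(labels) %in% outlier_ids)
}
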