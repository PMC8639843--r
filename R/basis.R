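#' Orthonormal Fourier design matrix on the angular grid
#'
#' Column 1 is the constant function 1/sqrt(360); columns 2m and 2m + 1 are
#' sqrt(2/360) sin(2 pi m t / 360) and sqrt(2/360) cos(2 pi m t / 360) for
#' harmonics m = 1 .. (p - 1)/2. Under this normalization the functions are
#' orthonormal with respect to the continuous inner product on [0, 360), and
#' on the uniform grid the Gram matrix of the columns is (L/360) I as long
#' as all harmonics are below the Nyquist order L/2.
#'
#' @param grid an \code{\link{angular_grid}}.
#' @param p odd number of basis functions, 1 <= p <= L.
#' @return L x p design matrix.
#' @export
fourier_design <- function(grid, p) {
  p <- as.integer(p)
  if (p %% 2L == 0L) stop("p must be odd (constant plus sine/cosine pairs)")
  if (p < 1L || p > grid$L) stop("p must lie in 1..L")
  t <- grid$angles
  Psi <- matrix(0, nrow = grid$L, ncol = p)
  Psi[, 1] <- 1 / sqrt(360)
  if (p > 1L) {
    for (m in seq_len((p - 1L) %/% 2L)) {
      w <- 2 * pi * m * t / 360
      Psi[, 2 * m]     <- sqrt(2 / 360) * sin(w)
      Psi[, 2 * m + 1] <- sqrt(2 / 360) * cos(w)
    }
  }
  Psi
}

#' Fit Fourier expansion coefficients by least squares
#'
#' Projects each curve onto the span of the first p orthonormal Fourier
#' functions. On the uniform periodic grid ordinary least squares equals the
#' discrete Fourier projection, so band-limited curves are reproduced
#' exactly.
#'
#' @param x a \code{\link{profile_set}}.
#' @param p odd number of basis functions.
#' @return An object of class \code{coefficient_set}: list with \code{gamma}
#'   (n x p coefficient matrix), \code{p}, \code{grid}, \code{sample_id}.
#' @export
fit_coefficients <- function(x, p) {
  Psi <- fourier_design(x$grid, p)
  G <- crossprod(Psi)
  gamma <- t(solve(G, crossprod(Psi, t(x$values))))
  dimnames(gamma) <- list(x$sample_id, paste0("gamma_", seq_len(ncol(gamma))))
  structure(list(gamma = gamma, p = as.integer(p), grid = x$grid,
                 sample_id = x$sample_id),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("coefficient_set:", nrow(x$gamma), "curves, p =", x$p,
      "Fourier basis functions\n")
  invisible(x)
}

#' Reconstruct curves from Fourier coefficients
#'
#' @param coeffs a \code{coefficient_set}.
#' @param grid evaluation grid; defaults to the grid the coefficients were
#'   fit on. Must share the 360-degree period.
#' @return A \code{\link{profile_set}} of the reconstructed curves.
#' @export
reconstruct <- function(coeffs, grid = coeffs$grid) {
  if (!isTRUE(all.equal(grid$period, 360))) {
    stop("evaluation grid period must be 360 degrees")
  }
  Psi <- fourier_design(grid, coeffs$p)
  vals <- coeffs$gamma %*% t(Psi)
  # reconstructions can carry tiny negative ripple; keep as-is (caller decides)
  profile_set(vals, grid = grid, sample_id = coeffs$sample_id)
}

#' Pointwise mean, standard deviation and total variation of a curve set
#'
#' The mean and standard deviation are computed pointwise over samples with
#' the n - 1 denominator for the sd. Total variation is the circular
#' integral of squared deviations from the pointwise mean, summed over
#' curves and divided by n - 1:
#' TV = 1/(n-1) sum_i integral (X_i - Xbar)^2 dt, with the rectangle rule
#' (Delta t = grid step). This equals Delta t times the trace of the
#' pointwise sample covariance matrix.
#'
#' @param x a \code{profile_set} (or plain matrix on a known grid).
#' @param grid grid when \code{x} is a matrix.
#' @return List of class \code{curve_stats}: \code{mean_curve},
#'   \code{sd_curve}, \code{tv}, \code{n}.
#' @export
curve_stats <- function(x, grid = NULL) {
  if (inherits(x, "profile_set")) {
    vals <- x$values
    grid <- x$grid
  } else {
    vals <- as.matrix(x)
    if (is.null(grid)) grid <- angular_grid(ncol(vals))
  }
  n <- nrow(vals)
  if (n < 2) stop("at least two curves are needed for sd and total variation")
  mean_curve <- colMeans(vals)
  dev <- sweep(vals, 2, mean_curve)
  var_curve <- colSums(dev^2) / (n - 1)
  structure(list(mean_curve = mean_curve, sd_curve = sqrt(var_curve),
                 tv = sum(var_curve) * grid$step, n = n),
            class = "curve_stats")
}

# residual variation of the p-term approximation, same normalization as TV
.residual_variation <- function(x, p) {
  rec <- reconstruct(fit_coefficients(x, p))
  n <- nrow(x$values)
  sum((rec$values - x$values)^2) / (n - 1) * x$grid$step
}

#' Fraction of variation explained by a p-term Fourier approximation
#'
#' FVE(p) = (TV - 1/(n-1) sum_i integral (X_i^p - X_i)^2 dt) / TV, where
#' X_i^p is the p-term reconstruction and integrals use the circular
#' rectangle rule. Equals 1 when curves are band-limited within the basis.
#'
#' @param x a \code{profile_set} with n >= 2 and TV > 0.
#' @param p odd basis order.
#' @return Scalar fraction in (-Inf, 1].
#' @export
fve <- function(x, p) {
  tv <- curve_stats(x)$tv
  if (tv <= 0) stop("total variation is zero; FVE undefined (identical curves)")
  (tv - .residual_variation(x, p)) / tv
}

#' Select the smallest basis order whose FVE exceeds a threshold
#'
#' Scans odd candidate orders in ascending order and returns the smallest
#' with FVE strictly above \code{threshold}. If none qualifies the largest
#' candidate is returned with attribute \code{converged = FALSE} and a
#' warning.
#'
#' @param x a \code{profile_set}.
#' @param threshold FVE threshold in (0, 1); default 0.99.
#' @param candidates ascending odd integers to scan.
#' @return Chosen p (integer) with attributes \code{fve} (named vector of
#'   the FVE values computed) and \code{converged}.
#' @export
select_p <- function(x, threshold = 0.99, candidates = seq(1L, 41L, by = 2L)) {
  if (!length(candidates)) stop("no candidate basis orders supplied")
  if (threshold >= 1) stop("threshold must be below 1")
  if (is.unsorted(candidates)) stop("candidates must be sorted ascending")
  fves <- numeric(0)
  for (p in candidates) {
    f <- fve(x, p)
    fves[as.character(p)] <- f
    if (f > threshold) {
      return(structure(as.integer(p), fve = fves, converged = TRUE))
    }
  }
  warning("no candidate reached FVE > ", threshold,
          "; returning the largest candidate")
  structure(as.integer(candidates[length(candidates)]),
            fve = fves, converged = FALSE)
}

#' Per-cluster templates: mean curve, size and total variation
#'
#' For each cluster, the pointwise mean curve (the cluster template), its
#' Fourier coefficients at the pipeline's basis order, the cluster size, and
#' the within-cluster total variation (the trace of the within-cluster
#' sample covariance matrix times the grid step; NA for singletons).
#'
#' @param x a \code{profile_set}.
#' @param labels per-sample cluster labels (any atomic type).
#' @param p odd basis order used when exporting template coefficients.
#' @return List of class \code{cluster_templates}: per-cluster list with
#'   \code{label}, \code{size}, \code{mean_curve}, \code{coef}, \code{tv}.
#' @export
cluster_templates <- function(x, labels, p = 11L) {
  if (length(labels) != nrow(x$values)) stop("labels must match sample count")
  labs <- sort(unique(labels))
  Psi <- fourier_design(x$grid, p)
  G <- crossprod(Psi)
  out <- lapply(labs, function(lb) {
    idx <- which(labels == lb)
    if (!length(idx)) stop("cluster ", lb, " has no members")
    vals <- x$values[idx, , drop = FALSE]
    m <- colMeans(vals)
    tv <- if (length(idx) >= 2) {
      dev <- sweep(vals, 2, m)
      sum(dev^2) / (length(idx) - 1) * x$grid$step
    } else NA_real_
    list(label = lb, size = length(idx), mean_curve = m,
         coef = drop(solve(G, crossprod(Psi, m))), tv = tv)
  })
  names(out) <- as.character(labs)
  class(out) <- "cluster_templates"
  out
}

#' Export cluster templates as a flat table
#'
#' One row per cluster: id, size, the template's basis coefficients and the
#' within-cluster total variation.
#'
#' @param templates result of \code{\link{cluster_templates}}.
#' @return data.frame suitable for \code{write.csv}.
#' @export
templates_table <- function(templates) {
  do.call(rbind, lapply(templates, function(tp) {
    co <- as.list(tp$coef)
    names(co) <- paste0("gamma_", seq_along(co))
    cbind(data.frame(cluster = tp$label, size = tp$size),
          as.data.frame(co), data.frame(total_variation = tp$tv))
  }))
}
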