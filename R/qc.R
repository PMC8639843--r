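#' Outlier-curve threshold
#'
#' A curve is called an outlier if any of its points exceeds
#' X_out = max_l mean(X(t_l)) + factor * max_l sd(X(t_l)),
#' with the pointwise mean and sd taken over the full input set (n - 1
#' denominator for the sd) and the two maxima taken separately over the
#' angular positions.
#'
#' @param x a \code{\link{profile_set}} with n >= 2.
#' @param factor multiplier on the maximal pointwise sd; default 3.5.
#' @return Scalar threshold in the units of the curves.
#' @export
outlier_threshold <- function(x, factor = 3.5) {
  st <- curve_stats(x)
  max(st$mean_curve) + factor * max(st$sd_curve)
}

#' Flag outlier curves in a single pass
#'
#' The threshold is computed once on the full set; it is not recomputed
#' after removals.
#'
#' @param x a \code{profile_set} with n >= 2.
#' @param factor threshold factor; default 3.5.
#' @return List of class \code{outlier_report}: \code{threshold},
#'   \code{factor}, \code{flagged} (named logical), \code{max_value}
#'   (per-sample maximum).
#' @export
flag_outliers <- function(x, factor = 3.5) {
  thr <- outlier_threshold(x, factor)
  mx <- apply(x$values, 1, max)
  flagged <- mx > thr
  names(flagged) <- x$sample_id
  structure(list(threshold = thr, factor = factor, flagged = flagged,
                 max_value = mx),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report: threshold", format(x$threshold), "(factor",
      x$factor, ");", sum(x$flagged), "of", length(x$flagged),
      "curves flagged\n")
  invisible(x)
}

#' Drop flagged outlier curves
#'
#' @param x a \code{profile_set}.
#' @param report an \code{outlier_report} for the same set (computed if
#'   missing).
#' @param factor threshold factor when the report is computed here.
#' @return A \code{profile_set} without the flagged curves.
#' @export
remove_outliers <- function(x, report = flag_outliers(x, factor), factor = 3.5) {
  subset_profiles(x, !report$flagged)
}

#' Normalize curves to unit-integral circular densities
#'
#' Divides each curve by its circular rectangle-rule integral
#' sum_l X_i(t_l) * Delta t, so every curve integrates to one and can be
#' read as a probability density around the circle. Idempotent and
#' invariant to positive rescaling of the input.
#'
#' @param x a \code{profile_set}; every row must have a positive integral.
#' @return Normalized \code{profile_set} with the \code{normalized} flag set.
#' @export
normalize_profiles <- function(x) {
  ints <- rowSums(x$values) * x$grid$step
  bad <- which(ints <= 0)
  if (length(bad)) {
    stop("nonpositive circular integral for sample(s): ",
         paste(x$sample_id[utils::head(bad, 5)], collapse = ", "))
  }
  profile_set(x$values / ints, grid = x$grid, sample_id = x$sample_id,
              eye = x$eye, age = x$age, normalized = TRUE)
}

#' QC report table
#'
#' @param report an \code{outlier_report}.
#' @return data.frame with sample_id, flagged, max_value, threshold.
#' @export
qc_table <- function(report) {
  data.frame(sample_id = names(report$flagged),
             flagged = unname(report$flagged),
             max_value = unname(report$max_value),
             threshold = report$threshold)
}
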