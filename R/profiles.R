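#' Angular measurement grid
#'
#' Defines the shared circular grid on which all profiles are sampled.
#' Position \code{l} corresponds to the angle \code{step * (l - 1)} degrees,
#' so the default 180-point grid holds angles 0, 2, ..., 358. The grid is
#' periodic: angle 360 is the same point as angle 0.
#'
#' @param L number of angular positions.
#' @param step spacing between positions in degrees; must satisfy
#'   \code{L * step == 360}.
#' @return An object of class \code{angular_grid} with elements \code{L},
#'   \code{step}, \code{angles} and \code{period}.
#' @export
angular_grid <- function(L = 180L, step = 360 / L) {
  L <- as.integer(L)
  if (L < 1L) stop("grid needs at least one angular position")
  if (!isTRUE(all.equal(L * step, 360))) {
    stop("L * step must equal 360 degrees (got ", L * step, ")")
  }
  structure(
    list(L = L, step = step, angles = step * (seq_len(L) - 1), period = 360),
    class = "angular_grid"
  )
}

#' @export
print.angular_grid <- function(x, ...) {
  cat("angular_grid:", x$L, "positions every", x$step,
      "degrees on [0, 360)\n")
  invisible(x)
}

#' Set of circular profiles
#'
#' Container for \code{n} circular curves sampled on a common
#' \code{\link{angular_grid}}, with per-sample metadata. Values are
#' thickness in micrometers before normalization and dimensionless
#' circular densities after.
#'
#' @param values n x L numeric matrix, one row per sample.
#' @param grid an \code{angular_grid}; defaults to the 180-point grid.
#' @param sample_id character vector of unique sample identifiers.
#' @param eye "OD" or "OS" per sample (optional).
#' @param age numeric age in years per sample (optional).
#' @param normalized logical flag: TRUE once rows integrate to one.
#' @return An object of class \code{profile_set}.
#' @export
profile_set <- function(values, grid = angular_grid(ncol(values)),
                        sample_id = NULL, eye = NULL, age = NULL,
                        normalized = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != grid$L) {
    stop("values has ", ncol(values), " columns but the grid has ",
         grid$L, " positions")
  }
  if (!all(is.finite(values))) {
    bad <- which(!apply(is.finite(values), 1, all))
    stop("non-finite profile values in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- nrow(values)
  if (is.null(sample_id)) sample_id <- sprintf("S%04d", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1])
  }
  if (length(sample_id) != n) stop("sample_id length must match rows")
  if (!is.null(eye) && length(eye) != n) stop("eye length must match rows")
  if (!is.null(age) && length(age) != n) stop("age length must match rows")
  rownames(values) <- sample_id
  structure(
    list(grid = grid, values = values, sample_id = sample_id,
         eye = eye, age = age, normalized = isTRUE(normalized)),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat("profile_set:", nrow(x$values), "curves on", x$grid$L,
      "angular positions",
      if (x$normalized) "(normalized circular densities)" else "(raw)", "\n")
  invisible(x)
}

#' Number of curves in a profile set
#' @param x a \code{profile_set}.
#' @return integer count of samples.
#' @export
n_profiles <- function(x) nrow(x$values)

#' Subset a profile set by row
#'
#' @param x a \code{profile_set}.
#' @param keep logical or integer index of samples to retain.
#' @return A \code{profile_set} with the selected rows and their metadata.
#' @export
subset_profiles <- function(x, keep) {
  profile_set(x$values[keep, , drop = FALSE], grid = x$grid,
              sample_id = x$sample_id[keep],
              eye = if (!is.null(x$eye)) x$eye[keep],
              age = if (!is.null(x$age)) x$age[keep],
              normalized = x$normalized)
}

# header label for the angle that position l maps to in the exported dialect:
# internal angle 0 is written as the wrap-around column t_360
.angle_headers <- function(grid) {
  deg <- grid$angles
  deg[deg == 0] <- 360
  sprintf("t_%03d", as.integer(round(deg)))
}

#' Read circular profiles from a wide CSV
#'
#' Expects columns \code{sample_id}, \code{eye}, \code{age} and one numeric
#' column per angular position labeled \code{t_002 ... t_360} (degrees).
#' The exported labels run 2..360 while the internal grid runs 0..358; by
#' periodicity the column labeled 360 degrees is stored at internal angle 0.
#'
#' @param path CSV file path.
#' @param grid target \code{angular_grid}.
#' @return A \code{profile_set}.
#' @export
read_profiles <- function(path, grid = angular_grid()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  expected <- .angle_headers(grid)
  have <- grepl("^t_[0-9]+$", names(df))
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df)[have], expected)
  if (length(missing) || length(extra)) {
    stop("angular column mismatch; missing: [",
         paste(missing, collapse = ", "), "]; unexpected: [",
         paste(extra, collapse = ", "), "]")
  }
  vals <- df[, expected, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("non-numeric thickness in column ", expected[j], ", row id ",
           if ("sample_id" %in% names(df)) df$sample_id[bad] else bad)
    }
  }
  profile_set(as.matrix(vals), grid = grid,
              sample_id = if ("sample_id" %in% names(df)) df$sample_id,
              eye = if ("eye" %in% names(df)) df$eye,
              age = if ("age" %in% names(df)) df$age)
}

#' Write circular profiles to the wide CSV dialect
#'
#' Inverse of \code{\link{read_profiles}}: one row per sample, angular
#' columns labeled \code{t_002 ... t_360}.
#'
#' @param x a \code{profile_set}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(x, path) {
  df <- data.frame(sample_id = x$sample_id,
                   eye = if (!is.null(x$eye)) x$eye else NA,
                   age = if (!is.null(x$age)) x$age else NA,
                   check.names = FALSE)
  # 17 significant digits so finite doubles survive the round trip exactly
  vals <- as.data.frame(matrix(sprintf("%.17g", x$values),
                               nrow(x$values)))
  names(vals) <- .angle_headers(x$grid)
  utils::write.csv(cbind(df, vals), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The nine clinical covariates used for metaclustering
#'
#' Intraocular pressure (mmHg), central corneal thickness (um), axial
#' length (mm), rim area (mm^2), disc area (mm^2), disc diameter (mm),
#' vertical cup-to-disc ratio, average cup-to-disc ratio, cup volume (mm^3).
#'
#' @return Character vector of the canonical covariate column names.
#' @export
covariate_names <- function() {
  c("iop", "cct", "axial_length", "rim_area", "disc_area",
    "disc_diameter", "vertical_cdr", "average_cdr", "cup_volume")
}

#' Read a per-sample clinical covariate table
#'
#' Keeps the recognized covariate columns (see \code{\link{covariate_names}})
#' and reports any unrecognized ones.
#'
#' @param path CSV with a \code{sample_id} column plus covariates.
#' @return data.frame with \code{sample_id} and the recognized covariates.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("covariate CSV needs a sample_id column")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in covariate table: ",
         df$sample_id[duplicated(df$sample_id)][1])
  }
  known <- intersect(covariate_names(), names(df))
  if (!length(known)) stop("no recognized covariate columns found")
  unknown <- setdiff(names(df), c("sample_id", covariate_names()))
  if (length(unknown)) {
    message("ignoring unrecognized covariate columns: ",
            paste(unknown, collapse = ", "))
  }
  absent <- setdiff(covariate_names(), known)
  if (length(absent)) {
    warning("covariates absent from table: ", paste(absent, collapse = ", "))
  }
  out <- df[, c("sample_id", known), drop = FALSE]
  for (v in known) {
    if (!all(is.finite(out[[v]]) | is.na(out[[v]]))) {
      stop("non-finite values in covariate ", v)
    }
  }
  out$sample_id <- as.character(out$sample_id)
  out
}

#' Stratify profiles into the three age groups
#'
#' Half-open strata: group 1 is ages [40, 50), group 2 is [50, 60),
#' group 3 is 60 and older.
#'
#' @param x a \code{profile_set} with ages recorded.
#' @return Named list of three \code{profile_set}s ("1", "2", "3");
#'   empty strata are dropped.
#' @export
stratify_by_age <- function(x) {
  if (is.null(x$age)) stop("profile set has no age metadata")
  bad <- which(is.na(x$age) | x$age < 40)
  if (length(bad)) {
    stop("age missing or below 40 for sample(s): ",
         paste(x$sample_id[utils::head(bad, 5)], collapse = ", "))
  }
  stratum <- findInterval(x$age, c(40, 50, 60))
  out <- list()
  for (g in 1:3) {
    if (any(stratum == g)) out[[as.character(g)]] <- subset_profiles(x, stratum == g)
  }
  out
}

#' Age stratum labels for a vector of ages
#' @param age numeric ages (>= 40).
#' @return Integer labels 1, 2, 3 for ages [40,50), [50,60), [60, Inf).
#' @export
age_stratum <- function(age) {
  if (any(is.na(age) | age < 40)) stop("ages must all be >= 40")
  findInterval(age, c(40, 50, 60))
}
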