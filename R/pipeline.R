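#' Run the full circular functional clustering pipeline
#'
#' Stratifies profiles by age, then per stratum: selects the basis order by
#' FVE (unless fixed), flags and removes outlier curves, optionally
#' normalizes to circular densities, fits Fourier coefficients, clusters
#' with the discriminative functional mixture model over a range of K,
#' computes cluster templates, metaclusters the clusters on their mean
#' clinical covariates with sparse feature selection, registers metacluster
#' correspondence across strata, and runs the comparative point-clustering
#' baselines. A manifest of counts and choices at every stage is returned
#' and, when \code{out_dir} is given, written to disk along with labels,
#' templates, weights and the QC report.
#'
#' @param profiles a \code{\link{profile_set}} with ages.
#' @param covariates covariate data.frame (see
#'   \code{\link{read_covariates}}); NULL skips metaclustering.
#' @param p fixed basis order; NULL selects by FVE.
#' @param fve_threshold FVE threshold for basis-order selection.
#' @param outlier_factor threshold factor of the outlier rule.
#' @param normalize normalize curves to unit circular integral.
#' @param K_range candidate cluster counts for the DFM.
#' @param variants DFM variant ids to scan.
#' @param d latent dimension (NULL: K - 1 per fit).
#' @param wbounds candidate sparsity bounds for metaclustering.
#' @param cut_height flat-cut height on the rescaled dendrogram.
#' @param baseline_methods baselines to run (NULL skips them).
#' @param baseline_K_range candidate K for the baselines.
#' @param seed integer seed for every stochastic stage.
#' @param n_restarts,max_iter EM controls.
#' @param out_dir output directory for artifacts; NULL writes nothing.
#' @return List of class \code{pipeline_run}: \code{manifest}, per-stratum
#'   \code{strata} (each with qc, p, solution, templates, metacluster,
#'   baselines), and \code{correspondence}.
#' @export
run_pipeline <- function(profiles, covariates = NULL, p = NULL,
                         fve_threshold = 0.99, outlier_factor = 3.5,
                         normalize = TRUE, K_range = 2:12,
                         variants = dfm_variants()$id, d = NULL,
                         wbounds = 2:5, cut_height = 0.1,
                         baseline_methods = c("kmeans", "kmedoids", "gmm"),
                         baseline_K_range = 2:10, seed = 1L,
                         n_restarts = 5L, max_iter = 200L,
                         out_dir = NULL) {
  strata <- stratify_by_age(profiles)
  runs <- list()
  manifest <- list(seed = seed, normalize = normalize,
                   n_input = n_profiles(profiles),
                   strata = list())
  for (g in names(strata)) {
    ps <- strata[[g]]
    rep_g <- flag_outliers(ps, factor = outlier_factor)
    kept <- remove_outliers(ps, rep_g)
    work <- if (normalize) normalize_profiles(kept) else kept
    p_g <- if (is.null(p)) as.integer(select_p(work, threshold = fve_threshold)) else as.integer(p)
    coeffs <- fit_coefficients(work, p_g)
    sol <- select_K(coeffs, K_range = K_range, variants = variants, d = d,
                    seed = seed, n_restarts = n_restarts,
                    max_iter = max_iter)
    labels <- stats::setNames(sol$labels, work$sample_id)
    tmpl <- cluster_templates(work, labels, p = p_g)
    meta <- NULL
    if (!is.null(covariates)) {
      M <- cluster_covariate_means(labels, covariates)
      wb <- if (length(wbounds) > 1) {
        as.numeric(select_wbound(M, wbounds = wbounds, seed = seed))
      } else wbounds
      sh <- sparse_hclust(M, wbound = wb)
      mlabels <- cut_metaclusters(sh, height = cut_height)
      meta <- list(M = M, wbound = wb, result = sh, labels = mlabels)
    }
    base <- NULL
    if (!is.null(baseline_methods)) {
      base <- lapply(baseline_methods, function(mth) {
        cluster_points(work, method = mth, K_range = baseline_K_range,
                       seed = seed)
      })
      names(base) <- baseline_methods
    }
    runs[[g]] <- list(profiles = work, qc = rep_g, p = p_g,
                      solution = sol, labels = labels, templates = tmpl,
                      metacluster = meta, baselines = base)
    manifest$strata[[g]] <- list(
      n_in = n_profiles(ps),
      n_outliers = sum(rep_g$flagged),
      n_clustered = n_profiles(kept),
      normalized = normalize,
      p = p_g,
      K = sol$K,
      variant = sol$model$variant,
      cluster_sizes = as.list(table(labels)),
      n_metaclusters = if (!is.null(meta)) length(unique(meta$labels)) else NULL,
      wbound = if (!is.null(meta)) meta$wbound else NULL,
      baseline_K = if (!is.null(base)) lapply(base, `[[`, "chosen_K") else NULL,
      baseline_dunn = if (!is.null(base)) lapply(base, `[[`, "dunn") else NULL)
  }
  corr <- NULL
  if (!is.null(covariates) && length(runs) >= 2) {
    metas <- lapply(runs, `[[`, "metacluster")
    corr <- correspond_metaclusters(lapply(metas, `[[`, "result"),
                                    lapply(metas, `[[`, "labels"),
                                    lapply(metas, `[[`, "M"))
    manifest$correspondence <- corr
  }
  out <- structure(list(manifest = manifest, strata = runs,
                        correspondence = corr),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run over", length(x$strata), "age strata\n")
  for (g in names(x$strata)) {
    m <- x$manifest$strata[[g]]
    cat("  stratum", g, ": n =", m$n_clustered, "(", m$n_outliers,
        "outliers removed ), p =", m$p, ", K =", m$K, "\n")
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the run manifest (JSON), per-stratum label / QC / template /
#' weight CSVs, and criterion traces.
#'
#' @param run a \code{pipeline_run}.
#' @param out_dir target directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_pipeline <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (g in names(run$strata)) {
    st <- run$strata[[g]]
    pre <- file.path(out_dir, paste0("stratum", g, "_"))
    utils::write.csv(data.frame(sample_id = names(st$labels),
                                cluster = unname(st$labels)),
                     paste0(pre, "labels.csv"), row.names = FALSE)
    utils::write.csv(qc_table(st$qc), paste0(pre, "qc.csv"),
                     row.names = FALSE)
    utils::write.csv(templates_table(st$templates),
                     paste0(pre, "templates.csv"), row.names = FALSE)
    utils::write.csv(st$solution$trace, paste0(pre, "criteria.csv"),
                     row.names = FALSE)
    if (!is.null(st$metacluster)) {
      w <- st$metacluster$result$weights
      utils::write.csv(data.frame(covariate = names(w), weight = unname(w),
                                  rank = rank(-w, ties.method = "first")),
                       paste0(pre, "weights.csv"), row.names = FALSE)
      utils::write.csv(data.frame(cluster = names(st$metacluster$labels),
                                  metacluster = unname(st$metacluster$labels)),
                       paste0(pre, "metaclusters.csv"), row.names = FALSE)
    }
  }
  if (!is.null(run$correspondence)) {
    utils::write.csv(run$correspondence,
                     file.path(out_dir, "correspondence.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
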