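# Circular visualization: curves drawn radially around the scan center,
# TSNIT orientation (0 degrees temporal, angles increasing clockwise).

.polar_xy <- function(angles_deg, r) {
  # clockwise from the positive x-axis (temporal at 0 degrees, to the right)
  th <- -angles_deg * pi / 180
  cbind(x = r * cos(th), y = r * sin(th))
}

.cluster_palette <- function(K) {
  grDevices::hcl.colors(max(K, 3), palette = "Dark 3")[seq_len(K)]
}

#' Circular plot of clustered curves with their templates
#'
#' One polar panel per cluster: member curves in the cluster color and the
#' cluster's mean curve (template) overlaid in bold black. Curves close
#' periodically (the value at 360 degrees rejoins the value at 0).
#'
#' @param x a \code{\link{profile_set}}.
#' @param labels per-sample cluster labels (default: one cluster).
#' @param templates optional \code{\link{cluster_templates}}; computed when
#'   missing and n allows.
#' @param file optional PNG path; when given, panels are written side by
#'   side to that file.
#' @param max_curves per-cluster cap on plotted member curves.
#' @return Invisibly, the vector of cluster labels plotted.
#' @export
plot_circular <- function(x, labels = rep(1L, nrow(x$values)),
                          templates = NULL, file = NULL, max_curves = 200L) {
  labs <- sort(unique(labels))
  if (is.null(templates) && nrow(x$values) >= 2) {
    templates <- cluster_templates(x, labels,
                                   p = min(11L, x$grid$L - 1 - (x$grid$L %% 2)))
  }
  cols <- .cluster_palette(length(labs))
  ang <- c(x$grid$angles, 360)
  if (!is.null(file)) {
    grDevices::png(file, width = 320 * length(labs), height = 340)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(1, length(labs)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  rmax <- max(x$values)
  for (i in seq_along(labs)) {
    idx <- which(labels == labs[i])
    graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                   asp = 1, axes = FALSE, xlab = "", ylab = "",
                   main = paste("cluster", labs[i]))
    for (j in utils::head(idx, max_curves)) {
      r <- c(x$values[j, ], x$values[j, 1])
      xy <- .polar_xy(ang, r)
      graphics::lines(xy[, 1], xy[, 2], col = cols[i], lwd = 0.5)
    }
    if (!is.null(templates)) {
      m <- templates[[as.character(labs[i])]]$mean_curve
      xy <- .polar_xy(ang, c(m, m[1]))
      graphics::lines(xy[, 1], xy[, 2], col = "black", lwd = 2.5)
    }
    graphics::text(rmax, 0, "T", cex = 0.8)
    graphics::text(0, rmax, "I", cex = 0.8)   # clockwise: inferior up-side
  }
  invisible(labs)
}

#' Dendrogram of the metaclustering with the flat cut
#'
#' Leaves are the functional-cluster ids; a horizontal line marks the cut
#' on the rescaled height axis and leaves are colored by metacluster.
#'
#' @param result a \code{metacluster_result}.
#' @param height cut threshold (rescaled tree, root at 1).
#' @param file optional PNG path.
#' @return Invisibly, the metacluster labels at the cut.
#' @export
plot_dendrogram <- function(result, height = 0.1, file = NULL) {
  labels <- cut_metaclusters(result, height = height)
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 420)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  tree <- result$tree
  scale <- max(tree$height)
  tree$height <- tree$height / scale
  graphics::plot(tree, main = "metaclusters", xlab = "functional cluster",
                 ylab = "rescaled merge height", sub = "")
  graphics::abline(h = height, lty = 2, col = "grey40")
  cols <- .cluster_palette(length(unique(labels)))
  ord <- tree$order
  graphics::mtext(side = 1, at = seq_along(ord),
                  text = tree$labels[ord],
                  col = cols[labels[tree$labels[ord]]], line = 1)
  invisible(labels)
}

#' Contour plots of key covariates per metacluster
#'
#' One 2-D kernel-density contour panel per metacluster on two covariates
#' (by default average CDR against cup volume). Metaclusters with too few
#' samples for density estimation are skipped with a warning.
#'
#' @param covs covariate data.frame with \code{sample_id}.
#' @param meta_labels per-sample metacluster labels (named by sample id).
#' @param x_var,y_var covariate names for the axes.
#' @param file optional PNG path.
#' @param min_n minimum samples per metacluster.
#' @return Invisibly, the metacluster ids plotted.
#' @export
plot_contours <- function(covs, meta_labels, x_var = "average_cdr",
                          y_var = "cup_volume", file = NULL, min_n = 10L) {
  groups <- sort(unique(meta_labels))
  idx <- match(names(meta_labels), covs$sample_id)
  xs <- covs[[x_var]][idx]; ys <- covs[[y_var]][idx]
  keep <- vapply(groups, function(g) sum(meta_labels == g) >= min_n, logical(1))
  if (any(!keep)) {
    warning("metacluster(s) skipped (fewer than ", min_n, " samples): ",
            paste(groups[!keep], collapse = ", "))
  }
  groups <- groups[keep]
  if (!length(groups)) return(invisible(groups))
  cols <- .cluster_palette(length(groups))
  if (!is.null(file)) {
    grDevices::png(file, width = 320 * length(groups), height = 340)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(1, length(groups)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (i in seq_along(groups)) {
    sel <- meta_labels == groups[i]
    kd <- MASS::kde2d(xs[sel], ys[sel], n = 50)
    graphics::contour(kd, main = paste("metacluster", groups[i]),
                      xlab = paste(x_var), ylab = paste(y_var, "(mm^3)"),
                      col = cols[i])
  }
  invisible(groups)
}
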