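make_covs <- function(labels, values_by_cluster) {
  # covariate table where each listed covariate is constant per cluster
  df <- data.frame(sample_id = names(labels))
  for (v in names(values_by_cluster)) {
    df[[v]] <- values_by_cluster[[v]][labels]
  }
  df
}

test_that("cluster covariate means aggregate per cluster", {
  labels <- setNames(c(1, 1, 2, 2), paste0("s", 1:4))
  covs <- data.frame(sample_id = paste0("s", 1:4),
                     average_cdr = c(1, 3, 10, 12),
                     cup_volume = c(0.1, 0.3, 1.0, 1.2))
  M <- cluster_covariate_means(labels, covs)
  expect_equal(unname(M$M[, "average_cdr"]), c(2, 11))
  expect_equal(unname(M$M[, "cup_volume"]), c(0.2, 1.1))
  expect_equal(M$sizes, c(2L, 2L))
  # single cluster: global means
  M1 <- cluster_covariate_means(setNames(rep(1, 4), paste0("s", 1:4)), covs)
  expect_equal(unname(M1$M[1, ]), c(6.5, 0.65))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  Mp <- cluster_covariate_means(labels[perm], covs)
  expect_equal(Mp$M, M$M)
  # samples without covariate rows are refused
  expect_error(cluster_covariate_means(setNames(1:2, c("s1", "zz")), covs),
               "zz")
})

test_that("symmetric two-covariate structure gets equal weights at the L1 boundary", {
  # two covariates carrying identical cluster structure
  M <- cbind(a = c(0, 0, 5, 5), b = c(10, 10, 20, 20))
  colnames(M) <- c("average_cdr", "cup_volume")
  res <- sparse_hclust(M, wbound = sqrt(2))
  expect_equal(unname(res$weights), c(1, 1) / sqrt(2), tolerance = 1e-6)
  # grid-search oracle over the constraint set {w >= 0, |w|_2 <= 1, |w|_1 <= wbound}:
  # the attained criterion ||D w||_2 is maximal at the returned weights
  D <- circlust:::.pairwise_sq(scale(M))
  crit <- function(w) sqrt(sum((D %*% w)^2))
  thetas <- seq(0, pi / 2, length.out = 2001)
  best <- max(vapply(thetas, function(th) {
    w <- c(cos(th), sin(th))
    if (sum(w) > sqrt(2) + 1e-12) w <- w * sqrt(2) / sum(w)
    crit(w)
  }, numeric(1)))
  expect_equal(crit(res$weights), best, tolerance = 1e-6)
})

test_that("constant covariates are weighted zero and constraints hold", {
  set.seed(19)
  M <- cbind(matrix(rnorm(8 * 3), 8), rep(5, 8))
  colnames(M) <- c("iop", "cct", "axial_length", "rim_area")
  res <- sparse_hclust(M, wbound = 1.5)
  expect_equal(unname(res$weights[["rim_area"]]), 0)
  # weight constraints at convergence, across wbounds and random matrices
  for (wb in c(1.2, 2, 3)) {
    Mr <- matrix(rnorm(10 * 9), 10, dimnames = list(NULL, covariate_names()))
    r <- sparse_hclust(Mr, wbound = wb)
    expect_lte(sqrt(sum(r$weights^2)), 1 + 1e-8)
    expect_lte(sum(r$weights), wb + 1e-6)
    expect_true(all(r$weights >= 0))
    expect_true(all(diff(r$tree$height) >= -1e-12))
  }
  expect_error(sparse_hclust(M, wbound = 0.5), "wbound")
  expect_error(sparse_hclust(matrix(1, 3, 2)), "zero")
})

test_that("at the loose L1 bound the weighted dissimilarity matches Euclidean", {
  # all features carry the same signal: weights equalize, and the weighted
  # dissimilarity is proportional to unweighted squared Euclidean distance
  base <- c(0, 0, 4, 4, 9)
  M <- cbind(base, base, base, base)
  colnames(M) <- c("iop", "cct", "rim_area", "disc_area")
  res <- sparse_hclust(M, wbound = 2)  # sqrt(4) = loosest bound
  ref <- as.matrix(stats::dist(scale(M)))^2
  got <- as.matrix(res$dist)
  ratio <- got[ref > 0] / ref[ref > 0]
  expect_lt(diff(range(ratio)), 1e-8)
})

test_that("flat cuts on the rescaled dendrogram partition the clusters", {
  # two near rows and one far row: rescaled heights are {small, 1}
  M <- rbind(c(0, 0), c(0.05, 0.05), c(10, 10))
  colnames(M) <- c("average_cdr", "cup_volume")
  rownames(M) <- c("c1", "c2", "c3")
  res <- sparse_hclust(M, wbound = sqrt(2))
  lab <- cut_metaclusters(res, height = 0.1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(lab[["c1"]], lab[["c2"]])
  expect_false(lab[["c1"]] == lab[["c3"]])
  # above the root: everything together
  expect_equal(length(unique(cut_metaclusters(res, height = 1.5))), 1)
  # below all merges: each leaf alone
  expect_equal(length(unique(cut_metaclusters(res, height = 1e-9))), 3)
})

test_that("the permutation gap statistic picks a sensible sparsity bound", {
  set.seed(43)
  # 10 cluster rows in two metagroups separated on two covariates
  M <- matrix(rnorm(10 * 9, 0, 0.2), 10,
              dimnames = list(NULL, covariate_names()))
  M[6:10, "average_cdr"] <- M[6:10, "average_cdr"] + 3
  M[6:10, "cup_volume"] <- M[6:10, "cup_volume"] + 3
  wb <- select_wbound(M, wbounds = 2:5, n_perm = 10, seed = 1)
  expect_true(wb %in% 2:5)
  expect_length(attr(wb, "gaps"), 4)
})

test_that("metaclusters correspond across strata by covariate proximity", {
  build <- function(M) {
    rownames(M) <- paste0("c", seq_len(nrow(M)))
    res <- sparse_hclust(M, wbound = sqrt(2))
    list(res = res, lab = cut_metaclusters(res, height = 0.1),
         M = structure(list(M = M, sizes = rep(10L, nrow(M))),
                       class = "cluster_covariate_matrix"))
  }
  # two strata whose two metaclusters sit at nearby covariate means
  M1 <- rbind(c(0.45, 0.10), c(0.451, 0.101), c(0.55, 0.20), c(0.549, 0.199))
  M2 <- rbind(c(0.46, 0.12), c(0.57, 0.22), c(0.571, 0.221))
  colnames(M1) <- colnames(M2) <- c("average_cdr", "cup_volume")
  a <- build(M1); b <- build(M2)
  corr <- correspond_metaclusters(list(`1` = a$res, `2` = b$res),
                                  list(`1` = a$lab, `2` = b$lab),
                                  list(`1` = a$M, `2` = b$M))
  s2 <- corr[corr$stratum == "2", ]
  expect_false(anyNA(s2$matched_to))          # both matched, none distinct
  # the low-CDR metacluster of stratum 2 maps to the low-CDR one of stratum 1
  low1 <- a$lab[["c1"]]; low2 <- b$lab[["c1"]]
  expect_equal(s2$matched_to[s2$metacluster == low2], low1)
  # 3 vs 2 metaclusters: exactly one left distinct (pigeonhole)
  M3 <- rbind(c(0.45, 0.10), c(0.55, 0.20), c(0.65, 0.30))
  colnames(M3) <- c("average_cdr", "cup_volume")
  c3 <- build(M3)
  expect_equal(length(unique(c3$lab)), 3)
  corr2 <- correspond_metaclusters(list(`1` = c3$res, `2` = b$res),
                                   list(`1` = c3$lab, `2` = b$lab),
                                   list(`1` = c3$M, `2` = b$M))
  expect_equal(sum(is.na(corr2$matched_to)), 0)  # smaller side fully matched
  corr3 <- correspond_metaclusters(list(`1` = b$res, `2` = c3$res),
                                   list(`1` = b$lab, `2` = c3$lab),
                                   list(`1` = b$M, `2` = c3$M))
  expect_equal(sum(is.na(corr3$matched_to)), 1)  # larger side: one distinct
  # swapping stratum order inverts the correspondence
  m23 <- corr3[corr3$stratum == "2" & !is.na(corr3$matched_to), ]
  for (r in seq_len(nrow(m23))) {
    back <- corr2$matched_to[corr2$stratum == "2" &
                               corr2$metacluster == m23$matched_to[r]]
    expect_equal(back, m23$metacluster[r])
  }
})
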