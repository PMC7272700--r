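test_that("row z-scores match hand arithmetic and handle flat rows", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1))
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2))
  expect_warning(zf <- zscore_rows(matrix(c(2, 2, 2), 1)),
                 "zero-variance")
  expect_equal(as.numeric(zf), c(0, 0, 0))
  m <- matrix(rnorm(50), 10)
  expect_true(all(abs(rowMeans(zscore_rows(m))) < 1e-12))
})

test_that("k-means recovers well-separated blobs and is deterministic", {
  set.seed(3)
  centers <- rbind(c(8, 0, 0), c(0, 8, 0), c(0, 0, 8), c(-8, -8, -8))
  truth <- rep(1:4, each = 12)
  m <- centers[truth, ] + matrix(rnorm(48 * 3, sd = 0.3), 48, 3)
  cl <- kmeans_cluster(m, k = 4, n_init = 50, seed = 1)
  expect_equal(ari_oracle(cl$assignments$cluster, truth), 1)
  cl2 <- kmeans_cluster(m, k = 4, n_init = 50, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)

  same <- matrix(1, 6, 3)
  expect_equal(kmeans_cluster(same, k = 1, n_init = 2)$tot_withinss, 0)
  expect_error(kmeans_cluster(same, k = 10), "exceeds")

  # label order follows order_by means (descending)
  ord <- kmeans_cluster(m, k = 4, n_init = 50, seed = 1,
                        order_by = -as.numeric(truth))
  means_by_label <- tapply(-as.numeric(truth),
                           ord$assignments$cluster, mean)
  expect_true(all(diff(means_by_label) < 0))

  g <- glance(cl)
  expect_equal(g$n, 48)
  expect_equal(sum(unlist(g[grep("size_", names(g))])), 48)
})

test_that("fold-change %CV matches its definition and is scale-free", {
  fc <- counts_tbl(rbind(c(1, 2, 2, 2), c(1, 1, 2, 3)),
                   samples = c("C1", "L1", "L2", "L3"))
  sheet <- two_group_sheet(1, 3)
  sheet$group[1] <- "control"
  res <- fold_change_cv(fc, sheet)
  expect_equal(res$per_gene$cv_pct[1], 0)
  expect_equal(res$per_gene$cv_pct[2], 50)   # SD 1, mean 2

  fc10 <- counts_tbl(rbind(c(1, 2, 2, 2), c(1, 10, 20, 30)),
                     samples = c("C1", "L1", "L2", "L3"))
  res10 <- fold_change_cv(fc10, sheet)
  expect_equal(res10$per_gene$cv_pct[2], 50)
})

test_that("cumulative distributions step to 100% and pool consistently", {
  ec <- cumulative_fc_distribution(c(0.5, -1, 2, 1), rep("I", 4))
  expect_equal(ec$cum_pct, c(25, 50, 75, 100))
  expect_equal(ec$log2fc, sort(c(0.5, -1, 2, 1)))

  lfc <- rnorm(40)
  cl <- rep(1:4, 10)
  per <- cumulative_fc_distribution(lfc, cl)
  pooled <- cumulative_fc_distribution(lfc, rep(1, 40))
  expect_setequal(per$log2fc, pooled$log2fc)
  expect_true(all(tapply(per$cum_pct, per$cluster, max) == 100))
})

test_that("sample PCA separates planted groups and orders variance", {
  sim <- simulate_paired_counts(sim_config(seed = 2, n_genes = 800,
                                           n_mirnas = 10, frac_de = 0.2))
  norm <- normalize_counts(sim$mrna)
  pca <- sample_pca(norm, sim$samples)
  expect_true(all(diff(pca$var_explained) < 1e-8))
  expect_lte(sum(pca$var_explained), 1 + 1e-8)
  pc1 <- split(pca$scores$PC1, pca$scores$group)
  gap <- abs(mean(pc1$case) - mean(pc1$control))
  expect_gt(gap, max(sd(pc1$case), sd(pc1$control)))

  # duplicated sample projects to identical scores
  dup <- dplyr::bind_cols(norm, C1b = norm$C1)
  pdup <- sample_pca(dup)
  sc <- pdup$scores
  expect_equal(unlist(sc[sc$sample_id == "C1", -1]),
               unlist(sc[sc$sample_id == "C1b", -1]), tolerance = 1e-8)
})

test_that("the near-control subgroup is recovered from planted structure", {
  cfg <- sim_config(seed = 4, n_genes = 700, n_mirnas = 10,
                    frac_de = 0.15, subgroup_mode = TRUE)
  sim <- simulate_paired_counts(cfg)
  norm <- normalize_counts(sim$mrna)
  tr <- sim$truth$genes
  de <- tr$feature_id[tr$de_status != "null"]
  z <- zscore_rows(norm[norm$feature_id %in% de, ])
  sub <- nearest_subgroup(z, sim$samples)
  expect_setequal(sub$subgroup, sim$truth$subgroup_samples)

  res <- subgroup_degs(sim$mrna, sim$samples, sub$subgroup, de)
  expect_true(all(res$reduced_set %in% de))

  # identical case samples: whole case group is the subgroup
  flat_m <- matrix(c(5, 6, 7, 5, 6, 7, 8, 1, 4, 8, 1, 4, 8, 1, 4), 3)
  colnames(flat_m) <- c("C1", "C2", "L1", "L2", "L3")
  flat_tbl <- counts_tbl(flat_m, samples = colnames(flat_m))
  sheet <- two_group_sheet(2, 3)
  out <- nearest_subgroup(flat_tbl, sheet)
  expect_setequal(out$subgroup, c("L1", "L2", "L3"))

  expect_error(nearest_subgroup(flat_tbl, dplyr::filter(sheet,
                                                        sample_id != "L2")))
})
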