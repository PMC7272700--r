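test_that("config validation rejects out-of-range fields", {
  expect_error(sim_config(n_control = 1), "at least 2")
  expect_error(sim_config(frac_de = 0.6), "frac_de")
  expect_error(sim_config(lfc_sd_uniform = -1), "SDs")
  expect_error(sim_config(n_genes = 10.5), "integer")
  expect_error(sim_config(library_size_range = c(10, 1)), "library_size_range")
})

test_that("no effects are planted when frac_de is zero", {
  sim <- simulate_paired_counts(small_config(frac_de = 0))
  expect_true(all(sim$truth$genes$de_status == "null"))
  expect_true(all(sim$truth$mirnas$de_status == "null"))
  expect_true(all(sim$truth$gene_log2fc == 0))
  expect_equal(nrow(sim$truth$target_pairs), 0)
})

test_that("zero uniform SD gives identical per-sample effects", {
  sim <- simulate_paired_counts(small_config(lfc_sd_uniform = 0))
  tr <- sim$truth$genes
  uni <- tr$feature_id[!is.na(tr$regulation_class) &
                         tr$regulation_class == "uniform"]
  spread <- apply(sim$truth$gene_log2fc[uni, , drop = FALSE], 1,
                  function(x) diff(range(x)))
  expect_true(all(spread == 0))
})

test_that("the same seed reproduces counts exactly", {
  a <- simulate_paired_counts(small_config(seed = 7))
  b <- simulate_paired_counts(small_config(seed = 7))
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$truth$target_pairs, b$truth$target_pairs)
  c <- simulate_paired_counts(small_config(seed = 8))
  expect_false(identical(a$mrna, c$mrna))
})

test_that("planted target pairs couple opposite-direction features", {
  sim <- simulate_paired_counts(small_config(frac_de = 0.2))
  pairs <- sim$truth$target_pairs
  expect_gt(nrow(pairs), 0)
  gdir <- setNames(sim$truth$genes$de_status, sim$truth$genes$feature_id)
  mdir <- setNames(sim$truth$mirnas$de_status, sim$truth$mirnas$feature_id)
  expect_true(all(gdir[pairs$gene_id] != mdir[pairs$mirna_id]))
  expect_true(all(gdir[pairs$gene_id] != "null"))
  expect_true(all(mdir[pairs$mirna_id] != "null"))
})

test_that("null-gene count moments match the configured NB dispersion", {
  cfg <- sim_config(seed = 3, n_genes = 3000, n_mirnas = 10, frac_de = 0,
                    dispersion = 0.05,
                    library_size_range = c(1e6, 1e6))
  sim <- simulate_paired_counts(cfg)
  m <- as.matrix(sim$mrna[-1])
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  keep <- mu > 50  # dispersion dominates shot noise here
  alpha_hat <- median((v[keep] - mu[keep]) / mu[keep]^2)
  expect_gt(alpha_hat, 0.02)
  expect_lt(alpha_hat, 0.09)
})

test_that("promoter generator plants and withholds motifs as asked", {
  cfg <- small_config(motif_plant_rate = 1)
  pfm <- matrix(1, 4, 6)
  pfm[cbind(c(1, 2, 3, 4, 1, 2), 1:6)] <- 20
  motif <- pwm_motif(pfm, "m1")
  out <- simulate_promoters(c("g1", "g2"), "g1", motif, cfg)
  expect_equal(nrow(out$promoters), 2)
  expect_true(grepl(motif_consensus(motif),
                    out$promoters$sequence[out$promoters$gene_id == "g1"]))
  expect_error(
    simulate_promoters("g1", "g1", motif, cfg, length_nt = 4L),
    "longer than promoter")
})

test_that("unplanted consensus occurrences match the background rate", {
  cfg <- small_config(motif_plant_rate = 0)
  pfm <- matrix(1, 4, 6)
  pfm[cbind(c(1, 2, 3, 4, 1, 2), 1:6)] <- 50
  motif <- pwm_motif(pfm, "m1")   # consensus ACGTAC
  genes <- sprintf("g%d", 1:400)
  out <- simulate_promoters(genes, genes, motif, cfg, gc = 0.4,
                            length_nt = 350L)
  n_hits <- sum(stringr::str_count(out$promoters$sequence, "ACGTAC"))
  p_site <- 0.3 * 0.2 * 0.2 * 0.3 * 0.3 * 0.2
  expected <- length(genes) * (350 - 6 + 1) * p_site
  expect_lt(abs(n_hits - expected), 4 * sqrt(expected))
})

test_that("target tables cover truth and respect decoy settings", {
  sim <- simulate_paired_counts(small_config(frac_de = 0.2))
  tt0 <- simulate_target_tables(sim$truth, n_sources = 3, decoy_rate = 0,
                                seed = 2)
  union0 <- unique(tt0[c("mirna_id", "gene_id")])
  truth_pairs <- sim$truth$target_pairs
  expect_setequal(paste(union0$mirna_id, union0$gene_id),
                  paste(truth_pairs$mirna_id, truth_pairs$gene_id))
  tt1 <- simulate_target_tables(sim$truth, n_sources = 1, decoy_rate = 0,
                                seed = 2)
  expect_true(all(tt1$source %in% c("source1", "validated")))
  # decoys pair DE miRNAs with non-DE genes only
  tt2 <- simulate_target_tables(sim$truth, n_sources = 3, decoy_rate = 1,
                                seed = 2)
  extra <- dplyr::anti_join(tt2, truth_pairs,
                            by = c("mirna_id", "gene_id"))
  gdir <- setNames(sim$truth$genes$de_status, sim$truth$genes$feature_id)
  expect_true(all(gdir[extra$gene_id] == "null"))
})

test_that("fractal fixtures have their constructed geometry", {
  carpet <- simulate_fractal_image("sierpinski_carpet", 3)
  expect_equal(dim(carpet$mask), c(27, 27))
  expect_equal(sum(carpet$mask), 512)
  expect_equal(attr(carpet, "true_dimension"), log(8) / log(3))

  filled <- simulate_fractal_image("filled", 64)
  expect_equal(mean(filled$mask), 1)

  fib <- simulate_fractal_image("random_fiber", 200, area_fraction = 0.25,
                                seed = 4)
  expect_lt(abs(mean(fib$mask) - 0.25), 0.02)
})
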