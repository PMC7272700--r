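toy_targets <- function() {
  tibble::tibble(
    mirna_id = c("m1", "m1", "m1", "m2", "m2", "m3"),
    gene_id = c("ga", "ga", "ga", "ga", "gb", "gc"),
    source = c("source1", "source2", "validated", "source1", "source2",
               "source1")
  )
}

de_tbl <- function(ids, dirs) {
  tibble::tibble(feature_id = ids, direction = dirs)
}

test_that("union-set semantics merge sources and keep provenance", {
  u <- union_targets(toy_targets())
  m1ga <- u[u$mirna_id == "m1" & u$gene_id == "ga", ]
  expect_equal(nrow(m1ga), 1)
  expect_setequal(m1ga$sources[[1]], c("source1", "source2", "validated"))
  expect_true(m1ga$validated)

  single <- toy_targets()[toy_targets()$source == "source1", ]
  u1 <- union_targets(single)
  expect_equal(nrow(u1), nrow(unique(single[c("mirna_id", "gene_id")])))

  # brute-force union equivalence on random maps
  set.seed(51)
  for (i in 1:10) {
    tt <- tibble::tibble(
      mirna_id = sample(sprintf("m%d", 1:5), 40, replace = TRUE),
      gene_id = sample(sprintf("g%d", 1:8), 40, replace = TRUE),
      source = sample(sprintf("source%d", 1:3), 40, replace = TRUE))
    u <- union_targets(tt)
    expect_equal(nrow(u),
                 nrow(unique(tt[c("mirna_id", "gene_id")])))
    expect_equal(sum(lengths(u$sources)),
                 nrow(unique(tt)))
  }

  # case-insensitive harmonization against expression namespaces
  tt2 <- tibble::tibble(mirna_id = c("M1", "mX"), gene_id = c("GA", "ga"),
                        source = "source1")
  u2 <- union_targets(tt2, gene_universe = "ga", mirna_universe = "m1")
  expect_equal(nrow(u2), 1)
  expect_equal(u2$mirna_id, "m1")
  expect_equal(u2$gene_id, "ga")
  expect_equal(attr(u2, "n_dropped"), 1)
})

test_that("anti-correlation keeps only opposite-direction DE pairs", {
  cand <- union_targets(toy_targets())
  de_m <- de_tbl(c("m1", "m2", "m3"), c("up", "up", "down"))
  de_g <- de_tbl(c("ga", "gb", "gc"), c("down", "up", "ns"))
  kept <- anticorrelation_filter(cand, de_g, de_m)
  # m1-ga and m2-ga survive; m2-gb same direction; m3-gc gene not DE
  expect_setequal(paste(kept$mirna_id, kept$gene_id),
                  c("m1 ga", "m2 ga"))
})

test_that("Jaccard weights equal brute-force set arithmetic", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index("a", "b"), 0)

  set.seed(52)
  pairs <- tibble::tibble(
    mirna_id = sample(sprintf("m%d", 1:6), 60, replace = TRUE),
    gene_id = sample(sprintf("g%d", 1:15), 60, replace = TRUE),
    mirna_direction = "up", gene_direction = "down", validated = FALSE
  ) |> dplyr::distinct(mirna_id, gene_id, .keep_all = TRUE)
  net <- build_network(pairs)
  sets <- split(pairs$gene_id, pairs$mirna_id)
  for (i in seq_len(nrow(net$overlap))) {
    a <- sets[[net$overlap$mirna_a[i]]]
    b <- sets[[net$overlap$mirna_b[i]]]
    expect_equal(net$overlap$jaccard[i],
                 length(intersect(a, b)) / length(union(a, b)))
  }
  expect_true(all(net$overlap$jaccard > 0))
  # handshake: per-gene regulator counts sum to the edge count
  coreg <- coregulation_table(net)
  expect_equal(sum(coreg$n_mirnas), nrow(net$edges))
})

test_that("subnetworks restrict genes and admit neutral interactors", {
  cand <- union_targets(toy_targets())
  de_m <- de_tbl(c("m1", "m2", "m3"), c("up", "up", "up"))
  de_g <- de_tbl(c("ga", "gb", "gc"), c("down", "down", "down"))
  net <- build_network(anticorrelation_filter(cand, de_g, de_m))

  empty <- subnetwork(net, character())
  expect_equal(nrow(empty$edges), 0)

  full <- subnetwork(net, net$gene_nodes$gene_id)
  expect_equal(nrow(full$edges), nrow(net$edges))

  ppi <- tibble::tibble(gene_a = "ga", gene_b = "gZ")
  sub <- subnetwork(net, "ga", ppi_edges = ppi)
  expect_true("gZ" %in% sub$gene_nodes$gene_id)
  expect_equal(sub$gene_nodes$direction[sub$gene_nodes$gene_id == "gZ"],
               "ns")

  # evidence typing follows provenance
  expect_equal(net$edges$evidence[net$edges$validated], "validated")
  expect_true(all(net$edges$evidence[!net$edges$validated] == "predicted"))
})

test_that("graph exports are readable and sign-consistent", {
  cand <- union_targets(toy_targets())
  de_m <- de_tbl(c("m1", "m2", "m3"), c("up", "up", "down"))
  de_g <- de_tbl(c("ga", "gb", "gc"), c("down", "up", "up"))
  kept <- anticorrelation_filter(cand, de_g, de_m)
  net <- build_network(kept)
  expect_true(all(kept$mirna_direction != kept$gene_direction))

  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_graphml(net, gml)
  write_network_sif(net, sif)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g),
               nrow(net$edges) + nrow(net$overlap))
  expect_equal(length(readLines(sif)),
               nrow(net$edges) + nrow(net$overlap))
})

test_that("decoys among non-DE genes are fully removed end to end", {
  sim <- simulate_paired_counts(small_config(seed = 6, frac_de = 0.2))
  targ <- simulate_target_tables(sim$truth, n_sources = 3,
                                 decoy_rate = 1, seed = 6)
  truth_keys <- paste(sim$truth$target_pairs$mirna_id,
                      sim$truth$target_pairs$gene_id)
  # oracle DE tables straight from planted truth
  de_g <- de_tbl(sim$truth$genes$feature_id,
                 ifelse(sim$truth$genes$de_status == "null", "ns",
                        sim$truth$genes$de_status))
  de_m <- de_tbl(sim$truth$mirnas$feature_id,
                 ifelse(sim$truth$mirnas$de_status == "null", "ns",
                        sim$truth$mirnas$de_status))
  kept <- anticorrelation_filter(union_targets(targ), de_g, de_m)
  kept_keys <- paste(kept$mirna_id, kept$gene_id)
  expect_setequal(kept_keys, truth_keys)   # all decoys gone, truth intact
})
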