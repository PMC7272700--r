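sharp_motif <- function(dominants, sharpness = 30) {
  pfm <- matrix(1, 4, length(dominants))
  pfm[cbind(dominants, seq_along(dominants))] <- sharpness
  pwm_motif(pfm, "sharp")
}

test_that("JASPAR PFM parsing handles both text layouts", {
  f1 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TEST1",
               "A [ 4 19  0  2 ]",
               "C [16  0 20  1 ]",
               "G [ 0  1  0 15 ]",
               "T [ 0  0  0  2 ]",
               ">MA0002.1 TEST2",
               "1 0 0 9",
               "0 9 0 0",
               "9 0 0 0",
               "0 1 10 1"), f1)
  motifs <- read_jaspar_pfm(f1)
  expect_length(motifs, 2)
  expect_equal(motifs[[1]]$motif_id, "MA0001.1")
  expect_equal(motifs[[1]]$name, "TEST1")
  expect_equal(dim(motifs[[1]]$pfm), c(4, 4))
  expect_equal(motif_consensus(motifs[[1]]), "CACG")
  expect_equal(motif_consensus(motifs[[2]]), "GCTA")
})

test_that("best-hit scores reach 1 on consensus and 0 on anti-consensus", {
  motif <- sharp_motif(c(1, 1, 1, 1, 1))  # A-rich; C/G/T tie for worst
  seq_hit <- paste0("GGGG", motif_consensus(motif), "GGGG")
  expect_equal(best_hit_score(seq_hit, motif), 1)
  expect_equal(best_hit_score(strrep("C", 12), motif), 0)
  s <- best_hit_score(strrep("N", 12), motif)
  expect_true(s >= 0 && s <= 1)
})

test_that("vectorized scanner equals the exhaustive-placement oracle", {
  set.seed(41)
  for (i in 1:30) {
    w <- sample(4:6, 1)
    len <- sample(w:12, 1)
    motif <- pwm_motif(matrix(sample(0:9, 4 * w, replace = TRUE) + 1, 4, w),
                       "rnd")
    seq <- random_seq(1, len)
    expect_equal(best_hit_score(seq, motif),
                 best_hit_oracle(seq, motif), tolerance = 1e-12)
  }
})

test_that("scores are reverse-complement invariant", {
  set.seed(42)
  motif <- pwm_motif(matrix(sample(1:20, 24, replace = TRUE), 4, 6), "m")
  seqs <- random_seq(20, 60)
  rc <- vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_equal(score_sequences(seqs, motif), score_sequences(rc, motif),
               tolerance = 1e-12)
})

test_that("CpG fraction counts CG dimers over dinucleotide positions", {
  expect_equal(cpg_fraction("CGCG"), 2 / 3)
  expect_equal(cpg_fraction("AAAA"), 0)
  expect_equal(cpg_fraction(c("CG", "ACGT")), c(1, 1 / 3))
})

test_that("promoter extraction uses strand-aware half-open windows", {
  contig <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  tss <- tibble::tibble(chrom = "chr1", start = c(1000L, 1000L),
                        name = c("plus", "minus"), strand = c("+", "-"))
  prom <- extract_promoters(tss, genome)
  expect_equal(prom$sequence[1], substr(contig, 701, 1050))
  minus_window <- substr(contig, 951, 1300)
  minus_rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", minus_window),
                                 "")[[1]]), collapse = "")
  expect_equal(prom$sequence[2], minus_rc)
  expect_false(any(prom$clipped))

  near_edge <- tibble::tibble(chrom = "chr1", start = 100L,
                              name = "edge", strand = "+")
  pe <- extract_promoters(near_edge, genome)
  expect_true(pe$clipped)
  expect_equal(nchar(pe$sequence), 350)
  expect_equal(substr(pe$sequence, 1, 200), strrep("N", 200))
})

test_that("background matching respects the CpG tolerance", {
  set.seed(43)
  fg <- promoter_set(random_seq(15, 200),
                     gene_ids = sprintf("f%d", 1:15))
  bg <- match_background(fg, fg, tolerance = 0)
  expect_setequal(bg$gene_id, fg$gene_id)

  pool <- promoter_set(random_seq(120, 200),
                       gene_ids = sprintf("p%d", 1:120))
  matched <- match_background(fg, pool, tolerance = 0.02, seed = 9)
  expect_equal(nrow(matched), nrow(fg))
  expect_true(all(abs(matched$cpg_fraction - fg$cpg_fraction) <= 0.02))
  expect_false(any(duplicated(matched$gene_id)))
  expect_error(match_background(fg, pool[1:3, ], tolerance = 0),
               "exhausted")
})

test_that("the enrichment z-test detects planted motifs and not itself", {
  fg <- promoter_set(random_seq(20, 200), gene_ids = sprintf("f%d", 1:20))
  self <- motif_ztest(fg, fg, sharp_motif(c(1, 2, 3, 4, 1, 2)))
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 0.5)

  cfg <- small_config(motif_plant_rate = 1)
  motif <- sharp_motif(c(1, 2, 3, 4, 1, 2, 3, 4))
  genes <- sprintf("g%d", 1:80)
  out <- simulate_promoters(genes, genes[1:25], motif, cfg)
  fg2 <- out$promoters[1:25, ]
  bg2 <- out$promoters[26:80, ]
  res <- motif_ztest(fg2, bg2, motif)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$fg_frac_occ, res$bg_frac_occ)
})
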