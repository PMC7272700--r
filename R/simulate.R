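# Synthetic-data generators with planted ground truth. These emulate the
# statistical structure of a paired mRNA/miRNA two-group muscle-wasting
# experiment (4 control vs 6 case animals, negative-binomial counts, a
# minority of DE features split into uniformly vs variably regulated
# blocks, miRNAs anti-correlated with planted target genes, promoters
# carrying planted motifs) so that every downstream stage can be tested
# against known truth.

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic paired mRNA/miRNA
#' experiment. Defaults emulate the study design the package targets:
#' 4 control vs 6 case samples, negative-binomial counts with dispersion
#' `0.05`, 10% differentially expressed features at a 3-fold mean effect,
#' and a uniform/variable split of the DE features (small vs large
#' per-case-sample log2 fold-change spread).
#'
#' @param seed Integer seed; the same seed reproduces every generated file
#'   byte for byte.
#' @param n_control,n_case Samples per group (each at least 2).
#' @param n_genes,n_mirnas Number of gene and miRNA features.
#' @param frac_de Fraction of features differentially expressed (< 0.5).
#' @param lfc_mean Mean |log2 fold change| of DE features (default
#'   `log2(3)`, a 3-fold effect).
#' @param lfc_sd_uniform,lfc_sd_variable Per-case-sample SD of the log2
#'   fold change for uniformly vs variably regulated DE features.
#' @param dispersion Negative-binomial dispersion `alpha` (variance
#'   `mu + alpha * mu^2`).
#' @param library_size_range Range of per-sample library sizes; sizes are
#'   drawn log-uniformly so size-factor estimation is exercised.
#' @param frac_targets_true Fraction of DE genes coupled to a DE miRNA of
#'   opposite direction in the planted target map.
#' @param motif_plant_rate Probability that a foreground promoter receives
#'   an exact motif consensus instance.
#' @param subgroup_mode If `TRUE`, variable-class heterogeneity is planted
#'   as coherent subgroup structure instead of independent noise: the
#'   effects of variable-class DE features are attenuated in the first 3
#'   case samples, which therefore sit near the controls (a near-control
#'   case subgroup); uniform-class features keep full effects everywhere.
#' @param subgroup_shrink Multiplier applied to variable-class log2 fold
#'   changes in the near-control samples under subgroup mode.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_control = 4L, n_case = 6L,
                       n_genes = 2000L, n_mirnas = 300L,
                       frac_de = 0.1,
                       lfc_mean = log2(3),
                       lfc_sd_uniform = 0.15,
                       lfc_sd_variable = 0.8,
                       dispersion = 0.05,
                       library_size_range = c(5e5, 2e6),
                       frac_targets_true = 0.3,
                       motif_plant_rate = 0.9,
                       subgroup_mode = FALSE,
                       subgroup_shrink = 0.3) {
  cfg <- list(
    seed = seed, n_control = n_control, n_case = n_case,
    n_genes = n_genes, n_mirnas = n_mirnas, frac_de = frac_de,
    lfc_mean = lfc_mean, lfc_sd_uniform = lfc_sd_uniform,
    lfc_sd_variable = lfc_sd_variable, dispersion = dispersion,
    library_size_range = library_size_range,
    frac_targets_true = frac_targets_true,
    motif_plant_rate = motif_plant_rate,
    subgroup_mode = subgroup_mode, subgroup_shrink = subgroup_shrink
  )
  for (f in c("seed", "n_control", "n_case", "n_genes", "n_mirnas")) {
    v <- cfg[[f]]
    if (length(v) != 1 || !is.numeric(v) || v != round(v)) {
      stop(sprintf("'%s' must be a single integer", f))
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$n_control < 2 || cfg$n_case < 2) {
    stop("need at least 2 samples per group")
  }
  if (cfg$frac_de < 0 || cfg$frac_de >= 0.5) stop("frac_de must be in [0, 0.5)")
  if (cfg$lfc_sd_uniform < 0 || cfg$lfc_sd_variable < 0) stop("SDs must be >= 0")
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (length(cfg$library_size_range) != 2 ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0) {
    stop("library_size_range must be an increasing positive pair")
  }
  for (f in c("frac_targets_true", "motif_plant_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(sprintf("'%s' must be in [0, 1]", f))
  }
  structure(cfg, class = "sim_config")
}

# Plant per-feature truth for one arm: DE status, regulation class and a
# per-case-sample matrix of true log2 fold changes.
plant_truth <- function(prefix, n, config, case_ids) {
  n_de <- round(config$frac_de * n)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  status <- rep("null", n)
  class <- rep(NA_character_, n)
  if (n_de > 0) {
    de_idx <- seq_len(n_de)   # leading block; identities are arbitrary
    status[de_idx] <- rep(c("up", "down"), length.out = n_de)
    class[de_idx] <- rep(c("uniform", "uniform", "variable", "variable"),
                         length.out = n_de)
  }
  lfc <- matrix(0, n, length(case_ids), dimnames = list(ids, case_ids))
  sgn <- ifelse(status == "up", 1, ifelse(status == "down", -1, 0))
  near <- if (config$subgroup_mode) {
    seq_len(min(3L, length(case_ids)))
  } else integer()
  for (j in seq_along(case_ids)) {
    if (config$subgroup_mode) {
      # variable-class heterogeneity comes from coherent subgroup
      # structure: attenuated effects in the near-control case samples,
      # full effects elsewhere, modest per-sample noise throughout
      mean_j <- sgn * config$lfc_mean *
        ifelse(!is.na(class) & class == "variable" & j %in% near,
               config$subgroup_shrink, 1)
      draw <- rnorm(n, mean = mean_j, sd = config$lfc_sd_uniform)
    } else {
      s <- ifelse(is.na(class), 0,
                  ifelse(class == "uniform",
                         config$lfc_sd_uniform, config$lfc_sd_variable))
      draw <- rnorm(n, mean = sgn * config$lfc_mean, sd = s)
    }
    lfc[, j] <- ifelse(sgn == 0, 0, draw)
  }
  list(feature_id = ids, de_status = status, regulation_class = class,
       true_log2fc = lfc)
}

nb_counts <- function(truth, baseline, size_factors, control_ids, config) {
  n <- length(truth$feature_id)
  samples <- c(control_ids, colnames(truth$true_log2fc))
  m <- matrix(0L, n, length(samples),
              dimnames = list(truth$feature_id, samples))
  for (s in samples) {
    l <- if (s %in% control_ids) rep(0, n) else truth$true_log2fc[, s]
    mu <- size_factors[[s]] * baseline * 2^l
    m[, s] <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  m
}

#' Simulate paired mRNA and miRNA count matrices with planted truth
#'
#' Draws negative-binomial counts `NB(mean = sf_s * baseline_g *
#' 2^lfc[g, s], dispersion)` for both arms. Uniform-class DE features get a
#' small per-case-sample log2 fold-change spread, variable-class a large
#' one; null features have zero fold change. Each planted miRNA-gene target
#' pair couples features with opposite effect signs.
#'
#' @param config A [sim_config()].
#' @return A list with `mrna` and `mirna` count tibbles (`feature_id` +
#'   one column per sample), a `samples` sheet (`sample_id`, `group`), and
#'   `truth`: per-arm truth tables, per-arm true log2 fold-change matrices,
#'   and a `target_pairs` tibble of truly coupled (miRNA, gene) pairs.
#' @export
simulate_paired_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "counts"), {
    control_ids <- sprintf("C%d", seq_len(config$n_control))
    case_ids <- sprintf("L%d", seq_len(config$n_case))
    samples <- tibble::tibble(
      sample_id = c(control_ids, case_ids),
      group = rep(c("control", "case"), c(config$n_control, config$n_case))
    )
    lib <- exp(runif(nrow(samples),
                     log(config$library_size_range[1]),
                     log(config$library_size_range[2])))
    sf <- setNames(lib / geometric_mean(lib), samples$sample_id)

    g_truth <- plant_truth("gene", config$n_genes, config, case_ids)
    m_truth <- plant_truth("mir", config$n_mirnas, config, case_ids)
    g_base <- rlnorm(config$n_genes, meanlog = log(50), sdlog = 1.5)
    m_base <- rlnorm(config$n_mirnas, meanlog = log(80), sdlog = 1.8)

    mrna <- nb_counts(g_truth, g_base, sf, control_ids, config)
    mirna <- nb_counts(m_truth, m_base, sf, control_ids, config)

    # couple DE miRNAs to DE genes of the opposite direction
    pairs <- tibble::tibble(mirna_id = character(), gene_id = character())
    de_mir <- tibble::tibble(id = m_truth$feature_id, st = m_truth$de_status)
    de_gene <- tibble::tibble(id = g_truth$feature_id, st = g_truth$de_status)
    n_true <- round(config$frac_targets_true * sum(de_gene$st != "null"))
    if (n_true > 0 && any(de_mir$st != "null")) {
      genes <- de_gene[de_gene$st != "null", ]
      genes <- genes[sample.int(nrow(genes), min(n_true, nrow(genes))), ]
      opp <- c(up = "down", down = "up")
      pairs <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
        pool <- de_mir$id[de_mir$st == opp[[genes$st[i]]]]
        if (length(pool) == 0) return(NULL)
        tibble::tibble(mirna_id = pool[sample.int(length(pool), 1)],
                       gene_id = genes$id[i])
      })
    }

    truth_tbl <- function(tr) tibble::tibble(
      feature_id = tr$feature_id, de_status = tr$de_status,
      regulation_class = tr$regulation_class
    )
    list(
      mrna = matrix_to_tibble(mrna),
      mirna = matrix_to_tibble(mirna),
      samples = samples,
      truth = list(
        genes = truth_tbl(g_truth),
        mirnas = truth_tbl(m_truth),
        gene_log2fc = g_truth$true_log2fc,
        mirna_log2fc = m_truth$true_log2fc,
        target_pairs = pairs,
        size_factors = sf,
        subgroup_samples = if (config$subgroup_mode)
          case_ids[seq_len(min(3L, length(case_ids)))] else character()
      )
    )
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Generates one 350-nt promoter per gene (matching the -300..+50 TSS
#' window convention used downstream) from an i.i.d. background with a
#' controllable GC content. Foreground genes receive one exact motif
#' consensus instance at a random position with probability
#' `motif_plant_rate`.
#'
#' @param genes Character vector of gene ids (one promoter each).
#' @param fg_genes Genes eligible for motif planting.
#' @param motif A `pwm_motif` (see [read_jaspar_pfm()]); its consensus is
#'   planted.
#' @param config A [sim_config()] (supplies seed and plant rate).
#' @param gc Background GC content in (0, 1).
#' @param length_nt Promoter length.
#' @return A list with `promoters` (a promoter-set tibble: `gene_id`,
#'   `sequence`, `cpg_fraction`) and `tss` (a BED-style tibble of 0-based
#'   TSS coordinates on a synthetic contig).
#' @export
simulate_promoters <- function(genes, fg_genes, motif, config,
                               gc = 0.4, length_nt = 350L) {
  stopifnot(inherits(config, "sim_config"))
  cons <- motif_consensus(motif)
  if (nchar(cons) > length_nt) stop("motif longer than promoter")
  with_seed(child_seed(config$seed, "promoters"), {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(genes, function(g) {
      s <- sample(names(p), length_nt, replace = TRUE, prob = p)
      if (g %in% fg_genes && runif(1) < config$motif_plant_rate) {
        at <- sample.int(length_nt - nchar(cons) + 1, 1)
        s[at:(at + nchar(cons) - 1)] <- strsplit(cons, "")[[1]]
      }
      paste(s, collapse = "")
    }, character(1))
    tss <- tibble::tibble(
      chrom = "chrSim",
      start = 1000L + seq_along(genes) * (length_nt + 50L),
      end = 1000L + seq_along(genes) * (length_nt + 50L) + 1L,
      name = genes,
      score = 0L,
      strand = "+"
    )
    list(promoters = promoter_set(seqs, gene_ids = genes), tss = tss)
  })
}

#' Simulate per-source miRNA-target prediction tables
#'
#' Every true pair appears in at least one prediction source; decoy pairs
#' with no expression coupling are added at `decoy_rate` (relative to the
#' number of true pairs). One source is flagged validated. By default
#' decoys pair DE miRNAs with non-DE genes, so a correct anti-correlation
#' filter must remove all of them.
#'
#' @param truth The `truth` element of [simulate_paired_counts()].
#' @param n_sources Number of prediction sources (>= 1).
#' @param decoy_rate Decoys per true pair.
#' @param seed Seed (defaults to a child of nothing; pass for
#'   reproducibility).
#' @return A tidy target table: `mirna_id`, `gene_id`, `source`,
#'   `validated`.
#' @export
simulate_target_tables <- function(truth, n_sources = 3L, decoy_rate = 0.5,
                                   seed = 1L) {
  stopifnot(n_sources >= 1, decoy_rate >= 0)
  with_seed(child_seed(seed, "targets"), {
    sources <- c(sprintf("source%d", seq_len(n_sources)), "validated")
    true <- truth$target_pairs
    rows <- list()
    if (nrow(true) > 0) {
      for (i in seq_len(nrow(true))) {
        k <- sample.int(n_sources, sample.int(n_sources, 1))
        src <- sprintf("source%d", k)
        if (runif(1) < 0.2) src <- c(src, "validated")
        rows[[length(rows) + 1]] <- tibble::tibble(
          mirna_id = true$mirna_id[i], gene_id = true$gene_id[i], source = src
        )
      }
    }
    n_decoy <- round(decoy_rate * nrow(true))
    if (n_decoy > 0) {
      null_genes <- truth$genes$feature_id[truth$genes$de_status == "null"]
      de_mirs <- truth$mirnas$feature_id[truth$mirnas$de_status != "null"]
      if (length(null_genes) > 0 && length(de_mirs) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          mirna_id = sample(de_mirs, n_decoy, replace = TRUE),
          gene_id = sample(null_genes, n_decoy,
                           replace = n_decoy > length(null_genes)),
          source = sample(sprintf("source%d", seq_len(n_sources)),
                          n_decoy, replace = TRUE)
        )
      }
    }
    tbl <- dplyr::bind_rows(rows)
    if (nrow(tbl) == 0) {
      tbl <- tibble::tibble(mirna_id = character(), gene_id = character(),
                            source = character())
    }
    tbl |>
      dplyr::distinct(.data$mirna_id, .data$gene_id, .data$source) |>
      dplyr::mutate(validated = .data$source == "validated") |>
      dplyr::arrange(.data$mirna_id, .data$gene_id, .data$source)
  })
}

#' Simulate binary images with known fractal dimension
#'
#' `filled` is an all-foreground square (dimension 2), `sierpinski_carpet`
#' at depth `d` is the exact `3^d x 3^d` carpet mask with `8^d` foreground
#' pixels (similarity dimension `log 8 / log 3`), and `random_fiber` is a
#' smoothed random field thresholded to a target foreground fraction,
#' mimicking a stained-tissue pattern.
#'
#' @param kind One of `"filled"`, `"sierpinski_carpet"`, `"random_fiber"`.
#' @param depth_or_size Carpet recursion depth, or image side length.
#' @param area_fraction Target foreground fraction for `random_fiber`.
#' @param seed Seed for `random_fiber`.
#' @return A `binary_image` whose `true_dimension` attribute holds the
#'   known dimension (`NA` for `random_fiber`).
#' @export
simulate_fractal_image <- function(kind = c("filled", "sierpinski_carpet",
                                            "random_fiber"),
                                   depth_or_size,
                                   area_fraction = 0.25, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "filled") {
    mask <- matrix(TRUE, depth_or_size, depth_or_size)
    dtrue <- 2
  } else if (kind == "sierpinski_carpet") {
    cell <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
    mask <- matrix(1, 1, 1)
    for (i in seq_len(depth_or_size)) mask <- kronecker(mask, cell)
    mask <- mask > 0
    dtrue <- log(8) / log(3)
  } else {
    mask <- with_seed(child_seed(seed, "image"), {
      n <- depth_or_size
      z <- matrix(rnorm(n * n), n, n)
      k <- 7L  # moving-average smoothing gives fiber-like blobs
      kern <- rep(1 / k, k)
      sm <- apply(z, 2, function(col) stats::filter(col, kern, circular = TRUE))
      sm <- t(apply(sm, 1, function(row) stats::filter(row, kern, circular = TRUE)))
      sm >= quantile(sm, 1 - area_fraction)
    })
    dtrue <- NA_real_
  }
  binary_image(mask, threshold = NA_real_, method = kind,
               true_dimension = dtrue)
}
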