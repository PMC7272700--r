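# End-to-end orchestration: file IO for the standard formats, a
# configuration object holding the study thresholds, the synthetic input
# bundle writer, and the staged pipeline with a provenance manifest.

#' Read a counts TSV
#'
#' @param path TSV with a `feature_id` column and one column per sample.
#' @return Counts tibble.
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with `sample_id` and `group` columns.
#' @return Sample sheet tibble.
#' @export
read_sample_sheet <- function(path) {
  check_samples(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read a FASTA file as a promoter set
#'
#' @param path FASTA path (record ids = gene ids).
#' @return Promoter-set tibble ([promoter_set()]).
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  promoter_set(setNames(as.character(x),
                        sub("\\s.*$", "", names(x))))
}

#' Pipeline configuration
#'
#' Collects input paths, the study's thresholds and the global seed.
#' Stages whose inputs are `NULL` are skipped.
#'
#' @param counts_mrna,counts_mirna,samples Paths to the count matrices
#'   and sample sheet (required).
#' @param promoters,motifs Promoter FASTA and JASPAR PFM paths (motif
#'   stage).
#' @param gmt Gene-set GMT path (enrichment stage).
#' @param targets Target-prediction TSV path (integration stage).
#' @param ppi Optional interaction edge-list TSV (`gene_a`, `gene_b`).
#' @param images Optional directory of PNG/TIFF micrographs.
#' @param cell_density Optional TSV (`image`, `group`, `cell_density`).
#' @param out_dir Output directory.
#' @param fc_threshold,alpha,use_fdr DEG call thresholds.
#' @param motif_alpha Motif significance threshold.
#' @param mirna_floor Expressed-miRNA count floor (strict `>`).
#' @param detect_floor Detected-gene count floor applied to the mRNA arm
#'   (strict `>`); defines the detected universe for DE, clustering and
#'   enrichment.
#' @param k,n_init K-means settings.
#' @param pseudo_count Fold-change pseudo-count.
#' @param seed Global seed feeding every stage's RNG.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts_mrna, counts_mirna, samples,
                            promoters = NULL, motifs = NULL, gmt = NULL,
                            targets = NULL, ppi = NULL, images = NULL,
                            cell_density = NULL,
                            out_dir = tempfile("cachexnet_run"),
                            fc_threshold = 1.5, alpha = 0.05,
                            use_fdr = TRUE, motif_alpha = 0.01,
                            mirna_floor = 32, detect_floor = 32,
                            k = 4, n_init = 100,
                            pseudo_count = 1, seed = 1L) {
  stopifnot(fc_threshold >= 1, alpha > 0, motif_alpha > 0, k >= 1,
            n_init >= 1, mirna_floor >= 0)
  cfg <- list(counts_mrna = counts_mrna, counts_mirna = counts_mirna,
              samples = samples, promoters = promoters, motifs = motifs,
              gmt = gmt, targets = targets, ppi = ppi, images = images,
              cell_density = cell_density, out_dir = out_dir,
              fc_threshold = fc_threshold, alpha = alpha,
              use_fdr = use_fdr, motif_alpha = motif_alpha,
              mirna_floor = mirna_floor, detect_floor = detect_floor,
              k = k, n_init = n_init,
              pseudo_count = pseudo_count, seed = as.integer(seed))
  for (f in c("counts_mrna", "counts_mirna", "samples")) {
    if (!file.exists(cfg[[f]])) stop("missing input file: ", cfg[[f]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Write the synthetic input bundle
#'
#' Generates every file the pipeline consumes - count TSVs, sample sheet,
#' promoter FASTA + TSS BED, a motif library, a gene-set GMT, target
#' tables, truth JSON, and fractal fixture images - from one
#' [sim_config()] seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @param motif Motif whose consensus is planted in up-regulated
#'   promoters (default a sharp 8-mer from [random_motif()]).
#' @param n_sources,decoy_rate Passed to [simulate_target_tables()].
#' @return Invisibly, a named list of written paths plus the in-memory
#'   simulation (`$sim`).
#' @export
write_simulation_bundle <- function(config, dir, motif = NULL,
                                    n_sources = 3L, decoy_rate = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  motif <- motif %||% random_motif(8L, seed = config$seed)
  sim <- simulate_paired_counts(config)
  up_genes <- sim$truth$genes$feature_id[sim$truth$genes$de_status == "up"]
  prom <- simulate_promoters(sim$truth$genes$feature_id, up_genes, motif,
                             config)
  targ <- simulate_target_tables(sim$truth, n_sources = n_sources,
                                 decoy_rate = decoy_rate,
                                 seed = config$seed)
  paths <- list(
    counts_mrna = file.path(dir, "mrna_counts.tsv"),
    counts_mirna = file.path(dir, "mirna_counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    tss = file.path(dir, "tss.bed"),
    motifs = file.path(dir, "motifs.pfm"),
    gmt = file.path(dir, "gene_sets.gmt"),
    targets = file.path(dir, "targets.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(sim$mrna, paths$counts_mrna)
  readr::write_tsv(sim$mirna, paths$counts_mirna)
  readr::write_tsv(sim$samples, paths$samples)
  writeLines(paste0(">", prom$promoters$gene_id, "\n",
                    prom$promoters$sequence), paths$promoters)
  readr::write_tsv(prom$tss, paths$tss, col_names = FALSE)
  writeLines(c(
    paste0(">", motif$motif_id, " ", motif$name),
    vapply(seq_len(4), function(i) {
      paste0(BASES[i], " [ ", paste(motif$pfm[i, ], collapse = " "), " ]")
    }, character(1))
  ), paths$motifs)
  # gene sets: one true DE-enriched set per direction + random sets
  truth <- sim$truth$genes
  sets <- with_seed(child_seed(config$seed, "split"), c(
    list(set_up = truth$feature_id[truth$de_status == "up"],
         set_down = truth$feature_id[truth$de_status == "down"]),
    setNames(lapply(1:5, function(i) {
      sample(truth$feature_id, 40)
    }), sprintf("set_random%d", 1:5))
  ))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1)), paths$gmt)
  readr::write_tsv(targ, paths$targets)
  jsonlite::write_json(
    list(genes = sim$truth$genes, mirnas = sim$truth$mirnas,
         target_pairs = sim$truth$target_pairs,
         subgroup_samples = sim$truth$subgroup_samples),
    paths$truth, dataframe = "columns", digits = NA
  )
  invisible(c(paths, list(sim = sim, motif = motif)))
}

stage_write <- function(x, dir, name, manifest) {
  path <- file.path(dir, name)
  drop <- vapply(x, is.list, logical(1))
  readr::write_tsv(x[!drop], path)
  manifest$outputs[[name]] <- nrow(x)
  manifest
}

#' Run the full pipeline
#'
#' Executes normalization, differential expression on both arms (with the
#' expressed-miRNA floor), clustering/stability analysis with PCA and the
#' near-control subgroup, promoter motif enrichment for up- and
#' down-regulated genes separately, gene-set enrichment, the
#' anti-correlation-filtered miRNA-target network, and (optionally)
#' histology quantification. Each stage writes TSV outputs under
#' `config$out_dir`, and a `manifest.json` records thresholds, the seed,
#' input MD5 hashes and per-stage record counts. The manifest carries no
#' timestamps, so identical inputs and seed reproduce the run byte for
#' byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list; all stage results are also
#'   returned in the `$results` element.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- purrr::compact(config[c("counts_mrna", "counts_mirna",
                                    "samples", "promoters", "motifs",
                                    "gmt", "targets", "ppi")])
  manifest <- list(
    package = "cachexnet",
    seed = config$seed,
    thresholds = config[c("fc_threshold", "alpha", "use_fdr",
                          "motif_alpha", "mirna_floor", "detect_floor",
                          "k", "n_init", "pseudo_count")],
    inputs = lapply(inputs, function(p) unname(tools::md5sum(p))),
    stages = character(),
    outputs = list()
  )
  res <- list()
  samples <- read_sample_sheet(config$samples)

  ## --- normalization + DE, mRNA arm -------------------------------------
  manifest$stages <- c(manifest$stages, "normalize", "de_mrna")
  mrna <- filter_detected(read_counts(config$counts_mrna),
                          threshold = config$detect_floor)
  sf <- estimate_size_factors(mrna)
  norm <- normalize_counts(mrna, sf)
  fc <- per_sample_fold_change(norm, samples,
                               pseudo_count = config$pseudo_count)
  de_mrna <- call_degs(nb_wald_test(mrna, samples, sf,
                                    pseudo_count = config$pseudo_count),
                       fc_threshold = config$fc_threshold,
                       alpha = config$alpha, use_fdr = config$use_fdr)
  manifest <- stage_write(sf, config$out_dir, "size_factors.tsv", manifest)
  manifest <- stage_write(norm, config$out_dir, "normalized_mrna.tsv",
                          manifest)
  manifest <- stage_write(de_mrna, config$out_dir, "de_mrna.tsv", manifest)
  res$de_mrna <- de_mrna; res$normalized <- norm; res$fold_changes <- fc

  ## --- miRNA arm: floor filter + DE -------------------------------------
  manifest$stages <- c(manifest$stages, "de_mirna")
  mirna <- read_counts(config$counts_mirna)
  mirna_kept <- filter_expressed_mirnas(mirna, threshold = config$mirna_floor)
  de_mirna <- call_degs(nb_wald_test(mirna_kept, samples,
                                     pseudo_count = config$pseudo_count),
                        fc_threshold = config$fc_threshold,
                        alpha = config$alpha, use_fdr = config$use_fdr)
  manifest <- stage_write(de_mirna, config$out_dir, "de_mirna.tsv",
                          manifest)
  res$de_mirna <- de_mirna

  ## --- clustering / stability -------------------------------------------
  manifest$stages <- c(manifest$stages, "cluster")
  degs <- de_mrna[de_mrna$direction != "ns", ]
  if (nrow(degs) >= config$k) {
    logged <- dplyr::mutate(
      norm[norm$feature_id %in% degs$feature_id, ],
      dplyr::across(-"feature_id", ~log2(.x + config$pseudo_count)))
    z <- zscore_rows(logged)
    cl <- kmeans_cluster(z, k = config$k, n_init = config$n_init,
                         seed = config$seed,
                         order_by = degs$log2fc[
                           match(z$feature_id, degs$feature_id)])
    cv <- fold_change_cv(fc, samples, genes = degs$feature_id)
    ecdf_tbl <- cumulative_fc_distribution(
      degs$log2fc[match(cl$assignments$feature_id, degs$feature_id)],
      cl$assignments$cluster)
    pca <- sample_pca(norm, samples, pseudo_count = config$pseudo_count)
    sub <- nearest_subgroup(z, samples)
    sub_de <- subgroup_degs(mrna, samples, sub$subgroup,
                            degs$feature_id,
                            fc_threshold = config$fc_threshold,
                            alpha = config$alpha,
                            use_fdr = config$use_fdr)
    manifest <- stage_write(cl$assignments, config$out_dir,
                            "clusters.tsv", manifest)
    manifest <- stage_write(cv$per_gene, config$out_dir,
                            "fold_change_cv.tsv", manifest)
    manifest <- stage_write(ecdf_tbl, config$out_dir, "ecdf.tsv", manifest)
    manifest <- stage_write(pca$scores, config$out_dir, "pca_scores.tsv",
                            manifest)
    manifest <- stage_write(
      tibble::tibble(feature_id = sub_de$reduced_set),
      config$out_dir, "subgroup_degs.tsv", manifest)
    res$clusters <- cl; res$cv <- cv; res$pca <- pca
    res$subgroup <- sub; res$subgroup_degs <- sub_de
  }

  ## --- motif enrichment (up and down promoters separately) --------------
  if (!is.null(config$promoters) && !is.null(config$motifs)) {
    manifest$stages <- c(manifest$stages, "motifs")
    prom <- read_promoter_fasta(config$promoters)
    motifs <- read_jaspar_pfm(config$motifs)
    sets <- deg_sets(de_mrna)
    for (dirn in c("up", "down")) {
      fg <- prom[prom$gene_id %in% sets[[dirn]], ]
      pool <- prom[!prom$gene_id %in% sets[[dirn]], ]
      if (nrow(fg) < 5 || nrow(pool) < nrow(fg)) next
      bg <- match_background(fg, pool, seed = config$seed)
      enr <- motif_enrichment(fg, bg, motifs)
      manifest <- stage_write(
        enr, config$out_dir, sprintf("motif_enrichment_%s.tsv", dirn),
        manifest)
      res[[sprintf("motifs_%s", dirn)]] <- enr
    }
  }

  ## --- gene-set enrichment ----------------------------------------------
  if (!is.null(config$gmt)) {
    manifest$stages <- c(manifest$stages, "enrich")
    sets <- deg_sets(de_mrna)
    enr <- hypergeom_enrich(c(sets$up, sets$down), read_gmt(config$gmt),
                            universe = mrna$feature_id)
    if (nrow(enr) > 0) {
      enr <- updown_fractions(enr, sets$up, sets$down)
    }
    manifest <- stage_write(enr, config$out_dir, "enrichment.tsv",
                            manifest)
    res$enrichment <- enr
  }

  ## --- miRNA-target integration -----------------------------------------
  if (!is.null(config$targets)) {
    manifest$stages <- c(manifest$stages, "integrate")
    targ <- readr::read_tsv(config$targets, show_col_types = FALSE)
    de_mir_ids <- de_mirna$feature_id[de_mirna$direction != "ns"]
    cand <- union_targets(targ, mirnas = de_mir_ids,
                          gene_universe = mrna$feature_id,
                          mirna_universe = mirna$feature_id)
    kept <- anticorrelation_filter(cand, de_mrna, de_mirna)
    net <- build_network(kept)
    if (!is.null(config$ppi)) {
      ppi <- readr::read_tsv(config$ppi, show_col_types = FALSE)
      net <- subnetwork(net, net$gene_nodes$gene_id, ppi_edges = ppi)
    }
    edges_flat <- dplyr::mutate(
      net$edges, sources = vapply(net$edges$sources, paste,
                                  character(1), collapse = ","))
    manifest <- stage_write(edges_flat, config$out_dir,
                            "network_edges.tsv", manifest)
    coreg <- coregulation_table(net)
    coreg_flat <- dplyr::mutate(
      coreg, mirnas = vapply(coreg$mirnas, paste, character(1),
                             collapse = ","))
    manifest <- stage_write(coreg_flat, config$out_dir,
                            "coregulation.tsv", manifest)
    write_network_graphml(net, file.path(config$out_dir, "network.graphml"))
    write_network_sif(net, file.path(config$out_dir, "network.sif"))
    res$network <- net
  }

  ## --- histology ---------------------------------------------------------
  if (!is.null(config$images) && !is.null(config$cell_density)) {
    manifest$stages <- c(manifest$stages, "histology")
    meta <- readr::read_tsv(config$cell_density, show_col_types = FALSE)
    histo <- purrr::map_dfr(seq_len(nrow(meta)), function(i) {
      img <- read_image(file.path(config$images, meta$image[i]))
      bi <- binarize(img)
      fr <- box_count_dimension(bi)
      dplyr::bind_cols(
        tibble::tibble(image = meta$image[i], group = meta$group[i]),
        stained_area_fraction(bi, meta$cell_density[i]),
        tibble::tibble(dimension = fr$dimension,
                       r_squared = fr$r_squared))
    })
    manifest <- stage_write(histo, config$out_dir, "histology.tsv",
                            manifest)
    if (all(c("control", "case") %in% histo$group)) {
      cmp <- dplyr::bind_rows(
        dplyr::mutate(group_compare(
          histo$score[histo$group == "control"],
          histo$score[histo$group == "case"]), measure = "score"),
        dplyr::mutate(group_compare(
          histo$dimension[histo$group == "control"],
          histo$dimension[histo$group == "case"]),
          measure = "dimension"))
      manifest <- stage_write(cmp, config$out_dir,
                              "histology_groups.tsv", manifest)
      res$histology_compare <- cmp
    }
    res$histology <- histo
  }

  jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$results <- res
  invisible(manifest)
}
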