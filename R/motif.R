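# Pscan-style promoter motif enrichment: JASPAR PFM parsing, log-odds
# best-hit scanning over both strands, CpG-matched background selection,
# and a z-test on mean best-hit scores.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Construct a PWM motif
#'
#' @param pfm 4 x w numeric matrix of base counts or probabilities, rows
#'   A, C, G, T.
#' @param motif_id,name Identifiers.
#' @return A `pwm_motif`.
#' @export
pwm_motif <- function(pfm, motif_id = "motif", name = motif_id) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 4) stop("motif width must be >= 4")
  if (any(pfm < 0) || any(colSums(pfm) <= 0)) {
    stop("PFM columns must have positive totals")
  }
  rownames(pfm) <- BASES
  structure(list(motif_id = motif_id, name = name, pfm = pfm),
            class = "pwm_motif")
}

#' Read motifs from JASPAR PFM text
#'
#' Accepts both JASPAR layouts: `A [ 4 19 0 ... ]` rows and bare 4-row
#' numeric blocks, each preceded by `>ID NAME`.
#'
#' @param path PFM file path.
#' @return List of `pwm_motif` objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no '>' motif headers found")
  purrr::map(seq_along(starts), function(i) {
    from <- starts[i] + 1
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "[ \t]+")[[1]]
    block <- lines[from:to]
    if (length(block) < 4) stop("motif block needs 4 rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][ACGTacgt]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    pfm <- do.call(rbind, rows)
    pwm_motif(pfm, motif_id = hdr[1],
              name = if (length(hdr) > 1) hdr[2] else hdr[1])
  })
}

#' Motif consensus sequence
#'
#' @param motif A `pwm_motif`.
#' @return Character scalar, the per-column argmax base.
#' @export
motif_consensus <- function(motif) {
  paste(BASES[apply(motif$pfm, 2, which.max)], collapse = "")
}

#' Random motif with graded columns
#'
#' Draws a random PFM whose column compositions follow a symmetric
#' Dirichlet distribution (gamma draws normalized per column), giving the
#' graded, variably informative columns typical of curated
#' transcription-factor matrices. Used both to provide a plantable motif
#' for the synthetic promoters and to calibrate enrichment under the
#' no-planting null.
#'
#' @param width Motif width (>= 4).
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration per base; smaller values
#'   give sharper columns.
#' @param total Approximate column count total.
#' @return A `pwm_motif`.
#' @export
random_motif <- function(width = 8L, seed = 1L, concentration = 0.7,
                         total = 40) {
  with_seed(child_seed(seed, "background"), {
    g <- matrix(rgamma(4 * width, shape = concentration), 4, width)
    p <- sweep(g, 2, colSums(g), "/")
    pwm_motif(round(p * total) + 1,
              motif_id = sprintf("rand%d_w%d", seed, width))
  })
}

# Log-odds score matrix with an extra row for N (its score is the
# background expectation of the column), plus the attainable score range.
pwm_log_odds <- function(motif, pseudocount = 0.1,
                         background = rep(0.25, 4)) {
  stopifnot(length(background) == 4, all(background > 0))
  background <- background / sum(background)
  prob <- sweep(motif$pfm + pseudocount, 2,
                colSums(motif$pfm + pseudocount), "/")
  lo <- log2(prob / background)
  lo <- rbind(lo, colSums(lo * background))  # N row
  list(lo = lo,
       min = sum(apply(lo[1:4, , drop = FALSE], 2, min)),
       max = sum(apply(lo[1:4, , drop = FALSE], 2, max)))
}

# reverse-complemented score matrix (same min/max range)
rc_log_odds <- function(lo) {
  m <- lo$lo[, rev(seq_len(ncol(lo$lo))), drop = FALSE]
  m[1:4, ] <- m[c(4, 3, 2, 1), ]
  list(lo = m, min = lo$min, max = lo$max)
}

encode_seq <- function(seq) {
  map <- integer(128)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("N")] <- 5L
  map[utf8ToInt("a")] <- 1L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("g")] <- 3L; map[utf8ToInt("t")] <- 4L
  map[utf8ToInt("n")] <- 5L
  code <- map[utf8ToInt(seq)]
  if (any(code == 0)) stop("sequence contains characters outside ACGTN")
  code
}

# best raw score per sequence for one strand, over a batch of
# equal-length sequences (codes: n x L integer matrix)
strand_best_batch <- function(codes, lom) {
  w <- ncol(lom)
  L <- ncol(codes)
  noff <- L - w + 1
  best <- rep(-Inf, nrow(codes))
  cols <- lapply(seq_len(w), function(j) lom[, j])
  for (o in seq_len(noff)) {
    s <- cols[[1]][codes[, o]]
    for (j in 2:w) s <- s + cols[[j]][codes[, o + j - 1]]
    best <- pmax(best, s)
  }
  best
}

#' Best-hit PWM score of a sequence
#'
#' Maximum log-odds score over both strands and all offsets, min-max
#' rescaled to \[0, 1\] by the motif's worst and best attainable scores:
#' a sequence containing the consensus scores 1, the anti-consensus at
#' every offset scores 0. N positions contribute the background
#' expectation.
#'
#' @param seq Character scalar (ACGTN).
#' @param motif A `pwm_motif`.
#' @param pseudocount PFM pseudocount per cell.
#' @param background Base frequencies (A, C, G, T).
#' @return Score in \[0, 1\].
#' @export
best_hit_score <- function(seq, motif, pseudocount = 0.1,
                           background = rep(0.25, 4)) {
  score_sequences(seq, motif, pseudocount, background)[[1]]
}

#' Best-hit scores for many sequences
#'
#' Vectorized form of [best_hit_score()].
#'
#' @param seqs Character vector of sequences (each at least motif width).
#' @inheritParams best_hit_score
#' @return Numeric vector of scores in \[0, 1\].
#' @export
score_sequences <- function(seqs, motif, pseudocount = 0.1,
                            background = rep(0.25, 4)) {
  lo <- pwm_log_odds(motif, pseudocount, background)
  rc <- rc_log_odds(lo)
  w <- ncol(motif$pfm)
  lens <- nchar(seqs)
  if (any(lens < w)) stop("sequence shorter than motif")
  out <- numeric(length(seqs))
  # batch equal-length sequences into one integer matrix sweep
  for (L in unique(lens)) {
    idx <- which(lens == L)
    codes <- matrix(0L, length(idx), L)
    for (i in seq_along(idx)) codes[i, ] <- encode_seq(seqs[idx[i]])
    best <- pmax(strand_best_batch(codes, lo$lo),
                 strand_best_batch(codes, rc$lo))
    out[idx] <- (best - lo$min) / (lo$max - lo$min)
  }
  out
}

#' CpG dinucleotide fraction
#'
#' Fraction of dinucleotide positions that read `CG`.
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector in \[0, 1\].
#' @export
cpg_fraction <- function(seq) {
  stringr::str_count(toupper(seq), "CG") / (nchar(seq) - 1)
}

#' Build a promoter-set tibble
#'
#' @param seqs Named character vector (names = gene ids) or bare vector
#'   with `gene_ids`.
#' @param gene_ids Gene ids when `seqs` is unnamed.
#' @return Tibble: `gene_id`, `sequence`, `cpg_fraction`; all sequences
#'   must share one length and the ACGTN alphabet.
#' @export
promoter_set <- function(seqs, gene_ids = names(seqs)) {
  stopifnot(length(gene_ids) == length(seqs))
  if (length(unique(nchar(seqs))) > 1) {
    stop("all promoter sequences must have the same length")
  }
  if (any(grepl("[^ACGTNacgtn]", seqs))) {
    stop("promoter alphabet must be ACGTN")
  }
  tibble::tibble(gene_id = gene_ids, sequence = unname(toupper(seqs)),
                 cpg_fraction = cpg_fraction(seqs))
}

#' Extract promoters around TSSs
#'
#' Strand-aware extraction of the `-upstream..+downstream` window around
#' each TSS (0-based coordinates, half-open arithmetic): plus-strand
#' promoters cover `[tss - upstream, tss + downstream)`; minus-strand
#' promoters are the reverse complement of
#' `[tss - downstream, tss + upstream)`. Windows running off a contig are
#' padded with N and flagged.
#'
#' @param tss BED-style tibble: `chrom`, `start` (0-based TSS), `name`,
#'   `strand` (`+`/`-`).
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param upstream,downstream Window extent in nt (defaults 300 and 50).
#' @return Promoter-set tibble with an extra `clipped` logical column.
#' @export
extract_promoters <- function(tss, genome, upstream = 300, downstream = 50) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  out <- purrr::pmap(tss[c("chrom", "start", "name", "strand")],
                     function(chrom, start, name, strand) {
    contig <- genome[[chrom]]
    if (is.null(contig)) stop("contig not found: ", chrom)
    len <- nchar(contig)
    if (strand == "+") {
      s <- start - upstream; e <- start + downstream
    } else {
      s <- start - downstream; e <- start + upstream
    }
    pad_l <- max(0, -s)
    pad_r <- max(0, e - len)
    core <- substr(contig, max(s, 0) + 1, min(e, len))
    seq <- paste0(strrep("N", pad_l), core, strrep("N", pad_r))
    if (strand == "-") seq <- revcomp(seq)
    list(gene_id = name, sequence = toupper(seq),
         clipped = pad_l > 0 || pad_r > 0)
  })
  seqs <- vapply(out, `[[`, character(1), "sequence")
  dplyr::mutate(
    promoter_set(seqs, gene_ids = vapply(out, `[[`, character(1), "gene_id")),
    clipped = vapply(out, `[[`, logical(1), "clipped")
  )
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' CpG-matched background selection
#'
#' For each foreground promoter, samples (without replacement) a pool
#' promoter whose CpG fraction differs by at most `tolerance`; errors if
#' a foreground promoter cannot be matched.
#'
#' @param fg,pool Promoter-set tibbles.
#' @param tolerance Maximum |CpG fraction| difference per matched pair.
#' @param seed RNG seed for the sampling.
#' @return Background promoter-set tibble, one row per foreground row.
#' @export
match_background <- function(fg, pool, tolerance = 0.02, seed = 1L) {
  with_seed(child_seed(seed, "background"), {
    avail <- rep(TRUE, nrow(pool))
    # match tightest-constrained foreground promoters first
    n_cand <- vapply(fg$cpg_fraction, function(x) {
      sum(abs(pool$cpg_fraction - x) <= tolerance)
    }, numeric(1))
    pick <- integer(nrow(fg))
    for (i in order(n_cand)) {
      cand <- which(avail & abs(pool$cpg_fraction -
                                  fg$cpg_fraction[i]) <= tolerance)
      if (length(cand) == 0) {
        stop("background pool exhausted at CpG tolerance ", tolerance)
      }
      pick[i] <- cand[sample.int(length(cand), 1)]
      avail[pick[i]] <- FALSE
    }
    pool[pick, , drop = FALSE]
  })
}

#' Z-test on best-hit score vectors
#'
#' The enrichment statistic on precomputed per-sequence best-hit scores:
#' `z = (mean(fg) - mean(bg)) / (sd(bg) * sqrt(1/n_fg + 1/n_bg))`, with a
#' one-sided p for over-representation. The background variance scales
#' both means' sampling noise; when the background is much larger than
#' the foreground (the whole-promoterome regime of promoter scanners)
#' this reduces to `sd(bg)/sqrt(n_fg)`, and unlike that limit form it
#' stays calibrated for same-size matched backgrounds. Identical score
#' sets give z = 0, p = 0.5.
#'
#' @param fg_scores,bg_scores Numeric score vectors.
#' @return Tibble: `z`, `p_value`, `fg_mean`, `bg_mean`.
#' @export
score_ztest <- function(fg_scores, bg_scores) {
  mf <- mean(fg_scores); mb <- mean(bg_scores)
  sb <- sd(bg_scores)
  denom <- sb * sqrt(1 / length(fg_scores) + 1 / length(bg_scores))
  z <- if (isTRUE(all.equal(mf, mb))) 0
       else if (sb == 0) sign(mf - mb) * Inf
       else (mf - mb) / denom
  tibble::tibble(z = z, p_value = pnorm(z, lower.tail = FALSE),
                 fg_mean = mf, bg_mean = mb)
}

#' Motif over-representation z-test
#'
#' Scores foreground and background promoter sets with [score_sequences()]
#' and applies [score_ztest()]; also reports the fraction of sequences in
#' each set with at least one occurrence (best-hit score above
#' `occurrence_cutoff`).
#'
#' @param fg,bg Promoter-set tibbles; `nrow(bg) >= nrow(fg)` expected.
#' @param motif A `pwm_motif`.
#' @param occurrence_cutoff Score cutoff defining an occurrence.
#' @inheritParams best_hit_score
#' @return One-row tibble: `motif_id`, `name`, `z`, `p_value`, `fg_mean`,
#'   `bg_mean`, `fg_frac_occ`, `bg_frac_occ`.
#' @export
motif_ztest <- function(fg, bg, motif, occurrence_cutoff = 0.8,
                        pseudocount = 0.1, background = rep(0.25, 4)) {
  if (nrow(bg) < nrow(fg)) {
    warning("background smaller than foreground")
  }
  fs <- score_sequences(fg$sequence, motif, pseudocount, background)
  bs <- score_sequences(bg$sequence, motif, pseudocount, background)
  dplyr::bind_cols(
    tibble::tibble(motif_id = motif$motif_id, name = motif$name),
    score_ztest(fs, bs),
    tibble::tibble(fg_frac_occ = mean(fs >= occurrence_cutoff),
                   bg_frac_occ = mean(bs >= occurrence_cutoff))
  )
}

#' Motif enrichment over a motif library
#'
#' @param fg,bg Promoter-set tibbles.
#' @param motifs List of `pwm_motif` objects.
#' @param ... Passed to [motif_ztest()].
#' @return Tibble sorted by `p_value`, one row per motif.
#' @export
motif_enrichment <- function(fg, bg, motifs, ...) {
  purrr::map_dfr(motifs, function(m) motif_ztest(fg, bg, m, ...)) |>
    dplyr::arrange(.data$p_value)
}
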