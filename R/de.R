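# Two-group negative-binomial differential expression with a Wald test,
# an in-package Benjamini-Hochberg step-up, and the combined
# fold-change/significance DEG call applied identically to the mRNA and
# miRNA arms.

#' Negative-binomial Wald test for two groups
#'
#' Fits per-group means on the normalized scale and tests
#' `log2(mean_case / mean_control) = 0` with a Wald statistic. The
#' per-feature dispersion is a pooled within-group moment estimate
#' `alpha = (s2 - mu) / mu^2`, floored at `alpha_min` and, by default, at
#' the genome-wide median of the moment estimates - a moderation that
#' keeps the small-sample test close to its nominal size (gene-wise moment
#' estimates at n ~ 10 are too noisy to plug in raw). The standard error
#' comes from the delta method with `Var(norm_s) = mu / sf_s + alpha *
#' mu^2`; p-values use the normal reference, two-sided.
#'
#' Features that are all-zero in a group do not crash: the pseudo-count
#' bounds the fold change, and a zero/degenerate standard error yields
#' p = 1.
#'
#' @param counts Raw counts tibble (`feature_id` + sample columns).
#' @param samples Sample sheet tibble (`sample_id`, `group` in
#'   control/case), both groups with at least 2 samples.
#' @param size_factors Optional size-factor tibble; estimated by
#'   median-of-ratios when `NULL`.
#' @param pseudo_count Pseudo-count on the normalized scale used in the
#'   fold change and its standard error.
#' @param alpha_min Dispersion floor for Poisson-like features.
#' @param moderate_dispersion If `TRUE` (default), floor each feature's
#'   dispersion at the genome-wide median moment estimate.
#' @return Tibble: `feature_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p_value`, `dispersion`.
#' @export
nb_wald_test <- function(counts, samples, size_factors = NULL,
                         pseudo_count = 1, alpha_min = 1e-8,
                         moderate_dispersion = TRUE) {
  m <- count_matrix(counts)
  check_samples(samples, colnames(m))
  ctrl <- group_ids(samples, "control")
  case <- group_ids(samples, "case")
  if (length(ctrl) < 2 || length(case) < 2) {
    stop("both groups need at least 2 samples")
  }
  size_factors <- size_factors %||% estimate_size_factors(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(m)]
  nm <- sweep(m, 2, sf, "/")

  n1 <- length(ctrl); n2 <- length(case)
  m1 <- rowMeans(nm[, ctrl, drop = FALSE])
  m2 <- rowMeans(nm[, case, drop = FALSE])
  v1 <- apply(nm[, ctrl, drop = FALSE], 1, var)
  v2 <- apply(nm[, case, drop = FALSE], 1, var)
  mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  disp <- pmax((s2 - mu) / mu^2, alpha_min)
  disp[!is.finite(disp)] <- alpha_min
  if (moderate_dispersion) {
    expressed <- mu > 0
    if (any(expressed)) disp <- pmax(disp, median(disp[expressed]))
  }

  lfc <- log2((m2 + pseudo_count) / (m1 + pseudo_count))
  # Var(mean of normalized counts); 1/sf enters through the NB sampling
  # variance of each library
  inv1 <- mean(1 / sf[ctrl]); inv2 <- mean(1 / sf[case])
  var_mean <- function(mm, n, inv) (mm * inv + disp * mm^2) / n
  se <- sqrt(var_mean(m1, n1, inv1) / (m1 + pseudo_count)^2 +
             var_mean(m2, n2, inv2) / (m2 + pseudo_count)^2) / log(2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  p[!is.finite(stat)] <- 1
  stat[!is.finite(stat)] <- 0
  tibble::tibble(
    feature_id = rownames(m),
    base_mean = unname(rowMeans(nm)),
    log2fc = unname(lfc),
    se = unname(se),
    stat = unname(stat),
    p_value = unname(p),
    dispersion = unname(disp)
  )
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_i = min over ranks j >= rank(i) of p_(j) * m / j`, capped at 1;
#' invariant under permutation of the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  ord <- order(p_values)
  q <- p_values[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Call differentially expressed features
#'
#' A feature is DE when its group fold change satisfies
#' `max(FC, 1/FC) >= fc_threshold` and its significance value (BH q by
#' default, raw p with `use_fdr = FALSE`) is `<= alpha`; both thresholds
#' are inclusive. DE features are split by the sign of `log2fc` into
#' `up` and `down`; everything else is `ns`.
#'
#' @param de_table Output of [nb_wald_test()].
#' @param fc_threshold Linear fold-change threshold (default 1.5).
#' @param alpha Significance threshold (default 0.05).
#' @param use_fdr Test BH q (`TRUE`, default) or raw p (`FALSE`).
#' @return The table with `q_value`, `fold_change` (linear, case vs
#'   control) and `direction` columns added.
#' @export
call_degs <- function(de_table, fc_threshold = 1.5, alpha = 0.05,
                      use_fdr = TRUE) {
  stopifnot(fc_threshold >= 1, alpha > 0)
  de_table |>
    dplyr::mutate(
      q_value = benjamini_hochberg(.data$p_value),
      fold_change = 2^.data$log2fc,
      .sig = if (use_fdr) .data$q_value else .data$p_value,
      direction = dplyr::case_when(
        pmax(.data$fold_change, 1 / .data$fold_change) >= fc_threshold &
          .data$.sig <= alpha & .data$log2fc > 0 ~ "up",
        pmax(.data$fold_change, 1 / .data$fold_change) >= fc_threshold &
          .data$.sig <= alpha & .data$log2fc < 0 ~ "down",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::select(-".sig")
}

#' Up- and down-regulated feature id sets
#'
#' @param deg_table Output of [call_degs()].
#' @return List with `up` and `down` character vectors.
#' @export
deg_sets <- function(deg_table) {
  list(up = deg_table$feature_id[deg_table$direction == "up"],
       down = deg_table$feature_id[deg_table$direction == "down"])
}
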