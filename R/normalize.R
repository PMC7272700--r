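# Count normalization: median-of-ratios size factors, per-sample fold
# changes against the reference-group mean, CPM/RPKM conversion, the
# expressed-miRNA floor, and quartile-based abundance classes.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (with
#' nonzero counts in every sample) of the ratio of that sample's count to
#' the feature's geometric mean across samples. Factors are rescaled so
#' their geometric mean is 1, keeping the normalized scale comparable
#' across runs.
#'
#' @param counts Counts tibble (`feature_id` + one numeric column per
#'   sample).
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- count_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) {
    stop("no feature has nonzero counts in every sample; ",
         "pre-filter the matrix to features detected in all samples")
  }
  logm <- log(m[ok, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(median(col - loggeo)))
  sf <- sf / geometric_mean(sf)
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Normalize counts by size factors
#'
#' @inheritParams estimate_size_factors
#' @param size_factors Optional tibble from [estimate_size_factors()];
#'   estimated from `counts` when `NULL`.
#' @return Normalized counts tibble; size factors attached as the
#'   `"size_factors"` attribute.
#' @export
normalize_counts <- function(counts, size_factors = NULL) {
  size_factors <- size_factors %||% estimate_size_factors(counts)
  m <- count_matrix(counts)
  sf <- setNames(size_factors$size_factor, size_factors$sample_id)[colnames(m)]
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factors must be finite and > 0")
  out <- matrix_to_tibble(sweep(m, 2, sf, "/"))
  attr(out, "size_factors") <- size_factors
  out
}

#' Per-sample fold changes against the reference-group mean
#'
#' `FC[g, s] = (norm[g, s] + eps) / (mean over reference samples + eps)`,
#' the study's per-sample expression-stability measure. A pseudo-count
#' guards all-zero features (their fold change is 1).
#'
#' @param normalized Normalized counts tibble ([normalize_counts()]).
#' @param samples Sample sheet tibble (`sample_id`, `group`).
#' @param reference_group Group whose mean is the denominator.
#' @param pseudo_count Pseudo-count `eps` in normalized units.
#' @return Tibble of per-feature, per-sample fold changes (all samples).
#' @export
per_sample_fold_change <- function(normalized, samples,
                                   reference_group = "control",
                                   pseudo_count = 1) {
  m <- count_matrix(normalized)
  check_samples(samples, colnames(m))
  ref <- samples$sample_id[samples$group == reference_group]
  if (length(ref) == 0) stop("reference group is empty")
  denom <- rowMeans(m[, ref, drop = FALSE]) + pseudo_count
  matrix_to_tibble((m + pseudo_count) / denom)
}

#' Counts per million
#'
#' @inheritParams estimate_size_factors
#' @return CPM tibble; each sample column sums to 1e6.
#' @export
to_cpm <- function(counts) {
  m <- count_matrix(counts)
  matrix_to_tibble(sweep(m, 2, colSums(m), "/") * 1e6)
}

#' Reads per kilobase per million
#'
#' `RPKM = count * 1e9 / (library size * length_bp)`.
#'
#' @inheritParams estimate_size_factors
#' @param feature_lengths Tibble (`feature_id`, `length_bp`) or named
#'   numeric vector of feature lengths in base pairs.
#' @return RPKM tibble.
#' @export
to_rpkm <- function(counts, feature_lengths) {
  m <- count_matrix(counts)
  if (is.data.frame(feature_lengths)) {
    feature_lengths <- setNames(feature_lengths$length_bp,
                                feature_lengths$feature_id)
  }
  len <- feature_lengths[rownames(m)]
  if (any(is.na(len)) || any(len <= 0)) {
    stop("every feature needs a positive length_bp")
  }
  matrix_to_tibble(sweep(m, 2, colSums(m), "/") * 1e9 / len)
}

#' Detected-feature floor
#'
#' Keeps features with a raw count strictly greater than `threshold` in at
#' least one sample. This is the expressed-feature rule ("mapped reads
#' >32 in at least one of the sequenced samples"); applied to the mRNA arm
#' it defines the detected-gene universe.
#'
#' @inheritParams estimate_size_factors
#' @param threshold Count floor (strict inequality).
#' @return Filtered counts tibble; dropped feature ids in the
#'   `"dropped"` attribute.
#' @export
filter_detected <- function(counts, threshold = 32) {
  m <- count_matrix(counts)
  keep <- apply(m, 1, function(x) any(x > threshold))
  out <- counts[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

#' @rdname filter_detected
#' @export
filter_expressed_mirnas <- filter_detected

#' Quartile-based abundance classes
#'
#' Classifies features as `low` (below Q1), `high` (above Q3) or `medium`
#' otherwise, with quartiles (type-7, linear interpolation) computed on
#' the supplied abundance values themselves.
#'
#' @param values Numeric vector of mean abundances (e.g. mean RPKM or CPM
#'   per feature).
#' @return Character vector of classes, one per value.
#' @export
abundance_class <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  dplyr::case_when(
    values < q[1] ~ "low",
    values > q[2] ~ "high",
    TRUE ~ "medium"
  )
}
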