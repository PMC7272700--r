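# Internal helpers shared across modules.

# Deterministic child seed so each generator can be re-run independently
# from one global seed. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  offs <- c(
    counts = 11L, promoters = 23L, targets = 37L, image = 53L,
    split = 71L, background = 89L, kmeans = 97L
  )
  k <- offs[[stream]]
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483587)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Convert a feature tibble (feature_id + one numeric column per sample)
# into a numeric matrix with feature rownames.
feature_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "feature_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "feature_id")])
  rownames(m) <- tbl$feature_id
  storage.mode(m) <- "double"
  m
}

# Same, but enforces the raw-count contract.
count_matrix <- function(counts) {
  m <- feature_matrix(counts)
  if (any(m < 0, na.rm = TRUE)) stop("counts must be non-negative")
  m
}

matrix_to_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

check_samples <- function(samples, sample_ids = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "group") %in% names(samples)))
  if (!all(samples$group %in% c("control", "case"))) {
    stop("sample groups must be 'control' or 'case'")
  }
  if (!all(c("control", "case") %in% samples$group)) {
    stop("both groups must be non-empty")
  }
  if (!is.null(sample_ids) && !setequal(samples$sample_id, sample_ids)) {
    stop("sample sheet does not cover the count matrix samples")
  }
  invisible(samples)
}

group_ids <- function(samples, group) {
  samples$sample_id[samples$group == group]
}
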