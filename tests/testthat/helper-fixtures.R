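# Shared fixtures and independent oracles used across the suite.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 400L, n_mirnas = 60L, ...)
}

# tiny counts tibble from a plain matrix
counts_tbl <- function(m, samples = NULL) {
  colnames(m) <- samples %||% sprintf("S%d", seq_len(ncol(m)))
  tibble::tibble(feature_id = sprintf("g%d", seq_len(nrow(m))),
                 !!!as.data.frame(m))
}

two_group_sheet <- function(n_control, n_case) {
  tibble::tibble(
    sample_id = c(sprintf("C%d", seq_len(n_control)),
                  sprintf("L%d", seq_len(n_case))),
    group = rep(c("control", "case"), c(n_control, n_case))
  )
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

# Brute-force BH step-up, straight from the definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(i) {
    min(c(ps[i:m] * m / (i:m), 1))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive-placement PWM oracle: score every offset on both strands
# with plain loops, duplicating none of the package's vectorized code.
best_hit_oracle <- function(seq, motif, pseudocount = 0.1,
                            background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  prob <- sweep(motif$pfm + pseudocount, 2,
                colSums(motif$pfm + pseudocount), "/")
  lo <- log2(prob / (background / sum(background)))
  score_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- ncol(lo)
    best <- -Inf
    for (off in seq_len(nchar(s) - w + 1)) {
      tot <- 0
      for (j in seq_len(w)) {
        b <- ch[off + j - 1]
        tot <- tot + if (b == "N") {
          sum(lo[, j] * background / sum(background))
        } else lo[match(b, bases), j]
      }
      best <- max(best, tot)
    }
    best
  }
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(seq, "")[[1]])), collapse = "")
  raw <- max(score_one(seq), score_one(rc))
  lo_min <- sum(apply(lo, 2, min)); lo_max <- sum(apply(lo, 2, max))
  (raw - lo_min) / (lo_max - lo_min)
}

# Adjusted Rand index (Hubert & Arabie), independent small implementation
# for unit tests; acceptance uses mclust's.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  e1 <- sum_comb(rowSums(tab)); e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  (idx - expected) / ((e1 + e2) / 2 - expected)
}
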