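# Histology quantification: image binarization, box-counting fractal
# dimension (tissue disorganization, 0..2), stained-area fraction
# normalized by cell density, and the two-group comparison.

#' Construct a binary image
#'
#' @param mask Logical matrix (foreground = stained pixels).
#' @param threshold Binarization threshold used (for provenance).
#' @param method Label of the thresholding method or generator.
#' @param true_dimension Known fractal dimension, for synthetic fixtures.
#' @return A `binary_image`.
#' @export
binary_image <- function(mask, threshold = NA_real_, method = "manual",
                         true_dimension = NA_real_) {
  stopifnot(is.matrix(mask), is.logical(mask), length(mask) > 0)
  structure(list(mask = mask, threshold = threshold, method = method),
            true_dimension = true_dimension, class = "binary_image")
}

#' Read a PNG or TIFF image
#'
#' @param path Image path (.png, .tif/.tiff).
#' @return Numeric matrix (grey) or H x W x channels array in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext)
}

# Collapse an RGB(A) array to the channel carrying the staining signal.
image_channel <- function(img, channel = c("red_dominance", "luminance",
                                           "value")) {
  channel <- match.arg(channel)
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  x <- switch(channel,
    red_dominance = r - (g + b) / 2,  # Picrosirius red over background
    luminance = 0.299 * r + 0.587 * g + 0.114 * b,
    value = pmax(r, g, b)
  )
  (x - min(x)) / max(max(x) - min(x), .Machine$double.eps)
}

#' Binarize a micrograph
#'
#' Thresholds the staining channel with Otsu's method (default) or a
#' fixed cutoff. `polarity = "bright"` calls pixels above the threshold
#' foreground (stained); `"dark"` the reverse.
#'
#' @param img Numeric matrix in \[0, 1\] or RGB array ([read_image()]).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Cutoff for `method = "fixed"`.
#' @param polarity Which side of the threshold is foreground.
#' @param channel Channel reduction for RGB input.
#' @return A `binary_image` recording the threshold used.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("bright", "dark"),
                     channel = "red_dominance") {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  x <- image_channel(img, channel)
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    threshold
  }
  mask <- if (polarity == "bright") x > thr else x <= thr
  binary_image(mask, threshold = thr, method = method)
}

#' Box-counting fractal dimension
#'
#' Counts, for each box size `s`, the boxes of an origin-anchored
#' `s x s` grid containing at least one foreground pixel, and estimates
#' the dimension as the least-squares slope of `log N(s)` versus
#' `log(1/s)`. Values near 2 indicate plane-filling (disorganized)
#' patterns; isolated points give ~0. Default ladder: powers of 2 from 2
#' to `min(H, W)/2`, or powers of 3 from 1 when both dimensions are
#' powers of 3 (the aligned ladder is exact for Sierpinski-carpet
#' fixtures).
#'
#' @param img A `binary_image` (or logical matrix).
#' @param sizes Optional integer vector of box sizes (at least 4).
#' @return A `fractal_estimate`: `dimension`, `sizes`, `counts`,
#'   `intercept`, `r_squared`.
#' @export
box_count_dimension <- function(img, sizes = NULL) {
  mask <- if (inherits(img, "binary_image")) img$mask else img
  stopifnot(is.matrix(mask), is.logical(mask))
  if (min(dim(mask)) < 8) stop("image too small for fractal estimation")
  if (!any(mask)) stop("no foreground")
  if (is.null(sizes)) {
    lim <- min(dim(mask)) / 2
    lg3 <- log(dim(mask)) / log(3)
    if (all(abs(lg3 - round(lg3)) < 1e-9)) {
      sizes <- 3^(0:floor(log(lim) / log(3)))
    } else {
      sizes <- 2^(seq_len(floor(log(lim) / log(2))))
    }
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) < 4) stop("need at least 4 box sizes")
  fg <- which(mask, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    bx <- (fg[, 1] - 1L) %/% s
    by <- (fg[, 2] - 1L) %/% s
    length(unique(bx * (max(by) + 1) + by))
  }, numeric(1))
  fit <- lm(log(counts) ~ log(1 / sizes))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log(counts) - mean(log(counts)))^2)
  structure(list(
    dimension = unname(coef(fit)[2]),
    sizes = sizes,
    counts = counts,
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  ), class = "fractal_estimate")
}

#' Stained-area fraction normalized by cell density
#'
#' `score = (foreground pixels / total pixels) / cell_density`; the
#' density normalization accounts for individual fiber atrophy when
#' comparing stained-area fractions across groups.
#'
#' @param img A `binary_image`.
#' @param cell_density Cells per field (> 0), counted externally.
#' @return Tibble: `area_fraction`, `cell_density`, `score`.
#' @export
stained_area_fraction <- function(img, cell_density = 1) {
  stopifnot(inherits(img, "binary_image"), cell_density > 0)
  frac <- mean(img$mask)
  tibble::tibble(area_fraction = frac, cell_density = cell_density,
                 score = frac / cell_density)
}

#' Two-group comparison of image scores
#'
#' Two-sample Student's t-test (equal variance by default), two-tailed.
#'
#' @param scores_control,scores_case Numeric score vectors.
#' @param var_equal Pool variances (default `TRUE`).
#' @return Tibble: `statistic`, `p_value`, `mean_control`, `mean_case`,
#'   `df`.
#' @export
group_compare <- function(scores_control, scores_case, var_equal = TRUE) {
  if (sd(c(scores_control, scores_case)) == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1,
                          mean_control = mean(scores_control),
                          mean_case = mean(scores_case),
                          df = length(scores_control) +
                            length(scores_case) - 2))
  }
  fit <- t.test(scores_case, scores_control, var.equal = var_equal)
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 mean_control = mean(scores_control),
                 mean_case = mean(scores_case),
                 df = unname(fit$parameter))
}
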