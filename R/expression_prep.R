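# Gene filtering and normalisation: mean-count filter, log2-CPM transform and
# a mean-variance precision-weight trend (a voom-style weighting; the
# smoother is lowess with span 0.5 and the trend is interpolated piecewise
# linearly).

#' Filter genes on mean count
#'
#' Keeps genes whose mean raw count over all samples of the tissue is strictly
#' greater than the threshold (default: mean count of more than five).
#'
#' @param counts Genes x samples count matrix.
#' @param mean_threshold Strict lower bound on the gene mean (default 5).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, mean_threshold = 5) {
  if (any(counts < 0)) stop("negative counts")
  counts[rowMeans(counts) > mean_threshold, , drop = FALSE]
}

#' log2 counts-per-million
#'
#' `log2((count + 0.5) / (library_size + 1) * 1e6)` with library sizes taken
#' as the column sums of the supplied (already filtered) matrix.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric matrix of the same shape.
#' @export
log_cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero-library sample")
  log2(sweep(counts + 0.5, 2, lib + 1, `/`) * 1e6)
}

#' Mean-variance precision weights
#'
#' Per gene, ordinary least squares on the design matrix gives residual
#' standard deviations; the square root of the sd is smoothed against the mean
#' log-expression with lowess (span 0.5), and each observation's weight is the
#' inverse fourth power of the trend interpolated at its fitted value
#' (piecewise linear, constant beyond the outer knots). Weights are clipped to
#' `[1e-6, 1e6]`.
#'
#' @param normalised Genes x samples log2-CPM matrix.
#' @param design Samples x covariates design matrix (with intercept); default
#'   intercept-only.
#' @param span lowess span (default 0.5).
#' @param sample_weights Optional per-sample weights multiplied into the
#'   gene-wise weights (a simplified stand-in for array-quality weighting).
#' @return List with `weights` (same shape as `normalised`), `fitted`
#'   (per-observation fitted values), and `trend` (list of `x`, `y` knots).
#' @export
mean_variance_weights <- function(normalised, design = NULL, span = 0.5,
                                  sample_weights = NULL) {
  n <- ncol(normalised)
  if (is.null(design)) design <- matrix(1, n, 1)
  design <- as.matrix(design)
  if (n < 4L) stop("need >= 4 samples")
  if (n < ncol(design) + 1L) stop("fewer samples than design columns + 1")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) stop("rank-deficient design")
  fit <- t(qr.fitted(qr_x, t(normalised)))
  res <- normalised - fit
  df_res <- n - qr_x$rank
  s <- sqrt(rowSums(res^2) / df_res)
  mean_expr <- rowMeans(normalised)
  lo <- stats::lowess(mean_expr, sqrt(s), f = span)
  trend_at <- function(x) {
    y <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = "ordered")$y
    pmax(y, 1e-3)  # guard against a non-positive smoothed sd
  }
  w <- trend_at(fit)^-4
  dim(w) <- dim(normalised)
  dimnames(w) <- dimnames(normalised)
  if (!is.null(sample_weights)) {
    stopifnot(length(sample_weights) == n, all(sample_weights > 0))
    w <- sweep(w, 2, sample_weights, `*`)
  }
  w <- pmin(pmax(w, 1e-6), 1e6)
  list(weights = w, fitted = fit, trend = list(x = lo$x, y = lo$y),
       trend_at = trend_at)
}

#' Prepare an expression set for one tissue
#'
#' Applies the mean-count filter, the log2-CPM transform (library sizes
#' computed after filtering) and the mean-variance weight trend.
#'
#' @param counts Raw genes x samples count matrix.
#' @param tissue Tissue label.
#' @param design Optional design matrix for the weight trend.
#' @param mean_threshold Mean-count filter threshold.
#' @return Object of class `expression_set`: list with `tissue`, `counts`
#'   (filtered), `normalised`, `weights`.
#' @export
prepare_expression <- function(counts, tissue = "tissue", design = NULL,
                               mean_threshold = 5) {
  filtered <- filter_low_expression(counts, mean_threshold)
  if (!nrow(filtered)) stop("no genes pass the mean-count filter")
  normalised <- log_cpm(filtered)
  mv <- mean_variance_weights(normalised, design)
  structure(list(tissue = tissue, counts = filtered,
                 normalised = normalised, weights = mv$weights),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set [", x$tissue, "]: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}
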