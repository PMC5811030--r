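# Matrix-formulated single-tissue cis/trans eQTL scan: covariates are
# projected out of both the genotype and expression matrices, rows are
# standardised to unit norm, and every gene-SNP correlation is obtained by a
# blockwise matrix product. t and p follow from r with df = n - rank(X) - 1.
# Pairs are classified cis when the SNP lies within the window around the
# gene body, and retained at class-specific p thresholds with BH FDR computed
# separately per class.

#' Project covariates out of a variable x sample matrix
#'
#' Each row is replaced by its least-squares residual against the covariate
#' column space.
#'
#' @param mat Variables x samples numeric matrix.
#' @param covariates Samples x covariates matrix of full column rank
#'   (include the intercept explicitly).
#' @return Residual matrix of the same shape; residuals are orthogonal to
#'   every covariate column.
#' @export
residualize <- function(mat, covariates) {
  covariates <- as.matrix(covariates)
  stopifnot(ncol(mat) == nrow(covariates))
  qr_x <- qr(covariates)
  if (qr_x$rank < ncol(covariates)) stop("rank-deficient covariates")
  t(qr.resid(qr_x, t(mat)))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1. Equivalent to
#' `p.adjust(p, "BH")`; implemented explicitly because it is part of the
#' method contract (applied separately within tissue x class).
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Group covariate matrix for the scan
#'
#' Intercept plus indicator columns for the non-reference boar-taint groups.
#'
#' @param samples Sample table with a `group` column.
#' @return Samples x 3 design matrix (intercept, medium, high).
#' @export
group_covariates <- function(samples) {
  g <- factor(samples$group, levels = c("low", "medium", "high"))
  stats::model.matrix(~g)
}

#' cis/trans eQTL scan
#'
#' @param genotypes Samples x variants dosage matrix (post-QC). Missing
#'   dosages are mean-imputed within variant for the correlation computation.
#' @param expression An `expression_set` (or a genes x samples normalised
#'   matrix).
#' @param variants Variant table for the panel.
#' @param annotation Gene annotation covering the expression rows.
#' @param covariates Samples x covariates matrix (default: intercept +
#'   group indicators cannot be derived here, so intercept-only; pass
#'   [group_covariates()] for the standard model).
#' @param config A [run_config()]; `p_cis`, `p_trans`, `cis_window_bp`,
#'   `fdr_target` are used.
#' @param tissue Tissue label stored on the records.
#' @param keep_all Retain every pair regardless of the p thresholds
#'   (classification and FDR still computed); used for calibration studies.
#' @param block_size Number of variants per matrix-product block.
#' @return data.frame of eQTL records: `variant_id`, `gene_id`, `tissue`,
#'   `eqtl_class` ("cis"/"trans"), `distance` (SNP pos - gene start; negative
#'   = upstream of the gene start), `r`, `t`, `p`, `fdr_eqtl`, `significant`
#'   (fdr_eqtl < target). Attributes: `df`, `n_samples`, `n_tests` (per
#'   class).
#' @export
eqtl_scan <- function(genotypes, expression, variants, annotation,
                      covariates = NULL, config = run_config(),
                      tissue = if (inherits(expression, "expression_set"))
                        expression$tissue else "tissue",
                      keep_all = FALSE, block_size = 2000L) {
  expr <- if (inherits(expression, "expression_set")) expression$normalised
          else expression
  stopifnot(identical(colnames(expr), rownames(genotypes)))
  n <- ncol(expr)
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  covariates <- as.matrix(covariates)

  # order/limit to annotated genes and panel variants
  ann <- annotation[match(rownames(expr), annotation$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id)) stop("expression rows missing from the annotation")
  variants <- variants[variants$variant_id %in% colnames(genotypes), ,
                       drop = FALSE]

  geno <- genotypes[, variants$variant_id, drop = FALSE]
  geno <- apply(geno, 2, function(x) {
    x <- as.numeric(x)
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  qr_x <- qr(covariates)
  if (qr_x$rank < ncol(covariates)) stop("rank-deficient covariates")
  df <- n - qr_x$rank - 1L
  if (df < 1L) stop("not enough residual degrees of freedom")

  std_rows <- function(m) {
    r <- t(qr.resid(qr_x, t(m)))
    nrm <- sqrt(rowSums(r^2))
    zero <- nrm < 1e-12
    if (any(zero)) {
      warning(sum(zero), " zero-variance rows dropped from the scan")
      r <- r[!zero, , drop = FALSE]
      nrm <- nrm[!zero]
    }
    r / nrm
  }
  e_std <- std_rows(expr)
  g_std <- std_rows(t(geno))
  keep_var <- match(rownames(g_std), variants$variant_id)
  variants <- variants[keep_var, , drop = FALSE]
  ann <- ann[match(rownames(e_std), ann$gene_id), , drop = FALSE]

  w <- config$cis_window_bp
  out <- vector("list", 0L)
  n_tests <- c(cis = 0, trans = 0)
  for (b_start in seq(1L, nrow(g_std), by = block_size)) {
    b <- b_start:min(b_start + block_size - 1L, nrow(g_std))
    r <- e_std %*% t(g_std[b, , drop = FALSE])       # genes x block
    same_chr <- outer(ann$chrom, variants$chrom[b], `==`)
    pos <- matrix(variants$pos[b], nrow(ann), length(b), byrow = TRUE)
    is_cis <- same_chr & pos >= (ann$start - w) & pos <= (ann$end + w)
    n_tests["cis"] <- n_tests["cis"] + sum(is_cis)
    n_tests["trans"] <- n_tests["trans"] + sum(!is_cis)
    r_c <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
    tt <- r_c * sqrt(df / (1 - r_c^2))
    p <- 2 * stats::pt(-abs(tt), df)
    thr <- ifelse(is_cis, config$p_cis, config$p_trans)
    sel <- if (keep_all) !is.na(p) else p < thr
    if (!any(sel)) next
    idx <- which(sel, arr.ind = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      variant_id = variants$variant_id[b][idx[, 2]],
      gene_id = ann$gene_id[idx[, 1]],
      tissue = tissue,
      eqtl_class = ifelse(is_cis[sel], "cis", "trans"),
      snp_chrom = variants$chrom[b][idx[, 2]],
      distance = variants$pos[b][idx[, 2]] - ann$start[idx[, 1]],
      r = r[sel], t = tt[sel], p = p[sel],
      stringsAsFactors = FALSE)
  }
  records <- if (length(out)) do.call(rbind, out) else
    data.frame(variant_id = character(), gene_id = character(),
               tissue = character(), eqtl_class = character(),
               snp_chrom = character(), distance = numeric(), r = numeric(),
               t = numeric(), p = numeric(), stringsAsFactors = FALSE)
  records$fdr_eqtl <- rep(NA_real_, nrow(records))
  for (cl in c("cis", "trans")) {
    i <- records$eqtl_class == cl
    # BH over the number of tests performed in the class, not only the
    # retained pairs: q = min over j>=i of p_(j) * m / j with m = n_tests.
    if (any(i)) records$fdr_eqtl[i] <-
        bh_fdr_partial(records$p[i], m_total = n_tests[[cl]])
  }
  records$significant <- records$fdr_eqtl < config$fdr_target
  ord <- order(records$fdr_eqtl, records$p)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "df") <- df
  attr(records, "n_samples") <- n
  attr(records, "n_tests") <- n_tests
  class(records) <- c("eqtl_records", "data.frame")
  records
}

# BH step-up when only the smallest p-values of a family are retained: ranks
# within the retained set equal ranks in the full family (the set contains
# every p below its threshold), and m is the full number of tests. Unretained
# (larger) p-values can only lower q via their own smaller m/j factors, so the
# values here are a (slightly conservative) upper bound on full-family BH;
# with keep_all scans the two coincide exactly.
bh_fdr_partial <- function(p, m_total) {
  k <- length(p)
  if (!k) return(numeric(0))
  o <- order(p)
  q <- p[o] * m_total / seq_len(k)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Recompute scan statistics for a fixed list of gene-SNP pairs
#'
#' Same statistic as [eqtl_scan()] but for given pairs, regardless of
#' thresholds; used to fill in the partner tissue's statistics for the
#' multi-tissue z-matrix.
#'
#' @param genotypes,expression,covariates As in [eqtl_scan()].
#' @param pairs data.frame with `gene_id` and `variant_id`.
#' @return `pairs` with `r`, `t`, `p` columns and attribute `df`.
#' @export
scan_pairs <- function(genotypes, expression, pairs, covariates = NULL) {
  expr <- if (inherits(expression, "expression_set")) expression$normalised
          else expression
  stopifnot(identical(colnames(expr), rownames(genotypes)))
  n <- ncol(expr)
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  qr_x <- qr(as.matrix(covariates))
  df <- n - qr_x$rank - 1L
  res <- function(v) {
    r <- qr.resid(qr_x, v)
    nrm <- sqrt(sum(r^2))
    if (nrm < 1e-12) rep(0, n) else r / nrm
  }
  r_out <- t_out <- p_out <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene_id[i]; v <- pairs$variant_id[i]
    if (!g %in% rownames(expr) || !v %in% colnames(genotypes)) next
    x <- as.numeric(genotypes[, v])
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    rv <- sum(res(expr[g, ]) * res(x))
    rv <- min(max(rv, -(1 - 1e-12)), 1 - 1e-12)
    r_out[i] <- rv
    t_out[i] <- rv * sqrt(df / (1 - rv^2))
    p_out[i] <- 2 * stats::pt(-abs(t_out[i]), df)
  }
  out <- cbind(pairs, r = r_out, t = t_out, p = p_out)
  attr(out, "df") <- df
  out
}

#' Write eQTL records as TSV
#'
#' Columns mirror the published table layout (SNP, Gene, FDR-eQTL, SNP
#' chromosome, Distance) plus the raw statistics.
#'
#' @param records eQTL record data.frame.
#' @param path Output path.
#' @export
write_eqtl_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
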