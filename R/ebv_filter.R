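# Per-eQTL association of genotype classes with summarised EBVs and with the
# gene's expression: nested-model F tests (response ~ covariates vs response ~
# covariates + genotype factor), BH-FDR corrected per tissue and test family.
# eQTLs significant in both families are the "filtered eQTLs".

#' Nested-model F test of a genotype factor
#'
#' Compares `response ~ covariates` against `response ~ covariates +
#' genotype class` by the extra-sum-of-squares F test; the genotype enters as
#' an unordered factor over its non-empty classes. With `interactions = TRUE`
#' covariate x genotype terms are added to the full model.
#'
#' @param response Numeric response (EBV or normalised expression).
#' @param dosage Genotype dosages (0/1/2/NA) defining the classes.
#' @param covariates Samples x covariates matrix (intercept added here).
#' @param interactions Add covariate x genotype interaction terms.
#' @return List: `f`, `p`, `df1`, `df2`, `k` (non-empty classes),
#'   `degenerate` (zero residual variance in the full model).
#' @export
genotype_anova <- function(response, dosage, covariates = NULL,
                           interactions = FALSE) {
  ok <- !is.na(dosage) & !is.na(response)
  y <- response[ok]; d <- dosage[ok]
  n <- length(y)
  x0 <- cbind(1, if (!is.null(covariates))
    as.matrix(covariates)[ok, , drop = FALSE])
  k <- length(unique(d))
  if (k < 2L) {
    warning("single non-empty genotype class; p = 1")
    return(list(f = 0, p = 1, df1 = 0L, df2 = n - qr(x0)$rank, k = k,
                degenerate = FALSE))
  }
  g <- stats::model.matrix(~factor(d))[, -1, drop = FALSE]
  x1 <- cbind(x0, g)
  if (interactions && !is.null(covariates)) {
    cv <- as.matrix(covariates)[ok, , drop = FALSE]
    for (j in seq_len(ncol(cv))) x1 <- cbind(x1, g * cv[, j])
  }
  q0 <- qr(x0); q1 <- qr(x1)
  rss0 <- sum(qr.resid(q0, y)^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- n - q1$rank
  if (df1 < 1L || df2 < 1L) stop("not enough samples for the nested F test")
  if (rss0 < .Machine$double.eps * max(1, sum(y^2)))  # constant-ish response
    return(list(f = 0, p = 1, df1 = df1, df2 = df2, k = k,
                degenerate = FALSE))
  if (rss1 < max(1e-12 * rss0, .Machine$double.eps))
    return(list(f = Inf, p = 0, df1 = df1, df2 = df2, k = k,
                degenerate = TRUE))
  f <- max(((rss0 - rss1) / df1) / (rss1 / df2), 0)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, k = k, degenerate = FALSE)
}

#' EBV association of one eQTL
#'
#' F test of the genotype classes against the summarised EBVs, adjusted for
#' the covariates (tissue yield, genotyping QC metric, RIN).
#'
#' @param dosage Dosages at the eQTL's SNP, in sample order.
#' @param samples Sample table ([read_samples()] layout).
#' @param interactions Passed to [genotype_anova()].
#' @return As [genotype_anova()].
#' @export
ebv_association <- function(dosage, samples, interactions = FALSE) {
  genotype_anova(samples$ebv, dosage,
                 covariates = as.matrix(samples[, c("yield_mg", "geno_qc",
                                                    "rin")]),
                 interactions = interactions)
}

#' Expression association of one eQTL
#'
#' As [ebv_association()] with the gene's normalised expression as response.
#'
#' @param expression_row Normalised expression of the eQTL's gene, in sample
#'   order.
#' @param dosage Dosages at the eQTL's SNP.
#' @param samples Sample table.
#' @param interactions Passed to [genotype_anova()].
#' @export
expression_association <- function(expression_row, dosage, samples,
                                   interactions = FALSE) {
  genotype_anova(expression_row, dosage,
                 covariates = as.matrix(samples[, c("yield_mg", "geno_qc",
                                                    "rin")]),
                 interactions = interactions)
}

#' Attach EBV and expression association FDRs to eQTL records
#'
#' Runs both association tests for every record, then BH-adjusts each test
#' family (EBV; expression) across all tested eQTLs of the tissue, pooled
#' over cis and trans.
#'
#' @param records `eqtl_records` for one tissue.
#' @param genotypes Post-QC dosage matrix.
#' @param expression `expression_set` (or normalised matrix) of the tissue.
#' @param samples Sample table.
#' @param interactions Passed to the association tests.
#' @return `records` with columns `p_ebv`, `p_expression`, `fdr_ebv`,
#'   `fdr_expression` appended.
#' @export
ebv_filter_tests <- function(records, genotypes, expression, samples,
                             interactions = FALSE) {
  expr <- if (inherits(expression, "expression_set")) expression$normalised
          else expression
  stopifnot(identical(rownames(genotypes), samples$sample_id),
            identical(colnames(expr), samples$sample_id))
  n <- nrow(records)
  p_ebv <- p_expr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- genotypes[, records$variant_id[i]]
    p_ebv[i] <- ebv_association(d, samples, interactions)$p
    p_expr[i] <- expression_association(expr[records$gene_id[i], ], d,
                                        samples, interactions)$p
  }
  records$p_ebv <- p_ebv
  records$p_expression <- p_expr
  records$fdr_ebv <- bh_fdr(p_ebv)
  records$fdr_expression <- bh_fdr(p_expr)
  records
}

#' Select the filtered eQTLs
#'
#' Retains records whose EBV-association FDR and expression-association FDR
#' are both below the target (conjunction rule).
#'
#' @param records Records with `fdr_ebv` and `fdr_expression` (from
#'   [ebv_filter_tests()]).
#' @param fdr_target FDR threshold (default 0.05).
#' @return The filtered subset, same columns.
#' @export
filter_eqtls <- function(records, fdr_target = 0.05) {
  stopifnot(all(c("fdr_ebv", "fdr_expression") %in% names(records)))
  out <- records[records$fdr_ebv < fdr_target &
                 records$fdr_expression < fdr_target, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-tissue/class bookkeeping of filtered eQTL counts
#'
#' Tallies records by tissue and cis/trans class and checks the additivity
#' identity total = cis + trans per tissue.
#'
#' @param records eQTL records with `tissue` and `eqtl_class` columns.
#' @return data.frame with one row per tissue: `cis`, `trans`, `total`.
#' @export
count_filtered <- function(records) {
  tab <- table(factor(records$tissue),
               factor(records$eqtl_class, levels = c("cis", "trans")))
  out <- data.frame(tissue = rownames(tab), cis = as.integer(tab[, "cis"]),
                    trans = as.integer(tab[, "trans"]),
                    stringsAsFactors = FALSE)
  out$total <- out$cis + out$trans
  out
}
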