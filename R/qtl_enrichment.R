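# Trait-QTL interval enrichment: breed filtering of the trait table, per-trait
# interval length over genome length as the per-SNP hit probability, a
# one-sided binomial test on observed SNP overlaps, BH FDR across traits, and
# the category-adjusted summary.

#' Filter a trait-QTL table by breed representation
#'
#' Keeps rows whose breed carries at least `min_qtls` QTLs in the input table
#' (removing sparsely represented breeds).
#'
#' @param traits A `trait_qtl_table`.
#' @param min_qtls Minimum per-breed QTL count (default 1000; rows of a breed
#'   with exactly `min_qtls` QTLs are kept).
#' @return The filtered table, with attribute `breed_counts`.
#' @export
breed_filter <- function(traits, min_qtls = 1000) {
  counts <- table(traits$breed)
  keep <- traits$breed %in% names(counts)[counts >= min_qtls]
  out <- traits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "breed_counts") <- counts
  class(out) <- class(traits)
  out
}

#' Summarised interval length of one trait
#'
#' With `merge = TRUE` (default) overlapping intervals are merged per
#' chromosome before summation (union length), preventing double counting;
#' `merge = FALSE` sums plain interval lengths. Interval length is
#' `end - start + 1`.
#'
#' @param trait_rows Rows of a trait-QTL table for one trait.
#' @param merge Merge overlapping intervals first (default TRUE).
#' @return Total length in bp.
#' @export
trait_length <- function(trait_rows, merge = TRUE) {
  if (!nrow(trait_rows)) return(0)
  if (!merge) return(sum(trait_rows$end - trait_rows$start + 1))
  total <- 0
  for (chr in unique(trait_rows$chrom)) {
    r <- trait_rows[trait_rows$chrom == chr, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
    total <- total + sum(IRanges::width(ir))
  }
  total
}

#' Count SNPs overlapping a trait's intervals
#'
#' A SNP counts once per trait no matter how many of the trait's intervals
#' cover it; interval ends are inclusive.
#'
#' @param snps Variant table subset (`variant_id`, `chrom`, `pos`).
#' @param trait_rows Rows of a trait-QTL table for one trait.
#' @return Integer overlap count `k`.
#' @export
count_overlaps <- function(snps, trait_rows) {
  sum(overlap_hits(snps, trait_rows))
}

# logical vector: does each SNP fall inside >= 1 interval of the trait
overlap_hits <- function(snps, trait_rows) {
  hit <- logical(nrow(snps))
  if (!nrow(snps) || !nrow(trait_rows)) return(hit)
  for (chr in unique(trait_rows$chrom)) {
    r <- trait_rows[trait_rows$chrom == chr, , drop = FALSE]
    on_chr <- which(snps$chrom == chr)
    if (!length(on_chr)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start, end = r$end))
    q <- IRanges::IRanges(start = snps$pos[on_chr], width = 1L)
    hit[on_chr] <- hit[on_chr] | (IRanges::countOverlaps(q, ir) > 0L)
  }
  hit
}

#' One-sided binomial enrichment p-value
#'
#' With per-SNP hit probability `pi = L_trait / G`, returns
#' `P(X >= k)` for `X ~ Binomial(n_snps, pi)`; `k = 0` gives p = 1.
#'
#' @param k Observed overlapping SNP count.
#' @param n_snps Number of SNPs tested.
#' @param l_trait Summarised trait interval length (bp).
#' @param g Genome background length (bp).
#' @return p-value.
#' @export
binomial_enrichment <- function(k, n_snps, l_trait, g) {
  if (l_trait > g) stop("trait length exceeds the genome background")
  if (l_trait <= 0) stop("non-positive trait length")
  if (k < 0 || k > n_snps) stop("k outside [0, n_snps]")
  pi <- min(l_trait / g, 1)
  if (k == 0) return(1)
  stats::pbinom(k - 1, n_snps, pi, lower.tail = FALSE)
}

#' Trait-QTL enrichment over all traits
#'
#' Deduplicates the SNP set (a SNP shared by several eQTLs is one trial),
#' computes per trait the summarised interval length, the observed overlap
#' count and the binomial p-value, applies BH across all tested traits, and
#' attaches the gene lists of the overlapping SNPs' eQTLs.
#'
#' @param records Filtered cis eQTL records (`variant_id`, `gene_id`).
#' @param variants Variant table giving SNP coordinates.
#' @param traits Trait-QTL table (breed-filter beforehand if desired).
#' @param g Genome background length in bp (default 2.7e9).
#' @param fdr_target Enrichment FDR threshold (default 0.05).
#' @param merge Merge overlapping intervals per trait (default TRUE).
#' @return data.frame of class `enrichment_results`: `trait`, `category`,
#'   `n_snps`, `k`, `l_trait`, `pi`, `p`, `fdr`, `enriched`, `genes`
#'   (comma-separated overlapping eQTL genes), sorted by FDR then p.
#' @export
enrich_all <- function(records, variants, traits, g = 2.7e9,
                       fdr_target = 0.05, merge = TRUE) {
  snps <- unique(records$variant_id)
  snp_tab <- variants[match(snps, variants$variant_id), , drop = FALSE]
  if (anyNA(snp_tab$variant_id)) stop("eQTL SNP missing from the variant table")
  n_snps <- nrow(snp_tab)
  trait_names <- unique(traits$trait)
  rows <- lapply(trait_names, function(tr) {
    tr_rows <- traits[traits$trait == tr, , drop = FALSE]
    l <- trait_length(tr_rows, merge = merge)
    hit <- overlap_hits(snp_tab, tr_rows)
    k <- sum(hit)
    genes <- sort(unique(records$gene_id[records$variant_id %in%
                                           snp_tab$variant_id[hit]]))
    data.frame(trait = tr, category = tr_rows$category[1],
               n_snps = n_snps, k = k, l_trait = l, pi = min(l / g, 1),
               p = binomial_enrichment(k, n_snps, l, g),
               genes = paste(genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$enriched <- out$fdr < fdr_target
  out <- out[order(out$fdr, out$p, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_results", "data.frame")
  out
}

#' Category summary of enriched traits
#'
#' Counts enriched traits per category and divides by the database-wide
#' category totals; the adjusted frequency is reported rounded to 3 decimals
#' (exact value kept in `adjusted_exact`).
#'
#' @param enriched Character vector of enriched trait names, or an
#'   `enrichment_results` (its `enriched` rows are used).
#' @param trait_categories Named character vector mapping trait -> category
#'   (ignored when `enriched` is an `enrichment_results`).
#' @param category_totals Named numeric vector of per-category database QTL
#'   totals.
#' @return data.frame: `category`, `n_enriched`, `total_qtls`,
#'   `adjusted_exact`, `adjusted` (3 decimals), sorted by `adjusted` then
#'   category.
#' @export
category_summary <- function(enriched, trait_categories = NULL,
                             category_totals) {
  if (inherits(enriched, "enrichment_results")) {
    sel <- enriched[enriched$enriched, , drop = FALSE]
    cats <- sel$category
  } else {
    if (is.null(trait_categories)) stop("trait_categories required")
    miss <- setdiff(enriched, names(trait_categories))
    if (length(miss)) stop("trait without category: ", miss[1])
    cats <- trait_categories[enriched]
  }
  tab <- table(cats)
  miss <- setdiff(names(tab), names(category_totals))
  if (length(miss)) stop("category missing from totals: ", miss[1])
  out <- data.frame(category = names(tab),
                    n_enriched = as.integer(tab),
                    total_qtls = as.numeric(category_totals[names(tab)]),
                    stringsAsFactors = FALSE)
  out$adjusted_exact <- out$n_enriched / out$total_qtls
  out$adjusted <- round(out$adjusted_exact, 3)
  out <- out[order(-out$adjusted, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
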