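# Candidate eQTL selection: filtered cis eQTLs whose genotype class carries a
# median summarised EBV at or below the low-group maximum, and whose SNP
# overlaps an enriched boar-taint trait.

#' Per-genotype-class EBV statistics at one eQTL
#'
#' @param dosage Dosages at the SNP (0/1/2/NA).
#' @param samples Sample table with `ebv`.
#' @param alleles Optional character(2) `c(allele_a, allele_b)` used to label
#'   classes (e.g. "AA"/"AB"/"BB"); defaults to dosage labels.
#' @return data.frame: `genotype`, `dosage`, `n`, `median_ebv`, `mean_ebv`;
#'   empty classes omitted.
#' @export
genotype_ebv_stats <- function(dosage, samples, alleles = NULL) {
  ok <- !is.na(dosage)
  if (!any(ok)) stop("all genotypes missing")
  d <- dosage[ok]; e <- samples$ebv[ok]
  lab <- if (!is.null(alleles)) {
    c(paste0(alleles[1], alleles[1]), paste0(alleles[1], alleles[2]),
      paste0(alleles[2], alleles[2]))
  } else c("0", "1", "2")
  rows <- lapply(sort(unique(d)), function(g) {
    ei <- e[d == g]
    data.frame(genotype = lab[g + 1L], dosage = g, n = length(ei),
               median_ebv = stats::median(ei), mean_ebv = mean(ei),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select candidate eQTLs for low-boar-taint selection
#'
#' Applies the two candidacy criteria to filtered cis eQTLs: (i) a genotype
#' class whose median summarised EBV is less than or equal to `ebv_max`
#' (inclusive), and (ii) the eQTL's SNP overlaps an enriched
#' (FDR < target) boar-taint trait. One row is emitted per (eQTL, qualifying
#' genotype, overlapped trait) triple.
#'
#' @param filtered_cis Filtered cis eQTL records (may span tissues; records
#'   of the same SNP-gene pair from both tissues are merged with tissue
#'   "both").
#' @param enrichment `enrichment_results` from [enrich_all()].
#' @param genotypes Post-QC dosage matrix.
#' @param samples Sample table.
#' @param variants Variant table (coordinates and allele labels).
#' @param traits Trait-QTL table used for the enrichment.
#' @param ebv_max Candidate genotype EBV cutoff (default -0.0699208, the
#'   low-group maximum).
#' @param boar_taint_traits Trait names considered boar-taint relevant.
#' @return data.frame of class `candidate_eqtls`: `variant_id`, `gene_id`,
#'   `genotype`, `n_carriers`, `median_ebv`, `mean_ebv`, `fdr_ebv`, `tissue`,
#'   `trait`.
#' @export
select_candidates <- function(filtered_cis, enrichment, genotypes, samples,
                              variants, traits,
                              ebv_max = -0.0699208,
                              boar_taint_traits = c("Fat androstenone level",
                                                    "indole, laboratory",
                                                    "Off-Flavor Score",
                                                    "Overall impression, sensory panel")) {
  if (!length(boar_taint_traits)) stop("boar-taint trait set is empty")
  bt <- enrichment[enrichment$enriched &
                   enrichment$trait %in% boar_taint_traits, , drop = FALSE]
  out <- list()
  if (nrow(bt) && nrow(filtered_cis)) {
    # merge duplicate SNP-gene pairs across tissues
    key <- paste(filtered_cis$variant_id, filtered_cis$gene_id, sep = "|")
    recs <- filtered_cis[!duplicated(key), , drop = FALSE]
    dup_tissue <- tapply(filtered_cis$tissue, key, function(ts)
      if (length(unique(ts)) > 1L) "both" else ts[1])
    recs$tissue <- as.character(dup_tissue[paste(recs$variant_id,
                                                 recs$gene_id, sep = "|")])
    fdr_min <- tapply(filtered_cis$fdr_ebv, key, min)
    recs$fdr_ebv <- as.numeric(fdr_min[paste(recs$variant_id, recs$gene_id,
                                             sep = "|")])
    for (i in seq_len(nrow(recs))) {
      v <- recs$variant_id[i]
      vrow <- variants[variants$variant_id == v, , drop = FALSE]
      if (!nrow(vrow)) next
      st <- genotype_ebv_stats(genotypes[, v], samples,
                               alleles = c(vrow$allele_a, vrow$allele_b))
      qual <- st[st$median_ebv <= ebv_max, , drop = FALSE]
      if (!nrow(qual)) next
      for (j in seq_len(nrow(bt))) {
        tr_rows <- traits[traits$trait == bt$trait[j], , drop = FALSE]
        if (!overlap_hits(vrow, tr_rows)) next
        out[[length(out) + 1L]] <- data.frame(
          variant_id = v, gene_id = recs$gene_id[i],
          genotype = qual$genotype, n_carriers = qual$n,
          median_ebv = qual$median_ebv, mean_ebv = qual$mean_ebv,
          fdr_ebv = recs$fdr_ebv[i], tissue = recs$tissue[i],
          trait = bt$trait[j], stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(variant_id = character(), gene_id = character(),
               genotype = character(), n_carriers = integer(),
               median_ebv = numeric(), mean_ebv = numeric(),
               fdr_ebv = numeric(), tissue = character(),
               trait = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  stopifnot(all(res$median_ebv <= ebv_max),
            all(res$trait %in% boar_taint_traits))
  class(res) <- c("candidate_eqtls", "data.frame")
  res
}

#' Candidate bookkeeping summary
#'
#' Reports the number of candidate eQTLs (unique SNP-gene pairs), unique
#' genes, and candidate genotypes (unique SNP-gene-genotype triples), plus the
#' per-gene genotype distribution. Row count and genotype count are reported
#' separately because a candidate eQTL can carry more than one qualifying
#' genotype and overlap more than one trait.
#'
#' @param candidates A `candidate_eqtls` data.frame, or any data.frame with
#'   `variant_id`, `gene_id` and (optionally) `genotype` columns.
#' @param gene_genotype_counts Optional named vector of per-gene candidate
#'   genotype counts to summarise instead of deriving them from `candidates`
#'   (used when replaying printed summaries where not every genotype is
#'   listed).
#' @return List: `n_rows`, `n_eqtls` (unique SNP-gene), `n_genes`,
#'   `n_genotypes`, `per_gene` (named vector, descending).
#' @export
summarise_candidates <- function(candidates, gene_genotype_counts = NULL) {
  key <- paste(candidates$variant_id, candidates$gene_id, sep = "|")
  if (is.null(gene_genotype_counts)) {
    gkey <- unique(paste(candidates$variant_id, candidates$gene_id,
                         candidates$genotype, sep = "|"))
    genes_of <- vapply(strsplit(gkey, "|", fixed = TRUE), `[[`, "", 2L)
    per_gene <- sort(table(genes_of), decreasing = TRUE)
  } else {
    per_gene <- sort(unlist(gene_genotype_counts), decreasing = TRUE)
  }
  list(n_rows = nrow(candidates),
       n_eqtls = length(unique(key)),
       n_genes = length(unique(candidates$gene_id)),
       n_genotypes = sum(per_gene),
       per_gene = per_gene)
}

#' Write candidates as TSV (published table layout)
#' @param candidates `candidate_eqtls`.
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(as.data.frame(candidates), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
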