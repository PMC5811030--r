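# Chromosomal eQTL densities and the Spearman co-expression network among
# multi-tissue eQTL genes.

#' Chromosomal eQTL densities
#'
#' Counts eQTL records by SNP chromosome and divides by chromosome length,
#' times a reporting scale (default 1e8; the absolute magnitude of published
#' density figures depends on an unstated scale, so it is configurable).
#' Chromosomes without eQTLs appear with density 0. Output is sorted from
#' highest to lowest density.
#'
#' @param records eQTL records with a `snp_chrom` column.
#' @param genome A `genome_build`.
#' @param scale Multiplier applied to count/length (default 1e8).
#' @return data.frame: `chrom`, `n_eqtls`, `length_bp`, `density`, sorted
#'   descending by density.
#' @export
chromosome_density <- function(records, genome, scale = 1e8) {
  if (!all(records$snp_chrom %in% genome$chrom_names))
    stop("eQTL on a chromosome absent from the genome build")
  counts <- table(factor(records$snp_chrom, levels = genome$chrom_names))
  out <- data.frame(chrom = genome$chrom_names,
                    n_eqtls = as.integer(counts),
                    length_bp = as.numeric(genome$chrom_lengths),
                    stringsAsFactors = FALSE)
  out$density <- out$n_eqtls / out$length_bp * scale
  out <- out[order(-out$density, out$chrom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman co-expression network over a gene set
#'
#' Computes the Spearman rank correlation (midranks for ties) for every
#' unordered gene pair of the set within each tissue and keeps edges with
#' `|rho| >= threshold`, recording the sign. Constant genes are excluded with
#' a warning.
#'
#' @param expressions Named list of `expression_set`s (or normalised
#'   matrices), one per tissue.
#' @param genes Character vector of gene ids to correlate.
#' @param threshold Absolute-coefficient threshold (default 0.5).
#' @return data.frame of edges: `gene_i`, `gene_j` (`gene_i < gene_j`),
#'   `tissue`, `rho`, `sign` ("positive"/"negative").
#' @export
spearman_network <- function(expressions, genes, threshold = 0.5) {
  edges <- list()
  for (tissue in names(expressions)) {
    expr <- expressions[[tissue]]
    if (inherits(expr, "expression_set")) expr <- expr$normalised
    if (ncol(expr) < 4L) stop("need >= 4 samples")
    gs <- intersect(genes, rownames(expr))
    if (length(gs) < 2L) next
    m <- expr[gs, , drop = FALSE]
    const <- apply(m, 1, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning("excluding constant genes: ",
              paste(gs[const], collapse = ", "))
      m <- m[!const, , drop = FALSE]
      gs <- gs[!const]
    }
    if (length(gs) < 2L) next
    rho <- stats::cor(t(m), method = "spearman")
    idx <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
    if (!nrow(idx)) next
    gi <- gs[idx[, 1]]; gj <- gs[idx[, 2]]
    swap <- gi > gj
    tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
    edges[[length(edges) + 1L]] <- data.frame(
      gene_i = gi, gene_j = gj, tissue = tissue,
      rho = rho[idx],
      sign = ifelse(rho[idx] >= 0, "positive", "negative"),
      stringsAsFactors = FALSE)
  }
  if (!length(edges))
    return(data.frame(gene_i = character(), gene_j = character(),
                      tissue = character(), rho = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
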