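# Readers/writers for the external formats the pipeline touches, the genome
# description, and the run configuration. All genomic coordinates are handled
# 1-based inclusive internally (PLINK/GFF3 convention); BED inputs are shifted
# on read (+1 to start) and on write (-1).

#' Construct a genome build
#'
#' A genome build names the chromosomes and their lengths in base pairs. It is
#' the coordinate frame for variant tables, gene annotations and trait-QTL
#' intervals, and supplies the background length for the interval enrichment
#' test.
#'
#' @param chrom_names Character vector of unique chromosome labels, in order.
#' @param chrom_lengths Positive integer-valued vector of lengths in bp,
#'   parallel to `chrom_names`.
#' @return An object of class `genome_build`: a list with `chrom_names`,
#'   `chrom_lengths` (named by chromosome) and `total_length`.
#' @examples
#' gb <- genome_build(c("1", "2"), c(5e6, 3e6))
#' gb$total_length
#' @export
genome_build <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) stop("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths lengths differ")
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive")
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
         total_length = sum(chrom_lengths)),
    class = "genome_build")
}

#' Approximate pig autosome + X genome build
#'
#' Chromosome lengths approximating the Sus scrofa 10.2 assembly (Mb scale,
#' synthetic convenience values for simulation; not an authoritative
#' assembly index). Total length is on the order of 2.6 Gb; the enrichment
#' test's background length is configured separately (default 2.7e9 bp).
#'
#' @return A `genome_build` with chromosomes 1-18 and X.
#' @export
pig_genome <- function() {
  lens_mb <- c(315.3, 162.6, 144.8, 143.5, 111.5, 157.8, 134.8, 148.5,
               153.7, 79.1, 87.7, 63.6, 218.6, 153.9, 157.7, 86.9,
               69.7, 61.2, 144.3)
  genome_build(c(as.character(1:18), "X"), round(lens_mb * 1e6))
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", length(x$chrom_names), "chromosomes,",
      format(x$total_length, big.mark = ","), "bp total\n")
  invisible(x)
}

#' Run configuration with the pipeline's stage thresholds
#'
#' Every tunable threshold of the pipeline with its default. Defaults follow
#' the analysed study design: variant call rate > 0.95, MAF > 0.05, exact
#' Hardy-Weinberg P > 1e-4, LD pruning with a 5 kb window and step at
#' r^2 <= 0.8, gene mean-count > 5, cis window 1 Mb around the gene body,
#' scan p thresholds 1e-3 (cis) and 1e-6 (trans), FDR 0.05 throughout,
#' co-expression threshold |rho| >= 0.5, breeds kept when they carry >= 1000
#' QTLs, a 2.7 Gb genome background, and candidate genotype cutoff
#' EBV_max = -0.0699208 (the maximum summarised EBV of the low group).
#'
#' @param ... Named overrides of any default listed above.
#' @return An object of class `run_config` (a named list).
#' @examples
#' cfg <- run_config(p_cis = 1e-4)
#' cfg$p_cis
#' @export
run_config <- function(...) {
  cfg <- list(
    call_rate_min   = 0.95,
    maf_min         = 0.05,
    hwe_p_min       = 1e-4,
    ld_window_bp    = 5000,
    ld_step_bp      = 5000,
    ld_r2_max       = 0.8,
    mean_count_min  = 5,
    cis_window_bp   = 1e6,
    p_cis           = 1e-3,
    p_trans         = 1e-6,
    fdr_target      = 0.05,
    network_threshold = 0.5,
    breed_min_qtls  = 1000,
    genome_bp       = 2.7e9,
    ebv_max         = -0.0699208,
    boar_taint_traits = c("Fat androstenone level", "indole, laboratory",
                          "Off-Flavor Score", "Overall impression, sensory panel"),
    use_weights_in_scan = FALSE,
    density_scale   = 1e8,
    seed            = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all config overrides must be named")
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (JSON, lossless)
#'
#' @param config A `run_config`.
#' @param path File path for the JSON document.
#' @return `read_config` returns the `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

# ---- genotypes: PED/MAP and VCF -------------------------------------------

#' Read genotypes from a PLINK PED/MAP pair or a VCF file
#'
#' Dosages are coded as the count of the B allele per sample in {0, 1, 2},
#' with missing calls kept as `NA` (never silently 0). The B allele is the
#' minor allele at load time; when both alleles are equally frequent the
#' allele whose label sorts last is taken as B, so write/read round trips are
#' stable. Only biallelic variants are accepted.
#'
#' @param path Path to a `.ped` file or a `.vcf` file (uncompressed or
#'   bgzipped, anything `VariantAnnotation::readVcf` accepts).
#' @param map_path Path to the `.map` file; defaults to `path` with its
#'   extension replaced by `.map`. Ignored for VCF input.
#' @return A list with `genotypes` (samples x variants integer matrix with
#'   dimnames) and `variants` (data.frame: `variant_id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, sorted by chromosome then position).
#' @export
read_genotypes <- function(path, map_path = NULL) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    return(read_genotypes_vcf(path))
  }
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  if (!file.exists(path)) stop("PED file not found: ", path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(vapply(map_fields, length, 1L) != 4L)
  if (length(bad)) stop("malformed MAP line ", bad[1], " in ", map_path)
  variants <- data.frame(
    variant_id = vapply(map_fields, `[[`, "", 2L),
    chrom = vapply(map_fields, `[[`, "", 1L),
    pos = as.integer(vapply(map_fields, `[[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(variants$pos)) stop("non-numeric position in MAP file")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant id in MAP file: ",
         variants$variant_id[anyDuplicated(variants$variant_id)])
  n_var <- nrow(variants)

  ped_lines <- readLines(path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  if (n_samp == 0L) stop("empty PED file: ", path)
  a1 <- matrix("0", n_samp, n_var)
  a2 <- matrix("0", n_samp, n_var)
  sample_ids <- character(n_samp)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_var)
      stop("malformed PED line ", i, ": expected ", 6L + 2L * n_var,
           " fields, found ", length(f))
    sample_ids[i] <- f[2L]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = n_var)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = n_var)]
  }
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in PED file")

  geno <- matrix(NA_integer_, n_samp, n_var,
                 dimnames = list(sample_ids, variants$variant_id))
  allele_a <- allele_b <- character(n_var)
  for (j in seq_len(n_var)) {
    als <- c(a1[, j], a2[, j])
    obs <- sort(unique(als[als != "0"]))
    if (length(obs) > 2L)
      stop("variant ", variants$variant_id[j], " has >2 alleles: ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0L) obs <- c("A", "B")      # all missing
    if (length(obs) == 1L)                         # monomorphic: B unseen
      obs <- c(obs, setdiff(c("A", "B", "C"), obs)[1])
    # B = minor allele; tie broken toward the later-sorting label
    f2 <- mean(als[als != "0"] == obs[2L])
    if (length(als[als != "0"]) && f2 > 0.5) obs <- rev(obs)
    allele_a[j] <- obs[1L]; allele_b[j] <- obs[2L]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == obs[2L]) + (a2[, j] == obs[2L])
    d[miss] <- NA_integer_
    geno[, j] <- as.integer(d)
  }
  variants$allele_a <- allele_a
  variants$allele_b <- allele_b
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  list(genotypes = geno[, variants$variant_id, drop = FALSE],
       variants = variants)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required to read VCF input")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    bad <- which(n_alt != 1L)[1]
    stop("multi-allelic VCF record at row ", bad, " (",
         rownames(vcf)[bad], "); only biallelic variants are supported")
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  variants <- data.frame(
    variant_id = rownames(vcf),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    allele_a = as.character(VariantAnnotation::ref(vcf)),
    allele_b = as.character(unlist(alt)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant id in VCF")
  dose_one <- function(g) {
    if (g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  d <- vapply(gt, dose_one, integer(1))
  geno <- t(matrix(d, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt)))
  # recode so B is the minor allele at load time
  for (j in seq_len(ncol(geno))) {
    x <- geno[, j]
    fB <- mean(x, na.rm = TRUE) / 2
    if (is.finite(fB) && fB > 0.5) {
      geno[, j] <- 2L - x
      tmp <- variants$allele_a[j]
      variants$allele_a[j] <- variants$allele_b[j]
      variants$allele_b[j] <- tmp
    }
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  list(genotypes = geno[, variants$variant_id, drop = FALSE],
       variants = variants)
}

#' Write genotypes as a PLINK PED/MAP pair
#'
#' Inverse of [read_genotypes()] for PED/MAP: writing then reading a
#' minor-coded dosage matrix (the package invariant: B counts the minor
#' allele) reproduces it exactly; a majority-coded column comes back flipped
#' to minor coding with swapped allele labels.
#'
#' @param genotypes Samples x variants dosage matrix (0/1/2/NA) with dimnames.
#' @param variants Variant table as returned by [read_genotypes()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_genotypes <- function(genotypes, variants, prefix) {
  validate_genotype_matrix(genotypes)
  stopifnot(identical(colnames(genotypes), variants$variant_id))
  map <- paste(variants$chrom, variants$variant_id, 0L, variants$pos,
               sep = "\t")
  writeLines(map, paste0(prefix, ".map"))
  n <- nrow(genotypes)
  lines <- character(n)
  aa <- variants$allele_a; ab <- variants$allele_b
  for (i in seq_len(n)) {
    d <- genotypes[i, ]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, ab, aa))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, ab, aa))
    lines[i] <- paste(c("FAM", rownames(genotypes)[i], "0", "0", "0", "-9",
                        as.vector(rbind(g1, g2))), collapse = "\t")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

validate_genotype_matrix <- function(genotypes) {
  if (!is.matrix(genotypes)) stop("genotypes must be a matrix")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotypes must carry sample and variant dimnames")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must lie in {0, 1, 2} or be NA")
  invisible(TRUE)
}

# ---- counts ----------------------------------------------------------------

#' Read / write a gene x sample count matrix (TSV)
#'
#' First column gene ids, header row of sample ids, integer cells >= 0.
#'
#' @param path TSV file path.
#' @return `read_counts` returns an integer matrix (genes x samples).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("counts table needs a gene column and >=1 sample")
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id: ", gene_ids[anyDuplicated(gene_ids)])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("counts contain missing or non-numeric cells")
  if (any(m < 0)) stop("counts contain negative cells")
  if (any(m != round(m))) stop("counts contain non-integer cells")
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  m
}

#' @rdname read_counts
#' @param counts Integer matrix genes x samples with dimnames.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene annotation -------------------------------------------------------

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 rows of type `gene` are used; the gene id is taken from the `ID=` (or
#' `gene_id=`) attribute. BED is converted to 1-based inclusive on read.
#'
#' @param path `.gff`/`.gff3` or `.bed` file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    ann <- data.frame(gene_id = as.character(tab[[4L]]),
                      chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[2L]]) + 1L,  # BED half-open 0-based
                      end = as.integer(tab[[3L]]),
                      strand = if (ncol(tab) >= 6L) as.character(tab[[6L]])
                               else "*",
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "#", quote = "")
    tab <- tab[tab[[3L]] == "gene", , drop = FALSE]
    ids <- sub(".*(?:^|;)\\s*(?:ID|gene_id)=([^;]+).*", "\\1", tab[[9L]],
               perl = TRUE)
    ann <- data.frame(gene_id = ids, chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[4L]]),
                      end = as.integer(tab[[5L]]),
                      strand = as.character(tab[[7L]]),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene id in annotation")
  if (any(ann$start > ann$end)) stop("gene with start > end in annotation")
  rownames(ann) <- NULL
  ann
}

#' @rdname read_gene_annotation
#' @param annotation Gene annotation data.frame.
#' @export
write_gene_annotation <- function(annotation, path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    tab <- data.frame(annotation$chrom, annotation$start - 1L, annotation$end,
                      annotation$gene_id, 0L, annotation$strand)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    rows <- sprintf("%s\ttaintQTL\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                    annotation$chrom, annotation$start, annotation$end,
                    annotation$strand, annotation$gene_id)
    writeLines(c("##gff-version 3", rows), path)
  }
  invisible(path)
}

# ---- samples ---------------------------------------------------------------

#' Read / write the per-sample table
#'
#' Columns: `sample_id`, `group` (low/medium/high), `ebv` (summarised
#' breeding value), and the numeric covariates `rin`, `yield_mg`, `geno_qc`.
#' Covariates must be complete after load.
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
read_samples <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "group", "ebv", "rin", "yield_mg", "geno_qc")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample id")
  if (!all(tab$group %in% c("low", "medium", "high")))
    stop("group must be one of low/medium/high")
  num <- c("ebv", "rin", "yield_mg", "geno_qc")
  if (anyNA(tab[num])) stop("missing covariate or EBV values")
  tab[num] <- lapply(tab[num], as.numeric)
  tab[need]
}

#' @rdname read_samples
#' @param samples Sample table data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- trait-QTL table -------------------------------------------------------

#' Read / write a trait-QTL interval table
#'
#' One row per QTL: `trait`, `category`, `breed`, `chrom`, `start`, `end`
#' (1-based inclusive). When a `genome_build` is supplied, intervals are
#' validated against it.
#'
#' @param path TSV path.
#' @param genome Optional `genome_build` for coordinate validation.
#' @return data.frame of class `trait_qtl_table`.
#' @export
read_trait_qtl <- function(path, genome = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("trait", "category", "breed", "chrom", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trait table missing columns: ",
                         paste(miss, collapse = ", "))
  tab <- tab[need]
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.numeric(tab$start); tab$end <- as.numeric(tab$end)
  validate_trait_qtl(tab, genome)
  class(tab) <- c("trait_qtl_table", "data.frame")
  tab
}

validate_trait_qtl <- function(tab, genome = NULL) {
  bad <- which(tab$start > tab$end | tab$start < 1)
  if (length(bad)) stop("invalid interval at trait table row ", bad[1])
  if (!is.null(genome)) {
    unk <- which(!tab$chrom %in% genome$chrom_names)
    if (length(unk)) stop("unknown chromosome '", tab$chrom[unk[1]],
                          "' at trait table row ", unk[1])
    over <- which(tab$end > genome$chrom_lengths[tab$chrom])
    if (length(over)) stop("interval beyond chromosome end at trait table row ",
                           over[1])
  }
  invisible(TRUE)
}

#' @rdname read_trait_qtl
#' @param traits Trait-QTL table.
#' @export
write_trait_qtl <- function(traits, path) {
  utils::write.table(as.data.frame(traits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
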