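# Synthetic-data generators emulating the assumed study design: 48 animals in
# three summarised-EBV groups of 16, a dense SNP panel with local LD, two
# tissues of negative-binomial RNA-Seq counts with planted cis/trans effects,
# genotype-linked EBVs, and a mock trait-QTL interval database. Everything is
# deterministic under the design seed.

#' Simulation design
#'
#' Collects every knob of the synthetic-data generators. Defaults state the
#' emulated study: 48 samples in groups of 16/16/16, a 20,827-variant panel,
#' 10,545 (liver) and 12,731 (testis) genes, MAF drawn from (0.05, 0.5],
#' 50 kb LD blocks with adjacent-haplotype copying probability 0.9, 50 planted
#' cis effects of 1 log2-unit per B allele within the 1 Mb window, 10 trans
#' effects, 10 causal EBV variants with effects of sd 0.15 plus Gaussian noise
#' (sd 0.1), negative-binomial dispersion 0.1 and library-size factors in
#' [0.7, 1.3]. Tests scale `n_variants`/`n_genes` down; the defaults are the
#' stated world, not a tuning surface.
#'
#' @param n_samples Number of animals (default 48).
#' @param group_sizes Sizes of the low/medium/high EBV groups; must sum to
#'   `n_samples`.
#' @param n_variants Panel size before QC.
#' @param n_genes Named vector of gene counts per tissue.
#' @param maf_range Interval from which per-variant MAFs are drawn.
#' @param ld_block_bp LD block length in bp.
#' @param ld_copy_prob Within-block probability that a haplotype allele is
#'   copied from the previous variant (tunes adjacent r^2).
#' @param n_cis_effects,cis_effect_size Number and per-allele log2 effect of
#'   planted cis gene-SNP pairs (SNP within `cis_window_bp` of the gene).
#' @param n_trans_effects,trans_effect_size Planted distal pairs.
#' @param n_causal_ebv,ebv_effect_sd,ebv_noise_sd EBV model: number of causal
#'   variants, sd of their per-allele effects, and residual noise sd.
#' @param n_pool Optional selection pool size; when larger than `n_samples`
#'   the generator simulates `n_pool` animals and keeps the extremes and
#'   middle of the EBV distribution (emulating selection of 48 from 114).
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_range Multiplicative library-size factor range.
#' @param base_mean_log,base_mean_sd Log-normal gene baseline mean parameters.
#' @param cis_window_bp cis window used to place planted cis pairs.
#' @param genome A `genome_build`; default [pig_genome()].
#' @param seed Integer seed governing all randomness.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(n_samples = 48L,
                              group_sizes = c(16L, 16L, 16L),
                              n_variants = 20827L,
                              n_genes = c(liver = 10545L, testis = 12731L),
                              maf_range = c(0.05, 0.5),
                              ld_block_bp = 50000,
                              ld_copy_prob = 0.9,
                              n_cis_effects = 50L,
                              cis_effect_size = 1.0,
                              n_trans_effects = 10L,
                              trans_effect_size = 1.0,
                              n_causal_ebv = 10L,
                              ebv_effect_sd = 0.15,
                              ebv_noise_sd = 0.1,
                              n_pool = n_samples,
                              dispersion = 0.1,
                              lib_size_range = c(0.7, 1.3),
                              base_mean_log = log(100),
                              base_mean_sd = 1,
                              cis_window_bp = 1e6,
                              genome = pig_genome(),
                              seed = 1L) {
  if (sum(group_sizes) != n_samples)
    stop("group sizes must sum to n_samples")
  if (n_samples < 2L) stop("need at least two samples")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (n_pool < n_samples) stop("n_pool must be >= n_samples")
  if (is.null(names(n_genes))) names(n_genes) <- paste0("tissue", seq_along(n_genes))
  structure(as.list(environment()), class = "simulation_design")
}

#' Simulate a genotype panel with local LD
#'
#' Variant positions are uniform per chromosome (proportional allocation by
#' chromosome length). Each LD block draws one MAF uniformly from the design's
#' MAF range, shared by its variants. Haplotypes are generated per block by
#' Markov copying: within a block each haplotype allele is copied from the
#' previous variant with probability `ld_copy_prob`, else drawn fresh, giving
#' tunable adjacent r^2 while leaving every variant's marginal frequency at
#' its drawn MAF; the two haplotypes are independent so each variant is in
#' Hardy-Weinberg proportion marginally.
#'
#' @param design A `simulation_design`.
#' @param n_samples Number of animals to draw (defaults to `design$n_pool`).
#' @return As [read_genotypes()]: list of `genotypes` and `variants`; the
#'   variant table carries attributes `maf` (the drawn per-variant MAF) and
#'   `block` (LD block membership) for calibration studies.
#' @export
simulate_genotypes <- function(design, n_samples = design$n_pool) {
  genome <- design$genome
  if (length(genome$chrom_names) == 0L) stop("empty genome")
  set.seed(design$seed)
  n_var <- design$n_variants
  # allocate variants to chromosomes proportionally to length
  alloc <- round(n_var * genome$chrom_lengths / genome$total_length)
  alloc[1] <- alloc[1] + (n_var - sum(alloc))
  chrom <- rep(genome$chrom_names, alloc)
  pos <- unlist(lapply(seq_along(alloc), function(k) {
    sort(sample.int(genome$chrom_lengths[k], alloc[k]))
  }), use.names = FALSE)
  # one MAF per LD block, shared by its variants: Markov copying then leaves
  # every variant's marginal frequency exactly at its drawn MAF
  block <- paste(chrom, floor(pos / design$ld_block_bp))
  block_maf <- stats::setNames(
    stats::runif(length(unique(block)), design$maf_range[1],
                 design$maf_range[2]), unique(block))
  maf <- as.numeric(block_maf[block])

  hap <- function() {
    h <- matrix(0L, n_samples, n_var)
    prev_block <- ""
    for (j in seq_len(n_var)) {
      fresh <- stats::rbinom(n_samples, 1L, maf[j])
      if (block[j] == prev_block) {
        copy <- stats::runif(n_samples) < design$ld_copy_prob
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      } else {
        h[, j] <- fresh
      }
      prev_block <- block[j]
    }
    h
  }
  geno <- hap() + hap()
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(sprintf("pig%03d", seq_len(n_samples)),
                         sprintf("rs%06d", seq_len(n_var)))
  variants <- data.frame(variant_id = colnames(geno), chrom = chrom,
                         pos = pos, allele_a = "A", allele_b = "B",
                         stringsAsFactors = FALSE)
  ord <- order(match(variants$chrom, genome$chrom_names), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  attr(variants, "maf") <- stats::setNames(maf[ord], variants$variant_id)
  attr(variants, "block") <- stats::setNames(block[ord], variants$variant_id)
  list(genotypes = geno[, variants$variant_id, drop = FALSE],
       variants = variants)
}

#' Simulate a gene annotation on the design genome
#'
#' Genes are placed uniformly with lengths 5-100 kb, clipped to chromosome
#' ends.
#'
#' @param design A `simulation_design`.
#' @param tissue Tissue name selecting `design$n_genes[tissue]`. Gene ids are
#'   shared across tissues (tissue panels are nested prefixes of one gene
#'   universe, emulating tissue-dependent expression filtering).
#' @return Gene annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
simulate_gene_annotation <- function(design, tissue = names(design$n_genes)[1]) {
  genome <- design$genome
  n_total <- max(design$n_genes)
  set.seed(design$seed + 1L)
  alloc <- round(n_total * genome$chrom_lengths / genome$total_length)
  alloc[1] <- alloc[1] + (n_total - sum(alloc))
  chrom <- rep(genome$chrom_names, alloc)
  start <- unlist(lapply(seq_along(alloc), function(k) {
    sort(sample.int(max(genome$chrom_lengths[k] - 1e5, 1), alloc[k]))
  }), use.names = FALSE)
  len <- sample(5000:100000, n_total, replace = TRUE)
  end <- pmin(start + len, genome$chrom_lengths[chrom])
  ann <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_total)),
                    chrom = chrom, start = start, end = end,
                    strand = sample(c("+", "-"), n_total, replace = TRUE),
                    stringsAsFactors = FALSE)
  ann[seq_len(design$n_genes[[tissue]]), , drop = FALSE]
}

# planted effect tables -------------------------------------------------------

#' Plant cis and trans effects for a tissue
#'
#' cis pairs are drawn among gene-SNP pairs whose SNP lies within the design's
#' cis window of the gene body; trans pairs among pairs on different
#' chromosomes.
#'
#' @param design A `simulation_design`.
#' @param variants Variant table.
#' @param annotation Gene annotation for the tissue.
#' @return data.frame `gene_id`, `variant_id`, `effect` (log2 units per B
#'   allele), `class`.
#' @export
plant_effects <- function(design, variants, annotation) {
  set.seed(design$seed + 2L)
  pick_cis <- function(n) {
    out <- vector("list", n)
    genes <- sample.int(nrow(annotation), min(n * 10L, nrow(annotation)))
    k <- 0L
    for (g in genes) {
      if (k >= n) break
      w <- which(variants$chrom == annotation$chrom[g] &
                 variants$pos >= annotation$start[g] - design$cis_window_bp &
                 variants$pos <= annotation$end[g] + design$cis_window_bp)
      if (!length(w)) next
      k <- k + 1L
      out[[k]] <- data.frame(gene_id = annotation$gene_id[g],
                             variant_id = variants$variant_id[sample(w, 1L)],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out[seq_len(k)])
  }
  pick_trans <- function(n) {
    out <- vector("list", n)
    k <- 0L
    for (g in sample.int(nrow(annotation), min(n * 10L, nrow(annotation)))) {
      if (k >= n) break
      w <- which(variants$chrom != annotation$chrom[g])
      if (!length(w)) next
      k <- k + 1L
      out[[k]] <- data.frame(gene_id = annotation$gene_id[g],
                             variant_id = variants$variant_id[sample(w, 1L)],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out[seq_len(k)])
  }
  cis <- pick_cis(design$n_cis_effects)
  trans <- pick_trans(design$n_trans_effects)
  eff <- rbind(
    if (!is.null(cis) && nrow(cis))
      cbind(cis, effect = design$cis_effect_size, class = "cis"),
    if (!is.null(trans) && nrow(trans))
      cbind(trans, effect = design$trans_effect_size, class = "trans"))
  if (is.null(eff)) eff <- data.frame(gene_id = character(),
                                      variant_id = character(),
                                      effect = numeric(), class = character())
  rownames(eff) <- NULL
  eff
}

#' Simulate RNA-Seq counts for one tissue
#'
#' Counts are negative binomial with log link: gene baselines are log-normal,
#' each sample carries a multiplicative library factor, and planted pairs
#' shift the log2 mean by dosage x effect.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param design A `simulation_design`.
#' @param annotation Gene annotation for the tissue (row count = gene count).
#' @param effects Planted-effect table from [plant_effects()]; pass an empty
#'   data.frame (or `NULL`) for a null simulation.
#' @param seed_offset Integer mixed into the design seed so tissues differ.
#' @return Integer count matrix genes x samples.
#' @export
simulate_expression <- function(genotypes, design, annotation,
                                effects = NULL, seed_offset = 0L) {
  if (design$dispersion <= 0) stop("non-positive dispersion")
  set.seed(design$seed + 10L + seed_offset)
  n_g <- nrow(annotation); n_s <- nrow(genotypes)
  base <- stats::rlnorm(n_g, design$base_mean_log, design$base_mean_sd)
  libf <- stats::runif(n_s, design$lib_size_range[1], design$lib_size_range[2])
  log2mu <- outer(log2(base), log2(libf), `+`)
  if (!is.null(effects) && nrow(effects)) {
    ok <- effects$gene_id %in% annotation$gene_id &
          effects$variant_id %in% colnames(genotypes)
    if (!all(ok)) stop("planted effect references unknown gene or variant")
    for (i in seq_len(nrow(effects))) {
      gi <- match(effects$gene_id[i], annotation$gene_id)
      dos <- genotypes[, effects$variant_id[i]]
      dos[is.na(dos)] <- 0
      log2mu[gi, ] <- log2mu[gi, ] + dos * effects$effect[i]
    }
  }
  mu <- 2^log2mu
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu,
                                  size = 1 / design$dispersion),
                   n_g, n_s,
                   dimnames = list(annotation$gene_id, rownames(genotypes)))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate summarised EBVs, groups and covariates
#'
#' EBV = sum over causal variants of dosage x effect, plus Gaussian noise.
#' Groups are assigned by EBV tertiles (ties broken by sample order) into the
#' design's group sizes. Covariates (RIN, tissue yield in mg, genotyping QC
#' metric) are simulated independently of the EBV.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param design A `simulation_design`.
#' @param causal Optional data.frame `variant_id`, `effect` overriding the
#'   design's random draw.
#' @return Sample table data.frame (`sample_id`, `group`, `ebv`, `rin`,
#'   `yield_mg`, `geno_qc`) with attribute `group_summary` (realised per-group
#'   mean and sd).
#' @export
simulate_ebv <- function(genotypes, design, causal = NULL) {
  n <- nrow(genotypes)
  if (n < sum(design$group_sizes))
    stop("sample count is not divisible into the designed group sizes")
  set.seed(design$seed + 3L)
  if (is.null(causal)) {
    idx <- sample.int(ncol(genotypes), min(design$n_causal_ebv,
                                           ncol(genotypes)))
    causal <- data.frame(variant_id = colnames(genotypes)[idx],
                         effect = stats::rnorm(length(idx), 0,
                                               design$ebv_effect_sd),
                         stringsAsFactors = FALSE)
  }
  if (!all(causal$variant_id %in% colnames(genotypes)))
    stop("causal variant not present in the panel")
  dose <- genotypes[, causal$variant_id, drop = FALSE]
  dose[is.na(dose)] <- 0
  ebv <- as.vector(dose %*% causal$effect) +
    stats::rnorm(n, 0, design$ebv_noise_sd)
  samples <- data.frame(
    sample_id = rownames(genotypes),
    group = NA_character_,
    ebv = ebv,
    rin = round(stats::rnorm(n, 8, 0.5), 2),
    yield_mg = round(stats::rnorm(n, 150, 10), 1),
    geno_qc = round(stats::rnorm(n, 0.995, 0.002), 4),
    stringsAsFactors = FALSE)

  if (n > design$n_samples) {
    # selection pool: keep extremes and the middle of the EBV distribution
    ord <- order(samples$ebv, seq_len(n))
    gs <- design$group_sizes
    low_idx <- ord[seq_len(gs[1])]
    high_idx <- ord[seq(n - gs[3] + 1L, n)]
    mid_rank <- order(abs(samples$ebv - mean(samples$ebv)), seq_len(n))
    mid_idx <- setdiff(mid_rank, c(low_idx, high_idx))[seq_len(gs[2])]
    keep <- c(low_idx, mid_idx, high_idx)
    samples <- samples[sort(keep), , drop = FALSE]
  }
  if (nrow(samples) != sum(design$group_sizes))
    stop("sample count is not divisible into the designed group sizes")
  ord <- order(samples$ebv, seq_len(nrow(samples)))   # ties by sample order
  gs <- design$group_sizes
  grp <- character(nrow(samples))
  grp[ord[seq_len(gs[1])]] <- "low"
  grp[ord[seq(gs[1] + 1L, gs[1] + gs[2])]] <- "medium"
  grp[ord[seq(gs[1] + gs[2] + 1L, sum(gs))]] <- "high"
  samples$group <- grp
  rownames(samples) <- NULL
  gsum <- do.call(rbind, lapply(split(samples$ebv, samples$group), function(e)
    data.frame(mean = mean(e), sd = stats::sd(e), max = max(e))))
  gsum <- gsum[c("high", "medium", "low"), ]
  attr(samples, "group_summary") <- gsum
  attr(samples, "causal") <- causal
  samples
}

#' Simulate a mock trait-QTL interval database
#'
#' Intervals are placed uniformly on the genome with log-normal lengths.
#' A designated subset of traits carries the four boar-taint trait names;
#' categories are drawn from the five standard trait categories; breeds are
#' assigned with controllable per-breed QTL counts.
#'
#' @param genome A `genome_build`.
#' @param n_traits Number of distinct traits.
#' @param qtls_per_trait Mean QTL count per trait (Poisson, floor 1).
#' @param length_meanlog,length_sdlog Log-normal interval length parameters
#'   (defaults give multi-Mb intervals typical of trait-QTL databases).
#' @param boar_taint_traits Trait names guaranteed present.
#' @param breeds Named integer vector of relative breed weights.
#' @param seed Integer seed.
#' @return A `trait_qtl_table`.
#' @export
simulate_trait_db <- function(genome, n_traits = 100L, qtls_per_trait = 30,
                              length_meanlog = log(4e6), length_sdlog = 0.8,
                              boar_taint_traits = c("Fat androstenone level",
                                                    "indole, laboratory",
                                                    "Off-Flavor Score",
                                                    "Overall impression, sensory panel"),
                              breeds = c(Duroc = 5L, Landrace = 4L,
                                         Pietrain = 1L),
                              seed = 1L) {
  set.seed(seed)
  categories <- c("Meat and carcass", "Health", "Production", "Exterior",
                  "Reproduction")
  n_named <- length(boar_taint_traits)
  if (n_traits < n_named) stop("n_traits smaller than the named trait set")
  traits <- c(boar_taint_traits,
              sprintf("Trait %03d", seq_len(n_traits - n_named)))
  cat_of <- stats::setNames(sample(categories, n_traits, replace = TRUE),
                            traits)
  cat_of[boar_taint_traits] <- "Meat and carcass"
  rows <- lapply(traits, function(tr) {
    k <- max(1L, stats::rpois(1L, qtls_per_trait))
    chrom <- sample(genome$chrom_names, k, replace = TRUE,
                    prob = genome$chrom_lengths)
    len <- pmin(stats::rlnorm(k, length_meanlog, length_sdlog),
                genome$chrom_lengths[chrom])
    start <- floor(stats::runif(k, 1, genome$chrom_lengths[chrom] - len + 1))
    data.frame(trait = tr, category = cat_of[[tr]],
               breed = sample(names(breeds), k, replace = TRUE,
                              prob = breeds),
               chrom = chrom, start = start, end = floor(start + len - 1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_trait_qtl(tab, genome)
  class(tab) <- c("trait_qtl_table", "data.frame")
  tab
}

#' Simulate a complete dataset
#'
#' Convenience wrapper producing everything the pipeline consumes: genotypes,
#' variant table, per-tissue annotations, planted effects, per-tissue counts,
#' sample table and a mock trait-QTL database. When `design$n_pool >
#' design$n_samples`, animals are simulated at pool size and the selected
#' subset (EBV extremes + middle) is returned.
#'
#' @param design A `simulation_design`.
#' @return Named list: `genotypes`, `variants`, `annotation` (per tissue),
#'   `effects` (per tissue), `counts` (per tissue), `samples`, `traits`,
#'   `design`.
#' @export
simulate_dataset <- function(design) {
  gt <- simulate_genotypes(design)
  tissues <- names(design$n_genes)
  annotation <- effects <- counts <- stats::setNames(
    vector("list", length(tissues)), tissues)
  for (k in seq_along(tissues)) {
    annotation[[k]] <- simulate_gene_annotation(design, tissues[k])
    effects[[k]] <- plant_effects(design, gt$variants, annotation[[k]])
  }
  # Genetic merit is mediated by the planted regulatory variants: EBV causal
  # variants are drawn from the planted cis SNPs (falling back to random
  # panel SNPs in a null design), so a subset of eQTLs carries a real EBV
  # association, as the filtered-eQTL stage assumes.
  cis_snps <- unique(unlist(lapply(effects, function(e)
    e$variant_id[e$class == "cis"])))
  causal <- if (length(cis_snps)) {
    set.seed(design$seed + 5L)
    picked <- sample(cis_snps, min(design$n_causal_ebv, length(cis_snps)))
    data.frame(variant_id = picked,
               effect = stats::rnorm(length(picked), 0, design$ebv_effect_sd),
               stringsAsFactors = FALSE)
  } else NULL
  samples <- simulate_ebv(gt$genotypes, design, causal = causal)
  gt$genotypes <- gt$genotypes[samples$sample_id, , drop = FALSE]
  for (k in seq_along(tissues)) {
    counts[[k]] <- simulate_expression(gt$genotypes, design, annotation[[k]],
                                       effects[[k]], seed_offset = k)
  }
  traits <- simulate_trait_db(design$genome, seed = design$seed + 4L)
  list(genotypes = gt$genotypes, variants = gt$variants,
       annotation = annotation, effects = effects, counts = counts,
       samples = samples, traits = traits, design = design)
}
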