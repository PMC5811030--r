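# candidate_selection: genotype EBV statistics and the two candidacy criteria

mk_enrichment <- function(traits, enriched = TRUE) {
  structure(data.frame(trait = traits, category = "Meat and carcass",
                       n_snps = 10L, k = 5L, l_trait = 1e6, pi = 1e-3,
                       p = 1e-8, fdr = if (enriched) 1e-7 else 0.5,
                       genes = "", enriched = enriched,
                       stringsAsFactors = FALSE),
            class = c("enrichment_results", "data.frame"))
}

candidate_world <- function(median_low = -0.2) {
  n <- 12L
  geno <- matrix(rep(c(0L, 1L, 2L), each = 4), n, 1,
                 dimnames = list(sprintf("s%02d", 1:n), "v1"))
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        group = rep(c("low", "medium", "high"), each = 4),
                        ebv = c(rep(median_low, 4), rep(0.1, 4), rep(0.6, 4)),
                        rin = 8, yield_mg = 150, geno_qc = 0.99,
                        stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = "v1", chrom = "1", pos = 5000,
                         allele_a = "A", allele_b = "G",
                         stringsAsFactors = FALSE)
  filtered <- data.frame(variant_id = "v1", gene_id = "gene1",
                         tissue = "liver", eqtl_class = "cis",
                         fdr_ebv = 0.01, stringsAsFactors = FALSE)
  traits <- data.frame(trait = "Fat androstenone level",
                       category = "Meat and carcass", breed = "D",
                       chrom = "1", start = 1000, end = 9000,
                       stringsAsFactors = FALSE)
  list(geno = geno, samples = samples, variants = variants,
       filtered = filtered, traits = traits)
}

test_that("genotype EBV statistics match sort-and-pick medians", {
  s <- data.frame(sample_id = paste0("s", 1:3), ebv = c(-0.1, 0.2, 0.5))
  st <- genotype_ebv_stats(c(0L, 1L, 2L), s, alleles = c("A", "G"))
  expect_identical(st$genotype, c("AA", "AG", "GG"))
  expect_equal(st$median_ebv, st$mean_ebv)   # one sample per class

  s2 <- data.frame(sample_id = paste0("s", 1:4), ebv = c(-0.1, -0.2, 1, 2))
  st2 <- genotype_ebv_stats(c(0L, 0L, 2L, 2L), s2)
  expect_equal(st2$median_ebv[st2$dosage == 0], -0.15)
  expect_false(any(st2$dosage == 1))         # empty class omitted

  set.seed(90)
  ebv <- rnorm(48); d <- sample(0:2, 48, TRUE)
  st3 <- genotype_ebv_stats(d, data.frame(sample_id = 1:48, ebv = ebv))
  for (g in unique(d)) {
    v <- sort(ebv[d == g]); m <- length(v)
    med <- if (m %% 2) v[(m + 1) / 2] else (v[m / 2] + v[m / 2 + 1]) / 2
    expect_equal(st3$median_ebv[st3$dosage == g], med)
  }
  expect_error(genotype_ebv_stats(rep(NA_integer_, 3),
                                  data.frame(ebv = 1:3)), "missing")
})

test_that("both candidacy criteria gate candidate emission", {
  w <- candidate_world(median_low = -0.2)
  enr <- mk_enrichment("Fat androstenone level")
  out <- select_candidates(w$filtered, enr, w$geno, w$samples, w$variants,
                           w$traits)
  expect_identical(nrow(out), 1L)
  expect_identical(out$genotype, "AA")
  expect_identical(out$trait, "Fat androstenone level")
  expect_equal(out$median_ebv, -0.2)
  expect_equal(out$mean_ebv, -0.2)

  # criterion i: qualifying class must have median <= ebv_max
  w2 <- candidate_world(median_low = 0.2)
  out2 <- select_candidates(w2$filtered, enr, w2$geno, w2$samples,
                            w2$variants, w2$traits)
  expect_identical(nrow(out2), 0L)

  # criterion ii: trait must be enriched
  out3 <- select_candidates(w$filtered, mk_enrichment("Fat androstenone level",
                                                      enriched = FALSE),
                            w$geno, w$samples, w$variants, w$traits)
  expect_identical(nrow(out3), 0L)

  # criterion ii: SNP must overlap the trait interval
  w4 <- candidate_world()
  w4$variants$pos <- 20000
  out4 <- select_candidates(w4$filtered, enr, w4$geno, w4$samples,
                            w4$variants, w4$traits)
  expect_identical(nrow(out4), 0L)

  # the EBV_max boundary is inclusive
  w5 <- candidate_world(median_low = -0.0699208)
  out5 <- select_candidates(w5$filtered, enr, w5$geno, w5$samples,
                            w5$variants, w5$traits)
  expect_identical(nrow(out5), 1L)
})

test_that("tightening ebv_max never adds candidates", {
  w <- candidate_world(median_low = -0.2)
  enr <- mk_enrichment("Fat androstenone level")
  loose <- select_candidates(w$filtered, enr, w$geno, w$samples, w$variants,
                             w$traits, ebv_max = -0.05)
  tight <- select_candidates(w$filtered, enr, w$geno, w$samples, w$variants,
                             w$traits, ebv_max = -0.5)
  key <- function(x) paste(x$variant_id, x$gene_id, x$genotype, x$trait)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("summarise_candidates matches a group-by oracle", {
  expect_identical(summarise_candidates(
    data.frame(variant_id = character(), gene_id = character(),
               genotype = character()))$n_genotypes, 0L)

  set.seed(91)
  cand <- data.frame(
    variant_id = sample(paste0("v", 1:6), 20, TRUE),
    gene_id = sample(paste0("g", 1:4), 20, TRUE),
    genotype = sample(c("AA", "AB", "BB"), 20, TRUE),
    stringsAsFactors = FALSE)
  s <- summarise_candidates(cand)
  expect_identical(s$n_eqtls,
                   nrow(unique(cand[c("variant_id", "gene_id")])))
  expect_identical(s$n_genes, length(unique(cand$gene_id)))
  oracle <- table(unique(cand)[["gene_id"]])
  expect_identical(sum(s$per_gene), sum(oracle))
  expect_identical(s$n_genotypes,
                   nrow(unique(cand[c("variant_id", "gene_id", "genotype")])))
})
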