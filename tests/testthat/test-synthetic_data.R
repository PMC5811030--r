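# synthetic_data: determinism, marginal frequencies, LD structure, EBV model,
# trait database

test_that("all generators are deterministic under the seed", {
  d <- small_design(seed = 11L)
  g1 <- simulate_genotypes(d); g2 <- simulate_genotypes(d)
  expect_identical(g1, g2)
  ann <- simulate_gene_annotation(d, "liver")
  eff <- plant_effects(d, g1$variants, ann)
  expect_identical(simulate_expression(g1$genotypes, d, ann, eff),
                   simulate_expression(g1$genotypes, d, ann, eff))
  expect_identical(simulate_ebv(g1$genotypes, d), simulate_ebv(g1$genotypes, d))
  expect_identical(simulate_trait_db(toy_genome(), seed = 3L),
                   simulate_trait_db(toy_genome(), seed = 3L))
})

test_that("empirical MAFs track the drawn values within the binomial bound", {
  d <- simulation_design(n_samples = 500L,
                         group_sizes = c(167L, 167L, 166L),
                         n_variants = 2000L, maf_range = c(0.1, 0.5),
                         genome = toy_genome(), seed = 5L)
  gt <- simulate_genotypes(d, n_samples = 500L)
  drawn <- attr(gt$variants, "maf")
  emp <- colMeans(gt$genotypes) / 2
  dev <- abs(emp - drawn[colnames(gt$genotypes)])
  # +-0.05 is ~3 sd of the binomial sampling error at n = 1000 haplotypes;
  # allow the handful of 3-sigma exceedances expected among 2000 variants
  expect_gt(mean(dev <= 0.05), 0.995)
  expect_lt(max(dev), 0.08)
})

test_that("within-block adjacent r^2 exceeds cross-block r^2", {
  d <- simulation_design(n_samples = 300L, group_sizes = c(100L, 100L, 100L),
                         n_variants = 400L, ld_copy_prob = 0.95,
                         genome = genome_build("1", 2e7), seed = 2L)
  gt <- simulate_genotypes(d, n_samples = 300L)
  v <- gt$variants
  blk <- attr(v, "block")[v$variant_id]
  r2_adj <- vapply(seq_len(nrow(v) - 1), function(i)
    ld_r2(gt$genotypes[, v$variant_id[i]], gt$genotypes[, v$variant_id[i + 1]]),
    numeric(1))
  same_block <- blk[-length(blk)] == blk[-1]
  expect_gt(mean(r2_adj[same_block]), mean(r2_adj[!same_block]))
  expect_gt(mean(r2_adj[same_block]), 0.5)
})

test_that("expression generator rejects bad dispersion and honours effects", {
  d <- small_design()
  gt <- simulate_genotypes(d, n_samples = 48L)
  ann <- simulate_gene_annotation(d, "liver")
  d_bad <- d; d_bad$dispersion <- 0
  expect_error(simulate_expression(gt$genotypes, d_bad, ann), "dispersion")
  eff <- data.frame(gene_id = "nope", variant_id = gt$variants$variant_id[1],
                    effect = 1, class = "cis")
  expect_error(simulate_expression(gt$genotypes, d, ann, eff), "unknown")
  # a strong planted effect shifts carriers upward
  eff <- data.frame(gene_id = ann$gene_id[1],
                    variant_id = gt$variants$variant_id[1],
                    effect = 2, class = "cis")
  counts <- simulate_expression(gt$genotypes, d, ann, eff)
  dos <- gt$genotypes[, eff$variant_id]
  if (length(unique(dos)) > 1) {
    m <- tapply(log1p(counts[eff$gene_id, ]), dos, mean)
    expect_true(m[length(m)] > m[1])
  }
})

test_that("EBV generator: analytic cases and tertile grouping", {
  d <- small_design()
  d$ebv_noise_sd <- 0
  gt <- simulate_genotypes(d, n_samples = 48L)
  # zero effects, zero noise -> all EBVs 0, sizes still 16/16/16
  s0 <- simulate_ebv(gt$genotypes,  d,
                     causal = data.frame(variant_id = gt$variants$variant_id[1],
                                         effect = 0))
  expect_true(all(s0$ebv == 0))
  expect_identical(as.integer(table(s0$group)[c("low", "medium", "high")]),
                   c(16L, 16L, 16L))
  # one causal variant, effect -0.3, no noise -> class means exactly 0/-.3/-.6
  v <- gt$variants$variant_id[which.max(apply(gt$genotypes, 2, function(x)
    min(table(factor(x, levels = 0:2)))))]
  s1 <- simulate_ebv(gt$genotypes, d,
                     causal = data.frame(variant_id = v, effect = -0.3))
  means <- tapply(s1$ebv, gt$genotypes[, v], mean)
  expect_equal(as.numeric(means[c("0", "1", "2")]), c(0, -0.3, -0.6))
  # realised group summary is reported, ordered high > medium > low
  s2 <- simulate_ebv(gt$genotypes, small_design())
  gs <- attr(s2, "group_summary")
  expect_identical(rownames(gs), c("high", "medium", "low"))
  expect_true(gs["high", "mean"] > gs["medium", "mean"])
  expect_true(gs["medium", "mean"] > gs["low", "mean"])
})

test_that("selection pool emulates extreme-group sampling", {
  d <- small_design()
  d$n_pool <- 114L
  gt <- simulate_genotypes(d)
  expect_identical(nrow(gt$genotypes), 114L)
  s <- simulate_ebv(gt$genotypes, d)
  expect_identical(nrow(s), 48L)
  gs <- attr(s, "group_summary")
  expect_true(gs["high", "mean"] > gs["medium", "mean"])
  expect_true(max(s$ebv[s$group == "low"]) <= min(s$ebv[s$group == "medium"]))
  expect_error(simulate_ebv(gt$genotypes[1:20, ], d), "group sizes")
})

test_that("trait database is seeded, named and placed on the genome", {
  db <- simulate_trait_db(toy_genome(), seed = 9L)
  expect_s3_class(db, "trait_qtl_table")
  expect_true(all(c("Fat androstenone level", "indole, laboratory",
                    "Off-Flavor Score", "Overall impression, sensory panel")
                  %in% db$trait))
  expect_true(all(db$category %in% c("Meat and carcass", "Health",
                                     "Production", "Exterior",
                                     "Reproduction")))
  expect_true(all(db$end <= toy_genome()$chrom_lengths[db$chrom]))
  # a whole-chromosome interval overlaps any SNP on that chromosome
  whole <- data.frame(trait = "W", category = "Health", breed = "X",
                      chrom = "1", start = 1,
                      end = toy_genome()$chrom_lengths[["1"]])
  snps <- data.frame(variant_id = c("a", "b"), chrom = "1",
                     pos = c(1, 2.9e7))
  expect_identical(count_overlaps(snps, whole), 2L)
})

test_that("planted cis effect sizes are recovered without bias by regression", {
  # parameter-recovery invariant: slope of log2-CPM on dosage ~ planted effect
  slopes <- vapply(1:50, function(s) {
    w <- null_scan_world(seed = 1000L + s, n = 48L, n_var = 10L,
                         n_genes = 30L, effect = 1.0, maf = 0.3)
    g <- w$effects$gene_id
    if (!g %in% rownames(w$normalised)) return(NA_real_)
    dos <- w$genotypes[, w$effects$variant_id]
    unname(stats::coef(stats::lm(w$normalised[g, ] ~ dos))["dos"])
  }, numeric(1))
  slopes <- slopes[!is.na(slopes)]
  mc_sd <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1.0), 2 * mc_sd + 0.02)
})
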