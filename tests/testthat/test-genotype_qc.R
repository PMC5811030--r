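# genotype_qc: call rate, exact HWE, MAF, LD pruning, full chain

test_that("call rate arithmetic and strict threshold", {
  x <- rep(1L, 48)
  expect_equal(call_rate(x), 1)
  x[1:3] <- NA
  expect_equal(call_rate(x), 45 / 48)
  expect_true(call_rate(x) <= 0.95)          # removed at > 0.95
  x <- rep(1L, 48); x[1:2] <- NA
  expect_true(call_rate(x) > 0.95)           # 46/48 kept
  expect_error(call_rate(integer(0)), "empty")
})

test_that("HWE exact test matches the enumeration oracle", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)    # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)
  expect_equal(hwe_exact_test(3, 5, 2), hwe_oracle(3, 5, 2), tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    n_ab <- sample(0:n, 1)
    n_bb <- sample(0:(n - n_ab), 1)
    n_aa <- n - n_ab - n_bb
    expect_equal(hwe_exact_test(n_aa, n_ab, n_bb),
                 hwe_oracle(n_aa, n_ab, n_bb), tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("HWE conditional probabilities sum to one", {
  for (case in list(c(50, 20), c(100, 37), c(17, 17))) {
    p <- taintQTL:::hwe_het_probabilities(case[1], case[2])
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("minor allele frequency handles fixed and mixed columns", {
  expect_equal(minor_allele_frequency(c(0L, 0L, 0L, 0L)), 0)
  expect_equal(minor_allele_frequency(c(2L, 2L, 2L, 2L)), 0)
  expect_equal(minor_allele_frequency(c(0L, 1L, 1L, 2L)), 0.5)
  expect_equal(minor_allele_frequency(c(NA, 1L, 2L, 2L)), 1 / 6)
  expect_error(minor_allele_frequency(c(NA_integer_, NA_integer_)), "missing")
})

test_that("ld_r2 equals the direct Pearson formula", {
  expect_equal(ld_r2(c(0, 1, 2, 0, 1), c(0, 1, 2, 0, 1)), 1)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(ld_r2(c(1, 1, 1, 1), c(0, 1, 2, 0)), 0)  # zero variance
  set.seed(3)
  x <- sample(0:2, 20, TRUE); y <- sample(0:2, 20, TRUE)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld_r2(x, y), (num / den)^2, tolerance = 1e-12)
})

test_that("ld_prune keeps independent variants and resolves duplicates", {
  set.seed(8)
  g <- random_genotypes(40, 6, miss_rate = 0, seed = 8)
  v <- data.frame(variant_id = colnames(g), chrom = "1",
                  pos = seq(100, by = 2000, length.out = 6),
                  stringsAsFactors = FALSE)
  # orthogonal-ish random variants: nothing above 0.8
  if (all(combn(6, 2, function(ij) ld_r2(g[, ij[1]], g[, ij[2]])) <= 0.8))
    expect_identical(ld_prune(g, v), v$variant_id)

  # duplicated variant 100 bp apart: exactly one survives, tie -> earlier kept
  g2 <- cbind(g[, 1, drop = FALSE], g[, 1, drop = FALSE])
  colnames(g2) <- c("dupA", "dupB")
  v2 <- data.frame(variant_id = c("dupA", "dupB"), chrom = "1",
                   pos = c(500, 600), stringsAsFactors = FALSE)
  expect_identical(ld_prune(g2, v2), "dupA")
})

test_that("ld_prune matches the brute-force oracle and is idempotent", {
  d <- simulation_design(n_samples = 60L, group_sizes = c(20L, 20L, 20L),
                         n_variants = 30L, ld_copy_prob = 0.97,
                         ld_block_bp = 2000,
                         genome = genome_build("1", 4000), seed = 13L)
  gt <- simulate_genotypes(d, n_samples = 60L)
  kept <- ld_prune(gt$genotypes, gt$variants)       # window covers everything
  expect_identical(kept, ld_prune_oracle(gt$genotypes, gt$variants))
  expect_lt(length(kept), nrow(gt$variants))        # pruning really happened
  v_kept <- gt$variants[gt$variants$variant_id %in% kept, ]
  expect_identical(ld_prune(gt$genotypes, v_kept), kept)
})

test_that("run_qc applies filters in order with balanced bookkeeping", {
  # clean panel: nothing removed
  d <- simulation_design(n_samples = 60L, group_sizes = c(20L, 20L, 20L),
                         n_variants = 40L, maf_range = c(0.3, 0.5),
                         ld_copy_prob = 0, genome = genome_build("1", 1e7),
                         seed = 21L)
  gt <- simulate_genotypes(d, n_samples = 60L)
  res <- run_qc(gt$genotypes, gt$variants)
  rep0 <- res$report
  expect_equal(rep0$n_input, rep0$n_retained + rep0$n_removed_callrate +
                 rep0$n_removed_hwe + rep0$n_removed_maf + rep0$n_removed_ld)

  # one designed failure per filter
  n <- 60L
  g <- res$genotypes[, 1:4]
  colnames(g) <- c("v_cr", "v_hwe", "v_maf", "v_base")
  g[1:4, "v_cr"] <- NA                                  # call rate 56/60 < .95
  g[, "v_hwe"] <- rep(c(0L, 2L), each = 30)             # no hets: HWE blows up
  g[, "v_maf"] <- c(1L, rep(0L, n - 1L))                # MAF 1/120 < 0.05
  g <- cbind(g, v_dup = g[, "v_base"], v_ok = res$genotypes[, 6])
  v <- data.frame(variant_id = colnames(g), chrom = "1",
                  pos = c(100, 200, 300, 400, 500, 600),
                  stringsAsFactors = FALSE)
  res2 <- run_qc(g, v)
  expect_equal(res2$report$n_removed_callrate, 1L)
  expect_equal(res2$report$n_removed_hwe, 1L)
  expect_equal(res2$report$n_removed_maf, 1L)
  expect_equal(res2$report$n_removed_ld, 1L)            # v_dup pruned (tie)
  expect_identical(res2$variants$variant_id, c("v_base", "v_ok"))
})

test_that("run_qc equals the sequential composition of the four filters", {
  data <- shared_dataset()
  cfg <- run_config()
  res <- run_qc(data$genotypes, data$variants, cfg)

  v <- data$variants; g <- data$genotypes[, v$variant_id]
  keep1 <- apply(g, 2, call_rate) > cfg$call_rate_min
  v <- v[keep1, ]
  keep2 <- vapply(v$variant_id, function(id) {
    x <- g[, id]; x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2)) > cfg$hwe_p_min
  }, logical(1))
  v <- v[keep2, ]
  keep3 <- vapply(v$variant_id, function(id)
    minor_allele_frequency(g[, id]) > cfg$maf_min, logical(1))
  v <- v[keep3, ]
  kept <- ld_prune(g, v, cfg$ld_window_bp, cfg$ld_step_bp, cfg$ld_r2_max)
  expect_identical(res$variants$variant_id, kept)
})
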