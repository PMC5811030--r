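# qtl_enrichment: breed filter, interval lengths, overlaps, binomial test,
# the all-traits driver, category summaries

mk_traits <- function(df) {
  class(df) <- c("trait_qtl_table", "data.frame")
  df
}

test_that("breed filter keeps >= min and matches a per-breed tally", {
  set.seed(80)
  tab <- mk_traits(data.frame(
    trait = sprintf("T%03d", 1:2000 %% 40), category = "Health",
    breed = sample(c("A", "B", "C"), 2000, TRUE, prob = c(0.55, 0.35, 0.10)),
    chrom = "1", start = 1, end = 100, stringsAsFactors = FALSE))
  counts <- table(tab$breed)
  out <- breed_filter(tab, min_qtls = 1000)
  expect_setequal(unique(out$breed), names(counts)[counts >= 1000])
  expect_identical(nrow(out), sum(counts[counts >= 1000]))

  # boundary: 999 dropped, exactly 1000 kept
  tab2 <- mk_traits(data.frame(trait = "T", category = "Health",
                               breed = c(rep("X", 999), rep("Y", 1000)),
                               chrom = "1", start = 1, end = 10))
  out2 <- breed_filter(tab2, 1000)
  expect_identical(unique(out2$breed), "Y")
  # a single breed above threshold leaves the table unchanged
  tab3 <- mk_traits(data.frame(trait = "T", category = "Health", breed = "Z",
                               chrom = "1", start = 1, end = 10)[rep(1, 1500), ])
  expect_identical(nrow(breed_filter(tab3, 1000)), 1500L)
})

test_that("trait_length: merged vs paper-literal, bitmap oracle", {
  rows <- data.frame(chrom = "1", start = c(11, 31), end = c(20, 40))
  expect_equal(trait_length(rows, merge = TRUE), 20)
  expect_equal(trait_length(rows, merge = FALSE), 20)
  dup <- data.frame(chrom = "1", start = c(11, 11), end = c(20, 20))
  expect_equal(trait_length(dup, merge = TRUE), 10)
  expect_equal(trait_length(dup, merge = FALSE), 20)

  set.seed(81)
  rnd <- data.frame(chrom = sample(c("1", "2"), 50, TRUE),
                    start = sample(1:900, 50, TRUE))
  rnd$end <- pmin(rnd$start + sample(5:120, 50, TRUE), 1000)
  expect_equal(trait_length(rnd, merge = TRUE), bitmap_length_oracle(rnd, 1000))
  expect_equal(trait_length(rnd, merge = FALSE), sum(rnd$end - rnd$start + 1))
})

test_that("count_overlaps is inclusive, deduplicated, and matches a double loop", {
  rows <- data.frame(chrom = "1", start = c(100, 150, 150), end = c(200, 250, 250))
  snps <- data.frame(variant_id = c("a", "b", "c"), chrom = "1",
                     pos = c(200, 99, 180))     # end-inclusive; 180 covered 3x
  expect_identical(count_overlaps(snps, rows), 2L)

  set.seed(82)
  snps2 <- data.frame(variant_id = sprintf("v%03d", 1:100),
                      chrom = sample(c("1", "2"), 100, TRUE),
                      pos = sample(1:5000, 100, TRUE))
  rows2 <- data.frame(chrom = sample(c("1", "2"), 20, TRUE),
                      start = sample(1:4500, 20, TRUE))
  rows2$end <- rows2$start + sample(10:500, 20, TRUE)
  naive <- sum(vapply(seq_len(100), function(i)
    any(snps2$chrom[i] == rows2$chrom & snps2$pos[i] >= rows2$start &
          snps2$pos[i] <= rows2$end), logical(1)))
  expect_identical(count_overlaps(snps2, rows2), naive)
})

test_that("binomial enrichment equals the explicit tail sum", {
  expect_equal(binomial_enrichment(3, 10, 100, 100), 1)   # pi = 1
  expect_equal(binomial_enrichment(0, 10, 1, 100), 1)     # k = 0
  tail_sum <- function(k, n, pi) sum(choose(n, k:n) * pi^(k:n) *
                                       (1 - pi)^(n - k:n))
  expect_equal(binomial_enrichment(3, 10, 10, 100),
               tail_sum(3, 10, 0.1), tolerance = 1e-12)
  set.seed(83)
  for (i in 1:25) {
    n <- sample(1:30, 1); k <- sample(0:n, 1)
    l <- runif(1, 1, 99)
    p <- binomial_enrichment(k, n, l, 100)
    expect_equal(p, if (k == 0) 1 else tail_sum(k, n, l / 100),
                 tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(1, 10, 200, 100), "exceeds")
})

test_that("enrich_all finds a planted trait and shares the BH code path", {
  gb <- genome_build("1", 1e8)
  set.seed(84)
  snps <- data.frame(variant_id = sprintf("v%02d", 1:20), chrom = "1",
                     pos = c(seq(1000, by = 50, length.out = 10),
                             sample(2e7:9e7, 10)), stringsAsFactors = FALSE)
  rec <- data.frame(variant_id = snps$variant_id,
                    gene_id = rep(sprintf("g%02d", 1:10), 2),
                    stringsAsFactors = FALSE)
  traits <- mk_traits(rbind(
    data.frame(trait = "planted", category = "Meat and carcass", breed = "D",
               chrom = "1", start = 900, end = 100900),   # pi = 1e-3, k = 10
    data.frame(trait = "genomewide", category = "Health", breed = "D",
               chrom = "1", start = 1, end = 1e8),
    do.call(rbind, lapply(1:8, function(i)
      data.frame(trait = paste0("null", i), category = "Production",
                 breed = "D", chrom = "1", start = i * 1e6,
                 end = i * 1e6 + 5e5)))))
  out <- enrich_all(rec, snps, traits, g = 1e8, fdr_target = 0.05)
  expect_true(out$enriched[out$trait == "planted"])
  expect_false(out$enriched[out$trait == "genomewide"])
  expect_equal(out$p[out$trait == "genomewide"], 1)
  expect_equal(sort(out$fdr), sort(bh_fdr(out$p)), tolerance = 1e-12)
  planted_genes <- strsplit(out$genes[out$trait == "planted"], ",")[[1]]
  expect_setequal(planted_genes, sprintf("g%02d", 1:10))

  # dedup invariance: duplicating an eQTL row changes nothing
  out2 <- enrich_all(rbind(rec, rec[1, ]), snps, traits, g = 1e8)
  expect_equal(out2$p, out$p, tolerance = 1e-15)
  expect_identical(out2$k, out$k)
})

test_that("enrichment is monotone in interval growth and overlap count", {
  set.seed(85)
  snps <- data.frame(variant_id = sprintf("v%02d", 1:30), chrom = "1",
                     pos = sample(1:1e6, 30))
  base <- data.frame(chrom = "1", start = 2e5, end = 4e5)
  grown <- data.frame(chrom = "1", start = 1e5, end = 6e5)
  k1 <- count_overlaps(snps, base); k2 <- count_overlaps(snps, grown)
  expect_gte(k2, k1)
  l1 <- trait_length(base); l2 <- trait_length(grown)
  expect_gte(l2, l1)
  # p non-increasing in k at fixed pi; non-decreasing in pi at fixed k
  expect_gte(binomial_enrichment(3, 30, l1, 1e6),
             binomial_enrichment(5, 30, l1, 1e6))
  expect_lte(binomial_enrichment(3, 30, l1, 1e6),
             binomial_enrichment(3, 30, l2, 1e6))
})

test_that("category summary reproduces the published adjusted frequencies", {
  totals <- c("Meat and carcass" = 13392, "Health" = 6011,
              "Production" = 1875, "Exterior" = 2366, "Reproduction" = 1966)
  enriched <- c(rep("Meat and carcass", 54), rep("Health", 22),
                rep("Production", 5), rep("Exterior", 6),
                rep("Reproduction", 2))
  traits <- paste0("T", seq_along(enriched))
  out <- category_summary(traits, stats::setNames(enriched, traits), totals)
  get <- function(cat, col) out[out$category == cat, col]
  expect_equal(get("Meat and carcass", "adjusted"), 0.004)
  expect_equal(get("Health", "adjusted"), 0.004)
  expect_equal(get("Production", "adjusted"), 0.003)
  expect_equal(get("Exterior", "adjusted"), 0.003)
  expect_equal(get("Reproduction", "adjusted"), 0.001)
  expect_equal(sum(out$n_enriched), 89)
  expect_error(category_summary(traits, stats::setNames(enriched, traits),
                                totals[-1]), "missing from totals")
})
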