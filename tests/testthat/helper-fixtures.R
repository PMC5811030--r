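# Shared fixtures and independent oracles. Everything is generated in code;
# the only stored fixtures are the printed worked-example tables under
# inst/extdata.

toy_genome <- function() genome_build(as.character(1:3), c(3e7, 2e7, 1e7))

small_design <- function(seed = 7L, ...) {
  simulation_design(n_variants = 600L,
                    n_genes = c(liver = 120L, testis = 140L),
                    genome = toy_genome(),
                    n_cis_effects = 15L, n_trans_effects = 3L,
                    seed = seed, ...)
}

# one shared dataset + pipeline run per test session
shared_env <- new.env()
shared_dataset <- function() {
  if (is.null(shared_env$data))
    shared_env$data <- simulate_dataset(small_design())
  shared_env$data
}
shared_pipeline <- function() {
  if (is.null(shared_env$res)) {
    cfg <- run_config(seed = 7L, genome_bp = toy_genome()$total_length)
    shared_env$res <- suppressWarnings(run_pipeline(shared_dataset(), cfg))
  }
  shared_env$res
}

# random valid dosage matrix with names
random_genotypes <- function(n = 10L, m = 6L, miss_rate = 0.1, seed = 1L) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:m)))
  g[sample(length(g), round(miss_rate * length(g)))] <- NA
  storage.mode(g) <- "integer"
  g
}

# ---- independent oracles ----------------------------------------------------

# exact HWE p by explicit enumeration of all heterozygote counts of the
# observed parity, with the closed-form conditional probability
# P(h | n, n_b) = n! n_b! (2n-n_b)! 2^h / (n_aa! h! n_bb! (2n)!)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- n_ab + 2 * n_bb
  if (n_b > n) n_b <- 2 * n - n_b
  hets <- seq(n_b %% 2, n_b, by = 2)
  logp <- vapply(hets, function(h) {
    nbb <- (n_b - h) / 2
    naa <- n - h - nbb
    lfactorial(n) + lfactorial(n_b) + lfactorial(2 * n - n_b) +
      h * log(2) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-10)])
}

# windowless brute-force LD pruning oracle: same removal rule, pair by pair in
# position order (valid when the window covers the whole chromosome)
ld_prune_oracle <- function(genotypes, variants, r2_max = 0.8) {
  ids <- variants$variant_id
  maf <- vapply(ids, function(v) minor_allele_frequency(genotypes[, v]),
                numeric(1))
  keep <- setNames(rep(TRUE, length(ids)), ids)
  for (a in seq_len(length(ids) - 1)) for (b in seq(a + 1, length(ids))) {
    va <- ids[a]; vb <- ids[b]
    if (!keep[va] || !keep[vb]) next
    if (variants$chrom[a] != variants$chrom[b]) next
    if (ld_r2(genotypes[, va], genotypes[, vb]) > r2_max) {
      drop <- if (maf[va] < maf[vb]) va else vb   # tie -> later position
      keep[drop] <- FALSE
    }
  }
  ids[keep]
}

# brute-force nested-model F by explicit residual sums of squares via lm
f_test_oracle <- function(response, dosage, covariates) {
  ok <- !is.na(dosage) & !is.na(response)
  y <- response[ok]; d <- factor(dosage[ok])
  cv <- as.data.frame(covariates)[ok, , drop = FALSE]
  m0 <- stats::lm(y ~ ., data = cv)
  m1 <- stats::lm(y ~ . + d, data = cbind(cv, d = d))
  rss0 <- sum(stats::resid(m0)^2); rss1 <- sum(stats::resid(m1)^2)
  df1 <- m0$df.residual - m1$df.residual
  df2 <- m1$df.residual
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# per-pair linear-regression oracle for the scan statistic
scan_oracle_pair <- function(expr_row, dosage, covariates) {
  d <- as.numeric(dosage)
  if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
  fit <- stats::lm(expr_row ~ d + covariates - 1)
  co <- summary(fit)$coefficients
  list(t = co["d", "t value"], p = co["d", "Pr(>|t|)"])
}

# base-by-base bitmap union length (small chromosomes only)
bitmap_length_oracle <- function(rows, chrom_len) {
  total <- 0
  for (chr in unique(rows$chrom)) {
    bits <- logical(chrom_len)
    r <- rows[rows$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(r))) bits[r$start[i]:r$end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

# simulate z rows from a known 2-tissue mixture model
simulate_z_mixture <- function(n, weights, signal_var = 9, signal_cor = 0.8,
                               rho0 = 0, seed = 1L) {
  set.seed(seed)
  configs <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  delta <- matrix(c(1, rho0, rho0, 1), 2)
  sig <- matrix(c(signal_var, signal_cor * signal_var,
                  signal_cor * signal_var, signal_var), 2)
  which_cfg <- sample.int(4, n, replace = TRUE, prob = weights)
  z <- matrix(NA_real_, n, 2)
  for (g in 1:4) {
    idx <- which(which_cfg == g)
    if (!length(idx)) next
    d <- diag(configs[g, ])
    s <- delta + d %*% sig %*% d
    ch <- chol(s)
    z[idx, ] <- matrix(rnorm(2 * length(idx)), ncol = 2) %*% ch
  }
  rownames(z) <- sprintf("pair%05d", seq_len(n))
  list(z = z, config = which_cfg)
}

# tiny single-tissue scan world for power/calibration studies: one chromosome,
# independent variants (no LD), optional planted pair on gene 1 / variant 1
null_scan_world <- function(seed, n = 48L, n_var = 150L, n_genes = 80L,
                            effect = 0, maf = 0.3) {
  design <- simulation_design(
    n_samples = n, group_sizes = c(n %/% 3, n %/% 3, n - 2 * (n %/% 3)),
    n_variants = n_var, n_genes = c(liver = n_genes),
    maf_range = c(maf, maf), ld_copy_prob = 0,
    n_cis_effects = 0L, n_trans_effects = 0L,
    genome = genome_build("1", 5e7), seed = seed)
  gt <- simulate_genotypes(design, n_samples = n)
  ann <- simulate_gene_annotation(design, "liver")
  eff <- if (effect != 0)
    data.frame(gene_id = ann$gene_id[1], variant_id = gt$variants$variant_id[1],
               effect = effect, class = "cis")
  else NULL
  counts <- simulate_expression(gt$genotypes, design, ann, eff)
  normalised <- log_cpm(filter_low_expression(counts))
  list(genotypes = gt$genotypes, variants = gt$variants, annotation = ann,
       normalised = normalised, effects = eff, design = design)
}
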