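# Variant-level quality control: call rate, exact Hardy-Weinberg test, minor
# allele frequency, and sliding-window LD pruning. Filters are applied in the
# order call-rate -> HWE -> MAF -> LD, and each removed variant is attributed
# to the first filter it fails.

#' Per-variant call rate
#'
#' @param x Dosage vector for one variant (0/1/2/NA).
#' @return Fraction of non-missing calls in `[0, 1]`.
#' @export
call_rate <- function(x) {
  if (!length(x)) stop("empty genotype column")
  mean(!is.na(x))
}

#' Exact two-sided Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, the probability of every
#' attainable heterozygote count (same parity as observed) follows the
#' hypergeometric-form distribution; the two-sided p-value sums the
#' probabilities of all configurations no more probable than the observed one.
#' Monomorphic variants admit a single configuration and return p = 1.
#'
#' @param n_aa,n_ab,n_bb Genotype class counts (AA homozygote, heterozygote,
#'   BB homozygote).
#' @return p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(3, 5, 2)
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("negative genotype counts")
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("all genotype counts are zero")
  n_b <- n_ab + 2L * n_bb            # count of the rarer-coded allele
  if (n_b > n) n_b <- 2L * n - n_b   # work with the minor allele
  probs <- hwe_het_probabilities(n, n_b)
  obs <- as.character(n_ab)
  if (is.na(probs[obs])) stop("heterozygote count inconsistent with alleles")
  p <- sum(probs[probs <= probs[[obs]] * (1 + 1e-10)])
  min(p, 1)
}

# Probability of each attainable heterozygote count given n genotypes and
# n_b copies of the minor allele; computed by the standard log-recurrence.
hwe_het_probabilities <- function(n, n_b) {
  het <- seq(n_b %% 2L, n_b, by = 2L)
  het <- het[(n_b - het) / 2L + (2L * n - n_b - het) / 2L + het == n]
  logp <- numeric(length(het))
  for (i in seq_along(het)[-1]) {
    h <- het[i]
    # P(h) / P(h-2) = 4 * n_aa(h-2) * n_bb(h-2) / (h * (h-1))
    n_bb_prev <- (n_b - (h - 2L)) / 2L
    n_aa_prev <- n - (h - 2L) - n_bb_prev
    logp[i] <- logp[i - 1] + log(4 * n_aa_prev * n_bb_prev) - log(h * (h - 1))
  }
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), het)
}

#' Minor allele frequency of a dosage column
#'
#' @param x Dosage vector (0/1/2/NA); at least one non-missing call.
#' @return MAF in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("all calls missing")
  f_b <- mean(x) / 2
  min(f_b, 1 - f_b)
}

#' Squared genotype correlation between two variants
#'
#' Pearson r^2 of dosages over pairwise-complete samples; zero variance in
#' either column yields 0 (no prunable signal).
#'
#' @param x,y Dosage vectors.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) stop("need >= 2 pairwise-complete samples")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Greedy left-to-right pruning per chromosome: within each bp window, every
#' still-retained pair with r^2 above the threshold loses its lower-MAF
#' member (tie: the later-position variant is removed); the window then
#' advances by the step size. Deterministic.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param variants Variant table (position-sorted per chromosome).
#' @param window_bp,step_bp Window and step sizes in bp (defaults 5000).
#' @param r2_max Pruning threshold (pairs with r^2 > `r2_max` are violations).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, variants, window_bp = 5000, step_bp = 5000,
                     r2_max = 0.8) {
  keep <- stats::setNames(rep(TRUE, nrow(variants)), variants$variant_id)
  maf <- apply(genotypes[, variants$variant_id, drop = FALSE], 2,
               minor_allele_frequency)
  for (chr in unique(variants$chrom)) {
    vi <- variants[variants$chrom == chr, , drop = FALSE]
    if (nrow(vi) < 2L) next
    w_start <- min(vi$pos)
    last <- max(vi$pos)
    while (w_start <= last) {
      in_win <- vi$variant_id[vi$pos >= w_start &
                              vi$pos < w_start + window_bp]
      in_win <- in_win[keep[in_win]]
      if (length(in_win) >= 2L) {
        for (a in seq_len(length(in_win) - 1L)) {
          for (b in seq((a + 1L), length(in_win))) {
            va <- in_win[a]; vb <- in_win[b]
            if (!keep[va] || !keep[vb]) next
            if (ld_r2(genotypes[, va], genotypes[, vb]) > r2_max) {
              # remove the lower-MAF member; tie -> later position
              drop <- if (maf[va] < maf[vb]) va
                      else if (maf[vb] < maf[va]) vb
                      else vb
              keep[drop] <- FALSE
            }
          }
        }
      }
      w_start <- w_start + step_bp
    }
  }
  variants$variant_id[keep[variants$variant_id]]
}

#' Run the full variant QC chain
#'
#' Applies call rate (> `call_rate_min`, strict), exact HWE
#' (p > `hwe_p_min`, strict), MAF (> `maf_min`, strict) and LD pruning in
#' that order, attributing each removal to the first failing filter.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param variants Variant table.
#' @param config A [run_config()].
#' @return List with `genotypes`, `variants` (the retained panel) and
#'   `report`, an object of class `qc_report` whose counts always balance:
#'   `n_input = n_retained + sum(removals)`.
#' @export
run_qc <- function(genotypes, variants, config = run_config()) {
  validate_genotype_matrix(genotypes)
  stopifnot(all(variants$variant_id %in% colnames(genotypes)))
  genotypes <- genotypes[, variants$variant_id, drop = FALSE]
  n_input <- nrow(variants)

  cr <- apply(genotypes, 2, call_rate)
  fail_cr <- cr <= config$call_rate_min

  hwe_p <- apply(genotypes, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(1)
    hwe_exact_test(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  })
  fail_hwe <- !fail_cr & hwe_p <= config$hwe_p_min

  maf <- apply(genotypes, 2, function(x)
    if (all(is.na(x))) 0 else minor_allele_frequency(x))
  fail_maf <- !fail_cr & !fail_hwe & maf <= config$maf_min

  pre_ld <- !(fail_cr | fail_hwe | fail_maf)
  v_ld <- variants[pre_ld, , drop = FALSE]
  kept_ids <- if (nrow(v_ld)) {
    ld_prune(genotypes, v_ld, config$ld_window_bp, config$ld_step_bp,
             config$ld_r2_max)
  } else character()
  fail_ld <- pre_ld & !(variants$variant_id %in% kept_ids)

  report <- structure(list(
    n_input = n_input,
    n_removed_callrate = sum(fail_cr),
    n_removed_hwe = sum(fail_hwe),
    n_removed_maf = sum(fail_maf),
    n_removed_ld = sum(fail_ld),
    n_retained = length(kept_ids)), class = "qc_report")
  stopifnot(report$n_input == report$n_retained + report$n_removed_callrate +
              report$n_removed_hwe + report$n_removed_maf +
              report$n_removed_ld)
  if (report$n_retained == 0L) warning("QC removed every variant")
  keep <- variants$variant_id %in% kept_ids
  list(genotypes = genotypes[, variants$variant_id[keep], drop = FALSE],
       variants = variants[keep, , drop = FALSE],
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("variant QC:", x$n_input, "in;",
      x$n_removed_callrate, "failed call rate;",
      x$n_removed_hwe, "failed HWE;",
      x$n_removed_maf, "failed MAF;",
      x$n_removed_ld, "pruned for LD;",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  df <- as.data.frame(unclass(report))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
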