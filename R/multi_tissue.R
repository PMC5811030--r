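# Empirical-Bayes hierarchical mixture model over tissue-activity
# configurations for gene-SNP pairs measured in T tissues (here T = 2).
# Each pair's vector of z-statistics is modelled as a mixture over the 2^T
# configurations gamma in {0,1}^T with covariance
#   Sigma_gamma = Delta + D_gamma Sigma D_gamma,
# where Delta is the null covariance (unit diagonal, off-diagonal rho0
# estimated once from clearly-null rows and then fixed) and Sigma is the
# signal covariance. Weights and Sigma are fitted by EM; multi-tissue calls
# rank pairs by the local false discovery rate of the all-active
# configuration and keep the largest prefix whose mean local fdr stays below
# the target.

#' Build the z-statistic matrix for the multi-tissue model
#'
#' Rows are the union of gene-SNP pairs retained by either tissue's scan; the
#' partner tissue's statistic is recomputed (never censored at threshold).
#' t-statistics are converted to z by the probability-preserving transform
#' `|z| = Phi^-1(1 - p/2)` with the sign of t.
#'
#' @param scans Named list of two (or more) `eqtl_records` from [eqtl_scan()].
#' @param genotypes Shared post-QC dosage matrix.
#' @param expressions Named list of `expression_set`s parallel to `scans`.
#' @param covariates Covariate matrix used by the scans.
#' @return Object of class `zmatrix`: numeric matrix pairs x tissues with
#'   rownames `gene_id|variant_id`, plus attributes `pairs` (data.frame) and
#'   `class` info (cis/trans and distance from the first scan that saw the
#'   pair).
#' @export
build_zmatrix <- function(scans, genotypes, expressions, covariates = NULL) {
  stopifnot(length(scans) >= 2L, length(scans) == length(expressions))
  measured <- Reduce(intersect, lapply(expressions, function(e)
    rownames(if (inherits(e, "expression_set")) e$normalised else e)))
  keys <- lapply(scans, function(s) {
    ok <- s$gene_id %in% measured & s$variant_id %in% colnames(genotypes)
    paste(s$gene_id[ok], s$variant_id[ok], sep = "|")
  })
  all_keys <- unique(unlist(keys))
  if (!length(all_keys))
    stop("no gene-SNP pairs measured in every tissue were retained")
  first <- do.call(rbind, lapply(scans, function(s)
    data.frame(key = paste(s$gene_id, s$variant_id, sep = "|"),
               gene_id = s$gene_id, variant_id = s$variant_id,
               eqtl_class = s$eqtl_class, snp_chrom = s$snp_chrom,
               distance = s$distance, stringsAsFactors = FALSE)))
  pairs <- first[!duplicated(first$key), , drop = FALSE]
  pairs <- pairs[match(all_keys, pairs$key), , drop = FALSE]

  z <- matrix(NA_real_, length(all_keys), length(scans),
              dimnames = list(all_keys, names(scans)))
  for (k in seq_along(scans)) {
    s <- scans[[k]]
    ok <- s$gene_id %in% measured & s$variant_id %in% colnames(genotypes)
    have <- match(paste(s$gene_id[ok], s$variant_id[ok], sep = "|"), all_keys)
    z[have, k] <- t_to_z(s$t[ok], attr(s, "df"))
    missing_rows <- which(is.na(z[, k]))
    if (length(missing_rows)) {
      ps <- scan_pairs(genotypes, expressions[[k]],
                       pairs[missing_rows, c("gene_id", "variant_id")],
                       covariates)
      z[missing_rows, k] <- t_to_z(ps$t, attr(ps, "df"))
    }
  }
  if (anyNA(z)) stop("z matrix has unresolved entries")
  structure(z, pairs = pairs, class = c("zmatrix", class(z)))
}

#' t to z probability-preserving transform
#'
#' Maps a t statistic with `df` degrees of freedom to the standard normal
#' quantile of the same two-sided tail probability, preserving sign. Computed
#' in log space so large |t| do not saturate.
#'
#' @param t t-statistics.
#' @param df Degrees of freedom.
#' @return z values.
#' @export
t_to_z <- function(t, df) {
  log_tail <- stats::pt(-abs(t), df, log.p = TRUE)
  zmag <- -stats::qnorm(log_tail, log.p = TRUE)
  sign(t) * zmag
}

# zero-mean multivariate normal density, vectorised over rows of z
dmvnorm0 <- function(z, sigma) {
  ch <- chol(sigma)
  back <- backsolve(ch, t(z), transpose = TRUE)
  q <- colSums(back^2)
  exp(-0.5 * q - sum(log(diag(ch))) - 0.5 * ncol(z) * log(2 * pi))
}

mt_configs <- function(T) {
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), T)))[, T:1, drop = FALSE]
  dimnames(g) <- list(apply(g, 1, paste, collapse = ""), NULL)
  g
}

mt_sigma_gamma <- function(gamma, delta, sigma) {
  d <- diag(gamma, nrow = length(gamma))
  delta + d %*% sigma %*% d
}

#' Fit the multi-tissue mixture model by EM
#'
#' The null cross-tissue correlation `rho0` is estimated once from rows with
#' `max |z| < 1` (Pearson correlation) and then held fixed. The E-step
#' computes responsibilities `r_ig` proportional to `p_g phi(z_i; 0,
#' Sigma_g)`; the M-step sets `p_g` to mean responsibilities and re-estimates
#' the signal covariance by responsibility-weighted moment matching on the
#' all-active component (`Sigma = S_11 - Delta`, eigenvalue-floored to keep
#' it positive semi-definite with variances >= 1e-4); partial configurations
#' inherit the corresponding sub-blocks. Iteration stops when the
#' log-likelihood gain drops below `tol`.
#'
#' @param z A `zmatrix` (or plain pairs x tissues matrix).
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @param seed Seed for the random weight initialisation.
#' @return Object of class `mt_model`: list with `configs`, `weights`,
#'   `rho0`, `delta`, `sigma`, `loglik_trace`, `converged`, `n_rows`.
#' @export
fit_mt_model <- function(z, tol = 1e-6, max_iter = 500L, seed = 1L) {
  z <- unclass(z)
  attr(z, "pairs") <- NULL
  if (nrow(z) < 100L)
    warning("fewer than 100 rows; mixture fit may be unstable")
  T <- ncol(z)
  configs <- mt_configs(T)
  n_cfg <- nrow(configs)

  null_rows <- apply(abs(z), 1, max) < 1
  rho0 <- if (sum(null_rows) >= 10L && T > 1L)
    stats::cor(z[null_rows, , drop = FALSE])[1, 2] else 0
  rho0 <- min(max(rho0, -0.95), 0.95)
  delta <- diag(T); delta[delta == 0] <- rho0

  set.seed(seed)
  w <- stats::runif(n_cfg, 0.5, 1.5); w[1] <- w[1] + n_cfg  # favour null
  weights <- stats::setNames(w / sum(w), rownames(configs))
  sigma <- diag(4, T) + 1  # signal variance 5, covariance 1 to start

  # Identifiability guard: a signal component must add at least 0.25 z-units
  # of variance, otherwise it collapses onto the null and the null weight
  # leaks into arbitrary partial configurations.
  floor_psd <- function(s) {
    e <- eigen((s + t(s)) / 2, symmetric = TRUE)
    e$values <- pmax(e$values, 0.25)
    e$vectors %*% diag(e$values, nrow = length(e$values)) %*% t(e$vectors)
  }
  mix_parts <- function(weights, sigma) {
    dens <- vapply(seq_len(n_cfg), function(g)
      dmvnorm0(z, mt_sigma_gamma(configs[g, ], delta, sigma)),
      numeric(nrow(z)))
    if (nrow(z) == 1L) dens <- matrix(dens, 1L)
    num <- sweep(dens, 2, weights, `*`)
    row_tot <- pmax(rowSums(num), .Machine$double.xmin)
    list(ll = sum(log(row_tot)), resp = num / row_tot)
  }

  loglik_trace <- numeric(0)
  converged <- FALSE
  cur <- mix_parts(weights, sigma)
  for (it in seq_len(max_iter)) {
    loglik_trace <- c(loglik_trace, cur$ll)
    resp <- cur$resp

    weights_new <- stats::setNames(colMeans(resp), rownames(configs))
    r_full <- resp[, n_cfg]
    sigma_new <- if (sum(r_full) > 1e-8) {
      s_full <- crossprod(z * sqrt(r_full)) / sum(r_full)
      floor_psd(s_full - delta)
    } else sigma
    # The weight update is exact EM (monotone); the covariance update is
    # moment matching and can overshoot, so accept it only if it does not
    # decrease the likelihood.
    cand <- mix_parts(weights_new, sigma_new)
    if (cand$ll >= cur$ll - 1e-9) {
      weights <- weights_new; sigma <- sigma_new
    } else {
      cand <- mix_parts(weights_new, sigma)
      weights <- weights_new
    }
    gain <- cand$ll - cur$ll
    cur <- cand
    if (gain < tol && gain > -1e-9) {
      loglik_trace <- c(loglik_trace, cur$ll)
      converged <- TRUE
      break
    }
  }
  structure(list(configs = configs, weights = weights, rho0 = rho0,
                 delta = delta, sigma = sigma, loglik_trace = loglik_trace,
                 converged = converged, n_rows = nrow(z),
                 tol = tol, max_iter = max_iter, seed = seed),
            class = "mt_model")
}

#' @export
print.mt_model <- function(x, ...) {
  cat("mt_model:", ncol(x$configs), "tissues;",
      length(x$loglik_trace), "EM iterations;",
      if (x$converged) "converged" else "NOT converged", "\nweights:",
      paste(sprintf("%s=%.4f", rownames(x$configs), x$weights),
            collapse = " "), "\n")
  invisible(x)
}

#' Posterior configuration probabilities under a fitted model
#'
#' @param z z matrix.
#' @param model A fitted `mt_model`.
#' @return Matrix pairs x configurations of posterior probabilities (rows sum
#'   to one).
#' @export
mt_posterior <- function(z, model) {
  z <- unclass(z); attr(z, "pairs") <- NULL
  n_cfg <- nrow(model$configs)
  dens <- vapply(seq_len(n_cfg), function(g)
    dmvnorm0(z, mt_sigma_gamma(model$configs[g, ], model$delta, model$sigma)),
    numeric(nrow(z)))
  if (nrow(z) == 1L) dens <- matrix(dens, 1L)
  num <- sweep(dens, 2, model$weights, `*`)
  post <- num / pmax(rowSums(num), .Machine$double.xmin)
  colnames(post) <- rownames(model$configs)
  rownames(post) <- rownames(z)
  post
}

#' Call multi-tissue eQTLs
#'
#' Ranks pairs by the local false discovery rate of the all-active
#' configuration, `lfdr = 1 - P(gamma = 1...1 | z)`, and calls the largest
#' prefix whose running mean lfdr (the set's global FDR estimate) stays at or
#' below the target.
#'
#' @param z A `zmatrix`.
#' @param model Fitted `mt_model`.
#' @param fdr_target Global FDR target (default 0.05).
#' @return data.frame with pair keys, the posterior columns, `lfdr`,
#'   `called`, and attribute `global_fdr` (mean lfdr of the call set).
#' @export
call_multitissue <- function(z, model, fdr_target = 0.05) {
  post <- mt_posterior(z, model)
  full_cfg <- paste(rep(1, ncol(model$configs)), collapse = "")
  lfdr <- 1 - post[, full_cfg]
  ord <- order(lfdr)
  run_mean <- cumsum(lfdr[ord]) / seq_along(ord)
  n_call <- max(c(0L, which(run_mean <= fdr_target)))
  called <- logical(length(lfdr))
  if (n_call > 0L) called[ord[seq_len(n_call)]] <- TRUE
  pairs <- attr(z, "pairs")
  out <- data.frame(key = rownames(post), stringsAsFactors = FALSE)
  if (!is.null(pairs)) out <- cbind(out, pairs[match(out$key, pairs$key),
                                               c("gene_id", "variant_id",
                                                 "eqtl_class", "snp_chrom",
                                                 "distance")])
  out <- cbind(out, post, lfdr = lfdr, called = called)
  rownames(out) <- NULL
  attr(out, "global_fdr") <- if (n_call > 0L) run_mean[n_call] else 0
  out
}

#' Serialise / load a fitted multi-tissue model (JSON)
#' @param model A `mt_model`.
#' @param path JSON path.
#' @export
write_mt_model <- function(model, path) {
  obj <- list(weights = as.numeric(model$weights),
              config_names = rownames(model$configs),
              rho0 = model$rho0, sigma = as.vector(model$sigma),
              T = ncol(model$configs), loglik_trace = model$loglik_trace,
              converged = model$converged, n_rows = model$n_rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mt_model
#' @export
read_mt_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  T <- obj$T
  delta <- diag(T); delta[delta == 0] <- obj$rho0
  structure(list(configs = mt_configs(T), weights = obj$weights,
                 rho0 = obj$rho0, delta = delta,
                 sigma = matrix(obj$sigma, T, T),
                 loglik_trace = obj$loglik_trace,
                 converged = obj$converged, n_rows = obj$n_rows),
            class = "mt_model")
}
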