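# End-to-end pipeline and a small command-line front end. Each CLI subcommand
# reads a JSON run configuration (flag overrides via --set key=value), logs
# the resolved configuration and seed, and writes TSV outputs.

#' Run the full analysis pipeline on in-memory data
#'
#' QC -> per-tissue expression prep -> cis/trans scans -> EBV/expression
#' filtering -> multi-tissue model -> chromosomal stats -> enrichment ->
#' candidate selection.
#'
#' @param data A dataset list as produced by [simulate_dataset()] (fields:
#'   `genotypes`, `variants`, `annotation`, `counts`, `samples`, `traits`).
#' @param config A [run_config()].
#' @param genome A `genome_build` (defaults to the design genome if present,
#'   else [pig_genome()]).
#' @return List with `qc`, `expressions`, `scans`, `tested`, `filtered`,
#'   `filtered_counts`, `zmatrix`, `mt_model`, `mt_calls`, `density`,
#'   `network`, `enrichment`, `category_summary`, `candidates`,
#'   `candidate_summary`.
#' @export
run_pipeline <- function(data, config = run_config(),
                         genome = if (!is.null(data$design))
                           data$design$genome else pig_genome()) {
  qc <- run_qc(data$genotypes, data$variants, config)
  covar <- group_covariates(data$samples)
  tissues <- names(data$counts)

  expressions <- scans <- tested <- filtered <- stats::setNames(
    vector("list", length(tissues)), tissues)
  for (ts in tissues) {
    expressions[[ts]] <- prepare_expression(data$counts[[ts]], tissue = ts,
                                            design = covar,
                                            mean_threshold = config$mean_count_min)
    scans[[ts]] <- eqtl_scan(qc$genotypes, expressions[[ts]], qc$variants,
                             data$annotation[[ts]], covariates = covar,
                             config = config, tissue = ts)
    sig <- scans[[ts]][scans[[ts]]$significant, , drop = FALSE]
    tested[[ts]] <- ebv_filter_tests(sig, qc$genotypes, expressions[[ts]],
                                     data$samples)
    filtered[[ts]] <- filter_eqtls(tested[[ts]], config$fdr_target)
  }
  all_filtered <- do.call(rbind, lapply(filtered, as.data.frame))
  filtered_counts <- count_filtered(all_filtered)

  mt <- tryCatch({
    zm <- build_zmatrix(scans, qc$genotypes, expressions, covariates = covar)
    model <- fit_mt_model(zm, seed = config$seed)
    calls <- call_multitissue(zm, model, config$fdr_target)
    list(zmatrix = zm, model = model, calls = calls)
  }, error = function(e) {
    warning("multi-tissue stage skipped: ", conditionMessage(e))
    list(zmatrix = NULL, model = NULL, calls = NULL)
  })

  density <- chromosome_density(all_filtered, genome,
                                scale = config$density_scale)
  mt_genes <- if (!is.null(mt$calls))
    unique(mt$calls$gene_id[mt$calls$called]) else character()
  network <- if (length(mt_genes) >= 2L)
    spearman_network(expressions, mt_genes, config$network_threshold)
  else NULL

  traits_kept <- breed_filter(data$traits, config$breed_min_qtls)
  filtered_cis <- all_filtered[all_filtered$eqtl_class == "cis", ,
                               drop = FALSE]
  enrichment <- if (nrow(filtered_cis) && nrow(traits_kept))
    enrich_all(filtered_cis, qc$variants, traits_kept, g = config$genome_bp,
               fdr_target = config$fdr_target)
  else NULL
  csum <- if (!is.null(enrichment) && any(enrichment$enriched)) {
    totals <- table(data$traits$category)
    category_summary(enrichment, category_totals = as.numeric(totals) |>
                       stats::setNames(names(totals)))
  } else NULL
  candidates <- if (!is.null(enrichment))
    select_candidates(filtered_cis, enrichment, qc$genotypes, data$samples,
                      qc$variants, traits_kept, ebv_max = config$ebv_max,
                      boar_taint_traits = config$boar_taint_traits)
  else NULL

  list(qc = qc, expressions = expressions, scans = scans, tested = tested,
       filtered = filtered, filtered_counts = filtered_counts,
       zmatrix = mt$zmatrix, mt_model = mt$model, mt_calls = mt$calls,
       density = density, network = network, enrichment = enrichment,
       category_summary = csum, candidates = candidates,
       candidate_summary = if (!is.null(candidates))
         summarise_candidates(candidates) else NULL)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `normalize`, `scan`, `multitissue`,
#' `ebv-filter`, `stats`, `enrich`, `candidates`, `run-all`. Every subcommand
#' accepts `--config <json>` (defaults are used otherwise), `--set key=value`
#' overrides, `--out <dir>` and data-file flags; a log with the resolved
#' configuration and seed is written next to the outputs. `run-all` (and, for
#' convenience, each stage command) regenerates the synthetic dataset from the
#' configured seed when no input files are given.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Invisibly, the output directory.
#' @export
taintqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: taintqtl <subcommand> [--config f] ",
                          "[--set k=v] [--out dir]")
  cmd <- args[1]; args <- args[-1]
  opt <- list(config = NULL, out = ".", set = character(), ped = NULL,
              counts = character(), samples = NULL, traits = NULL)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
           "--config" = { opt$config <- take() },
           "--out" = { opt$out <- take() },
           "--set" = { opt$set <- c(opt$set, take()) },
           "--ped" = { opt$ped <- take() },
           "--counts" = { opt$counts <- c(opt$counts, take()) },
           "--samples" = { opt$samples <- take() },
           "--traits" = { opt$traits <- take() },
           stop("unknown flag: ", a))
    i <- i + 1L
  }
  config <- if (!is.null(opt$config)) read_config(opt$config) else run_config()
  for (kv in opt$set) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    val <- utils::type.convert(parts[2], as.is = TRUE)
    config[[parts[1]]] <- val
  }
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(opt$out, paste0(cmd, ".log"))
  log_lines <- c(paste("subcommand:", cmd),
                 paste("time:", format(Sys.time())),
                 paste("seed:", config$seed), "resolved config:",
                 paste(" ", names(config), "=",
                       vapply(unclass(config), function(v)
                         paste(v, collapse = ","), "")))

  load_or_simulate <- function() {
    if (!is.null(opt$ped)) {
      gt <- read_genotypes(opt$ped)
      counts <- lapply(opt$counts, read_counts)
      names(counts) <- sub("\\.tsv$", "", basename(opt$counts))
      list(genotypes = gt$genotypes, variants = gt$variants,
           counts = counts,
           samples = if (!is.null(opt$samples)) read_samples(opt$samples),
           traits = if (!is.null(opt$traits)) read_trait_qtl(opt$traits),
           annotation = NULL, design = NULL)
    } else {
      design <- simulation_design(n_variants = 2000L,
                                  n_genes = c(liver = 200L, testis = 220L),
                                  seed = config$seed)
      simulate_dataset(design)
    }
  }

  if (cmd == "simulate") {
    design <- simulation_design(seed = config$seed)
    data <- simulate_dataset(design)
    write_genotypes(data$genotypes, data$variants,
                    file.path(opt$out, "genotypes"))
    for (ts in names(data$counts))
      write_counts(data$counts[[ts]], file.path(opt$out,
                                                paste0("counts_", ts, ".tsv")))
    write_samples(data$samples, file.path(opt$out, "samples.tsv"))
    write_trait_qtl(data$traits, file.path(opt$out, "traits.tsv"))
    for (ts in names(data$annotation))
      write_gene_annotation(data$annotation[[ts]],
                            file.path(opt$out, paste0("genes_", ts, ".gff3")))
  } else if (cmd == "qc") {
    data <- load_or_simulate()
    res <- run_qc(data$genotypes, data$variants, config)
    write_qc_report(res$report, file.path(opt$out, "qc_report.tsv"))
    write_genotypes(res$genotypes, res$variants,
                    file.path(opt$out, "genotypes_qc"))
  } else if (cmd == "normalize") {
    data <- load_or_simulate()
    for (ts in names(data$counts)) {
      es <- prepare_expression(data$counts[[ts]], tissue = ts,
                               mean_threshold = config$mean_count_min)
      write_counts(es$counts,
                   file.path(opt$out, paste0("counts_filtered_", ts, ".tsv")))
      utils::write.table(es$normalised,
                         file.path(opt$out, paste0("logcpm_", ts, ".tsv")),
                         sep = "\t", quote = FALSE)
      utils::write.table(es$weights,
                         file.path(opt$out, paste0("weights_", ts, ".tsv")),
                         sep = "\t", quote = FALSE)
    }
  } else if (cmd %in% c("scan", "multitissue", "ebv-filter", "stats",
                        "enrich", "candidates", "run-all")) {
    data <- load_or_simulate()
    res <- run_pipeline(data, config)
    for (ts in names(res$scans))
      write_eqtl_records(res$scans[[ts]],
                         file.path(opt$out, paste0("eqtls_", ts, ".tsv")))
    if (cmd %in% c("ebv-filter", "run-all", "candidates", "enrich", "stats"))
      for (ts in names(res$filtered))
        write_eqtl_records(res$filtered[[ts]],
                           file.path(opt$out,
                                     paste0("eqtls_filtered_", ts, ".tsv")))
    if (cmd %in% c("multitissue", "run-all") && !is.null(res$mt_model)) {
      write_mt_model(res$mt_model, file.path(opt$out, "mt_model.json"))
      utils::write.table(res$mt_calls,
                         file.path(opt$out, "mt_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (cmd %in% c("stats", "run-all")) {
      utils::write.table(res$density, file.path(opt$out, "density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(res$network))
        utils::write.table(res$network, file.path(opt$out, "network.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (cmd %in% c("enrich", "candidates", "run-all") &&
        !is.null(res$enrichment))
      utils::write.table(res$enrichment,
                         file.path(opt$out, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (cmd %in% c("candidates", "run-all") && !is.null(res$candidates))
      write_candidates(res$candidates, file.path(opt$out, "candidates.tsv"))
    write_qc_report(res$qc$report, file.path(opt$out, "qc_report.tsv"))
  } else {
    stop("unknown subcommand: ", cmd)
  }
  writeLines(log_lines, log_path)
  invisible(opt$out)
}
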