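# End-to-end orchestration: discovery -> TSS validation -> orthology
# (with and without the distance limit) -> chromosome summary ->
# expression correlations, with deterministic TSV outputs and a run log.

#' Default pipeline configuration
#'
#' @param ... named overrides of any threshold or path.
#' @return config list: input paths (`annotations_a`, `annotations_b`,
#'   `format` (`"genepred"`/`"bed12"`), `chain_ab`, `net_ab`, `cpg_a`,
#'   `cage_a`, `expr_a`, `expr_b`, `orthologs`, `single_tss`), thresholds
#'   (`max_tss_distance`, `cage_tolerance`, `cpg_flank`,
#'   `align_threshold`, `confidence_low`, `confidence_high`), `direction`
#'   and `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(annotations_a = NULL, annotations_b = NULL, format = "genepred",
              chain_ab = NULL, net_ab = NULL, cpg_a = NULL, cage_a = NULL,
              expr_a = NULL, expr_b = NULL, orthologs = NULL,
              single_tss = NULL,
              max_tss_distance = 1000, cage_tolerance = 100,
              cpg_flank = 500, align_threshold = 0.5,
              confidence_low = 2L, confidence_high = 5L,
              direction = "a2b", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  thr <- unlist(cfg[c("max_tss_distance", "cage_tolerance", "cpg_flank",
                      "align_threshold", "confidence_low", "confidence_high")])
  if (any(thr <= 0)) stop("all thresholds must be positive")
  cfg
}

.stage <- function(name, expr, log) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  cat(sprintf("[%s] stage %s: ok\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Executes discovery, validation, dual-limit orthology classification and
#' (when expression inputs are configured) the correlation analyses,
#' writing every result table plus a plain-text log to `out_dir`. Outputs
#' are deterministic given fixed inputs and seed; the serialised config and
#' its hash accompany the tables.
#'
#' @param config list from [pipeline_config()].
#' @param out_dir output directory.
#' @return list of the in-memory results (`pairs`, `loci`, `calls_limit`,
#'   `calls_nolimit`, `verdicts`, `chrom_summary`, `validation`,
#'   `coexpression`, `cross_species`, `output_files`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- file.path(out_dir, "run.log")
  cat("bidiortho pipeline\n", file = log)
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(cfg_txt) * seq_along(utf8ToInt(cfg_txt))) %% .Machine$integer.max)
  writeLines(c(paste("# config hash:", cfg_hash), cfg_txt),
             file.path(out_dir, "config.txt"))

  tx_a <- .stage("read_annotations_a",
                 read_transcripts(config$annotations_a, config$format), log)
  loci <- .stage("cluster", cluster_transcripts(tx_a), log)
  loci <- .attach_locus_exons(loci, tx_a)
  pairs <- .stage("discover", {
    p <- find_bidirectional_pairs(loci, config$max_tss_distance)
    p <- collapse_promoters(p)
    p$confidence <- assign_confidence(p, config$confidence_low, config$confidence_high)
    p
  }, log)
  pairs$config_hash <- cfg_hash
  write_results(pairs, file.path(out_dir, "promoters.tsv"), "tsv")
  write_results(pairs, file.path(out_dir, "promoters.bed"), "bed")

  validation <- NULL
  if (!is.null(config$cage_a)) {
    validation <- .stage("validate", {
      peaks <- read_cage_peaks(config$cage_a)
      prof <- tss_cage_profile(loci[loci$locus_id %in%
                                      c(pairs$left_locus, pairs$right_locus), ],
                               peaks)
      act <- coordinated_activation_fraction(pairs, peaks, config$cage_tolerance)
      cpg <- if (!is.null(config$cpg_a) && !is.null(config$single_tss)) {
        cpg_overlap_stats(pairs, read_results(config$single_tss),
                          read_bed_intervals(config$cpg_a), config$cpg_flank)
      }
      list(profile = prof, activation = act, cpg = cpg)
    }, log)
    write_results(validation$profile, file.path(out_dir, "cage_profile.tsv"), "tsv")
    rep <- data.frame(metric = c("coordinated_activation_pct",
                                 "cpg_bidirectional_pct", "cpg_single_pct"),
                      value = c(validation$activation$percent,
                                if (is.null(validation$cpg)) NA else validation$cpg$bidirectional_pct,
                                if (is.null(validation$cpg)) NA else validation$cpg$single_pct),
                      config_hash = cfg_hash)
    write_results(rep, file.path(out_dir, "validation_report.tsv"), "tsv")
  }

  calls_limit <- calls_nolimit <- verdicts <- chrom_sum <- NULL
  if (!is.null(config$chain_ab)) {
    resources <- .stage("orthology_resources", {
      tx_b <- read_transcripts(config$annotations_b, config$format)
      tl <- cluster_transcripts(tx_b)
      list(level1 = level1_regions(read_net(config$net_ab)),
           chains = read_chain(config$chain_ab),
           target_loci = tl,
           orthologs = read_orthologs(config$orthologs))
    }, log)
    calls_limit <- .stage("orthology_limit",
      classify_all(pairs, loci, resources, config$max_tss_distance,
                   config$align_threshold), log)
    calls_nolimit <- .stage("orthology_nolimit",
      classify_all(pairs, loci, resources, Inf, config$align_threshold), log)
    verdicts <- promoter_verdict(calls_limit)
    chrom_sum <- chromosome_summary(calls_limit)
    for (nm in c("calls_limit", "calls_nolimit")) {
      d <- get(nm); d$config_hash <- cfg_hash
      write_results(d, file.path(out_dir, paste0(nm, ".tsv")), "tsv")
    }
    write_results(cbind(category_summary(calls_limit), limit = "1000"),
                  file.path(out_dir, "category_summary_limit.tsv"), "tsv")
    write_results(cbind(category_summary(calls_nolimit), limit = "none"),
                  file.path(out_dir, "category_summary_nolimit.tsv"), "tsv")
    write_results(chrom_sum, file.path(out_dir, "chromosome_summary.tsv"), "tsv")
    write_results(verdicts, file.path(out_dir, "promoter_verdicts.tsv"), "tsv")
  }

  coexpr <- cross <- NULL
  if (!is.null(config$expr_a)) {
    coexpr <- .stage("coexpression", {
      mat <- aggregate_replicates(read_expression(config$expr_a))
      pair_coexpression(mat, pairs)
    }, log)
    write_results(coexpr$records, file.path(out_dir, "pair_coexpression.tsv"), "tsv")
    write_results(coexpr$histogram, file.path(out_dir, "pair_coexpression_hist.tsv"), "tsv")
    if (!is.null(config$expr_b) && !is.null(verdicts)) {
      cross <- .stage("cross_species", {
        mat_a <- aggregate_replicates(read_expression(config$expr_a))
        mat_b <- aggregate_replicates(read_expression(config$expr_b))
        confirmed <- verdicts$pair_id[verdicts$confirmed]
        orth <- read_orthologs(config$orthologs)
        genes <- unique(unlist(pairs[pairs$pair_id %in% confirmed,
                                     c("left_symbol", "right_symbol")]))
        shared <- intersect(colnames(mat_a), colnames(mat_b))
        cross_species_correlation(mat_a, mat_b,
                                  orth[orth$source %in% genes, , drop = FALSE],
                                  shared)
      }, log)
      write_results(cross$records, file.path(out_dir, "cross_species_corr.tsv"), "tsv")
      write_results(cross$histogram, file.path(out_dir, "cross_species_hist.tsv"), "tsv")
    }
  }
  list(pairs = pairs, loci = loci, calls_limit = calls_limit,
       calls_nolimit = calls_nolimit, verdicts = verdicts,
       chrom_summary = chrom_sum, validation = validation,
       coexpression = coexpr, cross_species = cross,
       output_files = list.files(out_dir, full.names = TRUE))
}
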