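#' Build and validate a pipeline configuration
#'
#' Collects the input paths and the analysis thresholds of a full run. All
#' validation errors are collected and reported together, not fail-fast.
#' The defaults carry the conventional thresholds of this analysis: caller
#' score 6.0 with >= 3 probes and |mean log2| > 0.25, differential
#' expression at p < 0.05 and FDR < 0.25, cytoband frequency filter at 25%
#' of the QNBC samples (30% available as the stricter preset), consensus
#' across >= 2 target databases, and PPI score >= 0.9.
#'
#' @param cohort_dir Directory laid out as written by [generate_cohort()]
#'   (annotation files, `acgh/`, `mirna_counts.csv`, `targets/`, ...).
#' @param out_dir Output directory for stage tables (created on run).
#' @param score_threshold,min_probes,min_abs_mean_log2 Caller parameters.
#' @param p_threshold,fdr_threshold Differential-expression thresholds.
#' @param min_frequency Cytoband frequency filter (proportion in \[0, 1\]).
#' @param frequency_group Group whose frequencies are filtered.
#' @param min_db Minimum supporting target databases.
#' @param ppi_min_score Minimum PPI interaction score.
#' @param k_sd Per-sample alteration threshold in reference SD units.
#' @param cv_folds 0 for in-sample panel ROC, k >= 2 for cross-validation.
#' @return List of class `pipeline_config`, or an error listing every
#'   problem found.
#' @export
pipeline_config <- function(cohort_dir, out_dir = file.path(cohort_dir,
                                                            "results"),
                            score_threshold = 6.0, min_probes = 3L,
                            min_abs_mean_log2 = 0.25,
                            p_threshold = 0.05, fdr_threshold = 0.25,
                            min_frequency = 0.25,
                            frequency_group = "QNBC",
                            min_db = 2L, ppi_min_score = 0.9,
                            k_sd = 1.0, cv_folds = 0L) {
  cfg <- list(cohort_dir = cohort_dir, out_dir = out_dir,
              score_threshold = score_threshold,
              min_probes = as.integer(min_probes),
              min_abs_mean_log2 = min_abs_mean_log2,
              p_threshold = p_threshold, fdr_threshold = fdr_threshold,
              min_frequency = min_frequency,
              frequency_group = frequency_group,
              min_db = as.integer(min_db), ppi_min_score = ppi_min_score,
              k_sd = k_sd, cv_folds = as.integer(cv_folds))
  errors <- character()
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(score_threshold > 0, "score_threshold must be > 0")
  chk(min_probes >= 1, "min_probes must be >= 1")
  chk(min_abs_mean_log2 > 0, "min_abs_mean_log2 must be > 0")
  chk(p_threshold >= 0 && p_threshold <= 1, "p_threshold must be in [0, 1]")
  chk(fdr_threshold >= 0 && fdr_threshold <= 1,
      "fdr_threshold must be in [0, 1]")
  chk(min_frequency >= 0 && min_frequency <= 1,
      "min_frequency must be in [0, 1]")
  chk(ppi_min_score >= 0 && ppi_min_score <= 1,
      "ppi_min_score must be in [0, 1]")
  chk(k_sd > 0, "k_sd must be > 0")
  for (f in c("cytobands.txt", "mirna_loci.bed", "gene_loci.bed",
              "mirna_counts.csv", "groups.tsv", "clinical.csv")) {
    chk(file.exists(file.path(cohort_dir, f)),
        paste0("missing input file: ", file.path(cohort_dir, f)))
  }
  chk(dir.exists(file.path(cohort_dir, "acgh")),
      paste0("missing probe-table directory: ",
             file.path(cohort_dir, "acgh")))
  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML key-value file whose keys mirror the [pipeline_config()]
#' arguments and returns the validated configuration. Unknown keys are
#' warned about and dropped.
#'
#' @param path Path to the YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
validate_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("unknown configuration key(s) ignored: ",
            paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Run the full integrated analysis
#'
#' Executes the stages in order — aberration calling, cytoband frequency
#' profiling, signature copy-number comparison, miRNA normalization and
#' differential expression, the two-step CNA/miRNA integration, enrichment
#' and network filtering, and ROC/clinical discrimination — writing each
#' stage's tables under `config$out_dir` before the next stage begins. The
#' run is deterministic for a fixed cohort and configuration (the only
#' stochastic step, cross-validated panel ROC, is off by default).
#'
#' @param config A `pipeline_config`.
#' @return A run report: per-stage record counts, parameter echo, and the
#'   main stage objects (`calls`, `summary`, `freq`, `de`, `concordant`,
#'   `integration`, `roc`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cd <- config$cohort_dir
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  ## inputs
  cytobands <- read_cytoband_table(file.path(cd, "cytobands.txt"))
  mirna_loci <- read_feature_loci(file.path(cd, "mirna_loci.bed"), "miRNA")
  gene_loci <- read_feature_loci(file.path(cd, "gene_loci.bed"),
                                 "protein_coding")
  sheet <- utils::read.table(file.path(cd, "groups.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  clinical <- utils::read.csv(file.path(cd, "clinical.csv"),
                              stringsAsFactors = FALSE)
  tick("load_inputs")

  ## stage 1: aberration calling and frequency profiling
  acgh_samples <- sheet$sample_id[sheet$has_acgh]
  acgh_groups <- stats::setNames(sheet$group[sheet$has_acgh], acgh_samples)
  params <- caller_params(config$score_threshold, config$min_probes,
                          config$min_abs_mean_log2)
  probes <- lapply(stats::setNames(acgh_samples, acgh_samples), function(s) {
    read_probe_table(file.path(cd, "acgh", paste0(s, ".tsv")))
  })
  calls <- do.call(rbind, lapply(acgh_samples, function(s) {
    call_aberrations(probes[[s]], params, sample_id = s)
  }))
  call_summary <- summarize_calls(calls, acgh_groups)
  regions <- derive_cna_regions(calls, cytobands)
  freq <- cytoband_frequency(calls, regions, acgh_groups)
  write_tsv(calls, file.path(config$out_dir, "aberration_calls.tsv"))
  write_tsv(call_summary$per_sample,
            file.path(config$out_dir, "calls_per_sample.tsv"))
  write_tsv(freq, file.path(config$out_dir, "cytoband_frequency.tsv"))
  tick("acgh")

  ## stage 2: signature copy-number comparison
  gene_cn_interval <- gene_copy_number(calls = calls, gene_loci = gene_loci,
                                       mode = "interval",
                                       samples = acgh_samples)
  gene_cn_probe <- gene_copy_number(probes_by_sample = probes,
                                    gene_loci = gene_loci,
                                    mode = "mean_probe")
  signatures <- list(
    ca20_interval = signature_cn_comparison(gene_cn_interval,
                                            ca20_signature(), acgh_groups),
    ca20_mean_probe = signature_cn_comparison(gene_cn_probe,
                                              ca20_signature(), acgh_groups),
    cin25_interval = signature_cn_comparison(gene_cn_interval,
                                             cin25_signature(), acgh_groups),
    cin25_mean_probe = signature_cn_comparison(gene_cn_probe,
                                               cin25_signature(),
                                               acgh_groups)
  )
  write_tsv(signatures$cin25_interval$results,
            file.path(config$out_dir, "cin25_interval_cn.tsv"))
  write_tsv(signatures$ca20_interval$results,
            file.path(config$out_dir, "ca20_interval_cn.tsv"))
  tick("signatures")

  ## stage 3: miRNA normalization and differential expression
  raw <- read_count_matrix(file.path(cd, "mirna_counts.csv"))
  norm <- normalize_counts(raw)
  expr_groups <- stats::setNames(sheet$group, sheet$sample_id)
  expr_groups <- expr_groups[colnames(norm$log2)]
  de <- differential_expression(norm, expr_groups, case = "QNBC",
                                p_threshold = config$p_threshold,
                                fdr_threshold = config$fdr_threshold)
  clust <- if (sum(de$significant) >= 2L) {
    supervised_clustering(norm, de$mirna[de$significant])
  } else NULL
  write_tsv(de, file.path(config$out_dir, "differential_expression.tsv"))
  tick("mirna")

  ## stage 4: two-step integration
  records <- map_de_mirnas_to_cna_cytobands(
    de, mirna_loci, freq, regions, group = config$frequency_group,
    min_frequency = config$min_frequency)
  concordant <- concordance_filter(records)
  target_files <- list.files(file.path(cd, "targets"), full.names = TRUE)
  tables <- lapply(target_files, read_target_table)
  consensus <- consensus_targets(tables, min_db = config$min_db)
  consensus <- consensus[consensus$mirna %in% concordant$mirna, ,
                         drop = FALSE]
  retained <- regions[regions$label %in%
                        freq$label[freq$group == config$frequency_group &
                                     freq$frequency >=
                                       100 * config$min_frequency], ,
                      drop = FALSE]
  cna_genes <- unique(unlist(lapply(seq_len(nrow(retained)), function(k) {
    g <- gene_loci[gene_loci$chrom == retained$chrom[k] &
                     gene_loci$start < retained$end[k] &
                     gene_loci$end > retained$start[k], ]
    g$feature_id
  })))
  integration <- intersect_targets_with_cna_genes(consensus, cna_genes)
  gmt_path <- file.path(cd, "gene_sets.gmt")
  enrichment <- if (file.exists(gmt_path) && integration$n_after > 0) {
    gene_set_overlap(integration$genes, read_gmt(gmt_path),
                     universe = gene_loci$feature_id)
  } else NULL
  ppi_path <- file.path(cd, "ppi_edges.tsv")
  network <- if (file.exists(ppi_path) && nrow(integration$pairs) > 0) {
    edges <- utils::read.table(ppi_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    filter_ppi_edges(edges, min_score = config$ppi_min_score,
                     mirna_edges = integration$pairs)
  } else NULL
  alteration <- if (nrow(concordant) > 0) {
    per_sample_alteration_count(norm, concordant, expr_groups,
                                reference_group = "TNBC",
                                k_sd = config$k_sd)
  } else NULL
  write_tsv(records, file.path(config$out_dir, "concordance_records.tsv"))
  if (!is.null(enrichment)) {
    write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }
  tick("integration")

  ## stage 5: discrimination and clinical association
  conc_mirnas <- sort(unique(concordant$mirna))
  roc_tab <- NULL
  panel <- NULL
  if (length(conc_mirnas) >= 1L) {
    roc_list <- lapply(conc_mirnas, function(m) {
      r <- roc_single(norm$log2[m, ], expr_groups)
      data.frame(id = m, auc = r$auc, ci_low = r$ci[["lower"]],
                 ci_high = r$ci[["upper"]], stringsAsFactors = FALSE)
    })
    roc_tab <- do.call(rbind, roc_list)
    if (length(conc_mirnas) >= 2L) {
      panel <- combined_panel_roc(t(norm$log2[conc_mirnas, , drop = FALSE]),
                                  expr_groups, cv_folds = config$cv_folds)
      roc_tab <- rbind(roc_tab, data.frame(
        id = "combined_panel", auc = panel$roc$auc,
        ci_low = panel$roc$ci[["lower"]], ci_high = panel$roc$ci[["upper"]],
        stringsAsFactors = FALSE))
    }
    write_tsv(roc_tab, file.path(config$out_dir, "roc.tsv"))
  }
  clin_types <- c(age = "continuous", tumor_size = "continuous",
                  race = "categorical", node_status = "categorical",
                  metastasis = "categorical", recurrence = "categorical")
  clin_tests <- compare_clinical_tables(clinical, clinical$group, clin_types)
  assoc <- NULL
  if (length(conc_mirnas)) {
    expr_clin <- clinical[match(colnames(norm$log2), clinical$sample_id), ]
    assoc <- do.call(rbind, lapply(conc_mirnas, function(m) {
      v <- norm$log2[m, ]
      rbind(
        cbind(mirna = m, covariate = "age",
              associate_continuous(v, expr_clin$age)[, c("model", "effect",
                                                         "p")]),
        cbind(mirna = m, covariate = "tumor_size",
              associate_continuous(v, expr_clin$tumor_size)[, c("model",
                                                                "effect",
                                                                "p")]),
        cbind(mirna = m, covariate = "metastasis",
              associate_binary(v, expr_clin$metastasis)[, c("model",
                                                            "effect", "p")])
      )
    }))
    write_tsv(assoc, file.path(config$out_dir, "clinical_association.tsv"))
  }
  write_tsv(clin_tests, file.path(config$out_dir, "clinical_tests.tsv"))
  tick("discrimination")

  report <- list(
    parameters = unclass(config),
    counts = list(
      n_acgh_samples = length(acgh_samples),
      n_calls = nrow(calls),
      n_regions = nrow(regions),
      n_mirnas_tested = nrow(de),
      n_de_mirnas = sum(de$significant),
      n_mapped_records = nrow(records),
      n_mapped_mirnas = length(unique(records$mirna)),
      n_concordant_mirnas = length(conc_mirnas),
      n_consensus_genes = length(unique(consensus$gene)),
      n_surviving_genes = integration$n_after,
      reduction_pct = integration$reduction_pct
    ),
    timings_sec = timings,
    calls = calls, summary = call_summary, regions = regions, freq = freq,
    signatures = signatures, de = de, clustering = clust,
    records = records, concordant = concordant, consensus = consensus,
    integration = integration, enrichment = enrichment, network = network,
    alteration = alteration, roc = roc_tab, panel = panel,
    clinical_tests = clin_tests, associations = assoc
  )
  jsonlite::write_json(
    c(report["parameters"], report["counts"], list(timings = timings)),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
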