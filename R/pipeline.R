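#' Pipeline configuration
#'
#' Collects every threshold and input of an end-to-end run. All randomness
#' (simulation, gene sets, permutation null) flows from the single `seed`.
#'
#' @param sim a [simulation_config()] describing the synthetic study (the
#'   simulation seed is overridden by `seed`).
#' @param n_sets,set_size_range,n_enriched gene-set collection parameters
#'   passed to [generate_gene_sets()].
#' @param min_rin sample QC threshold on the RNA integrity number.
#' @param detection_threshold,detection_alpha transcript detection filter
#'   parameters (defaults 0.5 and 0.05).
#' @param meta_q probe-level significance threshold on the BH q
#'   (default 0.01).
#' @param ora_alpha per-stratum BH level for over-representation
#'   (default 0.05).
#' @param graph_percentile Jaccard percentile for the overlap graph
#'   (default 90).
#' @param perm_B number of permutations for the enrichment robustness FDR
#'   (at least 100).
#' @param model_spec base-model covariates.
#' @param added_covariates covariates added in the sensitivity stage.
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            n_sets = 40L,
                            set_size_range = c(10L, 40L),
                            n_enriched = 8L,
                            min_rin = 7,
                            detection_threshold = 0.5,
                            detection_alpha = 0.05,
                            meta_q = 0.01,
                            ora_alpha = 0.05,
                            graph_percentile = 90,
                            perm_B = 1000L,
                            model_spec = base_model_spec(),
                            added_covariates = c("lymphocytes", "neutrophils",
                                                 "monocytes", "eosinophils",
                                                 "basophils"),
                            seed = 1L) {
  for (nmv in c("detection_threshold", "detection_alpha", "meta_q", "ora_alpha")) {
    v <- get(nmv)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(nmv, " must lie strictly in (0, 1)")
  }
  if (graph_percentile < 0 || graph_percentile > 100)
    stop("graph_percentile must lie in [0, 100]")
  if (perm_B < 100) stop("perm_B must be at least 100")
  if (n_enriched > n_sets) stop("n_enriched exceeds n_sets")
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(sim = sim, n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 n_enriched = as.integer(n_enriched), min_rin = min_rin,
                 detection_threshold = detection_threshold,
                 detection_alpha = detection_alpha, meta_q = meta_q,
                 ora_alpha = ora_alpha, graph_percentile = graph_percentile,
                 perm_B = as.integer(perm_B), model_spec = model_spec,
                 added_covariates = added_covariates, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_line <- function(dir, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE, sep = "")
  invisible(line)
}

cohort_ids <- function(config) {
  sprintf("cohort%d", seq_along(config$sim$n_samples_per_cohort))
}

#' Simulation stage: write synthetic study files
#'
#' Runs [generate_study()] and [generate_gene_sets()] and writes per-cohort
#' intensity/detection/covariate TSVs, the probe annotation, the truth
#' tables and the GMT collection into `dir`.
#'
#' @param config a [pipeline_config()].
#' @param dir run directory.
#' @return invisibly, `dir`.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- generate_study(config$sim)
  for (s in gs$studies) write_study(s, dir)
  write_tsv(gs$studies[[1]]$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(gs$truth$probe_truth, file.path(dir, "truth_probes.tsv"))
  coll <- generate_gene_sets(gs$truth, n_sets = config$n_sets,
                             set_size_range = config$set_size_range,
                             n_enriched = config$n_enriched,
                             seed = config$seed + 1L)
  gene_truth <- gs$truth$gene_truth
  write_tsv(gene_truth, file.path(dir, "truth_genes.tsv"))
  write_tsv(data.frame(set = names(coll$sets),
                       planted_enriched = unname(coll$enriched)),
            file.path(dir, "truth_sets.tsv"))
  write_gmt(coll$sets, file.path(dir, "gene_sets.gmt"))
  log_line(dir, "simulate",
           sprintf("cohorts=%d probes=%d genes=%d sets=%d",
                   length(gs$studies), config$sim$n_probes,
                   config$sim$n_genes, config$n_sets))
  invisible(dir)
}

read_cohort_studies <- function(config, dir, normalized = FALSE) {
  ann <- read_tsv(file.path(dir, "annotation.tsv"))
  lapply(cohort_ids(config), function(id) {
    s <- read_study(dir, id, ann)
    if (normalized) {
      s$exprs <- read_matrix_tsv(file.path(dir, paste0(id, "_normalized.tsv")))
      s$covariates <- read_tsv(file.path(dir, paste0(id, "_covariates_qc.tsv")))
    }
    s
  })
}

#' Preprocessing stage: QC, normalization, detection filter
#'
#' Reads the cohort files in `dir`, applies [filter_samples()],
#' [quantile_normalize()] + [log2_transform()] per cohort, and the
#' two-cohort [detection_filter()]; writes `<cohort>_normalized.tsv`,
#' `<cohort>_covariates_qc.tsv`, `qc_report.tsv`, `detection_rates.tsv` and
#' `kept_probes.txt`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_preprocess <- function(config, dir) {
  studies <- read_cohort_studies(config, dir)
  qc_logs <- list()
  processed <- lapply(studies, function(s) {
    ps <- preprocess_study(s, min_rin = config$min_rin)
    qc_logs[[ps$cohort_id]] <<- attr(ps, "qc_log")
    write_matrix_tsv(ps$exprs, file.path(dir, paste0(ps$cohort_id, "_normalized.tsv")))
    write_tsv(ps$covariates, file.path(dir, paste0(ps$cohort_id, "_covariates_qc.tsv")))
    ps
  })
  write_tsv(do.call(rbind, qc_logs), file.path(dir, "qc_report.tsv"))
  det <- detection_filter(processed, threshold = config$detection_threshold,
                          alpha = config$detection_alpha)
  write_tsv(det$summary, file.path(dir, "detection_rates.tsv"))
  writeLines(det$probes, file.path(dir, "kept_probes.txt"))
  log_line(dir, "preprocess",
           sprintf("samples_retained=%s probes_kept=%d",
                   paste(vapply(processed, function(s) ncol(s$exprs), 0L),
                         collapse = "+"),
                   length(det$probes)))
  invisible(dir)
}

#' Association stage: per-cohort transcript sweeps
#'
#' Reads the normalized matrices, QC'd covariates and kept probes from
#' `dir`, runs [run_cohort()] with the base model for each cohort, and
#' writes `assoc_<cohort>.tsv`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_assoc <- function(config, dir) {
  studies <- read_cohort_studies(config, dir, normalized = TRUE)
  probes <- readLines(file.path(dir, "kept_probes.txt"))
  for (s in studies) {
    res <- run_cohort(s, probes, model_spec = config$model_spec)
    write_tsv(res, file.path(dir, paste0("assoc_", s$cohort_id, ".tsv")))
  }
  log_line(dir, "assoc", sprintf("probes=%d cohorts=%d", length(probes),
                                 length(studies)))
  invisible(dir)
}

#' Meta-analysis stage
#'
#' Reads the per-cohort association TSVs, runs [meta_analyze()],
#' [collapse_genes()] and [direction_summary()], and writes
#' `meta_probes.tsv`, `meta_genes.tsv` and `direction_summary.tsv`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_meta <- function(config, dir) {
  assoc_list <- lapply(cohort_ids(config), function(id)
    read_tsv(file.path(dir, paste0("assoc_", id, ".tsv"))))
  meta <- meta_analyze(assoc_list, q_threshold = config$meta_q)
  ann <- read_tsv(file.path(dir, "annotation.tsv"))
  genes <- collapse_genes(meta, ann, q_threshold = config$meta_q)
  write_tsv(meta, file.path(dir, "meta_probes.tsv"))
  write_tsv(genes, file.path(dir, "meta_genes.tsv"))
  if (nrow(genes) > 0)
    write_tsv(direction_summary(genes), file.path(dir, "direction_summary.tsv"))
  else
    write_tsv(data.frame(class = character(0), count = integer(0),
                         percent = numeric(0)),
              file.path(dir, "direction_summary.tsv"))
  log_line(dir, "meta", sprintf("probes=%d significant=%d genes=%d",
                                nrow(meta), sum(meta$significant), nrow(genes)))
  invisible(dir)
}

#' Enrichment stage: direction-stratified ORA plus permutation FDR
#'
#' Builds the reference universe (genes represented among the filtered
#' probes), runs [run_ora()] on the all/positive/negative significant gene
#' lists, augments the `all` stratum with [permutation_fdr()], and writes
#' `enrichment.tsv` (one row per set) and `ora_long.tsv`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_enrich <- function(config, dir) {
  genes <- read_tsv(file.path(dir, "meta_genes.tsv"))
  ann <- read_tsv(file.path(dir, "annotation.tsv"))
  probes <- readLines(file.path(dir, "kept_probes.txt"))
  universe <- unique(ann$gene[ann$probe_id %in% probes])
  coll <- gene_set_collection(read_gmt(file.path(dir, "gene_sets.gmt")), universe)
  strata <- list(
    all = genes$gene,
    positive = genes$gene[genes$direction_class == "positive"],
    negative = genes$gene[genes$direction_class == "negative"])
  ora <- run_ora(strata, coll, alpha = config$ora_alpha)
  all_rows <- ora$stratum == "all"
  if (any(all_rows) && length(intersect(strata$all, coll$universe)) > 0) {
    ora_all <- permutation_fdr(ora[all_rows, ], coll, B = config$perm_B,
                               seed = config$seed + 2L)
    ora <- merge(ora, ora_all[, c("set", "stratum", "perm_fdr")],
                 by = c("set", "stratum"), all.x = TRUE)
  } else {
    ora$perm_fdr <- NA_real_
  }
  write_tsv(ora[order(ora$stratum, ora$q, ora$set), ],
            file.path(dir, "ora_long.tsv"))
  write_tsv(enrichment_table(ora), file.path(dir, "enrichment.tsv"))
  log_line(dir, "enrich",
           sprintf("sets=%d significant_all=%d", length(coll$sets),
                   sum(ora$significant[ora$stratum == "all"], na.rm = TRUE)))
  invisible(dir)
}

#' Graph stage: pathway-overlap network of associated transcripts
#'
#' Set memberships are the significant (q below the meta threshold) probes
#' whose gene belongs to the set; sets with no associated transcript are
#' dropped. Writes GraphML plus edge/node TSVs via [write_overlap_graph()].
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_graph <- function(config, dir) {
  meta <- read_tsv(file.path(dir, "meta_probes.tsv"))
  ann <- read_tsv(file.path(dir, "annotation.tsv"))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  sig <- meta[meta$significant, , drop = FALSE]
  sig_gene <- ann$gene[match(sig$probe_id, ann$probe_id)]
  memberships <- lapply(sets, function(g) sig$probe_id[sig_gene %in% g])
  memberships <- memberships[vapply(memberships, length, 0L) > 0]
  if (length(memberships) >= 2) {
    og <- build_graph(memberships, percentile = config$graph_percentile)
    write_overlap_graph(og, dir)
    log_line(dir, "graph", sprintf("nodes=%d edges=%d threshold=%.4g",
                                   nrow(og$nodes), nrow(og$edges), og$threshold))
  } else {
    write_tsv(data.frame(source = character(0), target = character(0),
                         jaccard = numeric(0), shared_count = integer(0)),
              file.path(dir, "overlap_graph_edges.tsv"))
    write_tsv(data.frame(set = character(0), size = integer(0),
                         label = character(0)),
              file.path(dir, "overlap_graph_nodes.tsv"))
    log_line(dir, "graph", "fewer than 2 sets with associated transcripts; empty graph")
  }
  invisible(dir)
}

#' Sensitivity stage: augmented-model concordance
#'
#' Re-runs association and meta-analysis with the added covariates and
#' writes `sensitivity_meta_probes.tsv` and `concordance.tsv`.
#'
#' @inheritParams stage_simulate
#' @return invisibly, `dir`.
#' @export
stage_sensitivity <- function(config, dir) {
  studies <- read_cohort_studies(config, dir, normalized = TRUE)
  probes <- readLines(file.path(dir, "kept_probes.txt"))
  sens <- run_sensitivity(studies, probes, base_spec = config$model_spec,
                          added_covariates = config$added_covariates,
                          q_threshold = config$meta_q)
  write_tsv(sens$meta, file.path(dir, "sensitivity_meta_probes.tsv"))
  write_tsv(sens$report, file.path(dir, "concordance.tsv"))
  log_line(dir, "sensitivity",
           sprintf("r2_beta=%.2f r2_se=%.2f r2_neglog10p=%.2f",
                   sens$report$r2_beta, sens$report$r2_se,
                   sens$report$r2_neglog10p))
  invisible(dir)
}

#' Run the full pipeline into an artifact directory
#'
#' Executes simulate, preprocess, assoc, meta, enrich, graph and
#' sensitivity in order, each stage reading the previous stage's files, and
#' writes a machine-readable `manifest.json` (package version, seed,
#' thresholds). Any stage error aborts with the stage name and leaves a
#' `FAILED` marker naming it; partial outputs are retained. All result
#' artifacts are byte-reproducible from the seed (`run.log` carries
#' timestamps and is the one exception).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- config[setdiff(names(config), c("sim"))]
  manifest$sim <- unclass(config$sim)
  manifest$package_version <- as.character(utils::packageVersion("btwas"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages <- list(simulate = stage_simulate, preprocess = stage_preprocess,
                 assoc = stage_assoc, meta = stage_meta,
                 enrich = stage_enrich, graph = stage_graph,
                 sensitivity = stage_sensitivity)
  for (nm in names(stages)) {
    tryCatch(stages[[nm]](config, out_dir), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", nm, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  invisible(out_dir)
}
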