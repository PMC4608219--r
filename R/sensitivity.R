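#' Concordance of two meta-analysis result sets
#'
#' Quantifies how much an augmented covariate model changes the results:
#' squared Pearson correlations (in percent) between the two runs' paired
#' meta-level effect sizes, standard errors, and -log10 p-values, over the
#' probes present in both.
#'
#' @param a,b data.frames from [meta_analyze()] (need columns probe_id,
#'   beta_meta, se_meta, p_meta).
#' @param label_a,label_b model labels for the report.
#' @return one-row data.frame: model_pair, r2_beta, r2_se, r2_neglog10p
#'   (percent), n_probes.
#' @export
concordance <- function(a, b, label_a = "base", label_b = "augmented") {
  shared <- intersect(a$probe_id, b$probe_id)
  if (length(shared) < 3) stop("need at least 3 shared probes")
  ai <- a[match(shared, a$probe_id), ]
  bi <- b[match(shared, b$probe_id), ]
  r2 <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0)
      stop("zero-variance vector; concordance undefined")
    100 * cor(x, y)^2
  }
  data.frame(
    model_pair = paste(label_a, label_b, sep = "_vs_"),
    r2_beta = r2(ai$beta_meta, bi$beta_meta),
    r2_se = r2(ai$se_meta, bi$se_meta),
    r2_neglog10p = r2(-log10(ai$p_meta), -log10(bi$p_meta)),
    n_probes = length(shared),
    stringsAsFactors = FALSE)
}

#' Sensitivity re-analysis under an augmented covariate model
#'
#' Re-runs the per-cohort association sweep and the meta-analysis with the
#' base covariate set plus `added_covariates`, and reports the concordance
#' against the base model run.
#'
#' @param studies list of preprocessed `expression_study` objects.
#' @param probes probe ids to analyze (the detection-filtered set).
#' @param base_spec character vector of base-model covariates.
#' @param added_covariates character vector of covariate columns to add
#'   (must exist in every cohort's covariate table).
#' @param q_threshold significance threshold passed to [meta_analyze()].
#' @return list with `meta` (the augmented-model meta results) and
#'   `report` (a [concordance()] row).
#' @export
run_sensitivity <- function(studies, probes, base_spec = base_model_spec(),
                            added_covariates = character(0),
                            q_threshold = 0.01) {
  for (s in studies) {
    missing_cols <- setdiff(added_covariates, names(s$covariates))
    if (length(missing_cols) > 0)
      stop("cohort ", s$cohort_id, " lacks covariate column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  aug_spec <- unique(c(base_spec, added_covariates))
  base_meta <- meta_analyze(
    lapply(studies, run_cohort, probes = probes, model_spec = base_spec,
           model_id = "base"),
    q_threshold = q_threshold)
  aug_meta <- meta_analyze(
    lapply(studies, run_cohort, probes = probes, model_spec = aug_spec,
           model_id = "augmented"),
    q_threshold = q_threshold)
  list(meta = aug_meta,
       report = concordance(base_meta, aug_meta))
}
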