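# small study configurations shared across test files

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_samples_per_cohort = c(120L, 130L),
                   n_probes = 300L, n_genes = 240L,
                   frac_positive = 0.05, frac_negative = 0.05,
                   reticulocyte_block_size = 10L,
                   detection_fail_frac = 0.2, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# generate, preprocess and meta-analyze one tiny study; returns everything
tiny_pipeline_objects <- function(seed = 1L, ...) {
  gs <- generate_study(tiny_config(seed = seed, ...))
  studies <- lapply(gs$studies, preprocess_study)
  det <- detection_filter(studies)
  assoc <- lapply(studies, run_cohort, probes = det$probes,
                  model_spec = base_model_spec())
  meta <- meta_analyze(assoc)
  genes <- collapse_genes(meta, gs$studies[[1]]$annotation)
  list(gs = gs, studies = studies, det = det, assoc = assoc,
       meta = meta, genes = genes)
}

small_pipeline_config <- function(seed = 7L) {
  pipeline_config(
    sim = simulation_config(n_samples_per_cohort = c(110L, 120L),
                            n_probes = 250L, n_genes = 200L,
                            frac_positive = 0.06, frac_negative = 0.06,
                            reticulocyte_block_size = 8L,
                            detection_fail_frac = 0.2),
    n_sets = 12L, set_size_range = c(8L, 20L), n_enriched = 3L,
    perm_B = 150L, seed = seed)
}

expect_close <- function(x, y, tol) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max abs diff %.3g <= %.3g", max(abs(x - y)), tol))
}
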