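#' Simulation configuration for a two-cohort expression study
#'
#' Defines the statistical structure of a synthetic whole-blood expression
#' study: two (or more) cohorts of samples with covariates and a BMI
#' phenotype, a probe universe mapping onto genes (several probes per gene,
#' as on an expression BeadChip), a planted fraction of probes whose log2
#' expression depends linearly on BMI with known sign, a block of probes
#' loading on a shared BMI-correlated latent factor (mimicking an
#' erythrocyte/reticulocyte ratio shift), and per-observation detection
#' p-values in which a subset of low-expressed probes fails detection.
#'
#' Default cohort sizes and BMI distributions follow the two population-based
#' cohorts the pipeline is designed for: 988 samples with BMI ~ N(28.9,
#' 4.5^2) and 989 samples with BMI ~ N(27.3, 4.6^2).
#'
#' Planted probes receive a standardized effect of fixed magnitude
#' `effect_size_sd` (log2-expression residual SDs per BMI SD), signed
#' positive or negative; planting is gene-coherent, i.e. all probes of a
#' planted gene share one sign, so the simulated truth contains no
#' inconsistent genes unless you construct them yourself.
#'
#' @param n_samples_per_cohort integer vector, samples per cohort.
#' @param n_probes number of probes on the synthetic array.
#' @param n_genes number of genes; must be strictly less than `n_probes` so
#'   that at least one gene carries multiple probes.
#' @param frac_positive,frac_negative fractions of probes with planted
#'   positive / negative BMI effects; their sum must be at most 1.
#' @param effect_size_sd magnitude of the planted effect in log2-expression
#'   units per BMI standard deviation; at the default unit residual SD this
#'   is the standardized effect size.
#' @param reticulocyte_block_size number of (otherwise null) probes loading
#'   positively on the shared BMI-correlated latent factor.
#' @param covariate_effect_scale SD of per-probe nuisance covariate
#'   coefficients (on standardized covariates), and of per-plate shifts.
#' @param detection_fail_frac fraction of probes with low detection rates
#'   (detection p-values drawn Uniform(0,1) rather than Beta(0.2, 5)).
#' @param bmi_mean,bmi_sd per-cohort Gaussian BMI parameters (kg/m^2);
#'   recycled to the number of cohorts.
#' @param noise_sd residual SD of log2 expression.
#' @param seed integer RNG seed; all randomness in [generate_study()] flows
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_samples_per_cohort = c(988L, 989L),
                              n_probes = 6000L,
                              n_genes = 4800L,
                              frac_positive = 0.035,
                              frac_negative = 0.065,
                              effect_size_sd = 0.3,
                              reticulocyte_block_size = 100L,
                              covariate_effect_scale = 0.1,
                              detection_fail_frac = 0.35,
                              bmi_mean = c(28.9, 27.3),
                              bmi_sd = c(4.5, 4.6),
                              noise_sd = 1,
                              seed = 1L) {
  cfg <- list(
    n_samples_per_cohort = as.integer(n_samples_per_cohort),
    n_probes = as.integer(n_probes),
    n_genes = as.integer(n_genes),
    frac_positive = frac_positive,
    frac_negative = frac_negative,
    effect_size_sd = effect_size_sd,
    reticulocyte_block_size = as.integer(reticulocyte_block_size),
    covariate_effect_scale = covariate_effect_scale,
    detection_fail_frac = detection_fail_frac,
    bmi_mean = rep_len(bmi_mean, length(n_samples_per_cohort)),
    bmi_sd = rep_len(bmi_sd, length(n_samples_per_cohort)),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$n_samples_per_cohort) < 1L || any(cfg$n_samples_per_cohort <= 0L))
    stop("n_samples_per_cohort must be positive integers")
  if (cfg$n_probes <= 0L) stop("n_probes must be positive")
  if (cfg$n_genes <= 0L || cfg$n_genes >= cfg$n_probes)
    stop("n_genes must be positive and strictly less than n_probes ",
         "(at least one gene must carry two probes)")
  if (cfg$frac_positive < 0 || cfg$frac_negative < 0 ||
      cfg$frac_positive + cfg$frac_negative > 1)
    stop("frac_positive + frac_negative must lie in [0, 1]")
  if (cfg$effect_size_sd < 0) stop("effect_size_sd must be nonnegative")
  if (cfg$reticulocyte_block_size < 0 ||
      cfg$reticulocyte_block_size > cfg$n_probes)
    stop("reticulocyte_block_size out of range")
  if (cfg$detection_fail_frac < 0 || cfg$detection_fail_frac > 1)
    stop("detection_fail_frac must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  invisible(cfg)
}

#' Construct an expression-study container
#'
#' Bundles one cohort's raw intensity matrix, detection p-values, covariate
#' table and BMI phenotype. Rarely called directly; [generate_study()]
#' produces these, and the file readers reconstruct them.
#'
#' @param intensities probe x sample matrix of nonnegative raw intensities.
#' @param detection_p probe x sample matrix of detection p-values in [0,1].
#' @param covariates data.frame with one row per sample (must include `bmi`
#'   and `rin` for the QC stage).
#' @param cohort_id cohort label.
#' @param annotation data.frame with columns `probe_id`, `gene`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(intensities, detection_p, covariates, cohort_id,
                             annotation) {
  stopifnot(is.matrix(intensities), is.matrix(detection_p),
            is.data.frame(covariates))
  if (!identical(dim(intensities), dim(detection_p)))
    stop("intensities and detection_p dimensions differ")
  if (ncol(intensities) != nrow(covariates))
    stop("covariate table rows must match sample columns")
  if (any(intensities < 0)) stop("negative intensities")
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values outside [0, 1]")
  structure(list(intensities = intensities, detection_p = detection_p,
                 covariates = covariates, cohort_id = cohort_id,
                 annotation = annotation, exprs = NULL),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> cohort '%s': %d probes x %d samples%s\n",
              x$cohort_id, nrow(x$intensities), ncol(x$intensities),
              if (is.null(x$exprs)) " (raw)" else " (preprocessed)"))
  invisible(x)
}

# Per-probe gene assignment: first n_genes probes map 1:1, the remainder are
# extra probes for randomly chosen genes, guaranteeing multi-probe genes.
assign_probes_to_genes <- function(n_probes, n_genes) {
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  gene_of <- c(seq_len(n_genes),
               sample.int(n_genes, n_probes - n_genes, replace = TRUE))
  data.frame(probe_id = sprintf("PRB%06d", seq_len(n_probes)),
             gene = gene_ids[gene_of], stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-cohort expression study with known truth
#'
#' Simulates log2-scale expression as
#' baseline + beta_true * BMI + covariate effects + reticulocyte-factor
#' loading + Gaussian noise, then maps onto the raw intensity scale by
#' `2^x`, so that the preprocessing stage's log2 transform inverts the
#' mapping. The latent reticulocyte-like factor is a per-sample standard
#' Gaussian correlated r = 0.3 with standardized BMI and loads positively on
#' the block probes only. Detection p-values are Beta(0.2, 5) (concentrated
#' near zero) for expressed probes and Uniform(0, 1) for the
#' `detection_fail_frac` of probes designated low-expressed; the latter are
#' drawn from unplanted, non-block probes. All cohorts share the probe
#' annotation and ground truth; given one seed the output is bitwise
#' reproducible.
#'
#' @param config a [simulation_config()] object.
#' @return A list with elements `studies` (list of `expression_study`, one
#'   per cohort) and `truth` (list with per-probe effects `probe_truth`,
#'   per-gene labels `gene_truth`, and the block/detection index sets).
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  P <- config$n_probes
  ann <- assign_probes_to_genes(P, config$n_genes)

  ## --- plant signed effects gene-coherently ----------------------------
  n_pos_target <- round(config$frac_positive * P)
  n_neg_target <- round(config$frac_negative * P)
  probes_by_gene <- split(seq_len(P), ann$gene)
  gene_order <- sample(names(probes_by_gene))
  delta <- numeric(P)                    # standardized effect per probe
  pick_genes <- function(order_pool, n_target, sign) {
    got <- 0L; used <- character(0)
    for (g in order_pool) {
      if (got >= n_target) break
      idx <- probes_by_gene[[g]]
      delta[idx] <<- sign * config$effect_size_sd
      got <- got + length(idx)
      used <- c(used, g)
    }
    used
  }
  pos_genes <- if (n_pos_target > 0)
    pick_genes(gene_order, n_pos_target, +1) else character(0)
  remaining <- setdiff(gene_order, pos_genes)
  neg_genes <- if (n_neg_target > 0)
    pick_genes(remaining, n_neg_target, -1) else character(0)

  planted <- which(delta != 0)

  ## --- reticulocyte block: unplanted probes with positive factor loads --
  free <- setdiff(seq_len(P), planted)
  B <- min(config$reticulocyte_block_size, length(free))
  block <- if (B > 0) sort(sample(free, B)) else integer(0)
  lambda <- numeric(P)
  if (B > 0)
    lambda[block] <- abs(rnorm(B, mean = 0.5, sd = 0.15))

  ## --- detection-failing probes: unplanted, non-block -------------------
  free2 <- setdiff(free, block)
  n_fail <- min(round(config$detection_fail_frac * P), length(free2))
  det_fail <- if (n_fail > 0) sort(sample(free2, n_fail)) else integer(0)

  baseline <- rnorm(P, mean = 7.5, sd = 1.2)
  bmi_sd_ref <- mean(config$bmi_sd)
  beta_true <- delta / bmi_sd_ref  # log2 units per kg/m^2

  nuis <- c("age", "sex", "rbc", "wbc", "hematocrit", "platelets",
            "rin", "storage_time")
  gamma <- matrix(rnorm(P * length(nuis), sd = config$covariate_effect_scale),
                  nrow = P, dimnames = list(NULL, nuis))

  studies <- vector("list", length(config$n_samples_per_cohort))
  for (c_i in seq_along(config$n_samples_per_cohort)) {
    n <- config$n_samples_per_cohort[c_i]
    bmi <- rnorm(n, config$bmi_mean[c_i], config$bmi_sd[c_i])
    bmi_std <- (bmi - config$bmi_mean[c_i]) / config$bmi_sd[c_i]

    cell_raw <- matrix(abs(rnorm(n * 5, mean = c(30, 55, 7, 2.5, 0.5),
                                 sd = c(6, 8, 2, 1, 0.3))),
                       nrow = 5)
    # relative differential counts with measurement noise (so the five
    # proportions do not sum exactly to 1, as in real hemograms)
    cell_prop <- sweep(cell_raw, 2, colSums(cell_raw), "/") *
      matrix(exp(rnorm(5 * n, 0, 0.05)), nrow = 5)
    cov <- data.frame(
      sample_id = sprintf("C%d_S%04d", c_i, seq_len(n)),
      bmi = bmi,
      age = rnorm(n, mean = 60, sd = 10),
      sex = rbinom(n, 1, 0.5),
      rbc = rnorm(n, 4.6, 0.4),
      wbc = rnorm(n, 5.9, 1.6),
      hematocrit = rnorm(n, 0.415, 0.03),
      platelets = rnorm(n, 235, 57),
      rin = 7 + 2.5 * rbeta(n, 2, 2),
      plate = sprintf("plate%02d", (seq_len(n) - 1L) %/% 96L + 1L),
      storage_time = runif(n, 1, 200),
      lymphocytes = cell_prop[1, ], neutrophils = cell_prop[2, ],
      monocytes = cell_prop[3, ], eosinophils = cell_prop[4, ],
      basophils = cell_prop[5, ],
      homa_ir = exp(rnorm(n, 0.3, 0.7)),
      stringsAsFactors = FALSE
    )

    reti <- 0.3 * bmi_std + sqrt(1 - 0.3^2) * rnorm(n)

    Z <- scale(as.matrix(cov[, nuis]))          # standardized nuisance
    plate_shift <- rnorm(length(unique(cov$plate)),
                         sd = config$covariate_effect_scale)
    names(plate_shift) <- unique(cov$plate)

    x <- baseline +
      outer(beta_true, bmi) +
      gamma %*% t(Z) +
      outer(lambda, reti) +
      matrix(rnorm(P * n, sd = config$noise_sd), nrow = P)
    x <- sweep(x, 2, plate_shift[cov$plate], "+")

    detp <- matrix(rbeta(P * n, 0.2, 5), nrow = P)
    if (length(det_fail) > 0)
      detp[det_fail, ] <- runif(length(det_fail) * n)

    dimnames(x) <- dimnames(detp) <- list(ann$probe_id, cov$sample_id)
    studies[[c_i]] <- expression_study(
      intensities = 2^x, detection_p = detp, covariates = cov,
      cohort_id = sprintf("cohort%d", c_i), annotation = ann)
  }

  gene_dir <- vapply(probes_by_gene, function(idx) {
    s <- unique(sign(delta[idx][delta[idx] != 0]))
    if (length(s) == 0) "null"
    else if (length(s) > 1) "inconsistent"
    else if (s > 0) "positive" else "negative"
  }, character(1))

  truth <- list(
    probe_truth = data.frame(
      probe_id = ann$probe_id, gene = ann$gene,
      beta_true = beta_true, delta = delta,
      reticulocyte_block = seq_len(P) %in% block,
      detection_fail = seq_len(P) %in% det_fail,
      stringsAsFactors = FALSE),
    gene_truth = data.frame(
      gene = names(gene_dir), direction_true = unname(gene_dir),
      stringsAsFactors = FALSE),
    config = config
  )
  list(studies = studies, truth = truth)
}

#' Generate a gene-set collection with planted enrichment
#'
#' Builds `n_sets` named gene sets over the simulated gene universe.
#' Planted-enriched sets draw at least 50% (here: 80% in expectation) of
#' their members from truly BMI-associated genes; null sets draw uniformly
#' from all genes. Stands in for a curated pathway knowledge base.
#'
#' @param truth the `truth` element returned by [generate_study()].
#' @param n_sets number of gene sets.
#' @param set_size_range length-2 integer vector of min/max set size
#'   (inclusive); sizes drawn uniformly.
#' @param n_enriched number of sets with planted enrichment (must not exceed
#'   `n_sets`).
#' @param seed integer RNG seed; use a value distinct from the study seed of
#'   [generate_study()] — reusing one seed aligns the two sampling streams
#'   and spuriously correlates "null" set membership with the planted genes.
#' @param enriched_frac expected fraction of an enriched set's members drawn
#'   from associated genes (default 0.8, at least 0.5).
#' @return list with `sets` (named list of gene vectors) and `enriched`
#'   (logical vector, the planted-enrichment flags).
#' @export
generate_gene_sets <- function(truth, n_sets, set_size_range, n_enriched,
                               seed = 1L, enriched_frac = 0.8) {
  if (n_enriched > n_sets) stop("n_enriched exceeds n_sets")
  if (enriched_frac < 0.5 || enriched_frac > 1)
    stop("enriched_frac must lie in [0.5, 1]")
  genes <- truth$gene_truth$gene
  assoc <- truth$gene_truth$gene[truth$gene_truth$direction_true != "null"]
  if (max(set_size_range) > length(genes))
    stop("set sizes exceed number of genes")
  if (n_enriched > 0 && length(assoc) == 0)
    stop("cannot plant enrichment: no associated genes in truth")
  set.seed(seed)
  size_pool <- seq.int(set_size_range[1], set_size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_sets, replace = TRUE)]
  enriched <- seq_len(n_sets) <= n_enriched
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    k <- sizes[i]
    if (enriched[i]) {
      k_assoc <- min(rbinom(1, k, enriched_frac), length(assoc))
      members <- c(sample(assoc, k_assoc),
                   sample(setdiff(genes, assoc), k - k_assoc))
    } else {
      members <- sample(genes, k)
    }
    sets[[i]] <- sort(members)
  }
  names(sets) <- sprintf("SET_%03d%s", seq_len(n_sets),
                         ifelse(enriched, "_planted", ""))
  list(sets = sets, enriched = setNames(enriched, names(sets)))
}
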