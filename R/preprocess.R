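#' Sample quality control: RIN and missing-value exclusions
#'
#' Removes samples with RNA integrity number (RIN) below `min_rin`
#' (strictly: a sample with RIN = 6.9 is excluded at the default threshold 7,
#' a sample with RIN = 7 is retained) and samples with a missing BMI or any
#' missing covariate value. Exclusion counts per reason are attached as the
#' `"qc_log"` attribute.
#'
#' @param study an `expression_study`.
#' @param min_rin minimum acceptable RIN (default 7).
#' @return The filtered `expression_study`; errors if no samples remain,
#'   naming the responsible filter.
#' @export
filter_samples <- function(study, min_rin = 7) {
  stopifnot(inherits(study, "expression_study"))
  cov <- study$covariates
  if (!all(c("rin", "bmi") %in% names(cov)))
    stop("covariates must include 'rin' and 'bmi'")
  low_rin <- !is.na(cov$rin) & cov$rin < min_rin
  incomplete <- !complete.cases(cov)
  keep <- !low_rin & !incomplete
  if (!any(keep)) {
    culprit <- if (all(low_rin)) "RIN filter" else "missing-value filter"
    stop("no samples remain after sample QC (", culprit, ")")
  }
  out <- study
  out$intensities <- study$intensities[, keep, drop = FALSE]
  out$detection_p <- study$detection_p[, keep, drop = FALSE]
  if (!is.null(study$exprs))
    out$exprs <- study$exprs[, keep, drop = FALSE]
  out$covariates <- cov[keep, , drop = FALSE]
  attr(out, "qc_log") <- data.frame(
    cohort = study$cohort_id,
    reason = c("rin_below_threshold", "missing_values", "retained"),
    n = c(sum(low_rin), sum(incomplete & !low_rin), sum(keep)))
  out
}

#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-column mean of order statistics, the standard microarray
#' between-sample normalization. Delegates to [limma::normalizeQuantiles()]
#' with `ties = TRUE`, whose tie convention (tied values receive the mean
#' reference quantile of their tied ranks) matches the package's contract.
#'
#' @param m probe x sample numeric matrix without missing values.
#' @return matrix of the same shape; with fewer than 2 columns the input is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("missing values are not supported; supply complete matrices")
  if (ncol(m) < 2) {
    warning("fewer than 2 samples; returning matrix unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Elementwise log2 transform with a floor for nonpositive entries
#'
#' @param m numeric matrix of raw intensities.
#' @param floor value substituted for entries <= 0 before taking logs
#'   (default 1, i.e. such entries map to 0); a warning reports how many
#'   entries were clipped.
#' @return log2-transformed matrix.
#' @export
log2_transform <- function(m, floor = 1.0) {
  bad <- m <= 0
  if (any(bad)) {
    warning(sum(bad), " nonpositive entries clipped to ", floor)
    m[bad] <- floor
  }
  log2(m)
}

#' Preprocess one cohort: QC, quantile normalization, log2
#'
#' Convenience wrapper running [filter_samples()], [quantile_normalize()]
#' and [log2_transform()] in that order (normalization quantiles are
#' computed on retained samples only) and storing the result in the study's
#' `exprs` slot.
#'
#' @inheritParams filter_samples
#' @return the study with `exprs` set to the normalized log2 matrix.
#' @export
preprocess_study <- function(study, min_rin = 7) {
  study <- filter_samples(study, min_rin = min_rin)
  study$exprs <- quantile_normalize(log2_transform(study$intensities))
  study
}

#' Two-cohort detection-rate transcript filter
#'
#' A probe's detection rate in a cohort is the proportion of samples with
#' detection p-value strictly below `alpha`. A probe passes if its detection
#' rate is strictly above `threshold` in every cohort.
#'
#' @param studies list of `expression_study` objects sharing a probe
#'   universe.
#' @param threshold detection-rate cutoff (default 0.5; strict ">").
#' @param alpha detection-call p-value cutoff (default 0.05; strict "<").
#' @return list with `probes` (character vector of passing probe ids, in
#'   input order) and `summary` (long data.frame: probe_id, cohort,
#'   detection_rate, pass).
#' @export
detection_filter <- function(studies, threshold = 0.5, alpha = 0.05) {
  stopifnot(length(studies) >= 1)
  common <- Reduce(intersect, lapply(studies, function(s) rownames(s$detection_p)))
  if (length(common) == 0) stop("cohorts have disjoint probe sets")
  rates <- vapply(studies, function(s)
    rowMeans(s$detection_p[common, , drop = FALSE] < alpha),
    numeric(length(common)))
  rates <- matrix(rates, nrow = length(common),
                  dimnames = list(common, vapply(studies, `[[`, "", "cohort_id")))
  pass_mat <- rates > threshold
  pass <- rowSums(pass_mat) == ncol(pass_mat)
  summary <- data.frame(
    probe_id = rep(common, times = ncol(rates)),
    cohort = rep(colnames(rates), each = length(common)),
    detection_rate = as.vector(rates),
    pass = as.vector(pass_mat),
    stringsAsFactors = FALSE)
  list(probes = common[pass], summary = summary)
}
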