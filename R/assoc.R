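#' Build the regression design matrix for the association model
#'
#' BMI enters first after the intercept; covariates follow. Categorical
#' covariates (character or factor, e.g. the amplification plate) are
#' encoded as reference-level indicator contrasts; `sex` is used as supplied
#' (0/1).
#'
#' @param bmi numeric phenotype vector.
#' @param covariates data.frame of sample covariates.
#' @param model_spec character vector of covariate column names (may be
#'   empty for the unadjusted model).
#' @return numeric design matrix with columns `(Intercept)`, `bmi`, then
#'   covariate terms.
#' @keywords internal
build_design <- function(bmi, covariates, model_spec) {
  missing_cols <- setdiff(model_spec, names(covariates))
  if (length(missing_cols) > 0)
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "))
  df <- data.frame(bmi = bmi)
  for (v in model_spec) {
    col <- covariates[[v]]
    # a single-level categorical is constant and absorbed by the intercept
    if ((is.character(col) || is.factor(col)) && length(unique(col)) < 2)
      next
    df[[v]] <- col
  }
  X <- stats::model.matrix(~ ., data = df)
  storage.mode(X) <- "double"
  X
}

# Core multi-response OLS: regresses each column of Y on X and returns the
# coefficient of interest (column `coef_idx` of X) with its standard error,
# t statistic and two-sided p-value from t(n - k). Residual-variance-zero
# fits are reported at the p-value floor and flagged.
ols_sweep <- function(X, Y, coef_idx = 2L, p_floor = 1e-300) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("fewer samples (", n, ") than model parameters + 1 (", k + 1, ")")
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, Y)                       # k x P
  fitted <- X %*% coefs
  res <- Y - fitted
  df_res <- n - k
  rss <- colSums(res^2)
  sigma2 <- rss / df_res
  xtx_inv_diag <- numeric(k)
  xtx_inv_diag[qr_x$pivot] <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(sigma2 * xtx_inv_diag[coef_idx])
  beta <- coefs[coef_idx, ]
  degenerate <- sigma2 <= .Machine$double.eps * mean(colSums(Y^2) + 1)
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * pt(abs(tstat), df = df_res, lower.tail = FALSE)
  p <- pmax(p, p_floor)
  data.frame(beta = beta, se = se, t = tstat, p = p, n = n,
             df = df_res, degenerate = degenerate,
             row.names = NULL)
}

#' Covariate-adjusted linear association of one transcript with BMI
#'
#' Ordinary least squares of a transcript's (log2, normalized) expression on
#' BMI plus the covariate set; returns the BMI coefficient only, with its
#' standard error and a two-sided p-value from the t distribution on
#' n - k residual degrees of freedom. p-values are floored at 1e-300 so the
#' downstream z-score conversion stays finite; a perfect fit (zero residual
#' variance) is reported at the floor and flagged `degenerate`.
#'
#' @param y numeric expression vector (one probe).
#' @param bmi numeric phenotype vector.
#' @param covariates data.frame of sample covariates.
#' @param model_spec character vector of covariate names to adjust for.
#' @param probe_id,cohort_id,model_id labels carried into the result.
#' @return one-row data.frame: probe_id, cohort, beta, se, t, p, n, df,
#'   degenerate, model.
#' @export
fit_transcript <- function(y, bmi, covariates, model_spec = character(0),
                           probe_id = NA_character_, cohort_id = NA_character_,
                           model_id = "base") {
  stopifnot(length(y) == length(bmi))
  X <- build_design(bmi, covariates, model_spec)
  out <- ols_sweep(X, matrix(as.numeric(y), ncol = 1))
  cbind(data.frame(probe_id = probe_id, cohort = cohort_id,
                   stringsAsFactors = FALSE),
        out,
        data.frame(model = model_id, stringsAsFactors = FALSE))
}

#' Per-transcript association sweep over one cohort
#'
#' Fits the same covariate-adjusted model to every requested probe of a
#' preprocessed cohort (one shared design matrix, vectorized OLS); results
#' are identical to calling [fit_transcript()] probe by probe, in the order
#' given.
#'
#' @param study a preprocessed `expression_study` (run
#'   [preprocess_study()] first so the `exprs` slot is set).
#' @param probes character vector of probe ids (subset of the study's
#'   probes).
#' @param model_spec character vector of covariate names.
#' @param model_id model label recorded in the results.
#' @return data.frame with one row per probe (columns as in
#'   [fit_transcript()]).
#' @export
run_cohort <- function(study, probes, model_spec = character(0),
                       model_id = "base") {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(study$exprs))
    stop("study has no preprocessed expression; run preprocess_study() first")
  if (length(probes) == 0)
    return(data.frame(probe_id = character(0), cohort = character(0),
                      beta = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), n = integer(0), df = integer(0),
                      degenerate = logical(0), model = character(0)))
  missing_probes <- setdiff(probes, rownames(study$exprs))
  if (length(missing_probes) > 0)
    stop("probes not in study: ", paste(head(missing_probes, 5), collapse = ", "))
  X <- build_design(study$covariates$bmi, study$covariates, model_spec)
  Y <- t(study$exprs[probes, , drop = FALSE])
  out <- ols_sweep(X, Y)
  cbind(data.frame(probe_id = probes, cohort = study$cohort_id,
                   stringsAsFactors = FALSE),
        out,
        data.frame(model = model_id, stringsAsFactors = FALSE))
}

#' Default covariate adjustment set
#'
#' The base association model adjusts for age, sex, red and white blood cell
#' counts, hematocrit, platelet count, RNA integrity (RIN), amplification
#' plate and sample storage time.
#' @return character vector of covariate names.
#' @export
base_model_spec <- function() {
  c("age", "sex", "rbc", "wbc", "hematocrit", "platelets",
    "rin", "plate", "storage_time")
}
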