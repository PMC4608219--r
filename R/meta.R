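#' Signed z-score from a per-cohort association result
#'
#' Converts a two-sided p-value and effect sign into a signed standard
#' normal deviate: z = sign(beta) * qnorm(1 - p/2).
#'
#' @param beta effect estimate (only its sign is used).
#' @param p two-sided p-value in (0, 1].
#' @return signed z-score (0 when p = 1 or beta = 0).
#' @export
z_from_assoc <- function(beta, p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (any(!is.finite(beta))) stop("beta must be finite")
  sign(beta) * qnorm(p / 2, lower.tail = FALSE)
}

#' Sample-size-weighted z-score combination
#'
#' Stouffer's method with weights sqrt(n_i):
#' z_meta = sum(sqrt(n_i) z_i) / sqrt(sum n_i), with two-sided
#' p_meta = 2 (1 - Phi(|z_meta|)). With a single study it reduces to that
#' study's z.
#'
#' @param z numeric vector of signed per-study z-scores.
#' @param n positive integer vector of per-study sample sizes.
#' @return list with `z_meta` and `p_meta`.
#' @export
stouffer <- function(z, n) {
  if (length(z) != length(n) || length(z) < 1)
    stop("z and n must be nonempty and of equal length")
  if (any(n <= 0)) stop("sample sizes must be positive")
  z_meta <- sum(sqrt(n) * z) / sqrt(sum(n))
  p_meta <- 2 * pnorm(abs(z_meta), lower.tail = FALSE)
  list(z_meta = z_meta, p_meta = max(p_meta, 1e-300))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_(i) = min_{j >= i} min(1, m p_(j) / j) on the sorted p-values, mapped
#' back to the input order; tied p-values share a q.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Meta-analyze per-cohort association sweeps
#'
#' Joins per-cohort results by probe, converts each cohort's (beta, p) to a
#' signed z, combines with [stouffer()] weights sqrt(n_i), applies
#' [bh_adjust()] across all probes, and attaches a meta-level effect
#' (the n_i-weighted mean of per-cohort betas) and standard error (the
#' n_i-weighted mean of per-cohort SEs) used by the sensitivity stage.
#'
#' @param assoc_list list of per-cohort data.frames from [run_cohort()];
#'   probes present in every cohort are used.
#' @param q_threshold significance threshold on the BH-adjusted q
#'   (default 0.01, strict "<").
#' @return data.frame: probe_id, per-cohort z/n columns, z_meta, p_meta, q,
#'   significant, direction (sign of z_meta), beta_meta, se_meta.
#' @export
meta_analyze <- function(assoc_list, q_threshold = 0.01) {
  stopifnot(length(assoc_list) >= 1)
  common <- Reduce(intersect, lapply(assoc_list, function(d) d$probe_id))
  if (length(common) == 0) stop("no shared probes across cohorts")
  per <- lapply(assoc_list, function(d) {
    d <- d[match(common, d$probe_id), ]
    d$z <- z_from_assoc(d$beta, d$p)
    d
  })
  zs <- vapply(per, `[[`, numeric(length(common)), "z")
  ns <- vapply(per, `[[`, numeric(length(common)), "n")
  betas <- vapply(per, `[[`, numeric(length(common)), "beta")
  ses <- vapply(per, `[[`, numeric(length(common)), "se")
  zs <- matrix(zs, nrow = length(common)); ns <- matrix(ns, nrow = length(common))
  betas <- matrix(betas, nrow = length(common)); ses <- matrix(ses, nrow = length(common))

  w <- sqrt(ns)
  z_meta <- rowSums(w * zs) / sqrt(rowSums(ns))
  p_meta <- pmax(2 * pnorm(abs(z_meta), lower.tail = FALSE), 1e-300)
  q <- bh_adjust(p_meta)
  out <- data.frame(probe_id = common, stringsAsFactors = FALSE)
  for (i in seq_along(per)) {
    out[[paste0("z_", per[[i]]$cohort[1])]] <- zs[, i]
    out[[paste0("n_", per[[i]]$cohort[1])]] <- ns[, i]
  }
  out$z_meta <- z_meta
  out$p_meta <- p_meta
  out$q <- q
  out$significant <- q < q_threshold
  out$direction <- sign(z_meta)
  out$beta_meta <- rowSums(ns * betas) / rowSums(ns)
  out$se_meta <- rowSums(ns * ses) / rowSums(ns)
  out$n_meta <- rowSums(ns)
  out
}

#' Collapse probe-level meta results to genes
#'
#' For every gene with at least one significant probe (q strictly below
#' `q_threshold`), the representative probe is the one with the smallest
#' p_meta (ties broken by lexicographically smallest probe id). The
#' direction class is derived from the signs of all the gene's significant
#' probes: `positive` / `negative` when concordant, `inconsistent` when both
#' signs occur.
#'
#' @param meta data.frame from [meta_analyze()].
#' @param annotation data.frame with columns `probe_id`, `gene`.
#' @param q_threshold significance threshold (default 0.01).
#' @return data.frame: gene, probe_id (representative), p_meta, q,
#'   direction_class, n_probes (annotated probes measured for the gene),
#'   n_significant.
#' @export
collapse_genes <- function(meta, annotation, q_threshold = 0.01) {
  m <- merge(meta, annotation[, c("probe_id", "gene")], by = "probe_id")
  n_unannotated <- nrow(meta) - nrow(m)
  sig <- m[m$q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    out <- data.frame(gene = character(0), probe_id = character(0),
                      p_meta = numeric(0), q = numeric(0),
                      direction_class = character(0),
                      n_probes = integer(0), n_significant = integer(0))
    attr(out, "n_unannotated") <- n_unannotated
    return(out)
  }
  probes_per_gene <- table(m$gene)
  sig <- sig[order(sig$gene, sig$p_meta, sig$probe_id), ]
  rep_rows <- sig[!duplicated(sig$gene), ]
  dir_class <- vapply(split(sig$direction, sig$gene), function(s) {
    s <- unique(s[s != 0])
    if (length(s) > 1) "inconsistent" else if (s[1] > 0) "positive" else "negative"
  }, character(1))
  n_sig <- vapply(split(sig$direction, sig$gene), length, integer(1))
  out <- data.frame(
    gene = rep_rows$gene,
    probe_id = rep_rows$probe_id,
    p_meta = rep_rows$p_meta,
    q = rep_rows$q,
    direction_class = unname(dir_class[rep_rows$gene]),
    n_probes = as.integer(probes_per_gene[rep_rows$gene]),
    n_significant = unname(n_sig[rep_rows$gene]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- n_unannotated
  out
}

# round half up to `digits` decimals (matches the presentation convention;
# base round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Direction-class summary of gene-level results
#'
#' Counts genes per direction class and expresses them as percentages of
#' the total, rounded half-up to one decimal.
#'
#' @param genes data.frame from [collapse_genes()], or a named integer
#'   vector/list of counts with names among positive/negative/inconsistent.
#' @return data.frame: class, count, percent.
#' @export
direction_summary <- function(genes) {
  classes <- c("positive", "negative", "inconsistent")
  if (is.data.frame(genes)) {
    if (nrow(genes) == 0) stop("no genes to summarize")
    counts <- vapply(classes, function(cl)
      sum(genes$direction_class == cl), integer(1))
  } else {
    counts <- setNames(integer(3), classes)
    counts[names(genes)] <- as.integer(unlist(genes))
    if (sum(counts) == 0) stop("no genes to summarize")
  }
  total <- sum(counts)
  data.frame(class = classes,
             count = as.integer(counts),
             percent = round_half_up(100 * counts / total, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
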