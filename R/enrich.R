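#' Restrict a gene-set collection to a reference universe
#'
#' The reference universe is the set of genes represented on the array;
#' set members outside it are dropped, and sets left empty are removed
#' (their count is attached as attribute `"n_dropped"`).
#'
#' @param sets named list of character vectors (gene symbols).
#' @param universe character vector of genes represented on the array.
#' @return object of class `gene_set_collection`: list with `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  restricted <- lapply(sets, function(s) intersect(unique(s), universe))
  empty <- vapply(restricted, length, integer(1)) == 0
  out <- structure(list(sets = restricted[!empty], universe = universe),
                   class = "gene_set_collection")
  attr(out, "n_dropped") <- sum(empty)
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Right-tailed Fisher's exact (hypergeometric) over-representation p-value
#'
#' P(X >= x) where X ~ Hypergeometric(N, K, n): the probability that a
#' uniformly drawn input list of n genes from a universe of N overlaps a set
#' of K genes in at least x members. Evaluated through the hypergeometric
#' upper tail, which base R computes stably in log space.
#'
#' @param x overlap count.
#' @param K set size.
#' @param n input-list size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
fisher_right_tail <- function(x, K, n, N) {
  if (any(x < 0) || any(K > N) || any(n > N) || any(x > pmin(K, n)))
    stop("invalid hypergeometric bounds: need 0 <= x <= min(K, n) <= N")
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 1e-300), 1)
}

# overlap counts of every set with one gene list, given an indicator matrix
set_overlaps <- function(collection, genes) {
  vapply(collection$sets, function(s) length(intersect(s, genes)), integer(1))
}

#' Direction-stratified over-representation analysis
#'
#' For each stratum (`all`, `positive`, `negative`) the input gene list is
#' intersected with the collection's universe and each set is tested by
#' [fisher_right_tail()]; BH adjustment is applied across sets within each
#' stratum. The enrichment ratio is x / K (input genes mapping to the set
#' over the set's size). An empty stratum yields not-applicable records
#' (NA p and q, x = 0), and an input list equal to the whole universe is
#' flagged degenerate (the overlap is forced, p = 1).
#'
#' @param genes_by_stratum named list of character vectors, e.g.
#'   `list(all = ..., positive = ..., negative = ...)`.
#' @param collection a [gene_set_collection()].
#' @param alpha per-stratum BH significance level (default 0.05).
#' @return data.frame: set, stratum, N, K, n, x, ratio, p, q, significant,
#'   not_applicable, degenerate.
#' @export
run_ora <- function(genes_by_stratum, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  N <- length(collection$universe)
  if (N == 0) stop("empty universe")
  K <- vapply(collection$sets, length, integer(1))
  res <- lapply(names(genes_by_stratum), function(st) {
    genes <- intersect(unique(genes_by_stratum[[st]]), collection$universe)
    n <- length(genes)
    if (n == 0) {
      return(data.frame(set = names(collection$sets), stratum = st, N = N,
                        K = K, n = 0L, x = 0L, ratio = 0,
                        p = NA_real_, q = NA_real_, significant = FALSE,
                        not_applicable = TRUE, degenerate = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE))
    }
    x <- set_overlaps(collection, genes)
    p <- fisher_right_tail(x, K, n, N)
    data.frame(set = names(collection$sets), stratum = st, N = N, K = K,
               n = n, x = x, ratio = x / K, p = p, q = bh_adjust(p),
               significant = bh_adjust(p) < alpha,
               not_applicable = FALSE, degenerate = n == N,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Permutation-based empirical FDR for over-representation results
#'
#' Robustness check on the Fisher over-representation p-values: B uniform
#' random gene lists of the observed input size are drawn from the
#' universe, each set's Fisher p is recomputed for every draw, and each
#' set's empirical FDR is the add-one-corrected fraction of permutations
#' with a p-value at most the observed one,
#' (1 + #\{b : p_b <= p_obs\}) / (B + 1). The resampling scheme is a
#' reconstruction (random gene-list resampling of matched size) and is
#' deliberately pluggable.
#'
#' @param observed data.frame from [run_ora()] for a single stratum (rows
#'   with `not_applicable` are passed through with NA FDR).
#' @param collection the [gene_set_collection()] used.
#' @param n_input input-list size to resample (defaults to the observed n).
#' @param B number of permutations (at least 100; default 5000).
#' @param seed integer RNG seed.
#' @return `observed` with an added `perm_fdr` column.
#' @export
permutation_fdr <- function(observed, collection, n_input = NULL, B = 5000,
                            seed = 1L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (B < 100) stop("B must be at least 100")
  N <- length(collection$universe)
  if (is.null(n_input)) n_input <- max(observed$n)
  if (n_input > N) stop("n_input exceeds universe size")
  set.seed(seed)
  K <- vapply(collection$sets, length, integer(1))
  # indicator matrix: sets x universe
  M <- matrix(vapply(collection$sets,
                     function(s) collection$universe %in% s,
                     logical(N)),
              nrow = N)                      # N x n_sets
  perm_p <- matrix(NA_real_, nrow = length(collection$sets), ncol = B)
  for (b in seq_len(B)) {
    idx <- sample.int(N, n_input)
    x_b <- colSums(M[idx, , drop = FALSE])
    perm_p[, b] <- fisher_right_tail(x_b, K, n_input, N)
  }
  ord <- match(observed$set, names(collection$sets))
  fdr <- vapply(seq_len(nrow(observed)), function(i) {
    if (isTRUE(observed$not_applicable[i]) || is.na(observed$p[i]))
      return(NA_real_)
    (1 + sum(perm_p[ord[i], ] <= observed$p[i])) / (B + 1)
  }, numeric(1))
  observed$perm_fdr <- fdr
  observed
}

#' Direction composition of one gene set
#'
#' Fractions of a set's array-represented genes that are significantly
#' positively associated, significantly negatively associated, or neither
#' (not significant; genes with inconsistent probe directions are counted
#' here so the three fractions partition the set).
#'
#' @param set_name name of a set in `collection`.
#' @param collection a [gene_set_collection()].
#' @param gene_results data.frame from [collapse_genes()].
#' @return named numeric vector `c(positive=, negative=, not_significant=)`
#'   summing to 1.
#' @export
direction_composition <- function(set_name, collection, gene_results) {
  if (!set_name %in% names(collection$sets)) stop("unknown set: ", set_name)
  members <- collection$sets[[set_name]]
  cls <- gene_results$direction_class[match(members, gene_results$gene)]
  n <- length(members)
  pos <- sum(cls == "positive", na.rm = TRUE)
  neg <- sum(cls == "negative", na.rm = TRUE)
  c(positive = pos / n, negative = neg / n,
    not_significant = (n - pos - neg) / n)
}

#' Table of direction-stratified enrichment results
#'
#' Combines the three strata of [run_ora()] (plus the permutation FDR of
#' the `all` stratum) into one row per set, mirroring the usual pathway
#' report layout: per-stratum FDRs, per-stratum associated-gene counts,
#' enrichment ratio, permutation FDR.
#'
#' @param ora data.frame from [run_ora()] run with strata all/positive/
#'   negative; if a `perm_fdr` column is present on the `all` stratum it is
#'   carried over.
#' @return wide data.frame, one row per set, sorted by the all-stratum q.
#' @export
enrichment_table <- function(ora) {
  get <- function(st) ora[ora$stratum == st, , drop = FALSE]
  a <- get("all"); p <- get("positive"); n <- get("negative")
  stopifnot(nrow(a) > 0)
  p <- p[match(a$set, p$set), ]; n <- n[match(a$set, n$set), ]
  out <- data.frame(
    set = a$set, set_size = a$K, ratio = a$ratio,
    n_all = a$x, n_positive = p$x, n_negative = n$x,
    fdr_all = a$q, fdr_positive = p$q, fdr_negative = n$q,
    perm_fdr = if ("perm_fdr" %in% names(a)) a$perm_fdr else NA_real_,
    stringsAsFactors = FALSE)
  out[order(out$fdr_all, out$set), ]
}
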