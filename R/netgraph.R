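#' Jaccard similarity of two sets
#'
#' |A intersect B| / |A union B|.
#'
#' @param A,B character (or atomic) vectors treated as sets.
#' @return similarity in [0, 1]; errors when both sets are empty.
#' @export
jaccard <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) stop("both sets are empty")
  length(intersect(A, B)) / u
}

#' Pathway-overlap graph with a percentile Jaccard threshold
#'
#' Nodes are gene sets sized by their count of associated transcripts;
#' all pairwise Jaccard coefficients of the membership sets are computed
#' (including zero-overlap pairs by default), and an edge is drawn between
#' two sets when they share at least one transcript and their Jaccard
#' coefficient reaches the percentile threshold. The threshold is the
#' nearest-rank upper-tail percentile: the ceil((1 - percentile/100) * m)-th
#' largest of the m pairwise coefficients, so at the default percentile 90
#' at most ceil(0.10 m) pairs (ties aside) can form edges.
#'
#' @param memberships named list mapping each set to its associated
#'   transcripts/genes (character vectors); at least 2 sets.
#' @param percentile percentile of the pairwise Jaccard distribution used
#'   as edge threshold (default 90; 0 admits every sharing pair).
#' @param include_zero_pairs logical; if FALSE the threshold is computed
#'   over pairs with nonzero overlap only (default TRUE).
#' @param node_labels optional named character vector of signature labels
#'   attached to nodes.
#' @return object of class `overlap_graph`: list with `graph` (an igraph),
#'   `nodes` (set, size, label), `edges` (source, target, jaccard,
#'   shared_count) and `threshold`.
#' @export
build_graph <- function(memberships, percentile = 90,
                        include_zero_pairs = TRUE, node_labels = NULL) {
  if (length(memberships) < 2) stop("need at least 2 sets")
  if (percentile < 0 || percentile > 100) stop("percentile must lie in [0, 100]")
  sets <- lapply(memberships, unique)
  nm <- names(sets)
  pairs <- utils::combn(length(sets), 2)
  shared <- apply(pairs, 2, function(ij)
    length(intersect(sets[[ij[1]]], sets[[ij[2]]])))
  unions <- apply(pairs, 2, function(ij)
    length(union(sets[[ij[1]]], sets[[ij[2]]])))
  if (any(unions == 0)) stop("a pair of empty sets has no Jaccard coefficient")
  J <- shared / unions

  pool <- if (include_zero_pairs) J else J[shared > 0]
  if (length(pool) == 0 || percentile == 0) {
    threshold <- 0
  } else {
    k <- max(1L, ceiling((1 - percentile / 100) * length(pool)))
    vals <- sort(pool, decreasing = TRUE)
    threshold <- vals[k]
    # tie policy: if ties at the threshold would admit more than the
    # nominal share of pairs, move up to the next distinct coefficient
    # (kept as-is when no higher value exists, e.g. duplicated sets)
    if (sum(pool >= threshold) > k && any(vals > threshold))
      threshold <- min(vals[vals > threshold])
  }
  keep <- shared >= 1 & J >= threshold

  edges <- data.frame(
    source = nm[pairs[1, keep]], target = nm[pairs[2, keep]],
    jaccard = J[keep], shared_count = shared[keep],
    stringsAsFactors = FALSE)
  nodes <- data.frame(
    set = nm, size = vapply(sets, length, integer(1)),
    label = if (is.null(node_labels)) NA_character_
            else unname(node_labels[nm]),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges,
                 threshold = threshold),
            class = "overlap_graph")
}

#' @export
print.overlap_graph <- function(x, ...) {
  cat(sprintf("<overlap_graph> %d nodes, %d edges (Jaccard threshold %.4g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write an overlap graph to GraphML plus TSV node/edge tables
#'
#' @param og an [build_graph()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "overlap_graph").
#' @return invisibly, the paths written.
#' @export
write_overlap_graph <- function(og, dir, prefix = "overlap_graph") {
  stopifnot(inherits(og, "overlap_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c(".graphml", "_edges.tsv",
                                           "_nodes.tsv")))
  igraph::write_graph(og$graph, paths[1], format = "graphml")
  write_tsv(og$edges, paths[2])
  write_tsv(og$nodes, paths[3])
  invisible(paths)
}
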