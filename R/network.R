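#' Scan-by-scan Pearson correlation matrix
#'
#' Correlates every pair of scan profiles (rows of the centered matrix)
#' across parameters. Scans with a constant profile have undefined
#' correlations; they are excluded with a warning.
#'
#' @param mat a `morph_matrix` (normally stage `"centered"`)
#' @return symmetric numeric matrix, unit diagonal, dimnames = scan ids, with
#'   attribute `constant_scans` naming any excluded scans
#' @export
pearson_matrix <- function(mat) {
  stopifnot(inherits(mat, "morph_matrix"))
  v <- mat$values
  if (ncol(v) < 3) stop("need at least 3 parameters per scan profile")
  sds <- apply(v, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning("excluding scan(s) with constant profile: ",
            paste(rownames(v)[constant], collapse = ", "))
    v <- v[!constant, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  diag(r) <- 1
  attr(r, "constant_scans") <- rownames(mat$values)[constant]
  r
}

#' Threshold a correlation matrix into a weighted network
#'
#' Retains scan pairs whose correlation is strictly greater than `threshold`;
#' edge weights are the raw Pearson r. Scans left with no retained edge are
#' reported in `excluded_nodes` and are absent from the graph.
#'
#' @param corr symmetric correlation matrix from [pearson_matrix()]
#' @param threshold r value in `[0, 1)`; default 0.7
#' @return a `corr_network`: list with `graph` (igraph, weighted, undirected),
#'   `edges` (data.frame scan_a/scan_b/r), `nodes`, `excluded_nodes`,
#'   `threshold`
#' @export
threshold_graph <- function(corr, threshold = 0.7) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  ids <- rownames(corr)
  ut <- upper.tri(corr)
  keep <- ut & corr > threshold
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(scan_a = ids[idx[, 1]], scan_b = ids[idx[, 2]],
                      r = corr[keep], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$scan_a, edges$scan_b)))
  excluded <- setdiff(ids, nodes)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (nrow(edges) > 0) igraph::E(g)$weight <- edges$r
  structure(list(graph = g, edges = edges, nodes = nodes,
                 excluded_nodes = sort(excluded), threshold = threshold),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf(
    "<corr_network> r > %.3g: %d nodes, %d edges, %d excluded scans\n",
    x$threshold, length(x$nodes), nrow(x$edges), length(x$excluded_nodes)))
  invisible(x)
}

#' Node/edge counts across candidate thresholds
#'
#' Diagnostic for threshold selection: for each candidate r the number of
#' non-isolated scans and retained edges. Both counts are non-increasing in
#' the threshold.
#'
#' @param corr correlation matrix
#' @param thresholds ascending numeric vector of candidate r values
#' @return data.frame with `threshold`, `n_nodes`, `n_edges`
#' @export
threshold_scan <- function(corr, thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  ids <- rownames(corr)
  ut <- corr[upper.tri(corr)]
  pair_idx <- which(upper.tri(corr), arr.ind = TRUE)
  rows <- lapply(thresholds, function(t) {
    keep <- ut > t
    n_edges <- sum(keep)
    n_nodes <- length(unique(c(pair_idx[keep, 1], pair_idx[keep, 2])))
    data.frame(threshold = t, n_nodes = n_nodes, n_edges = n_edges)
  })
  do.call(rbind, rows)
}

#' Suggest a correlation threshold from a threshold scan
#'
#' Picks the largest threshold whose node count is still within
#' `node_fraction` of the maximum node count over the scanned range — i.e.
#' keeps close to the maximum number of nodes with a minimum number of edges.
#' The choice is advisory; the user makes the final call.
#'
#' @param scan_table output of [threshold_scan()]
#' @param node_fraction minimum retained fraction of the maximal node count
#' @return a single threshold value
#' @export
suggest_threshold <- function(scan_table, node_fraction = 0.95) {
  ok <- scan_table$n_nodes >= node_fraction * max(scan_table$n_nodes)
  max(scan_table$threshold[ok])
}

#' Write a network edge list as TSV (scan_a, scan_b, r)
#' @param net a `corr_network`
#' @param path output file
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV into a `corr_network`
#'
#' @param path TSV with columns scan_a, scan_b, r
#' @param threshold recorded threshold provenance (not re-applied)
#' @export
read_edge_list <- function(path, threshold = NA_real_) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$scan_a, edges$scan_b)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  if (nrow(edges) > 0) igraph::E(g)$weight <- edges$r
  structure(list(graph = g, edges = edges, nodes = nodes,
                 excluded_nodes = character(0), threshold = threshold),
            class = "corr_network")
}

#' Export a network as GraphML
#' @param net a `corr_network`
#' @param path output .graphml file
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
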