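#' Markov clustering parameters
#'
#' @param inflation granularity parameter (entry-wise power), > 1; higher
#'   values give more, smaller clusters. Default 2.2.
#' @param expansion matrix-power exponent per iteration, integer >= 2.
#' @param prune_threshold entries below this are zeroed after inflation
#'   (each column's maximum is always kept so columns never empty).
#' @param max_iterations iteration cap.
#' @param convergence_tol max-norm difference between successive matrices
#'   below which iteration stops.
#' @param min_cluster_size clusters smaller than this are moved to the
#'   unclustered set. Default 3.
#' @param self_loop self-loop weight rule: `"max_incident"` (default; each
#'   node's loop weight is its maximum incident edge weight, keeping
#'   attractors stable on weighted graphs) or `"one"` (unit loops).
#' @return an `mcl_params` list
#' @export
mcl_params <- function(inflation = 2.2, expansion = 2L,
                       prune_threshold = 1e-6, max_iterations = 200L,
                       convergence_tol = 1e-8, min_cluster_size = 3L,
                       self_loop = c("max_incident", "one")) {
  self_loop <- match.arg(self_loop)
  stopifnot(inflation > 1, expansion >= 2, prune_threshold >= 0,
            max_iterations >= 1, convergence_tol > 0, min_cluster_size >= 1)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 min_cluster_size = as.integer(min_cluster_size),
                 self_loop = self_loop),
            class = "mcl_params")
}

# Weighted adjacency with self-loops per the configured rule.
.mcl_adjacency <- function(net, self_loop) {
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph, attr = "weight",
                                             sparse = TRUE))
  diag(A) <- 0
  loops <- if (self_loop == "max_incident") apply(A, 2, max) else 1
  loops[loops <= 0] <- 1  # isolated node in an imported graph
  diag(A) <- loops
  A
}

.col_normalize <- function(M) sweep(M, 2, colSums(M), `/`)

# Interpretation of a converged MCL matrix (column-stochastic, columns are
# source nodes, rows are destinations). Documented conventions, shared with
# the naive oracle's independent re-implementation:
#   eps = 1e-4; attractors are nodes with M[i,i] > eps; attractors belong to
#   one system when linked directly (M[i,k] > eps either way); node j is
#   attracted to system S when M[i,j] > eps for some attractor i in S. A node
#   attracted to several systems (an MCL overlap) goes to the larger system
#   (counting its unambiguous members), ties to the system whose smallest
#   member id sorts first.
.mcl_interpret <- function(M, ids, eps = 1e-4) {
  n <- length(ids)
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate fallback
  support <- lapply(seq_len(n), function(j) {
    s <- intersect(which(M[, j] > eps), attractors)
    if (length(s) == 0) s <- attractors[which.max(M[attractors, j])]
    s
  })
  # union attractors linked directly
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (i in attractors) for (k in attractors)
    if (i < k && (M[i, k] > eps || M[k, i] > eps)) union_(i, k)
  sys_of_attr <- vapply(attractors, find, integer(1))
  systems <- split(attractors, sys_of_attr)
  sys_ids <- names(systems)
  # candidate systems per node
  cand <- lapply(support, function(s)
    unique(vapply(s, function(a) as.character(find(a)), character(1))))
  n_cand <- lengths(cand)
  base_size <- table(factor(unlist(cand[n_cand == 1]), levels = sys_ids))
  assign_sys <- character(n)
  assign_sys[n_cand == 1] <- unlist(cand[n_cand == 1])
  for (j in which(n_cand > 1)) {
    cs <- cand[[j]]
    sizes <- as.integer(base_size[cs])
    best <- cs[sizes == max(sizes)]
    if (length(best) > 1) {
      firsts <- vapply(best, function(s)
        min(ids[sort(unique(c(systems[[s]],
                              which(assign_sys == s & n_cand == 1))))]),
        character(1))
      best <- best[order(firsts)][1]
    }
    assign_sys[j] <- best[1]
  }
  unname(split(ids, assign_sys))
}

# order clusters by descending size, ties by smallest member id
.order_clusters <- function(clusters) {
  clusters <- lapply(clusters, sort)
  if (length(clusters) == 0) return(clusters)
  sizes <- lengths(clusters)
  firsts <- vapply(clusters, `[`, character(1), 1)
  clusters[order(-sizes, firsts)]
}

.make_partition <- function(clusters, excluded, min_cluster_size,
                            converged = TRUE, iterations = NA_integer_) {
  clusters <- .order_clusters(clusters)
  small <- lengths(clusters) < min_cluster_size
  unclustered <- sort(unique(c(unlist(clusters[small]), excluded)))
  structure(list(clusters = clusters[!small], unclustered = unclustered,
                 converged = converged, iterations = iterations),
            class = "cluster_partition")
}

#' Markov clustering of a correlation network
#'
#' Canonical MCL on the weighted adjacency matrix: add self-loops, normalize
#' columns to a stochastic matrix, then iterate expansion (matrix power),
#' inflation (entry-wise power with column renormalization) and pruning
#' until successive matrices agree to `convergence_tol` in max-norm. Clusters
#' are read off the attractor structure of the converged matrix; clusters
#' smaller than `min_cluster_size`, plus scans excluded from the graph, form
#' the unclustered set.
#'
#' @param net a `corr_network` from [threshold_graph()] (its
#'   `excluded_nodes` are carried into the unclustered set)
#' @param params an [mcl_params()] object
#' @return a `cluster_partition`: list with `clusters` (list of scan-id
#'   vectors, descending size, ties by smallest member id), `unclustered`,
#'   `converged`, `iterations`
#' @export
mcl_cluster <- function(net, params = mcl_params()) {
  stopifnot(inherits(net, "corr_network"), inherits(params, "mcl_params"))
  ids <- net$nodes
  if (length(ids) == 0)
    return(.make_partition(list(), net$excluded_nodes,
                           params$min_cluster_size, TRUE, 0L))
  A <- .mcl_adjacency(net, params$self_loop)
  ids <- colnames(A)
  M <- .col_normalize(A)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    Mx <- M
    for (e in seq_len(params$expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^params$inflation
    Mx <- .col_normalize(Mx)
    if (params$prune_threshold > 0) {  # prune after inflation only
      colmax <- apply(Mx, 2, max)
      drop <- Mx < params$prune_threshold &
        Mx < rep(colmax, each = nrow(Mx))
      Mx[drop] <- 0
      Mx <- .col_normalize(Mx)
    }
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < params$convergence_tol) { converged <- TRUE; break }
    if (iter >= params$max_iterations) break
  }
  if (!converged)
    warning(sprintf("MCL did not converge within %d iterations; clustering final matrix",
                    params$max_iterations))
  clusters <- .mcl_interpret(M, ids)
  .make_partition(clusters, net$excluded_nodes, params$min_cluster_size,
                  converged, iter)
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("<cluster_partition> %d clusters (%d scans), %d unclustered%s\n",
              length(x$clusters), sum(lengths(x$clusters)),
              length(x$unclustered),
              if (isTRUE(x$converged)) "" else " [non-converged]"))
  invisible(x)
}

#' Export a partition as TSV (scan_id, cluster)
#'
#' Cluster labels are `cluster_01`, `cluster_02`, ... in partition order;
#' unclustered scans carry the sentinel label `"unclustered"`.
#' @param partition a `cluster_partition`
#' @param path output file
#' @export
write_partition <- function(partition, path) {
  df <- partition_to_frame(partition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition as a two-column data.frame (scan_id, cluster)
#' @param partition a `cluster_partition`
#' @export
partition_to_frame <- function(partition) {
  labs <- sprintf("cluster_%02d", seq_along(partition$clusters))
  df <- data.frame(
    scan_id = c(unlist(partition$clusters), partition$unclustered),
    cluster = c(rep(labs, lengths(partition$clusters)),
                rep("unclustered", length(partition$unclustered))),
    stringsAsFactors = FALSE)
  df[order(df$scan_id), , drop = FALSE]
}

#' Read a partition TSV written by [write_partition()]
#' @param path TSV with scan_id, cluster columns
#' @param min_cluster_size retained for provenance only
#' @export
read_partition <- function(path, min_cluster_size = 3L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  uncl <- df$scan_id[df$cluster == "unclustered"]
  rest <- df[df$cluster != "unclustered", , drop = FALSE]
  clusters <- unname(split(rest$scan_id, rest$cluster))
  .make_partition(clusters, uncl, 1L)
}
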