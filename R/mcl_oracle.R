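#' Naive dense Markov-clustering oracle
#'
#' A literal, unoptimized re-implementation of the MCL iteration used by
#' [mcl_cluster()] — explicit loops, dense matrices, and no pruning — kept as
#' an independent code path so the two can be compared in tests. Follows the
#' same documented conventions (self-loop rule, expansion then inflation with
#' column renormalization, max-norm convergence, attractor interpretation)
#' but shares no code with the optimized implementation.
#'
#' @param net a `corr_network` with at most 50 nodes
#' @param params an [mcl_params()] object (its `prune_threshold` is ignored)
#' @return a `cluster_partition`
#' @export
naive_mcl_oracle <- function(net, params = mcl_params()) {
  ids <- net$nodes
  n <- length(ids)
  if (n > 50) stop("naive_mcl_oracle is restricted to graphs of <= 50 nodes")
  if (n == 0)
    return(.make_partition(list(), net$excluded_nodes,
                           params$min_cluster_size, TRUE, 0L))
  ids <- sort(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges) > 0)
    for (e in seq_len(nrow(net$edges))) {
      i <- match(net$edges$scan_a[e], ids)
      j <- match(net$edges$scan_b[e], ids)
      A[i, j] <- net$edges$r[e]
      A[j, i] <- net$edges$r[e]
    }
  for (j in seq_len(n)) {
    loop <- if (params$self_loop == "max_incident") max(A[, j]) else 1
    if (loop <= 0) loop <- 1
    A[j, j] <- loop
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])

  mat_mult <- function(X, Y) {
    Z <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + X[i, k] * Y[k, j]
      Z[i, j] <- acc
    }
    Z
  }

  iter <- 0L
  converged <- FALSE
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    Mx <- M
    for (e in seq_len(params$expansion - 1L)) Mx <- mat_mult(Mx, M)
    for (i in seq_len(n)) for (j in seq_len(n))
      Mx[i, j] <- Mx[i, j]^params$inflation
    for (j in seq_len(n)) Mx[, j] <- Mx[, j] / sum(Mx[, j])
    delta <- 0
    for (i in seq_len(n)) for (j in seq_len(n))
      delta <- max(delta, abs(Mx[i, j] - M[i, j]))
    M <- Mx
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }

  eps <- 1e-4
  attractors <- integer(0)
  for (i in seq_len(n)) if (M[i, i] > eps) attractors <- c(attractors, i)
  if (length(attractors) == 0) attractors <- seq_len(n)
  # support sets
  support <- vector("list", n)
  for (j in seq_len(n)) {
    s <- integer(0)
    for (i in attractors) if (M[i, j] > eps) s <- c(s, i)
    if (length(s) == 0) {
      best <- attractors[1]
      for (i in attractors) if (M[i, j] > M[best, j]) best <- i
      s <- best
    }
    support[[j]] <- s
  }
  # systems: attractors linked directly share a system label
  sys <- seq_len(n)
  for (i in attractors) for (k in attractors)
    if (M[i, k] > eps || M[k, i] > eps) {
      tgt <- min(sys[i], sys[k])
      sys[sys == sys[i]] <- tgt
      sys[sys == sys[k]] <- tgt
    }
  cand <- lapply(support, function(s) unique(sys[s]))
  # unambiguous members first, then resolve overlaps by size / smallest id
  size <- rep(0L, n)
  members <- vector("list", n)  # indexed by system label
  for (j in seq_len(n)) if (length(cand[[j]]) == 1) {
    s <- cand[[j]]
    size[s] <- size[s] + 1L
    members[[s]] <- c(members[[s]], j)
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    cs <- cand[[j]]
    if (length(cs) == 1) { assignment[j] <- cs; next }
    best <- cs[1]
    for (s in cs[-1]) {
      if (size[s] > size[best]) best <- s
      else if (size[s] == size[best] &&
               min(ids[members[[s]]]) < min(ids[members[[best]]])) best <- s
    }
    assignment[j] <- best
  }
  clusters <- unname(split(ids, assignment))
  .make_partition(clusters, net$excluded_nodes, params$min_cluster_size,
                  converged, iter)
}
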