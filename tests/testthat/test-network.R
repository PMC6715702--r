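make_matrix <- function(values, ids = sprintf("s%02d", seq_len(nrow(values)))) {
  structure(list(values = matrix(values, nrow = nrow(values),
                                 dimnames = list(ids, sprintf("p%d", seq_len(ncol(values))))),
                 stage = "centered", dropped_scans = character(0),
                 registry = NULL),
            class = "morph_matrix")
}

test_that("pearson_matrix matches hand-computed correlations", {
  m <- make_matrix(rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1), c(1, 2, 4)))
  r <- pearson_matrix(m)
  expect_equal(r["s01", "s02"], 1.0)
  expect_equal(r["s01", "s03"], -1.0)
  # closed-form oracle for profiles (1,2,4) vs (1,3,5) computed from sums
  x <- c(1, 2, 4); y <- c(1, 3, 5)
  oracle <- (sum(x * y) - 3 * mean(x) * mean(y)) /
    sqrt((sum(x^2) - 3 * mean(x)^2) * (sum(y^2) - 3 * mean(y)^2))
  m2 <- make_matrix(rbind(x, y), ids = c("a", "b"))
  expect_equal(pearson_matrix(m2)["a", "b"], oracle)
  expect_true(isSymmetric(unname(r)))
  expect_equal(unname(diag(r)), rep(1, 4))
})

test_that("constant profiles are excluded with a warning", {
  m <- make_matrix(rbind(c(1, 2, 3), c(5, 5, 5), c(3, 1, 2)))
  expect_warning(r <- pearson_matrix(m), "s02")
  expect_equal(rownames(r), c("s01", "s03"))
  expect_equal(attr(r, "constant_scans"), "s02")
})

test_that("threshold_graph keeps strict exceedances and reports isolates", {
  # 3 scans with pairwise r {0.9, 0.8, 0.1}: 2 edges, 3 nodes, 0 excluded
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.8
  r[2, 3] <- r[3, 2] <- 0.1
  dimnames(r) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- threshold_graph(r, 0.7)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("a", "b", "c"))
  expect_length(net$excluded_nodes, 0)
  # strict inequality: r exactly at the threshold is not an edge
  net2 <- threshold_graph(r, 0.8)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(net2$excluded_nodes, "c")
  # all r below threshold: empty graph, all scans excluded
  net3 <- threshold_graph(r, 0.95)
  expect_equal(nrow(net3$edges), 0)
  expect_setequal(net3$excluded_nodes, c("a", "b", "c"))
  # invariant: nodes + excluded = scans
  for (n in list(net, net2, net3))
    expect_equal(length(n$nodes) + length(n$excluded_nodes), 3)
  expect_error(threshold_graph(r, 1), "threshold")
})

test_that("threshold 0 with all-positive correlations yields the complete graph", {
  set.seed(3)
  base <- rnorm(6)
  v <- outer(runif(4, 0.9, 1.1), base) + matrix(rnorm(24, sd = 0.01), 4)
  m <- make_matrix(v)
  r <- pearson_matrix(m)
  expect_true(all(r > 0))
  net <- threshold_graph(r, 0)
  expect_equal(nrow(net$edges), choose(4, 2))
  expect_length(net$excluded_nodes, 0)
})

test_that("threshold_scan is monotone and matches brute-force enumeration", {
  set.seed(11)
  v <- matrix(rnorm(5 * 8), 5)
  r <- pearson_matrix(make_matrix(v))
  ths <- c(-0 + 0.0, 0.3, 0.5, 0.7, 0.9)
  tab <- threshold_scan(r, ths)
  # brute force over all pairs at each threshold
  ids <- rownames(r)
  for (row in seq_len(nrow(tab))) {
    t <- tab$threshold[row]
    cnt <- 0; touched <- character(0)
    for (i in 1:4) for (j in (i + 1):5)
      if (r[i, j] > t) { cnt <- cnt + 1; touched <- c(touched, ids[c(i, j)]) }
    expect_equal(tab$n_edges[row], cnt)
    expect_equal(tab$n_nodes[row], length(unique(touched)))
  }
  expect_true(all(diff(tab$n_edges) <= 0))
  expect_true(all(diff(tab$n_nodes) <= 0))
  expect_error(threshold_scan(r, c(0.9, 0.5)), "ascending")
})

test_that("property: node/edge counts are non-increasing over random sweeps", {
  set.seed(23)
  for (rep in 1:20) {
    v <- matrix(rnorm(8 * 6), 8)
    r <- pearson_matrix(make_matrix(v))
    tab <- threshold_scan(r, seq(0, 0.9, by = 0.1))
    expect_true(all(diff(tab$n_edges) <= 0))
    expect_true(all(diff(tab$n_nodes) <= 0))
  }
})

test_that("graph is invariant under scan reordering", {
  set.seed(5)
  v <- matrix(rnorm(6 * 7), 6)
  m <- make_matrix(v)
  r1 <- pearson_matrix(m)
  perm <- sample(6)
  m2 <- make_matrix(v[perm, ], ids = rownames(m$values)[perm])
  r2 <- pearson_matrix(m2)
  n1 <- threshold_graph(r1, 0.3)
  n2 <- threshold_graph(r2, 0.3)
  key <- function(net) {
    e <- net$edges
    sorted <- t(apply(e[, 1:2], 1, sort))
    k <- paste(sorted[, 1], sorted[, 2])
    e$r[order(k)]
  }
  e1 <- n1$edges; e2 <- n2$edges
  expect_setequal(paste(pmin(e1$scan_a, e1$scan_b), pmax(e1$scan_a, e1$scan_b)),
                  paste(pmin(e2$scan_a, e2$scan_b), pmax(e2$scan_a, e2$scan_b)))
  expect_equal(key(n1), key(n2))
})

test_that("suggest_threshold keeps nearly-maximal nodes with fewest edges", {
  tab <- data.frame(threshold = c(0.5, 0.6, 0.7, 0.8),
                    n_nodes = c(100, 99, 96, 70),
                    n_edges = c(4000, 2500, 1200, 300))
  expect_equal(suggest_threshold(tab, 0.95), 0.7)
  expect_equal(suggest_threshold(tab, 1.0), 0.5)
})

test_that("edge list and GraphML exports round-trip", {
  set.seed(9)
  v <- matrix(rnorm(5 * 6), 5)
  net <- threshold_graph(pearson_matrix(make_matrix(v)), 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path, threshold = 0.2)
  expect_equal(back$edges, net$edges)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
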