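test_that("disconnected cliques come out as separate clusters", {
  edges <- rbind(complete_graph_edges(c("a1", "a2", "a3")),
                 complete_graph_edges(c("b1", "b2", "b3")))
  net <- net_from_edges(edges)
  part <- mcl_cluster(net)
  expect_length(part$clusters, 2)
  expect_setequal(part$clusters[[1]], c("a1", "a2", "a3"))
  expect_setequal(part$clusters[[2]], c("b1", "b2", "b3"))
  expect_length(part$unclustered, 0)
})

test_that("a single K5 clique is one cluster; K2 falls below min size", {
  part5 <- mcl_cluster(net_from_edges(complete_graph_edges(sprintf("k%d", 1:5))))
  expect_length(part5$clusters, 1)
  expect_length(part5$clusters[[1]], 5)
  part2 <- mcl_cluster(net_from_edges(
    data.frame(scan_a = "x1", scan_b = "x2", r = 1)))
  expect_length(part2$clusters, 0)
  expect_setequal(part2$unclustered, c("x1", "x2"))
})

test_that("barbell of two K4s splits at the bridge (oracle-verified)", {
  ids_a <- sprintf("a%d", 1:4); ids_b <- sprintf("b%d", 1:4)
  edges <- rbind(complete_graph_edges(ids_a), complete_graph_edges(ids_b),
                 data.frame(scan_a = "a1", scan_b = "b1", r = 1))
  net <- net_from_edges(edges)
  part <- mcl_cluster(net)
  oracle <- naive_mcl_oracle(net)
  expect_equal(partition_signature(part), partition_signature(oracle))
  expect_length(part$clusters, 2)
  expect_setequal(part$clusters[[1]], ids_a)
  expect_setequal(part$clusters[[2]], ids_b)
})

test_that("partition property holds on random weighted graphs", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:14, 1)
    net <- net_from_edges(random_edges(n, p = runif(1, 0.2, 0.8)))
    part <- mcl_cluster(net)
    covered <- c(unlist(part$clusters), part$unclustered)
    expect_setequal(covered, c(net$nodes, net$excluded_nodes))
    expect_equal(anyDuplicated(covered), 0)
    expect_true(all(lengths(part$clusters) >= 3))
    # ordering contract: descending size, ties by smallest member id
    sizes <- lengths(part$clusters)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("graph-excluded scans are carried into the unclustered set", {
  net <- net_from_edges(complete_graph_edges(c("a", "b", "c")),
                        excluded = c("iso1", "iso2"))
  part <- mcl_cluster(net)
  expect_setequal(part$unclustered, c("iso1", "iso2"))
})

test_that("clustering is deterministic and permutation-equivariant", {
  set.seed(55)
  edges <- planted_edges(5, 0.9, 0.15)
  net <- net_from_edges(edges)
  p1 <- mcl_cluster(net)
  p2 <- mcl_cluster(net)
  expect_identical(partition_signature(p1), partition_signature(p2))
  # relabel nodes with a random permutation: partition permutes identically
  ids <- sort(unique(c(edges$scan_a, edges$scan_b)))
  relabel <- setNames(sprintf("z%02d", sample(length(ids))), ids)
  edges2 <- data.frame(scan_a = unname(relabel[edges$scan_a]),
                       scan_b = unname(relabel[edges$scan_b]),
                       r = edges$r, stringsAsFactors = FALSE)
  p3 <- mcl_cluster(net_from_edges(edges2))
  mapped <- lapply(p1$clusters, function(cl) sort(unname(relabel[cl])))
  sig <- function(cls) sort(vapply(cls, paste, "", collapse = ","))
  expect_equal(sig(lapply(p3$clusters, sort)), sig(mapped))
})

test_that("higher inflation yields at least as many clusters on average", {
  set.seed(77)
  counts <- replicate(15, {
    net <- net_from_edges(planted_edges(5, 0.85, 0.25))
    c(lo = length(mcl_cluster(net, mcl_params(inflation = 1.5))$clusters),
      hi = length(mcl_cluster(net, mcl_params(inflation = 3.0))$clusters))
  })
  expect_gte(mean(counts["hi", ]), mean(counts["lo", ]))
})

test_that("empty and degenerate graphs are handled", {
  empty <- net_from_edges(data.frame(scan_a = character(0),
                                     scan_b = character(0), r = numeric(0)))
  part <- mcl_cluster(empty)
  expect_length(part$clusters, 0)
  expect_length(part$unclustered, 0)
  oracle <- naive_mcl_oracle(empty)
  expect_length(oracle$clusters, 0)
  # single node with a self-loop only: one singleton, unclustered at min size 3
  one <- net_from_edges(data.frame(scan_a = "a", scan_b = "a", r = 1))
  p1 <- naive_mcl_oracle(one)
  expect_length(p1$clusters, 0)
  expect_equal(p1$unclustered, "a")
})

test_that("non-convergence warns and still returns a flagged partition", {
  net <- net_from_edges(planted_edges(4, 0.9, 0.2))
  expect_warning(part <- mcl_cluster(net, mcl_params(max_iterations = 1)),
                 "converge")
  expect_false(part$converged)
  covered <- c(unlist(part$clusters), part$unclustered)
  expect_setequal(covered, net$nodes)
})

test_that("oracle equivalence on mixed random and planted graphs", {
  # the full >= 100-graph sweep is the acceptance criterion; this is the
  # fast regression version
  set.seed(202)
  for (rep in 1:20) {
    edges <- if (rep %% 2 == 0) random_edges(sample(4:12, 1), runif(1, 0.3, 0.8))
             else planted_edges(sample(3:6, 1), 0.9, 0.2)
    net <- net_from_edges(edges)
    expect_identical(partition_signature(mcl_cluster(net)),
                     partition_signature(naive_mcl_oracle(net)),
                     info = sprintf("rep %d", rep))
  }
})

test_that("unit self-loop option changes the matrix but still partitions", {
  net <- net_from_edges(planted_edges(4, 0.9, 0.1))
  part <- mcl_cluster(net, mcl_params(self_loop = "one"))
  covered <- c(unlist(part$clusters), part$unclustered)
  expect_setequal(covered, net$nodes)
})

test_that("partition TSV round-trips with the unclustered sentinel", {
  edges <- rbind(complete_graph_edges(c("a1", "a2", "a3", "a4")))
  net <- net_from_edges(edges, excluded = "iso")
  part <- mcl_cluster(net)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(df$cluster[df$scan_id == "iso"], "unclustered")
  back <- read_partition(path)
  expect_equal(partition_signature(back)$clusters,
               partition_signature(part)$clusters)
})
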