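test_that("hypergeom_tail matches the combinatorial oracle", {
  # worked value: all 5 of a 5-scan cluster carry a descriptor held by
  # exactly 5 of 20 scans -> 1/C(20,5)
  expect_equal(hypergeom_tail(5, 5, 5, 20), 1 / 15504)
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1.0)
  expect_equal(hypergeom_tail(7, 7, 7, 7), 1.0)
  set.seed(31)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(k, n, K, N), hyper_tail_oracle(k, n, K, N),
                 tolerance = 1e-12,
                 info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
  }
  expect_error(hypergeom_tail(6, 5, 5, 20))
})

make_annotations <- function(n, labels) {
  data.frame(scan_id = sprintf("s%02d", seq_len(n)), grp = labels,
             stringsAsFactors = FALSE)
}

test_that("enrich reproduces the direct hypergeometric computation", {
  # 20 scans; descriptor A on s01..s05; cluster = exactly those five
  ann <- make_annotations(20, c(rep("A", 5), rep("B", 15)))
  groups <- list(c1 = sprintf("s%02d", 1:5))
  tab <- enrich(groups, ann, min_observed = 3)
  rowA <- tab[tab$descriptor == "A", ]
  expect_equal(rowA$p_value, 1 / 15504)
  expect_equal(rowA$observed, 5)
  expect_equal(rowA$expected, 5 * 5 / 20)
  expect_true(rowA$reported)
  # group = whole population: p = 1, never significant
  tab_all <- enrich(list(all = ann$scan_id), ann)
  expect_true(all(tab_all$p_value == 1))
  # observed below min_observed -> row present but reported = FALSE
  groups2 <- list(c2 = c("s01", "s02", "s06", "s07"))
  tab2 <- enrich(groups2, ann)
  rowA2 <- tab2[tab2$descriptor == "A", ]
  expect_equal(rowA2$observed, 2)
  expect_false(rowA2$reported)
  # invariants: 0 <= k <= min(n, K); expected > 0 when K > 0; adj >= raw
  expect_true(all(tab$observed <= pmin(tab$n, tab$K)))
  expect_true(all(tab$expected > 0 | tab$K == 0))
  expect_true(all(tab$adjusted_p >= tab$p_value - 1e-15))
})

test_that("enrichment p-values equal the enumeration oracle across random cases", {
  set.seed(41)
  for (rep in 1:25) {
    N <- sample(8:30, 1)
    labels <- sample(c("x", "y", "z"), N, replace = TRUE)
    ann <- make_annotations(N, labels)
    grp <- list(g = sample(ann$scan_id, sample(3:N, 1)))
    tab <- enrich(grp, ann, min_observed = 3)
    for (i in seq_len(nrow(tab)))
      expect_equal(tab$p_value[i],
                   hyper_tail_oracle(tab$observed[i], tab$n[i], tab$K[i],
                                     tab$N[i]),
                   tolerance = 1e-12)
  }
})

test_that("BH adjustment preserves raw-p ranking; bonferroni is at least BH", {
  set.seed(43)
  ann <- make_annotations(30, sample(letters[1:5], 30, replace = TRUE))
  grp <- list(g1 = ann$scan_id[1:8], g2 = ann$scan_id[9:20])
  bh <- enrich(grp, ann, adjust_method = "BH")
  bf <- enrich(grp, ann, adjust_method = "bonferroni")
  ord <- order(bh$p_value)
  expect_true(all(diff(bh$adjusted_p[ord]) >= -1e-15))
  expect_true(all(bf$adjusted_p >= bh$adjusted_p - 1e-15))
})

test_that("missing annotations shrink the category universe", {
  ann <- make_annotations(10, c(rep("A", 4), rep("B", 4), NA, NA))
  tab <- enrich(list(g = sprintf("s%02d", 1:4)), ann)
  expect_true(all(tab$N == 8))
})

test_that("empty groups are skipped with a warning", {
  ann <- make_annotations(6, rep(c("A", "B"), 3))
  expect_warning(tab <- enrich(list(ok = ann$scan_id[1:3], bad = character(0)),
                               ann), "empty")
  expect_setequal(unique(tab$group), "ok")
})

test_that("co_enrich forms intersection descriptors consistently", {
  n <- 20
  ann <- data.frame(scan_id = sprintf("s%02d", 1:n),
                    breed = c(rep("boxer", 6), rep("lab", 14)),
                    age = c(rep("old", 3), rep("young", 17)),
                    stringsAsFactors = FALSE)
  grp <- list(g = sprintf("s%02d", 1:4))
  tab <- co_enrich(grp, ann, c("breed", "age"))
  row <- tab[tab$descriptor == "boxer & old", ]
  # 3 of the 4 group members are boxer&old; K = 3 overall
  expect_equal(row$observed, 3)
  expect_equal(row$K, 3)
  expect_equal(row$p_value, hyper_tail_oracle(3, 4, 3, 20), tolerance = 1e-12)
  # degenerate pair: intersection equal to a single-category descriptor
  ann2 <- ann
  ann2$age <- ifelse(ann2$breed == "boxer", "old", "young")
  t_single <- enrich(grp, ann2[, c("scan_id", "breed")])
  t_pair <- co_enrich(grp, ann2, c("breed", "age"))
  expect_equal(t_pair[t_pair$descriptor == "boxer & old", "p_value"],
               t_single[t_single$descriptor == "boxer", "p_value"])
  # empty intersection in the group: k = 0, p = 1
  grp2 <- list(g = sprintf("s%02d", 10:14))
  t3 <- co_enrich(grp2, ann, c("breed", "age"))
  expect_equal(t3[t3$descriptor == "boxer & old", "observed"], 0)
  expect_equal(t3[t3$descriptor == "boxer & old", "p_value"], 1)
})

test_that("enrich accepts a cluster_partition directly", {
  edges <- rbind(complete_graph_edges(sprintf("s%02d", 1:4)),
                 complete_graph_edges(sprintf("s%02d", 5:8)))
  part <- mcl_cluster(net_from_edges(edges))
  ann <- make_annotations(8, c(rep("A", 4), rep("B", 4)))
  tab <- enrich(part, ann)
  expect_setequal(unique(tab$group), c("cluster_01", "cluster_02"))
  expect_equal(min(tab$p_value), hyper_tail_oracle(4, 4, 4, 8),
               tolerance = 1e-12)
})
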