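# Shared fixtures: all built in code at test time.

# minimal scan record with sane measurements; override any field
make_record <- function(scan_id, ..., breed = "labrador_retriever",
                        breed_group = "Gundog", purebred = TRUE) {
  base <- list(
    scan_id = scan_id, patient_id = paste0("dog_", scan_id),
    body_weight = 20, age = 5, sex = "female", neutered = FALSE,
    breed = breed, breed_group = breed_group, clade = NA_character_,
    diagnostic_class = "normal", purebred = purebred,
    brain_length = 80, cerebellar_volume = 9000, cerebellar_diameter = 40,
    interthalamic_adhesion_height = 7, corpus_callosum_thickness = 2.5,
    ventricular_volume = 2000, cranial_length = 130, brain_width = 55,
    total_brain_volume = 95000, sulcus_depth = 10,
    cerebellar_compression_length = 20, cerebellar_compression_index = 0.5,
    obex_position = 10, corpus_callosum_angle = 25, head_angle = 35,
    muzzle_length = 75, ventricle_height = 0)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_cohort <- function(n = 6, ...) {
  recs <- do.call(rbind, lapply(seq_len(n), function(i)
    make_record(sprintf("s%02d", i), ...)))
  cohort_table(recs)
}

# corr_network from an explicit edge data.frame (round-trips through the
# edge-list reader so the import path gets exercised too)
net_from_edges <- function(edges, excluded = character(0),
                           threshold = NA_real_) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  net <- read_edge_list(path, threshold = threshold)
  net$excluded_nodes <- excluded
  net
}

complete_graph_edges <- function(ids, w = 1) {
  pairs <- t(utils::combn(ids, 2))
  data.frame(scan_a = pairs[, 1], scan_b = pairs[, 2], r = w,
             stringsAsFactors = FALSE)
}

# random Erdos-Renyi edge table over n nodes (connected nodes only appear
# in the network, mirroring threshold_graph output)
random_edges <- function(n, p = 0.5, weights = c(0.3, 1)) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  data.frame(scan_a = pairs[keep, 1], scan_b = pairs[keep, 2],
             r = stats::runif(sum(keep), weights[1], weights[2]),
             stringsAsFactors = FALSE)
}

# planted two-block edge table: dense blocks, sparse bridge
planted_edges <- function(n_per = 4, p_in = 0.9, p_out = 0.1) {
  ids <- sprintf("n%02d", seq_len(2 * n_per))
  g1 <- ids[seq_len(n_per)]
  pairs <- t(utils::combn(ids, 2))
  same <- (pairs[, 1] %in% g1) == (pairs[, 2] %in% g1)
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  if (!any(keep)) keep[which(same)[1]] <- TRUE
  data.frame(scan_a = pairs[keep, 1], scan_b = pairs[keep, 2],
             r = stats::runif(sum(keep), 0.5, 1),
             stringsAsFactors = FALSE)
}

# canonical comparable form of a partition
partition_signature <- function(p) {
  list(clusters = lapply(p$clusters, sort), unclustered = sort(p$unclustered))
}

# independent hypergeometric upper-tail oracle: explicit sum of
# choose()-ratio terms
hyper_tail_oracle <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent two-sided Fisher oracle: enumerate every table with the
# observed margins via choose() products
fisher_two_sided_oracle <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; N <- a + b + c + d
  support <- max(0, row1 + col1 - N):min(row1, col1)
  prob <- function(x)
    choose(col1, x) * choose(N - col1, row1 - x) / choose(N, row1)
  probs <- vapply(support, prob, numeric(1))
  sum(probs[probs <= prob(a) * (1 + 1e-7)])
}

# independent pair-counting ARI oracle: loop over all item pairs
ari_oracle <- function(labels1, labels2) {
  n <- length(labels1)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s1 <- labels1[i] == labels1[j]
    s2 <- labels2[i] == labels2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) c_ <- c_ + 1
    else d <- d + 1
  }
  total <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / total
  max_index <- ((a + b) + (a + c_)) / 2
  if (max_index == expected) return(1)
  (a - expected) / (max_index - expected)
}
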