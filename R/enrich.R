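#' Hypergeometric upper-tail probability
#'
#' One-sided over-representation probability `P(X >= k)` for X distributed
#' hypergeometric with population `N`, `K` marked items, and a draw of `n` —
#' the Fisher's exact test of seeing at least `k` marked members in a group
#' of `n`. Computed with log-stable arithmetic via [stats::phyper()].
#'
#' @param k observed count, `0 <= k <= min(n, K)`
#' @param n group (draw) size
#' @param K descriptor total in the population
#' @param N population size
#' @return probability in `[0, 1]`
#' @export
hypergeom_tail <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, n <= N, K <= N, k <= n)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.annotation_categories <- function(annotations)
  setdiff(names(annotations), "scan_id")

.as_grouping <- function(groups) {
  if (inherits(groups, "cluster_partition")) {
    g <- groups$clusters
    names(g) <- sprintf("cluster_%02d", seq_along(g))
    g
  } else if (is.list(groups)) {
    if (is.null(names(groups)))
      names(groups) <- sprintf("group_%02d", seq_along(groups))
    groups
  } else stop("groups must be a cluster_partition or a named list of scan ids")
}

#' Enrichment of categorical descriptors within groups
#'
#' For every (group, descriptor) pair, tests whether the descriptor is
#' disproportionately highly represented in the group relative to the
#' annotated population, using the one-sided hypergeometric upper tail
#' ([hypergeom_tail()]). P-values are multiplicity-adjusted across all rows
#' of each category family. Rows with fewer than `min_observed` observed
#' members are retained but flagged `reported = FALSE`.
#'
#' The population `N` for each category is the set of grouped-or-groupable
#' scans with a non-missing annotation for that category (scans with missing
#' annotations are excluded from that category's tests).
#'
#' @param groups a `cluster_partition` or named list of scan-id vectors
#'   (e.g. clusters, or diagnostic classes for class-set enrichment)
#' @param annotations data.frame from [annotate_cohort()] (`scan_id` plus one
#'   column per category); only scans present here are tested
#' @param categories category columns to test; default all
#' @param min_observed minimum observed count for a row to be reported
#'   (default 3, the minimum cluster size)
#' @param adjust_method `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`
#' @param population optional character vector fixing the scan universe
#'   (default: all annotated scans)
#' @return data.frame of class `enrichment_table`: `group`, `category`,
#'   `descriptor`, `n` (group size), `K` (descriptor total), `N`
#'   (population), `observed`, `expected` (= n*K/N), `p_value`,
#'   `adjusted_p`, `reported`
#' @export
enrich <- function(groups, annotations, categories = NULL, min_observed = 3,
                   adjust_method = c("BH", "bonferroni"),
                   population = NULL) {
  adjust_method <- match.arg(adjust_method)
  grouping <- .as_grouping(groups)
  if (any(lengths(grouping) == 0)) {
    warning("skipping empty group(s): ",
            paste(names(grouping)[lengths(grouping) == 0], collapse = ", "))
    grouping <- grouping[lengths(grouping) > 0]
  }
  if (is.null(categories)) categories <- .annotation_categories(annotations)
  if (is.null(population)) population <- annotations$scan_id
  rows <- list()
  for (cat_name in categories) {
    ann <- annotations[match(population, annotations$scan_id), ]
    ok <- !is.na(ann[[cat_name]])
    universe <- ann$scan_id[ok]
    labels <- ann[[cat_name]][ok]
    N <- length(universe)
    if (N == 0) next
    totals <- table(labels)
    for (g in names(grouping)) {
      in_group <- intersect(grouping[[g]], universe)
      n <- length(in_group)
      if (n == 0) next
      group_labels <- labels[match(in_group, universe)]
      obs <- table(factor(group_labels, levels = names(totals)))
      for (d in names(totals)) {
        K <- as.integer(totals[[d]])
        k <- as.integer(obs[[d]])
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, category = cat_name, descriptor = d,
          n = n, K = K, N = N, observed = k, expected = n * K / N,
          p_value = hypergeom_tail(k, n, K, N),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), category = character(0),
               descriptor = character(0), n = integer(0), K = integer(0),
               N = integer(0), observed = integer(0), expected = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  out$adjusted_p <- rep(NA_real_, nrow(out))
  for (cat_name in unique(out$category)) {
    i <- out$category == cat_name
    out$adjusted_p[i] <- stats::p.adjust(out$p_value[i],
                                         method = adjust_method)
  }
  out$reported <- out$observed >= min_observed
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Co-enrichment of a pair of categories
#'
#' Forms intersection descriptors (`labelA & labelB`, e.g. a breed x age
#' combination) from two annotation categories and runs [enrich()] on the
#' combined category.
#'
#' @inheritParams enrich
#' @param category_pair character vector of two category names
#' @return an `enrichment_table` with category `"A*B"`
#' @export
co_enrich <- function(groups, annotations, category_pair, min_observed = 3,
                      adjust_method = c("BH", "bonferroni")) {
  stopifnot(length(category_pair) == 2,
            all(category_pair %in% names(annotations)))
  a <- annotations[[category_pair[1]]]
  b <- annotations[[category_pair[2]]]
  combined <- ifelse(is.na(a) | is.na(b), NA_character_, paste(a, b, sep = " & "))
  ann2 <- data.frame(scan_id = annotations$scan_id, stringsAsFactors = FALSE)
  ann2[[paste(category_pair, collapse = "*")]] <- combined
  enrich(groups, ann2, min_observed = min_observed,
         adjust_method = adjust_method)
}

#' Write an enrichment table as TSV
#' @param table an `enrichment_table`
#' @param path output file
#' @export
write_enrichment <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
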