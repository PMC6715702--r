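#' Default pipeline configuration
#'
#' All stage parameters in one list, with the study defaults: correlation
#' threshold r = 0.7, MCL inflation 2.2, minimum cluster size 3, minimum
#' observed count 3 for reported enrichments, ratio median-centering and
#' Benjamini-Hochberg adjustment.
#'
#' @return named list of pipeline settings
#' @export
default_config <- function() {
  list(threshold = 0.7, inflation = 2.2, expansion = 2,
       prune_threshold = 1e-6, max_iterations = 200, convergence_tol = 1e-8,
       min_cluster_size = 3, self_loop = "max_incident",
       center_mode = "ratio", adjust_method = "BH", min_observed = 3,
       threshold_scan = seq(0.5, 0.95, by = 0.05))
}

#' Read / write a pipeline configuration (JSON)
#' @param path JSON file
#' @return named list merged over [default_config()]
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @param config configuration list
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.cfg_mcl_params <- function(cfg)
  mcl_params(inflation = cfg$inflation, expansion = cfg$expansion,
             prune_threshold = cfg$prune_threshold,
             max_iterations = cfg$max_iterations,
             convergence_tol = cfg$convergence_tol,
             min_cluster_size = cfg$min_cluster_size,
             self_loop = cfg$self_loop)

#' Run the full analysis pipeline on a cohort file
#'
#' Preprocess -> correlate -> threshold -> cluster -> enrich -> risk, writing
#' every intermediate artifact plus a run manifest and plain-text summary to
#' `out_dir`: the centered matrix (`matrix_centered.tsv`), edge list
#' (`edges.tsv`) and GraphML export, threshold-scan diagnostic
#' (`threshold_scan.tsv`), partition (`partition.tsv`), enrichment table
#' (`enrichment.tsv`), female neuter-status tumour risk table (`risk.tsv`,
#' when the cohort supports it), `manifest.json` and `summary.txt`.
#'
#' @param cohort_path cohort TSV/CSV path
#' @param out_dir output directory (created if needed)
#' @param config_path optional JSON config overriding [default_config()]
#' @return (invisibly) list with all in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(cohort_path, out_dir, config_path = NULL) {
  cfg <- if (is.null(config_path)) default_config() else
    read_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_path)
  res <- analyze_cohort(cohort, threshold = cfg$threshold,
                        params = .cfg_mcl_params(cfg),
                        center_mode = cfg$center_mode,
                        adjust_method = cfg$adjust_method,
                        min_observed = cfg$min_observed)
  scan_tab <- threshold_scan(res$corr, cfg$threshold_scan)

  write_morph_matrix(res$matrix, file.path(out_dir, "matrix_centered.tsv"))
  write_edge_list(res$network, file.path(out_dir, "edges.tsv"))
  write_graphml(res$network, file.path(out_dir, "network.graphml"))
  utils::write.table(scan_tab, file.path(out_dir, "threshold_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_partition(res$partition, file.path(out_dir, "partition.tsv"))
  write_enrichment(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  risk <- tryCatch({
    tab <- female_neuter_table(cohort)
    or <- odds_ratio(tab)
    rr <- suppressWarnings(relative_risk(tab))
    df <- data.frame(exposure = "neutered_female",
                     reference = "entire_female", outcome = "tumour",
                     a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
                     d = tab[2, 2], odds_ratio = or$or, ci_low = or$ci_low,
                     ci_high = or$ci_high, fisher_p = or$p_value,
                     relative_risk = rr)
    utils::write.table(df, file.path(out_dir, "risk.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    df
  }, error = function(e) NULL)

  n_scans <- nrow(cohort$records)
  manifest <- list(
    input = list(path = cohort_path,
                 md5 = unname(tools::md5sum(cohort_path))),
    config = cfg,
    version = as.character(utils::packageVersion("morphnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    counts = list(
      scans = n_scans,
      scans_in_matrix = nrow(res$matrix$values),
      dropped_scans = length(res$matrix$dropped_scans),
      nodes = length(res$network$nodes),
      edges = nrow(res$network$edges),
      excluded_scans = length(res$network$excluded_nodes),
      clusters = length(res$partition$clusters),
      clustered_scans = sum(lengths(res$partition$clusters)),
      unclustered_scans = length(res$partition$unclustered)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("scans: %d (matrix: %d, dropped: %d)", n_scans,
            manifest$counts$scans_in_matrix, manifest$counts$dropped_scans),
    sprintf("network (r > %g): %d nodes, %d edges, %d excluded",
            cfg$threshold, manifest$counts$nodes, manifest$counts$edges,
            manifest$counts$excluded_scans),
    sprintf("MCL (inflation %g): %d clusters covering %d scans; %d unclustered",
            cfg$inflation, manifest$counts$clusters,
            manifest$counts$clustered_scans,
            manifest$counts$unclustered_scans),
    sprintf("enrichment rows: %d (%d reported)", nrow(res$enrichment),
            sum(res$enrichment$reported)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  if (length(res$partition$clusters) == 0)
    warning("no clusters found (threshold above maximal correlation?)")
  invisible(c(res, list(threshold_scan = scan_tab, manifest = manifest,
                        risk = risk)))
}

#' Network statistics for an externally supplied study cohort
#'
#' Computes the headline network statistics (node, edge and isolate counts
#' of the thresholded graph; cluster count and clustered-scan count of the
#' MCL partition) for a cohort file, e.g. a deposited study dataset. The
#' original study's printed values are reproducible only when its deposited
#' data file is supplied; this helper makes that comparison a one-liner.
#'
#' @param cohort_path cohort TSV/CSV
#' @param threshold correlation threshold (default 0.7)
#' @param params [mcl_params()] (default inflation 2.2, min size 3)
#' @return named list: `n_nodes`, `n_edges`, `n_isolates`, `n_clusters`,
#'   `n_clustered`, `largest_cluster`
#' @export
study_network_statistics <- function(cohort_path, threshold = 0.7,
                                     params = mcl_params()) {
  cohort <- read_cohort(cohort_path)
  res <- analyze_cohort(cohort, threshold = threshold, params = params)
  list(n_nodes = length(res$network$nodes),
       n_edges = nrow(res$network$edges),
       n_isolates = length(res$network$excluded_nodes),
       n_clusters = length(res$partition$clusters),
       n_clustered = sum(lengths(res$partition$clusters)),
       largest_cluster = if (length(res$partition$clusters))
         length(res$partition$clusters[[1]]) else 0L)
}
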