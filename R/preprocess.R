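#' Normalize a cohort into a scans x parameters matrix
#'
#' Applies each registered parameter's normalization class per scan:
#' `BRAIN_VOLUME_NORM` divides by total brain volume (which includes
#' ventricular volume), `BODY_WEIGHT_NORM` by body weight (kg),
#' `HEAD_ANGLE_NORM` by head angle (degrees), `NONE` leaves the value
#' unchanged. `EXCLUDE` parameters are dropped and `CATEGORIZE` parameters
#' (ventricle height) are removed from the numeric matrix — they are consumed
#' by [assign_septal_integrity()] instead. Normalized total brain volume is
#' retained as a matrix column.
#'
#' Scans missing any retained parameter after normalization are dropped with
#' a warning (pairwise-complete correlation is deliberately not used, keeping
#' the downstream correlation matrix well-defined and reproducible).
#'
#' @param cohort a [cohort_table()]
#' @return a `morph_matrix`: list with `values` (numeric matrix, rownames =
#'   scan ids), `stage = "normalized"`, `dropped_scans`, `registry`.
#' @export
normalize_cohort <- function(cohort) {
  rec <- cohort$records
  reg <- cohort$registry
  keep <- names(reg)[reg %in% c("BRAIN_VOLUME_NORM", "BODY_WEIGHT_NORM",
                                "HEAD_ANGLE_NORM", "NONE")]
  denom_of <- function(cls) switch(cls,
    BRAIN_VOLUME_NORM = rec$total_brain_volume,
    BODY_WEIGHT_NORM  = rec$body_weight,
    HEAD_ANGLE_NORM   = rec$head_angle,
    NONE = rep(1, nrow(rec)))
  for (cls in c("BRAIN_VOLUME_NORM", "BODY_WEIGHT_NORM", "HEAD_ANGLE_NORM")) {
    if (!any(reg == cls)) next
    d <- denom_of(cls)
    bad <- !is.na(d) & d <= 0
    if (any(bad))
      stop(sprintf("non-positive %s normalizer for scan(s): %s", cls,
                   paste(rec$scan_id[bad], collapse = ", ")))
  }
  vals <- sapply(keep, function(p) rec[[p]] / denom_of(reg[[p]]))
  vals <- matrix(as.numeric(vals), nrow = nrow(rec),
                 dimnames = list(rec$scan_id, keep))
  complete <- stats::complete.cases(vals)
  if (any(!complete))
    warning(sprintf("dropping %d scan(s) with missing measurements: %s",
                    sum(!complete),
                    paste(rec$scan_id[!complete], collapse = ", ")))
  structure(list(values = vals[complete, , drop = FALSE],
                 stage = "normalized",
                 dropped_scans = rec$scan_id[!complete],
                 registry = reg),
            class = "morph_matrix")
}

#' Median-center a normalized matrix per parameter
#'
#' Ratio mode (default) divides each value by its parameter's cohort median,
#' so every parameter's median becomes 1 and parameters of very different
#' magnitude contribute comparably to profile correlations. Difference mode
#' subtracts the median (median becomes 0); Pearson correlations between scan
#' profiles are generally *not* invariant between the two modes.
#'
#' @param mat a `morph_matrix` at stage `"normalized"`
#' @param mode `"ratio"` or `"difference"`
#' @return the matrix at stage `"centered"`, with `center_mode` recorded
#' @export
median_center <- function(mat, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mat, "morph_matrix"))
  if (!mat$stage %in% c("normalized", "centered"))
    stop("median_center expects a matrix at stage 'normalized' (or 'centered', for re-centering)")
  med <- apply(mat$values, 2, stats::median)
  if (mode == "ratio" && any(med == 0))
    stop("zero median in ratio mode for parameter(s): ",
         paste(colnames(mat$values)[med == 0], collapse = ", "))
  v <- if (mode == "ratio") sweep(mat$values, 2, med, `/`)
       else sweep(mat$values, 2, med, `-`)
  out <- mat
  out$values <- v
  out$stage <- "centered"
  out$center_mode <- mode
  out
}

#' Residual brain tissue volume per unit body weight
#'
#' Ventricular volume subtracted from total brain volume, normalized to body
#' weight (mm^3/kg).
#'
#' @param total_brain_volume mm^3
#' @param ventricular_volume mm^3, `0 <= ventricular <= total`
#' @param body_weight kg, > 0
#' @return mm^3/kg (vectorized)
#' @export
residual_brain_volume <- function(total_brain_volume, ventricular_volume,
                                  body_weight) {
  ok <- is.na(total_brain_volume) | is.na(ventricular_volume) |
    (ventricular_volume >= 0 & ventricular_volume <= total_brain_volume)
  if (!all(ok))
    stop("invalid measurement: ventricular volume exceeds total brain volume")
  if (any(!is.na(body_weight) & body_weight <= 0))
    stop("invalid measurement: body weight must be positive")
  (total_brain_volume - ventricular_volume) / body_weight
}

#' Export a morphometric matrix as TSV
#'
#' Writes a `# stage: <stage>` comment header followed by a scan x parameter
#' table.
#' @param mat a `morph_matrix`
#' @param path output file
#' @export
write_morph_matrix <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", mat$stage), con)
  df <- data.frame(scan_id = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a morphometric matrix written by [write_morph_matrix()]
#' @param path TSV file with a `# stage:` header comment
#' @return a `morph_matrix`
#' @export
read_morph_matrix <- function(path) {
  first <- readLines(path, n = 1)
  stage <- sub("^# stage: *", "", first)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$scan_id
  structure(list(values = vals, stage = stage, dropped_scans = character(0),
                 registry = NULL),
            class = "morph_matrix")
}

#' @export
print.morph_matrix <- function(x, ...) {
  cat(sprintf("<morph_matrix> %d scans x %d parameters, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}
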