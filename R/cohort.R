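#' Default morphometric parameter registry
#'
#' Maps each measured parameter to the normalization class applied before
#' network analysis. Compartment measurements (brain length, cerebellar
#' volume/diameter, interthalamic adhesion height, corpus callosum thickness
#' and ventricular parameters) are expressed relative to total brain volume;
#' whole-head measurements (cranial length, brain width, total brain volume,
#' sulcus depth) are scaled by body weight to control allometry; positioning-
#' sensitive measurements (cerebellar compression length/index, obex position)
#' are scaled by head angle; corpus callosum angle enters unchanged. Head
#' angle itself and muzzle length (used only for the craniofacial ratio) are
#' excluded from the numeric matrix, and ventricle height is routed to the
#' septal-integrity categorization instead.
#'
#' The registry is an ordinary named character vector, so users may extend it
#' with additional parameters (any `"ventricle"`-prefixed numeric parameter
#' should normally be `"BRAIN_VOLUME_NORM"`).
#'
#' @return Named character vector: parameter name -> normalization class, one
#'   of `"BRAIN_VOLUME_NORM"`, `"BODY_WEIGHT_NORM"`, `"HEAD_ANGLE_NORM"`,
#'   `"NONE"`, `"EXCLUDE"`, `"CATEGORIZE"`.
#' @export
default_registry <- function() {
  c(
    brain_length                 = "BRAIN_VOLUME_NORM",
    cerebellar_volume            = "BRAIN_VOLUME_NORM",
    cerebellar_diameter          = "BRAIN_VOLUME_NORM",
    interthalamic_adhesion_height = "BRAIN_VOLUME_NORM",
    corpus_callosum_thickness    = "BRAIN_VOLUME_NORM",
    ventricular_volume           = "BRAIN_VOLUME_NORM",
    cranial_length               = "BODY_WEIGHT_NORM",
    brain_width                  = "BODY_WEIGHT_NORM",
    total_brain_volume           = "BODY_WEIGHT_NORM",
    sulcus_depth                 = "BODY_WEIGHT_NORM",
    cerebellar_compression_length = "HEAD_ANGLE_NORM",
    cerebellar_compression_index = "HEAD_ANGLE_NORM",
    obex_position                = "HEAD_ANGLE_NORM",
    corpus_callosum_angle        = "NONE",
    head_angle                   = "EXCLUDE",
    muzzle_length                = "EXCLUDE",
    ventricle_height             = "CATEGORIZE"
  )
}

.norm_classes <- c("BRAIN_VOLUME_NORM", "BODY_WEIGHT_NORM", "HEAD_ANGLE_NORM",
                   "NONE", "EXCLUDE", "CATEGORIZE")

.meta_cols <- c("scan_id", "patient_id", "body_weight", "age", "sex",
                "neutered", "breed", "breed_group", "clade",
                "diagnostic_class", "purebred")

#' Construct a cohort table
#'
#' @param records data.frame with one row per scan. Required columns:
#'   `scan_id`, `patient_id`, `body_weight` (kg), `age` (years), `sex`
#'   (`"female"`/`"male"`), `neutered` (logical), `breed`, `breed_group`,
#'   `diagnostic_class`, `purebred` (logical); optional `clade`; plus one
#'   numeric column per registered measurement (missing values allowed as
#'   `NA`).
#' @param registry named character vector of normalization classes; see
#'   [default_registry()].
#' @return Object of class `cohort_table` (list with `records`, `registry`).
#' @export
cohort_table <- function(records, registry = default_registry()) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!("clade" %in% names(records))) records$clade <- NA_character_
  missing_meta <- setdiff(.meta_cols, names(records))
  if (length(missing_meta) > 0)
    stop("cohort records lack metadata columns: ",
         paste(missing_meta, collapse = ", "))
  if (anyDuplicated(records$scan_id))
    stop("scan_id values must be unique within a cohort")
  if (any(!is.finite(records$body_weight) | records$body_weight <= 0))
    stop("body_weight must be strictly positive for every scan")
  if (any(!is.finite(records$age) | records$age <= 0))
    stop("age must be strictly positive for every scan")
  bad_sex <- setdiff(unique(records$sex), c("female", "male"))
  if (length(bad_sex) > 0)
    stop("sex must be 'female' or 'male'; found: ",
         paste(bad_sex, collapse = ", "))
  if (length(bad <- setdiff(unname(registry), .norm_classes)) > 0)
    stop("unknown normalization class(es): ", paste(bad, collapse = ", "))
  absent <- setdiff(names(registry), names(records))
  for (p in absent) records[[p]] <- NA_real_  # flagged missing
  structure(list(records = records, registry = registry),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d scans, %d registered parameters\n",
              nrow(x$records), length(x$registry)))
  invisible(x)
}

#' Read a cohort table from delimited text
#'
#' One row per scan; header names must match the metadata columns and the
#' parameter registry; empty fields are missing values.
#'
#' @param path TSV or CSV file (delimiter inferred from extension, or set
#'   `sep`).
#' @param registry parameter registry, see [default_registry()].
#' @param sep field separator; default `"\t"` unless `path` ends in `.csv`.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, registry = default_registry(), sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          check.names = FALSE, comment.char = "#")
  for (col in c("neutered", "purebred"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  cohort_table(df, registry)
}

#' Write a cohort table as TSV
#' @param cohort a [cohort_table()]
#' @param path output file
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Craniofacial ratio (CFR)
#'
#' Muzzle length divided by cranial length; low values indicate short-faced
#' (brachycephalic) conformation.
#'
#' @param muzzle_length mm, > 0 (vectorized)
#' @param cranial_length mm, > 0 (vectorized)
#' @return numeric ratio(s)
#' @export
compute_cfr <- function(muzzle_length, cranial_length) {
  if (any(!is.na(muzzle_length) & muzzle_length <= 0) ||
      any(!is.na(cranial_length) & cranial_length <= 0))
    stop("invalid measurement: muzzle and cranial lengths must be positive")
  muzzle_length / cranial_length
}

#' Craniofacial category from a CFR value
#'
#' Cut-offs: CFR <= 0.52 brachycephalic; 0.52 < CFR < 0.67 mesocephalic;
#' CFR >= 0.67 dolichocephalic.
#'
#' @param cfr positive ratio (vectorized; `NA` passes through)
#' @return character vector of categories
#' @export
assign_craniofacial_from_cfr <- function(cfr) {
  if (any(!is.na(cfr) & cfr <= 0)) stop("invalid CFR: must be positive")
  out <- rep(NA_character_, length(cfr))
  out[!is.na(cfr) & cfr <= 0.52] <- "brachycephalic"
  out[!is.na(cfr) & cfr > 0.52 & cfr < 0.67] <- "mesocephalic"
  out[!is.na(cfr) & cfr >= 0.67] <- "dolichocephalic"
  out
}

#' Resolve craniofacial categories for a whole cohort
#'
#' Assignment rules, in order of preference: (i) the scan's own CFR where
#' muzzle length was measurable; (ii) the mean CFR of the scan's breed within
#' the cohort, for purebred dogs whose breed has more than two representatives
#' with measurable CFRs; (iii) otherwise unassigned (the category may then be
#' supplied externally via an `craniofacial` metadata column, recorded with
#' provenance `"metadata"`).
#'
#' @param cohort a [cohort_table()]
#' @return data.frame with `scan_id`, `craniofacial`, `provenance`
#'   (`"individual_cfr"`, `"breed_average_cfr"`, `"metadata"`,
#'   `"unassigned"`).
#' @export
resolve_craniofacial <- function(cohort) {
  rec <- cohort$records
  cfr <- compute_cfr(rec$muzzle_length, rec$cranial_length)
  cat_i <- assign_craniofacial_from_cfr(cfr)
  prov <- ifelse(!is.na(cat_i), "individual_cfr", "unassigned")
  out <- cat_i

  # rule (ii): breed-average CFR for purebreds with > 2 measured breed-mates
  measured <- !is.na(cfr)
  n_measured <- tapply(measured, rec$breed, sum)
  breed_mean <- tapply(ifelse(measured, cfr, NA_real_), rec$breed,
                       mean, na.rm = TRUE)
  need <- is.na(out) & rec$purebred %in% TRUE
  eligible <- need & n_measured[rec$breed] > 2
  eligible[is.na(eligible)] <- FALSE
  out[eligible] <- assign_craniofacial_from_cfr(breed_mean[rec$breed[eligible]])
  prov[eligible] <- "breed_average_cfr"

  # rule (iii): externally supplied category, if present in metadata
  if ("craniofacial" %in% names(rec)) {
    ext <- is.na(out) & !is.na(rec$craniofacial)
    out[ext] <- rec$craniofacial[ext]
    prov[ext] <- "metadata"
  }
  data.frame(scan_id = rec$scan_id, craniofacial = out, provenance = prov,
             stringsAsFactors = FALSE)
}

#' Age category
#'
#' Half-open bins: (0,2) Immature; [2,4) Young adult; [4,8) Middle-aged;
#' [8,10) Mature; [10, Inf) Geriatric.
#'
#' @param age years, > 0 (vectorized; `NA` passes through)
#' @return character vector
#' @export
assign_age_category <- function(age) {
  if (any(!is.na(age) & age <= 0)) stop("invalid age: must be positive")
  as.character(cut(age, breaks = c(0, 2, 4, 8, 10, Inf), right = FALSE,
                   labels = c("Immature", "Young adult", "Middle-aged",
                              "Mature", "Geriatric")))
}

#' Septal integrity category from ventricle height
#'
#' Measured ventricle height (the gap in the septum pellucidum) is binned:
#' 0 mm intact; (0,3) minor; [3,6) moderate; [6,10) severe; [10, Inf) absent.
#' Exact boundary values 3, 6 and 10 mm fall in the more severe category
#' (consistent half-open convention; the source bins leave them unassigned).
#'
#' @param ventricle_height mm, >= 0 (vectorized; `NA` passes through)
#' @return character vector
#' @export
assign_septal_integrity <- function(ventricle_height) {
  if (any(!is.na(ventricle_height) & ventricle_height < 0))
    stop("invalid ventricle height: must be non-negative")
  out <- rep(NA_character_, length(ventricle_height))
  h <- ventricle_height
  out[!is.na(h) & h == 0] <- "intact"
  out[!is.na(h) & h > 0 & h < 3] <- "minor"
  out[!is.na(h) & h >= 3 & h < 6] <- "moderate"
  out[!is.na(h) & h >= 6 & h < 10] <- "severe"
  out[!is.na(h) & h >= 10] <- "absent"
  out
}

#' Build the annotation set used by enrichment analysis
#'
#' Derives the categorical descriptors for every scan: breed, breed group,
#' clade, craniofacial category (via [resolve_craniofacial()]), age category,
#' combined sex/neuter status, septal integrity, and diagnostic class.
#'
#' @param cohort a [cohort_table()]
#' @return data.frame keyed by `scan_id`, one column per category; missing
#'   annotations are `NA` and are excluded from that category's tests.
#' @export
annotate_cohort <- function(cohort) {
  rec <- cohort$records
  cf <- resolve_craniofacial(cohort)
  data.frame(
    scan_id = rec$scan_id,
    breed = rec$breed,
    breed_group = rec$breed_group,
    clade = rec$clade,
    craniofacial = cf$craniofacial[match(rec$scan_id, cf$scan_id)],
    age_category = assign_age_category(rec$age),
    sex_neuter = paste0(ifelse(rec$neutered, "neutered_", "entire_"), rec$sex),
    septal_integrity = assign_septal_integrity(rec$ventricle_height),
    diagnostic_class = rec$diagnostic_class,
    stringsAsFactors = FALSE
  )
}
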