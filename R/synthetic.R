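#' Default morphometric archetype profiles
#'
#' Six archetype mean profiles on the normalized scale, expressed as a base
#' normalized value per matrix parameter times an archetype-specific
#' multiplier. The motifs emulate the structure the analysis is meant to
#' resolve: an "aged-brain" profile (small normalized brain width and volume
#' with ventriculomegaly and deep sulci), a brachycephalic-ventriculomegaly
#' profile, a cerebellar-compression profile, an immature large-brain
#' profile, a dolichocephalic narrow-brain profile, and a mesocephalic
#' compact profile. Multiplier vectors are built to point in distinct
#' directions so that between-archetype profile correlations stay well below
#' within-archetype correlations.
#'
#' @return list with `base` (named numeric, typical normalized values) and
#'   `multipliers` (archetype x parameter matrix)
#' @export
default_archetypes <- function() {
  params <- c("brain_length", "cerebellar_volume", "cerebellar_diameter",
              "interthalamic_adhesion_height", "corpus_callosum_thickness",
              "ventricular_volume", "cranial_length", "brain_width",
              "total_brain_volume", "sulcus_depth",
              "cerebellar_compression_length",
              "cerebellar_compression_index", "obex_position",
              "corpus_callosum_angle")
  base <- stats::setNames(
    c(8.3e-4, 0.10, 4.4e-4, 7.8e-5, 2.8e-5, 0.022, 6.5, 2.75, 4500, 0.5,
      0.57, 0.014, 0.29, 25),
    params)
  mult <- rbind(
    aged_brain = c(1.00, 0.95, 1.00, 0.85, 0.80, 2.60, 1.00, 0.78, 0.82,
                   1.45, 1.00, 1.00, 1.00, 0.90),
    brachy_ventriculomegaly = c(0.85, 0.90, 0.95, 1.00, 1.05, 1.80, 0.80,
                                1.40, 1.15, 0.90, 1.30, 1.30, 1.15, 1.25),
    cerebellar_compression = c(1.00, 0.80, 0.85, 1.00, 1.00, 1.00, 0.95,
                               1.05, 1.00, 0.95, 2.00, 2.10, 1.70, 0.95),
    immature_large_brain = c(1.12, 1.05, 1.05, 1.10, 1.15, 0.50, 1.00, 1.10,
                             1.35, 0.70, 0.80, 0.80, 0.85, 1.00),
    dolicho_narrow = c(1.20, 1.05, 1.00, 1.00, 1.00, 0.85, 1.35, 0.82, 0.95,
                       1.10, 0.90, 0.90, 0.95, 0.85),
    meso_compact = c(0.97, 1.15, 1.10, 1.15, 0.90, 0.62, 0.90, 1.00, 0.88,
                     1.05, 0.95, 0.90, 0.95, 1.10))
  colnames(mult) <- params
  list(base = base, multipliers = mult)
}

#' Default synthetic breed panel
#'
#' Twenty breeds with lognormal body-weight distributions, normal CFR
#' distributions, cohort frequencies, breed group/clade labels and a
#' dominant morphometric archetype. Values are simulation defaults chosen to
#' span a realistic referral cohort (2.5-60 kg, CFR 0.33-0.73), not claims
#' about any real dataset.
#'
#' @return data.frame, one row per breed
#' @export
default_breeds <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
breed breed_group clade weight_median cfr_mean freq archetype
boxer Working euro_mastiff 30 0.44 0.08 aged_brain
labrador_retriever Gundog retriever 30 0.60 0.10 meso_compact
cavalier_king_charles_spaniel Toy spaniel 8 0.50 0.09 cerebellar_compression
chihuahua Toy toy_clade 2.5 0.48 0.06 immature_large_brain
french_bulldog Utility euro_mastiff 12 0.35 0.04 brachy_ventriculomegaly
pug Toy asian_toy 8 0.33 0.04 brachy_ventriculomegaly
greyhound Hound sighthound 30 0.73 0.03 dolicho_narrow
whippet Hound sighthound 12 0.72 0.03 dolicho_narrow
border_collie Pastoral collie 18 0.62 0.04 meso_compact
german_shepherd_dog Pastoral shepherd 35 0.64 0.04 dolicho_narrow
staffordshire_bull_terrier Terrier euro_mastiff 15 0.52 0.04 brachy_ventriculomegaly
jack_russell_terrier Terrier terrier_clade 8 0.58 0.04 meso_compact
cocker_spaniel Gundog spaniel 13 0.55 0.04 cerebellar_compression
springer_spaniel Gundog spaniel 20 0.58 0.04 meso_compact
weimaraner Gundog pointer 32 0.65 0.04 aged_brain
rottweiler Working euro_mastiff 45 0.55 0.04 aged_brain
dogue_de_bordeaux Working euro_mastiff 50 0.40 0.02 brachy_ventriculomegaly
yorkshire_terrier Toy toy_clade 3 0.50 0.04 immature_large_brain
great_dane Working euro_mastiff 60 0.60 0.03 dolicho_narrow
crossbreed Crossbreed NA 15 0.55 0.12 mixed
")
  df$weight_sdlog <- 0.12
  df$cfr_sd <- 0.03
  df$purebred <- df$breed != "crossbreed"
  df
}

#' Synthetic cohort configuration
#'
#' The stated world for the generator: cohort scale (~286 scans, 20 breeds,
#' 6 archetypes), within-archetype profile correlation ~0.95, neutered-female
#' fraction ~0.33, a morphometric aged-brain shift for neutered females, and
#' a programmed neuter-status x tumour association (default odds ratio 13.5
#' against a 4.6% baseline tumour probability in entire females).
#'
#' @param n_scans cohort size
#' @param within_r target within-archetype Pearson correlation between scan
#'   profiles (sets the per-archetype noise sd)
#' @param archetypes see [default_archetypes()]
#' @param breeds see [default_breeds()]
#' @param dominant_weight mixture weight of a breed's dominant archetype
#' @param planted_breed breed whose archetype link is the planted enrichment
#'   (its dominant-archetype weight is raised to 0.9)
#' @param or_exposure programmed odds ratio, neutered vs entire females, for
#'   a tumour diagnosis
#' @param or_male odds ratio of entire males vs entire females
#' @param baseline_p tumour probability in entire females
#' @param p_female,p_neutered_female,p_neutered_male demographic proportions
#' @param nf_aged_shift fraction of a neutered female's archetype mixture
#'   reassigned to the aged-brain archetype (the morphometric link between
#'   neuter status and the aged profile)
#' @param allometric_exponent power-law exponent of total brain volume vs
#'   body weight (applied as a weight-dependent tilt of the normalized
#'   volume, so the body-weight and brain-volume denominators are distinct)
#' @param cfr_measurable_p probability a scan's muzzle length (hence CFR) is
#'   measurable
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_scans = 286, within_r = 0.95,
                             archetypes = default_archetypes(),
                             breeds = default_breeds(),
                             dominant_weight = 0.8,
                             planted_breed = "boxer",
                             or_exposure = 13.5, or_male = 7.5,
                             baseline_p = 0.046,
                             p_female = 0.5, p_neutered_female = 0.66,
                             p_neutered_male = 0.5,
                             nf_aged_shift = 0.4,
                             allometric_exponent = 0.9,
                             cfr_measurable_p = 0.85) {
  stopifnot(n_scans >= 10, within_r > 0, within_r < 1,
            abs(sum(breeds$freq) - 1) < 1e-6)
  structure(as.list(environment()), class = "synthetic_config")
}

# archetype mixture weights for one breed
.archetype_weights <- function(breed_row, arche_names, dominant_weight,
                               planted_breed) {
  k <- length(arche_names)
  if (breed_row$archetype == "mixed" || k == 1 ||
      !(breed_row$archetype %in% arche_names))
    return(stats::setNames(rep(1 / k, k), arche_names))
  w <- if (breed_row$breed == planted_breed) 0.9 else dominant_weight
  out <- stats::setNames(rep((1 - w) / (k - 1), k), arche_names)
  out[breed_row$archetype] <- w
  out
}

# per-archetype profile noise sd targeting the configured within-archetype r
.archetype_noise_sd <- function(mult_row, within_r) {
  v <- stats::var(mult_row) * (length(mult_row) - 1) / length(mult_row)
  sqrt(v / mean(mult_row^2) * (1 - within_r) / within_r)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws demographics per scan (breed, weight, sex, neuter status, age),
#' assigns a morphometric archetype from the breed's mixture (tilted toward
#' the aged-brain archetype for neutered females), draws the normalized
#' profile as archetype mean plus Gaussian noise, then *inverts* the
#' normalization rules — multiplying by the drawn body weight, simulated
#' total brain volume and head angle — to emit raw measurements, so the
#' preprocessing stage is genuinely exercised. Tumour outcomes follow a
#' logistic model on sex and neuter status with the configured odds ratios.
#'
#' @param config a [synthetic_config()]
#' @param seed integer; the run is fully reproducible from it
#' @return list with `cohort` (a [cohort_table()]), `truth` (data.frame with
#'   per-scan archetype, demographics and outcome), `profiles` (the drawn
#'   normalized matrix, for round-trip checks) and `config`
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  n <- config$n_scans
  br <- config$breeds
  arch <- config$archetypes
  params <- colnames(arch$multipliers)
  arche_names <- rownames(arch$multipliers)

  scan_id <- sprintf("scan_%04d", seq_len(n))
  b_idx <- sample.int(nrow(br), n, replace = TRUE, prob = br$freq)
  weight <- stats::rlnorm(n, log(br$weight_median[b_idx]),
                          br$weight_sdlog[b_idx])
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  neutered <- ifelse(sex == "female",
                     stats::runif(n) < config$p_neutered_female,
                     stats::runif(n) < config$p_neutered_male)
  # archetype assignment: breed mixture, tilted for neutered females
  archetype <- character(n)
  for (i in seq_len(n)) {
    w <- .archetype_weights(br[b_idx[i], ], arche_names,
                            config$dominant_weight, config$planted_breed)
    if (neutered[i] && sex[i] == "female" && config$nf_aged_shift > 0 &&
        "aged_brain" %in% names(w) && length(w) > 1) {
      w <- (1 - config$nf_aged_shift) * w
      w["aged_brain"] <- w["aged_brain"] + config$nf_aged_shift
    }
    archetype[i] <- sample(arche_names, 1, prob = w)
  }
  age_mult <- c(aged_brain = 1.5, brachy_ventriculomegaly = 1.0,
                cerebellar_compression = 0.9, immature_large_brain = 0.45,
                dolicho_narrow = 1.0, meso_compact = 1.0)
  am <- age_mult[archetype]
  am[is.na(am)] <- 1
  age <- stats::rlnorm(n, log(5), 0.5) * am

  # normalized profiles: archetype mean + Gaussian noise (sd set by within_r)
  sds <- vapply(arche_names, function(a)
    .archetype_noise_sd(arch$multipliers[a, ], config$within_r), numeric(1))
  a_idx <- match(archetype, arche_names)
  mult <- arch$multipliers[a_idx, , drop = FALSE] +
    matrix(stats::rnorm(n * length(params)), n) * sds[a_idx]
  profiles <- sweep(abs(mult), 2, arch$base, `*`)
  dimnames(profiles) <- list(scan_id, params)
  # allometric tilt: total brain volume scales sublinearly with weight
  profiles[, "total_brain_volume"] <- profiles[, "total_brain_volume"] *
    (weight / 20)^(config$allometric_exponent - 1)

  head_angle <- stats::rnorm(n, 35, 4)
  tbv_raw <- profiles[, "total_brain_volume"] * weight
  reg <- default_registry()
  raw <- profiles
  for (p in params) {
    raw[, p] <- switch(reg[[p]],
      BRAIN_VOLUME_NORM = profiles[, p] * tbv_raw,
      BODY_WEIGHT_NORM  = profiles[, p] * weight,
      HEAD_ANGLE_NORM   = profiles[, p] * head_angle,
      NONE = profiles[, p])
  }
  # ventricle height: inflated in the ventriculomegalic archetypes
  big_vent <- archetype %in% c("aged_brain", "brachy_ventriculomegaly")
  has_gap <- stats::runif(n) < ifelse(big_vent, 0.7, 0.2)
  ventricle_height <- ifelse(
    has_gap, stats::rlnorm(n, log(ifelse(big_vent, 3, 1)), 0.5), 0)
  # CFR and muzzle length (missing for scans without a measurable muzzle)
  cfr <- stats::rnorm(n, br$cfr_mean[b_idx], br$cfr_sd[b_idx])
  cfr <- pmax(cfr, 0.2)
  muzzle_length <- ifelse(stats::runif(n) < config$cfr_measurable_p,
                          cfr * raw[, "cranial_length"], NA_real_)
  # tumour outcome: logistic on sex x neuter status
  lp <- stats::qlogis(config$baseline_p) +
    log(config$or_exposure) * (neutered & sex == "female") +
    log(config$or_male) * (sex == "male")
  tumour <- stats::runif(n) < stats::plogis(lp)
  other_classes <- c("vascular", "inflammatory", "anomalous", "degenerative",
                     "idiopathic", "metabolic", "traumatic", "normal")
  diagnostic_class <- ifelse(
    tumour, "tumour",
    sample(other_classes, n, replace = TRUE,
           prob = c(0.14, 0.22, 0.18, 0.06, 0.22, 0.04, 0.04, 0.10)))

  records <- data.frame(
    scan_id = scan_id, patient_id = sub("scan", "dog", scan_id),
    body_weight = weight, age = age, sex = sex, neutered = neutered,
    breed = br$breed[b_idx], breed_group = br$breed_group[b_idx],
    clade = br$clade[b_idx], diagnostic_class = diagnostic_class,
    purebred = br$purebred[b_idx],
    raw, head_angle = head_angle, muzzle_length = muzzle_length,
    ventricle_height = ventricle_height,
    stringsAsFactors = FALSE, check.names = FALSE)
  truth <- data.frame(
    scan_id = scan_id, archetype = archetype, breed = br$breed[b_idx],
    sex = sex, neutered = neutered, tumour = tumour,
    stringsAsFactors = FALSE)
  list(cohort = cohort_table(records), truth = truth, profiles = profiles,
       config = config)
}

#' Write the ground-truth table of a synthetic cohort as TSV
#' @param truth the `truth` element of [generate_cohort()] output
#' @param path output file
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
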