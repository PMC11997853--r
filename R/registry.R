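#' Moment-matched lognormal organ-dose sampler
#'
#' Within a stratum, per-organ absorbed doses are modeled as lognormal with
#' parameters chosen so the distribution's mean and SD equal the configured
#' stratum mean and SD (sigma^2 = log(1 + (sd/mean)^2), mu = log(mean) -
#' sigma^2/2). Doses are therefore strictly positive and right-skewed, as in
#' dosimetry practice. With sd = 0 every sample equals the mean.
#'
#' @param n Number of doses to draw.
#' @param mean,sd Target mean and SD in mGy; `mean` must be > 0, `sd` >= 0.
#' @param seed Optional integer seed set before sampling.
#' @return Numeric vector of `n` doses in mGy, all > 0.
#' @export
#' @examples
#' d <- sample_organ_doses(1000, mean = 48, sd = 27.3, seed = 1)
#' mean(d)
sample_organ_doses <- function(n, mean, sd, seed = NULL) {
  if (any(mean <= 0)) stop("dose mean must be > 0")
  if (any(sd < 0)) stop("dose sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sigma2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sigma2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sqrt(sigma2))
}

# lognormal (meanlog, sdlog) matched to arithmetic mean/sd, vectorized
.lnorm_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Default patient demographic mix
#'
#' Probability of a registry patient falling in each (sex, age-group) cell.
#' Calibrated so that, combined with the default exams-per-patient means,
#' about 3.3% of examinations are pediatric and 52% are in female patients,
#' mirroring national utilization.
#'
#' @return Tibble with columns `sex`, `age_group`, `prob` (sums to 1).
#' @export
default_demo_mix <- function() {
  w <- tibble::tribble(
    ~age_group, ~female, ~male,
    "<1", 0.0015, 0.0017,
    "1-4", 0.0027, 0.0036,
    "5-9", 0.0033, 0.0043,
    "10-14", 0.0055, 0.0060,
    "15-17", 0.0065, 0.0067,
    "18-29", 0.0520, 0.0430,
    "30-39", 0.0450, 0.0410,
    "40-49", 0.0660, 0.0570,
    "50-59", 0.0800, 0.0690,
    "60-69", 0.1060, 0.1000,
    "70-79", 0.0890, 0.0840,
    "80-89", 0.0550, 0.0420,
    "90-99", 0.0170, 0.0115
  )
  out <- tidyr::pivot_longer(w, c("female", "male"),
    names_to = "sex", values_to = "prob"
  )
  out$prob <- out$prob / sum(out$prob)
  dplyr::select(out, "sex", "age_group", "prob")
}

#' Default annual examinations per patient
#'
#' Mean CT examinations per imaged patient by sex and age group; means rise
#' from about 1.1 in infants to about 1.7 in the oldest adults.
#'
#' @return Tibble with columns `sex`, `age_group`, `mean_exams`.
#' @export
default_exams_per_patient <- function() {
  w <- tibble::tribble(
    ~age_group, ~female, ~male,
    "<1", 1.12, 1.14,
    "1-4", 1.18, 1.18,
    "5-9", 1.18, 1.18,
    "10-14", 1.18, 1.23,
    "15-17", 1.18, 1.23,
    "18-29", 1.34, 1.41,
    "30-39", 1.34, 1.41,
    "40-49", 1.46, 1.52,
    "50-59", 1.46, 1.52,
    "60-69", 1.56, 1.61,
    "70-79", 1.56, 1.61,
    "80-89", 1.63, 1.66,
    "90-99", 1.63, 1.70
  )
  tidyr::pivot_longer(w, c("female", "male"),
    names_to = "sex", values_to = "mean_exams"
  ) |> dplyr::select("sex", "age_group", "mean_exams")
}

#' Default last-year-of-life probabilities
#'
#' Fraction of examinations performed in the patient's last year of life, by
#' sex and age group; rises from under 1% in young children to roughly 40%
#' past age 90, higher in males, with an exam-weighted overall fraction near
#' 10.6%.
#'
#' @return Tibble with columns `sex`, `age_group`, `eol_prob`.
#' @export
default_eol_prob <- function() {
  w <- tibble::tribble(
    ~age_group, ~female, ~male,
    "<1", 0.020, 0.022,
    "1-4", 0.014, 0.005,
    "5-9", 0.008, 0.008,
    "10-14", 0.008, 0.009,
    "15-17", 0.010, 0.012,
    "18-29", 0.012, 0.016,
    "30-39", 0.018, 0.024,
    "40-49", 0.028, 0.036,
    "50-59", 0.048, 0.062,
    "60-69", 0.075, 0.095,
    "70-79", 0.125, 0.155,
    "80-89", 0.220, 0.270,
    "90-99", 0.351, 0.444
  )
  tidyr::pivot_longer(w, c("female", "male"),
    names_to = "sex", values_to = "eol_prob"
  ) |> dplyr::select("sex", "age_group", "eol_prob")
}

#' Default category mix by sex and age group
#'
#' Conditional probability of each CT category given (sex, age group).
#' Region weights follow national utilization (abdomen/pelvis and head
#' dominate in adults; head dominates in children), split across the dose
#' tiers within each region. Probabilities sum to 1 within each (sex,
#' age-group) cell and every valid stratum has positive probability.
#'
#' @return Tibble with columns `sex`, `age_group`, `category`, `prob`.
#' @export
default_category_mix <- function() {
  keys <- strata_keys()
  adult_region_w <- c(
    abdomen_pelvis = 0.328, head = 0.250, chest = 0.219, spine = 0.083,
    head_neck_combined = 0.031, cardiac = 0.012, full_body = 0.051,
    extremity = 0.026
  )
  child_region_w <- c(
    abdomen_pelvis = 0.225, head = 0.521, chest = 0.090, spine = 0.095,
    head_neck_combined = 0, cardiac = 0.009, full_body = 0.019,
    extremity = 0.041
  )
  # within-region split across the categories available to that life stage
  tier_w <- c(low = 0.18, routine = 0.64, high = 0.18, not_tiered = 1)
  keys |>
    dplyr::mutate(
      region_w = ifelse(.data$life_stage == "adult",
        adult_region_w[.data$body_region], child_region_w[.data$body_region]
      ),
      tier_w = tier_w[.data$dose_tier]
    ) |>
    dplyr::group_by(.data$sex, .data$age_group, .data$body_region) |>
    dplyr::mutate(cat_w = .data$region_w * .data$tier_w / sum(.data$tier_w)) |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::mutate(prob = .data$cat_w / sum(.data$cat_w)) |>
    dplyr::ungroup() |>
    dplyr::select("sex", "age_group", "category", "prob")
}

# organ dose profile (mGy) for an adult routine-dose exam, by body region
.region_dose_profile <- function() {
  prof <- list(
    head = c(
      brain = 45, oral_cavity_pharynx = 9, thyroid = 2.2,
      red_bone_marrow = 3.5, other = 1.2
    ),
    abdomen_pelvis = c(
      stomach = 13, colon = 15, liver = 14, pancreas = 13, kidney = 16,
      bladder = 15, ovary = 13, uterus = 13, prostate = 12, rectum = 14,
      red_bone_marrow = 6, other = 9, lung = 2.5, esophagus = 1.2,
      breast = 1.2
    ),
    chest = c(
      lung = 14, breast = 11, esophagus = 10, thyroid = 7, liver = 5,
      stomach = 4, red_bone_marrow = 4.5, other = 5.5, pancreas = 2.5,
      kidney = 2
    ),
    spine = c(
      red_bone_marrow = 8, esophagus = 5, lung = 4, thyroid = 4,
      stomach = 3, liver = 3, kidney = 3, other = 4
    ),
    head_neck_combined = c(
      brain = 28, thyroid = 16, oral_cavity_pharynx = 16,
      red_bone_marrow = 3, esophagus = 4, other = 3
    ),
    cardiac = c(
      lung = 11, breast = 9, esophagus = 6, liver = 3, stomach = 2.5,
      red_bone_marrow = 3, other = 3.5
    ),
    full_body = c(
      brain = 20, oral_cavity_pharynx = 6, thyroid = 8, lung = 13,
      breast = 10, esophagus = 9, stomach = 13, colon = 14, liver = 13,
      pancreas = 13, kidney = 15, bladder = 14, ovary = 12, uterus = 12,
      prostate = 11, rectum = 13, red_bone_marrow = 7, other = 10
    ),
    extremity = c(red_bone_marrow = 1.2, other = 0.4)
  )
  prof
}

#' Default per-stratum organ-dose parameters
#'
#' Mean and SD of absorbed dose (mGy) for each of the 18 organs in every
#' stratum. Built from a per-region in-beam dose profile scaled by dose tier
#' (low 0.5x, high 1.8x), age (body doses lower in small children, slightly
#' higher in older adults; head doses highest in infants; marrow dose from
#' head CT decreasing with age) and sex (males ~5% higher). Out-of-beam
#' organs receive a small scatter dose. SD is 0.58x the mean, a typical
#' within-stratum coefficient of variation. These are synthetic but
#' magnitude-realistic dosimetry values.
#'
#' @return Tibble with columns `sex`, `age_group`, `category`, `organ`,
#'   `mean`, `sd`.
#' @export
default_dose_params <- function() {
  keys <- strata_keys()
  prof <- .region_dose_profile()
  ag <- age_groups()$age_group
  body_age_f <- stats::setNames(
    c(0.50, 0.55, 0.62, 0.72, 0.85, 0.95, 1.00, 1.00, 1.05, 1.08, 1.10, 1.10, 1.10),
    ag
  )
  head_age_f <- stats::setNames(
    c(1.33, 1.15, 1.06, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    ag
  )
  marrow_head_f <- stats::setNames(
    c(7.6, 5.5, 4.2, 3.2, 2.5, 1.6, 1.4, 1.2, 1.0, 1.0, 1.0, 1.0, 1.0),
    ag
  )
  tier_f <- c(low = 0.5, routine = 1, high = 1.8, not_tiered = 1)
  scatter <- 0.15 # mGy, out-of-beam organs

  rows <- tidyr::expand_grid(keys, organ = organs())
  base <- purrr::map2_dbl(rows$body_region, rows$organ, function(r, o) {
    v <- prof[[r]][o]
    if (is.na(v)) scatter else unname(v)
  })
  head_like <- rows$body_region %in% c("head", "head_neck_combined")
  agef <- ifelse(head_like, head_age_f[rows$age_group], body_age_f[rows$age_group])
  agef <- ifelse(head_like & rows$organ == "red_bone_marrow",
    marrow_head_f[rows$age_group], agef
  )
  sexf <- ifelse(rows$sex == "male", 1.05, 1.0)
  m <- base * tier_f[rows$dose_tier] * agef * sexf
  tibble::tibble(
    sex = rows$sex, age_group = rows$age_group, category = rows$category,
    organ = rows$organ, mean = m, sd = 0.58 * m
  )
}

#' Registry generator configuration
#'
#' Bundles everything [generate_registry()] needs. The defaults mimic the
#' national utilization structure: ~3.3% pediatric exam share, 28.5% of
#' exams multiphase, exams-per-patient means between 1.1 and 1.7, and
#' last-year-of-life fractions rising from under 1% in young children to
#' about 40% past age 90.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param demo_mix,category_mix,dose_params,exams_per_patient,eol_prob
#'   Component tables; see the corresponding `default_*()` functions.
#' @param multiphase_prob Probability an exam is multiphase (descriptive
#'   flag; configured doses are per-exam totals over all phases).
#' @param excluded_probs Named probabilities of exclusion flags
#'   (biopsy_procedure, pet, research).
#' @return A list of class `ctlar_registry_config`.
#' @export
registry_config <- function(n_patients = 50000, seed = 1,
                            demo_mix = default_demo_mix(),
                            category_mix = default_category_mix(),
                            dose_params = default_dose_params(),
                            exams_per_patient = default_exams_per_patient(),
                            eol_prob = default_eol_prob(),
                            multiphase_prob = 0.285,
                            excluded_probs = c(
                              biopsy_procedure = 0.004,
                              pet = 0.002, research = 0.001
                            )) {
  cfg <- list(
    n_patients = n_patients, seed = seed, demo_mix = demo_mix,
    category_mix = category_mix, dose_params = dose_params,
    exams_per_patient = exams_per_patient, eol_prob = eol_prob,
    multiphase_prob = multiphase_prob, excluded_probs = excluded_probs
  )
  validate_registry_config(cfg)
  structure(cfg, class = "ctlar_registry_config")
}

#' @rdname registry_config
#' @param config A registry configuration list.
#' @export
validate_registry_config <- function(config) {
  stopifnot(
    config$n_patients >= 1,
    is.numeric(config$seed),
    all(config$category_mix$prob >= 0),
    all(config$category_mix$prob <= 1),
    config$multiphase_prob >= 0, config$multiphase_prob <= 1,
    all(config$eol_prob$eol_prob >= 0), all(config$eol_prob$eol_prob <= 1),
    all(config$exams_per_patient$mean_exams >= 1)
  )
  sums <- config$category_mix |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(s = sum(.data$prob), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-09)) {
    bad <- sums[abs(sums$s - 1) > 1e-09, ]
    stop(
      "category_mix probabilities must sum to 1 per (sex, age_group); off in ",
      paste(bad$sex, bad$age_group, collapse = ", ")
    )
  }
  if (abs(sum(config$demo_mix$prob) - 1) > 1e-09) {
    stop("demo_mix probabilities must sum to 1")
  }
  invisible(config)
}

#' Generate an exam-level synthetic CT registry
#'
#' Simulates `n_patients` patients and their CT examinations. Each patient
#' draws a (sex, age-group) cell from the demographic mix, an exact age
#' uniformly within the group, an exam count of 1 + Poisson(mean - 1)
#' (median 1 across all groups), and a last-year-of-life flag. Each exam
#' draws a CT category from the cell's category mix, a multiphase flag, an
#' infrequent exclusion flag, and per-organ doses from the stratum's
#' moment-matched lognormal dose distributions. Bit-reproducible given
#' `config$seed`.
#'
#' @param config A [registry_config()].
#' @return A tibble with one row per examination: `exam_id`, `patient_id`,
#'   `age_years`, `sex`, `age_group`, `category`, `multiphase`,
#'   `last_year_of_life`, `excluded_reason` and 18 dose columns
#'   `dose_<organ>_mGy`.
#' @export
generate_registry <- function(config) {
  validate_registry_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  demo <- config$demo_mix
  cell <- sample.int(nrow(demo), n, replace = TRUE, prob = demo$prob)
  ag <- age_groups()
  ag_idx <- match(demo$age_group[cell], ag$age_group)
  patients <- tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    sex = demo$sex[cell],
    age_group = demo$age_group[cell],
    age_years = ag$age_min[ag_idx] +
      floor(stats::runif(n) * (ag$age_max[ag_idx] - ag$age_min[ag_idx] + 1))
  )
  epp <- dplyr::left_join(patients, config$exams_per_patient,
    by = c("sex", "age_group")
  )
  if (any(is.na(epp$mean_exams))) stop("exams_per_patient missing a (sex, age_group) cell")
  patients$n_exams <- 1L + stats::rpois(n, epp$mean_exams - 1)
  eol <- dplyr::left_join(patients, config$eol_prob, by = c("sex", "age_group"))
  if (any(is.na(eol$eol_prob))) stop("eol_prob missing a (sex, age_group) cell")
  patients$last_year_of_life <- stats::runif(n) < eol$eol_prob

  exams <- patients[rep(seq_len(n), patients$n_exams), ] |>
    dplyr::select(-"n_exams")
  m <- nrow(exams)
  exams$exam_id <- sprintf("E%07d", seq_len(m))

  # category per exam: sample within each (sex, age_group) cell
  mix <- config$category_mix
  exams <- exams |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::mutate(category = {
      cm <- mix[mix$sex == .data$sex[1] & mix$age_group == .data$age_group[1], ]
      if (nrow(cm) == 0) {
        stop("category_mix missing cell (", .data$sex[1], ", ", .data$age_group[1], ")")
      }
      sample(cm$category, dplyr::n(), replace = TRUE, prob = cm$prob)
    }) |>
    dplyr::ungroup()

  exams$multiphase <- stats::runif(m) < config$multiphase_prob
  ep <- config$excluded_probs
  u <- stats::runif(m)
  exams$excluded_reason <- dplyr::case_when(
    u < ep[["biopsy_procedure"]] ~ "biopsy_procedure",
    u < ep[["biopsy_procedure"]] + ep[["pet"]] ~ "pet",
    u < sum(ep) ~ "research",
    TRUE ~ "none"
  )

  # per-organ doses, vectorized over exams via a dose-parameter join
  dp <- config$dose_params
  for (org in organs()) {
    dpo <- dp[dp$organ == org, c("sex", "age_group", "category", "mean", "sd")]
    j <- dplyr::left_join(
      exams[, c("sex", "age_group", "category")], dpo,
      by = c("sex", "age_group", "category")
    )
    if (anyNA(j$mean)) {
      miss <- j[is.na(j$mean), ][1, ]
      stop(
        "dose_params missing for stratum (", miss$sex, ", ", miss$age_group,
        ", ", miss$category, "), organ ", org
      )
    }
    lp <- .lnorm_params(j$mean, j$sd)
    exams[[paste0("dose_", org, "_mGy")]] <-
      stats::rlnorm(m, lp$meanlog, lp$sdlog)
  }

  dplyr::select(
    exams, "exam_id", "patient_id", "age_years", "sex", "age_group",
    "category", "multiphase", "last_year_of_life", "excluded_reason",
    dplyr::starts_with("dose_")
  )
}

#' Read or write an exam-level registry as CSV
#'
#' Fixed column order and header: identifiers, demographics, category, the
#' flags, then 18 `dose_<organ>_mGy` columns.
#'
#' @param records Registry tibble from [generate_registry()].
#' @param path File path.
#' @return `write_registry_csv()` returns `path` invisibly;
#'   `read_registry_csv()` the registry tibble.
#' @export
write_registry_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_registry_csv
#' @export
read_registry_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
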