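#' CT category vocabulary
#'
#' The default vocabulary of 26 CT examination categories, each a combination
#' of body region and dose tier reflecting the clinical indication (for
#' example, low-dose abdomen for kidney stones versus high-dose abdomen for
#' cancer staging). 18 categories apply to adults, 13 to children, and 5 are
#' shared, so the names enumerate 26 distinct categories. The names are
#' configuration, not a contract: downstream code keys on the `category`
#' column and the `body_region`/`applicability` attributes only.
#'
#' @return A tibble with columns `category`, `body_region` (one of
#'   `r paste(body_regions(), collapse = ", ")`), `dose_tier`
#'   (low/routine/high/not_tiered) and `applicability` (adult/child/both).
#' @export
#' @examples
#' ct_categories()
ct_categories <- function() {
  tribble_cat <- function(category, body_region, dose_tier, applicability) {
    tibble::tibble(
      category = category, body_region = body_region,
      dose_tier = dose_tier, applicability = applicability
    )
  }
  dplyr::bind_rows(
    # shared between adults and children (5)
    tribble_cat("head_routine", "head", "routine", "both"),
    tribble_cat("abdomen_pelvis_routine", "abdomen_pelvis", "routine", "both"),
    tribble_cat("chest_routine", "chest", "routine", "both"),
    tribble_cat("spine_cervical", "spine", "routine", "both"),
    tribble_cat("extremity_upper", "extremity", "not_tiered", "both"),
    # adult only (13)
    tribble_cat("abdomen_pelvis_low", "abdomen_pelvis", "low", "adult"),
    tribble_cat("abdomen_pelvis_high", "abdomen_pelvis", "high", "adult"),
    tribble_cat("head_low", "head", "low", "adult"),
    tribble_cat("head_high", "head", "high", "adult"),
    tribble_cat("chest_low", "chest", "low", "adult"),
    tribble_cat("chest_high", "chest", "high", "adult"),
    tribble_cat("spine_thoracolumbar", "spine", "routine", "adult"),
    tribble_cat("head_neck_combined", "head_neck_combined", "routine", "adult"),
    tribble_cat("cardiac_calcium", "cardiac", "low", "adult"),
    tribble_cat("cardiac_angiography", "cardiac", "routine", "adult"),
    tribble_cat("full_body_routine", "full_body", "routine", "adult"),
    tribble_cat("full_body_high", "full_body", "high", "adult"),
    tribble_cat("extremity_lower", "extremity", "not_tiered", "adult"),
    # child only (8)
    tribble_cat("head_low_peds", "head", "low", "child"),
    tribble_cat("abdomen_pelvis_low_peds", "abdomen_pelvis", "low", "child"),
    tribble_cat("chest_low_peds", "chest", "low", "child"),
    tribble_cat("spine_peds", "spine", "routine", "child"),
    tribble_cat("cardiac_peds", "cardiac", "routine", "child"),
    tribble_cat("full_body_peds", "full_body", "routine", "child"),
    tribble_cat("extremity_lower_peds", "extremity", "not_tiered", "child"),
    tribble_cat("airway_peds", "chest", "low", "child")
  )
}

#' @rdname ct_categories
#' @export
body_regions <- function() {
  c(
    "abdomen_pelvis", "head", "chest", "spine", "head_neck_combined",
    "cardiac", "full_body", "extremity"
  )
}

#' Age groups used for stratification
#'
#' Thirteen age groups: five pediatric (<1, 1-4, 5-9, 10-14, 15-17) and
#' eight adult decades (18-29 through 90-99). Combined with the category
#' vocabulary and two sexes this yields the 418 analysis strata
#' (288 adult, 130 child).
#'
#' @return A tibble with columns `age_group`, `age_min`, `age_max`,
#'   `age_mid` (midpoint used as the age at exposure for a stratum) and
#'   `life_stage` (child/adult).
#' @export
age_groups <- function() {
  tb <- tibble::tibble(
    age_group = c(
      "<1", "1-4", "5-9", "10-14", "15-17",
      "18-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80-89", "90-99"
    ),
    age_min = c(0, 1, 5, 10, 15, 18, 30, 40, 50, 60, 70, 80, 90),
    age_max = c(0, 4, 9, 14, 17, 29, 39, 49, 59, 69, 79, 89, 99)
  )
  tb$age_mid <- (tb$age_min + tb$age_max + 1) / 2
  tb$life_stage <- ifelse(tb$age_max < 18, "child", "adult")
  tb
}

#' @rdname age_groups
#' @export
sexes <- function() c("female", "male")

#' Age group label for an age in years
#'
#' @param age_years Integer vector of ages, 0-99.
#' @return Character vector of age-group labels.
#' @export
age_group_of <- function(age_years) {
  stopifnot(all(age_years >= 0 & age_years <= 99))
  ag <- age_groups()
  idx <- findInterval(age_years, ag$age_min)
  ag$age_group[idx]
}

#' Enumerate the default analysis strata
#'
#' Crosses sex, age group, and CT category, keeping only combinations whose
#' category applicability matches the age group's life stage. The default
#' vocabulary yields 288 adult strata (18 categories x 8 age groups x 2
#' sexes) and 130 child strata (13 x 5 x 2), 418 in all.
#'
#' @param categories Category vocabulary, as from [ct_categories()].
#' @return A tibble with one row per stratum: `sex`, `age_group`,
#'   `category`, plus the category and age-group attributes.
#' @export
#' @examples
#' nrow(strata_keys()) # 418
strata_keys <- function(categories = ct_categories()) {
  tidyr::expand_grid(
    sex = sexes(),
    age_groups(),
    categories
  ) |>
    dplyr::filter(
      .data$applicability == "both" |
        (.data$applicability == "adult" & .data$life_stage == "adult") |
        (.data$applicability == "child" & .data$life_stage == "child")
    ) |>
    dplyr::select(
      "sex", "age_group", "category", "body_region", "dose_tier",
      "applicability", "age_min", "age_max", "age_mid", "life_stage"
    ) |>
    dplyr::arrange(.data$sex, .data$age_min, .data$category)
}

#' Organ and cancer-site vocabularies
#'
#' Eighteen organs receive a dose per examination; each maps to one of the
#' eighteen modeled cancer sites (red bone marrow carries the leukemia risk;
#' the remainder organ carries the pooled "other and ill-defined sites"
#' risk).
#'
#' @return `organs()` and `cancer_sites()` return character vectors;
#'   `organ_site_map()` a tibble with columns `organ`, `site`.
#' @export
organs <- function() {
  c(
    "brain", "thyroid", "lung", "breast", "stomach", "colon", "liver",
    "pancreas", "kidney", "bladder", "ovary", "uterus", "prostate",
    "esophagus", "oral_cavity_pharynx", "rectum", "red_bone_marrow", "other"
  )
}

#' @rdname organs
#' @export
cancer_sites <- function() {
  c(
    "brain_cns", "thyroid", "lung", "breast", "stomach", "colon", "liver",
    "pancreas", "kidney", "bladder", "ovary", "uterus", "prostate",
    "esophagus", "oral_cavity_pharynx", "rectum", "leukemia", "other"
  )
}

#' @rdname organs
#' @export
organ_site_map <- function() {
  tibble::tibble(organ = organs(), site = cancer_sites())
}

#' Sites restricted to one sex
#'
#' @return Named character vector mapping site to the sex it applies to;
#'   sites absent from the map apply to both sexes. Breast is configured
#'   female-only, following the risk models in use.
#' @export
sex_specific_sites <- function() {
  c(
    prostate = "male", ovary = "female", uterus = "female",
    breast = "female"
  )
}
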