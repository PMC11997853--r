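#' Generate a synthetic sex-specific life table
#'
#' Builds survival-from-birth S(a) for integer ages 0-100 from a
#' Gompertz-Makeham hazard h(a) = makeham + gompertz_scale * exp(gompertz_rate
#' * a), a standard parametric stand-in for a national life table. Survival
#' is the discrete product S(a) = exp(-sum_{k<a} h(k)), so a constant hazard
#' h gives exactly S(a) = exp(-h*a).
#'
#' @param sex "female" or "male".
#' @param gompertz_scale,gompertz_rate,makeham Hazard parameters (all >= 0);
#'   defaults give adult life expectancy and S(100) in the range of a
#'   contemporary US population, with males dying slightly faster.
#' @return A tibble with columns `sex`, `age` (0-100) and `survival`,
#'   satisfying S(0) = 1, S non-increasing, S(100) > 0.
#' @export
#' @examples
#' lt <- generate_life_table("female")
#' lt$survival[lt$age == 0] # 1
generate_life_table <- function(sex,
                                gompertz_scale = if (sex == "male") 4.2e-05 else 2.8e-05,
                                gompertz_rate = 0.094,
                                makeham = if (sex == "male") 9e-04 else 6e-04) {
  sex <- match.arg(sex, sexes())
  stopifnot(gompertz_scale >= 0, gompertz_rate >= 0, makeham >= 0)
  ages <- 0:100
  hazard <- makeham + gompertz_scale * exp(gompertz_rate * ages)
  cumhaz <- c(0, cumsum(hazard))[seq_along(ages)]
  tibble::tibble(sex = sex, age = ages, survival = exp(-cumhaz))
}

#' Default two-sex life table
#'
#' @return Tibble stacking [generate_life_table()] for both sexes.
#' @export
default_life_tables <- function() {
  dplyr::bind_rows(generate_life_table("female"), generate_life_table("male"))
}

#' Generate synthetic baseline cancer incidence for one site and sex
#'
#' Produces age-specific baseline incidence rates lambda(a) in cases per
#' person-year. Solid sites use a power-law-in-age template
#' rate60 * ((a + 1) / 61)^exponent; leukemia adds a childhood peak
#' child_peak * exp(-a / 6) on top of the power law. Sites restricted to one
#' sex (prostate, ovary, uterus, breast) return zero rates for the other sex.
#'
#' @param site One of [cancer_sites()].
#' @param sex "female" or "male".
#' @param rate60 Incidence at age 60 (per person-year) for the power-law
#'   component.
#' @param exponent Power-law age exponent (>= 0); 0 gives a flat rate.
#' @param child_peak Added rate at age 0 for the childhood-peaked component
#'   (used for leukemia; default 0 elsewhere).
#' @return Tibble with columns `site`, `sex`, `age` (0-100), `rate`.
#' @export
generate_baseline_incidence <- function(site, sex, rate60 = 1e-03,
                                        exponent = 4, child_peak = 0) {
  if (!site %in% cancer_sites()) {
    stop(
      "unknown site '", site, "'; valid sites: ",
      paste(cancer_sites(), collapse = ", ")
    )
  }
  sex <- match.arg(sex, sexes())
  stopifnot(rate60 >= 0, exponent >= 0, child_peak >= 0)
  ages <- 0:100
  rate <- rate60 * ((ages + 1) / 61)^exponent + child_peak * exp(-ages / 6)
  restricted <- sex_specific_sites()
  if (site %in% names(restricted) && restricted[[site]] != sex) {
    rate <- rep(0, length(ages))
  }
  tibble::tibble(site = site, sex = sex, age = ages, rate = rate)
}

#' Default baseline incidence table for all sites and sexes
#'
#' Site-level magnitudes are loosely ordered like US incidence (breast,
#' prostate, lung large; rarer sites small); leukemia uses the
#' childhood-peaked template. These are synthetic stand-ins with realistic
#' orders of magnitude, not SEER rates.
#'
#' @return Tibble with columns `site`, `sex`, `age`, `rate` covering the 18
#'   sites, both sexes, ages 0-100.
#' @export
default_baseline_incidence <- function() {
  params <- tibble::tribble(
    ~site, ~rate60, ~exponent, ~child_peak,
    "brain_cns", 1.2e-04, 1.5, 2e-05,
    "thyroid", 2.0e-04, 0.5, 0,
    "lung", 1.4e-03, 5.0, 0,
    "breast", 2.2e-03, 2.5, 0,
    "stomach", 1.5e-04, 4.0, 0,
    "colon", 9.0e-04, 4.0, 0,
    "liver", 2.0e-04, 4.0, 0,
    "pancreas", 2.5e-04, 4.5, 0,
    "kidney", 3.5e-04, 3.0, 0,
    "bladder", 4.5e-04, 5.0, 0,
    "ovary", 2.5e-04, 2.5, 0,
    "uterus", 5.0e-04, 3.0, 0,
    "prostate", 2.5e-03, 5.0, 0,
    "esophagus", 1.0e-04, 4.5, 0,
    "oral_cavity_pharynx", 2.5e-04, 3.0, 0,
    "rectum", 3.0e-04, 3.5, 0,
    "leukemia", 2.5e-04, 3.0, 6e-05,
    "other", 8.0e-04, 3.5, 0
  )
  purrr::pmap_dfr(params, function(site, rate60, exponent, child_peak) {
    dplyr::bind_rows(
      generate_baseline_incidence(site, "female", rate60, exponent, child_peak),
      generate_baseline_incidence(site, "male", rate60, exponent, child_peak)
    )
  })
}
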