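#' Default site- and sex-specific risk-model coefficients
#'
#' One row per (site, sex) with the coefficients of the excess relative
#' (ERR) and excess absolute (EAR) risk models, the transfer weight mixing
#' them, and the lognormal spread used for coefficient uncertainty. Values
#' for the eleven classical sites (stomach, colon, liver, lung, breast,
#' uterus, ovary, prostate, bladder, thyroid, leukemia) are transcribed by
#' the package authors from the BEIR VII preferred models; the six
#' additional sites (oral cavity/pharynx, esophagus, rectum, pancreas,
#' kidney, brain/CNS) and the residual "other" category use the pooled
#' residual-site coefficients. All coefficients are editable configuration,
#' not assertions: pass a modified tibble to the risk functions to use other
#' values.
#'
#' Columns: `beta_err` (ERR per Gy at reference ages), `beta_ear` (EAR per
#' 10^4 person-year-Gy), `gamma_err`/`eta_err` and `gamma_ear`/`eta_ear`
#' (age modifiers per model), `theta` (leukemia dose curvature, 0 for solid
#' sites), `delta_*`/`phi_*` (leukemia time-since-exposure modifiers),
#' `transfer_weight` (weight on the ERR transfer; default 0.7, lung 0.3,
#' breast 0 = EAR-only, thyroid 1 = ERR-only), `beta_gsd` (geometric SD of
#' the lognormal coefficient-uncertainty multiplier), `model_class`
#' (solid/leukemia) and `latency_group` (solid/thyroid/leukemia). Sites not
#' applicable to a sex (prostate in females, etc.) carry zero betas.
#'
#' @return A tibble with 36 rows (18 sites x 2 sexes).
#' @export
default_risk_config <- function() {
  solid <- tibble::tribble(
    ~site, ~beta_err_m, ~beta_err_f, ~beta_ear_m, ~beta_ear_f, ~transfer_weight,
    "stomach", 0.21, 0.48, 4.9, 4.9, 0.7,
    "colon", 0.63, 0.43, 3.2, 1.6, 0.7,
    "liver", 0.32, 0.32, 2.2, 1.0, 0.7,
    "lung", 0.32, 1.40, 2.3, 3.4, 0.3,
    "breast", 0, 0.51, 0, 9.4, 0.0,
    "prostate", 0.12, 0, 0.11, 0, 0.7,
    "uterus", 0, 0.055, 0, 1.2, 0.7,
    "ovary", 0, 0.38, 0, 0.7, 0.7,
    "bladder", 0.50, 1.65, 1.2, 0.75, 0.7,
    "thyroid", 0.53, 1.05, 0, 0, 1.0,
    "oral_cavity_pharynx", 0.27, 0.45, 1.2, 1.3, 0.7,
    "esophagus", 0.27, 0.45, 1.2, 1.3, 0.7,
    "rectum", 0.27, 0.45, 1.2, 1.3, 0.7,
    "pancreas", 0.27, 0.45, 1.2, 1.3, 0.7,
    "kidney", 0.27, 0.45, 1.2, 1.3, 0.7,
    "brain_cns", 0.27, 0.45, 1.2, 1.3, 0.7,
    "other", 0.27, 0.45, 1.2, 1.3, 0.7
  )
  solid_long <- solid |>
    tidyr::pivot_longer(
      cols = -c("site", "transfer_weight"),
      names_to = c("coef", "sex"), names_pattern = "(beta_err|beta_ear)_(m|f)"
    ) |>
    tidyr::pivot_wider(names_from = "coef", values_from = "value") |>
    dplyr::mutate(
      sex = ifelse(.data$sex == "f", "female", "male"),
      # thyroid follows its own ERR age model; others the common solid values
      gamma_err = ifelse(.data$site == "thyroid", -0.83, -0.3),
      eta_err = ifelse(.data$site == "thyroid", 0, -1.4),
      gamma_ear = -0.41,
      eta_ear = ifelse(.data$site == "lung", 5.2, 2.8),
      theta = 0, delta_err = 0, phi_err = 0, delta_ear = 0, phi_ear = 0,
      beta_gsd = 1.3,
      model_class = "solid",
      latency_group = ifelse(.data$site == "thyroid", "thyroid", "solid")
    )
  leuk <- tidyr::expand_grid(site = "leukemia", sex = sexes()) |>
    dplyr::mutate(
      beta_err = ifelse(.data$sex == "male", 1.1, 1.2),
      beta_ear = ifelse(.data$sex == "male", 1.62, 0.93),
      transfer_weight = 0.7,
      gamma_err = -0.40, eta_err = 0,
      gamma_ear = 0.29, eta_ear = 0,
      theta = 0.87,
      delta_err = -0.48, phi_err = 0.42,
      delta_ear = 0.0, phi_ear = 0.56,
      beta_gsd = 1.3,
      model_class = "leukemia", latency_group = "leukemia"
    )
  out <- dplyr::bind_rows(solid_long, leuk)
  # zero out sex-restricted sites in the non-applicable sex
  restricted <- sex_specific_sites()
  bad <- out$site %in% names(restricted) & out$sex != restricted[out$site]
  out$beta_err[bad] <- 0
  out$beta_ear[bad] <- 0
  dplyr::arrange(out, .data$site, .data$sex)
}

#' Default latency phase-in configuration
#'
#' For each latency group, the triangular distribution of the ramp midpoint
#' mu and the 5-95% phase-in window at the modal midpoint: solid cancers
#' other than thyroid T(5, 7.5, 10) over 4.0-11.0 years, thyroid T(3, 5, 7)
#' over 2.5-7.6 years, leukemia T(2, 2.25, 2.5) over 0.4-4.1 years.
#'
#' @return Tibble with columns `group`, `tri_min`, `tri_mode`, `tri_max`,
#'   `window_start`, `window_end`.
#' @export
default_latency_config <- function() {
  tibble::tribble(
    ~group, ~tri_min, ~tri_mode, ~tri_max, ~window_start, ~window_end,
    "solid", 5, 7.5, 10, 4.0, 11.0,
    "thyroid", 3, 5, 7, 2.5, 7.6,
    "leukemia", 2, 2.25, 2.5, 0.4, 4.1
  )
}

#' Default DDREF configuration
#'
#' The dose and dose-rate effectiveness factor divides solid-cancer risk at
#' low doses; leukemia (already linear-quadratic) is not divided. Median 1.5
#' with 90% uncertainty interval (1.1, 2.3), represented as a lognormal with
#' median 1.5 and log-scale sigma chosen by least squares against the two
#' interval endpoints. The printed interval is not exactly log-symmetric
#' around 1.5, so no lognormal reproduces both endpoints; the fitted sigma
#' minimizes the total squared endpoint error.
#'
#' @return List with `median`, `interval90`, `sigma`, `applies_to`.
#' @export
default_ddref_config <- function() {
  list(
    median = 1.5, interval90 = c(1.1, 2.3),
    sigma = ddref_lognormal_sigma(1.5, c(1.1, 2.3)),
    applies_to = "solid"
  )
}

#' @rdname default_ddref_config
#' @param median Lognormal median.
#' @param interval90 Target 90% interval (5th and 95th percentiles).
#' @export
ddref_lognormal_sigma <- function(median = 1.5, interval90 = c(1.1, 2.3)) {
  stopifnot(interval90[1] < median, median < interval90[2])
  z <- stats::qnorm(0.95)
  obj <- function(s) {
    (median * exp(-z * s) - interval90[1])^2 +
      (median * exp(z * s) - interval90[2])^2
  }
  stats::optimize(obj, c(1e-04, 2))$minimum
}
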