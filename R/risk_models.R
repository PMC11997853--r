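#' BEIR VII-style solid-cancer excess relative risk
#'
#' ERR(D, e, a) = beta * D * exp(gamma * estar) * (a / 60)^eta with
#' estar = (min(e, 30) - 30) / 10, the preferred solid-cancer form: risk is
#' linear in dose, declines with age at exposure up to age 30 (gamma < 0),
#' and varies as a power of attained age relative to age 60.
#'
#' @param dose_gy Absorbed organ dose in Gy (>= 0).
#' @param age_exposure Age at exposure e, 0-100 years.
#' @param age_attained Attained age a, e <= a <= 100.
#' @param beta ERR per Gy at the reference ages (e >= 30, a = 60).
#' @param gamma Per-decade age-at-exposure log-linear modifier.
#' @param eta Attained-age power exponent.
#' @return Dimensionless excess relative risk, >= 0 for beta >= 0.
#' @export
#' @examples
#' err_solid(0.1, e = 10, a = 60, beta = 1, gamma = 0, eta = 0) # 0.1
err_solid <- function(dose_gy, age_exposure, age_attained, beta,
                      gamma = -0.3, eta = -1.4) {
  check_exposure_ages(dose_gy, age_exposure, age_attained)
  estar <- (pmin(age_exposure, 30) - 30) / 10
  beta * dose_gy * exp(gamma * estar) * (age_attained / 60)^eta
}

#' BEIR VII-style solid-cancer excess absolute risk
#'
#' Same functional form as [err_solid()] but scaled as excess cases per
#' 10^4 person-years per Gy; gamma and eta take the EAR-model values.
#'
#' @inheritParams err_solid
#' @param beta EAR per 10^4 person-year-Gy at the reference ages.
#' @return Excess cases per 10^4 person-years.
#' @export
ear_solid <- function(dose_gy, age_exposure, age_attained, beta,
                      gamma = -0.41, eta = 2.8) {
  check_exposure_ages(dose_gy, age_exposure, age_attained)
  estar <- (pmin(age_exposure, 30) - 30) / 10
  beta * dose_gy * exp(gamma * estar) * (age_attained / 60)^eta
}

check_exposure_ages <- function(dose_gy, age_exposure, age_attained) {
  if (any(dose_gy < 0)) stop("dose must be >= 0")
  if (any(age_exposure < 0) || any(age_attained > 100)) {
    stop("ages must lie in [0, 100]")
  }
  if (any(age_attained < age_exposure)) {
    stop("attained age must be >= age at exposure")
  }
  invisible(TRUE)
}

#' Leukemia excess risk (linear-quadratic in dose)
#'
#' excess = beta * D * (1 + theta * D) *
#'   exp(gamma * estar + delta * log(t / 25) + phi * estar * log(t / 25)),
#' with estar = (min(e, 30) - 30) / 10 and t the time since exposure in
#' years. The same form serves the relative and absolute leukemia models
#' with their respective coefficient sets; theta > 0 gives upward dose
#' curvature (super-linearity).
#'
#' @param dose_gy Absorbed red-bone-marrow dose in Gy (>= 0).
#' @param age_exposure Age at exposure in years.
#' @param t_since Years since exposure (> 0).
#' @param beta Linear coefficient (per Gy, or per 10^4 person-year-Gy).
#' @param theta Dose-curvature per Gy.
#' @param gamma Per-decade age-at-exposure modifier.
#' @param delta Log time-since-exposure modifier.
#' @param phi Interaction of age at exposure with log time.
#' @return Excess risk on the scale of `beta`.
#' @export
excess_leukemia <- function(dose_gy, age_exposure, t_since, beta,
                            theta = 0.87, gamma = -0.4, delta = -0.48,
                            phi = 0.42) {
  if (any(dose_gy < 0)) stop("dose must be >= 0")
  if (any(t_since <= 0)) stop("time since exposure must be > 0")
  estar <- (pmin(age_exposure, 30) - 30) / 10
  lt <- log(t_since / 25)
  beta * dose_gy * (1 + theta * dose_gy) *
    exp(gamma * estar + delta * lt + phi * estar * lt)
}

#' Latency phase-in weight
#'
#' Excess risk is phased in smoothly after exposure: a logistic ramp in time
#' since exposure with midpoint `mu` (weight 0.5 at t = mu) and steepness
#' set so the weight rises from 5% to 95% across the group's phase-in
#' window when `mu` sits at its modal value. Windows: solid cancers 4.0-11.0
#' years, thyroid 2.5-7.6, leukemia 0.4-4.1; `mu` is sampled per
#' uncertainty draw from the group's triangular distribution.
#'
#' @param t_since Years since exposure (>= 0); vector.
#' @param mu Ramp midpoint in years (scalar or vector, recycled against
#'   `t_since` by [outer()] when both have length > 1 is not supported; pass
#'   one vector at a time).
#' @param window Length-2 numeric, the (start, end) of the 5-95% phase-in
#'   window at the modal midpoint.
#' @return Weights in (0, 1), non-decreasing in `t_since`.
#' @export
#' @examples
#' latency_weight(7.5, mu = 7.5, window = c(4, 11)) # 0.5
latency_weight <- function(t_since, mu, window) {
  stopifnot(length(window) == 2, window[2] > window[1], all(t_since >= 0))
  k <- 2 * log(19) / (window[2] - window[1])
  stats::plogis(k * (t_since - mu))
}

# latency weights as a length(t) x length(mu) matrix (draw-vectorized)
latency_weight_matrix <- function(t_since, mu, window) {
  k <- 2 * log(19) / (window[2] - window[1])
  stats::plogis(k * outer(t_since, mu, "-"))
}
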