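# Shared fixtures: tiny configs and analytically tractable model inputs.

# life table with S(a) = exp(-h * a) for both sexes (h = 0 gives S == 1)
const_hazard_life_table <- function(h = 0) {
  dplyr::bind_rows(
    generate_life_table("female", gompertz_scale = 0, gompertz_rate = 0, makeham = h),
    generate_life_table("male", gompertz_scale = 0, gompertz_rate = 0, makeham = h)
  )
}

# constant baseline incidence for every site, sex and age
const_baseline <- function(rate = 0.001) {
  tidyr::expand_grid(site = cancer_sites(), sex = sexes(), age = 0:100) |>
    dplyr::mutate(rate = rate)
}

# default risk config with all betas zeroed, then selected sites re-enabled.
# overrides: named list site -> list(beta_err=, beta_ear=, gamma_err=, ...)
zeroed_risk_config <- function(overrides = list()) {
  rc <- default_risk_config()
  rc$beta_err <- 0
  rc$beta_ear <- 0
  for (site in names(overrides)) {
    i <- which(rc$site == site)
    for (f in names(overrides[[site]])) rc[[f]][i] <- overrides[[site]][[f]]
  }
  rc
}

# solid-only variant of the default config (leukemia switched off)
solid_only_config <- function() {
  rc <- default_risk_config()
  i <- rc$site == "leukemia"
  rc$beta_err[i] <- 0
  rc$beta_ear[i] <- 0
  rc
}

# a draw tibble with every multiplier 1 and explicit ddref / latency midpoints;
# mu = -1000 pushes the logistic latency weight to 1 for all t >= 0
fixed_draw <- function(risk_config = default_risk_config(), ddref = 1, mu = -1000) {
  d <- central_draw(risk_config)
  d$ddref <- ddref
  d$mu_solid <- mu
  d$mu_thyroid <- mu
  d$mu_leukemia <- mu
  d
}

# minimal stratum-summary tibble: one row per stratum with all organ doses
# equal to dose_mgy (a scalar or vector recycled over strata)
toy_summary <- function(sex = "female", age_group = "50-59",
                        category = "abdomen_pelvis_routine", dose_mgy = 10,
                        n_exams = 100) {
  n <- max(length(sex), length(age_group), length(category), length(dose_mgy))
  tb <- tibble::tibble(
    sex = rep_len(sex, n), age_group = rep_len(age_group, n),
    category = rep_len(category, n),
    n_exams = rep_len(n_exams, n)
  )
  tb$proportion <- tb$n_exams / sum(tb$n_exams)
  for (org in organs()) {
    tb[[paste0("dose_mean_", org)]] <- rep_len(dose_mgy, n)
    tb[[paste0("dose_sd_", org)]] <- 0
  }
  tb
}

# hand-built exam records (doses constant per record unless given)
toy_records <- function(n, sex = "female", age_years = 55,
                        category = "abdomen_pelvis_routine", dose = 10,
                        patient_id = NULL, excluded_reason = "none") {
  tb <- tibble::tibble(
    exam_id = sprintf("E%05d", seq_len(n)),
    patient_id = if (is.null(patient_id)) sprintf("P%05d", seq_len(n)) else rep_len(patient_id, n),
    age_years = rep_len(age_years, n),
    sex = rep_len(sex, n),
    age_group = age_group_of(rep_len(age_years, n)),
    category = rep_len(category, n),
    multiphase = FALSE,
    last_year_of_life = FALSE,
    excluded_reason = rep_len(excluded_reason, n)
  )
  for (org in organs()) tb[[paste0("dose_", org, "_mGy")]] <- rep_len(dose, n)
  tb
}

# independent straight-line LAR oracle: direct annual summation, no shared
# code with .lar_unit. Handles one draw (scalars ddref, mu, multipliers).
lar_oracle <- function(dose_gy, e, sex, site, life_table, baseline,
                       risk_config, latency_config,
                       ddref = 1, mu = NULL, bmult_err = 1, bmult_ear = 1) {
  rc <- risk_config[risk_config$site == site & risk_config$sex == sex, ]
  lg <- latency_config[latency_config$group == rc$latency_group, ]
  if (is.null(mu)) mu <- lg$tri_mode
  lt <- life_table[life_table$sex == sex, ]
  bl <- baseline[baseline$site == site & baseline$sex == sex, ]
  s_e <- approx(lt$age, lt$survival, xout = e)$y
  k <- 2 * log(19) / (lg$window_end - lg$window_start)
  estar <- (min(e, 30) - 30) / 10
  total <- 0
  a <- floor(e) + 1
  while (a <= 100) {
    t_since <- a - e
    wlat <- 1 / (1 + exp(-k * (t_since - mu)))
    s_ratio <- lt$survival[lt$age == a] / s_e
    lam <- bl$rate[bl$age == a]
    if (rc$model_class == "solid") {
      err <- rc$beta_err * dose_gy * exp(rc$gamma_err * estar) * (a / 60)^rc$eta_err
      ear <- rc$beta_ear * dose_gy * exp(rc$gamma_ear * estar) * (a / 60)^rc$eta_ear
      m <- (rc$transfer_weight * bmult_err * err * lam +
        (1 - rc$transfer_weight) * bmult_ear * ear / 1e4) / ddref
    } else {
      lt_mod <- log(t_since / 25)
      err <- rc$beta_err * dose_gy * (1 + rc$theta * dose_gy) *
        exp(rc$gamma_err * estar + rc$delta_err * lt_mod + rc$phi_err * estar * lt_mod)
      ear <- rc$beta_ear * dose_gy * (1 + rc$theta * dose_gy) *
        exp(rc$gamma_ear * estar + rc$delta_ear * lt_mod + rc$phi_ear * estar * lt_mod)
      m <- rc$transfer_weight * bmult_err * err * lam +
        (1 - rc$transfer_weight) * bmult_ear * ear / 1e4
    }
    total <- total + wlat * m * s_ratio
    a <- a + 1
  }
  total
}
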