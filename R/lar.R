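# Per-unit-dose LAR for one (site, sex, exposure age), vectorized over draws.
# Returns U such that LAR(D) = D * U for solid sites and D * (1 + theta * D)
# * U for leukemia. U_d combines the ERR transfer (against baseline rates)
# and the EAR transfer, weighted by the transfer weight, survival-adjusted,
# latency-weighted, and (solid only) divided by the draw's DDREF.
.lar_unit <- function(site, sex, age_exposure, life_table, baseline,
                      risk_config, latency_config, draws) {
  rc <- risk_config[risk_config$site == site & risk_config$sex == sex, ]
  if (nrow(rc) != 1) stop("risk_config must have one row for (", site, ", ", sex, ")")
  n <- nrow(draws)
  e <- age_exposure
  a <- seq(floor(e) + 1, 100)
  if (floor(e) + 1 > 100) return(rep(0, n))
  t_since <- a - e

  lt <- life_table[life_table$sex == sex, ]
  s_a <- lt$survival[match(a, lt$age)]
  s_e <- stats::approx(lt$age, lt$survival, xout = e)$y
  surv <- s_a / s_e

  bl <- baseline[baseline$site == site & baseline$sex == sex, ]
  if (nrow(bl) == 0) stop("baseline incidence missing for (", site, ", ", sex, ")")
  lam <- bl$rate[match(a, bl$age)]

  lg <- latency_config[latency_config$group == rc$latency_group, ]
  mu <- draws[[paste0("mu_", rc$latency_group)]]
  w_lat <- latency_weight_matrix(t_since, mu, c(lg$window_start, lg$window_end))

  estar <- (min(e, 30) - 30) / 10
  w <- rc$transfer_weight
  if (rc$model_class == "solid") {
    shape_err <- rc$beta_err * exp(rc$gamma_err * estar) * (a / 60)^rc$eta_err
    shape_ear <- rc$beta_ear * exp(rc$gamma_ear * estar) * (a / 60)^rc$eta_ear
    v_err <- shape_err * lam * surv
    v_ear <- shape_ear / 1e4 * surv
    a_err <- colSums(w_lat * v_err)
    a_ear <- colSums(w_lat * v_ear)
    (w * draws[[paste0("bmult_err_", site)]] * a_err +
      (1 - w) * draws[[paste0("bmult_ear_", site)]] * a_ear) / draws$ddref
  } else {
    lt_mod <- log(t_since / 25)
    shape_err <- rc$beta_err *
      exp(rc$gamma_err * estar + rc$delta_err * lt_mod + rc$phi_err * estar * lt_mod)
    shape_ear <- rc$beta_ear *
      exp(rc$gamma_ear * estar + rc$delta_ear * lt_mod + rc$phi_ear * estar * lt_mod)
    v_err <- shape_err * lam * surv
    v_ear <- shape_ear / 1e4 * surv
    a_err <- colSums(w_lat * v_err)
    a_ear <- colSums(w_lat * v_ear)
    w * draws[[paste0("bmult_err_", site)]] * a_err +
      (1 - w) * draws[[paste0("bmult_ear_", site)]] * a_ear
  }
}

#' Lifetime attributable risk for one site and exposure
#'
#' Computes LAR(D, e) = sum over attained ages a = floor(e)+1 .. 100 of
#' latency_weight(a - e) * M(D, e, a) * S(a)/S(e), the expected excess
#' lifetime cancers per exposed person, where for solid sites
#' M = [w * ERR * lambda(a) + (1 - w) * EAR / 10^4] / DDREF and for leukemia
#' M = w * ERR_LQ * lambda(a) + (1 - w) * EAR_LQ / 10^4 (no DDREF). Survival
#' S from the sex-specific life table treats death as a competing risk;
#' lambda are the baseline incidence rates. The sum is annual and runs to
#' age 100, so LAR at e = 100 is 0. Sites not applicable to the given sex
#' (configured with zero coefficients) return 0.
#'
#' @param dose_gy Organ absorbed dose in Gy (scalar, >= 0).
#' @param age_exposure Age at exposure, 0-100 (may be fractional, e.g. a
#'   stratum midpoint).
#' @param sex "female" or "male".
#' @param site One of [cancer_sites()].
#' @param life_table Tibble `sex`, `age`, `survival` ([default_life_tables()]).
#' @param baseline Tibble `site`, `sex`, `age`, `rate`
#'   ([default_baseline_incidence()]).
#' @param risk_config Coefficients, [default_risk_config()].
#' @param latency_config [default_latency_config()].
#' @param draws Draw tibble ([sample_uncertainty()] and/or [central_draw()]);
#'   the result is vectorized over its rows.
#' @return Numeric vector of LAR values, one per draw row; all >= 0.
#' @export
lar_site <- function(dose_gy, age_exposure, sex, site,
                     life_table = default_life_tables(),
                     baseline = default_baseline_incidence(),
                     risk_config = default_risk_config(),
                     latency_config = default_latency_config(),
                     draws = central_draw(risk_config, latency_config)) {
  stopifnot(length(dose_gy) == 1, dose_gy >= 0)
  if (age_exposure < 0 || age_exposure > 100) stop("age at exposure must be in [0, 100]")
  u <- .lar_unit(
    site, sex, age_exposure, life_table, baseline,
    risk_config, latency_config, draws
  )
  rc <- risk_config[risk_config$site == site & risk_config$sex == sex, ]
  dose_fac <- if (rc$model_class == "leukemia") {
    dose_gy * (1 + rc$theta * dose_gy)
  } else {
    dose_gy
  }
  dose_fac * u
}

#' Per-examination lifetime risk for every stratum and site
#'
#' Evaluates [lar_site()] at each stratum's mean organ dose (mGy converted
#' to Gy, optionally scaled) and the midpoint age of its age group, for
#' every modeled cancer site, under the central parameter set and every
#' uncertainty draw. The per-unit-dose risk is computed once per
#' (sex, age-group, site) cell and reused across strata (the models are
#' linear, or linear-quadratic with known curvature, in dose).
#'
#' @param summaries Stratum summary from [summarize_strata()] (needs
#'   `dose_mean_<organ>` columns).
#' @param draws Uncertainty draws from [sample_uncertainty()].
#' @inheritParams lar_site
#' @param dose_scale Multiplier applied to all organ doses before risk
#'   evaluation (sensitivity scenarios).
#' @return An object of class `ctlar_risk`: a list with `table` (tibble
#'   `sex`, `age_group`, `category`, `site`, `organ`, `dose_mgy`,
#'   `central` = central per-exam excess cancers), `draws` (matrix, rows
#'   aligned with `table`, one column per draw) and `n_draws`.
#' @export
lar_per_exam <- function(summaries, draws,
                         life_table = default_life_tables(),
                         baseline = default_baseline_incidence(),
                         risk_config = default_risk_config(),
                         latency_config = default_latency_config(),
                         dose_scale = 1) {
  osm <- organ_site_map()
  miss <- setdiff(paste0("dose_mean_", osm$organ), names(summaries))
  if (length(miss) > 0) {
    stop("summaries lack organ dose columns: ", paste(miss, collapse = ", "))
  }
  ag <- age_groups()
  cells <- summaries |>
    dplyr::distinct(.data$sex, .data$age_group) |>
    dplyr::mutate(age_mid = ag$age_mid[match(.data$age_group, ag$age_group)])

  all_draws <- dplyr::bind_rows(
    central_draw(risk_config, latency_config),
    draws
  )
  n_all <- nrow(all_draws)

  # per-unit-dose risk for each (cell, site) across all draws
  unit <- tidyr::expand_grid(cells, site = unique(osm$site))
  umat <- matrix(0, nrow(unit), n_all)
  for (i in seq_len(nrow(unit))) {
    umat[i, ] <- .lar_unit(
      unit$site[i], unit$sex[i], unit$age_mid[i],
      life_table, baseline, risk_config, latency_config, all_draws
    )
  }
  unit$unit_idx <- seq_len(nrow(unit))

  long <- summaries |>
    dplyr::select(
      "sex", "age_group", "category",
      dplyr::starts_with("dose_mean_")
    ) |>
    tidyr::pivot_longer(
      dplyr::starts_with("dose_mean_"),
      names_to = "organ", names_prefix = "dose_mean_", values_to = "dose_mgy"
    ) |>
    dplyr::inner_join(osm, by = "organ") |>
    dplyr::left_join(
      unit[, c("sex", "age_group", "site", "unit_idx")],
      by = c("sex", "age_group", "site")
    )

  theta <- risk_config$theta[match(
    paste(long$site, long$sex),
    paste(risk_config$site, risk_config$sex)
  )]
  d_gy <- long$dose_mgy * dose_scale / 1000
  dose_fac <- d_gy * (1 + theta * d_gy)
  risk_all <- umat[long$unit_idx, , drop = FALSE] * dose_fac

  table <- long |>
    dplyr::select("sex", "age_group", "category", "site", "organ", "dose_mgy") |>
    dplyr::mutate(central = risk_all[, 1])
  structure(
    list(
      table = table,
      draws = risk_all[, -1, drop = FALSE],
      n_draws = n_all - 1
    ),
    class = "ctlar_risk"
  )
}

#' @export
print.ctlar_risk <- function(x, ...) {
  cat(
    "<ctlar_risk> per-examination lifetime attributable risk\n",
    nrow(x$table), " stratum-site rows, ", x$n_draws, " uncertainty draws\n",
    "total central risk per exam (exam-weighted requires counts): range ",
    format(range(x$table$central), digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}
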