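#' Sensitivity scenario definition
#'
#' A declarative modification of the baseline projection configuration.
#' Exactly one coherent set of modifications is applied before projection;
#' draws are shared with the baseline run (same seed) so comparisons are
#' paired.
#'
#' @param name Scenario name.
#' @param dose_scale Organ-dose multiplier (> 0, default 1).
#' @param volume_scale Examination-volume multiplier (> 0, default 1).
#' @param pediatric_share_override Optional fraction replacing the baseline
#'   pediatric share.
#' @param lung_female_uses_male_coefs If TRUE, female lung ERR and EAR
#'   coefficients are replaced by the male values (modifiers stay shared).
#' @param eol_years 1 or 2: years-of-life exclusion window.
#' @param distribution_profile Name of a registry-mix profile in
#'   `config$profiles` ("baseline" uses the baseline summaries).
#' @return List of class `ctlar_scenario`.
#' @export
scenario_config <- function(name, dose_scale = 1, volume_scale = 1,
                            pediatric_share_override = NULL,
                            lung_female_uses_male_coefs = FALSE,
                            eol_years = 1,
                            distribution_profile = "baseline") {
  stopifnot(dose_scale > 0, volume_scale > 0, eol_years %in% c(1, 2))
  if (!is.null(pediatric_share_override)) {
    stopifnot(pediatric_share_override >= 0, pediatric_share_override <= 1)
  }
  structure(
    list(
      name = name, dose_scale = dose_scale, volume_scale = volume_scale,
      pediatric_share_override = pediatric_share_override,
      lung_female_uses_male_coefs = lung_female_uses_male_coefs,
      eol_years = eol_years, distribution_profile = distribution_profile
    ),
    class = "ctlar_scenario"
  )
}

#' The eight named sensitivity scenarios
#'
#' 1. Male lung-cancer coefficients applied to female patients; 2-3. annual
#' imaging volume reduced/increased by 10%; 4-5. organ doses reduced/
#' increased by 20%; 6. the higher pediatric examination share (9.0% vs
#' 3.3%); 7. an alternative examination-distribution profile (pre-2020
#' mix); 8. exclusion of examinations in the last 2 (rather than 1) years
#' of life.
#'
#' @return Named list of eight [scenario_config()] objects.
#' @export
default_scenarios <- function() {
  list(
    lung_male_coefs_in_females =
      scenario_config("lung_male_coefs_in_females", lung_female_uses_male_coefs = TRUE),
    volume_down_10 = scenario_config("volume_down_10", volume_scale = 0.9),
    volume_up_10 = scenario_config("volume_up_10", volume_scale = 1.1),
    dose_down_20 = scenario_config("dose_down_20", dose_scale = 0.8),
    dose_up_20 = scenario_config("dose_up_20", dose_scale = 1.2),
    pediatric_share_high = scenario_config("pediatric_share_high",
      pediatric_share_override = 0.09
    ),
    distribution_2018_2019 = scenario_config("distribution_2018_2019",
      distribution_profile = "profile_2018_2019"
    ),
    eol_two_year = scenario_config("eol_two_year", eol_years = 2)
  )
}

# apply a scenario's modifications to a projection config
apply_scenario <- function(config, scenario) {
  stopifnot(inherits(scenario, "ctlar_scenario"))
  cfg <- config
  cfg$dose_scale <- config$dose_scale * scenario$dose_scale
  cfg$volume_scale <- config$volume_scale * scenario$volume_scale
  if (!is.null(scenario$pediatric_share_override)) {
    cfg$pediatric_share <- scenario$pediatric_share_override
  }
  if (scenario$lung_female_uses_male_coefs) {
    rc <- cfg$risk_config
    lung_m <- rc[rc$site == "lung" & rc$sex == "male", ]
    i <- which(rc$site == "lung" & rc$sex == "female")
    rc$beta_err[i] <- lung_m$beta_err
    rc$beta_ear[i] <- lung_m$beta_ear
    cfg$risk_config <- rc
  }
  if (scenario$distribution_profile != "baseline") {
    prof <- config$profiles[[scenario$distribution_profile]]
    if (is.null(prof)) {
      stop(
        "unknown distribution profile '", scenario$distribution_profile,
        "'; available: baseline",
        if (length(config$profiles) > 0) {
          paste0(", ", paste(names(config$profiles), collapse = ", "))
        }
      )
    }
    cfg$summaries <- prof
  }
  cfg
}

#' Run one sensitivity scenario
#'
#' Applies the scenario to the baseline configuration, reruns the
#' projection with the same seed (paired draws), and reports the change in
#' the projected total.
#'
#' @param config Baseline [projection_config()].
#' @param scenario A [scenario_config()], or the name of one of the eight
#'   [default_scenarios()].
#' @param baseline_run Optional precomputed [run_projection()] result for
#'   `config` (avoids recomputation across a suite).
#' @return List with `scenario`, `run` (the scenario's projection run),
#'   `total`, `baseline_total`, `delta_abs`, `delta_pct`.
#' @export
run_scenario <- function(config, scenario, baseline_run = NULL) {
  if (is.character(scenario)) {
    sc <- default_scenarios()[[scenario]]
    if (is.null(sc)) {
      stop(
        "unknown scenario '", scenario, "'; the eight scenarios are: ",
        paste(names(default_scenarios()), collapse = ", ")
      )
    }
    scenario <- sc
  }
  if (is.null(baseline_run)) baseline_run <- run_projection(config)
  cfg <- apply_scenario(config, scenario)
  run <- run_projection(cfg, eol_years = scenario$eol_years)
  total <- glance(run$projection)$total_cancers
  base_total <- glance(baseline_run$projection)$total_cancers
  list(
    scenario = scenario, run = run, total = total,
    baseline_total = base_total,
    delta_abs = total - base_total,
    delta_pct = 100 * (total - base_total) / base_total
  )
}

#' Run the full sensitivity suite
#'
#' Runs the eight named scenarios against the baseline with shared draws
#' and returns one row per scenario.
#'
#' @param config Baseline [projection_config()].
#' @param scenarios List of scenarios (default the eight named ones).
#' @return Tibble with columns `scenario`, `total`, `lower90`, `upper90`,
#'   `delta_abs`, `delta_pct`; attribute `baseline` holds the baseline
#'   glance row.
#' @export
scenario_suite <- function(config, scenarios = default_scenarios()) {
  baseline_run <- run_projection(config)
  rows <- purrr::map(scenarios, function(sc) {
    r <- run_scenario(config, sc, baseline_run = baseline_run)
    g <- glance(r$run$projection)
    tibble::tibble(
      scenario = r$scenario$name, total = r$total,
      lower90 = g$lower90, upper90 = g$upper90,
      delta_abs = r$delta_abs, delta_pct = r$delta_pct
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- glance(baseline_run$projection)
  out
}

#' Synthetic pre-2020 distribution profile
#'
#' An alternative stratum summary standing in for the 2018-2019
#' examination mix: category proportions tilted modestly toward head and
#' away from chest imaging (renormalized), doses unchanged. Synthetic: the
#' actual pre-2020 mix is configuration the user can supply via
#' `profiles`.
#'
#' @param summaries Baseline stratum summary.
#' @param tilt Relative tilt applied to head (+) and chest (-) category
#'   proportions (default 0.1).
#' @return A stratum summary tibble with adjusted proportions.
#' @export
profile_2018_2019 <- function(summaries, tilt = 0.1) {
  cats <- ct_categories()
  region <- cats$body_region[match(summaries$category, cats$category)]
  w <- ifelse(region == "head", 1 + tilt, ifelse(region == "chest", 1 - tilt, 1))
  dplyr::mutate(summaries, proportion = .data$proportion * w / sum(.data$proportion * w))
}
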