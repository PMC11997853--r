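#' Projection-stage configuration
#'
#' Bundles the inputs of the national projection: the stratum summaries,
#' national scaling totals, exclusion maps, risk-model configuration and
#' draw settings. This is the object sensitivity scenarios modify.
#'
#' @param summaries Stratum summary ([summarize_strata()]).
#' @param total_exams National annual CT examinations (default 93,000,000).
#' @param pediatric_share Fraction of examinations in children (default
#'   0.033).
#' @param exams_per_patient,eol_prob,eol_prob_2yr Cell-level tables; the
#'   2-year end-of-life map defaults to 1.6x the 1-year map capped at 1 (a
#'   synthetic stand-in; supply measured values where available).
#' @param life_tables,baseline,risk_config,latency_config,ddref_config
#'   Risk-engine inputs; see the `default_*()` functions.
#' @param n_draws Uncertainty draws (default 500).
#' @param seed Root seed for the draw stage.
#' @param dose_scale,volume_scale Global multipliers (baseline 1).
#' @param profiles Named list of alternative stratum summaries
#'   (distribution-profile scenarios); `"baseline"` maps to `summaries`.
#'   Defaults to the synthetic pre-2020 mix from [profile_2018_2019()].
#' @return List of class `ctlar_projection_config`.
#' @export
projection_config <- function(summaries,
                              total_exams = 93e6,
                              pediatric_share = 0.033,
                              exams_per_patient = default_exams_per_patient(),
                              eol_prob = default_eol_prob(),
                              eol_prob_2yr = NULL,
                              life_tables = default_life_tables(),
                              baseline = default_baseline_incidence(),
                              risk_config = default_risk_config(),
                              latency_config = default_latency_config(),
                              ddref_config = default_ddref_config(),
                              n_draws = 500, seed = 1,
                              dose_scale = 1, volume_scale = 1,
                              profiles = NULL) {
  if (is.null(eol_prob_2yr)) {
    eol_prob_2yr <- dplyr::mutate(eol_prob, eol_prob = pmin(1.6 * .data$eol_prob, 1))
  }
  if (is.null(profiles)) {
    profiles <- list(profile_2018_2019 = profile_2018_2019(summaries))
  }
  structure(
    list(
      summaries = summaries, total_exams = total_exams,
      pediatric_share = pediatric_share,
      exams_per_patient = exams_per_patient,
      eol_prob = eol_prob, eol_prob_2yr = eol_prob_2yr,
      life_tables = life_tables, baseline = baseline,
      risk_config = risk_config, latency_config = latency_config,
      ddref_config = ddref_config, n_draws = n_draws, seed = seed,
      dose_scale = dose_scale, volume_scale = volume_scale,
      profiles = profiles
    ),
    class = "ctlar_projection_config"
  )
}

#' Run the projection stage
#'
#' Scales the stratum summaries to national volume, applies the end-of-life
#' exclusion, samples uncertainty draws, computes per-exam risks, and
#' projects national cancer counts. Deterministic given `config$seed`.
#'
#' @param config A [projection_config()].
#' @param eol_years 1 (default) or 2: which end-of-life map to apply.
#' @return List with `counts`, `risks`, `projection` (a `ctlar_projection`),
#'   and `draws`.
#' @export
run_projection <- function(config, eol_years = 1) {
  stopifnot(inherits(config, "ctlar_projection_config"), eol_years %in% c(1, 2))
  counts <- scale_to_national(
    config$summaries,
    total_exams = config$total_exams,
    pediatric_share = config$pediatric_share,
    exams_per_patient = config$exams_per_patient
  )
  eol <- if (eol_years == 1) config$eol_prob else config$eol_prob_2yr
  counts <- apply_eol_exclusion(counts, eol)
  if (config$volume_scale != 1) counts <- .scale_counts(counts, config$volume_scale)
  draws <- sample_uncertainty(
    config$risk_config, config$latency_config, config$ddref_config,
    n_draws = config$n_draws, seed = split_seed(config$seed, "draws")
  )
  risks <- lar_per_exam(
    config$summaries, draws,
    life_table = config$life_tables, baseline = config$baseline,
    risk_config = config$risk_config, latency_config = config$latency_config,
    dose_scale = config$dose_scale
  )
  projection <- project_cancers(counts, risks)
  list(counts = counts, risks = risks, projection = projection, draws = draws)
}

# multiply national counts by a volume factor after allocation, so volume
# scenarios commute exactly with projection (no re-rounding of strata)
.scale_counts <- function(counts, k) {
  out <- dplyr::mutate(counts,
    scaled_exams = .data$scaled_exams * k,
    eol_excluded = .data$eol_excluded * k,
    included_exams = .data$included_exams * k
  )
  pbc <- attr(counts, "patients_by_cell")
  pbc$exams <- pbc$exams * k
  pbc$patients <- pbc$patients * k
  attr(out, "total_exams") <- attr(counts, "total_exams") * k
  attr(out, "total_patients") <- attr(counts, "total_patients") * k
  attr(out, "total_included") <- attr(counts, "total_included") * k
  attr(out, "total_eol_excluded") <- attr(counts, "total_eol_excluded") * k
  attr(out, "patients_by_cell") <- pbc
  class(out) <- unique(c("ctlar_national_counts", class(out)))
  out
}

#' Run the full pipeline from synthetic registry to projection
#'
#' Chains registry generation, stratum summarization, national scaling with
#' end-of-life exclusion, risk computation with uncertainty, and projection.
#' All randomness derives from one root seed, split per stage, so each
#' stage is independently reproducible.
#'
#' @param registry_cfg A [registry_config()]; its `seed` is overwritten by
#'   the split of `seed`.
#' @param seed Root seed.
#' @param n_draws Uncertainty draws.
#' @param total_exams,pediatric_share National scaling inputs.
#' @param ... Further arguments passed to [projection_config()].
#' @return List with `registry`, `summaries`, `exams_per_patient_est`,
#'   `counts`, `risks`, `projection`, `draws`, `config`, `manifest`.
#' @export
run_ct_pipeline <- function(registry_cfg = registry_config(),
                            seed = 1, n_draws = 500,
                            total_exams = 93e6, pediatric_share = 0.033, ...) {
  registry_cfg$seed <- split_seed(seed, "registry")
  registry <- generate_registry(registry_cfg)
  summaries <- summarize_strata(registry)
  epp <- estimate_exams_per_patient(registry)
  config <- projection_config(
    summaries,
    total_exams = total_exams, pediatric_share = pediatric_share,
    exams_per_patient = registry_cfg$exams_per_patient,
    eol_prob = registry_cfg$eol_prob,
    n_draws = n_draws, seed = seed, ...
  )
  run <- run_projection(config)
  manifest <- run_manifest(config, seed = seed, n_draws = n_draws)
  c(
    list(
      registry = registry, summaries = summaries,
      exams_per_patient_est = epp, config = config, manifest = manifest
    ),
    run
  )
}

#' Derive a stage seed from the root seed
#'
#' Hashes the root seed together with a stage label and folds the hash into
#' a 31-bit integer, so stages draw from unrelated streams and each stage
#' can be rerun on its own.
#'
#' @param seed Root integer seed.
#' @param stage Stage label, e.g. "registry", "draws".
#' @return Integer seed in [0, 2^31 - 1).
#' @export
split_seed <- function(seed, stage) {
  h <- rlang::hash(list(seed = as.integer(seed), stage = as.character(stage)))
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

#' Run manifest
#'
#' Records what produced a set of outputs: a configuration digest (stable
#' under key reordering), the seed, draw count, package version and
#' timestamp, plus any output paths.
#'
#' @param config Configuration object (any list).
#' @param seed Root seed used.
#' @param n_draws Draws used.
#' @param outputs Character vector of output file paths.
#' @return List of class `ctlar_manifest`.
#' @export
run_manifest <- function(config, seed, n_draws, outputs = character()) {
  structure(
    list(
      config_digest = config_digest(config),
      seed = seed, n_draws = n_draws,
      package_version = as.character(utils::packageVersion("ctlar")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = outputs
    ),
    class = "ctlar_manifest"
  )
}

#' @rdname run_manifest
#' @export
config_digest <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names2(x))]
      lapply(x, canon)
    } else {
      x
    }
  }
  names2 <- function(x) {
    n <- names(x)
    if (is.null(n)) rep("", length(x)) else n
  }
  rlang::hash(canon(unclass(config)))
}

#' Write a manifest alongside outputs
#'
#' @param manifest A `ctlar_manifest`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
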