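#' Triangular distribution quantile function
#'
#' @param p Probabilities in [0, 1].
#' @param tri_min,tri_mode,tri_max Support and mode, min <= mode <= max.
#' @return Quantiles of the triangular distribution.
#' @export
qtriangular <- function(p, tri_min, tri_mode, tri_max) {
  stopifnot(tri_min <= tri_mode, tri_mode <= tri_max, all(p >= 0 & p <= 1))
  fc <- (tri_mode - tri_min) / (tri_max - tri_min)
  ifelse(
    p < fc,
    tri_min + sqrt(p * (tri_max - tri_min) * (tri_mode - tri_min)),
    tri_max - sqrt((1 - p) * (tri_max - tri_min) * (tri_max - tri_mode))
  )
}

#' Latin hypercube uncertainty draws
#'
#' Samples the uncertain components of the risk model by Latin hypercube
#' sampling: each parameter's `n_draws` values occupy distinct
#' equal-probability bins of its marginal distribution. Sampled components:
#' one lognormal multiplier (median 1, geometric SD `beta_gsd`) per site for
#' the ERR coefficients and one per site for the EAR coefficients (shared
#' across sexes, so parameter uncertainty is systematic); the DDREF
#' (lognormal, median 1.5, 90% interval ~(1.1, 2.3)); and the latency
#' midpoint mu for each of the three latency groups (triangular). One set
#' of draws is shared across all strata in a run, so national uncertainty
#' limits reflect systematic model uncertainty rather than sampling noise.
#'
#' @param risk_config Coefficient table, see [default_risk_config()].
#' @param latency_config See [default_latency_config()].
#' @param ddref_config See [default_ddref_config()].
#' @param n_draws Number of draws (>= 2).
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A tibble of class `ctlar_draws` with columns `draw_id`, `ddref`,
#'   `mu_solid`, `mu_thyroid`, `mu_leukemia`, and `bmult_err_<site>` /
#'   `bmult_ear_<site>` multiplier columns.
#' @export
sample_uncertainty <- function(risk_config = default_risk_config(),
                               latency_config = default_latency_config(),
                               ddref_config = default_ddref_config(),
                               n_draws = 500, seed = 1) {
  stopifnot(n_draws >= 2)
  sites <- unique(risk_config$site)
  gsd <- risk_config$beta_gsd[match(sites, risk_config$site)]
  k <- 2 * length(sites) + 1 + nrow(latency_config)
  set.seed(seed)
  u <- lhs::randomLHS(n_draws, k)
  out <- tibble::tibble(draw_id = seq_len(n_draws))
  col <- 1
  for (i in seq_along(sites)) {
    out[[paste0("bmult_err_", sites[i])]] <-
      stats::qlnorm(u[, col], meanlog = 0, sdlog = log(gsd[i]))
    col <- col + 1
  }
  for (i in seq_along(sites)) {
    out[[paste0("bmult_ear_", sites[i])]] <-
      stats::qlnorm(u[, col], meanlog = 0, sdlog = log(gsd[i]))
    col <- col + 1
  }
  out$ddref <- stats::qlnorm(u[, col],
    meanlog = log(ddref_config$median), sdlog = ddref_config$sigma
  )
  col <- col + 1
  for (g in seq_len(nrow(latency_config))) {
    lc <- latency_config[g, ]
    out[[paste0("mu_", lc$group)]] <-
      qtriangular(u[, col], lc$tri_min, lc$tri_mode, lc$tri_max)
    col <- col + 1
  }
  structure(out, class = c("ctlar_draws", class(out)))
}

#' Central (no-uncertainty) draw
#'
#' The deterministic evaluation point: all coefficient multipliers 1, DDREF
#' at its median, latency midpoints at their modes.
#'
#' @inheritParams sample_uncertainty
#' @return A one-row tibble with the same columns as [sample_uncertainty()].
#' @export
central_draw <- function(risk_config = default_risk_config(),
                         latency_config = default_latency_config(),
                         ddref_config = default_ddref_config()) {
  sites <- unique(risk_config$site)
  out <- tibble::tibble(draw_id = 0L)
  for (s in sites) out[[paste0("bmult_err_", s)]] <- 1
  for (s in sites) out[[paste0("bmult_ear_", s)]] <- 1
  out$ddref <- ddref_config$median
  for (g in seq_len(nrow(latency_config))) {
    out[[paste0("mu_", latency_config$group[g])]] <- latency_config$tri_mode[g]
  }
  out
}

#' 90% uncertainty limits from per-draw totals
#'
#' The 5th and 95th empirical percentiles of the simulated distribution.
#'
#' @param per_draw_totals Numeric vector of >= 20 draw totals.
#' @return Named numeric vector `c(lower90 = ..., upper90 = ...)`.
#' @export
uncertainty_limits <- function(per_draw_totals) {
  stopifnot(length(per_draw_totals) >= 20)
  q <- stats::quantile(per_draw_totals, c(0.05, 0.95), names = FALSE)
  c(lower90 = q[1], upper90 = q[2])
}
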