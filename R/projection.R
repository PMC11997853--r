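#' Project national lifetime cancer counts
#'
#' Multiplies each stratum's included examination count by its per-exam
#' risk and aggregates: cancers(group, draw) = sum over the group's strata
#' of included_exams x per-exam risk(draw). Point estimates use the central
#' risk evaluation; 90% uncertainty limits are the 5th/95th percentiles of
#' each group's own per-draw totals (so limits are coherent within a table
#' but, like any percentile, not additive across rows).
#'
#' @param counts National counts with `included_exams`
#'   ([apply_eol_exclusion()]).
#' @param risks A `ctlar_risk` from [lar_per_exam()].
#' @return An object of class `ctlar_projection`: list with `results`
#'   (tibble `grouping`, `level`, `point`, `lower90`, `upper90`, `n_draws`),
#'   `group_draws` (named list of per-draw total matrices by grouping),
#'   `total_draws`, `by_stratum` (per-stratum central cancers) and
#'   `total_exams` metadata.
#' @export
project_cancers <- function(counts, risks) {
  tb <- risks$table
  key_r <- paste(tb$sex, tb$age_group, tb$category)
  key_c <- paste(counts$sex, counts$age_group, counts$category)
  idx <- match(key_r, key_c)
  if (anyNA(idx)) {
    miss <- unique(key_r[is.na(idx)])[1]
    stop("no national count for stratum (", miss, ")")
  }
  missing_risk <- setdiff(key_c, key_r)
  if (length(missing_risk) > 0) {
    stop("stratum without risk: (", missing_risk[1], ")")
  }
  included <- counts$included_exams[idx]
  ag <- age_groups()
  cats <- ct_categories()

  work <- tb |>
    dplyr::mutate(
      included = included,
      central_cancers = included * .data$central,
      life_stage = ag$life_stage[match(.data$age_group, ag$age_group)],
      body_region = cats$body_region[match(.data$category, cats$category)]
    )
  draws_cancers <- risks$draws * included

  groupings <- list(
    total = rep("all", nrow(work)),
    by_site = work$site,
    by_body_region = work$body_region,
    by_age_group = work$age_group,
    by_sex = work$sex,
    by_life_stage = work$life_stage,
    by_site_life_stage = paste(work$site, work$life_stage, sep = "|"),
    by_region_life_stage = paste(work$body_region, work$life_stage, sep = "|")
  )
  n_draws <- risks$n_draws
  res <- list()
  group_draws <- list()
  for (g in names(groupings)) {
    f <- groupings[[g]]
    pt <- rowsum(work$central_cancers, f)
    dm <- rowsum(draws_cancers, f)
    lim <- t(apply(dm, 1, uncertainty_limits))
    res[[g]] <- tibble::tibble(
      grouping = g, level = rownames(pt), point = unname(pt[, 1]),
      lower90 = unname(lim[, 1]), upper90 = unname(lim[, 2]),
      n_draws = n_draws
    )
    group_draws[[g]] <- dm
  }
  by_stratum <- work |>
    dplyr::group_by(.data$sex, .data$age_group, .data$category) |>
    dplyr::summarise(
      included_exams = .data$included[1],
      cancers = sum(.data$central_cancers),
      .groups = "drop"
    )
  structure(
    list(
      results = dplyr::bind_rows(res),
      group_draws = group_draws,
      total_draws = as.numeric(group_draws$total),
      by_stratum = by_stratum,
      total_exams = attr(counts, "total_exams"),
      total_included = attr(counts, "total_included"),
      total_patients = attr(counts, "total_patients")
    ),
    class = "ctlar_projection"
  )
}

#' @export
print.ctlar_projection <- function(x, ...) {
  tot <- x$results[x$results$grouping == "total", ]
  cat(
    "<ctlar_projection> projected lifetime cancers\n",
    "total: ", format(round(tot$point)), " (90% UL ",
    format(round(tot$lower90)), "-", format(round(tot$upper90)), "), ",
    tot$n_draws, " draws\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a projection into its grouped results table
#'
#' @param x A `ctlar_projection`.
#' @param ... Unused.
#' @return The `results` tibble (grouping, level, point, lower90, upper90,
#'   n_draws).
#' @export
tidy.ctlar_projection <- function(x, ...) x$results

#' One-row summary of a projection
#'
#' @param x A `ctlar_projection`.
#' @param ... Unused.
#' @return One-row tibble: total point estimate, 90% limits, exam totals,
#'   draws.
#' @export
glance.ctlar_projection <- function(x, ...) {
  tot <- x$results[x$results$grouping == "total", ]
  tibble::tibble(
    total_cancers = tot$point, lower90 = tot$lower90, upper90 = tot$upper90,
    total_exams = x$total_exams, total_included_exams = x$total_included,
    total_patients = x$total_patients, n_draws = tot$n_draws
  )
}

#' Projected cancers per 1000 examinations
#'
#' Uses the reporting convention that the denominator is the TOTAL number
#' of examinations in the group (not the end-of-life-reduced count), a
#' conservative choice.
#'
#' @param cancers Projected cancers in the group.
#' @param total_exams Total examinations in the group (> 0).
#' @return Cancers per 1000 examinations.
#' @export
#' @examples
#' risk_per_1000_exams(1900, 97000) # 19.6, displayed as 20
risk_per_1000_exams <- function(cancers, total_exams) {
  if (any(total_exams <= 0)) stop("rate undefined: group has zero examinations")
  1000 * cancers / total_exams
}

#' Patients-based versus exams-based projection equivalence
#'
#' Because the risk model is linear in the number of examinations, the
#' projected total is the same whether computed per examination
#' (sum of included exams x per-exam risk) or per patient (patients x mean
#' exams per patient x per-exam risk). This function computes both
#' aggregations and compares them; a deliberately nonlinear
#' `per_patient_risk` (e.g. quadratic in the exam count) breaks the
#' equivalence.
#'
#' @param counts National counts with `included_exams`.
#' @param risks A `ctlar_risk`.
#' @param exams_per_patient Tibble `sex`, `age_group`, `mean_exams`.
#' @param per_patient_risk Function (per_exam_risk, mean_exams) -> risk per
#'   patient; default linear `r * m`.
#' @param tol Relative tolerance for equality.
#' @return List with `equal`, `exam_based`, `patient_based`,
#'   `relative_difference`.
#' @export
patients_vs_exams_equivalence <- function(counts, risks,
                                          exams_per_patient = default_exams_per_patient(),
                                          per_patient_risk = function(r, m) r * m,
                                          tol = 1e-09) {
  tb <- risks$table |>
    dplyr::group_by(.data$sex, .data$age_group, .data$category) |>
    dplyr::summarise(risk = sum(.data$central), .groups = "drop")
  j <- counts |>
    dplyr::inner_join(tb, by = c("sex", "age_group", "category")) |>
    dplyr::left_join(exams_per_patient, by = c("sex", "age_group")) |>
    dplyr::mutate(
      patients = .data$included_exams / .data$mean_exams,
      exam_cancers = .data$included_exams * .data$risk,
      patient_cancers = .data$patients * per_patient_risk(.data$risk, .data$mean_exams)
    )
  exam_based <- sum(j$exam_cancers)
  patient_based <- sum(j$patient_cancers)
  rel <- abs(patient_based - exam_based) / max(exam_based, .Machine$double.eps)
  list(
    equal = rel <= tol, exam_based = exam_based,
    patient_based = patient_based, relative_difference = rel
  )
}
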