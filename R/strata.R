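#' Summarize exam records into analysis strata
#'
#' Groups retained examinations into (sex, age-group, CT-category) strata,
#' computing counts, the share of all retained exams, and per-organ dose
#' means and SDs. Records flagged as biopsy/procedure, PET or research are
#' excluded first; strata with fewer than `min_exams` examinations are then
#' dropped (their estimated doses would be imprecise) and the remaining
#' proportions renormalized to sum to 1.
#'
#' @param records Exam-level tibble as from [generate_registry()].
#' @param min_exams Minimum examinations for a stratum to be retained
#'   (default 12).
#' @return A tibble with one row per retained stratum: `sex`, `age_group`,
#'   `category`, `n_exams`, `proportion`, and `dose_mean_*` / `dose_sd_*`
#'   columns per organ.
#' @export
summarize_strata <- function(records, min_exams = 12) {
  stopifnot(nrow(records) > 0)
  kept <- dplyr::filter(records, .data$excluded_reason == "none")
  if (nrow(kept) == 0) stop("all records carry an exclusion flag; nothing to summarize")
  dose_cols <- grep("^dose_.*_mGy$", names(kept), value = TRUE)
  out <- kept |>
    dplyr::group_by(.data$sex, .data$age_group, .data$category) |>
    dplyr::summarise(
      n_exams = dplyr::n(),
      dplyr::across(
        dplyr::all_of(dose_cols),
        list(mean = mean, sd = ~ if (length(.x) > 1) stats::sd(.x) else 0)
      ),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_exams >= min_exams) |>
    dplyr::mutate(proportion = .data$n_exams / sum(.data$n_exams))
  if (nrow(out) == 0) stop("no stratum reaches the minimum of ", min_exams, " examinations")
  # dose_<organ>_mGy_mean -> dose_mean_<organ>
  names(out) <- sub("^dose_(.*)_mGy_mean$", "dose_mean_\\1", names(out))
  names(out) <- sub("^dose_(.*)_mGy_sd$", "dose_sd_\\1", names(out))
  dplyr::relocate(out, "proportion", .after = "n_exams")
}

#' Mean examinations per patient by sex and age group
#'
#' @param records Exam-level tibble with `patient_id`.
#' @return A list with `by_group` (tibble `sex`, `age_group`, `n_exams`,
#'   `n_patients`, `mean_exams`) and `overall` (single mean across all
#'   patients).
#' @export
#' @examples
#' # national totals: 93,000,000 exams in 61,510,000 patients -> 1.51
#' round(93000000 / 61510000, 2)
estimate_exams_per_patient <- function(records) {
  by_group <- records |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(
      n_exams = dplyr::n(),
      n_patients = dplyr::n_distinct(.data$patient_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_exams = .data$n_exams / .data$n_patients)
  list(
    by_group = by_group,
    overall = nrow(records) / dplyr::n_distinct(records$patient_id)
  )
}

# largest-remainder apportionment of `total` along weights w (sums exactly)
largest_remainder <- function(w, total) {
  if (length(w) == 0) return(integer(0))
  stopifnot(all(w >= 0), sum(w) > 0, total >= 0)
  q <- w / sum(w) * total
  fl <- floor(q)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    idx <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

#' Scale stratum proportions to national examination volume
#'
#' Allocates `pediatric_share * total_exams` examinations across pediatric
#' strata in proportion to their registry mix, and the remainder across adult
#' strata (the pediatric share is set first, then within-group allocation is
#' proportional). Counts are rounded to whole examinations by the
#' largest-remainder method so stratum counts sum exactly to `total_exams`.
#' National patient counts are derived by dividing exam counts by the mean
#' examinations per patient in each (sex, age-group) cell.
#'
#' @param summaries Stratum summary from [summarize_strata()].
#' @param total_exams National annual examination total (e.g., 93,000,000).
#' @param pediatric_share Fraction of examinations in children (e.g., 0.033).
#' @param exams_per_patient Tibble `sex`, `age_group`, `mean_exams` used to
#'   derive patient counts; defaults to [default_exams_per_patient()].
#' @return A tibble of class `ctlar_national_counts`: stratum keys plus
#'   `scaled_exams`, and attributes `total_exams`, `total_patients`,
#'   `patients_by_cell`.
#' @export
scale_to_national <- function(summaries, total_exams,
                              pediatric_share = 0.033,
                              exams_per_patient = default_exams_per_patient()) {
  stopifnot(pediatric_share >= 0, pediatric_share <= 1, total_exams >= 0)
  ag <- age_groups()
  summaries <- summaries |>
    dplyr::mutate(
      life_stage = ag$life_stage[match(.data$age_group, ag$age_group)]
    )
  is_child <- summaries$life_stage == "child"
  if (pediatric_share > 0 && !any(is_child)) {
    stop("pediatric_share > 0 but no pediatric strata are present")
  }
  child_total <- round(pediatric_share * total_exams)
  adult_total <- total_exams - child_total
  scaled <- integer(nrow(summaries))
  if (any(is_child)) {
    scaled[is_child] <- largest_remainder(summaries$proportion[is_child], child_total)
  }
  scaled[!is_child] <- largest_remainder(summaries$proportion[!is_child], adult_total)
  out <- summaries |>
    dplyr::mutate(scaled_exams = scaled) |>
    dplyr::select(-"life_stage")

  cell <- out |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(exams = sum(.data$scaled_exams), .groups = "drop") |>
    dplyr::left_join(exams_per_patient, by = c("sex", "age_group")) |>
    dplyr::mutate(patients = .data$exams / .data$mean_exams)
  structure(
    out,
    class = c("ctlar_national_counts", class(out)),
    total_exams = sum(out$scaled_exams),
    total_patients = sum(cell$patients),
    patients_by_cell = cell
  )
}

#' Exclude examinations in the last year(s) of life
#'
#' Multiplies each stratum's scaled examination count by 1 - eol_prob for
#' its (sex, age-group) cell; examinations near the end of life cannot
#' contribute future radiation-induced cancers given the latency between
#' exposure and cancer.
#'
#' @param counts National counts from [scale_to_national()].
#' @param eol_prob Tibble `sex`, `age_group`, `eol_prob`, fractions in
#'   [0, 1]; defaults to [default_eol_prob()].
#' @return `counts` with added columns `eol_excluded` and `included_exams`,
#'   plus attributes `total_included`, `total_eol_excluded`.
#' @export
apply_eol_exclusion <- function(counts, eol_prob = default_eol_prob()) {
  stopifnot(all(eol_prob$eol_prob >= 0), all(eol_prob$eol_prob <= 1))
  j <- dplyr::left_join(
    counts[, c("sex", "age_group")], eol_prob,
    by = c("sex", "age_group")
  )
  if (anyNA(j$eol_prob)) {
    miss <- unique(j[is.na(j$eol_prob), c("sex", "age_group")])[1, ]
    stop("eol_prob missing cell (", miss$sex, ", ", miss$age_group, ")")
  }
  out <- counts |>
    dplyr::mutate(
      eol_excluded = .data$scaled_exams * j$eol_prob,
      included_exams = .data$scaled_exams - .data$eol_excluded
    )
  attr(out, "total_exams") <- attr(counts, "total_exams")
  attr(out, "total_patients") <- attr(counts, "total_patients")
  attr(out, "patients_by_cell") <- attr(counts, "patients_by_cell")
  attr(out, "total_included") <- sum(out$included_exams)
  attr(out, "total_eol_excluded") <- sum(out$eol_excluded)
  class(out) <- unique(c("ctlar_national_counts", class(out)))
  out
}
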