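#' Display rounding for projected counts
#'
#' Counts of 1000 and above are rounded to the nearest 100, counts of 10 to
#' 999 to the nearest 10, and smaller counts to the nearest integer,
#' mirroring how national projections are printed. Stored values stay
#' unrounded; rounding is display-only.
#'
#' @param x Numeric vector of counts.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' display_round(c(102684.2, 19.6, 562.8, 9.4)) # 102700, 20, 560, 9
display_round <- function(x) {
  half_up <- function(v, unit) floor(v / unit + 0.5) * unit
  ifelse(x >= 1000, half_up(x, 100), ifelse(x >= 10, half_up(x, 10), half_up(x, 1)))
}

#' Percent change between two totals
#'
#' @param new,old Numeric values; `old` != 0.
#' @return 100 * (new - old) / old.
#' @export
#' @examples
#' pct_change(126600, 102700) # +23.3
pct_change <- function(new, old) {
  stopifnot(all(old != 0))
  100 * (new - old) / old
}

# "point (lower-upper)" display string
format_ul <- function(point, lower, upper) {
  fmt <- function(v) format(display_round(v), big.mark = ",", trim = TRUE, scientific = FALSE)
  paste0(fmt(point), " (", fmt(lower), "-", fmt(upper), ")")
}

# Table-1-style display age bands over the 13 analysis groups
.display_age_bands <- function() {
  tibble::tribble(
    ~age_group, ~band,
    "<1", "<1",
    "1-4", "1-9", "5-9", "1-9",
    "10-14", "10-17", "15-17", "10-17",
    "18-29", "18-39", "30-39", "18-39",
    "40-49", "40-59", "50-59", "40-59",
    "60-69", "60-79", "70-79", "60-79",
    "80-89", "80-99", "90-99", "80-99"
  )
}

#' Examination-volume table (national utilization analog)
#'
#' Summarizes national counts into the familiar utilization table: overall,
#' child and adult rows plus sex-by-age-band blocks, with patient counts,
#' examination counts and shares, mean examinations per patient (from
#' unrounded values), and examinations by body region.
#'
#' @param counts National counts from [scale_to_national()] /
#'   [apply_eol_exclusion()].
#' @return A tibble with one row per display group.
#' @export
make_table_examinations <- function(counts) {
  ag <- age_groups()
  cats <- ct_categories()
  pbc <- attr(counts, "patients_by_cell")
  if (is.null(pbc)) stop("counts lack patients_by_cell; use scale_to_national()")
  work <- counts |>
    dplyr::mutate(
      life_stage = ag$life_stage[match(.data$age_group, ag$age_group)],
      body_region = cats$body_region[match(.data$category, cats$category)]
    ) |>
    dplyr::left_join(.display_age_bands(), by = "age_group")
  pbc <- pbc |>
    dplyr::mutate(life_stage = ag$life_stage[match(.data$age_group, ag$age_group)]) |>
    dplyr::left_join(.display_age_bands(), by = "age_group")
  total_exams <- sum(work$scaled_exams)

  row_for <- function(w, p, group) {
    regions <- w |>
      dplyr::group_by(.data$body_region) |>
      dplyr::summarise(exams = sum(.data$scaled_exams), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "body_region", values_from = "exams")
    for (r in setdiff(body_regions(), names(regions))) regions[[r]] <- NA_real_
    dplyr::bind_cols(
      tibble::tibble(
        group = group,
        patients = sum(p$patients),
        exams = sum(w$scaled_exams),
        exam_pct = 100 * sum(w$scaled_exams) / total_exams,
        mean_exams_per_patient = sum(w$scaled_exams) / sum(p$patients)
      ),
      regions[body_regions()]
    )
  }
  rows <- list(
    row_for(work, pbc, "all"),
    row_for(
      dplyr::filter(work, .data$life_stage == "child"),
      dplyr::filter(pbc, .data$life_stage == "child"), "child"
    ),
    row_for(
      dplyr::filter(work, .data$life_stage == "adult"),
      dplyr::filter(pbc, .data$life_stage == "adult"), "adult"
    )
  )
  for (s in sexes()) {
    ws <- dplyr::filter(work, .data$sex == s)
    ps <- dplyr::filter(pbc, .data$sex == s)
    rows <- c(rows, list(row_for(ws, ps, paste0(s, ": all ages"))))
    for (b in unique(.display_age_bands()$band)) {
      wb <- dplyr::filter(ws, .data$band == b)
      pb <- dplyr::filter(ps, .data$band == b)
      if (nrow(wb) > 0) {
        rows <- c(rows, list(row_for(wb, pb, paste0(s, ": ", b))))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Projected-cancers table (site and body-region analog)
#'
#' Renders the projection as 18 cancer-type rows plus 8 body-region rows,
#' each as "point (lower-upper)" for all examinations and for adult and
#' child examinations separately. A pure function of the stored unrounded
#' results; rounding is display-only.
#'
#' @param projection A `ctlar_projection` from [project_cancers()].
#' @return Tibble with columns `block`, `level`, `all`, `adult`, `child`.
#' @export
make_table_projected <- function(projection) {
  res <- projection$results
  pick <- function(grouping) res[res$grouping == grouping, ]
  split_level <- function(df) {
    parts <- strsplit(df$level, "|", fixed = TRUE)
    df$level <- vapply(parts, `[`, "", 1)
    df$life_stage <- vapply(parts, `[`, "", 2)
    df
  }
  cell <- function(df) {
    ifelse(is.na(df$point), "NA", format_ul(df$point, df$lower90, df$upper90))
  }
  wide <- function(total_df, cross_df, levels) {
    cross_df <- split_level(cross_df)
    out <- tibble::tibble(level = levels)
    tt <- total_df[match(levels, total_df$level), ]
    out$all <- cell(tt)
    for (ls in c("adult", "child")) {
      sub <- cross_df[cross_df$life_stage == ls, ]
      m <- sub[match(levels, sub$level), ]
      out[[ls]] <- ifelse(is.na(m$point), "NA", format_ul(m$point, m$lower90, m$upper90))
    }
    out
  }
  tot <- pick("total")
  ls <- pick("by_life_stage")
  total_row <- tibble::tibble(
    block = "total", level = "total",
    all = cell(tot),
    adult = cell(ls[ls$level == "adult", ]),
    child = cell(ls[ls$level == "child", ])
  )
  site_rows <- wide(pick("by_site"), pick("by_site_life_stage"),
    levels = sort(unique(pick("by_site")$level))
  )
  site_rows$block <- "cancer_type"
  region_rows <- wide(pick("by_body_region"), pick("by_region_life_stage"),
    levels = sort(unique(pick("by_body_region")$level))
  )
  region_rows$block <- "body_region"
  dplyr::bind_rows(total_row, site_rows, region_rows) |>
    dplyr::relocate("block")
}

#' Plot projected cancers by site or region
#'
#' @param projection A `ctlar_projection`.
#' @param grouping Which marginal to plot ("by_site", "by_body_region",
#'   "by_age_group", "by_sex").
#' @return A ggplot: point estimates with 90% uncertainty-limit error bars.
#' @export
plot_projected <- function(projection, grouping = "by_site") {
  df <- projection$results[projection$results$grouping == grouping, ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$level, .data$point), y = .data$point
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower90, ymax = .data$upper90),
      width = 0.3
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Projected lifetime cancers",
      title = paste("Projected cancers", sub("^by_", "by ", grouping))
    )
}

#' @rdname plot_projected
#' @param object A `ctlar_projection`.
#' @param ... Passed to [plot_projected()].
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ctlar_projection <- function(object, ...) plot_projected(object, ...)

#' Risk per 1000 examinations by age group, figure-ready
#'
#' Combines per-stratum projected cancers and total examination counts into
#' cancers per 1000 examinations by sex and age group (denominator: total
#' examinations, the conservative convention).
#'
#' @param projection A `ctlar_projection`.
#' @param counts The national counts used for the projection.
#' @return Long tibble `sex`, `age_group`, `exams`, `cancers`, `per_1000`.
#' @export
risk_by_age_table <- function(projection, counts) {
  cancers <- projection$by_stratum |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(cancers = sum(.data$cancers), .groups = "drop")
  exams <- counts |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(exams = sum(.data$scaled_exams), .groups = "drop")
  ag <- age_groups()
  dplyr::inner_join(cancers, exams, by = c("sex", "age_group")) |>
    dplyr::mutate(
      per_1000 = risk_per_1000_exams(.data$cancers, .data$exams),
      age_group = factor(.data$age_group, levels = ag$age_group)
    ) |>
    dplyr::arrange(.data$sex, .data$age_group)
}

#' @rdname risk_by_age_table
#' @export
plot_risk_by_age <- function(projection, counts) {
  df <- risk_by_age_table(projection, counts)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$age_group, y = .data$per_1000,
      colour = .data$sex, group = .data$sex
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Age group at exposure",
      y = "Projected cancers per 1000 examinations", colour = NULL
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
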