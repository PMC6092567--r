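#' Percent of control
#'
#' Expresses a case-group biomarker level as a percentage of the matched
#' control level, `100 * case / control`.
#'
#' @param case_level,control_level Numeric vectors (recycled);
#'   `control_level` must be positive.
#' @return Numeric vector of percentages.
#' @export
percent_of_control <- function(case_level, control_level) {
  if (any(control_level <= 0)) stop("control level must be positive", call. = FALSE)
  100 * case_level / control_level
}

#' Gestational-age trend of a biomarker panel
#'
#' For each marker, the Pearson correlation (with two-sided p-value) of the
#' percent-of-control values with gestational week, plus the mean percent in
#' the first trimester (weeks before the cutoff) and the sign of the
#' post-cutoff linear slope.
#'
#' @param measurements Tibble with columns `marker`, `week`,
#'   `percent_of_control` (e.g. from [simulate_biomarker_db()]).
#' @param cutoff_week First-trimester boundary (default 12).
#' @return Tibble: `marker`, `r`, `p_value`, `n`, `first_trimester_mean`,
#'   `late_slope_sign`. Markers with fewer than 3 distinct weeks or a
#'   constant percent are skipped with a warning (an error if every marker
#'   fails).
#' @export
ga_trend <- function(measurements, cutoff_week = 12) {
  m <- tibble::as_tibble(measurements)
  need <- c("marker", "week", "percent_of_control")
  if (!all(need %in% names(m))) {
    stop("need columns marker, week, percent_of_control", call. = FALSE)
  }
  skipped <- character()
  res <- m |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_map(function(g, key) {
      if (length(unique(g$week)) < 3 ||
          stats::sd(g$percent_of_control) == 0) {
        skipped <<- c(skipped, key$marker[[1]])
        return(NULL)
      }
      ct <- stats::cor.test(g$week, g$percent_of_control, method = "pearson")
      late <- g[g$week >= cutoff_week, ]
      slope_sign <- if (nrow(late) >= 2 && stats::sd(late$week) > 0) {
        sign(stats::coef(stats::lm(percent_of_control ~ week, data = late))[[2]])
      } else {
        NA_real_
      }
      early <- g$percent_of_control[g$week < cutoff_week]
      tibble::tibble(
        marker = key$marker[[1]],
        r = unname(ct$estimate), p_value = ct$p.value, n = nrow(g),
        first_trimester_mean = if (length(early)) mean(early) else NA_real_,
        late_slope_sign = slope_sign
      )
    }) |>
    dplyr::bind_rows()
  if (length(skipped) > 0) {
    msg <- sprintf("undefined correlation for marker(s): %s",
                   paste(skipped, collapse = ", "))
    if (nrow(res) == 0) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  res
}

#' Trimester summary of percent-of-control levels
#'
#' Splits each marker's measurements at the cutoff week into half-open bins
#' `[start, cutoff)` and `[cutoff, end]` and reports the mean percent of
#' control and its direction relative to control levels (below / at /
#' above 100%) in each bin. Bins with no data are reported absent
#' (`NA` mean, `"absent"` direction).
#'
#' @inheritParams ga_trend
#' @return Tibble: `marker`, `period` (`"first_trimester"` /
#'   `"after_cutoff"`), `n`, `mean_percent`, `direction`.
#' @export
trimester_summary <- function(measurements, cutoff_week = 12) {
  m <- tibble::as_tibble(measurements)
  need <- c("marker", "week", "percent_of_control")
  if (!all(need %in% names(m))) {
    stop("need columns marker, week, percent_of_control", call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    marker = unique(m$marker),
    period = c("first_trimester", "after_cutoff")
  )
  m |>
    dplyr::mutate(
      period = ifelse(.data$week < cutoff_week, "first_trimester", "after_cutoff")
    ) |>
    dplyr::group_by(.data$marker, .data$period) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_percent = mean(.data$percent_of_control),
      .groups = "drop"
    ) |>
    dplyr::right_join(grid, by = c("marker", "period")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      direction = dplyr::case_when(
        is.na(.data$mean_percent) ~ "absent",
        abs(.data$mean_percent - 100) < 1e-8 ~ "at control",
        .data$mean_percent > 100 ~ "above control",
        .default = "below control"
      )
    ) |>
    dplyr::arrange(.data$marker, dplyr::desc(.data$period))
}
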