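#' Define a trend-fitting period
#'
#' @param label period label, e.g. `"1978/80-2012"`.
#' @param start,end inclusive calendar-year bounds, `start < end`.
#' @return an object of class `cog_period`.
#' @export
period_spec <- function(label, start, end) {
  if (!(start < end)) stop("`start` must be before `end`", call. = FALSE)
  structure(list(label = label, start = start, end = end),
            class = "cog_period")
}

#' Ordinary-least-squares slope of a standardized series on calendar year
#'
#' Fits `value ~ year` by OLS over the observations falling inside the
#' (inclusive) period window and returns the slope in standardized points
#' per calendar year. Each subject keeps its own survey years as x-values;
#' offset subjects (mathematics 1978 vs reading 1980) must be fit
#' separately, never on the combined cohort series.
#'
#' @param points data frame with columns `year` and `value`.
#' @param period optional [period_spec()]; `NULL` uses all points.
#' @return slope (numeric scalar).
#' @examples
#' fit_slope(data.frame(year = c(2000, 2010), value = c(100, 101)))
#' @export
fit_slope <- function(points, period = NULL) {
  check_columns(points, c("year", "value"), "points")
  if (!is.null(period)) {
    stopifnot(inherits(period, "cog_period"))
    points <- points[points$year >= period$start & points$year <= period$end, ]
  }
  points <- points[is.finite(points$year) & is.finite(points$value), ]
  if (nrow(points) < 2) {
    stop("insufficient data: need at least 2 observations in the period",
         call. = FALSE)
  }
  if (length(unique(points$year)) < 2) {
    stop("degenerate design: zero variance in `year`", call. = FALSE)
  }
  unname(coef(lm(value ~ year, data = points))[2])
}

#' Average per-subject slopes into one group slope
#'
#' Group trend = arithmetic mean of the subject-specific OLS slopes, kept at
#' full precision. This is not in general equal to the slope of the
#' combined cohort series when subjects are surveyed in offset years.
#'
#' @param slopes named numeric vector (or list) of per-subject slopes.
#' @return mean slope.
#' @examples
#' average_subject_slopes(c(mathematics = 0.0914, reading = 0.0016))
#' @export
average_subject_slopes <- function(slopes) {
  slopes <- unlist(slopes)
  if (length(slopes) == 0) {
    stop("missing data: no subject slopes to average", call. = FALSE)
  }
  base::mean(slopes)
}

#' Fit per-group trend slopes for one or more periods
#'
#' Runs [fit_slope()] per (group, subject, period) on the per-subject rows of
#' a standardized series and appends `subject = "Average"` rows from
#' [average_subject_slopes()].
#'
#' @param std output of [standardize_assessment()] (per-subject rows are
#'   used; `"__combined__"` rows are ignored).
#' @param periods list of [period_spec()] objects.
#' @return tibble `group`, `subject`, `period`, `slope`.
#' @export
fit_group_slopes <- function(std, periods) {
  check_columns(std, c("group", "subject", "year", "value"), "std")
  if (inherits(periods, "cog_period")) periods <- list(periods)
  per_subject <- std %>% filter(.data$subject != "__combined__")

  rows <- list()
  for (p in periods) {
    fits <- per_subject %>%
      group_by(.data$group, .data$subject) %>%
      summarise(slope = fit_slope(
        data.frame(year = .data$year, value = .data$value), p
      ), .groups = "drop") %>%
      mutate(period = p$label)
    avg <- fits %>%
      group_by(.data$group) %>%
      summarise(slope = average_subject_slopes(.data$slope),
                .groups = "drop") %>%
      mutate(subject = "Average", period = p$label)
    rows[[p$label]] <- bind_rows(fits, avg)
  }
  bind_rows(rows) %>% select("group", "subject", "period", "slope")
}

#' Build anchored linear trend models
#'
#' A trend model predicts `anchor_value + slope * (year - anchor_year)`.
#' The intercept is the observed value at the anchor year (the last survey),
#' not a regression intercept, so projections start exactly at the latest
#' measured level.
#'
#' @param anchors named numeric vector: group -> observed standardized value
#'   at `anchor_year`.
#' @param slopes named numeric vector: group -> slope (points/year); names
#'   must match `anchors`.
#' @param period period label the slopes were fit on.
#' @param anchor_year calendar year of the anchor (default 2012).
#' @return tibble `group`, `slope`, `anchor_year`, `anchor_value`, `period`
#'   of class `cog_trend_models`.
#' @export
trend_models <- function(anchors, slopes, period, anchor_year = 2012) {
  groups <- names(anchors)
  if (is.null(groups) || is.null(names(slopes))) {
    stop("`anchors` and `slopes` must be named by group", call. = FALSE)
  }
  if (!setequal(groups, names(slopes))) {
    stop("`anchors` and `slopes` must cover the same groups", call. = FALSE)
  }
  if (any(!is.finite(anchors)) || any(!is.finite(slopes))) {
    stop("anchors and slopes must be finite", call. = FALSE)
  }
  out <- tibble(
    group = groups,
    slope = unname(slopes[groups]),
    anchor_year = anchor_year,
    anchor_value = unname(anchors[groups]),
    period = period
  )
  class(out) <- c("cog_trend_models", class(out))
  out
}

#' Build one trend model from a standardized series
#'
#' Reads the anchor value off the combined series at `anchor_year` (matching
#' the cohort whose label or display year equals the anchor) and pairs it
#' with an externally fitted slope.
#'
#' @param series standardized series for one group (rows of
#'   [standardize_assessment()] output with `subject == "__combined__"`).
#' @param slope slope in points per year.
#' @param period period label.
#' @param anchor_year anchor calendar year (default 2012).
#' @return one-row `cog_trend_models` tibble.
#' @export
build_trend_model <- function(series, slope, period, anchor_year = 2012) {
  check_columns(series, c("group", "cohort_year", "value"), "series")
  if ("subject" %in% names(series)) {
    series <- series %>% filter(.data$subject == "__combined__")
  }
  hit <- series[series$cohort_year == anchor_year, ]
  if (nrow(hit) != 1) {
    stop(sprintf("anchor missing: no combined observation at year %s",
                 anchor_year), call. = FALSE)
  }
  trend_models(
    anchors = setNames(hit$value, hit$group),
    slopes = setNames(slope, hit$group),
    period = period, anchor_year = anchor_year
  )
}

#' Best/worst-case scenario slopes
#'
#' Assigns every group the maximum (`"best"`) or minimum (`"worst"`) slope
#' observed across groups — the socially possible envelope. Ties are broken
#' deterministically by `group_order` (default: the models' own group order):
#' the donor group is the first tied group in that order.
#'
#' @param models a `cog_trend_models` tibble (all rows must share a period).
#' @param mode `"best"` or `"worst"`.
#' @param group_order optional character vector fixing tie-break precedence.
#' @return named numeric vector group -> scenario slope (all equal), with the
#'   donor group in attribute `"donor"`.
#' @export
scenario_slopes <- function(models, mode = c("best", "worst"),
                            group_order = NULL) {
  mode <- match.arg(mode)
  check_columns(models, c("group", "slope", "period"), "models")
  if (length(unique(models$period)) > 1) {
    stop("inconsistent periods: all models must share one period",
         call. = FALSE)
  }
  if (is.null(group_order)) group_order <- models$group
  ord <- match(models$group, group_order)
  models <- models[order(ord), ]
  pick <- if (mode == "best") which.max(models$slope) else
    which.min(models$slope)
  out <- setNames(rep(models$slope[pick], nrow(models)), models$group)
  attr(out, "donor") <- models$group[pick]
  out
}

#' Evaluate trend models at given years
#'
#' @param models `cog_trend_models` tibble.
#' @param years calendar years.
#' @return tibble `group`, `year`, `value`.
#' @export
predict_trend <- function(models, years) {
  check_columns(models, c("group", "slope", "anchor_year", "anchor_value"),
                "models")
  tidyr::crossing(models, year = years) %>%
    mutate(value = .data$anchor_value +
             .data$slope * (.data$year - .data$anchor_year)) %>%
    select("group", "year", "value")
}
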