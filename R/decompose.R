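#' Four-term decomposition of projected population change
#'
#' Splits the projected change of the population-weighted mean between the
#' baseline year `y0` (the models' anchor year) and a horizon year `y` into
#' four exactly additive components, with one group (the largest, here
#' White) as baseline:
#'
#' * `e_base  = (y - y0) * m_base` — the rise if every group shared the
#'   baseline group's slope;
#' * `e_minor = (y - y0) * sum_r p_{y0,r} (m_r - m_base)` — minority
#'   catch-up, at baseline-year composition;
#' * `e_pop   = sum_r v_{y0,r} (p_{y,r} - p_{y0,r})` — composition change at
#'   baseline-year levels;
#' * `e_pm    = (y - y0) * sum_r (p_{y,r} - p_{y0,r}) (m_r - m_base)` — the
#'   interaction of catch-up with composition change.
#'
#' All shares are renormalized over the modeled groups before use; the
#' algebra requires weights summing to one, and only then does
#' `e_base + e_minor + e_pop + e_pm` equal the directly computed population
#' change exactly. The catch-up term uses baseline-year shares — the form
#' under which the identity closes.
#'
#' @param models `cog_trend_models` from [trend_models()].
#' @param shares a [share_table()] covering `year` and the anchor year.
#' @param year horizon year(s).
#' @param baseline_group group whose slope is the baseline trend.
#' @return tibble `period`, `year`, `e_base`, `e_minor`, `e_pop`, `e_pm`,
#'   `e_total` (one row per horizon year).
#' @export
decompose <- function(models, shares, year, baseline_group) {
  check_columns(models, c("group", "slope", "anchor_year", "anchor_value",
                          "period"), "models")
  if (!baseline_group %in% models$group) {
    stop(sprintf("configuration error: baseline group '%s' not among models",
                 baseline_group), call. = FALSE)
  }
  y0 <- models$anchor_year[1]
  groups <- models$group
  m <- setNames(models$slope, groups)
  v0 <- setNames(models$anchor_value, groups)
  m_base <- m[[baseline_group]]

  p0 <- renormalize_shares(interpolate_shares(shares, y0)[groups])

  rows <- lapply(year, function(y) {
    py <- renormalize_shares(interpolate_shares(shares, y)[groups])
    dt <- y - y0
    e_base <- dt * m_base
    e_minor <- dt * sum(p0 * (m - m_base))
    e_pop <- sum(v0 * (py - p0))
    e_pm <- dt * sum((py - p0) * (m - m_base))
    tibble(period = models$period[1], year = y,
           e_base = e_base, e_minor = e_minor, e_pop = e_pop, e_pm = e_pm,
           e_total = e_base + e_minor + e_pop + e_pm)
  })
  bind_rows(rows)
}

renormalize_shares <- function(p) {
  s <- sum(p)
  if (s <= 0) stop("empty population: share sum must be positive",
                   call. = FALSE)
  p / s
}

#' Per-decade rates for a decomposition row
#'
#' Divides each component of a single-year [decompose()] row by the number
#' of decades elapsed since the anchor year, at full precision.
#'
#' @param effects one-row tibble from [decompose()].
#' @param anchor_year baseline year (default 2012).
#' @return one-row tibble with the five components per decade.
#' @export
per_decade_effects <- function(effects, anchor_year = 2012) {
  stopifnot(nrow(effects) == 1)
  decades <- (effects$year - anchor_year) / 10
  if (decades <= 0) stop("invalid horizon", call. = FALSE)
  effects %>%
    mutate(across(all_of(c("e_base", "e_minor", "e_pop", "e_pm", "e_total")),
                  ~ .x / decades))
}

#' Convert an ability change into per-capita economic gain
#'
#' Applies a constant-dollar conversion: each standardized point is worth
#' `dollars_per_point` of per-capita GDP per year (default $810, 2010/2011
#' USD at purchasing-power parity), with no inflation or baseline growth.
#' The result is rounded to whole currency units for reporting; pass deltas
#' at the precision you report them (published figures multiply the
#' two-decimal component values).
#'
#' @param delta ability change in standardized points (vectorized).
#' @param dollars_per_point currency per point per capita per year.
#' @return whole-dollar gain(s).
#' @examples
#' economic_gain(3.68) # 2981
#' @export
economic_gain <- function(delta, dollars_per_point = 810) {
  if (!is.finite(dollars_per_point)) {
    stop("`dollars_per_point` must be finite", call. = FALSE)
  }
  round_half_up(delta * dollars_per_point, 0)
}
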