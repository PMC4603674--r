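#' Construct a composition share table
#'
#' A share table holds population proportions per (year, group). Modeled
#' groups need not exhaust the population: excluded small groups mean
#' per-year sums below 1, which downstream weighting handles by
#' renormalization.
#'
#' @param df data frame with columns `year`, `group`, `proportion`
#'   (fractions in `[0, 1]`).
#' @return tibble of class `cog_shares`, sorted by year.
#' @export
share_table <- function(df) {
  check_columns(df, c("year", "group", "proportion"), "df")
  if (any(df$proportion < -1e-12 | df$proportion > 1 + 1e-12)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  sums <- tapply(df$proportion, df$year, sum)
  if (any(sums > 1 + 1e-9)) {
    stop("per-year share sums must not exceed 1", call. = FALSE)
  }
  out <- as_tibble(df) %>% arrange(.data$year, .data$group)
  class(out) <- c("cog_shares", class(out))
  out
}

#' Composition shares at an arbitrary year
#'
#' Returns the tabulated row when the year is on the grid, otherwise linear
#' interpolation per group between the bracketing rows. Years outside the
#' table's range raise an error — there is no silent extrapolation.
#'
#' @param shares a [share_table()].
#' @param year calendar year.
#' @return named numeric vector group -> proportion.
#' @export
interpolate_shares <- function(shares, year) {
  check_columns(shares, c("year", "group", "proportion"), "shares")
  rng <- range(shares$year)
  if (year < rng[1] || year > rng[2]) {
    stop(sprintf(
      "extrapolation error: year %s outside share table range [%s, %s]",
      year, rng[1], rng[2]
    ), call. = FALSE)
  }
  groups <- unique(shares$group)
  vapply(groups, function(g) {
    rows <- shares[shares$group == g, ]
    approx(rows$year, rows$proportion, xout = year, method = "linear",
           ties = "ordered")$y
  }, numeric(1))
}

#' Population-share-weighted mean of group values
#'
#' With `renormalize = TRUE` (default) the weights are divided by their sum,
#' so the result is a convex combination of the group values even when the
#' modeled groups cover less than the whole population.
#'
#' @param group_values named numeric vector group -> value.
#' @param shares named numeric vector group -> proportion; must cover the
#'   same groups.
#' @param renormalize divide by the share sum (default `TRUE`).
#' @return weighted mean.
#' @examples
#' weighted_population_mean(c(a = 100, b = 90), c(a = 0.6, b = 0.3))
#' @export
weighted_population_mean <- function(group_values, shares,
                                     renormalize = TRUE) {
  if (!setequal(names(group_values), names(shares))) {
    stop("groups of values and shares must coincide", call. = FALSE)
  }
  w <- shares[names(group_values)]
  s <- sum(w)
  if (s <= 0) stop("empty population: share sum must be positive",
                   call. = FALSE)
  total <- sum(w * group_values)
  if (renormalize) total / s else total
}

#' Project group and population trajectories
#'
#' Evaluates each group's anchored linear trend at the requested years and
#' adds a `"population"` row per year: the share-weighted (renormalized)
#' mean of the group values using that year's composition. Under
#' `scenario = "best"`/`"worst"` every group is first assigned the
#' maximum/minimum group slope via [scenario_slopes()].
#'
#' @param models `cog_trend_models` from [trend_models()].
#' @param shares a [share_table()] covering all requested years.
#' @param years calendar years to project.
#' @param scenario `"standard"`, `"best"` or `"worst"`.
#' @param renormalize passed to [weighted_population_mean()].
#' @param group_order tie-break order for [scenario_slopes()].
#' @return tibble `scenario`, `period`, `year`, `group` (including
#'   `"population"`), `value`.
#' @export
project <- function(models, shares, years,
                    scenario = c("standard", "best", "worst"),
                    renormalize = TRUE, group_order = NULL) {
  scenario <- match.arg(scenario)
  check_columns(models, c("group", "slope", "anchor_year", "anchor_value",
                          "period"), "models")
  if (length(unique(models$anchor_year)) > 1 ||
      length(unique(models$period)) > 1) {
    stop("all models must share `anchor_year` and `period`", call. = FALSE)
  }
  if (scenario != "standard") {
    sl <- scenario_slopes(models, mode = scenario, group_order = group_order)
    models$slope <- unname(sl[models$group])
  }
  traj <- predict_trend(models, years)
  pop <- lapply(years, function(y) {
    p <- interpolate_shares(shares, y)
    v <- traj$value[traj$year == y]
    names(v) <- traj$group[traj$year == y]
    tibble(group = "population", year = y,
           value = unname(weighted_population_mean(v, p[names(v)],
                                                   renormalize)))
  })
  bind_rows(traj, bind_rows(pop)) %>%
    mutate(scenario = scenario, period = models$period[1]) %>%
    select("scenario", "period", "year", "group", "value") %>%
    arrange(.data$year, .data$group)
}

#' Difference between two groups' projected values
#'
#' @param result output of [project()].
#' @param year calendar year present in `result`.
#' @param group_a,group_b group labels; the gap is `a - b`.
#' @return numeric gap.
#' @export
group_gap <- function(result, year, group_a, group_b) {
  check_columns(result, c("year", "group", "value"), "result")
  get1 <- function(g) {
    v <- result$value[result$year == year & result$group == g]
    if (length(v) != 1) {
      stop(sprintf("lookup error: no unique value for group '%s' at %s",
                   g, year), call. = FALSE)
    }
    v
  }
  get1(group_a) - get1(group_b)
}

#' Change per decade
#'
#' @param total_change change over the whole horizon (standardized points).
#' @param horizon_years length of the horizon in years (> 0).
#' @return change per 10 years.
#' @examples
#' per_decade_rate(2.16, 48) # 0.45
#' @export
per_decade_rate <- function(total_change, horizon_years) {
  if (any(horizon_years <= 0)) {
    stop("invalid horizon: `horizon_years` must be positive", call. = FALSE)
  }
  total_change / (horizon_years / 10)
}
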