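#' Define a synthetic assessment scenario
#'
#' A scenario fixes the ground truth for simulation: per-(group, subject)
#' linear trends on the standardized scale, anchored at `anchor_year`;
#' a raw-scale benchmark used to map standardized values back to assessment
#' scale units; additive Gaussian survey noise (in standardized points); and
#' linearly drifting composition shares. Everything downstream of the
#' generator is the ordinary pipeline, so true parameter values are known
#' exactly and recovery can be measured.
#'
#' @param groups character vector of group labels.
#' @param survey_years named list: subject -> vector of survey years.
#' @param true_slopes data frame `group`, `subject`, `slope` (points/year).
#' @param bench a [benchmark()] carrying explicit raw-scale anchors
#'   (`raw` with one row per subject) so generation and standardization use
#'   the same scale.
#' @param anchor_levels named vector: group -> standardized level at
#'   `anchor_year`.
#' @param anchor_year year at which `anchor_levels` hold (default 2012).
#' @param noise_sd standard deviation of additive Gaussian noise per
#'   observation, standardized points (>= 0; default 0).
#' @param share_start,share_end named vectors: group -> share at the ends of
#'   `share_range`; each must sum to at most 1.
#' @param share_range two years between which shares drift linearly.
#' @param seed integer seed; all generation is reproducible given it.
#' @return object of class `cog_scenario`.
#' @export
synthetic_scenario <- function(groups, survey_years, true_slopes, bench,
                               anchor_levels, anchor_year = 2012,
                               noise_sd = 0, share_start = NULL,
                               share_end = NULL,
                               share_range = c(2012, 2060), seed = 1L) {
  stopifnot(inherits(bench, "cog_benchmark"), !is.null(bench$raw))
  check_columns(true_slopes, c("group", "subject", "slope"), "true_slopes")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(survey_years) == 0 || any(lengths(survey_years) == 0)) {
    stop("`survey_years` must be non-empty per subject", call. = FALSE)
  }
  if (!setequal(names(anchor_levels), groups)) {
    stop("`anchor_levels` must be named by the scenario groups",
         call. = FALSE)
  }
  for (p in list(share_start, share_end)) {
    if (!is.null(p) && sum(p) > 1 + 1e-9) {
      stop("invalid scenario: share path implies a year-sum > 1",
           call. = FALSE)
    }
  }
  structure(
    list(groups = groups, survey_years = survey_years,
         true_slopes = as_tibble(true_slopes), bench = bench,
         anchor_levels = anchor_levels, anchor_year = anchor_year,
         noise_sd = noise_sd, share_start = share_start,
         share_end = share_end, share_range = share_range,
         seed = as.integer(seed)),
    class = "cog_scenario"
  )
}

#' Publication-calibrated default scenario
#'
#' Mirrors the motivating study's structure: four groups, two subjects
#' surveyed in offset years (11 cohorts, 1978-2012), true per-subject slopes
#' and 2012 anchor levels taken from the packaged fixtures, and a share path
#' drifting from the 2012 to the 2060 census row. The raw-scale benchmark
#' constants (mathematics 306/31, reading 286/39) are synthetic plausible
#' assessment-scale values: the published source does not print raw means
#' and dispersions, and the standardized results do not depend on them.
#'
#' @param noise_sd Gaussian noise SD in standardized points (default 0).
#' @param seed integer seed (default 1).
#' @return a [synthetic_scenario()].
#' @export
paper_scenario <- function(noise_sd = 0, seed = 1L) {
  slopes <- load_fixture("table2_slopes") %>%
    filter(.data$period == "1978/80-2012", .data$subject != "Average") %>%
    select("group", "subject", "slope") %>%
    mutate(subject = tolower(.data$subject))
  t1 <- load_fixture("table1_standardized") %>%
    filter(.data$cohort_year == 2012, .data$group != "Average")
  t4 <- load_fixture("table4_census_shares")
  p12 <- interpolate_shares(t4, 2012)
  p60 <- interpolate_shares(t4, 2060)
  groups <- unique(slopes$group)
  bench <- benchmark(
    group = "White",
    subject_years = c(mathematics = 1978, reading = 1980),
    raw = tibble(subject = c("mathematics", "reading"),
                 mean = c(306, 286), sd = c(31, 39))
  )
  synthetic_scenario(
    groups = groups,
    survey_years = list(
      mathematics = c(1978, 1982, 1986, 1990, 1992, 1994, 1996, 1999,
                      2004, 2008, 2012),
      reading = c(1980, 1984, 1988, 1990, 1992, 1994, 1996, 1999,
                  2004, 2008, 2012)
    ),
    true_slopes = slopes,
    bench = bench,
    anchor_levels = setNames(t1$value, t1$group),
    anchor_year = 2012,
    noise_sd = noise_sd,
    share_start = p12[groups], share_end = p60[groups],
    share_range = c(2012, 2060),
    seed = seed
  )
}

#' Generate a raw-scale assessment dataset from a scenario
#'
#' True standardized value for (group g, subject s, year y) is
#' `anchor_level[g] + slope[g, s] * (y - anchor_year)` plus Gaussian noise;
#' the raw mean is obtained by inverting the standardization formula against
#' the scenario's raw benchmark, and the reported dispersion equals the
#' benchmark SD. Deterministic given the seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed overrides `scenario$seed` (used for replicate streams).
#' @return tibble `group`, `subject`, `year`, `mean`, `sd`.
#' @export
generate_assessment <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "cog_scenario"))
  set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
  bench <- scenario$bench
  grid <- tidyr::crossing(
    group = scenario$groups,
    tibble(subject = rep(names(scenario$survey_years),
                         lengths(scenario$survey_years)),
           year = unlist(scenario$survey_years, use.names = FALSE))
  ) %>%
    left_join(scenario$true_slopes, by = c("group", "subject"))
  if (any(is.na(grid$slope))) {
    stop("`true_slopes` must cover every (group, subject)", call. = FALSE)
  }
  n <- nrow(grid)
  noise <- rnorm(n, 0, scenario$noise_sd)
  value <- unname(scenario$anchor_levels[grid$group]) +
    grid$slope * (grid$year - scenario$anchor_year) + noise
  bench_mean <- setNames(bench$raw$mean, bench$raw$subject)
  bench_sd <- setNames(bench$raw$sd, bench$raw$subject)
  tibble(
    group = grid$group, subject = grid$subject, year = grid$year,
    mean = (value - bench$target_mean) / bench$target_sd *
      unname(bench_sd[grid$subject]) + unname(bench_mean[grid$subject]),
    sd = unname(bench_sd[grid$subject])
  )
}

#' Generate a composition share table from a scenario
#'
#' Shares drift linearly from `share_start` to `share_end` over
#' `share_range`; per-year sums are preserved and validated to stay at or
#' below 1.
#'
#' @param scenario a [synthetic_scenario()] with share paths.
#' @param years years to tabulate.
#' @return a [share_table()].
#' @export
generate_shares <- function(scenario, years) {
  stopifnot(inherits(scenario, "cog_scenario"))
  if (is.null(scenario$share_start) || is.null(scenario$share_end)) {
    stop("scenario has no share path", call. = FALSE)
  }
  r <- scenario$share_range
  rows <- lapply(years, function(y) {
    w <- (y - r[1]) / (r[2] - r[1])
    p <- (1 - w) * scenario$share_start + w * scenario$share_end
    if (sum(p) > 1 + 1e-9) {
      stop("invalid scenario: share path implies a year-sum > 1",
           call. = FALSE)
    }
    tibble(year = y, group = names(p), proportion = unname(p))
  })
  share_table(bind_rows(rows))
}

#' Parameter-recovery experiment
#'
#' Runs the full pipeline (generate, standardize against the scenario's raw
#' benchmark, fit per-subject slopes, average) on `replicates` independent
#' datasets and reports per-group bias and RMSE of the recovered average
#' slope, plus the largest violation of the decomposition additivity
#' identity observed when decomposing each replicate's fitted models at the
#' share-path horizon. Replicate r uses seed `scenario$seed + r - 1`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param replicates number of replicate datasets (>= 1).
#' @return list with `slopes` (tibble `group`, `truth`, `bias`, `rmse`),
#'   `estimates` (tibble `replicate`, `group`, `estimate`), and
#'   `max_identity_violation`.
#' @export
recovery_experiment <- function(scenario, replicates) {
  stopifnot(inherits(scenario, "cog_scenario"), replicates >= 1)
  span <- range(unlist(scenario$survey_years))
  full_period <- period_spec("full", span[1], span[2])
  truth <- scenario$true_slopes %>%
    group_by(.data$group) %>%
    summarise(truth = base::mean(.data$slope), .groups = "drop")

  has_shares <- !is.null(scenario$share_start)
  horizon <- scenario$share_range[2]
  shares <- if (has_shares) {
    generate_shares(scenario, scenario$share_range)
  }

  est <- list()
  max_viol <- 0
  for (r in seq_len(replicates)) {
    dat <- generate_assessment(scenario, seed = scenario$seed + r - 1L)
    std <- standardize_assessment(dat, scenario$bench)
    sl <- fit_group_slopes(std, full_period) %>%
      filter(.data$subject == "Average")
    est[[r]] <- tibble(replicate = r, group = sl$group, estimate = sl$slope)

    if (has_shares) {
      anchors <- std %>%
        filter(.data$subject == "__combined__",
               .data$cohort_year == scenario$anchor_year)
      models <- trend_models(
        anchors = setNames(anchors$value, anchors$group),
        slopes = setNames(sl$slope, sl$group),
        period = "full", anchor_year = scenario$anchor_year
      )
      eff <- decompose(models, shares, horizon,
                       baseline_group = scenario$groups[1])
      direct <- project(models, shares, c(scenario$anchor_year, horizon))
      pop <- direct$value[direct$group == "population"]
      max_viol <- max(max_viol, abs(eff$e_total - (pop[2] - pop[1])))
    }
  }
  estimates <- bind_rows(est)
  slopes <- estimates %>%
    left_join(truth, by = "group") %>%
    group_by(.data$group, .data$truth) %>%
    summarise(
      bias = base::mean(.data$estimate - .data$truth),
      rmse = sqrt(base::mean((.data$estimate - .data$truth)^2)),
      .groups = "drop"
    )
  list(slopes = slopes, estimates = estimates,
       max_identity_violation = max_viol)
}
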