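#' Convert a raw assessment score to the benchmark-standardized metric
#'
#' Linearly rescales a raw group mean so that the benchmark group-year mean
#' maps to `target_mean` and one benchmark standard deviation maps to
#' `target_sd` points. With the defaults (100/15) this is the conventional
#' IQ-metric conversion:
#' `(mean - benchmark_mean) / benchmark_sd * target_sd + target_mean`.
#'
#' @param mean raw scale score (vectorized).
#' @param benchmark_mean raw scale mean of the benchmark group-year.
#' @param benchmark_sd raw scale standard deviation of the benchmark
#'   group-year; must be strictly positive.
#' @param target_mean,target_sd location and scale of the standardized
#'   metric (defaults 100 and 15).
#' @return standardized score(s), same length as `mean`.
#' @examples
#' standardize_score(250, 290, 40) # 85
#' @export
standardize_score <- function(mean, benchmark_mean, benchmark_sd,
                              target_mean = 100, target_sd = 15) {
  if (any(!is.finite(benchmark_sd)) || any(benchmark_sd <= 0)) {
    stop("invalid benchmark: `benchmark_sd` must be strictly positive",
         call. = FALSE)
  }
  if (target_sd <= 0) {
    stop("invalid benchmark: `target_sd` must be strictly positive",
         call. = FALSE)
  }
  (mean - benchmark_mean) / benchmark_sd * target_sd + target_mean
}

#' Define a standardization benchmark
#'
#' The benchmark fixes the origin and unit of the standardized metric. It
#' names a reference group and, per subject, the survey year whose observed
#' mean and dispersion anchor the scale (the motivating analysis uses the
#' White group, mathematics 1978 and reading 1980). Raw-scale anchor values
#' are normally resolved from the dataset itself; `raw` supplies them
#' explicitly instead (a data frame with columns `subject`, `mean`, `sd`),
#' which synthetic round-trip experiments use so the generating scale and the
#' standardizing scale coincide exactly.
#'
#' @param group benchmark group label.
#' @param subject_years named vector/list mapping subject to benchmark year.
#' @param target_mean,target_sd standardized location/scale (100/15).
#' @param raw optional data frame `subject`, `mean`, `sd` of explicit
#'   raw-scale anchors overriding data-derived ones.
#' @return an object of class `cog_benchmark`.
#' @export
benchmark <- function(group, subject_years, target_mean = 100,
                      target_sd = 15, raw = NULL) {
  if (target_sd <= 0) stop("`target_sd` must be positive", call. = FALSE)
  subject_years <- unlist(subject_years)
  if (is.null(names(subject_years)) || any(names(subject_years) == "")) {
    stop("`subject_years` must be named by subject", call. = FALSE)
  }
  if (!is.null(raw)) {
    check_columns(raw, c("subject", "mean", "sd"), "raw")
    if (any(raw$sd <= 0)) {
      stop("invalid benchmark: raw `sd` must be strictly positive",
           call. = FALSE)
    }
  }
  structure(
    list(group = group, subject_years = subject_years,
         target_mean = target_mean, target_sd = target_sd, raw = raw),
    class = "cog_benchmark"
  )
}

#' Pair offset survey years into combined cohorts
#'
#' Long-running assessments often alternate subjects across nearby years
#' (e.g. mathematics surveyed in 1978 and reading in 1980). For display the
#' two surveys form one cohort labelled by the year span ("1978/80"); trend
#' fitting still uses each subject's own calendar year. Years of different
#' subjects are merged greedily, earliest first, while they lie within
#' `max_gap` years of the cohort's first year.
#'
#' @param subject_years named list mapping subject to a sorted vector of
#'   survey years.
#' @param max_gap largest year offset merged into one cohort (default 2).
#' @return tibble with columns `cohort_label`, `cohort_year` (the earliest
#'   year of the cohort, used for display), `subject`, `year`. Cohorts that
#'   do not include every subject are kept as singletons with a warning.
#' @examples
#' pair_survey_years(list(mathematics = c(1978, 1990), reading = c(1980, 1990)))
#' @export
pair_survey_years <- function(subject_years, max_gap = 2) {
  stopifnot(is.list(subject_years), length(subject_years) > 0)
  for (s in names(subject_years)) {
    if (is.unsorted(subject_years[[s]])) {
      stop(sprintf("survey years for subject '%s' must be sorted", s),
           call. = FALSE)
    }
  }
  entries <- tibble(
    subject = rep(names(subject_years), lengths(subject_years)),
    year = unlist(subject_years, use.names = FALSE)
  ) %>% arrange(year, subject)

  assigned <- integer(nrow(entries))
  cohort <- 0L
  for (i in seq_len(nrow(entries))) {
    if (assigned[i] != 0L) next
    cohort <- cohort + 1L
    assigned[i] <- cohort
    start_year <- entries$year[i]
    members <- entries$subject[i]
    j <- i + 1L
    while (j <= nrow(entries) && entries$year[j] - start_year <= max_gap) {
      if (assigned[j] == 0L && !(entries$subject[j] %in% members)) {
        assigned[j] <- cohort
        members <- c(members, entries$subject[j])
      }
      j <- j + 1L
    }
  }
  entries$cohort <- assigned

  out <- entries %>%
    group_by(.data$cohort) %>%
    mutate(
      cohort_year = min(.data$year),
      cohort_label = cohort_span_label(.data$year)
    ) %>%
    ungroup() %>%
    select("cohort_label", "cohort_year", "subject", "year")

  n_subjects <- length(subject_years)
  if (n_subjects > 1) {
    sizes <- table(assigned)
    incomplete <- sum(sizes < n_subjects)
    if (incomplete > 0) {
      warning(sprintf(
        "%d survey cohort(s) could not be paired across all subjects within a gap of %d years; kept as singletons",
        incomplete, max_gap
      ), call. = FALSE)
    }
  }
  out
}

# "1978/80" style label: earliest year, then two-digit suffixes of the rest
cohort_span_label <- function(years) {
  u <- sort(unique(years))
  if (length(u) == 1) return(as.character(u))
  paste0(u[1], "/", paste(sprintf("%02d", u[-1] %% 100), collapse = "/"))
}

#' Average per-subject standardized values into one cohort value
#'
#' The combined cohort series is the arithmetic mean of the per-subject
#' standardized values; standardization always happens per subject first.
#'
#' @param values named numeric vector (or list) of per-subject values.
#' @return the arithmetic mean.
#' @examples
#' combine_subjects(c(mathematics = 98, reading = 102))
#' @export
combine_subjects <- function(values) {
  values <- unlist(values)
  if (length(values) == 0) {
    stop("missing data: no subject values to combine", call. = FALSE)
  }
  base::mean(values)
}

#' Standardize an assessment dataset against a benchmark
#'
#' Takes raw group-level summaries (one row per group x subject x survey
#' year) and returns the standardized series: per-subject standardized values
#' plus a combined row (`subject = "__combined__"`) averaging the subjects
#' within each paired survey cohort.
#'
#' @param obs data frame with columns `group`, `subject`, `year`, `mean`,
#'   `sd` (and optionally `share`).
#' @param bench a [benchmark()] object. Raw anchors are taken from `bench$raw`
#'   when supplied, otherwise from the benchmark group's own row at the
#'   benchmark year for each subject.
#' @param exclude_groups character vector of group labels dropped before
#'   standardization (groups with insufficient data are excluded explicitly,
#'   never silently).
#' @param max_gap passed to [pair_survey_years()].
#' @return tibble `group`, `cohort_label`, `cohort_year`, `subject`, `year`,
#'   `value`; combined rows have `year = NA`.
#' @export
standardize_assessment <- function(obs, bench, exclude_groups = character(),
                                   max_gap = 2) {
  check_columns(obs, c("group", "subject", "year", "mean", "sd"), "obs")
  stopifnot(inherits(bench, "cog_benchmark"))
  if (any(obs$sd <= 0, na.rm = TRUE)) {
    stop("invalid data: `sd` must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(obs[c("group", "subject", "year")]) > 0) {
    stop("(group, subject, year) must be unique", call. = FALSE)
  }
  obs <- obs %>% filter(!(.data$group %in% exclude_groups))

  subjects <- unique(obs$subject)
  missing_bench <- setdiff(subjects, names(bench$subject_years))
  if (length(missing_bench) > 0) {
    stop(sprintf("no benchmark year for subject(s): %s",
                 paste(missing_bench, collapse = ", ")), call. = FALSE)
  }

  anchors <- resolve_benchmark_raw(obs, bench)

  std <- obs %>%
    left_join(anchors, by = "subject") %>%
    mutate(value = standardize_score(
      .data$mean, .data$bench_mean, .data$bench_sd,
      bench$target_mean, bench$target_sd
    )) %>%
    select("group", "subject", "year", "value")

  pairing <- pair_survey_years(
    lapply(split(obs$year, obs$subject), function(y) sort(unique(y))),
    max_gap = max_gap
  )
  std <- std %>% left_join(pairing, by = c("subject", "year"))

  combined <- std %>%
    group_by(.data$group, .data$cohort_label, .data$cohort_year) %>%
    summarise(value = combine_subjects(.data$value), .groups = "drop") %>%
    mutate(subject = "__combined__", year = NA_real_)

  bind_rows(
    std %>% select("group", "cohort_label", "cohort_year", "subject",
                   "year", "value"),
    combined %>% select("group", "cohort_label", "cohort_year", "subject",
                        "year", "value")
  ) %>%
    arrange(.data$group, .data$cohort_year, .data$subject)
}

# per-subject raw anchor mean/sd, explicit or data-derived
resolve_benchmark_raw <- function(obs, bench) {
  if (!is.null(bench$raw)) {
    return(tibble(subject = bench$raw$subject,
                  bench_mean = bench$raw$mean, bench_sd = bench$raw$sd))
  }
  subjects <- unique(obs$subject)
  rows <- lapply(subjects, function(s) {
    yr <- bench$subject_years[[s]]
    hit <- obs[obs$group == bench$group & obs$subject == s & obs$year == yr, ]
    if (nrow(hit) != 1) {
      stop(sprintf(
        "invalid benchmark: no observation for group '%s', subject '%s', year %s",
        bench$group, s, yr
      ), call. = FALSE)
    }
    tibble(subject = s, bench_mean = hit$mean, bench_sd = hit$sd)
  })
  bind_rows(rows)
}
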