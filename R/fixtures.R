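#' Load a packaged input table
#'
#' The four published input tables ship with the package at full printed
#' precision and are parsed into tidy form on load. Percentages are
#' converted to fractions for share tables.
#'
#' @param name one of `"table1_standardized"` (group x survey-cohort
#'   standardized scores, plus the participation-weighted `Average` column),
#'   `"table2_slopes"` (per-subject and average slopes for the two fitting
#'   periods), `"table3_student_shares"` (assessment participant shares), or
#'   `"table4_census_shares"` (census population-share projections
#'   2012-2060).
#' @return a tibble; shape depends on the table (see Details).
#' @details
#' * `table1_standardized`: `cohort_label`, `cohort_year`, `group`, `value`
#'   (`group` includes `"Average"`).
#' * `table2_slopes`: `group`, `subject`, `period`, `slope`.
#' * `table3_student_shares`: `subject`, `year`, `group`, `proportion`
#'   (fractions).
#' * `table4_census_shares`: a [share_table()] (`year`, `group`,
#'   `proportion`, fractions; the printed `Sum` column is dropped).
#' @export
load_fixture <- function(name) {
  known <- c("table1_standardized", "table2_slopes",
             "table3_student_shares", "table4_census_shares")
  if (!name %in% known) {
    stop(sprintf("unknown fixture '%s'; expected one of: %s",
                 name, paste(known, collapse = ", ")), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "cogtrend",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  switch(name,
    table1_standardized = raw %>%
      mutate(cohort_year = cohort_display_year(.data$cohort_label)) %>%
      tidyr::pivot_longer(-c("cohort_label", "cohort_year"),
                          names_to = "group", values_to = "value") %>%
      select("cohort_label", "cohort_year", "group", "value"),
    table2_slopes = raw %>%
      tidyr::pivot_longer(-c("subject", "period"),
                          names_to = "group", values_to = "slope") %>%
      select("group", "subject", "period", "slope"),
    table3_student_shares = raw %>%
      select(-"Sum") %>%
      tidyr::pivot_longer(-c("subject", "year"),
                          names_to = "group", values_to = "proportion") %>%
      mutate(proportion = .data$proportion / 100),
    table4_census_shares = share_table(
      raw %>%
        select(-"Sum") %>%
        tidyr::pivot_longer(-"year", names_to = "group",
                            values_to = "proportion") %>%
        mutate(proportion = .data$proportion / 100)
    )
  )
}

# display year of a survey cohort label: the earlier year of the span
cohort_display_year <- function(label) {
  as.numeric(sub("/.*$", "", label))
}

# published projection/effect tables used as golden values by
# reproduce_paper(); internal.
load_golden <- function(name) {
  stopifnot(name %in% paste0("table", 5:10))
  path <- system.file("extdata", "golden", paste0(name, ".csv"),
                      package = "cogtrend", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read/write the tabular interchange schemas
#'
#' Thin readers and writers for the pipeline's CSV schemas. All files are
#' UTF-8 with dot decimals and a header row; writes keep full precision so
#' write-read round trips are lossless.
#'
#' @param path file path.
#' @param percent for `read_shares()`: divide proportions by 100 on load
#'   (for tables typed as printed percentages).
#' @return `read_assessment()`: tibble `group`, `subject`, `year`, `mean`,
#'   `sd` (+ optional `share`); `read_shares()`: a [share_table()];
#'   `read_slopes()`: tibble `group`, `subject`, `period`, `slope`.
#' @name io_schemas
NULL

#' @rdname io_schemas
#' @export
read_assessment <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("group", "subject", "year", "mean", "sd"), "assessment")
  df
}

#' @rdname io_schemas
#' @export
read_shares <- function(path, percent = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("year", "group", "proportion"), "shares")
  if (percent) df$proportion <- df$proportion / 100
  share_table(df)
}

#' @rdname io_schemas
#' @export
read_slopes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("group", "subject", "period", "slope"), "slopes")
  df
}

#' @rdname io_schemas
#' @param x data frame to write.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
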