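#' Trend models from the packaged input tables
#'
#' Builds the anchored trend models the published analysis uses: anchor
#' values are the 2012 row of the packaged standardized-score table, and
#' group slopes are the full-precision mean of the mathematics and reading
#' slopes for the requested period (averaging the printed per-subject
#' slopes, not consuming the printed — independently rounded — average row).
#'
#' @param period `"1978/80-2012"` (optimistic) or `"1992-2012"`
#'   (pessimistic).
#' @return a [trend_models()] tibble for the four groups.
#' @export
paper_models <- function(period = c("1978/80-2012", "1992-2012")) {
  period <- match.arg(period)
  t1 <- load_fixture("table1_standardized") %>%
    filter(.data$cohort_year == 2012, .data$group != "Average")
  slopes <- load_fixture("table2_slopes") %>%
    filter(.data$period == !!period, .data$subject != "Average") %>%
    group_by(.data$group) %>%
    summarise(slope = average_subject_slopes(.data$slope), .groups = "drop")
  trend_models(
    anchors = setNames(t1$value, t1$group),
    slopes = setNames(slopes$slope, slopes$group),
    period = period, anchor_year = 2012
  )
}

# horizon grid of the published projection tables
paper_years <- function() c(2012, seq(2015, 2060, by = 5))

paper_group_order <- function() c("White", "Black", "Hispanic", "Asian")

# wide (year x group + Population) view of a project() result
projection_wide <- function(result) {
  result %>%
    mutate(group = ifelse(.data$group == "population", "Population",
                          .data$group)) %>%
    select("year", "group", "value") %>%
    tidyr::pivot_wider(names_from = "group", values_from = "value") %>%
    select(all_of(c("year", paper_group_order(), "Population")))
}

#' Recompute the published projection and effect tables
#'
#' Runs the whole pipeline from the packaged inputs: standard projections
#' per group and population for both fitting periods, best/worst-case
#' scenario projections with total-increase rows, the four-term effect
#' decomposition with per-decade rates, group-gap summaries and economic
#' conversions. All values are full precision; rounding to printed
#' precision happens only in the written CSVs.
#'
#' @return named list of tibbles: `table5`, `table6` (group/population
#'   projections), `table7`, `table8` (effect decompositions),
#'   `table9`, `table10` (scenario comparisons with `Total increase`),
#'   `per_decade` (components per decade at 2060), `gaps`, `economics`.
#' @export
compute_paper_tables <- function() {
  shares <- load_fixture("table4_census_shares")
  years <- paper_years()
  periods <- c(optimistic = "1978/80-2012", pessimistic = "1992-2012")

  out <- list()
  scen_tabs <- list()
  eff_tabs <- list()
  for (i in seq_along(periods)) {
    models <- paper_models(periods[[i]])
    std <- project(models, shares, years, "standard")
    best <- project(models, shares, years, "best",
                    group_order = paper_group_order())
    worst <- project(models, shares, years, "worst",
                     group_order = paper_group_order())
    out[[paste0("table", 4 + i)]] <- projection_wide(std)

    pop_of <- function(res) {
      res %>% filter(.data$group == "population") %>%
        select("year", "value")
    }
    scen <- pop_of(std) %>% rename(Standard = "value") %>%
      left_join(pop_of(best) %>% rename(Best = "value"), by = "year") %>%
      left_join(pop_of(worst) %>% rename(Worst = "value"), by = "year")
    totals <- scen %>% filter(.data$year %in% c(2012, 2060))
    scen_tabs[[i]] <- list(
      table = scen,
      total = sapply(c("Standard", "Best", "Worst"),
                     function(cn) scen[[cn]][scen$year == 2060] -
                       scen[[cn]][scen$year == 2012])
    )

    eff <- decompose(models, shares, setdiff(years, 2012),
                     baseline_group = "White")
    eff_tabs[[i]] <- eff
    out[[paste0("table", 6 + i)]] <- eff %>% select(-"period")
  }
  out$table9 <- scen_tabs[[1]]$table
  out$table9_total <- scen_tabs[[1]]$total
  out$table10 <- scen_tabs[[2]]$table
  out$table10_total <- scen_tabs[[2]]$total

  out$per_decade <- bind_rows(lapply(seq_along(periods), function(i) {
    per_decade_effects(eff_tabs[[i]] %>% filter(.data$year == 2060))
  }))

  out$gaps <- bind_rows(lapply(seq_along(periods), function(i) {
    models <- paper_models(periods[[i]])
    res <- project(models, shares, c(2012, 2060), "standard")
    tidyr::crossing(
      tibble(pair = c("White-Black", "White-Hispanic", "Asian-White")),
      year = c(2012, 2060)
    ) %>%
      mutate(
        period = periods[[i]],
        gap = vapply(seq_along(.data$pair), function(k) {
          gs <- strsplit(.data$pair[k], "-")[[1]]
          group_gap(res, .data$year[k], gs[1], gs[2])
        }, numeric(1))
      )
  }))

  out$economics <- bind_rows(lapply(seq_along(periods), function(i) {
    eff60 <- eff_tabs[[i]] %>% filter(.data$year == 2060)
    comp <- c(e_base = eff60$e_base, e_minor = eff60$e_minor,
              e_pop = eff60$e_pop, e_pm = eff60$e_pm,
              e_total = eff60$e_total)
    delta <- round_half_up(comp, 2) # dollars reported at printed precision
    tibble(period = periods[[i]], component = names(comp),
           delta_iq = unname(delta),
           dollars = economic_gain(unname(delta)))
  }))
  out
}

#' Regenerate the published tables and check them cell by cell
#'
#' Recomputes every projection, scenario and effect table from the packaged
#' inputs, writes them (rounded to printed precision) plus gap, per-decade
#' and economic summaries under `outdir`, and compares each unrounded
#' computed cell against the packaged printed values at `tolerance`. A
#' comparison report is always written; with `strict = TRUE` any mismatch
#' raises an error (non-zero exit when scripted). Output is deterministic:
#' repeated runs write byte-identical CSVs.
#'
#' @param outdir output directory (created if needed).
#' @param tolerance maximum |computed - printed| per cell (default 0.01).
#' @param strict error on any mismatch (default `TRUE`).
#' @return (invisibly) list with `tables` (computed, full precision),
#'   `comparison` (tibble `table`, `year`, `column`, `printed`, `computed`,
#'   `pass`), and `all_pass`.
#' @export
reproduce_paper <- function(outdir, tolerance = 0.01, strict = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- compute_paper_tables()

  comparison <- list()
  for (nm in paste0("table", 5:10)) {
    printed <- load_golden(nm)
    computed <- tabs[[nm]]
    cols <- setdiff(names(printed), "year")
    merged <- left_join(printed, computed, by = "year",
                        suffix = c(".printed", ".computed"))
    for (cn in cols) {
      comparison[[paste(nm, cn)]] <- tibble(
        table = nm, year = merged$year, column = cn,
        printed = merged[[paste0(cn, ".printed")]],
        computed = merged[[paste0(cn, ".computed")]]
      )
    }
  }
  comparison <- bind_rows(comparison) %>%
    mutate(pass = abs(.data$computed - .data$printed) <= tolerance + 1e-12)

  # written tables carry printed precision (2 decimals on the IQ metric)
  for (nm in paste0("table", 5:10)) {
    rounded <- tabs[[nm]] %>%
      mutate(across(-"year", ~ round_half_up(.x, 2)))
    write_table_csv(rounded, file.path(outdir, paste0(nm, ".csv")))
  }
  write_table_csv(
    bind_rows(
      tibble(table = "table9", scenario = names(tabs$table9_total),
             total_increase = round_half_up(unname(tabs$table9_total), 2)),
      tibble(table = "table10", scenario = names(tabs$table10_total),
             total_increase = round_half_up(unname(tabs$table10_total), 2))
    ),
    file.path(outdir, "total_increase.csv")
  )
  write_table_csv(tabs$per_decade %>%
                    mutate(across(-c("period", "year"),
                                  ~ round_half_up(.x, 2))),
                  file.path(outdir, "per_decade.csv"))
  write_table_csv(tabs$gaps %>% mutate(gap = round_half_up(.data$gap, 1)),
                  file.path(outdir, "gaps.csv"))
  write_table_csv(tabs$economics, file.path(outdir, "economics.csv"))
  write_table_csv(comparison, file.path(outdir, "comparison.csv"))
  write_run_info(outdir)

  all_pass <- all(comparison$pass)
  if (!all_pass && strict) {
    bad <- comparison %>% filter(!.data$pass)
    stop(sprintf(
      "golden comparison failed for %d cell(s); see %s",
      nrow(bad), file.path(outdir, "comparison.csv")
    ), call. = FALSE)
  }
  invisible(list(tables = tabs, comparison = comparison,
                 all_pass = all_pass))
}

# provenance log: package version, fixture checksums, session seed state
write_run_info <- function(outdir, seed = NA) {
  fixtures <- c("table1_standardized", "table2_slopes",
                "table3_student_shares", "table4_census_shares")
  paths <- vapply(fixtures, function(f) {
    system.file("extdata", paste0(f, ".csv"), package = "cogtrend",
                mustWork = TRUE)
  }, character(1))
  info <- list(
    package = "cogtrend",
    version = as.character(utils::packageVersion("cogtrend")),
    r_version = as.character(getRversion()),
    seed = seed,
    fixture_md5 = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(info, file.path(outdir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(info)
}

#' Write projection/effect results as CSVs or plots
#'
#' `format = "csv"` writes tidy CSVs of whatever result tables are passed.
#' `format = "plots"` draws the two report figures: population trajectories
#' (one curve per scenario-period combination) and effect-component curves
#' over the horizon, saved as PDFs.
#'
#' @param results named list; recognised elements are `projections` (rows
#'   from [project()], possibly several scenarios/periods bound together)
#'   and `effects` (rows from [decompose()]).
#' @param outdir output directory (created if needed).
#' @param format `"csv"` or `"plots"`.
#' @return (invisibly) character vector of files written; empty input
#'   writes nothing and warns.
#' @export
write_report <- function(results, outdir, format = c("csv", "plots")) {
  format <- match.arg(format)
  keep <- Filter(function(x) !is.null(x) && nrow(x) > 0, results)
  if (length(keep) == 0) {
    warning("empty results: nothing to write", call. = FALSE)
    return(invisible(character(0)))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (format == "csv") {
    for (nm in names(keep)) {
      f <- file.path(outdir, paste0(nm, ".csv"))
      write_table_csv(keep[[nm]], f)
      files <- c(files, f)
    }
    return(invisible(files))
  }
  if (!is.null(keep$projections)) {
    d <- keep$projections %>% filter(.data$group == "population")
    g <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$year, y = .data$value,
      colour = interaction(.data$scenario, .data$period, sep = " / ")
    )) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Year", y = "Projected population score (IQ metric)",
                    colour = "Scenario / period") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "projections.pdf")
    ggplot2::ggsave(f, g, width = 7, height = 4.5)
    files <- c(files, f)
  }
  if (!is.null(keep$effects)) {
    d <- keep$effects %>%
      tidyr::pivot_longer(all_of(c("e_base", "e_minor", "e_pop", "e_pm",
                                   "e_total")),
                          names_to = "component", values_to = "value")
    g <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$year, y = .data$value, colour = .data$component,
      linetype = .data$period
    )) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Year", y = "Effect size (IQ points)") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "effects.pdf")
    ggplot2::ggsave(f, g, width = 7, height = 4.5)
    files <- c(files, f)
  }
  invisible(files)
}
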