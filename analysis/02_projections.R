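#!/usr/bin/env Rscript
# Project each group and the population-weighted average to 2060 under the
# optimistic (1978/80-2012) and pessimistic (1992-2012) trend periods, and
# summarise the group gaps the projections imply.

library(cogtrend)
suppressPackageStartupMessages(library(dplyr))

dir.create("results", showWarnings = FALSE)
shares <- load_fixture("table4_census_shares")
years <- c(2012, seq(2015, 2060, 5))
periods <- c(optimistic = "1978/80-2012", pessimistic = "1992-2012")

all_proj <- list()
for (nm in names(periods)) {
  models <- paper_models(periods[[nm]])
  res <- project(models, shares, years)
  all_proj[[nm]] <- res
  pop <- res %>% filter(group == "population")
  cat(sprintf(
    "%s period (%s): population %.2f (2012) -> %.2f (2060), %.2f per decade\n",
    nm, periods[[nm]], pop$value[pop$year == 2012],
    pop$value[pop$year == 2060],
    per_decade_rate(pop$value[pop$year == 2060] -
                      pop$value[pop$year == 2012], 48)
  ))
  for (pair in list(c("White", "Black"), c("White", "Hispanic"),
                    c("Asian", "White"))) {
    cat(sprintf("  %s-%s gap: %.1f (2012) -> %.1f (2060)\n",
                pair[1], pair[2],
                group_gap(res, 2012, pair[1], pair[2]),
                group_gap(res, 2060, pair[1], pair[2])))
  }
}

write_table_csv(bind_rows(all_proj, .id = "model"),
                "results/projections.csv")
cat("wrote results/projections.csv\n")
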