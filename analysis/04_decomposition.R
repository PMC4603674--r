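#!/usr/bin/env Rscript
# Decompose the projected population change into baseline trend, minority
# catch-up, composition and interaction components, and convert the 2060
# components into per-capita economic gains (constant prices, no baseline
# growth).

library(cogtrend)
suppressPackageStartupMessages(library(dplyr))

dir.create("results", showWarnings = FALSE)
shares <- load_fixture("table4_census_shares")
horizons <- seq(2015, 2060, 5)

effects <- list()
for (p in c("1978/80-2012", "1992-2012")) {
  models <- paper_models(p)
  eff <- decompose(models, shares, horizons, "White")
  effects[[p]] <- eff
  e60 <- eff %>% filter(year == 2060)
  pd <- per_decade_effects(e60)
  cat(sprintf("%s at 2060: base %.2f + catch-up %.2f + composition %.2f + interaction %.2f = %.2f (%.2f/decade)\n",
              p, e60$e_base, e60$e_minor, e60$e_pop, e60$e_pm, e60$e_total,
              pd$e_total))
  delta <- round_half_up(
    c(e60$e_base, e60$e_minor, e60$e_pop, e60$e_pm, e60$e_total), 2
  )
  cat(sprintf("  dollars/capita/year: base $%d, catch-up $%d, composition $%d, interaction $%d, total $%d\n",
              economic_gain(delta[1]), economic_gain(delta[2]),
              economic_gain(delta[3]), economic_gain(delta[4]),
              economic_gain(delta[5])))
}

write_table_csv(bind_rows(effects), "results/effects.csv")
cat("wrote results/effects.csv\n")
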