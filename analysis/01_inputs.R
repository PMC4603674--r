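#!/usr/bin/env Rscript
# Load the packaged input tables (standardized scores, fitted slopes,
# participant and census shares), show the quantities the projection
# consumes, and write them in tidy form for the downstream steps.

library(cogtrend)
suppressPackageStartupMessages(library(dplyr))

out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

t1 <- load_fixture("table1_standardized")
t2 <- load_fixture("table2_slopes")
t3 <- load_fixture("table3_student_shares")
t4 <- load_fixture("table4_census_shares")

anchors <- t1 %>% filter(cohort_year == 2012, group != "Average")
cat("2012 anchor levels (IQ metric):\n")
print(anchors %>% select(group, value))

cat("\nGroup slopes (IQ points/year), full-precision subject averages:\n")
for (p in unique(t2$period)) {
  sl <- t2 %>%
    filter(period == p, subject != "Average") %>%
    group_by(group) %>%
    summarise(slope = average_subject_slopes(slope), .groups = "drop")
  cat(sprintf("  %s: %s\n", p,
              paste(sprintf("%s %.5f", sl$group, sl$slope), collapse = ", ")))
}

cat(sprintf("\nCensus share coverage of the four modeled groups: %.2f%% (2012) -> %.2f%% (2060)\n",
            100 * sum(interpolate_shares(t4, 2012)),
            100 * sum(interpolate_shares(t4, 2060))))

write_table_csv(t1, file.path(out, "standardized_series.csv"))
write_table_csv(t2, file.path(out, "slopes.csv"))
write_table_csv(t3, file.path(out, "student_shares.csv"))
write_table_csv(t4, file.path(out, "census_shares.csv"))
cat(sprintf("\nwrote tidy inputs under %s\n", out))
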