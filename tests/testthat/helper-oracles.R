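# Independent closed-form OLS slope: covariance ratio, no lm().
ols_slope_bruteforce <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Analytic sampling SD of the OLS slope under iid Gaussian noise sigma.
ols_slope_sampling_sd <- function(x, sigma) {
  sigma / sqrt(sum((x - mean(x))^2))
}

# Tiny two-group scenario used by synthetic-module tests.
tiny_scenario <- function(noise_sd = 0, seed = 1,
                          slopes = c(a_math = 0.10, a_read = 0.05,
                                     b_math = -0.02, b_read = 0.08)) {
  bench <- benchmark(
    group = "A",
    subject_years = c(mathematics = 2000, reading = 2002),
    raw = data.frame(subject = c("mathematics", "reading"),
                     mean = c(300, 280), sd = c(30, 40))
  )
  synthetic_scenario(
    groups = c("A", "B"),
    survey_years = list(mathematics = c(2000, 2004, 2008, 2012),
                        reading = c(2002, 2006, 2010, 2012)),
    true_slopes = data.frame(
      group = rep(c("A", "B"), each = 2),
      subject = rep(c("mathematics", "reading"), 2),
      slope = unname(slopes)
    ),
    bench = bench,
    anchor_levels = c(A = 101, B = 94),
    anchor_year = 2012,
    noise_sd = noise_sd,
    share_start = c(A = 0.8, B = 0.15),
    share_end = c(A = 0.6, B = 0.35),
    share_range = c(2012, 2060),
    seed = seed
  )
}

# Single-group, single-subject scenario for sampling-distribution checks.
one_track_scenario <- function(noise_sd, seed = 1) {
  years <- c(1978, 1982, 1986, 1990, 1992, 1994, 1996, 1999, 2004, 2008, 2012)
  bench <- benchmark(
    group = "G", subject_years = c(mathematics = 1978),
    raw = data.frame(subject = "mathematics", mean = 300, sd = 30)
  )
  synthetic_scenario(
    groups = "G",
    survey_years = list(mathematics = years),
    true_slopes = data.frame(group = "G", subject = "mathematics",
                             slope = 0.1),
    bench = bench,
    anchor_levels = c(G = 100),
    anchor_year = 2012,
    noise_sd = noise_sd,
    seed = seed
  )
}

# Random decomposition instance: slopes, anchors and two share rows for
# k groups whose sums stay below 1.
random_decomposition_instance <- function(k = sample(3:5, 1)) {
  groups <- paste0("g", seq_len(k))
  p0 <- runif(k); p0 <- p0 / sum(p0) * runif(1, 0.6, 0.98)
  p1 <- runif(k); p1 <- p1 / sum(p1) * runif(1, 0.6, 0.98)
  list(
    models = trend_models(
      anchors = setNames(runif(k, 85, 110), groups),
      slopes = setNames(runif(k, -0.25, 0.35), groups),
      period = "sim", anchor_year = 2012
    ),
    shares = share_table(data.frame(
      year = rep(c(2012, 2060), each = k),
      group = rep(groups, 2),
      proportion = c(p0, p1)
    )),
    groups = groups
  )
}
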