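test_that("generation is deterministic given the seed", {
  sc <- tiny_scenario(noise_sd = 0.8, seed = 42)
  expect_identical(generate_assessment(sc), generate_assessment(sc))
  expect_false(identical(generate_assessment(sc, seed = 43),
                         generate_assessment(sc)))
})

test_that("the noiseless pipeline recovers slopes and trajectories exactly", {
  sc <- tiny_scenario(noise_sd = 0)
  std <- standardize_assessment(generate_assessment(sc), sc$bench)
  fits <- fit_group_slopes(std, period_spec("full", 2000, 2012))

  truth <- stats::aggregate(slope ~ group, sc$true_slopes, mean)
  avg <- fits[fits$subject == "Average", ]
  expect_equal(avg$slope[match(truth$group, avg$group)], truth$slope,
               tolerance = 1e-9)

  # per-subject slopes too
  for (i in seq_len(nrow(sc$true_slopes))) {
    r <- sc$true_slopes[i, ]
    expect_equal(
      fits$slope[fits$group == r$group & fits$subject == r$subject],
      r$slope, tolerance = 1e-9
    )
  }

  # full round trip: models built from the recovered pieces reproduce the
  # generating trajectories at every projection year
  anchors <- std[std$subject == "__combined__" & std$cohort_year == 2012, ]
  models <- trend_models(
    anchors = setNames(anchors$value, anchors$group),
    slopes = setNames(avg$slope, avg$group),
    period = "full", anchor_year = 2012
  )
  years <- seq(2012, 2060, 12)
  traj <- predict_trend(models, years)
  for (g in sc$groups) {
    m_true <- mean(sc$true_slopes$slope[sc$true_slopes$group == g])
    expect_equal(
      traj$value[traj$group == g],
      sc$anchor_levels[[g]] + m_true * (years - 2012),
      tolerance = 1e-9
    )
  }
})

test_that("generate_shares interpolates linearly and validates sums", {
  sc <- tiny_scenario()
  tab <- generate_shares(sc, c(2012, 2036, 2060))
  p36 <- interpolate_shares(tab, 2036)
  expect_equal(unname(p36[c("A", "B")]), c(0.7, 0.25))

  const <- synthetic_scenario(
    groups = "G",
    survey_years = list(mathematics = c(2000, 2012)),
    true_slopes = data.frame(group = "G", subject = "mathematics",
                             slope = 0),
    bench = benchmark("G", c(mathematics = 2000),
                      raw = data.frame(subject = "mathematics", mean = 300,
                                       sd = 30)),
    anchor_levels = c(G = 100), share_start = c(G = 0.4),
    share_end = c(G = 0.4)
  )
  tab2 <- generate_shares(const, c(2012, 2030, 2060))
  expect_equal(unique(tab2$proportion), 0.4)

  bad <- synthetic_scenario(
    groups = c("A", "B"),
    survey_years = list(mathematics = c(2000, 2012)),
    true_slopes = data.frame(group = c("A", "B"), subject = "mathematics",
                             slope = 0),
    bench = benchmark("A", c(mathematics = 2000),
                      raw = data.frame(subject = "mathematics", mean = 300,
                                       sd = 30)),
    anchor_levels = c(A = 100, B = 95),
    share_start = c(A = 0.5, B = 0.2), share_end = c(A = 0.2, B = 0.5)
  )
  expect_no_error(generate_shares(bad, c(2012, 2060)))
  expect_error(
    synthetic_scenario(
      groups = c("A", "B"),
      survey_years = list(mathematics = c(2000, 2012)),
      true_slopes = data.frame(group = c("A", "B"),
                               subject = "mathematics", slope = 0),
      bench = benchmark("A", c(mathematics = 2000),
                        raw = data.frame(subject = "mathematics",
                                         mean = 300, sd = 30)),
      anchor_levels = c(A = 100, B = 95),
      share_start = c(A = 0.7, B = 0.5), share_end = c(A = 0.2, B = 0.5)
    ),
    "invalid scenario"
  )
})

test_that("recovery_experiment reports exact recovery without noise", {
  rec <- recovery_experiment(tiny_scenario(noise_sd = 0), replicates = 3)
  expect_equal(rec$slopes$bias, rep(0, 2), tolerance = 1e-9)
  expect_equal(rec$slopes$rmse, rep(0, 2), tolerance = 1e-9)
  expect_lt(rec$max_identity_violation, 1e-9)
})

test_that("the publication-calibrated scenario reproduces the projected 2060 level", {
  sc <- paper_scenario(noise_sd = 0, seed = 1)
  std <- standardize_assessment(generate_assessment(sc), sc$bench)
  fits <- fit_group_slopes(std, period_spec("1978/80-2012", 1978, 2012))
  avg <- fits[fits$subject == "Average", ]
  anchors <- std[std$subject == "__combined__" & std$cohort_year == 2012, ]
  models <- trend_models(
    anchors = setNames(anchors$value, anchors$group),
    slopes = setNames(avg$slope, avg$group),
    period = "1978/80-2012", anchor_year = 2012
  )
  res <- project(models, generate_shares(sc, c(2012, 2060)), 2060)
  expect_equal(res$value[res$group == "population"], 103.17,
               tolerance = 0.01)
})

test_that("slope-estimate spread matches the analytic OLS sampling SD", {
  sigma <- 0.5
  sc <- one_track_scenario(noise_sd = sigma, seed = 2)
  rec <- recovery_experiment(sc, replicates = 200)
  analytic <- ols_slope_sampling_sd(sc$survey_years$mathematics, sigma)
  expect_equal(rec$slopes$rmse, analytic, tolerance = 0.2)
  expect_lt(abs(rec$slopes$bias), 3 * analytic / sqrt(200))
})

test_that("slope RMSE does not decrease as noise grows", {
  rmse_at <- function(noise) {
    rec <- recovery_experiment(one_track_scenario(noise, seed = 5),
                               replicates = 60)
    rec$slopes$rmse
  }
  r <- vapply(c(0, 0.5, 2), rmse_at, numeric(1))
  expect_equal(r[1], 0, tolerance = 1e-9)
  # coarse monotonicity: a four-fold noise increase must show
  expect_gt(r[3], r[2])
})
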