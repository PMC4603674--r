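test_that("fit_slope matches the closed-form covariance-ratio oracle", {
  expect_equal(fit_slope(data.frame(year = c(2000, 2010),
                                    value = c(100, 101))), 0.1)
  expect_equal(fit_slope(data.frame(year = c(1992, 2002, 2012),
                                    value = c(100, 100, 100))), 0)
  pts <- data.frame(year = c(1990, 2000, 2010), value = c(100, 102, 101))
  expect_equal(fit_slope(pts), ols_slope_bruteforce(pts$year, pts$value),
               tolerance = 1e-12)
  set.seed(123)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    x <- sort(sample(1970:2015, n))
    y <- runif(n, 80, 120)
    expect_equal(fit_slope(data.frame(year = x, value = y)),
                 ols_slope_bruteforce(x, y), tolerance = 1e-10)
  }
})

test_that("fit_slope is shift-invariant in year and scale-equivariant in value", {
  set.seed(5)
  x <- c(1978, 1984, 1999, 2008, 2012); y <- runif(5, 85, 115)
  s0 <- fit_slope(data.frame(year = x, value = y))
  expect_equal(fit_slope(data.frame(year = x + 1000, value = y)), s0,
               tolerance = 1e-10)
  expect_equal(fit_slope(data.frame(year = x, value = 3.5 * y)), 3.5 * s0,
               tolerance = 1e-10)
})

test_that("fit_slope recovers a noiseless linear trend on any year subset", {
  years <- c(1978, 1982, 1986, 1990, 1992, 1994, 1996, 1999, 2004, 2008, 2012)
  set.seed(99)
  for (i in 1:10) {
    m <- runif(1, -0.3, 0.3); a <- runif(1, 90, 110)
    sub <- sort(sample(years, sample(2:11, 1)))
    pts <- data.frame(year = sub, value = a + m * (sub - 2012))
    expect_equal(fit_slope(pts), m, tolerance = 1e-10)
  }
})

test_that("fit_slope rejects unusable inputs and honours period bounds", {
  expect_error(fit_slope(data.frame(year = 2000, value = 100)),
               "insufficient data")
  expect_error(
    fit_slope(data.frame(year = c(2000, 2000), value = c(100, 101))),
    "degenerate design"
  )
  pts <- data.frame(year = c(1978, 1980, 1992, 2012),
                    value = c(100, 101, 104, 110))
  # inclusive window keeps the 1978 and 1980 observations
  p <- period_spec("1978/80-2012", 1978, 2012)
  expect_equal(fit_slope(pts, p),
               ols_slope_bruteforce(pts$year, pts$value))
  p92 <- period_spec("1992-2012", 1992, 2012)
  expect_equal(fit_slope(pts, p92),
               ols_slope_bruteforce(c(1992, 2012), c(104, 110)))
  expect_error(fit_slope(pts, period_spec("late", 2013, 2020)),
               "insufficient data")
  expect_error(period_spec("bad", 2012, 2012), "before")
})

test_that("average_subject_slopes reproduces the published average rows", {
  # printed averages are rounded to 4 decimals; the mean of printed
  # per-subject slopes can differ in the 4th decimal
  expect_equal(average_subject_slopes(c(math = 0.0914, reading = 0.0016)),
               0.0465, tolerance = 5e-4)
  expect_equal(average_subject_slopes(c(math = 0.1186, reading = 0.2150)),
               0.1668, tolerance = 5e-4)
  expect_equal(average_subject_slopes(c(math = 0.2, reading = 0.2)), 0.2)
  expect_error(average_subject_slopes(numeric(0)), "missing data")
})

test_that("trend models anchor at the observed value, not a fitted intercept", {
  series <- data.frame(group = "White", subject = "__combined__",
                       cohort_year = c(2008, 2012), value = c(102.29, 102.28))
  m <- build_trend_model(series, slope = 0.0465, period = "1978/80-2012")
  expect_equal(m$anchor_value, 102.28)
  # evaluated at the anchor year the model returns the anchor value
  expect_equal(predict_trend(m, 2012)$value, 102.28)
  # White optimistic at 2060 matches the published projection
  expect_equal(predict_trend(m, 2060)$value, 104.51, tolerance = 0.01)
  expect_error(
    build_trend_model(series[1, ], 0.0465, "1978/80-2012"),
    "anchor missing"
  )
  # Asian pessimistic at 2060
  m2 <- trend_models(c(Asian = 105.05), c(Asian = 0.1995), "1992-2012")
  expect_equal(predict_trend(m2, 2060)$value, 114.62, tolerance = 0.01)
})

test_that("scenario slopes assign the extreme slope to every group", {
  m <- trend_models(
    anchors = c(W = 102.28, B = 91.14, H = 93.60, A = 105.05),
    slopes = c(W = 0.0465, B = 0.1439, H = 0.1539, A = 0.1668),
    period = "1978/80-2012"
  )
  best <- scenario_slopes(m, "best")
  expect_equal(as.numeric(best), rep(0.1668, 4))
  expect_equal(attr(best, "donor"), "A")
  worst <- scenario_slopes(m, "worst")
  expect_equal(as.numeric(worst), rep(0.0465, 4))
  expect_equal(attr(worst, "donor"), "W")

  single <- trend_models(c(W = 100), c(W = 0.1), "p")
  expect_equal(as.numeric(scenario_slopes(single, "best")), 0.1)
  expect_equal(as.numeric(scenario_slopes(single, "worst")), 0.1)

  # ties break deterministically by the configured group order
  tied <- trend_models(c(X = 100, Y = 100), c(X = 0.2, Y = 0.2), "p")
  expect_equal(attr(scenario_slopes(tied, "best",
                                    group_order = c("Y", "X")), "donor"), "Y")
  expect_equal(attr(scenario_slopes(tied, "best",
                                    group_order = c("X", "Y")), "donor"), "X")

  mixed <- dplyr::bind_rows(m, trend_models(c(Z = 100), c(Z = 0.1), "other"))
  expect_error(scenario_slopes(mixed, "best"), "inconsistent period")
})

test_that("per-subject fitting, not the combined cohort series, matches the published slopes", {
  # fitting the combined series on cohort display years conflates the
  # offset reading years with the mathematics years and gives a visibly
  # different White slope (~0.07, not the published per-subject average)
  t1 <- load_fixture("table1_standardized")
  white <- t1[t1$group == "White", ]
  combined_fit <- fit_slope(
    data.frame(year = white$cohort_year, value = white$value)
  )
  expect_gt(abs(combined_fit - 0.0465), 0.01)
  expect_equal(combined_fit, 0.07, tolerance = 0.015)

  # on a noiseless synthetic dataset with the published per-subject slopes,
  # the per-subject-then-average path recovers the published average
  sc <- paper_scenario(noise_sd = 0, seed = 1)
  std <- standardize_assessment(generate_assessment(sc), sc$bench)
  fits <- fit_group_slopes(std, period_spec("full", 1978, 2012))
  avg <- fits[fits$subject == "Average", ]
  t2 <- load_fixture("table2_slopes")
  t2avg <- t2[t2$period == "1978/80-2012" & t2$subject == "Average", ]
  expect_equal(
    avg$slope[match(t2avg$group, avg$group)], t2avg$slope,
    tolerance = 5e-4
  )
})
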