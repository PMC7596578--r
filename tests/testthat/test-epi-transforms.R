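test_that("conditional annual probability from a cumulative curve", {
  flat <- curve_table(20:22, c(0.5, 0.5, 0.5))
  expect_equal(annual_prob_from_cumulative(curve_table(20:21, c(0, 0)), 20), 0)
  expect_equal(annual_prob_from_cumulative(flat, 20), 0)
  rising <- curve_table(20:22, c(0, 0.20, 0.28))
  expect_equal(annual_prob_from_cumulative(rising, 21), 0.1)
  expect_error(annual_prob_from_cumulative(rising, 25), "outside")
  expect_error(annual_prob_from_cumulative(curve_table(20:22, c(0, 1, 1)), 21),
               "degenerate")
})

test_that("annual probability matches an individual-level simulation", {
  # draw event ages from F directly and estimate the conditional one-year
  # probability among those event-free, as the independent oracle
  cv <- curve_table(20:30, cumsum(c(0, 0.01, 0.02, 0.05, 0.08, 0.06, 0.05,
                                    0.04, 0.03, 0.02, 0.01)))
  n <- 500000
  set.seed(314)
  ev <- sample_event_ages(cv, n)
  for (a in c(23, 26)) {
    at_risk <- is.na(ev) | ev > a
    hit <- !is.na(ev) & ev == a + 1
    p_hat <- sum(hit) / sum(at_risk)
    mcse <- sqrt(p_hat * (1 - p_hat) / sum(at_risk))
    expect_lt(abs(p_hat - annual_prob_from_cumulative(cv, a)), 3 * mcse)
  }
})

test_that("probability-rate conversion round-trips", {
  expect_equal(prob_to_rate(0), 0)
  expect_equal(rate_to_prob(0.693147), 1 - exp(-0.693147))
  expect_equal(rate_to_prob(prob_to_rate(0.37)), 0.37, tolerance = 1e-12)
  expect_error(prob_to_rate(1), "\\[0,1\\)")
})

test_that("hazard ratios act on the rate scale", {
  expect_equal(apply_hazard_ratio(0.1, 1), 0.1)
  expect_equal(apply_hazard_ratio(0.2, 0), 0)
  expect_equal(apply_hazard_ratio(0.2, 0.5), 1 - exp(0.5 * log(0.8)),
               tolerance = 1e-12)
  expect_equal(round(apply_hazard_ratio(0.2, 0.5), 6), 0.105573)
  # monotone in hr
  hrs <- seq(0, 3, by = 0.25)
  expect_true(all(diff(apply_hazard_ratio(0.15, hrs)) > 0))
  expect_error(apply_hazard_ratio(0.1, -1), ">= 0")
})

test_that("odds ratios act exactly on the odds scale", {
  expect_equal(round(apply_odds_ratio(0.01, 2.97), 6), 0.029126)
  expect_equal(apply_odds_ratio(0.3, 1), 0.3)
  expect_equal(apply_odds_ratio(0, 18.5), 0)
  # stays in [0,1) even for extreme odds ratios
  expect_lt(apply_odds_ratio(0.5, 808.1), 1)
  ors <- c(0.5, 1, 2, 5, 20)
  expect_true(all(diff(apply_odds_ratio(0.05, ors)) > 0))
})

test_that("5-year relative mortality converts to annual excess probability", {
  expect_equal(annual_excess_mortality(0), 0)
  expect_equal(annual_excess_mortality(0.119), 1 - 0.881^0.2, tolerance = 1e-12)
  expect_equal(round(annual_excess_mortality(0.119), 6), 0.025021)
  expect_equal(annual_excess_mortality(0.791), 1 - 0.209^0.2, tolerance = 1e-12)
  # five-fold compounding recovers the input
  for (m5 in c(0.05, 0.119, 0.505, 0.791, 0.949)) {
    p <- annual_excess_mortality(m5)
    expect_equal(1 - (1 - p)^5, m5, tolerance = 1e-12)
  }
  expect_error(annual_excess_mortality(1), "\\[0,1\\)")
})

test_that("discount factors follow (1+r)^-t", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(round(discount_factor(1, 0.03), 6), 0.970874)
  expect_equal(round(discount_factor(10, 0.03), 6), 0.744094)
})

test_that("uptake probabilities apply the rate ratio on the rate scale", {
  up <- curve_table(40:42, c(0.30, 0.37, 0.44))
  expect_equal(annual_uptake_prob(up, 40, 1),
               annual_prob_from_cumulative(up, 40))
  expect_equal(annual_uptake_prob(up, 40, 0), 0)
  expect_equal(round(annual_uptake_prob(up, 40, 0.5), 6), 0.051317)
})

test_that("annual probabilities telescope back to the cumulative curve", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- cumsum(runif(30, 0, 0.03))
    cv <- curve_table(20:49, c(0, vals[-30]))
    p <- vapply(20:48, function(a) annual_prob_from_cumulative(cv, a),
                numeric(1))
    event_free <- cumprod(c(1, 1 - p))
    reconstructed <- cumsum(event_free[-30] * p)
    expect_equal(reconstructed, cv$values[-1], tolerance = 1e-9)
  }
})

test_that("curve and life tables validate and round-trip through text files", {
  expect_error(curve_table(20:22, c(0.3, 0.2, 0.4)), "nondecreasing")
  expect_error(curve_table(20:22, c(0, 0.5, 1.2)), "outside")
  expect_error(life_table(0:10, rep(0.5, 11)), "terminal")
  cv <- make_cumulative_curve(0.4, 50)
  f <- tempfile(fileext = ".csv")
  write_curve_table(cv, f)
  cv2 <- read_curve_table(f)
  expect_equal(cv2$values, cv$values, tolerance = 1e-12)
  # coarse grids interpolate to annual steps
  coarse <- curve_table(c(20, 30, 40), c(0, 0.1, 0.4))
  expect_equal(coarse$ages, 20:40)
  expect_equal(coarse$values[11], 0.1)
  expect_equal(coarse$values[6], 0.05)
})
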