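# cheap deterministic runner: a transparent stand-in model whose incremental
# cost depends linearly on the assay cost and whose QALY gain depends on MRI
# uptake, letting tornado mechanics be checked against brute force exactly
toy_runner <- function(ps) {
  c(cost = 1e5 * param_value(ps, "cost_assay") * 0.95,
    qaly = 200 + 400 * param_value(ps, "mri_uptake"),
    ly = 0, cases_early = 0, cases_late = 0, cases_total = 0)
}

test_that("tornado bars equal brute-force recomputation at the bounds", {
  ids <- c("cost_assay", "mri_uptake", "cascade_inform")
  tor <- run_one_way(base_params, ids, toy_runner)
  expect_setequal(tor$param, ids)
  for (id in ids) {
    lo <- toy_runner(perturb_one_way(base_params, id, "low"))
    hi <- toy_runner(perturb_one_way(base_params, id, "high"))
    row <- tor[tor$param == id, ]
    expect_equal(row$icer_low, compute_icer(lo[["cost"]], lo[["qaly"]])$value)
    expect_equal(row$icer_high, compute_icer(hi[["cost"]], hi[["qaly"]])$value)
  }
  # sorted by decreasing width; cascade_inform does not enter the toy model
  expect_true(all(diff(tor$width) <= 0))
  expect_equal(tor$width[tor$param == "cascade_inform"], 0)
  # ICER strictly increasing in assay cost (QALYs fixed)
  row <- tor[tor$param == "cost_assay", ]
  expect_lt(row$icer_low, row$icer_high)
  expect_error(run_one_way(base_params, "nope", toy_runner), "unknown parameter")
})

test_that("a degenerate bound gives a zero-width tornado bar", {
  ps <- base_params
  ps$registry$cost_assay$low <- 200
  ps$registry$cost_assay$high <- 200
  tor <- run_one_way(ps, "cost_assay", toy_runner)
  expect_equal(tor$width, 0)
  expect_equal(tor$icer_low, tor$icer_high)
})

test_that("PSA is seed-reproducible with counter-based substreams", {
  p1 <- run_psa(base_params, 6, seed = 11, runner = toy_runner)
  p2 <- run_psa(base_params, 6, seed = 11, runner = toy_runner)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)
  # the first k draws of a longer run equal a k-draw run (stream discipline)
  p3 <- run_psa(base_params, 3, seed = 11, runner = toy_runner)
  expect_equal(p3$draws, p1$draws[1:3, ], ignore_attr = TRUE)
  # a different seed moves the draws
  p4 <- run_psa(base_params, 6, seed = 12, runner = toy_runner)
  expect_false(isTRUE(all.equal(p1$draws, p4$draws)))
})

test_that("single-draw credible ranges collapse and point masses reproduce base", {
  p1 <- run_psa(base_params, 1, seed = 5, runner = toy_runner)
  expect_equal(p1$credible["2.5%", "cost"], p1$draws$cost[1])
  expect_equal(p1$credible["97.5%", "cost"], p1$draws$cost[1])

  ps_fixed <- base_params
  for (nm in names(ps_fixed$registry)) {
    ps_fixed$registry[[nm]]$dist <- "fixed"
    ps_fixed$registry[[nm]]$low <- ps_fixed$registry[[nm]]$value
    ps_fixed$registry[[nm]]$high <- ps_fixed$registry[[nm]]$value
  }
  pfix <- run_psa(ps_fixed, 5, seed = 5, runner = toy_runner)
  base_res <- toy_runner(base_params)
  for (i in 1:5) {
    expect_equal(unlist(pfix$draws[i, ]), base_res, tolerance = 1e-12)
  }
})

test_that("failed draws are excluded with an explicit count", {
  flaky <- local({
    k <- 0
    function(ps) {
      k <<- k + 1
      if (k %% 3 == 0) stop("numerical failure")
      toy_runner(ps)
    }
  })
  expect_warning(p <- run_psa(base_params, 9, seed = 3, runner = flaky),
                 "3 of 9 draws failed")
  expect_equal(p$n_failed, 3)
  expect_equal(nrow(p$draws), 6)
})

test_that("acceptability curves follow their definition", {
  draws <- data.frame(cost = c(-10, 5, 20, 40), qaly = c(1, 1, 2, 4) * 1e-3)
  cc <- compute_ceac(draws, c(0, 10000, 1e6))
  expect_equal(cc$prob_ce[cc$wtp == 0], 0.25)        # fraction cost-saving
  expect_equal(cc$prob_ce[cc$wtp == 1e6], 1)
  # all cost-saving with positive gains: identically 1
  saving <- data.frame(cost = c(-1, -2), qaly = c(0.1, 0.2))
  expect_true(all(compute_ceac(saving, c(0, 5e4, 1e5))$prob_ce == 1))
  # nondecreasing in willingness to pay when all QALY gains are nonnegative
  set.seed(77)
  d <- data.frame(cost = rnorm(500, 100, 50), qaly = abs(rnorm(500, 1e-3, 5e-4)))
  curve <- compute_ceac(d, seq(0, 3e5, by = 1e4))$prob_ce
  expect_true(all(diff(curve) >= 0))
})

test_that("acceptability probability matches the analytic orthant probability", {
  # draws from a known bivariate normal: qaly ~ N(1, 1), cost ~ N(0, 1),
  # independent, so P(l*q - c >= 0) = pnorm(l / sqrt(l^2 + 1))
  n <- 40000
  set.seed(555)
  draws <- data.frame(cost = rnorm(n), qaly = rnorm(n, mean = 1))
  for (l in c(0.5, 1, 2)) {
    p_true <- pnorm(l / sqrt(l^2 + 1))
    p_hat <- compute_ceac(draws, l)$prob_ce
    mcse <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * mcse)
  }
})
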