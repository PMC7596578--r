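test_that("packaged configuration loads with percent fields converted", {
  ps <- base_params
  expect_equal(param_value(ps, "carrier_prevalence"), 0.00495)
  expect_equal(param_value(ps, "gene_prop.BRCA1"), 0.276)
  expect_equal(param_value(ps, "fh_identification"), 0.174)
  expect_equal(param_value(ps, "cost_assay"), 200)
  expect_equal(sum(param_block(ps, "gene_prop")), 1, tolerance = 1e-12)
  # every bound is ordered, every HR printed as zero stays fixed
  for (e in ps$registry) expect_true(e$low <= e$value && e$value <= e$high)
  expect_equal(ps$registry[["hr_bc_rrm.BRCA1"]]$dist, "fixed")
})

test_that("malformed configurations are rejected with informative errors", {
  cfg <- yaml::read_yaml(system.file("extdata", "table1_base.yaml",
                                     package = "hbocScreen"))
  bad <- cfg
  bad$parameters$gene_prop$BRCA1$base <- 0.1   # block now sums to < 1
  bad$parameters$gene_prop$BRCA1$low <- 0.1
  bad$parameters$gene_prop$BRCA1$high <- 0.1
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, f)
  expect_error(load_parameter_set(f), "gene proportions sum")

  bad2 <- cfg
  bad2$parameters$mri_uptake$dist <- NULL
  yaml::write_yaml(bad2, f)
  expect_error(load_parameter_set(f), "mri_uptake.*dist")
})

test_that("one-way perturbation touches exactly the named parameter", {
  lo <- perturb_one_way(base_params, "cost_assay", "low")
  expect_equal(param_value(lo, "cost_assay"), 160)
  hi <- perturb_one_way(base_params, "mri_uptake", "high")
  expect_equal(param_value(hi, "mri_uptake"), 0.90)

  # all other values are untouched
  v0 <- param_values(base_params)
  v1 <- param_values(lo)
  expect_equal(v1[setdiff(names(v1), "cost_assay")],
               v0[setdiff(names(v0), "cost_assay")])

  # round trip back to base restores the original set
  back <- perturb_one_way(lo, "cost_assay", "base")
  expect_equal(param_values(back), v0)

  expect_error(perturb_one_way(base_params, "not_a_parameter", "low"),
               "unknown parameter")
})

test_that("perturbing a gene proportion renormalises the Dirichlet block", {
  hi <- perturb_one_way(base_params, "gene_prop.BRCA1", "high")
  gp <- param_block(hi, "gene_prop")
  expect_equal(gp[["BRCA1"]], 0.332)
  expect_equal(sum(gp), 1, tolerance = 1e-12)
  # relative proportions of the others preserved
  gp0 <- param_block(base_params, "gene_prop")
  expect_equal(gp[["BRCA2"]] / gp[["ATM"]], gp0[["BRCA2"]] / gp0[["ATM"]],
               tolerance = 1e-12)
})

test_that("PSA draws are seed-deterministic and honour each family", {
  set.seed(42); d1 <- draw_psa_sample(base_params)
  set.seed(42); d2 <- draw_psa_sample(base_params)
  expect_identical(param_values(d1), param_values(d2))

  set.seed(7)
  beta_draws <- replicate(1000, param_value(draw_psa_sample(base_params),
                                            "mri_uptake"))
  expect_true(all(beta_draws >= 0 & beta_draws <= 1))

  set.seed(8)
  sums <- replicate(200, sum(param_block(draw_psa_sample(base_params),
                                         "gene_prop")))
  expect_true(all(abs(sums - 1) < 1e-9))

  # fixed parameters never move
  set.seed(9); d <- draw_psa_sample(base_params)
  expect_equal(param_value(d, "hr_bc_rrm.BRCA1"), 0)
  expect_equal(param_value(d, "discount_rate"), 0.03)
})

test_that("beta draws are moment-matched to the printed base value", {
  n <- 10000
  for (nm in c("mri_uptake", "fh_identification", "cascade_inform")) {
    e <- base_params$registry[[nm]]
    s <- (e$high - e$low) / (2 * qnorm(0.975))
    sh <- hbocScreen:::.beta_shapes(e$value, s)
    set.seed(101)
    x <- rbeta(n, sh[["a"]], sh[["b"]])
    mcse <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - e$value), 3 * mcse)
  }
})

test_that("log-normal draws reproduce printed confidence limits", {
  # for parameters whose printed base sits at the geometric midpoint of the
  # interval, the implied 2.5th/97.5th percentiles match the printed CI
  n <- 40000
  for (nm in c("or_bc.ATM", "hr_bc_rrso.BRCA1", "or_oc.MSH6")) {
    e <- base_params$registry[[nm]]
    sdlog <- (log(e$high) - log(e$low)) / (2 * qnorm(0.975))
    set.seed(202)
    x <- rlnorm(n, log(e$value), sdlog)
    q <- quantile(x, c(0.025, 0.975))
    expect_lt(abs(q[[1]] - e$low) / e$low, 0.05)
    expect_lt(abs(q[[2]] - e$high) / e$high, 0.05)
  }
})
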