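test_that("transition matrices encode the surgical risk-reduction structure", {
  ps <- base_params
  sg_id <- subgroup("BRCA1", TRUE, "mammo_mri")
  P <- build_transition_matrix(40, sg_id, ps, base_inputs)
  # absorbing death
  expect_equal(P["DEAD", ], c(rep(0, 15), 1), ignore_attr = TRUE)
  # no residual breast cancer after mastectomy, for any gene
  for (g in c("BRCA1", "BRCA2", "ATM", "TP53")) {
    Pg <- build_transition_matrix(45, subgroup(g, TRUE, "mammo_only"),
                                  ps, base_inputs)
    expect_equal(Pg["POST_RRM", c("BC_early_y1", "BC_late_y1")], c(0, 0),
                 ignore_attr = TRUE)
    expect_equal(Pg["POST_RRM_RRSO", c("BC_early_y1", "BC_late_y1")], c(0, 0),
                 ignore_attr = TRUE)
  }
  # BRCA2 and non-BRCA have no residual ovarian cancer after RRSO
  for (g in c("BRCA2", "CHEK2")) {
    Pg <- build_transition_matrix(45, subgroup(g, TRUE, "mammo_only"),
                                  ps, base_inputs)
    expect_equal(Pg["POST_RRSO", c("OC_early_y1", "OC_late_y1")], c(0, 0),
                 ignore_attr = TRUE)
  }
  # unidentified carriers cannot take up surgery
  Pu <- build_transition_matrix(40, subgroup("BRCA1", FALSE, "mammo_only"),
                                ps, base_inputs)
  expect_equal(sum(Pu[, c("RRM_y1", "RRSO_y1")]), 0)
  # tunnel states have zero self-transition
  for (s in c("BC_early_y1", "BC_late_y1", "OC_early_y1", "OC_late_y1",
              "RRM_y1", "RRSO_y1")) {
    expect_equal(P[s, s], 0)
  }
})

test_that("cohort iteration matches the geometric closed form", {
  P <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("alive", "dead"), c("alive", "dead")))
  tr <- markov_trace(P, c(alive = 1, dead = 0), 12)
  expect_equal(tr$occupancy[, "alive"], 0.5^(0:12), tolerance = 1e-12)
  # flows record the per-cycle deaths
  expect_equal(tr$flows[, 1, 2], 0.5^(1:12), tolerance = 1e-12)
})

test_that("a static cohort stays static and all-dead cohorts stay dead", {
  P <- diag(2)
  dimnames(P) <- list(c("alive", "dead"), c("alive", "dead"))
  tr <- markov_trace(P, c(alive = 1, dead = 0), 10)
  expect_true(all(tr$occupancy[, "alive"] == 1))

  S <- hboc_states()
  init <- setNames(numeric(16), S)
  init["DEAD"] <- 1
  sg <- subgroup("BRCA1", TRUE, "mammo_mri")
  tr2 <- run_subgroup(30, sg, base_params, base_inputs, init = init)
  expect_true(all(tr2$occupancy[, "DEAD"] == 1))
  expect_equal(sum(tr2$flows[, , match("BC_early_y1", S)]), 0)
})

test_that("discounted accrual reproduces the annuity closed form", {
  P <- matrix(1, 1, 1, dimnames = list("alive", "alive"))
  tr <- markov_trace(P, c(alive = 1), 3)
  acc <- accrue_trace(tr, state_cost = 0, state_util = 1, rate = 0.03,
                      dead_state = NA)
  expect_equal(acc$disc_qaly, sum(1.03^-(1:3)), tolerance = 1e-12)
  expect_equal(round(acc$disc_qaly, 6), 2.828611)
  acc0 <- accrue_trace(tr, state_cost = 0, state_util = 1, rate = 0,
                       dead_state = NA)
  expect_equal(acc0$disc_qaly, 3)
  # zero utility gives zero QALYs
  accz <- accrue_trace(tr, state_cost = 0, state_util = 0, rate = 0.03,
                       dead_state = NA)
  expect_equal(accz$disc_qaly, 0)
})

test_that("undiscounted life-years equal life-table life expectancy for a
           cancer-free noncarrier", {
  inputs0 <- base_inputs
  zero <- curve_table(20:100, rep(0, 81))
  for (nm in c("bc_general", "oc_general")) inputs0[[nm]] <- zero
  ps0 <- set_param(base_params, "discount_rate", 0)
  tr <- run_subgroup(30, subgroup("noncarrier", FALSE, "mammo_only"),
                     ps0, inputs0)
  util <- rep(1, 16)
  util[match("DEAD", hboc_states())] <- 0
  acc <- accrue_trace(tr, state_cost = 0, state_util = util, rate = 0)
  lt <- inputs0$life
  surv <- cumprod(1 - lt$qx[lt$ages >= 30 & lt$ages < 100])
  expect_equal(acc$disc_ly, sum(surv), tolerance = 1e-6)
  expect_equal(acc$disc_qaly, acc$disc_ly, tolerance = 1e-9)
})

test_that("fast evaluation path agrees with the reference engine", {
  ps <- base_params
  ctx <- hbocScreen:::.model_context(ps, base_inputs)
  cases <- expand.grid(gene = c("BRCA1", "BRCA2", "CHEK2", "TP53", "noncarrier"),
                       identified = c(TRUE, FALSE), stringsAsFactors = FALSE)
  cases <- cases[!(cases$gene == "noncarrier" & cases$identified), ]
  for (i in seq_len(nrow(cases))) {
    g <- cases$gene[i]; id <- cases$identified[i]
    sv <- if (id) "mammo_mri" else "mammo_only"
    ref <- accrue_outcomes(run_subgroup(35, subgroup(g, id, sv), ps, base_inputs), ps)
    fast <- hbocScreen:::.subgroup_bundle(ctx, 35, g, id, sv)
    expect_equal(unlist(ref), unlist(fast), tolerance = 1e-10)
  }
})

test_that("raising RRSO uptake never increases lifetime ovarian cancer cases", {
  lvls <- c(0.3, 0.6, 0.9)
  oc_cases <- vapply(lvls, function(L) {
    inp <- base_inputs
    inp$rrso_uptake <- make_cumulative_curve(L, 45, 0.15, kind = "uptake")
    b <- accrue_outcomes(run_subgroup(30, subgroup("BRCA1", TRUE, "mammo_mri"),
                                      base_params, inp), base_params)
    b$cases_oc
  }, numeric(1))
  expect_true(all(diff(oc_cases) < 0))
})

test_that("without MRI, surgery, or screening harm the arms differ only by
           upfront testing costs and knowledge disutility", {
  inp <- base_inputs
  inp$rrm_uptake <- make_cumulative_curve(0, 40, kind = "uptake")
  inp$rrso_uptake <- make_cumulative_curve(0, 45, kind = "uptake")
  ps <- set_param(base_params, "mri_uptake", 0)
  res <- screen_cea(30, ps, inp, cascade = FALSE)
  al_s <- res$allocations$screening
  al_f <- res$allocations$family_history
  expect_equal(res$incremental[["cost"]] / res$cohort,
               al_s$upfront_cost - al_f$upfront_cost, tolerance = 1e-8)
  expect_equal(res$incremental[["qaly"]] / res$cohort,
               -(al_s$upfront_disutility - al_f$upfront_disutility),
               tolerance = 1e-8)
  expect_equal(res$incremental[["cases_total"]], 0, tolerance = 1e-6)
})
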