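#' Health-state labels of the HBOC Markov model
#'
#' Sixteen states: two precancer monitoring states (mammography plus MRI;
#' mammography only), one-year tunnel states for incident early/late-stage
#' breast and ovarian cancer and for the RRM and RRSO procedures, post-cancer
#' and post-surgery states, and absorbing death.
#'
#' @return Character vector of state names in canonical order.
#' @export
hboc_states <- function() {
  c("MON_mri", "MON_mammo",
    "BC_early_y1", "BC_late_y1", "OC_early_y1", "OC_late_y1",
    "POST_BC_early", "POST_BC_late", "POST_OC_early", "POST_OC_late",
    "RRM_y1", "RRSO_y1", "POST_RRM", "POST_RRSO", "POST_RRM_RRSO",
    "DEAD")
}

#' Cohort subgroup descriptor
#'
#' @param gene One of the eight modelled genes or `"noncarrier"`.
#' @param identified Is the carrier status known? Noncarriers are never
#'   identified carriers.
#' @param surveillance `"mammo_mri"` (identified carriers who take up MRI)
#'   or `"mammo_only"`.
#' @return A list of class `hboc_subgroup`.
#' @export
subgroup <- function(gene, identified, surveillance = c("mammo_only", "mammo_mri")) {
  surveillance <- match.arg(surveillance)
  stopifnot(gene %in% c(GENES, "noncarrier"))
  if (gene == "noncarrier" && identified) {
    stop("noncarriers cannot be identified carriers")
  }
  if (surveillance == "mammo_mri" && !identified) {
    stop("MRI surveillance requires identified carrier status")
  }
  structure(list(gene = gene, identified = identified,
                 surveillance = surveillance), class = "hboc_subgroup")
}

# competing-event decomposition on the rate scale: given marginal annual
# probabilities of mutually exclusive first events, returns event
# probabilities that sum to 1 - exp(-sum of rates)
first_event_probs <- function(p) {
  r <- -log1p(-p)
  R <- sum(r)
  if (R == 0) return(p * 0)
  (-expm1(-R)) * r / R
}

.age_band <- function(age) {
  if (age < 45) "lt45"
  else if (age < 55) "a45_54"
  else if (age < 65) "a55_64"
  else if (age < 75) "a65_74"
  else "ge75"
}

.hr_group <- function(gene) {
  if (gene %in% c("BRCA1", "BRCA2")) gene else "nonBRCA"
}

# Annual baseline cancer probabilities for one subgroup at one age.
# BRCA1/2 use their own cumulative curves; non-BRCA genes take the
# general-population annual probability adjusted on the odds scale by the
# gene's odds ratio (genes with no odds ratio for a cancer keep baseline);
# noncarriers take the general-population probability.
.cancer_probs <- function(age, gene, params, inputs) {
  if (gene %in% c("BRCA1", "BRCA2")) {
    p_bc <- annual_prob_from_cumulative(inputs[[paste0("bc_", gene)]], age)
    p_oc <- annual_prob_from_cumulative(inputs[[paste0("oc_", gene)]], age)
  } else {
    p_bc <- annual_prob_from_cumulative(inputs$bc_general, age)
    p_oc <- annual_prob_from_cumulative(inputs$oc_general, age)
    if (gene != "noncarrier") {
      or_bc <- param_block(params, "or_bc")
      or_oc <- param_block(params, "or_oc")
      if (gene %in% names(or_bc)) p_bc <- apply_odds_ratio(p_bc, or_bc[[gene]])
      if (gene %in% names(or_oc)) p_oc <- apply_odds_ratio(p_oc, or_oc[[gene]])
    }
  }
  c(bc = p_bc, oc = p_oc)
}

#' Build one annual transition matrix
#'
#' Constructs the full 16-state one-cycle transition matrix for a given age
#' and subgroup. Competing events within a cycle (cancer incidence, surgery
#' uptake, death) are made mutually exclusive by a first-event decomposition
#' on the rate scale, so rows sum to one exactly; any row failing the 1e-9
#' check raises an error rather than being renormalised.
#'
#' @param age Age at the start of the cycle.
#' @param sg An [subgroup()] descriptor.
#' @param params An `hboc_params` parameter set.
#' @param inputs An `hboc_inputs` bundle of curves and life table.
#' @return A 16 x 16 matrix with dimnames [hboc_states()].
#' @export
build_transition_matrix <- function(age, sg, params, inputs) {
  S <- hboc_states()
  n <- length(S)
  P <- matrix(0, n, n, dimnames = list(S, S))
  qx <- lt_qx(inputs$life, age)
  cp <- .cancer_probs(age, sg$gene, params, inputs)
  grp <- .hr_group(sg$gene)

  # surgery uptake: identified carriers only, rate-scaled for non-BRCA genes
  if (sg$identified && sg$gene != "noncarrier") {
    rr_rrm <- if (grp == "nonBRCA") param_value(params, "uptake_ratio_rrm") else 1
    rr_rrso <- if (grp == "nonBRCA") param_value(params, "uptake_ratio_rrso") else 1
    p_rrm <- annual_uptake_prob(inputs$rrm_uptake, age, rr_rrm)
    p_rrso <- annual_uptake_prob(inputs$rrso_uptake, age, rr_rrso)
  } else {
    p_rrm <- 0
    p_rrso <- 0
  }

  # stage-at-detection split
  bc_early <- if (sg$surveillance == "mammo_mri") {
    model_setting(params, "stage_early_mammo_mri")
  } else if (sg$identified) {
    model_setting(params, "stage_early_mammo")
  } else {
    model_setting(params, "stage_early_undetected")
  }
  oc_early <- model_setting(params, "stage_early_oc")

  hr_bc_rrso <- param_block(params, "hr_bc_rrso")[[grp]]
  hr_oc_rrso <- param_block(params, "hr_oc_rrso")[[grp]]
  hr_bc_rrm <- param_block(params, "hr_bc_rrm")[[grp]]

  fill_row <- function(from, events, stay_to = from) {
    # events: named list to = prob contributions (already mutually exclusive)
    tot <- 0
    for (to in names(events)) {
      P[from, to] <<- P[from, to] + events[[to]]
      tot <- tot + events[[to]]
    }
    P[from, stay_to] <<- P[from, stay_to] + (1 - tot)
  }

  split_cancer <- function(p_bc, p_oc, p_rrm = 0, p_rrso = 0) {
    fe <- first_event_probs(c(bc = p_bc, oc = p_oc, rrm = p_rrm,
                              rrso = p_rrso, death = qx))
    list(
      BC_early_y1 = fe[["bc"]] * bc_early,
      BC_late_y1  = fe[["bc"]] * (1 - bc_early),
      OC_early_y1 = fe[["oc"]] * oc_early,
      OC_late_y1  = fe[["oc"]] * (1 - oc_early),
      RRM_y1      = fe[["rrm"]],
      RRSO_y1     = fe[["rrso"]],
      DEAD        = fe[["death"]]
    )
  }

  # monitoring states: full competing-event set
  for (mon in c("MON_mri", "MON_mammo")) {
    fill_row(mon, split_cancer(cp[["bc"]], cp[["oc"]], p_rrm, p_rrso))
  }

  # surgery tunnel years: residual cancer risk of the completed surgery
  # applies immediately; the other surgery is not taken up in the same year
  fe_rrm <- first_event_probs(c(oc = cp[["oc"]], death = qx))
  fill_row("RRM_y1", list(
    OC_early_y1 = fe_rrm[["oc"]] * oc_early,
    OC_late_y1  = fe_rrm[["oc"]] * (1 - oc_early),
    DEAD = fe_rrm[["death"]]), stay_to = "POST_RRM")

  p_bc_rrso <- apply_hazard_ratio(cp[["bc"]], hr_bc_rrso)
  p_oc_rrso <- apply_hazard_ratio(cp[["oc"]], hr_oc_rrso)
  fe_rrso <- first_event_probs(c(bc = p_bc_rrso, death = qx))
  fill_row("RRSO_y1", list(
    BC_early_y1 = fe_rrso[["bc"]] * bc_early,
    BC_late_y1  = fe_rrso[["bc"]] * (1 - bc_early),
    DEAD = fe_rrso[["death"]]), stay_to = "POST_RRSO")

  # post-surgery states; the complementary surgery can still follow
  p_bc_rrm <- apply_hazard_ratio(cp[["bc"]], hr_bc_rrm)
  fe <- first_event_probs(c(bc = p_bc_rrm, oc = cp[["oc"]],
                            rrso = p_rrso, death = qx))
  fill_row("POST_RRM", list(
    BC_early_y1 = fe[["bc"]] * bc_early,
    BC_late_y1  = fe[["bc"]] * (1 - bc_early),
    OC_early_y1 = fe[["oc"]] * oc_early,
    OC_late_y1  = fe[["oc"]] * (1 - oc_early),
    POST_RRM_RRSO = fe[["rrso"]],
    DEAD = fe[["death"]]))

  fe <- first_event_probs(c(bc = p_bc_rrso, oc = p_oc_rrso,
                            rrm = p_rrm, death = qx))
  fill_row("POST_RRSO", list(
    BC_early_y1 = fe[["bc"]] * bc_early,
    BC_late_y1  = fe[["bc"]] * (1 - bc_early),
    OC_early_y1 = fe[["oc"]] * oc_early,
    OC_late_y1  = fe[["oc"]] * (1 - oc_early),
    POST_RRM_RRSO = fe[["rrm"]],
    DEAD = fe[["death"]]))

  p_bc_both <- apply_hazard_ratio(p_bc_rrso, hr_bc_rrm)
  fe <- first_event_probs(c(bc = p_bc_both, oc = p_oc_rrso, death = qx))
  fill_row("POST_RRM_RRSO", list(
    BC_early_y1 = fe[["bc"]] * bc_early,
    BC_late_y1  = fe[["bc"]] * (1 - bc_early),
    OC_early_y1 = fe[["oc"]] * oc_early,
    OC_late_y1  = fe[["oc"]] * (1 - oc_early),
    DEAD = fe[["death"]]))

  # cancer states: background plus cancer-specific excess mortality,
  # additive competing risks capped at 1
  band <- .age_band(age)
  ex_bc <- annual_excess_mortality(param_block(params, "rel_mort_bc")[[band]])
  ex_oc <- annual_excess_mortality(param_block(params, "rel_mort_oc")[[band]])
  red <- param_value(params, "early_stage_mortality_reduction")
  ex_bc_early <- if (identical(model_setting(params, "early_stage_reading"),
                               "multiplier")) {
    ex_bc * red
  } else {
    ex_bc * (1 - red)
  }
  persists <- isTRUE(model_setting(params, "excess_mortality_persists"))
  dth <- function(excess) min(1, qx + excess)
  cancer_rows <- list(
    BC_early_y1 = c("POST_BC_early", dth(ex_bc_early)),
    BC_late_y1  = c("POST_BC_late",  dth(ex_bc)),
    OC_early_y1 = c("POST_OC_early", dth(ex_oc)),
    OC_late_y1  = c("POST_OC_late",  dth(ex_oc))
  )
  for (from in names(cancer_rows)) {
    to <- cancer_rows[[from]][1]
    pd <- as.numeric(cancer_rows[[from]][2])
    P[from, "DEAD"] <- pd
    P[from, to] <- 1 - pd
  }
  post_rows <- c(POST_BC_early = if (persists) ex_bc_early else 0,
                 POST_BC_late  = if (persists) ex_bc else 0,
                 POST_OC_early = if (persists) ex_oc else 0,
                 POST_OC_late  = if (persists) ex_oc else 0)
  for (from in names(post_rows)) {
    pd <- dth(post_rows[[from]])
    P[from, "DEAD"] <- pd
    P[from, from] <- 1 - pd
  }
  P["DEAD", "DEAD"] <- 1

  bad <- which(abs(rowSums(P) - 1) > 1e-9)
  if (length(bad)) {
    stop(sprintf("transition construction error: row(s) %s do not sum to 1",
                 paste(S[bad], collapse = ", ")))
  }
  P
}

#' Run a cohort trace through a state-transition model
#'
#' Generic annual-cycle cohort iteration: occupancy is advanced by
#' matrix multiplication and the full flow matrix of each cycle is retained
#' so that event counts and transition-attached costs can be accrued.
#'
#' @param P A transition matrix, or a function `function(cycle)` returning
#'   the matrix for that cycle (1-based).
#' @param init Initial occupancy vector (sums to 1).
#' @param cycles Number of annual cycles.
#' @return An object of class `hboc_trace`: list with `occupancy`
#'   ((cycles+1) x S, row 1 = cycle 0) and `flows` (cycles x S x S array).
#' @export
markov_trace <- function(P, init, cycles) {
  if (abs(sum(init) - 1) > 1e-9) stop("engine error: init mass must sum to 1")
  Pfun <- if (is.function(P)) P else function(t) P
  S <- length(init)
  occ <- matrix(0, cycles + 1, S)
  occ[1, ] <- init
  flows <- array(0, dim = c(cycles, S, S))
  cur <- init
  for (t in seq_len(cycles)) {
    M <- Pfun(t)
    f <- M * cur               # row i scaled by occupancy of state i
    cur <- colSums(f)
    if (abs(sum(cur) - 1) > 1e-9) {
      stop(sprintf("engine error: mass not conserved at cycle %d (sum = %.12f)",
                   t, sum(cur)))
    }
    flows[t, , ] <- f
    occ[t + 1, ] <- cur
  }
  colnames(occ) <- names(init) %||% colnames(Pfun(1))
  structure(list(occupancy = occ, flows = flows), class = "hboc_trace")
}

#' Discounted accrual over a cohort trace
#'
#' End-of-cycle accounting: cycle t accrues state costs and utilities on the
#' occupancy after the t-th transition, plus any transition-attached costs
#' and utility decrements on the flows of that cycle, all discounted by
#' `(1+rate)^-t`. Life-years count occupancy of non-dead states.
#'
#' @param trace An `hboc_trace`.
#' @param state_cost,state_util Per-cycle state cost/utility: either a
#'   vector of length S or a function `function(cycle)` returning one.
#' @param trans_cost,trans_util Optional S x S matrices (or
#'   `function(cycle)`) of one-time costs / utility decrements attached to
#'   flows.
#' @param rate Annual discount rate.
#' @param dead_state Index or name of the absorbing death state.
#' @return List with `disc_cost`, `disc_qaly`, `disc_ly` (per person).
#' @export
accrue_trace <- function(trace, state_cost, state_util,
                         trans_cost = NULL, trans_util = NULL,
                         rate = 0.03, dead_state = "DEAD") {
  occ <- trace$occupancy
  S <- ncol(occ)
  cycles <- nrow(occ) - 1
  if (is.character(dead_state)) dead_state <- match(dead_state, colnames(occ))
  alive <- rep(1, S)
  if (!is.na(dead_state)) alive[dead_state] <- 0
  costf <- if (is.function(state_cost)) state_cost else function(t) state_cost
  utilf <- if (is.function(state_util)) state_util else function(t) state_util
  tcf <- if (is.null(trans_cost)) NULL else if (is.function(trans_cost)) trans_cost else function(t) trans_cost
  tuf <- if (is.null(trans_util)) NULL else if (is.function(trans_util)) trans_util else function(t) trans_util
  disc_cost <- disc_qaly <- disc_ly <- 0
  for (t in seq_len(cycles)) {
    d <- discount_factor(t, rate)
    o <- occ[t + 1, ]
    cost_t <- sum(o * costf(t))
    qaly_t <- sum(o * utilf(t))
    if (!is.null(tcf)) cost_t <- cost_t + sum(trace$flows[t, , ] * tcf(t))
    if (!is.null(tuf)) qaly_t <- qaly_t + sum(trace$flows[t, , ] * tuf(t))
    disc_cost <- disc_cost + d * cost_t
    disc_qaly <- disc_qaly + d * qaly_t
    disc_ly <- disc_ly + d * sum(o * alive)
  }
  list(disc_cost = disc_cost, disc_qaly = disc_qaly, disc_ly = disc_ly)
}

# number of annual cycles from entry age to the model horizon (age 100 or
# the end of the life table, whichever comes first)
.n_cycles <- function(age0, inputs, horizon_age = 100) {
  min(horizon_age, max(inputs$life$ages)) - age0
}

#' Run the lifetime trace for one subgroup
#'
#' Builds the age-specific transition matrices from entry age to the model
#' horizon (age 100) and iterates the cohort.
#'
#' @param age0 Entry age.
#' @param sg An [subgroup()].
#' @param params `hboc_params`.
#' @param inputs `hboc_inputs`.
#' @param init Initial occupancy (defaults to all mass in the monitoring
#'   state implied by the subgroup's surveillance).
#' @return An `hboc_trace` with attribute `age0`.
#' @export
run_subgroup <- function(age0, sg, params, inputs, init = NULL) {
  S <- hboc_states()
  cycles <- .n_cycles(age0, inputs)
  if (cycles < 1) stop("entry age at or beyond the model horizon")
  if (is.null(init)) {
    init <- stats::setNames(numeric(length(S)), S)
    init[if (sg$surveillance == "mammo_mri") "MON_mri" else "MON_mammo"] <- 1
  }
  tr <- markov_trace(function(t) {
    build_transition_matrix(age0 + t - 1, sg, params, inputs)
  }, init, cycles)
  attr(tr, "age0") <- age0
  tr
}

# state cost/utility vectors for the full model at a given current age
.model_state_cost <- function(params, age) {
  sfx <- if (age < 65) "lt65" else "ge65"
  v <- c(
    MON_mri = param_value(params, "cost_mammography") + param_value(params, "cost_mri"),
    MON_mammo = param_value(params, "cost_mammography"),
    BC_early_y1 = param_value(params, paste0("cost_bc_initial_", sfx)),
    BC_late_y1 = param_value(params, paste0("cost_bc_initial_", sfx)),
    OC_early_y1 = param_value(params, paste0("cost_oc_initial_", sfx)),
    OC_late_y1 = param_value(params, paste0("cost_oc_initial_", sfx)),
    POST_BC_early = param_value(params, paste0("cost_bc_continuing_", sfx)),
    POST_BC_late = param_value(params, paste0("cost_bc_continuing_", sfx)),
    POST_OC_early = param_value(params, paste0("cost_oc_continuing_", sfx)),
    POST_OC_late = param_value(params, paste0("cost_oc_continuing_", sfx)),
    RRM_y1 = param_value(params, "cost_mastectomy"),
    RRSO_y1 = param_value(params, "cost_oophorectomy"),
    POST_RRM = 0, POST_RRSO = 0, POST_RRM_RRSO = 0, DEAD = 0)
  v[hboc_states()]
}

.model_state_util <- function(params) {
  v <- c(
    MON_mri = 1, MON_mammo = 1,
    BC_early_y1 = param_value(params, "util_bc"),
    BC_late_y1 = param_value(params, "util_bc"),
    OC_early_y1 = param_value(params, "util_oc"),
    OC_late_y1 = param_value(params, "util_oc"),
    POST_BC_early = param_value(params, "util_post_bc"),
    POST_BC_late = param_value(params, "util_post_bc"),
    POST_OC_early = param_value(params, "util_post_oc"),
    POST_OC_late = param_value(params, "util_post_oc"),
    RRM_y1 = 1 - param_value(params, "disutil_mastectomy"),
    RRSO_y1 = 1 - param_value(params, "disutil_oophorectomy"),
    POST_RRM = 1, POST_RRSO = 1, POST_RRM_RRSO = 1, DEAD = 0)
  v[hboc_states()]
}

.model_trans_cost <- function(params, age) {
  S <- hboc_states()
  sfx <- if (age < 65) "lt65" else "ge65"
  M <- matrix(0, length(S), length(S), dimnames = list(S, S))
  bc_states <- c("BC_early_y1", "BC_late_y1", "POST_BC_early", "POST_BC_late")
  oc_states <- c("OC_early_y1", "OC_late_y1", "POST_OC_early", "POST_OC_late")
  M[bc_states, "DEAD"] <- param_value(params, paste0("cost_bc_lastyear_", sfx))
  M[oc_states, "DEAD"] <- param_value(params, paste0("cost_oc_lastyear_", sfx))
  M["POST_RRM", "POST_RRM_RRSO"] <- param_value(params, "cost_oophorectomy")
  M["POST_RRSO", "POST_RRM_RRSO"] <- param_value(params, "cost_mastectomy")
  M
}

.model_trans_util <- function(params) {
  S <- hboc_states()
  M <- matrix(0, length(S), length(S), dimnames = list(S, S))
  M["POST_RRM", "POST_RRM_RRSO"] <- -param_value(params, "disutil_oophorectomy")
  M["POST_RRSO", "POST_RRM_RRSO"] <- -param_value(params, "disutil_mastectomy")
  M
}

#' Accrue lifetime outcomes for one subgroup trace
#'
#' Applies the model's cost and utility schedule to a subgroup trace:
#' mammography (plus MRI in the MRI monitoring state) while cancer-free,
#' surgery costs and one-year disutilities in the procedure tunnel years
#' (and on direct post-surgery-to-both transitions), cancer initial /
#' continuing / palliative last-year costs, cancer utilities, all
#' discounted; and the undiscounted event counters.
#'
#' @param trace An `hboc_trace` from [run_subgroup()].
#' @param params `hboc_params`.
#' @param upfront_cost,upfront_disutility Per-person decision-tree accruals
#'   added at time zero (undiscounted).
#' @return An `outcome_bundle`: discounted cost, QALYs, life-years, plus
#'   undiscounted case and event counts per person entering.
#' @export
accrue_outcomes <- function(trace, params, upfront_cost = 0,
                            upfront_disutility = 0) {
  age0 <- attr(trace, "age0")
  if (is.null(age0)) stop("trace is missing its entry age")
  rate <- param_value(params, "discount_rate")
  acc <- accrue_trace(
    trace,
    state_cost = function(t) .model_state_cost(params, age0 + t - 1),
    state_util = .model_state_util(params),
    trans_cost = function(t) .model_trans_cost(params, age0 + t - 1),
    trans_util = .model_trans_util(params),
    rate = rate)
  S <- hboc_states()
  idx <- function(nm) match(nm, S)
  inflow <- function(nm) sum(trace$flows[, , idx(nm)])
  flow <- function(from, to) sum(trace$flows[, idx(from), idx(to)])
  cases_early <- inflow("BC_early_y1") + inflow("OC_early_y1")
  cases_late <- inflow("BC_late_y1") + inflow("OC_late_y1")
  cancer_states <- c("BC_early_y1", "BC_late_y1", "OC_early_y1", "OC_late_y1",
                     "POST_BC_early", "POST_BC_late", "POST_OC_early", "POST_OC_late")
  deaths_cancer <- sum(vapply(cancer_states, function(s) flow(s, "DEAD"),
                              numeric(1)))
  structure(list(
    disc_cost = acc$disc_cost + upfront_cost,
    disc_qaly = acc$disc_qaly - upfront_disutility,
    disc_ly = acc$disc_ly,
    cases_early = cases_early,
    cases_late = cases_late,
    cases_total = cases_early + cases_late,
    cases_bc = inflow("BC_early_y1") + inflow("BC_late_y1"),
    cases_oc = inflow("OC_early_y1") + inflow("OC_late_y1"),
    deaths_cancer = deaths_cancer,
    n_rrm = inflow("RRM_y1") + flow("POST_RRSO", "POST_RRM_RRSO"),
    n_rrso = inflow("RRSO_y1") + flow("POST_RRM", "POST_RRM_RRSO")
  ), class = "outcome_bundle")
}

# weighted sum / difference of outcome bundles
bundle_combine <- function(bundles, weights) {
  fields <- names(bundles[[1]])
  out <- stats::setNames(vector("list", length(fields)), fields)
  for (f in fields) {
    out[[f]] <- sum(vapply(seq_along(bundles),
                           function(i) bundles[[i]][[f]] * weights[i],
                           numeric(1)))
  }
  structure(out, class = "outcome_bundle")
}
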