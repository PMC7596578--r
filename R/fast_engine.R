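# Internal fast path for whole-model evaluations (PSA, tornado, age sweeps).
# Precomputes every age-indexed probability and cost schedule once per
# (params, inputs) pair, then runs a fused trace-and-accrual loop without
# dimname lookups. Equivalence with the reference implementation
# (build_transition_matrix / markov_trace / accrue_outcomes) is asserted in
# the test suite.

.S <- list(MON1 = 1L, MON2 = 2L, BCE1 = 3L, BCL1 = 4L, OCE1 = 5L, OCL1 = 6L,
           PBCE = 7L, PBCL = 8L, POCE = 9L, POCL = 10L, RRM1 = 11L,
           RRSO1 = 12L, PRRM = 13L, PRRSO = 14L, PRRMRRSO = 15L, DEAD = 16L)

.model_context <- function(params, inputs) {
  amin <- min(inputs$bc_general$ages)
  amax <- min(100, max(inputs$life$ages)) - 1   # last age with a transition
  ages <- amin:amax
  nA <- length(ages)
  annual_vec <- function(curve) {
    f <- curve$values[match(c(ages, amax + 1), curve$ages)]
    p <- (f[-1] - f[-length(f)]) / (1 - f[-length(f)])
    pmin(pmax(p, 0), 1)
  }
  or_bc <- param_block(params, "or_bc")
  or_oc <- param_block(params, "or_oc")
  p_bc_gen <- annual_vec(inputs$bc_general)
  p_oc_gen <- annual_vec(inputs$oc_general)
  p_bc <- list(); p_oc <- list()
  for (g in c(GENES, "noncarrier")) {
    if (g %in% c("BRCA1", "BRCA2")) {
      p_bc[[g]] <- annual_vec(inputs[[paste0("bc_", g)]])
      p_oc[[g]] <- annual_vec(inputs[[paste0("oc_", g)]])
    } else {
      p_bc[[g]] <- if (g %in% names(or_bc)) {
        apply_odds_ratio(p_bc_gen, or_bc[[g]])
      } else p_bc_gen
      p_oc[[g]] <- if (g %in% names(or_oc)) {
        apply_odds_ratio(p_oc_gen, or_oc[[g]])
      } else p_oc_gen
    }
  }
  p_rrm_brca <- annual_vec(inputs$rrm_uptake)
  p_rrso_brca <- annual_vec(inputs$rrso_uptake)
  rr_rrm <- param_value(params, "uptake_ratio_rrm")
  rr_rrso <- param_value(params, "uptake_ratio_rrso")

  qx <- vapply(ages, function(a) lt_qx(inputs$life, a), numeric(1))

  bands <- vapply(ages, .age_band, character(1))
  ex_bc <- annual_excess_mortality(param_block(params, "rel_mort_bc"))[bands]
  ex_oc <- annual_excess_mortality(param_block(params, "rel_mort_oc"))[bands]
  red <- param_value(params, "early_stage_mortality_reduction")
  ex_bc_early <- if (identical(model_setting(params, "early_stage_reading"),
                               "multiplier")) ex_bc * red else ex_bc * (1 - red)
  persists <- isTRUE(model_setting(params, "excess_mortality_persists"))

  hr_bc_rrm <- param_block(params, "hr_bc_rrm")
  hr_bc_rrso <- param_block(params, "hr_bc_rrso")
  hr_oc_rrso <- param_block(params, "hr_oc_rrso")

  cost_band <- function(sfx) {
    v <- numeric(16)
    v[.S$MON1] <- param_value(params, "cost_mammography") + param_value(params, "cost_mri")
    v[.S$MON2] <- param_value(params, "cost_mammography")
    v[c(.S$BCE1, .S$BCL1)] <- param_value(params, paste0("cost_bc_initial_", sfx))
    v[c(.S$OCE1, .S$OCL1)] <- param_value(params, paste0("cost_oc_initial_", sfx))
    v[c(.S$PBCE, .S$PBCL)] <- param_value(params, paste0("cost_bc_continuing_", sfx))
    v[c(.S$POCE, .S$POCL)] <- param_value(params, paste0("cost_oc_continuing_", sfx))
    v[.S$RRM1] <- param_value(params, "cost_mastectomy")
    v[.S$RRSO1] <- param_value(params, "cost_oophorectomy")
    v
  }
  util <- numeric(16)
  util[c(.S$MON1, .S$MON2, .S$PRRM, .S$PRRSO, .S$PRRMRRSO)] <- 1
  util[c(.S$BCE1, .S$BCL1)] <- param_value(params, "util_bc")
  util[c(.S$OCE1, .S$OCL1)] <- param_value(params, "util_oc")
  util[c(.S$PBCE, .S$PBCL)] <- param_value(params, "util_post_bc")
  util[c(.S$POCE, .S$POCL)] <- param_value(params, "util_post_oc")
  util[.S$RRM1] <- 1 - param_value(params, "disutil_mastectomy")
  util[.S$RRSO1] <- 1 - param_value(params, "disutil_oophorectomy")

  list(
    amin = amin, amax = amax, nA = nA,
    p_bc = p_bc, p_oc = p_oc,
    p_rrm = list(brca = p_rrm_brca,
                 nonbrca = apply_hazard_ratio(p_rrm_brca, rr_rrm)),
    p_rrso = list(brca = p_rrso_brca,
                  nonbrca = apply_hazard_ratio(p_rrso_brca, rr_rrso)),
    qx = qx, ex_bc = ex_bc, ex_oc = ex_oc, ex_bc_early = ex_bc_early,
    persists = persists,
    hr_bc_rrm = hr_bc_rrm, hr_bc_rrso = hr_bc_rrso, hr_oc_rrso = hr_oc_rrso,
    stage = c(mri = model_setting(params, "stage_early_mammo_mri"),
              mammo = model_setting(params, "stage_early_mammo"),
              undet = model_setting(params, "stage_early_undetected"),
              oc = model_setting(params, "stage_early_oc")),
    cost_lt65 = cost_band("lt65"), cost_ge65 = cost_band("ge65"),
    bc_last = c(lt65 = param_value(params, "cost_bc_lastyear_lt65"),
                ge65 = param_value(params, "cost_bc_lastyear_ge65")),
    oc_last = c(lt65 = param_value(params, "cost_oc_lastyear_lt65"),
                ge65 = param_value(params, "cost_oc_lastyear_ge65")),
    c_mast = param_value(params, "cost_mastectomy"),
    c_ooph = param_value(params, "cost_oophorectomy"),
    du_mast = param_value(params, "disutil_mastectomy"),
    du_ooph = param_value(params, "disutil_oophorectomy"),
    util = util,
    rate = param_value(params, "discount_rate"),
    cache = new.env(parent = emptyenv())
  )
}

# transition matrix at one age index for one subgroup; mirrors
# build_transition_matrix exactly but on plain integer indices
.fast_P <- function(ctx, ai, gene, identified, surv) {
  s <- .S
  P <- matrix(0, 16, 16)
  qx <- ctx$qx[ai]
  pbc <- ctx$p_bc[[gene]][ai]
  poc <- ctx$p_oc[[gene]][ai]
  if (identified && gene != "noncarrier") {
    grp <- if (gene %in% c("BRCA1", "BRCA2")) "brca" else "nonbrca"
    prrm <- ctx$p_rrm[[grp]][ai]
    prrso <- ctx$p_rrso[[grp]][ai]
  } else {
    prrm <- 0; prrso <- 0
  }
  hg <- .hr_group(gene)
  bc_e <- if (surv == "mammo_mri") ctx$stage[["mri"]] else if (identified)
    ctx$stage[["mammo"]] else ctx$stage[["undet"]]
  oc_e <- ctx$stage[["oc"]]

  fe <- function(p) {
    r <- -log1p(-p); R <- sum(r)
    if (R == 0) p * 0 else (-expm1(-R)) * r / R
  }
  put_cancer <- function(i, pb, po, extra_idx = integer(0), extra_p = numeric(0),
                         stay = i) {
    v <- fe(c(pb, po, extra_p, qx))
    P[i, s$BCE1] <<- v[1] * bc_e
    P[i, s$BCL1] <<- v[1] * (1 - bc_e)
    P[i, s$OCE1] <<- v[2] * oc_e
    P[i, s$OCL1] <<- v[2] * (1 - oc_e)
    k <- 2
    for (j in seq_along(extra_idx)) {
      P[i, extra_idx[j]] <<- v[k + j]
    }
    P[i, s$DEAD] <<- v[length(v)]
    P[i, stay] <<- P[i, stay] + 1 - sum(v)
  }
  for (mon in c(s$MON1, s$MON2)) {
    put_cancer(mon, pbc, poc, c(s$RRM1, s$RRSO1), c(prrm, prrso))
  }
  # tunnels
  v <- fe(c(poc, qx))
  P[s$RRM1, s$OCE1] <- v[1] * oc_e
  P[s$RRM1, s$OCL1] <- v[1] * (1 - oc_e)
  P[s$RRM1, s$DEAD] <- v[2]
  P[s$RRM1, s$PRRM] <- 1 - sum(v)
  pbc_rrso <- -expm1(ctx$hr_bc_rrso[[hg]] * log1p(-pbc))
  poc_rrso <- -expm1(ctx$hr_oc_rrso[[hg]] * log1p(-poc))
  pbc_rrm <- -expm1(ctx$hr_bc_rrm[[hg]] * log1p(-pbc))
  v <- fe(c(pbc_rrso, qx))
  P[s$RRSO1, s$BCE1] <- v[1] * bc_e
  P[s$RRSO1, s$BCL1] <- v[1] * (1 - bc_e)
  P[s$RRSO1, s$DEAD] <- v[2]
  P[s$RRSO1, s$PRRSO] <- 1 - sum(v)
  # post-surgery
  put_cancer(s$PRRM, pbc_rrm, poc, s$PRRMRRSO, prrso)
  put_cancer(s$PRRSO, pbc_rrso, poc_rrso, s$PRRMRRSO, prrm)
  pbc_both <- -expm1(ctx$hr_bc_rrm[[hg]] * log1p(-pbc_rrso))
  put_cancer(s$PRRMRRSO, pbc_both, poc_rrso)
  # cancer states
  dth <- function(excess) min(1, qx + excess)
  trans <- rbind(c(s$BCE1, s$PBCE, dth(ctx$ex_bc_early[ai])),
                 c(s$BCL1, s$PBCL, dth(ctx$ex_bc[ai])),
                 c(s$OCE1, s$POCE, dth(ctx$ex_oc[ai])),
                 c(s$OCL1, s$POCL, dth(ctx$ex_oc[ai])))
  for (r in seq_len(4)) {
    P[trans[r, 1], s$DEAD] <- trans[r, 3]
    P[trans[r, 1], trans[r, 2]] <- 1 - trans[r, 3]
  }
  post_ex <- if (ctx$persists) {
    c(ctx$ex_bc_early[ai], ctx$ex_bc[ai], ctx$ex_oc[ai], ctx$ex_oc[ai])
  } else rep(0, 4)
  post_idx <- c(s$PBCE, s$PBCL, s$POCE, s$POCL)
  for (r in seq_len(4)) {
    pd <- dth(post_ex[r])
    P[post_idx[r], s$DEAD] <- pd
    P[post_idx[r], post_idx[r]] <- 1 - pd
  }
  P[s$DEAD, s$DEAD] <- 1
  P
}

# fused lifetime trace + accrual for one subgroup; returns outcome_bundle
.subgroup_bundle <- function(ctx, age0, gene, identified, surv) {
  key <- paste(age0, gene, identified, surv, sep = "|")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- .S
  cycles <- (ctx$amax + 1) - age0
  if (cycles < 1) stop("entry age at or beyond the model horizon")
  occ <- numeric(16)
  occ[if (surv == "mammo_mri") s$MON1 else s$MON2] <- 1
  disc_cost <- disc_qaly <- disc_ly <- 0
  cases <- c(bce = 0, bcl = 0, oce = 0, ocl = 0)
  deaths_cancer <- 0; n_rrm <- 0; n_rrso <- 0
  cancer_idx <- c(s$BCE1, s$BCL1, s$OCE1, s$OCL1, s$PBCE, s$PBCL, s$POCE, s$POCL)
  bc_idx <- c(s$BCE1, s$BCL1, s$PBCE, s$PBCL)
  oc_idx <- c(s$OCE1, s$OCL1, s$POCE, s$POCL)
  vd <- (1 + ctx$rate)^-(seq_len(cycles))
  for (t in seq_len(cycles)) {
    a <- age0 + t - 1
    ai <- a - ctx$amin + 1
    P <- .fast_P(ctx, ai, gene, identified, surv)
    cross_rrso <- occ[s$PRRM] * P[s$PRRM, s$PRRMRRSO]
    cross_rrm <- occ[s$PRRSO] * P[s$PRRSO, s$PRRMRRSO]
    dead_bc <- sum(occ[bc_idx] * P[bc_idx, s$DEAD])
    dead_oc <- sum(occ[oc_idx] * P[oc_idx, s$DEAD])
    occ <- as.numeric(occ %*% P)
    band <- if (a < 65) "lt65" else "ge65"
    costv <- if (a < 65) ctx$cost_lt65 else ctx$cost_ge65
    cost_t <- sum(occ * costv) +
      dead_bc * ctx$bc_last[[band]] + dead_oc * ctx$oc_last[[band]] +
      cross_rrso * ctx$c_ooph + cross_rrm * ctx$c_mast
    qaly_t <- sum(occ * ctx$util) -
      cross_rrso * ctx$du_ooph - cross_rrm * ctx$du_mast
    disc_cost <- disc_cost + vd[t] * cost_t
    disc_qaly <- disc_qaly + vd[t] * qaly_t
    disc_ly <- disc_ly + vd[t] * (1 - occ[s$DEAD])
    cases <- cases + occ[c(s$BCE1, s$BCL1, s$OCE1, s$OCL1)]
    deaths_cancer <- deaths_cancer + dead_bc + dead_oc
    n_rrm <- n_rrm + occ[s$RRM1] + cross_rrm
    n_rrso <- n_rrso + occ[s$RRSO1] + cross_rrso
  }
  out <- structure(list(
    disc_cost = disc_cost, disc_qaly = disc_qaly, disc_ly = disc_ly,
    cases_early = cases[["bce"]] + cases[["oce"]],
    cases_late = cases[["bcl"]] + cases[["ocl"]],
    cases_total = sum(cases),
    cases_bc = cases[["bce"]] + cases[["bcl"]],
    cases_oc = cases[["oce"]] + cases[["ocl"]],
    deaths_cancer = deaths_cancer,
    n_rrm = n_rrm, n_rrso = n_rrso
  ), class = "outcome_bundle")
  ctx$cache[[key]] <- out
  out
}
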