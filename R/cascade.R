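#' Expected surviving first-degree female relatives of an index carrier
#'
#' Deterministic expectations: one mother aged `index_age + maternal_gap`,
#' `n_sisters` sisters of the index age, and `n_daughters` daughters aged
#' `index_age - maternal_gap` (zero if the index is younger than the
#' maternal gap). Each expectation is weighted by life-table survival from
#' the start of the table to the relative's age.
#'
#' @param index_age Age of the index carrier.
#' @param life A `life_table`.
#' @param assumptions List with `n_sisters`, `n_daughters`, `maternal_gap`.
#' @return Data frame of class `family_profile` with columns `relation`,
#'   `age`, `expected`.
#' @export
expected_relatives <- function(index_age, life,
                               assumptions = list(n_sisters = 1,
                                                  n_daughters = 1,
                                                  maternal_gap = 27)) {
  gap <- assumptions$maternal_gap
  a0 <- min(life$ages)
  surv_to <- function(a) {
    if (a > max(life$ages)) return(0)
    lt_survival(life, a0, a)
  }
  rows <- data.frame(
    relation = c("mother", "sister", "daughter"),
    age = c(index_age + gap, index_age, index_age - gap),
    count = c(1, assumptions$n_sisters, assumptions$n_daughters)
  )
  rows$expected <- ifelse(rows$age < a0, 0,
                          rows$count * vapply(rows$age, surv_to, numeric(1)))
  rows$count <- NULL
  class(rows) <- c("family_profile", "data.frame")
  rows
}

#' Cascade-testing increment from screen-identified carriers
#'
#' For each surviving first-degree relative of an identified carrier, the
#' inform (0.70) and ever-tested (0.20) probabilities determine the tested
#' mass; tested relatives carry the family variant with Mendelian
#' probability one half and are detected with the assay sensitivity.
#' Detected relatives are run through the Markov engine at their own ages as
#' identified carriers (MRI uptake applied, knowledge disutility included)
#' and their unidentified counterfactual is subtracted, so the increment
#' carries only the consequence of identification. Relatives younger than
#' the curve grid enter the model at its start age, with survival to entry
#' and discounting of the delay applied.
#'
#' @param identified_by_gene Named vector: identified-carrier mass per gene,
#'   on the cohort scale being analysed (e.g. incremental identified
#'   carriers per woman screened).
#' @param index_age Age of the index carriers.
#' @param params `hboc_params`.
#' @param inputs `hboc_inputs`.
#' @param ctx Optional precomputed model context (internal reuse).
#' @return An object of class `cascade_increment`: `tested_count`,
#'   `detected_count`, `testing_cost` and `deltas` (named vector with
#'   `cost`, `qaly`, `ly`, `cases_early`, `cases_late`, `cases_total`),
#'   all on the same cohort scale as the input masses. `deltas["cost"]`
#'   includes the testing cost.
#' @export
run_cascade <- function(identified_by_gene, index_age, params, inputs,
                        ctx = NULL) {
  stopifnot(all(names(identified_by_gene) %in% GENES))
  if (is.null(ctx)) ctx <- .model_context(params, inputs)
  assum <- model_setting(params, "cascade_assumptions")
  fam <- expected_relatives(index_age, inputs$life, assum)
  inform <- param_value(params, "cascade_inform")
  ptest <- param_value(params, "cascade_test")
  sens <- param_value(params, "test_sensitivity")
  spec <- param_value(params, "test_specificity")
  mri <- param_value(params, "mri_uptake")
  rate <- param_value(params, "discount_rate")
  know <- param_value(params, "disutil_knowledge")
  index_mass <- sum(identified_by_gene)

  tested_per_index <- sum(fam$expected) * inform * ptest
  detected_per_index_rel <- fam$expected * inform * ptest * 0.5 * sens
  positives_per_index <- tested_per_index * (0.5 * sens + 0.5 * (1 - spec))
  testing_cost_per_index <- tested_per_index * param_value(params, "cost_assay") +
    positives_per_index * param_value(params, "cost_confirmation")

  entry_floor <- min(inputs$bc_general$ages)
  horizon <- max(inputs$life$ages)
  zero <- c(cost = 0, qaly = 0, ly = 0,
            cases_early = 0, cases_late = 0, cases_total = 0)
  deltas <- zero
  for (g in names(identified_by_gene)) {
    mg <- identified_by_gene[[g]]
    if (mg <= 0) next
    for (r in seq_len(nrow(fam))) {
      if (detected_per_index_rel[r] <= 0) next
      a_rel <- fam$age[r]
      a_eff <- max(a_rel, entry_floor)
      if (a_eff >= horizon) next   # beyond the model horizon
      delay <- a_eff - a_rel
      w <- mg * detected_per_index_rel[r] *
        lt_survival(inputs$life, max(a_rel, min(inputs$life$ages)), a_eff) *
        discount_factor(delay, rate)
      ident <- bundle_combine(list(
        .subgroup_bundle(ctx, a_eff, g, TRUE, "mammo_mri"),
        .subgroup_bundle(ctx, a_eff, g, TRUE, "mammo_only")
      ), c(mri, 1 - mri))
      ident$disc_qaly <- ident$disc_qaly - know
      unident <- .subgroup_bundle(ctx, a_eff, g, FALSE, "mammo_only")
      deltas <- deltas + w * c(
        cost = ident$disc_cost - unident$disc_cost,
        qaly = ident$disc_qaly - unident$disc_qaly,
        ly = ident$disc_ly - unident$disc_ly,
        cases_early = ident$cases_early - unident$cases_early,
        cases_late = ident$cases_late - unident$cases_late,
        cases_total = ident$cases_total - unident$cases_total)
    }
  }
  testing_cost <- index_mass * testing_cost_per_index
  deltas[["cost"]] <- deltas[["cost"]] + testing_cost
  structure(list(
    tested_count = index_mass * tested_per_index,
    detected_count = index_mass * sum(detected_per_index_rel),
    testing_cost = testing_cost,
    family_profile = fam,
    deltas = deltas
  ), class = "cascade_increment")
}

#' Add cascade increments to primary incremental results
#'
#' Element-wise addition of two incremental-result vectors on the same
#' cohort scale (cost, QALYs, life-years, early/late/total case deltas).
#' The names present in both vectors must agree.
#'
#' @param base Named numeric vector of primary incremental results.
#' @param cascade Named numeric vector of cascade increments.
#' @return Named numeric vector of combined incremental results.
#' @export
#' @examples
#' combine_outcomes(c(cases_early = 117, cases_late = -184, cases_total = -67),
#'                  c(cases_early = 21, cases_late = -29, cases_total = -8))
combine_outcomes <- function(base, cascade) {
  base <- unlist(base)
  cascade <- unlist(cascade)
  if (!setequal(names(base), names(cascade))) {
    stop("unit error: incremental results have mismatched components")
  }
  base + cascade[names(base)]
}

#' @export
print.cascade_increment <- function(x, ...) {
  cat("Cascade-testing increment (per unit cohort)\n")
  cat(sprintf("  relatives tested: %.6g; carriers detected: %.6g\n",
              x$tested_count, x$detected_count))
  cat(sprintf("  testing cost: %.6g; delta QALY: %.6g; delta cost: %.6g\n",
              x$testing_cost, x$deltas[["qaly"]], x$deltas[["cost"]]))
  invisible(x)
}
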