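#' Distribute the entering cohort across Markov starting subgroups
#'
#' Implements the decision tree for one strategy arm. In the screening arm a
#' fraction `1 - avoid_screening` participates and is assay-tested; carriers
#' are detected with the test sensitivity, and tested noncarriers return a
#' false positive with `1 - specificity`, incurring one confirmation cost
#' before returning to the noncarrier pathway. Family history-based testing
#' identifies a fraction `fh_identification` of carriers in both arms; in
#' the screening arm it applies only to non-participants and false negatives
#' so no carrier is counted twice. Identified carriers split by MRI uptake
#' into the mammography-plus-MRI or mammography-only monitoring state and
#' incur the one-year variant-knowledge disutility; participants are charged
#' the assay and every positive (true or false) one confirmation test.
#'
#' @param arm `"screening"` or `"family_history"`.
#' @param params An `hboc_params` parameter set.
#' @return An object of class `hboc_allocation`: list with `arm`, `masses`
#'   (data frame of subgroup fractions), `upfront_cost` and
#'   `upfront_disutility` (per woman entering), and bookkeeping counts
#'   (`assays`, `confirmations`, `identified` fraction).
#' @export
#' @examples
#' al <- allocate_cohort("family_history", hboc_parameters())
#' sum(al$masses$mass)  # 1
allocate_cohort <- function(arm = c("screening", "family_history"), params) {
  arm <- match.arg(arm)
  prev <- param_value(params, "carrier_prevalence")
  gp <- param_block(params, "gene_prop")
  fh <- param_value(params, "fh_identification")
  sens <- param_value(params, "test_sensitivity")
  spec <- param_value(params, "test_specificity")
  avoid <- param_value(params, "avoid_screening")
  mri <- param_value(params, "mri_uptake")

  participate <- if (arm == "screening") 1 - avoid else 0

  # per-carrier identification probability
  p_ident <- if (arm == "screening") {
    participate * sens + (participate * (1 - sens) + (1 - participate)) * fh
  } else {
    fh
  }

  rows <- list()
  add <- function(gene, identified, surveillance, mass) {
    if (mass > 0) {
      rows[[length(rows) + 1]] <<- data.frame(
        gene = gene, identified = identified, surveillance = surveillance,
        mass = mass, stringsAsFactors = FALSE)
    }
  }
  for (g in names(gp)) {
    m <- prev * gp[[g]]
    add(g, TRUE, "mammo_mri", m * p_ident * mri)
    add(g, TRUE, "mammo_only", m * p_ident * (1 - mri))
    add(g, FALSE, "mammo_only", m * (1 - p_ident))
  }
  add("noncarrier", FALSE, "mammo_only", 1 - prev)
  masses <- do.call(rbind, rows)
  if (abs(sum(masses$mass) - 1) > 1e-9) {
    stop("allocation error: subgroup masses do not sum to 1")
  }

  assays <- participate                       # all participants are assayed
  true_pos <- prev * participate * sens
  false_pos <- (1 - prev) * participate * (1 - spec)
  confirmations <- true_pos + false_pos
  identified <- prev * p_ident

  structure(list(
    arm = arm,
    masses = masses,
    assays = assays,
    confirmations = confirmations,
    false_positives = false_pos,
    identified = identified,
    upfront_cost = assays * param_value(params, "cost_assay") +
      confirmations * param_value(params, "cost_confirmation"),
    upfront_disutility = identified * param_value(params, "disutil_knowledge")
  ), class = "hboc_allocation")
}

#' @export
print.hboc_allocation <- function(x, ...) {
  cat(sprintf("Cohort allocation, %s arm\n", x$arm))
  cat(sprintf("  identified carriers: %.6f of cohort; upfront cost $%.2f/woman\n",
              x$identified, x$upfront_cost))
  cat(sprintf("  subgroups: %d (mass sums to %.9f)\n",
              nrow(x$masses), sum(x$masses$mass)))
  invisible(x)
}
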