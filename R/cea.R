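#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost Incremental cost (any consistent scale).
#' @param delta_qaly Incremental QALYs (same scale).
#' @return An object of class `hboc_icer`: list with `value` (the ratio, or
#'   `NA` under dominance) and `status`, one of `"ratio"` (more costly, more
#'   effective), `"ratio_sw"` (less costly, less effective: the ratio is the
#'   comparator's value per QALY forgone), `"dominant"`, `"dominated"`,
#'   `"undefined"` (both increments zero). A strategy with zero QALY gain at
#'   positive extra cost is classed dominated by convention.
#' @export
#' @examples
#' compute_icer(240, 0.0026)   # 92307.7
compute_icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (delta_cost == 0 && delta_qaly == 0) {
    res <- list(value = NA_real_, status = "undefined")
  } else if (delta_qaly > 0 && delta_cost > 0) {
    res <- list(value = delta_cost / delta_qaly, status = "ratio")
  } else if (delta_cost <= 0 && delta_qaly >= 0) {
    res <- list(value = NA_real_, status = "dominant")
  } else if (delta_qaly <= 0 && delta_cost >= 0) {
    res <- list(value = NA_real_, status = "dominated")
  } else {
    res <- list(value = delta_cost / delta_qaly, status = "ratio_sw")
  }
  structure(res, class = "hboc_icer")
}

#' @export
print.hboc_icer <- function(x, ...) {
  if (x$status %in% c("ratio", "ratio_sw")) {
    cat(sprintf("ICER: $%s per QALY (%s)\n",
                format(round(x$value, 1), big.mark = ","), x$status))
  } else {
    cat(sprintf("ICER: %s\n", x$status))
  }
  invisible(x)
}

#' One-time QALY decrement for the noncarrier-harm scenario
#'
#' Screened noncarriers who receive a negative result may reduce adherence
#' to recommended mammography; this is modelled as a one-time disutility
#' applied to a fraction of screened noncarriers:
#' `cohort x participation x (1 - prevalence) x harm_affected_fraction x
#' harm_disutility`. Under the lifetime-annual reading
#' (`settings$harm_one_time: false`) the disutility instead accrues every
#' remaining life-year, scaled by `lifetime_ly`.
#'
#' @param params `hboc_params`.
#' @param cohort Cohort size (default 100000).
#' @param lifetime_ly Discounted life expectancy used only by the
#'   lifetime-annual reading.
#' @return QALY decrement on the cohort scale.
#' @export
harm_qaly_decrement <- function(params, cohort = 1e5, lifetime_ly = NULL) {
  base <- cohort * (1 - param_value(params, "avoid_screening")) *
    (1 - param_value(params, "carrier_prevalence")) *
    param_value(params, "harm_affected_fraction") *
    param_value(params, "disutil_noncarrier_harm")
  if (isTRUE(model_setting(params, "harm_one_time"))) {
    base
  } else {
    if (is.null(lifetime_ly)) {
      stop("lifetime-annual harm reading requires lifetime_ly")
    }
    base * lifetime_ly
  }
}

#' Incremental summary of two strategy outcome bundles
#'
#' @param screening,family_history Per-woman `outcome_bundle`s for the two
#'   arms (same cohort).
#' @param cohort_size Cohort size used for the per-100000 scale.
#' @return An object of class `hboc_ce_result`: per-arm per-woman values,
#'   incremental results on the cohort scale (named vector with `cost`,
#'   `qaly`, `ly`, `cases_early`, `cases_late`, `cases_total`), per-woman
#'   incrementals, and the ICER.
#' @export
summarize_per_100k <- function(screening, family_history, cohort_size = 1e5) {
  stopifnot(cohort_size > 0)
  d <- function(f) screening[[f]] - family_history[[f]]
  incr <- c(cost = d("disc_cost"), qaly = d("disc_qaly"), ly = d("disc_ly"),
            cases_early = d("cases_early"), cases_late = d("cases_late"),
            cases_total = d("cases_total")) * cohort_size
  per_arm <- data.frame(
    arm = c("screening", "family_history"),
    cost_per_woman = c(screening$disc_cost, family_history$disc_cost),
    qaly_per_woman = c(screening$disc_qaly, family_history$disc_qaly),
    ly_per_woman = c(screening$disc_ly, family_history$disc_ly),
    cases_early_per_100k = c(screening$cases_early, family_history$cases_early) * cohort_size,
    cases_late_per_100k = c(screening$cases_late, family_history$cases_late) * cohort_size,
    cases_total_per_100k = c(screening$cases_total, family_history$cases_total) * cohort_size
  )
  structure(list(
    per_arm = per_arm,
    incremental = incr,
    incr_cost_per_woman = incr[["cost"]] / cohort_size,
    incr_qaly_per_woman = incr[["qaly"]] / cohort_size,
    cohort_size = cohort_size,
    icer = compute_icer(incr[["cost"]], incr[["qaly"]])
  ), class = "hboc_ce_result")
}

# identified-carrier mass per gene from an allocation
.identified_by_gene <- function(alloc) {
  m <- alloc$masses
  out <- stats::setNames(numeric(length(GENES)), GENES)
  sel <- m$identified
  if (any(sel)) {
    agg <- tapply(m$mass[sel], m$gene[sel], sum)
    out[names(agg)] <- agg
  }
  out
}

#' Cost-effectiveness of population genomic screening at one entry age
#'
#' Top-level model run: allocates the entering cohort of women of one age
#' across Markov subgroups for the screening and family history-based
#' testing arms, runs every subgroup to the lifetime horizon (age 100),
#' accrues discounted costs, QALYs and life-years and undiscounted cancer
#' case counts, optionally adds the cascade-testing increment generated by
#' the carriers screening identifies beyond family history, optionally
#' applies the noncarrier-harm scenario, and computes incremental results
#' and the ICER.
#'
#' @param age Entry age of the cohort (within the curve grid, 20-99).
#' @param params `hboc_params` parameter set; default packaged base case.
#' @param inputs `hboc_inputs` curve bundle; default synthetic curves.
#' @param cohort Cohort size for per-100000 reporting.
#' @param cascade Include the cascade-testing module?
#' @param harm Apply the noncarrier-harm scenario?
#' @return An object of class `hboc_cea`.
#' @export
#' @examples
#' \donttest{
#' res <- screen_cea(30)
#' print(res)
#' }
screen_cea <- function(age, params = hboc_parameters(),
                       inputs = default_inputs(), cohort = 1e5,
                       cascade = TRUE, harm = FALSE) {
  alloc_s <- allocate_cohort("screening", params)
  alloc_f <- allocate_cohort("family_history", params)

  # subgroup traces are arm-independent; compute each unique subgroup once
  ctx <- .model_context(params, inputs)
  sg_bundle <- function(g, id, sv) .subgroup_bundle(ctx, age, g, id, sv)
  arm_bundle <- function(alloc) {
    m <- alloc$masses
    bundles <- lapply(seq_len(nrow(m)), function(i) {
      sg_bundle(m$gene[i], m$identified[i], m$surveillance[i])
    })
    b <- bundle_combine(bundles, m$mass)
    b$disc_cost <- b$disc_cost + alloc$upfront_cost
    b$disc_qaly <- b$disc_qaly - alloc$upfront_disutility
    b
  }
  b_s <- arm_bundle(alloc_s)
  b_f <- arm_bundle(alloc_f)
  base_res <- summarize_per_100k(b_s, b_f, cohort)
  base_incr <- base_res$incremental

  cascade_incr <- NULL
  casc <- NULL
  if (cascade) {
    extra_ident <- .identified_by_gene(alloc_s) - .identified_by_gene(alloc_f)
    casc <- run_cascade(extra_ident, age, params, inputs, ctx = ctx)
    cascade_incr <- c(cost = casc$deltas[["cost"]],
                      qaly = casc$deltas[["qaly"]],
                      ly = casc$deltas[["ly"]],
                      cases_early = casc$deltas[["cases_early"]],
                      cases_late = casc$deltas[["cases_late"]],
                      cases_total = casc$deltas[["cases_total"]]) * cohort
  }
  combined <- if (is.null(cascade_incr)) base_incr else {
    combine_outcomes(base_incr, cascade_incr)
  }

  harm_decrement <- 0
  if (harm) {
    harm_decrement <- harm_qaly_decrement(params, cohort,
                                          lifetime_ly = b_s$disc_ly)
    combined[["qaly"]] <- combined[["qaly"]] - harm_decrement
  }

  structure(list(
    age = age, cohort = cohort,
    cascade = cascade, harm = harm,
    allocations = list(screening = alloc_s, family_history = alloc_f),
    arms = list(screening = b_s, family_history = b_f),
    base = base_res,
    base_incremental = base_incr,
    cascade_increment = casc,
    cascade_incremental = cascade_incr,
    harm_decrement = harm_decrement,
    incremental = combined,
    icer = compute_icer(combined[["cost"]], combined[["qaly"]]),
    icer_no_cascade = base_res$icer
  ), class = "hboc_cea")
}

#' Re-derive a model result under the noncarrier-harm scenario
#'
#' Subtracts the one-time noncarrier QALY decrement from the screening arm
#' of an existing [screen_cea()] result and recomputes the ICER, without
#' re-running the Markov engine.
#'
#' @param result An `hboc_cea` object.
#' @param params `hboc_params` (supplies the harm parameters).
#' @return A new `hboc_cea` object with `harm = TRUE`.
#' @export
apply_harm_scenario <- function(result, params) {
  stopifnot(inherits(result, "hboc_cea"))
  dec <- harm_qaly_decrement(params, result$cohort,
                             lifetime_ly = result$arms$screening$disc_ly)
  result$harm <- TRUE
  result$harm_decrement <- dec
  result$incremental[["qaly"]] <- result$incremental[["qaly"]] - dec
  result$icer <- compute_icer(result$incremental[["cost"]],
                              result$incremental[["qaly"]])
  result
}

#' ICER across a range of screening entry ages
#'
#' @param ages Integer ages to evaluate.
#' @param ... Passed to [screen_cea()].
#' @return Data frame with `age`, `icer`, `status`, `incr_cost`,
#'   `incr_qaly`, `cases_prevented` (cohort scale).
#' @export
sweep_ages <- function(ages, ...) {
  rows <- lapply(ages, function(a) {
    r <- screen_cea(a, ...)
    data.frame(age = a, icer = r$icer$value, status = r$icer$status,
               incr_cost = r$incremental[["cost"]],
               incr_qaly = r$incremental[["qaly"]],
               cases_prevented = -r$incremental[["cases_total"]])
  })
  do.call(rbind, rows)
}

#' @export
print.hboc_cea <- function(x, ...) {
  cat(sprintf("Population genomic screening vs family history-based testing, age %d\n",
              x$age))
  cat(sprintf("  scenario: cascade %s, noncarrier harm %s; cohort %s women\n",
              if (x$cascade) "on" else "off",
              if (x$harm) "on" else "off",
              format(x$cohort, big.mark = ",")))
  i <- x$incremental
  cat(sprintf("  incremental cost:  $%s per cohort ($%.0f per woman)\n",
              format(round(i[["cost"]]), big.mark = ","),
              i[["cost"]] / x$cohort))
  cat(sprintf("  incremental QALYs: %.1f per cohort (%.5f per woman)\n",
              i[["qaly"]], i[["qaly"]] / x$cohort))
  cat(sprintf("  cancer cases per %s: %+.1f early, %+.1f late, %+.1f total\n",
              format(x$cohort, big.mark = ","), i[["cases_early"]],
              i[["cases_late"]], i[["cases_total"]]))
  if (x$harm) {
    cat(sprintf("  noncarrier-harm QALY decrement: %.1f\n", x$harm_decrement))
  }
  print(x$icer)
  invisible(x)
}

#' @export
summary.hboc_cea <- function(object, ...) {
  x <- object
  per_arm <- x$base$per_arm
  cat(sprintf("Strategy outcomes at entry age %d (per woman; cases per %s)\n",
              x$age, format(x$cohort, big.mark = ",")))
  print(per_arm, row.names = FALSE, digits = 6)
  cat("\nIncremental (cohort scale):\n")
  print(round(x$base_incremental, 2))
  if (!is.null(x$cascade_incremental)) {
    cat("Cascade increment (cohort scale):\n")
    print(round(x$cascade_incremental, 2))
    cat("Combined:\n")
    print(round(x$incremental, 2))
  }
  print(x$icer)
  invisible(x)
}
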