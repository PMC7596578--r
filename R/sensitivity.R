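#' Model-runner closure for sensitivity analyses
#'
#' Wraps [screen_cea()] so sensitivity routines can re-evaluate the model on
#' perturbed or sampled parameter sets. The returned function maps an
#' `hboc_params` object to the named incremental-result vector on the
#' cohort scale (`cost`, `qaly`, `ly`, `cases_early`, `cases_late`,
#' `cases_total`).
#'
#' @param age Entry age.
#' @param inputs `hboc_inputs`.
#' @param cohort Cohort size.
#' @param cascade,harm Scenario switches, as in [screen_cea()].
#' @return A function of one `hboc_params` argument.
#' @export
cea_runner <- function(age, inputs = default_inputs(), cohort = 1e5,
                       cascade = TRUE, harm = FALSE) {
  force(age); force(inputs); force(cohort); force(cascade); force(harm)
  function(params) {
    screen_cea(age, params, inputs, cohort, cascade = cascade,
               harm = harm)$incremental
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the model with each parameter at its low and then its high
#' bound, all other parameters held at base values, and reports the ICER at
#' both bounds sorted by bar width.
#'
#' @param params Base `hboc_params`.
#' @param param_ids Parameter ids to vary; default: every parameter whose
#'   low and high bounds differ.
#' @param runner A model runner, e.g. from [cea_runner()].
#' @return Data frame of class `hboc_tornado`: `param`, `icer_low`,
#'   `icer_high`, `status_low`, `status_high`, `width`, sorted by
#'   decreasing `width`. Dominance flags yield `NA` ratios; their width uses
#'   the available finite values only.
#' @export
run_one_way <- function(params, param_ids = NULL, runner) {
  if (is.null(param_ids)) {
    param_ids <- names(params$registry)[vapply(params$registry, function(e) {
      e$dist != "fixed" && e$low < e$high
    }, logical(1))]
  }
  unknown <- setdiff(param_ids, names(params$registry))
  if (length(unknown)) {
    stop(sprintf("unknown parameter id(s): %s", paste(unknown, collapse = ", ")))
  }
  one <- function(id, bound) {
    r <- runner(perturb_one_way(params, id, bound))
    compute_icer(r[["cost"]], r[["qaly"]])
  }
  rows <- lapply(param_ids, function(id) {
    lo <- one(id, "low")
    hi <- one(id, "high")
    vals <- c(lo$value, hi$value)
    width <- if (all(is.na(vals))) 0 else diff(range(vals, na.rm = TRUE))
    data.frame(param = id, icer_low = lo$value, icer_high = hi$value,
               status_low = lo$status, status_high = hi$status,
               width = width, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  class(out) <- c("hboc_tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets via [draw_psa_sample()] and runs each through
#' the model. Per-draw RNG substreams are derived from the master seed by a
#' counter (the first k draws of an n-draw run equal a k-draw run with the
#' same seed), so results do not depend on evaluation order. Draws on which
#' the model fails are excluded and counted, never silently dropped.
#'
#' @param params Base `hboc_params`.
#' @param n Number of draws.
#' @param seed Master seed (integer).
#' @param runner A model runner, e.g. from [cea_runner()].
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve;
#'   default the conventional $50,000 / $100,000 / $150,000 thresholds plus
#'   a fine grid to $250,000.
#' @return An object of class `hboc_psa`: `draws` (data frame of per-draw
#'   incrementals), `ceac` (data frame `wtp`, `prob_ce`), `credible`
#'   (2.5/97.5 percentile matrix), `n_failed`, `failed_draws`, `seed`.
#' @export
run_psa <- function(params, n, seed, runner,
                    wtp_grid = sort(unique(c(seq(0, 250000, by = 10000),
                                             50000, 100000, 150000)))) {
  stopifnot(n >= 1)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, n)
  rows <- vector("list", n)
  failed <- integer(0)
  for (i in seq_len(n)) {
    set.seed(substreams[i])
    res <- tryCatch({
      ps_i <- draw_psa_sample(params)
      runner(ps_i)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
    } else {
      rows[[i]] <- res
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  draws <- as.data.frame(do.call(rbind, rows[ok]))
  if (length(failed)) {
    warning(sprintf("PSA: %d of %d draws failed and were excluded", length(failed), n))
  }
  cred <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = TRUE)
  structure(list(
    draws = draws,
    ceac = compute_ceac(draws, wtp_grid),
    credible = cred,
    n = n, n_failed = length(failed), failed_draws = failed,
    seed = seed
  ), class = "hboc_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of draws with
#' nonnegative incremental net monetary benefit:
#' `lambda * delta_QALY - delta_cost >= 0`.
#'
#' @param draws Data frame with columns `cost` and `qaly` (incrementals).
#' @param wtp_grid Nonnegative willingness-to-pay values.
#' @return Data frame with columns `wtp`, `prob_ce`.
#' @export
compute_ceac <- function(draws, wtp_grid) {
  stopifnot(nrow(draws) >= 1, all(wtp_grid >= 0))
  prob <- vapply(wtp_grid, function(l) {
    mean(l * draws$qaly - draws$cost >= 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_ce = prob)
}

#' @export
print.hboc_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (%d failed), seed %d\n",
              x$n, x$n_failed, x$seed))
  cat("95% credible ranges:\n")
  print(signif(x$credible, 4))
  for (l in c(50000, 100000, 150000)) {
    row <- x$ceac[x$ceac$wtp == l, ]
    if (nrow(row)) {
      cat(sprintf("  P(cost-effective at $%s/QALY) = %.2f\n",
                  format(l, big.mark = ","), row$prob_ce))
    }
  }
  invisible(x)
}

#' @export
plot.hboc_psa <- function(x, ...) {
  graphics::plot(x$ceac$wtp / 1000, x$ceac$prob_ce, type = "l", lwd = 2,
                 xlab = "Willingness to pay ($1000 per QALY)",
                 ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::abline(v = c(50, 100, 150), lty = 3, col = "grey50")
  invisible(x)
}
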