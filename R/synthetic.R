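#' Synthetic Gompertz-Makeham life table
#'
#' Parametric stand-in for a national period life table:
#' `qx(a) = 1 - exp(-(c + b * exp(g * a)))`, with the terminal age forced to
#' qx = 1. Deterministic (no RNG), so written files are stable.
#'
#' @param c Makeham (age-independent) hazard component.
#' @param b Gompertz baseline hazard.
#' @param g Gompertz log-slope per year of age.
#' @param ages Integer age grid; default 0:100.
#' @return A `life_table`.
#' @export
#' @examples
#' lt <- make_life_table()
#' plot(lt$ages, lt$qx, type = "l", log = "y")
make_life_table <- function(c = 5e-4, b = 3e-5, g = 0.095, ages = 0:100) {
  stopifnot(c >= 0, b >= 0)
  qx <- 1 - exp(-(c + b * exp(g * ages)))
  qx[length(qx)] <- 1
  life_table(ages, qx)
}

#' Synthetic logistic cumulative curve
#'
#' Generates a monotone cumulative incidence or surgery-uptake curve with a
#' logistic shape: zero at the start age, rising to `lifetime_level` at age
#' 80 and flat thereafter. The shape is controlled by the age of the
#' half-level (`midpoint`) and a steepness per year. These are structural
#' stand-ins for externally digitized curves, not published values; see the
#' methods vignette for the defaults chosen per curve.
#'
#' @param lifetime_level Cumulative value reached at age 80, in [0, 1].
#' @param midpoint Age at which half the lifetime level is reached.
#' @param steepness Logistic slope per year (larger = more concentrated).
#' @param ages Integer age grid; default 20:100.
#' @param kind `"incidence"` or `"uptake"` (label only).
#' @param name Optional curve label.
#' @return A `curve_table`.
#' @export
make_cumulative_curve <- function(lifetime_level, midpoint, steepness = 0.12,
                                  ages = 20:100, kind = c("incidence", "uptake"),
                                  name = NULL) {
  kind <- match.arg(kind)
  stopifnot(lifetime_level >= 0, lifetime_level <= 1, steepness > 0)
  a0 <- min(ages)
  acap <- min(80, max(ages))
  sg <- function(a) stats::plogis(steepness * (a - midpoint))
  denom <- sg(acap) - sg(a0)
  vals <- if (lifetime_level == 0 || denom <= 0) {
    rep(0, length(ages))
  } else {
    lifetime_level * (sg(pmin(ages, acap)) - sg(a0)) / denom
  }
  curve_table(ages, vals, name = name %||% sprintf("synthetic_%s", kind))
}

#' Default synthetic model inputs
#'
#' Bundles every externally sourced curve the model needs: per-gene
#' cumulative breast/ovarian cancer incidence for BRCA1 and BRCA2 carriers,
#' general-population cumulative incidence (basis for odds-ratio-adjusted
#' non-BRCA risk and for noncarriers), cumulative RRM and RRSO uptake for
#' BRCA carriers, and a background life table. Lifetime levels and midpoints
#' are synthetic structural choices emulating the qualitative features the
#' analysis relies on: surgical uptake concentrated before age 50, cancer
#' incidence concentrated after age 50. They are NOT published values;
#' substitute digitized curves via the same interface to reproduce a
#' specific study.
#'
#' @return A named list of class `hboc_inputs` with elements `bc_BRCA1`,
#'   `bc_BRCA2`, `oc_BRCA1`, `oc_BRCA2`, `bc_general`, `oc_general`,
#'   `rrm_uptake`, `rrso_uptake` (each a `curve_table`) and `life`
#'   (a `life_table`).
#' @export
default_inputs <- function() {
  structure(list(
    bc_BRCA1   = make_cumulative_curve(0.72, 50, 0.11, name = "bc_BRCA1"),
    bc_BRCA2   = make_cumulative_curve(0.69, 52, 0.10, name = "bc_BRCA2"),
    oc_BRCA1   = make_cumulative_curve(0.44, 58, 0.11, name = "oc_BRCA1"),
    oc_BRCA2   = make_cumulative_curve(0.17, 62, 0.11, name = "oc_BRCA2"),
    bc_general = make_cumulative_curve(0.125, 62, 0.09, name = "bc_general"),
    oc_general = make_cumulative_curve(0.013, 63, 0.09, name = "oc_general"),
    rrm_uptake  = make_cumulative_curve(0.45, 40, 0.15, kind = "uptake",
                                        name = "rrm_uptake"),
    rrso_uptake = make_cumulative_curve(0.75, 45, 0.15, kind = "uptake",
                                        name = "rrso_uptake"),
    life = make_life_table()
  ), class = "hboc_inputs")
}

#' Write a full synthetic input bundle as delimited text
#'
#' Emits one `age,value` CSV per curve plus an `age,qx` life table, in the
#' exact format [read_curve_table()] and [read_life_table()] consume.
#'
#' @param inputs An `hboc_inputs` bundle (default [default_inputs()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_inputs <- function(inputs = default_inputs(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in setdiff(names(inputs), "life")) {
    write_curve_table(inputs[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  utils::write.csv(data.frame(age = inputs$life$ages, qx = inputs$life$qx),
                   file.path(dir, "life_table.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a full input bundle from a directory written by [write_inputs()]
#' @param dir Directory holding the curve CSVs and `life_table.csv`.
#' @return An `hboc_inputs` bundle.
#' @export
read_inputs <- function(dir) {
  nms <- c("bc_BRCA1", "bc_BRCA2", "oc_BRCA1", "oc_BRCA2",
           "bc_general", "oc_general", "rrm_uptake", "rrso_uptake")
  out <- lapply(nms, function(nm) {
    read_curve_table(file.path(dir, paste0(nm, ".csv")), name = nm)
  })
  names(out) <- nms
  out$life <- read_life_table(file.path(dir, "life_table.csv"))
  structure(out, class = "hboc_inputs")
}

#' Frozen toy state-transition model
#'
#' A deterministic three-state model (well, cancer, dead) with hand-set
#' annual probabilities, state costs and utilities, a one-time cost attached
#' to the well-to-cancer transition and a palliative cost attached to the
#' cancer-to-dead transition. Used as the fixture for the engine-vs-
#' microsimulation oracle and for tornado-diagram tests; small enough that
#' its discounted outcomes have simple closed forms.
#'
#' @return A list with elements `states`, `P` (3x3 transition matrix),
#'   `init`, `state_cost`, `state_util`, `trans_cost` (3x3), `rate`,
#'   `cycles`.
#' @export
make_toy_model <- function() {
  states <- c("well", "cancer", "dead")
  P <- matrix(c(
    0.93, 0.05, 0.02,
    0.00, 0.80, 0.20,
    0.00, 0.00, 1.00
  ), nrow = 3, byrow = TRUE, dimnames = list(states, states))
  trans_cost <- matrix(0, 3, 3, dimnames = list(states, states))
  trans_cost["well", "cancer"] <- 20000   # diagnosis work-up, one time
  trans_cost["cancer", "dead"] <- 15000   # last-year palliative care
  list(
    states = states,
    P = P,
    init = c(well = 1, cancer = 0, dead = 0),
    state_cost = c(well = 100, cancer = 5000, dead = 0),
    state_util = c(well = 1, cancer = 0.7, dead = 0),
    trans_cost = trans_cost,
    rate = 0.03,
    cycles = 40
  )
}
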