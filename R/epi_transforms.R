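#' Age-indexed cumulative curve
#'
#' Container for a cumulative incidence or cumulative surgery-uptake curve
#' F(a) on a contiguous integer age grid. Values must be nondecreasing and
#' lie in [0, 1]. Inputs on a coarser grid are linearly interpolated to
#' single years of age.
#'
#' @param ages Integer ages (need not be contiguous; interpolated if not).
#' @param values Cumulative probabilities at `ages`.
#' @param name Optional curve label.
#' @return An object of class `curve_table` with elements `ages`, `values`.
#' @export
curve_table <- function(ages, values, name = NULL) {
  stopifnot(length(ages) == length(values), length(ages) >= 2)
  if (any(diff(ages) <= 0)) stop("curve error: ages must be strictly increasing")
  if (any(values < -1e-12 | values > 1 + 1e-12)) {
    stop("curve error: cumulative values outside [0,1]")
  }
  if (any(diff(values) < -1e-12)) {
    stop("curve error: cumulative values must be nondecreasing")
  }
  grid <- seq(min(ages), max(ages))
  vals <- stats::approx(ages, values, xout = grid, method = "linear")$y
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(ages = grid, values = vals, name = name), class = "curve_table")
}

#' Read a cumulative curve from a delimited text file
#'
#' Expects a header and two columns, `age` and `value`.
#' @param path File path.
#' @param name Optional label (defaults to the file name).
#' @return A `curve_table`.
#' @export
read_curve_table <- function(path, name = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("age", "value") %in% names(d))) {
    stop("curve file must have columns 'age' and 'value'")
  }
  curve_table(d$age, d$value, name = name)
}

#' Write a cumulative curve as delimited text
#' @param curve A `curve_table`.
#' @param path Output path.
#' @export
write_curve_table <- function(curve, path) {
  utils::write.csv(data.frame(age = curve$ages, value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

# F(a) with range checking
curve_value <- function(curve, age) {
  i <- match(age, curve$ages)
  if (is.na(i)) stop(sprintf("age %s outside curve range [%d, %d]",
                             age, min(curve$ages), max(curve$ages)))
  curve$values[i]
}

#' Life table of annual death probabilities
#'
#' @param ages Integer ages.
#' @param qx Annual all-cause death probability at each age; the terminal
#'   age must have qx = 1 so the cohort closes out.
#' @return An object of class `life_table`.
#' @export
life_table <- function(ages, qx) {
  stopifnot(length(ages) == length(qx))
  if (any(qx < 0 | qx > 1)) stop("life table error: qx outside [0,1]")
  if (qx[length(qx)] != 1) stop("life table error: terminal qx must be 1")
  structure(list(ages = ages, qx = qx), class = "life_table")
}

#' Read a life table from delimited text (columns `age`, `qx`)
#' @param path File path.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d))) {
    stop("life table file must have columns 'age' and 'qx'")
  }
  life_table(d$age, d$qx)
}

lt_qx <- function(lt, age) {
  i <- match(age, lt$ages)
  if (is.na(i)) {
    if (age > max(lt$ages)) return(1)
    stop(sprintf("age %s below life table range", age))
  }
  lt$qx[i]
}

# survival from age a0 to age a1 (product of 1-qx), conditional on alive at a0
lt_survival <- function(lt, a0, a1) {
  if (a1 <= a0) return(1)
  idx <- which(lt$ages >= a0 & lt$ages < a1)
  prod(1 - lt$qx[idx])
}

#' Annual event probability from a cumulative curve
#'
#' Conditional one-year event probability among those still event-free at
#' `age`: `(F(age+1) - F(age)) / (1 - F(age))`.
#'
#' @param curve A `curve_table` of cumulative probabilities.
#' @param age Integer age; both `age` and `age + 1` must be on the grid.
#' @return One-year conditional probability in [0, 1].
#' @export
#' @examples
#' cv <- curve_table(20:22, c(0, 0.20, 0.28))
#' annual_prob_from_cumulative(cv, 21)  # (0.28-0.20)/(1-0.20) = 0.1
annual_prob_from_cumulative <- function(curve, age) {
  f0 <- curve_value(curve, age)
  f1 <- curve_value(curve, age + 1)
  if (f0 >= 1) stop("degenerate population: cumulative probability already 1")
  p <- (f1 - f0) / (1 - f0)
  min(max(p, 0), 1)
}

#' Convert between a one-year probability and the equivalent constant rate
#'
#' `prob_to_rate` returns -log(1 - p); `rate_to_prob` its inverse
#' 1 - exp(-r). The pair round-trips exactly and underlies hazard-ratio
#' application on the rate scale.
#'
#' @param p Probability in [0, 1).
#' @param r Nonnegative rate (per year).
#' @return Rate, or probability.
#' @export
prob_to_rate <- function(p) {
  if (any(p < 0 | p >= 1)) stop("prob_to_rate requires p in [0,1)")
  -log1p(-p)
}

#' @rdname prob_to_rate
#' @export
rate_to_prob <- function(r) {
  if (any(r < 0)) stop("rate_to_prob requires r >= 0")
  -expm1(-r)
}

#' Apply a hazard ratio to an annual probability
#'
#' Multiplies on the rate scale: returns `1 - (1 - p)^hr`, so hr = 0 removes
#' all risk and hr = 1 leaves the probability unchanged.
#'
#' @param p Annual probability in [0, 1).
#' @param hr Hazard ratio, >= 0.
#' @return Adjusted annual probability.
#' @export
apply_hazard_ratio <- function(p, hr) {
  if (any(hr < 0)) stop("hazard ratio must be >= 0")
  if (any(p < 0 | p >= 1)) stop("apply_hazard_ratio requires p in [0,1)")
  -expm1(hr * log1p(-p))
}

#' Apply an odds ratio to a baseline annual probability
#'
#' Exact odds-scale adjustment: odds are multiplied by `or_val` and mapped
#' back, keeping the result in [0, 1) even for large odds ratios.
#'
#' @param p0 Baseline annual probability in [0, 1).
#' @param or_val Odds ratio, > 0.
#' @return Adjusted probability.
#' @export
apply_odds_ratio <- function(p0, or_val) {
  if (any(or_val <= 0)) stop("odds ratio must be > 0")
  if (any(p0 < 0 | p0 >= 1)) stop("apply_odds_ratio requires p0 in [0,1)")
  odds <- or_val * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Annual excess death probability from 5-year relative mortality
#'
#' Constant annual cancer-specific excess death probability whose 5-year
#' cumulative equals the input: `1 - (1 - m5)^(1/5)`. The engine adds it to
#' background mortality (additive competing risks, capped at 1).
#'
#' @param five_yr_rel_mortality 5-year relative mortality in [0, 1).
#' @return Annual excess probability.
#' @export
annual_excess_mortality <- function(five_yr_rel_mortality) {
  if (any(five_yr_rel_mortality < 0 | five_yr_rel_mortality >= 1)) {
    stop("5-year relative mortality must lie in [0,1)")
  }
  1 - (1 - five_yr_rel_mortality)^(1 / 5)
}

#' Discount factor for an annual cycle index
#'
#' @param year Cycle index (0 = no discounting).
#' @param rate Annual discount rate, default 0.03.
#' @return `(1 + rate)^(-year)`.
#' @export
discount_factor <- function(year, rate = 0.03) {
  stopifnot(all(year >= 0), rate >= 0)
  (1 + rate)^(-year)
}

#' Annual surgery-uptake probability from a cumulative uptake curve
#'
#' Conditional annual uptake among those who have not yet had the surgery,
#' rate-scaled by `rate_ratio` (e.g. 0.5 for non-BRCA carriers relative to
#' the combined BRCA uptake curve).
#'
#' @param curve Cumulative uptake `curve_table`.
#' @param age Integer age.
#' @param rate_ratio Uptake rate ratio, >= 0 (1 = the curve as given).
#' @return Annual uptake probability.
#' @export
annual_uptake_prob <- function(curve, age, rate_ratio = 1) {
  p <- annual_prob_from_cumulative(curve, age)
  if (rate_ratio == 1) return(p)
  apply_hazard_ratio(p, rate_ratio)
}
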