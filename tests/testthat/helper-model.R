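# Shared fixtures: loaded once per test run.
base_params <- hboc_parameters()
base_inputs <- default_inputs()

# set a parameter's current value, widening its bounds if needed so the
# object still validates (for constructing what-if parameter sets in tests)
set_param <- function(ps, name, value) {
  e <- ps$registry[[name]]
  stopifnot(!is.null(e))
  e$value <- value
  e$low <- min(e$low, value)
  e$high <- max(e$high, value)
  if (e$dist == "fixed") {
    e$low <- value
    e$high <- value
  }
  ps$registry[[name]] <- e
  ps
}

# life table with no mortality before a terminal age, for hand-computable
# cascade and survival checks
immortal_life_table <- function(terminal = 120) {
  life_table(0:terminal, c(rep(0, terminal), 1))
}

# Monte Carlo microsimulation of the frozen toy model; the independent
# oracle for the cohort-matrix engine. Per-person discounted outcomes with
# end-of-cycle accrual, matching accrue_trace() semantics.
simulate_toy <- function(toy, n, seed) {
  set.seed(seed)
  cp <- t(apply(toy$P, 1, cumsum))
  state <- rep(1L, n)
  disc_cost <- disc_qaly <- numeric(n)
  cases <- numeric(n)
  for (t in seq_len(toy$cycles)) {
    u <- stats::runif(n)
    nxt <- integer(n)
    for (s in seq_len(nrow(cp))) {
      idx <- state == s
      if (any(idx)) nxt[idx] <- findInterval(u[idx], cp[s, ]) + 1L
    }
    d <- (1 + toy$rate)^(-t)
    disc_cost <- disc_cost +
      d * (toy$state_cost[nxt] + toy$trans_cost[cbind(state, nxt)])
    disc_qaly <- disc_qaly + d * toy$state_util[nxt]
    cases <- cases + (state == 1L & nxt == 2L)
    state <- nxt
  }
  list(cost = disc_cost, qaly = disc_qaly, cases = cases)
}

# draw individual event ages from a cumulative incidence curve (event never
# happens with probability 1 - F(max age)); returns integer event ages with
# NA for no event. Oracle for the conditional annual probability transform.
sample_event_ages <- function(curve, n) {
  ages <- curve$ages
  pmass <- diff(c(0, curve$values))
  pnone <- 1 - curve$values[length(curve$values)]
  draw <- sample.int(length(ages) + 1L, n, replace = TRUE,
                     prob = c(pmass, pnone))
  out <- ages[draw]
  out[draw > length(ages)] <- NA
  out
}
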