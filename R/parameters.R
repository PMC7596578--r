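GENES <- c("BRCA1", "BRCA2", "ATM", "CHEK2", "MSH6", "PALB2", "RAD51C", "TP53")
AGE_BANDS <- c("lt45", "a45_54", "a55_64", "a65_74", "ge75")
DIST_FAMILIES <- c("beta", "dirichlet", "log_normal", "normal", "fixed")

# Parameter names holding proportions/probabilities, used for validation and
# for capping log-normal draws at 1.
.proportion_params <- function(nm) {
  grepl(paste0(
    "^(carrier_prevalence|gene_prop\\.|fh_identification|test_sensitivity|",
    "test_specificity|avoid_screening|mri_uptake|",
    "early_stage_mortality_reduction|rel_mort_|util_|disutil_|cascade_inform|",
    "cascade_test|harm_affected_fraction)"), nm)
}

.nonnegative_params <- function(nm) {
  grepl("^(cost_|or_|hr_|uptake_ratio|discount_rate)", nm)
}

#' Load a model parameter set from a configuration file
#'
#' Reads a YAML configuration holding every model parameter with its base
#' value, low/high bound and distribution family, plus structural settings
#' (stage-detection probabilities, cascade family assumptions, switches).
#' Values flagged `unit: percent` are stored on the printed percentage scale
#' in the file and converted to proportions at load (e.g. a carrier
#' prevalence written as 0.495 becomes 0.00495).
#'
#' @param path Path to a YAML configuration. Defaults to the packaged
#'   base-case configuration.
#' @return An object of class `hboc_params`: a validated parameter set.
#' @export
#' @examples
#' ps <- hboc_parameters()
#' param_value(ps, "carrier_prevalence")
load_parameter_set <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) {
    stop("config error: missing top-level 'parameters' block")
  }
  registry <- list()
  flatten <- function(node, prefix) {
    if (is.list(node) && !is.null(node$base)) {
      for (f in c("base", "low", "high", "dist")) {
        if (is.null(node[[f]])) {
          stop(sprintf("schema error: parameter '%s' is missing field '%s'",
                       prefix, f))
        }
      }
      if (!node$dist %in% DIST_FAMILIES) {
        stop(sprintf("schema error: parameter '%s' has unknown distribution '%s'",
                     prefix, node$dist))
      }
      scale <- if (identical(node$unit, "percent")) 0.01 else 1
      registry[[prefix]] <<- list(
        value = node$base * scale,
        low   = node$low * scale,
        high  = node$high * scale,
        dist  = node$dist
      )
    } else if (is.list(node)) {
      for (nm in names(node)) {
        flatten(node[[nm]], if (nzchar(prefix)) paste0(prefix, ".", nm) else nm)
      }
    } else {
      stop(sprintf("schema error: malformed entry at '%s'", prefix))
    }
  }
  flatten(doc$parameters, "")
  ps <- structure(
    list(registry = registry,
         settings = doc$settings %||% list()),
    class = "hboc_params"
  )
  validate_parameter_set(ps)
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged base-case parameter set
#'
#' Convenience wrapper loading the configuration shipped with the package.
#' @return An `hboc_params` object.
#' @export
hboc_parameters <- function() {
  load_parameter_set(system.file("extdata", "table1_base.yaml",
                                 package = "hbocScreen", mustWork = TRUE))
}

#' Validate a parameter set
#'
#' Checks bound ordering (low <= base <= high), proportion domains,
#' non-negativity of costs and ratios, the unit-sum constraint on the gene
#' proportions, and that fixed-family parameters have degenerate bounds.
#' Called automatically by [load_parameter_set()] and [perturb_one_way()].
#'
#' @param ps An `hboc_params` object.
#' @return `ps`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "hboc_params"))
  reg <- ps$registry
  for (nm in names(reg)) {
    e <- reg[[nm]]
    if (!(e$low <= e$value + 1e-12 && e$value <= e$high + 1e-12)) {
      stop(sprintf("validation error: '%s' violates low <= base <= high", nm))
    }
    if (.proportion_params(nm)) {
      if (e$value < 0 || e$value > 1) {
        stop(sprintf("validation error: proportion '%s' = %g outside [0,1]",
                     nm, e$value))
      }
    }
    if (.nonnegative_params(nm) && e$value < 0) {
      stop(sprintf("validation error: '%s' = %g must be >= 0", nm, e$value))
    }
    if (e$dist == "fixed" && !(e$low == e$value && e$high == e$value)) {
      stop(sprintf("validation error: fixed parameter '%s' has non-degenerate bounds", nm))
    }
  }
  gp <- param_block(ps, "gene_prop")
  if (length(gp) != length(GENES) || !setequal(names(gp), GENES)) {
    stop("validation error: gene_prop must cover exactly the modelled genes")
  }
  if (abs(sum(gp) - 1) > 1e-9) {
    stop(sprintf("validation error: gene proportions sum to %.10f, not 1", sum(gp)))
  }
  invisible(ps)
}

#' Look up a parameter value
#'
#' @param ps An `hboc_params` object.
#' @param name Flat parameter id, e.g. `"cost_assay"` or `"gene_prop.BRCA1"`.
#' @return The current (possibly perturbed or sampled) numeric value.
#' @export
param_value <- function(ps, name) {
  e <- ps$registry[[name]]
  if (is.null(e)) stop(sprintf("unknown parameter id '%s'", name))
  e$value
}

#' Values of a parameter block as a named vector
#'
#' @param ps An `hboc_params` object.
#' @param prefix Block prefix, e.g. `"gene_prop"` or `"or_bc"`.
#' @return Named numeric vector keyed by the suffix after the dot.
#' @export
param_block <- function(ps, prefix) {
  nms <- names(ps$registry)
  sel <- startsWith(nms, paste0(prefix, "."))
  vals <- vapply(ps$registry[sel], `[[`, numeric(1), "value")
  names(vals) <- sub(paste0("^", prefix, "\\."), "", nms[sel])
  vals
}

#' All parameter values as a flat named vector
#' @param ps An `hboc_params` object.
#' @return Named numeric vector over every parameter id.
#' @export
param_values <- function(ps) {
  vapply(ps$registry, `[[`, numeric(1), "value")
}

.set_param <- function(ps, name, value) {
  ps$registry[[name]]$value <- value
  ps
}

#' One-way perturbation of a single parameter
#'
#' Sets the named parameter to its low or high bound, leaving every other
#' parameter untouched, and re-validates. When a gene-proportion is
#' perturbed the remaining proportions are rescaled so the block still sums
#' to one (the joint Dirichlet constraint).
#'
#' @param ps An `hboc_params` object.
#' @param name Parameter id.
#' @param bound `"low"`, `"high"`, or `"base"` (restore the base value).
#' @return A new `hboc_params` object.
#' @export
perturb_one_way <- function(ps, name, bound = c("low", "high", "base")) {
  bound <- match.arg(bound)
  e <- ps$registry[[name]]
  if (is.null(e)) stop(sprintf("unknown parameter id '%s'", name))
  target <- switch(bound,
    low = e$low, high = e$high,
    base = (load_parameter_set_cache())$registry[[name]]$value)
  ps <- .set_param(ps, name, target)
  if (startsWith(name, "gene_prop.")) {
    gp <- param_block(ps, "gene_prop")
    this <- sub("^gene_prop\\.", "", name)
    others <- setdiff(names(gp), this)
    rest <- sum(gp[others])
    if (rest > 0) {
      scale <- (1 - gp[[this]]) / rest
      for (g in others) {
        ps <- .set_param(ps, paste0("gene_prop.", g), gp[[g]] * scale)
      }
    }
    # rescaling may push a proportion outside its printed bounds; only the
    # structural invariants are re-checked for the block
    for (g in names(gp)) {
      v <- param_value(ps, paste0("gene_prop.", g))
      ps$registry[[paste0("gene_prop.", g)]]$low <-
        min(ps$registry[[paste0("gene_prop.", g)]]$low, v)
      ps$registry[[paste0("gene_prop.", g)]]$high <-
        max(ps$registry[[paste0("gene_prop.", g)]]$high, v)
    }
  }
  validate_parameter_set(ps)
  ps
}

# memoised copy of the packaged base config, for bound = "base" restores
.param_cache_env <- new.env(parent = emptyenv())
load_parameter_set_cache <- function() {
  if (is.null(.param_cache_env$base)) {
    .param_cache_env$base <- hboc_parameters()
  }
  .param_cache_env$base
}

# Moment-matched Beta(a, b) with mean m and sd s; the sd is clamped below the
# feasibility limit sqrt(m (1-m)) so extreme printed ranges (e.g. test
# specificity 0.999 with a +/-20% band) keep the stated mean.
.beta_shapes <- function(m, s) {
  if (m <= 0 || m >= 1) return(NULL)
  smax <- sqrt(m * (1 - m))
  s <- min(s, 0.95 * smax)
  nu <- m * (1 - m) / s^2 - 1
  c(a = m * nu, b = (1 - m) * nu)
}

#' Draw one probabilistic-sensitivity-analysis parameter sample
#'
#' Every non-fixed parameter is drawn from its assigned family using the
#' current R random-number stream (seed with [set.seed()] for
#' reproducibility): Beta moment-matched to mean = base and
#' sd = (high - low) / (2 * 1.96); Normal with that same sd (truncated at 0
#' for costs); log-normal with median = base and
#' sdlog = (log high - log low) / (2 * 1.96), capped at 1 for proportions;
#' the eight gene proportions drawn jointly from a Dirichlet with
#' concentration `settings$dirichlet_concentration` times the base
#' proportions. Draw order is the registry order, so results are
#' deterministic given the seed.
#'
#' @param ps An `hboc_params` object.
#' @return A new `hboc_params` object holding the sampled values.
#' @export
#' @examples
#' set.seed(1); d1 <- draw_psa_sample(hboc_parameters())
#' set.seed(1); d2 <- draw_psa_sample(hboc_parameters())
#' identical(param_values(d1), param_values(d2))
draw_psa_sample <- function(ps) {
  reg <- ps$registry
  conc <- ps$settings$dirichlet_concentration %||% 100
  dirichlet_done <- FALSE
  for (nm in names(reg)) {
    e <- reg[[nm]]
    if (e$dist == "fixed" || e$low == e$high) next
    if (e$dist == "dirichlet") {
      if (!dirichlet_done) {
        gp <- param_block(ps, "gene_prop")
        alpha <- gp * conc
        g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
        draw <- g / sum(g)
        for (i in seq_along(gp)) {
          ps$registry[[paste0("gene_prop.", names(gp)[i])]]$value <- draw[i]
        }
        dirichlet_done <- TRUE
      }
      next
    }
    s <- (e$high - e$low) / (2 * stats::qnorm(0.975))
    v <- switch(e$dist,
      beta = {
        sh <- .beta_shapes(e$value, s)
        if (is.null(sh)) {
          stop(sprintf("configuration error: beta parameter '%s' has degenerate mean", nm))
        }
        stats::rbeta(1, sh[["a"]], sh[["b"]])
      },
      normal = max(0, stats::rnorm(1, e$value, s)),
      log_normal = {
        sdlog <- (log(e$high) - log(e$low)) / (2 * stats::qnorm(0.975))
        x <- stats::rlnorm(1, meanlog = log(e$value), sdlog = sdlog)
        # proportions are truncated at the boundary; strictly below 1 so
        # downstream probability transforms stay defined
        if (.proportion_params(nm)) min(x, 1 - 1e-9) else x
      },
      stop(sprintf("configuration error: no sampler for family '%s' (parameter '%s')",
                   e$dist, nm))
    )
    ps$registry[[nm]]$value <- v
  }
  ps
}

#' @export
print.hboc_params <- function(x, ...) {
  v <- param_values(x)
  cat(sprintf("HBOC model parameter set: %d parameters\n", length(v)))
  cat(sprintf("  carrier prevalence: %.5f; genes: %s\n",
              param_value(x, "carrier_prevalence"), paste(GENES, collapse = " ")))
  nfixed <- sum(vapply(x$registry, function(e) e$dist == "fixed", logical(1)))
  cat(sprintf("  distribution families: %d sampled, %d fixed\n",
              length(v) - nfixed, nfixed))
  invisible(x)
}

# Structural setting accessor with defaults shared across the engine.
model_setting <- function(ps, name) {
  defaults <- list(
    stage_early_mammo_mri = 0.8,
    stage_early_mammo = 0.5,
    stage_early_undetected = 0.5,
    stage_early_oc = 0.5,
    excess_mortality_persists = TRUE,
    early_stage_reading = "reduction",
    harm_one_time = TRUE,
    dirichlet_concentration = 100,
    cascade_assumptions = list(n_sisters = 1, n_daughters = 1, maternal_gap = 27)
  )
  ps$settings[[name]] %||% defaults[[name]]
}
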