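# Monte-Carlo machinery: i.i.d. normal measurement generation with
# per-replicate L'Ecuyer-CMRG streams, coverage estimation for the upper
# confidence limit, and operating characteristics of the fuzzy test.

#' Define a Monte-Carlo scenario
#'
#' A scenario fixes the true measurement distribution
#' \eqn{X \sim N(\mu, \sigma^2)}, the item specification, the per-sample
#' size, the number of replicates and the seed.  The true index
#' \eqn{PF = (U-\mu)/\sigma} or \eqn{(\mu-L)/\sigma} (by orientation) is
#' derived and stored.
#'
#' @param true_mu True mean of the measurement distribution.
#' @param true_sigma True standard deviation (> 0).
#' @param spec The item's [fitness_spec()].
#' @param n_per_sample Measurements per replicate sample (default 10).
#' @param n_replicates Number of Monte-Carlo replicates (default 10000).
#' @param seed Integer seed; fully determines all draws.
#' @return An object of class \code{"simulation_scenario"}.
#' @export
simulation_scenario <- function(true_mu, true_sigma, spec,
                                n_per_sample = 10, n_replicates = 10000,
                                seed = 1) {
  pf_check(inherits(spec, "fitness_spec"), "pf_parameter_error",
           "spec must be a fitness_spec")
  pf_check(is.numeric(true_sigma) && length(true_sigma) == 1L &&
             is.finite(true_sigma) && true_sigma > 0,
           "pf_parameter_error", "true_sigma must be > 0")
  pf_check(is.numeric(true_mu) && length(true_mu) == 1L && is.finite(true_mu),
           "pf_parameter_error", "true_mu must be finite")
  pf_check(n_per_sample >= 2 && n_per_sample == round(n_per_sample),
           "pf_parameter_error", "n_per_sample must be an integer >= 2")
  pf_check(n_replicates >= 1 && n_replicates == round(n_replicates),
           "pf_parameter_error", "n_replicates must be an integer >= 1")
  pf_check(is.numeric(seed) && length(seed) == 1L && is.finite(seed) &&
             seed == round(seed),
           "pf_parameter_error", "seed must be an integer")
  pf_true <- if (spec$orientation == "smaller_better")
    (spec$limit - true_mu) / true_sigma
  else
    (true_mu - spec$limit) / true_sigma
  structure(
    list(true_mu = true_mu, true_sigma = true_sigma, spec = spec,
         n_per_sample = as.integer(n_per_sample),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), pf_true = pf_true),
    class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': N(%g, %g^2), n = %d x %d replicates, seed %d, PF_true = %.3f\n",
    x$spec$item_id, x$true_mu, x$true_sigma, x$n_per_sample,
    x$n_replicates, x$seed, x$pf_true))
  invisible(x)
}

# One L'Ecuyer-CMRG stream per replicate, split from the scenario seed.
# Same seed -> same streams -> same draws, independent of execution order.
replicate_streams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_stream <- function(stream, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", stream, envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  expr
}

#' Generate synthetic measurement samples
#'
#' Draws \code{n_replicates} i.i.d. samples of \code{n_per_sample}
#' measurements from \eqn{N(\mu, \sigma^2)} and summarizes each with
#' [summarize_sample()].  Each replicate consumes its own RNG stream split
#' from the scenario seed, so results are reproducible replicate-by-replicate
#' regardless of execution order.
#'
#' @param scenario A [simulation_scenario()].
#' @return List of \code{"measurement_sample"} objects, length
#'   \code{n_replicates}.
#' @export
generate_measurements <- function(scenario) {
  pf_check(inherits(scenario, "simulation_scenario"), "pf_parameter_error",
           "scenario must be a simulation_scenario")
  streams <- replicate_streams(scenario$seed, scenario$n_replicates)
  lapply(seq_len(scenario$n_replicates), function(i) {
    values <- with_stream(streams[[i]],
      stats::rnorm(scenario$n_per_sample, scenario$true_mu,
                   scenario$true_sigma))
    summarize_sample(values,
                     sprintf("%s_rep%04d", scenario$spec$item_id, i))
  })
}

#' Estimate coverage and fuzzy-test operating characteristics
#'
#' Runs the full public pipeline — [summarize_sample()],
#' [estimate_index()], [upper_confidence_limit()], [build_fuzzy_index()],
#' [fuzzy_test()] — on every replicate of a scenario and tabulates:
#' the empirical coverage of the upper confidence limit (fraction of
#' replicates with \eqn{PF_{true} \le U_{PF}}), the rates of the three fuzzy
#' outcomes at the scenario's \eqn{k}, and the mean \eqn{d_R/d_T} ratio.
#' Because the limit combines its two pieces through Boole's inequality, the
#' empirical coverage should sit at or above \eqn{1-\alpha}.
#'
#' Replicates with zero sample standard deviation (probability ~0 for
#' continuous data) are counted in \code{n_degenerate}, excluded from the
#' rates with a warning, and never silently dropped.
#'
#' @param scenario A [simulation_scenario()].
#' @return An object of class \code{"operating_characteristics"} with fields
#'   \code{pf_true}, \code{coverage}, \code{outcome_rates} (named proportions
#'   summing to 1), \code{mean_ratio}, \code{n_effective},
#'   \code{n_degenerate}, and the scenario parameters.
#' @export
estimate_coverage <- function(scenario) {
  pf_check(inherits(scenario, "simulation_scenario"), "pf_parameter_error",
           "scenario must be a simulation_scenario")
  samples <- generate_measurements(scenario)
  oc_from_samples(samples, scenario$spec, scenario$pf_true,
                  n_per_sample = scenario$n_per_sample,
                  seed = scenario$seed)
}

# pipeline over an explicit sample list; split out so degenerate handling
# can be exercised with constructed samples
oc_from_samples <- function(samples, spec, pf_true, n_per_sample = NA_integer_,
                            seed = NA_integer_) {
  nrep <- length(samples)
  covered <- logical(nrep)
  outcomes <- character(nrep)
  ratios <- numeric(nrep)
  keep <- logical(nrep)
  n_degenerate <- 0L
  for (i in seq_len(nrep)) {
    sm <- samples[[i]]
    est <- tryCatch(estimate_index(sm, spec), pf_degenerate_sample =
                      function(e) NULL)
    if (is.null(est)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    ucl <- upper_confidence_limit(est$pf_star, est$n, spec$alpha)
    fz <- build_fuzzy_index(est, alpha = spec$alpha)
    dec <- fuzzy_test(fz, spec)
    covered[i] <- pf_true <= ucl
    outcomes[i] <- dec$outcome
    ratios[i] <- dec$ratio
    keep[i] <- TRUE
  }
  covered <- covered[keep]
  outcomes <- outcomes[keep]
  ratios <- ratios[keep]
  if (n_degenerate > 0L)
    warning(sprintf("%d degenerate replicate(s) (sd = 0) excluded",
                    n_degenerate))
  n_eff <- length(covered)
  pf_check(n_eff > 0L, "pf_numerical_error",
           "all replicates degenerate; no operating characteristics")
  rates <- vapply(c("improve", "re_evaluate", "maintain"),
                  function(o) mean(outcomes == o), numeric(1))
  structure(
    list(pf_true = pf_true,
         coverage = mean(covered),
         outcome_rates = rates,
         mean_ratio = mean(ratios),
         n_effective = n_eff,
         n_degenerate = n_degenerate,
         n_per_sample = n_per_sample,
         alpha = spec$alpha, k = spec$k, seed = seed),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf(
    "Operating characteristics (PF_true = %.3f, n = %d, k = %g, alpha = %g)\n",
    x$pf_true, x$n_per_sample, x$k, x$alpha))
  cat(sprintf("  UCL coverage: %.4f over %d replicates (%d degenerate)\n",
              x$coverage, x$n_effective, x$n_degenerate))
  cat(sprintf("  outcomes: improve %.3f | re_evaluate %.3f | maintain %.3f\n",
              x$outcome_rates[["improve"]], x$outcome_rates[["re_evaluate"]],
              x$outcome_rates[["maintain"]]))
  cat(sprintf("  mean d_R/d_T = %.3f\n", x$mean_ratio))
  invisible(x)
}

#' Read a Monte-Carlo scenario file
#'
#' The YAML file holds a list of scenario entries, each with \code{true_mu},
#' \code{true_sigma}, optional \code{n_per_sample}, \code{n_replicates},
#' \code{seed}, and an inline \code{spec} map (fields of [fitness_spec()]).
#'
#' @param path Path to a YAML scenario file.
#' @return List of [simulation_scenario()] objects.
#' @export
read_scenarios <- function(path) {
  pf_check(file.exists(path), "pf_parse_error",
           sprintf("scenario file not found: %s", path))
  raw <- yaml::read_yaml(path)
  pf_check(is.list(raw) && length(raw) > 0, "pf_parse_error",
           "scenario file must hold a non-empty list")
  lapply(seq_along(raw), function(i) {
    sc <- raw[[i]]
    pf_check(!is.null(sc$true_mu) && !is.null(sc$true_sigma) &&
               is.list(sc$spec),
             "pf_parse_error",
             sprintf("scenario %d: need true_mu, true_sigma and a spec map", i))
    sp <- sc$spec
    spec <- fitness_spec(
      item_id = if (is.null(sp$item_id)) sprintf("scenario_%d", i) else
        sp$item_id,
      limit = as.numeric(sp$limit),
      orientation = sp$orientation,
      k = as.numeric(if (is.null(sp$k)) 6 else sp$k),
      alpha = as.numeric(if (is.null(sp$alpha)) 0.05 else sp$alpha),
      phi1 = as.numeric(if (is.null(sp$phi1)) 0.4 else sp$phi1),
      phi2 = as.numeric(if (is.null(sp$phi2)) 0.8 else sp$phi2),
      name = if (is.null(sp$name)) sp$item_id else sp$name)
    simulation_scenario(
      true_mu = as.numeric(sc$true_mu),
      true_sigma = as.numeric(sc$true_sigma),
      spec = spec,
      n_per_sample = as.integer(if (is.null(sc$n_per_sample)) 10 else
        sc$n_per_sample),
      n_replicates = as.integer(if (is.null(sc$n_replicates)) 10000 else
        sc$n_replicates),
      seed = as.integer(if (is.null(sc$seed)) 1 else sc$seed))
  })
}
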