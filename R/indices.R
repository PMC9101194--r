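#' Summarize a repeated-measurement sample
#'
#' Computes the sample mean and sample standard deviation of one item's
#' repeated measurements.  The standard deviation uses the \eqn{n-1}
#' denominator by default; a \code{"n"} mode (divide the sum of squared
#' deviations by \eqn{n}) is available for comparison with texts that
#' print the population-style formula.  The worked numbers this package
#' reproduces are only consistent with the \eqn{n-1} denominator.
#'
#' @param values Numeric vector of measurements (length \eqn{\ge 2}, all
#'   finite).
#' @param item_id Short label for the item the values belong to.
#' @param sd_denominator \code{"n_minus_1"} (default) or \code{"n"}.
#' @return An object of class \code{"measurement_sample"} with fields
#'   \code{item_id}, \code{values}, \code{n}, \code{mean}, \code{sd},
#'   \code{sd_denominator}.
#' @examples
#' s <- summarize_sample(c(589, 593, 590, 591, 589, 590, 589, 589, 592, 594),
#'                       "cardio")
#' s$mean  # 590.6
#' @seealso [summary_sample()] to build the same object from already-computed
#'   summary statistics.
#' @export
summarize_sample <- function(values, item_id,
                             sd_denominator = c("n_minus_1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  pf_check(is.numeric(values) && length(values) >= 2L,
           "pf_invalid_sample",
           sprintf("item '%s': need at least 2 measurements, got %d",
                   item_id, length(values)))
  pf_check(all(is.finite(values)), "pf_invalid_sample",
           sprintf("item '%s': non-finite measurement value", item_id))
  n <- length(values)
  m <- mean(values)
  ss <- sum((values - m)^2)
  denom <- if (sd_denominator == "n_minus_1") n - 1 else n
  s <- sqrt(ss / denom)
  structure(
    list(item_id = item_id, values = as.numeric(values), n = n,
         mean = m, sd = s, sd_denominator = sd_denominator),
    class = "measurement_sample")
}

#' Build a measurement sample from summary statistics
#'
#' Some report tables provide only \eqn{\bar{x}}, \eqn{s} and \eqn{n} rather
#' than the raw measurements.  This constructor produces a
#' \code{"measurement_sample"} carrying those statistics (with
#' \code{values = NULL}) so the rest of the pipeline can run from a printed
#' summary.
#'
#' @param item_id Short label for the item.
#' @param n Number of measurements the statistics were computed from.
#' @param mean,sd Sample mean and sample standard deviation.
#' @param sd_denominator Denominator convention the supplied \code{sd} was
#'   computed with (metadata only; default \code{"n_minus_1"}).
#' @return A \code{"measurement_sample"} object.
#' @export
summary_sample <- function(item_id, n, mean, sd,
                           sd_denominator = c("n_minus_1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  pf_check(is.numeric(n) && length(n) == 1L && n >= 2 && n == round(n),
           "pf_invalid_sample", "n must be an integer >= 2")
  pf_check(is.numeric(mean) && is.finite(mean) &&
             is.numeric(sd) && is.finite(sd) && sd >= 0,
           "pf_invalid_sample", "mean must be finite and sd finite, >= 0")
  structure(
    list(item_id = item_id, values = NULL, n = as.integer(n),
         mean = mean, sd = sd, sd_denominator = sd_denominator),
    class = "measurement_sample")
}

#' @export
print.measurement_sample <- function(x, ...) {
  src <- if (is.null(x$values)) "summary statistics" else
    sprintf("%d raw values", length(x$values))
  cat(sprintf("Measurement sample '%s' (%s)\n", x$item_id, src))
  cat(sprintf("  n = %d, mean = %g, sd = %g (%s denominator)\n",
              x$n, x$mean, x$sd,
              if (x$sd_denominator == "n_minus_1") "n-1" else "n"))
  invisible(x)
}

#' Estimate a one-sided fitness index
#'
#' The index measures the distance from the sample mean to the
#' specification limit in units of the sample standard deviation:
#' \deqn{PF^* = (U - \bar{x})/s} for a smaller-the-better item and
#' \deqn{PF^* = (\bar{x} - L)/s} for a larger-the-better item.
#' It is dimensionless and may be negative when the mean lies beyond the
#' limit; negative values propagate unclipped.
#'
#' @param sample A \code{"measurement_sample"} with \code{sd > 0}.
#' @param spec The item's [fitness_spec()].
#' @return An object of class \code{"index_estimate"} with fields
#'   \code{item_id}, \code{pf_star}, \code{n}.
#' @examples
#' sp <- fitness_spec("cardio", limit = 598, orientation = "smaller_better")
#' sm <- summary_sample("cardio", n = 10, mean = 590.6, sd = 1.838)
#' estimate_index(sm, sp)$pf_star  # ~ 4.03
#' @export
estimate_index <- function(sample, spec) {
  pf_check(inherits(sample, "measurement_sample"), "pf_parameter_error",
           "sample must be a measurement_sample")
  pf_check(inherits(spec, "fitness_spec"), "pf_parameter_error",
           "spec must be a fitness_spec")
  if (sample$sd <= 0)
    pf_stop("pf_degenerate_sample",
            sprintf("item '%s': zero sample standard deviation; index undefined",
                    sample$item_id))
  pf_star <- if (spec$orientation == "smaller_better")
    (spec$limit - sample$mean) / sample$sd
  else
    (sample$mean - spec$limit) / sample$sd
  structure(list(item_id = sample$item_id, pf_star = pf_star, n = sample$n),
            class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, ...) {
  cat(sprintf("Index estimate '%s': PF* = %.4f (n = %d)\n",
              x$item_id, x$pf_star, x$n))
  invisible(x)
}

#' Compliance ratio of an index value
#'
#' Under the normal model, the population proportion of test performances
#' meeting the specification limit relates one-to-one to the index through
#' the standard normal CDF: \eqn{r = \Phi(PF)}.
#'
#' @param pf Index value(s), finite.
#' @return The compliance ratio(s) in (0, 1); strictly increasing in
#'   \code{pf}, with \code{compliance_ratio(0) == 0.5}.
#' @export
compliance_ratio <- function(pf) {
  pf_check(is.numeric(pf) && all(is.finite(pf)), "pf_parameter_error",
           "pf must be finite")
  stats::pnorm(pf)
}
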