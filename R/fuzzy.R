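# Half-triangular fuzzy number built on the index's upper confidence limit.
#
# The alpha-cuts of the fuzzy index are nested one-sided confidence
# intervals: the apex sits at the chi-square-median-corrected point
# estimate, and the right endpoint is the 100(1-alpha)% upper confidence
# limit obtained by combining a chi-square bound on sigma with a normal
# bound on the mean through Boole's inequality (hence the bound is
# conservative: actual coverage >= 1 - alpha).

# forward map alpha -> x(alpha); strictly decreasing in alpha for pf_star >= 0
ucl_at_level <- function(pf_star, n, level) {
  pf_star * sqrt(stats::qchisq(1 - level / 2, df = n - 1) / n) +
    stats::qnorm(1 - level / 2) / sqrt(n)
}

check_ucl_args <- function(n, alpha) {
  pf_check(is.numeric(n) && length(n) == 1L && is.finite(n) &&
             n >= 2 && n == round(n),
           "pf_parameter_error", "n must be an integer >= 2")
  pf_check(is.numeric(alpha) && length(alpha) == 1L &&
             alpha > 0 && alpha < 1,
           "pf_parameter_error", "alpha must lie strictly in (0, 1)")
  invisible(TRUE)
}

#' Upper confidence limit of a fitness index
#'
#' Computes the observed \eqn{100(1-\alpha)\%} upper confidence limit
#' \deqn{U_{PF} = PF^* \sqrt{\chi^2_{1-\alpha/2;\,n-1}/n} + z_{\alpha/2}/\sqrt{n},}
#' where \eqn{\chi^2_{q;\,n-1}} is the lower-\eqn{q} chi-square quantile with
#' \eqn{n-1} degrees of freedom and \eqn{z_{\alpha/2}} the upper-\eqn{\alpha/2}
#' standard normal quantile.  The two \eqn{1-\alpha/2} pieces are joined by
#' Boole's inequality, so \eqn{P(PF \le U_{PF}) \ge 1-\alpha} (conservative).
#'
#' @param pf_star Index point estimate(s) (may be negative).
#' @param n Sample size (integer \eqn{\ge 2}).
#' @param alpha Confidence parameter in (0, 1). Default 0.05.
#' @return The upper confidence limit, vectorized over \code{pf_star}.
#' @examples
#' upper_confidence_limit(4.03, n = 10)  # 6.178
#' @export
upper_confidence_limit <- function(pf_star, n, alpha = 0.05) {
  check_ucl_args(n, alpha)
  pf_check(is.numeric(pf_star) && all(is.finite(pf_star)),
           "pf_parameter_error", "pf_star must be finite")
  ucl_at_level(pf_star, n, alpha)
}

#' Build the half-triangular fuzzy index
#'
#' Converts an index point estimate into a half-triangular fuzzy number
#' \eqn{\tilde{PF} = \Delta(PF_M, PF_R)}: the apex (membership 1)
#' \deqn{PF_M = PF^* \sqrt{\chi^2_{0.5;\,n-1}/n}}
#' uses the chi-square median, and the right endpoint (membership 0)
#' \eqn{PF_R} is [upper_confidence_limit()] at the same \code{alpha}.  For
#' \eqn{PF^* > 0} the median correction pulls the apex below the point
#' estimate because the chi-square median is below \eqn{n-1 < n}.
#'
#' @param pf_star Index point estimate, or an \code{"index_estimate"} object
#'   (in which case \code{n} is taken from it).
#' @param n Sample size (integer \eqn{\ge 2}).
#' @param alpha Confidence parameter in (0, 1). Default 0.05.
#' @param item_id Optional label carried into the result.
#' @return An object of class \code{"fuzzy_index"} with fields
#'   \code{item_id}, \code{pf_star}, \code{n}, \code{alpha}, \code{pf_m},
#'   \code{pf_r}, \code{ucl} (\code{ucl == pf_r}: same \code{alpha} for both).
#' @examples
#' fz <- build_fuzzy_index(4.03, n = 10)
#' c(fz$pf_m, fz$pf_r)  # 3.681 6.178
#' @export
build_fuzzy_index <- function(pf_star, n = NULL, alpha = 0.05,
                              item_id = NA_character_) {
  if (inherits(pf_star, "index_estimate")) {
    if (is.null(n)) n <- pf_star$n
    if (is.na(item_id)) item_id <- pf_star$item_id
    pf_star <- pf_star$pf_star
  }
  pf_check(!is.null(n), "pf_parameter_error", "n is required")
  check_ucl_args(n, alpha)
  pf_check(is.numeric(pf_star) && length(pf_star) == 1L && is.finite(pf_star),
           "pf_parameter_error", "pf_star must be a single finite number")
  pf_m <- pf_star * sqrt(stats::qchisq(0.5, df = n - 1) / n)
  pf_r <- ucl_at_level(pf_star, n, alpha)
  structure(
    list(item_id = item_id, pf_star = pf_star, n = as.integer(n),
         alpha = alpha, pf_m = pf_m, pf_r = pf_r, ucl = pf_r),
    class = "fuzzy_index")
}

#' @export
print.fuzzy_index <- function(x, ...) {
  cat(sprintf("Half-triangular fuzzy index%s: PF* = %.4f, n = %d, alpha = %g\n",
              if (is.na(x$item_id)) "" else sprintf(" '%s'", x$item_id),
              x$pf_star, x$n, x$alpha))
  cat(sprintf("  apex PF_M = %.4f, right endpoint PF_R = %.4f\n",
              x$pf_m, x$pf_r))
  invisible(x)
}

#' Membership function of a fuzzy index
#'
#' Evaluates the membership grade \eqn{\eta(x)} of the half-triangular fuzzy
#' number: 0 for \eqn{x < PF_M}, 1 at \eqn{x = PF_M}, and for
#' \eqn{PF_M < x < PF_R} the level \eqn{a} solving
#' \deqn{x = PF^* \sqrt{\chi^2_{1-a/2;\,n-1}/n} + z_{a/2}/\sqrt{n},}
#' found by bracketed root-finding on the monotone map \eqn{a \mapsto x(a)}
#' (larger \eqn{a} means smaller quantiles, so the map is strictly
#' decreasing).  For \eqn{x \ge PF_R} the grade is 0 — the function is
#' deliberately discontinuous at \eqn{PF_R}, where the interior limit is the
#' floor level rather than 0.
#'
#' Alpha-cuts below 0.05 reuse the 0.05-level interval, so the inverse is
#' solved on \eqn{a \in [0.05, 1]} and any interior \eqn{x} beyond the
#' 0.05-level endpoint (possible only when the fuzzy number was built with
#' \code{alpha < 0.05}) is capped at grade 0.05.
#'
#' @param fz A \code{"fuzzy_index"} from [build_fuzzy_index()].
#' @param x Numeric vector of candidate index values.
#' @param tol Root-finding tolerance on the membership level. Default 1e-9.
#' @return Membership grades in \[0, 1\], non-increasing on
#'   \eqn{[PF_M, \infty)}.
#' @export
membership <- function(fz, x, tol = 1e-9) {
  pf_check(inherits(fz, "fuzzy_index"), "pf_parameter_error",
           "fz must be a fuzzy_index")
  pf_check(is.numeric(x) && all(is.finite(x)), "pf_parameter_error",
           "x must be finite")
  floor_level <- 0.05
  x_floor <- ucl_at_level(fz$pf_star, fz$n, floor_level)
  one_grade <- function(xi) {
    if (xi < fz$pf_m) return(0)
    if (xi == fz$pf_m) return(1)
    if (xi >= fz$pf_r) return(0)
    if (xi >= x_floor) return(floor_level)  # capped cut, alpha < 0.05 only
    f <- function(a) ucl_at_level(fz$pf_star, fz$n, a) - xi
    lo <- floor_level
    hi <- 1
    if (!(f(lo) > 0 && f(hi) < 0))
      pf_stop("pf_numerical_error",
              sprintf(paste0("membership: no sign change on [%g, 1] for ",
                             "x = %g (pf_star = %g, n = %d)"),
                      lo, xi, fz$pf_star, fz$n))
    root <- tryCatch(
      stats::uniroot(f, lower = lo, upper = hi, tol = tol),
      error = function(e)
        pf_stop("pf_numerical_error",
                sprintf("membership: root finding failed for x = %g: %s",
                        xi, conditionMessage(e))))
    root$root
  }
  vapply(x, one_grade, numeric(1))
}

#' Fuzzy hypothesis test of an index against a required level
#'
#' Tests \eqn{H_0: PF \ge k} with the simplified base-ratio statistic
#' \deqn{d_R/d_T = (PF_R - k) / (PF_R - PF_M),}
#' the fraction of the fuzzy number's base lying to the right of \eqn{k}.
#' The ratio is returned unclamped: it is negative when \eqn{PF_R < k} and
#' exceeds 1 when \eqn{k < PF_M}.  Decision rule with the spec's thresholds:
#' ratio \eqn{\le \phi_1} rejects \eqn{H_0} (\code{"improve"}); ratio
#' \eqn{\ge \phi_2} retains it (\code{"maintain"}); otherwise
#' \code{"re_evaluate"}.
#'
#' @param fz A \code{"fuzzy_index"} with \eqn{PF_R > PF_M}.
#' @param spec The item's [fitness_spec()] (supplies \code{k}, \code{phi1},
#'   \code{phi2}).
#' @return An object of class \code{"fuzzy_decision"} with fields
#'   \code{item_id}, \code{k}, \code{d_r}, \code{d_t}, \code{ratio},
#'   \code{outcome}.
#' @examples
#' sp <- fitness_spec("cardio", limit = 598, orientation = "smaller_better")
#' fuzzy_test(build_fuzzy_index(4.03, n = 10), sp)  # ratio 0.071, improve
#' @export
fuzzy_test <- function(fz, spec) {
  pf_check(inherits(fz, "fuzzy_index"), "pf_parameter_error",
           "fz must be a fuzzy_index")
  pf_check(inherits(spec, "fitness_spec"), "pf_parameter_error",
           "spec must be a fitness_spec")
  d_t <- fz$pf_r - fz$pf_m
  if (d_t <= 0)
    pf_stop("pf_degenerate_fuzzy",
            sprintf("degenerate fuzzy number (PF_R - PF_M = %g <= 0)", d_t))
  d_r <- fz$pf_r - spec$k
  ratio <- d_r / d_t
  outcome <- if (ratio <= spec$phi1) "improve"
  else if (ratio < spec$phi2) "re_evaluate"
  else "maintain"
  structure(
    list(item_id = fz$item_id, k = spec$k, d_r = d_r, d_t = d_t,
         ratio = ratio, outcome = outcome),
    class = "fuzzy_decision")
}

#' @export
print.fuzzy_decision <- function(x, ...) {
  cat(sprintf("Fuzzy decision%s vs k = %g:\n",
              if (is.na(x$item_id)) "" else sprintf(" '%s'", x$item_id), x$k))
  cat(sprintf("  d_R = %.3f, d_T = %.3f, d_R/d_T = %.3f -> %s\n",
              x$d_r, x$d_t, x$ratio, x$outcome))
  invisible(x)
}
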