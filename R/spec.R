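#' Define one physical fitness item and its test configuration
#'
#' A fitness specification couples a measured item with the one-sided
#' requirement it is judged against: the orientation of the quality
#' characteristic, the specification limit on the measurement scale, the
#' required index level \code{k} for the hypothesis \eqn{H_0: PF \ge k},
#' the confidence parameter \code{alpha}, and the two decision thresholds
#' \code{phi1 < phi2} that partition the fuzzy-test ratio into the three
#' outcomes (improve / re-evaluate / maintain).
#'
#' For a smaller-the-better item (e.g. a run time) \code{limit} is the upper
#' limit \eqn{U}; for a larger-the-better item (sit-ups, jump distance,
#' flexion distance) it is the lower limit \eqn{L}.  Exactly one limit per
#' item.
#'
#' @param item_id Short label identifying the item.
#' @param limit Specification limit, in measurement units.
#' @param orientation \code{"smaller_better"} or \code{"larger_better"}.
#' @param k Required index level (dimensionless). Default 6, the level used
#'   for an intermediate fitness requirement.
#' @param alpha Confidence parameter in (0, 1); the fuzzy number's right
#'   endpoint is the \eqn{100(1-\alpha)\%} upper confidence limit. Default 0.05.
#' @param phi1,phi2 Decision thresholds with \eqn{0 < \phi_1 < \phi_2 < 1}.
#'   Ratio \eqn{\le \phi_1} rejects \eqn{H_0} (improve); ratio \eqn{\ge \phi_2}
#'   retains it (maintain); in between, re-evaluate. Defaults 0.4 and 0.8.
#' @param name Free-text description of the item (defaults to \code{item_id}).
#'
#' @return An object of class \code{"fitness_spec"}.
#' @examples
#' fitness_spec("cardio", limit = 598, orientation = "smaller_better")
#' @export
fitness_spec <- function(item_id, limit,
                         orientation = c("smaller_better", "larger_better"),
                         k = 6, alpha = 0.05, phi1 = 0.4, phi2 = 0.8,
                         name = item_id) {
  orientation <- match.arg(orientation)
  if (is.null(name)) name <- item_id
  pf_check(is.character(item_id) && length(item_id) == 1L && nzchar(item_id),
           "pf_parameter_error", "item_id must be a non-empty string")
  pf_check(is.numeric(limit) && length(limit) == 1L && is.finite(limit),
           "pf_parameter_error", "limit must be a single finite number")
  pf_check(is.numeric(k) && length(k) == 1L && is.finite(k),
           "pf_parameter_error", "k must be a single finite number")
  pf_check(is.numeric(alpha) && length(alpha) == 1L &&
             alpha > 0 && alpha < 1,
           "pf_parameter_error", "alpha must lie strictly in (0, 1)")
  pf_check(is.numeric(phi1) && is.numeric(phi2) &&
             length(phi1) == 1L && length(phi2) == 1L &&
             phi1 > 0 && phi1 < phi2 && phi2 < 1,
           "pf_parameter_error", "need 0 < phi1 < phi2 < 1")
  structure(
    list(item_id = item_id, name = name, orientation = orientation,
         limit = limit, k = k, alpha = alpha, phi1 = phi1, phi2 = phi2),
    class = "fitness_spec")
}

#' @export
print.fitness_spec <- function(x, ...) {
  side <- if (x$orientation == "smaller_better") "U" else "L"
  cat(sprintf("Fitness spec '%s' (%s)\n", x$item_id, x$name))
  cat(sprintf("  orientation: %s, %s = %g\n", x$orientation, side, x$limit))
  cat(sprintf("  k = %g, alpha = %g, phi1 = %g, phi2 = %g\n",
              x$k, x$alpha, x$phi1, x$phi2))
  invisible(x)
}

#' Read a specification configuration file (YAML or JSON)
#'
#' The file maps item ids to per-item fields (\code{name},
#' \code{orientation}, \code{limit}, \code{k}, \code{alpha}, \code{phi1},
#' \code{phi2}) under a top-level \code{items} key; per-item \code{k},
#' \code{alpha} and \code{phi} values missing from an item fall back to a
#' top-level \code{defaults} map, then to the package defaults.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return Named list of [fitness_spec()] objects, one per item.
#' @export
read_spec_config <- function(path) {
  pf_check(file.exists(path), "pf_parse_error",
           sprintf("spec config not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    pf_stop("pf_parse_error",
            sprintf("unsupported spec config extension '.%s' (need yaml/json)",
                    ext)))
  items <- raw[["items"]]
  pf_check(is.list(items) && length(items) > 0 &&
             !is.null(names(items)) && all(nzchar(names(items))),
           "pf_parse_error", "spec config needs a named 'items' map")
  defaults <- raw[["defaults"]]
  if (is.null(defaults)) defaults <- list()
  pick <- function(entry, field, fallback) {
    if (!is.null(entry[[field]])) entry[[field]]
    else if (!is.null(defaults[[field]])) defaults[[field]]
    else fallback
  }
  specs <- lapply(names(items), function(id) {
    it <- items[[id]]
    pf_check(!is.null(it[["orientation"]]) && !is.null(it[["limit"]]),
             "pf_parse_error",
             sprintf("item '%s': orientation and limit are required", id))
    fitness_spec(id,
                 limit = as.numeric(it[["limit"]]),
                 orientation = it[["orientation"]],
                 k = as.numeric(pick(it, "k", 6)),
                 alpha = as.numeric(pick(it, "alpha", 0.05)),
                 phi1 = as.numeric(pick(it, "phi1", 0.4)),
                 phi2 = as.numeric(pick(it, "phi2", 0.8)),
                 name = if (is.null(it[["name"]])) id else it[["name"]])
  })
  names(specs) <- names(items)
  specs
}
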