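#' Define a model parameter
#'
#' A parameter carries a base-case value, a plausible low/high range used by
#' the deterministic sensitivity analyses, a role that fixes its admissible
#' domain, and an optional sampling distribution for probabilistic
#' sensitivity analysis.
#'
#' Roles and their constraints:
#' * `cost` — US dollars; `low >= 0`.
#' * `probability` — dimensionless; the whole range must lie in \[0, 1\].
#' * `effect` — standardized effect size (Cohen's-d-like), dimensionless.
#' * `count` — non-negative quantities such as session counts or
#'   utilization multipliers.
#'
#' @param name Parameter identifier (used in model expressions).
#' @param base Base-case value; `low <= base <= high` is enforced.
#' @param low,high Range endpoints for sensitivity analysis; default to
#'   `base` (a fixed parameter).
#' @param role One of `"cost"`, `"probability"`, `"effect"`, `"count"`.
#' @param dist Optional sampling distribution, see [dist_spec()]. `NULL`
#'   means a point mass at `base`.
#' @param note Optional free-text provenance note (e.g. "reconstructed").
#' @return An object of class `cea_parameter`.
#' @examples
#' new_parameter("sam_device_cost", base = 4635, low = 2000, high = 6000,
#'               role = "cost")
#' @export
new_parameter <- function(name, base, low = base, high = base,
                          role = c("cost", "probability", "effect", "count"),
                          dist = NULL, note = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", name)) {
    stop("parameter name '", name, "' is not a valid identifier", call. = FALSE)
  }
  base <- as.numeric(base); low <- as.numeric(low); high <- as.numeric(high)
  if (!all(is.finite(c(base, low, high)))) {
    stop("parameter '", name, "': base/low/high must be finite", call. = FALSE)
  }
  if (!(low <= base && base <= high)) {
    stop("parameter '", name, "': requires low <= base <= high (got ",
         low, ", ", base, ", ", high, ")", call. = FALSE)
  }
  if (role == "probability" && (low < 0 || high > 1)) {
    stop("parameter '", name, "': probability range must lie within [0, 1]",
         call. = FALSE)
  }
  if (role %in% c("cost", "count") && low < 0) {
    stop("parameter '", name, "': ", role, " range must be non-negative",
         call. = FALSE)
  }
  if (!is.null(dist)) {
    dist <- as_dist_spec(dist)
    .check_dist_bounds(dist, role, name)
  }
  structure(
    list(name = name, base = base, low = low, high = high, role = role,
         dist = dist, note = note),
    class = "cea_parameter"
  )
}

#' @export
print.cea_parameter <- function(x, ...) {
  cat(sprintf("<cea_parameter> %s [%s] base=%g range=[%g, %g]%s\n",
              x$name, x$role, x$base, x$low, x$high,
              if (is.null(x$dist)) "" else paste0(" dist=", x$dist$kind)))
  invisible(x)
}

#' Tabulate a parameter set
#'
#' @param parameters A list of [new_parameter()] objects (e.g.
#'   `model$parameters`).
#' @return A data frame with one row per parameter: name, role, base, low,
#'   high, distribution kind and note.
#' @export
parameter_table <- function(parameters) {
  data.frame(
    name = vapply(parameters, `[[`, character(1), "name"),
    role = vapply(parameters, `[[`, character(1), "role"),
    base = vapply(parameters, `[[`, numeric(1), "base"),
    low = vapply(parameters, `[[`, numeric(1), "low"),
    high = vapply(parameters, `[[`, numeric(1), "high"),
    dist = vapply(parameters, function(p) {
      if (is.null(p$dist)) "point" else p$dist$kind
    }, character(1)),
    note = vapply(parameters, function(p) {
      if (is.null(p$note)) "" else p$note
    }, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Base-case values of a parameter set
#'
#' @param model A `cea_model`, or a bare list of `cea_parameter`s.
#' @return Named list of base values, in declaration order.
#' @export
base_values <- function(model) {
  parameters <- if (inherits(model, "cea_model")) model$parameters else model
  vals <- lapply(parameters, `[[`, "base")
  names(vals) <- vapply(parameters, `[[`, character(1), "name")
  vals
}
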