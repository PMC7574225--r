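# One-way deterministic sensitivity analysis: sweeps of the incremental
# cost/effect over a parameter grid, break-even threshold search by
# bisection on the cost difference, and tornado ranking of parameters by
# the swing their range induces in the cost difference.

#' Incremental result as a function of one parameter
#'
#' Internal workhorse: evaluates the comparison pair with one parameter set
#' to `value` (vectorised) and all others at base.
#' @noRd
.delta_at <- function(model, parameter, value, comparison) {
  values <- base_values(model)
  if (!parameter %in% names(values)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  values[[parameter]] <- value
  inc <- incremental(model, comparison = comparison, values = values)
  list(delta_cost = inc$delta_cost, delta_effect = inc$delta_effect)
}

#' One-way parameter sweep
#'
#' Re-evaluates both strategies of a comparison at each grid value of one
#' parameter, all other parameters held at base, and reports the incremental
#' cost and effect.
#'
#' @param model A `cea_model`.
#' @param parameter Parameter name to vary.
#' @param grid Numeric vector of values (for probability-role parameters,
#'   must lie in \[0, 1\]).
#' @param comparison Comparison pair, as in [incremental()].
#' @return Data frame with columns `value`, `delta_cost`, `delta_effect`.
#' @examples
#' m <- knee_oa_model()
#' sweep_parameter(m, "sam_device_cost", c(2000, 4635))
#' @export
sweep_parameter <- function(model, parameter, grid, comparison = 1L) {
  stopifnot(inherits(model, "cea_model"))
  if (length(grid) == 0L) stop("empty sweep grid", call. = FALSE)
  p <- .find_parameter(model, parameter)
  if (p$role == "probability" && (min(grid) < 0 || max(grid) > 1)) {
    stop("sweep grid for probability parameter '", parameter,
         "' must lie within [0, 1]", call. = FALSE)
  }
  d <- .delta_at(model, parameter, as.numeric(grid), comparison)
  data.frame(value = as.numeric(grid),
             delta_cost = rep_len(d$delta_cost, length(grid)),
             delta_effect = rep_len(d$delta_effect, length(grid)),
             row.names = NULL)
}

.find_parameter <- function(model, parameter) {
  pnames <- vapply(model$parameters, `[[`, character(1), "name")
  i <- match(parameter, pnames)
  if (is.na(i)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  model$parameters[[i]]
}

#' Break-even threshold of a parameter
#'
#' Finds the parameter value at which the two strategies' expected costs are
#' equal (incremental cost crosses zero) by bisection over a bracket whose
#' endpoints must give opposite signs of the cost difference. Iterates until
#' the cost difference is within `tol` dollars of zero or the bracket has
#' shrunk to 1e-6 of its initial width.
#'
#' @param model A `cea_model`.
#' @param parameter Parameter name to solve over.
#' @param bracket Length-2 numeric `c(low, high)` search interval.
#' @param comparison Comparison pair, as in [incremental()].
#' @param tol Absolute tolerance on the cost difference, in USD.
#' @return An object of class `cea_threshold`: `parameter`, `threshold`,
#'   `direction` (`"below_makes_new_cheaper"` or
#'   `"above_makes_new_cheaper"`), `bracket`, `delta_cost_at_threshold` and
#'   the iteration count.
#' @examples
#' m <- knee_oa_model()
#' find_threshold(m, "sam_device_cost", c(0, 4635))  # ~2276 USD
#' @export
find_threshold <- function(model, parameter, bracket, comparison = 1L,
                           tol = 0.01) {
  stopifnot(inherits(model, "cea_model"), length(bracket) == 2L)
  lo <- min(bracket); hi <- max(bracket)
  f <- function(x) .delta_at(model, parameter, x, comparison)$delta_cost
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) {
    mid <- lo; fmid <- flo; iter <- 0L
  } else if (fhi == 0) {
    mid <- hi; fmid <- fhi; iter <- 0L
  } else if (sign(flo) == sign(fhi)) {
    stop("no break-even threshold for '", parameter, "' in [", lo, ", ", hi,
         "]: delta cost has the same sign (", signif(flo, 6), " and ",
         signif(fhi, 6), ") at both endpoints", call. = FALSE)
  } else {
    width0 <- hi - lo
    iter <- 0L
    repeat {
      iter <- iter + 1L
      mid <- (lo + hi) / 2
      fmid <- f(mid)
      if (abs(fmid) <= tol || (hi - lo) <= 1e-6 * width0) break
      if (sign(fmid) == sign(flo)) {
        lo <- mid; flo <- fmid
      } else {
        hi <- mid; fhi <- fmid
      }
    }
  }
  direction <- if (f(min(bracket)) < 0) "below_makes_new_cheaper"
               else "above_makes_new_cheaper"
  structure(
    list(parameter = parameter, threshold = mid, direction = direction,
         bracket = c(min(bracket), max(bracket)),
         delta_cost_at_threshold = fmid, iterations = iter),
    class = "cea_threshold"
  )
}

#' @export
print.cea_threshold <- function(x, ...) {
  cat(sprintf("Break-even for '%s': %.2f (reported $%d)\n", x$parameter,
              x$threshold, as.integer(round(x$threshold))))
  cat(sprintf("  direction: %s; bracket [%g, %g]; |delta cost| = %.4g after %d bisections\n",
              x$direction, x$bracket[1], x$bracket[2],
              abs(x$delta_cost_at_threshold), x$iterations))
  invisible(x)
}

#' Tornado analysis
#'
#' For each parameter, evaluates the incremental cost of a comparison with
#' that parameter at its low and at its high bound (all others at base) and
#' ranks parameters by the absolute swing of the cost difference. Ties are
#' broken alphabetically by parameter name.
#'
#' @param model A `cea_model`.
#' @param parameters Character vector of parameter names; defaults to every
#'   parameter with a non-degenerate range (`low < high`).
#' @param comparison Comparison pair, as in [incremental()].
#' @return Data frame of class `cea_tornado`, one row per parameter, sorted
#'   by `swing` descending: `parameter`, `low`, `high`, `delta_cost_at_low`,
#'   `delta_cost_at_high`, `swing`.
#' @examples
#' m <- knee_oa_model()
#' head(tornado(m), 3)
#' @export
tornado <- function(model, parameters = NULL, comparison = 1L) {
  stopifnot(inherits(model, "cea_model"))
  tab <- parameter_table(model$parameters)
  if (is.null(parameters)) {
    parameters <- tab$name[tab$low < tab$high]
  }
  rows <- lapply(parameters, function(nm) {
    p <- .find_parameter(model, nm)
    at_low <- .delta_at(model, nm, p$low, comparison)$delta_cost
    at_high <- .delta_at(model, nm, p$high, comparison)$delta_cost
    data.frame(parameter = nm, low = p$low, high = p$high,
               delta_cost_at_low = at_low, delta_cost_at_high = at_high,
               swing = abs(at_high - at_low), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' @export
print.cea_tornado <- function(x, ...) {
  cat("Tornado analysis (swing of incremental cost over parameter range)\n")
  print.data.frame(x, digits = 6)
  invisible(x)
}
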