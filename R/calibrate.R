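#' Calibrate per-arm residual constants to target payoffs
#'
#' Decision-tree reconstructions often fix every stage-level parameter that
#' is publicly known and leave one residual cost (and optionally one
#' residual effect) constant per strategy arm to absorb everything that is
#' not: the residual parameter appears with coefficient 1 in every terminal
#' of its arm, so the rollback is linear in it and the calibration is exact
#' in one step — residual = target minus the arm's rollback with the
#' residual at zero.
#'
#' @param model A `cea_model` in which each strategy to calibrate has a
#'   dedicated residual cost parameter (and optionally a residual effect
#'   parameter) entering every terminal of that arm additively.
#' @param targets Named list, one entry per strategy label, each
#'   `c(cost, effect)`: the expected payoffs the calibrated arm must
#'   reproduce.
#' @param residual_params Named list parallel to `targets`:
#'   `list(cost = "<param>", effect = "<param>" or NULL)` per strategy. When
#'   `effect` is `NULL` the arm's rollback effect must already match the
#'   target (within 1e-9).
#' @return The model with residual parameter bases (and ranges, collapsed to
#'   the point) set; the solved residuals are attached as attribute
#'   `"calibration"` (data frame: strategy, residual type, parameter,
#'   value).
#' @section Errors: a target that implies a negative residual cost is
#'   infeasible (the fixed stage costs already exceed the target) and stops
#'   with a calibration error.
#' @examples
#' m <- build_knee_oa_model(calibrated = FALSE)
#' m <- calibrate_model(m, knee_oa_targets(), knee_oa_residual_params())
#' attr(m, "calibration")
#' @export
calibrate_model <- function(model, targets, residual_params) {
  stopifnot(inherits(model, "cea_model"))
  stopifnot(setequal(names(targets), names(residual_params)))
  values <- base_values(model)
  resid_names <- unlist(lapply(residual_params, function(r) {
    c(r$cost, r$effect)
  }), use.names = FALSE)
  unknown <- setdiff(resid_names, names(values))
  if (length(unknown) > 0L) {
    stop("residual parameter(s) not declared in the model: ",
         paste0("'", unknown, "'", collapse = ", "), call. = FALSE)
  }
  values[resid_names] <- 0
  payoffs <- rollback(model$tree, values)
  solved <- list()
  for (strategy in names(targets)) {
    if (!strategy %in% names(payoffs)) {
      stop("no strategy '", strategy, "' in the model tree", call. = FALSE)
    }
    target <- targets[[strategy]]
    rp <- residual_params[[strategy]]
    resid_cost <- target[[1L]] - payoffs[[strategy]]$cost
    if (resid_cost < 0) {
      stop("calibration infeasible for strategy '", strategy,
           "': fixed stage costs (", format(payoffs[[strategy]]$cost),
           ") exceed the target cost (", format(target[[1L]]), ")",
           call. = FALSE)
    }
    solved[[length(solved) + 1L]] <-
      data.frame(strategy = strategy, type = "cost", parameter = rp$cost,
                 value = resid_cost)
    if (is.null(rp$effect)) {
      if (abs(payoffs[[strategy]]$effect - target[[2L]]) > 1e-9) {
        stop("strategy '", strategy, "' has no residual effect parameter ",
             "but its rollback effect (",
             format(payoffs[[strategy]]$effect), ") does not match the ",
             "target (", format(target[[2L]]), ")", call. = FALSE)
      }
    } else {
      solved[[length(solved) + 1L]] <-
        data.frame(strategy = strategy, type = "effect",
                   parameter = rp$effect,
                   value = target[[2L]] - payoffs[[strategy]]$effect)
    }
  }
  solved <- do.call(rbind, solved)
  for (i in seq_len(nrow(solved))) {
    model <- .set_parameter_point(model, solved$parameter[i],
                                  solved$value[i])
  }
  attr(model, "calibration") <- solved
  model
}

.set_parameter_point <- function(model, name, value) {
  pnames <- vapply(model$parameters, `[[`, character(1), "name")
  i <- match(name, pnames)
  p <- model$parameters[[i]]
  model$parameters[[i]] <- new_parameter(
    p$name, base = value, low = value, high = value, role = p$role,
    dist = NULL, note = p$note)
  model
}
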