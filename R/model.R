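#' Construct a cost-effectiveness model
#'
#' Bundles a parameter set, a decision tree (decision root whose children
#' are the strategies), and the list of strategy pairs to compare.
#'
#' @param parameters List of [new_parameter()] objects.
#' @param tree A `cea_node` of kind `"decision"`.
#' @param comparisons List of `list(new = , standard = )` strategy-label
#'   pairs; defaults to the decision node's first two strategies.
#' @param name Optional model name (used in reports and manifests).
#' @param horizon Free-text time horizon note (documentation only; no
#'   discounting is applied).
#' @return An object of class `cea_model`.
#' @export
new_cea_model <- function(parameters, tree, comparisons = NULL,
                          name = "model", horizon = NULL) {
  stopifnot(is.list(parameters),
            all(vapply(parameters, inherits, logical(1), "cea_parameter")))
  pnames <- vapply(parameters, `[[`, character(1), "name")
  if (anyDuplicated(pnames)) {
    stop("duplicate parameter name(s): ",
         paste(unique(pnames[duplicated(pnames)]), collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(tree, "cea_node") || tree$kind != "decision") {
    stop("tree must be a decision node (use decision_node())", call. = FALSE)
  }
  validate_tree(tree, pnames)
  strategies <- names(tree$strategies)
  if (is.null(comparisons)) {
    if (length(strategies) < 2L) {
      stop("a model needs at least two strategies to compare", call. = FALSE)
    }
    comparisons <- list(list(new = strategies[[1L]],
                             standard = strategies[[2L]]))
  }
  for (cmp in comparisons) {
    if (!is.list(cmp) || !all(c("new", "standard") %in% names(cmp))) {
      stop("each comparison must be list(new = , standard = )", call. = FALSE)
    }
    missing <- setdiff(c(cmp$new, cmp$standard), strategies)
    if (length(missing) > 0L) {
      stop("comparison references unknown strategy: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  model <- structure(
    list(name = name, horizon = horizon, parameters = parameters,
         tree = tree, comparisons = comparisons),
    class = "cea_model"
  )
  validate_model(model)
  model
}

#' Validate a cost-effectiveness model
#'
#' Structural validation of a `cea_model`: well-formed parameters, a
#' decision-node root, declared-only parameter references, branch
#' probabilities summing to 1 at the base case, and payoffs evaluable at
#' the base case. Errors name the offending parameter or node.
#'
#' @param model A `cea_model`.
#' @return Invisibly `TRUE`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  pnames <- vapply(model$parameters, `[[`, character(1), "name")
  validate_tree(model$tree, pnames)
  # base-case evaluability doubles as the probability-sum check
  payoffs <- rollback(model$tree, base_values(model))
  for (nm in names(payoffs)) {
    if (!all(is.finite(c(payoffs[[nm]]$cost, payoffs[[nm]]$effect)))) {
      stop("strategy '", nm, "' has non-finite base-case payoff",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Strategy labels of a model
#'
#' @param model A `cea_model`.
#' @return Character vector of strategy labels in tree order.
#' @export
strategies <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  names(model$tree$strategies)
}

#' Expected cost and effect per strategy
#'
#' Rolls back the model tree at the base case (optionally with some
#' parameters overridden) and tabulates one row per strategy.
#'
#' @param model A `cea_model`.
#' @param overrides Optional named list of parameter values overriding the
#'   base case.
#' @return Data frame with columns `strategy`, `cost`, `effect`.
#' @examples
#' evaluate_strategies(knee_oa_model())
#' @export
evaluate_strategies <- function(model, overrides = NULL) {
  stopifnot(inherits(model, "cea_model"))
  values <- base_values(model)
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown) > 0L) {
      stop("unknown parameter(s) in overrides: ",
           paste0("'", unknown, "'", collapse = ", "), call. = FALSE)
    }
    values[names(overrides)] <- overrides
  }
  payoffs <- rollback(model$tree, values)
  data.frame(
    strategy = names(payoffs),
    cost = vapply(payoffs, function(p) p$cost[1], numeric(1)),
    effect = vapply(payoffs, function(p) p$effect[1], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> %s\n", x$name))
  if (!is.null(x$horizon)) cat("  horizon: ", x$horizon, "\n", sep = "")
  cat(sprintf("  %d parameters, %d strategies (%s), %d comparison(s)\n",
              length(x$parameters), length(strategies(x)),
              paste(strategies(x), collapse = ", "),
              length(x$comparisons)))
  invisible(x)
}
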