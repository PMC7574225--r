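# Decision-tree node types and the rollback (expected value) engine.
#
# A tree is a nested list structure of three node kinds:
#   decision - root of a strategy comparison; children are labelled
#              strategies with no branch probabilities (no automatic
#              optimisation: every strategy's expected payoff is reported);
#   chance   - children carry branch-probability expressions which must sum
#              to 1 at every admissible parameter assignment;
#   terminal - carries a (cost, effect) payoff expression pair.

PROB_SUM_TOL <- 1e-9

#' Terminal node
#'
#' @param label Node label (used in error messages and reports).
#' @param cost,effect Payoff expressions (strings or numerics accepted by
#'   [parse_model_expr()]): cost in USD and effectiveness as a dimensionless
#'   effect size, both accumulated over the model horizon.
#' @return A `cea_node` of kind `"terminal"`.
#' @examples
#' terminal_node("PT initiated", cost = "device_cost + 41.8 * n", effect = 0.6)
#' @export
terminal_node <- function(label, cost, effect) {
  structure(
    list(kind = "terminal", label = as.character(label),
         payoff = list(cost = parse_model_expr(cost),
                       effect = parse_model_expr(effect))),
    class = "cea_node"
  )
}

#' Chance node
#'
#' @param label Node label.
#' @param branches List of child `cea_node`s.
#' @param probs List of branch-probability expressions, parallel to
#'   `branches`; they must sum to 1 at every admissible parameter
#'   assignment (checked at evaluation time, tolerance `1e-9`).
#' @return A `cea_node` of kind `"chance"`.
#' @export
chance_node <- function(label, branches, probs) {
  if (length(branches) != length(probs) || length(branches) < 1L) {
    stop("chance node '", label, "': branches and probs must be non-empty ",
         "parallel lists", call. = FALSE)
  }
  stopifnot(all(vapply(branches, inherits, logical(1), "cea_node")))
  structure(
    list(kind = "chance", label = as.character(label),
         probs = lapply(probs, parse_model_expr), branches = branches),
    class = "cea_node"
  )
}

#' Decision node
#'
#' @param label Node label.
#' @param strategies Named list of `cea_node`s, one per strategy; names are
#'   the strategy labels.
#' @return A `cea_node` of kind `"decision"`.
#' @export
decision_node <- function(label, strategies) {
  if (is.null(names(strategies)) || any(!nzchar(names(strategies)))) {
    stop("decision node '", label, "': strategies must be a named list",
         call. = FALSE)
  }
  stopifnot(all(vapply(strategies, inherits, logical(1), "cea_node")))
  structure(
    list(kind = "decision", label = as.character(label),
         strategies = strategies),
    class = "cea_node"
  )
}

#' @export
print.cea_node <- function(x, indent = 0, prefix = "", ...) {
  pad <- strrep("  ", indent)
  switch(x$kind,
    terminal = cat(sprintf("%s%s[%s] cost = %s, effect = %s\n", pad, prefix,
                           x$label, x$payoff$cost$text, x$payoff$effect$text)),
    chance = {
      cat(sprintf("%s%s(%s)\n", pad, prefix, x$label))
      for (i in seq_along(x$branches)) {
        print(x$branches[[i]], indent = indent + 1L,
              prefix = paste0("p = ", x$probs[[i]]$text, " -> "))
      }
    },
    decision = {
      cat(sprintf("%s%s<%s>\n", pad, prefix, x$label))
      for (nm in names(x$strategies)) {
        print(x$strategies[[nm]], indent = indent + 1L,
              prefix = paste0(nm, ": "))
      }
    }
  )
  invisible(x)
}

#' Parameter names referenced anywhere in a tree
#'
#' @param node A `cea_node`.
#' @return Character vector of parameter names (unique, unsorted).
#' @export
tree_parameters <- function(node) {
  switch(node$kind,
    terminal = unique(c(expr_parameters(node$payoff$cost),
                        expr_parameters(node$payoff$effect))),
    chance = unique(c(unlist(lapply(node$probs, expr_parameters)),
                      unlist(lapply(node$branches, tree_parameters)))),
    decision = unique(unlist(lapply(node$strategies, tree_parameters)))
  )
}

#' Validate a tree against a parameter set
#'
#' Checks structural invariants (terminal nodes have payoffs and no children;
#' chance branches have probabilities; decision nodes appear only at the
#' root) and that every referenced parameter name is declared.
#'
#' @param node A `cea_node` (usually the decision root).
#' @param param_names Character vector of declared parameter names.
#' @param at_root Internal; whether `node` is the tree root.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_tree <- function(node, param_names, at_root = TRUE) {
  if (!inherits(node, "cea_node")) {
    stop("tree nodes must be built with terminal_node()/chance_node()/",
         "decision_node()", call. = FALSE)
  }
  unknown <- setdiff(tree_parameters(node), param_names)
  if (length(unknown) > 0L) {
    stop("tree references undeclared parameter(s): ",
         paste0("'", unknown, "'", collapse = ", "), call. = FALSE)
  }
  .walk <- function(n, root) {
    if (n$kind == "decision" && !root) {
      stop("decision node '", n$label, "' must be the tree root ",
           "(strategies are compared, not chosen adaptively)", call. = FALSE)
    }
    kids <- switch(n$kind, terminal = list(), chance = n$branches,
                   decision = n$strategies)
    for (k in kids) .walk(k, FALSE)
  }
  .walk(node, at_root)
  invisible(TRUE)
}

#' Roll back a decision tree to expected payoffs
#'
#' Evaluates the tree bottom-up: a terminal node yields its payoff pair, a
#' chance node the probability-weighted sum of its branches, and a decision
#' node one expected payoff pair per strategy (both strategies are always
#' reported; there is no automatic optimisation). Equivalently, the result is
#' the sum over all root-to-leaf paths of path probability times terminal
#' payoff.
#'
#' Parameter values may be equal-length vectors, in which case the whole
#' rollback is evaluated element-wise — this is how the probabilistic
#' sensitivity analysis evaluates thousands of parameter draws in one pass.
#'
#' @param node A `cea_node`.
#' @param values Named list (or named vector) of parameter values binding
#'   every parameter the tree references; scalars or equal-length vectors.
#' @param prob_tol Absolute tolerance for the branch-probability sum check
#'   at each chance node.
#' @return For terminal/chance nodes, a list with numeric `cost` and
#'   `effect`. For a decision node, a named list of such pairs, one per
#'   strategy (class `strategy_payoffs`).
#' @examples
#' leaf_a <- terminal_node("a", 100, 0.2)
#' leaf_b <- terminal_node("b", 300, 0.4)
#' rollback(chance_node("toss", list(leaf_a, leaf_b), list(0.5, 0.5)),
#'          values = list())
#' @export
rollback <- function(node, values, prob_tol = PROB_SUM_TOL) {
  unknown <- setdiff(tree_parameters(node), names(values))
  if (length(unknown) > 0L) {
    stop("unbound parameter(s) ", paste0("'", unknown, "'", collapse = ", "),
         " when rolling back node '", node$label, "'", call. = FALSE)
  }
  .rollback(node, values, prob_tol)
}

.rollback <- function(node, values, prob_tol) {
  switch(node$kind,
    terminal = list(cost = eval_model_expr(node$payoff$cost, values),
                    effect = eval_model_expr(node$payoff$effect, values)),
    chance = {
      p <- lapply(node$probs, eval_model_expr, values = values)
      psum <- Reduce(`+`, p)
      if (any(abs(psum - 1) > prob_tol)) {
        stop("branch probabilities at chance node '", node$label,
             "' sum to ", format(max(psum), digits = 12),
             " (must sum to 1 within ", prob_tol, ")", call. = FALSE)
      }
      cost <- 0; effect <- 0
      for (i in seq_along(node$branches)) {
        sub <- .rollback(node$branches[[i]], values, prob_tol)
        cost <- cost + p[[i]] * sub$cost
        effect <- effect + p[[i]] * sub$effect
      }
      list(cost = cost, effect = effect)
    },
    decision = {
      out <- lapply(node$strategies, .rollback, values = values,
                    prob_tol = prob_tol)
      class(out) <- "strategy_payoffs"
      out
    }
  )
}

#' @export
print.strategy_payoffs <- function(x, ...) {
  cat("Expected payoffs per strategy:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s cost = %12.2f   effect = %7.4f\n",
                nm, x[[nm]]$cost[1], x[[nm]]$effect[1]))
  }
  invisible(x)
}
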