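# Synthetic-model generators with closed-form / enumerated oracle values,
# so every engine (rollback, threshold search, tornado) can be checked
# against an answer computed by an independent code path.

#' Enumerate root-to-leaf paths of a tree
#'
#' Independent oracle for [rollback()]: walks every root-to-leaf path of a
#' chance/terminal tree, accumulating the product of branch probabilities
#' along the path, and sums path probability times terminal payoff. Shares
#' no code with the recursive rollback (which never enumerates paths).
#'
#' @param node A `cea_node` of kind `"chance"` or `"terminal"`.
#' @param values Named list of parameter values (may be empty for trees
#'   with constant expressions).
#' @return List with `cost`, `effect`, `n_paths` and `total_prob` (the sum
#'   of all path probabilities, equal to 1 for a well-formed tree).
#' @export
enumerate_paths <- function(node, values = list()) {
  cost <- 0; effect <- 0; n_paths <- 0L; total_prob <- 0
  # explicit stack of (node, accumulated path probability)
  stack <- list(list(node = node, prob = 1))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    if (n$kind == "terminal") {
      n_paths <- n_paths + 1L
      total_prob <- total_prob + top$prob
      cost <- cost + top$prob * eval_model_expr(n$payoff$cost, values)
      effect <- effect + top$prob * eval_model_expr(n$payoff$effect, values)
    } else if (n$kind == "chance") {
      for (i in seq_along(n$branches)) {
        p <- eval_model_expr(n$probs[[i]], values)
        stack[[length(stack) + 1L]] <-
          list(node = n$branches[[i]], prob = top$prob * p)
      }
    } else {
      stop("enumerate_paths expects a chance/terminal tree, not a ",
           n$kind, " node", call. = FALSE)
    }
  }
  list(cost = cost, effect = effect, n_paths = n_paths,
       total_prob = total_prob)
}

#' Generate a random chance tree with a known expected value
#'
#' Builds a random tree of the requested depth: internal nodes are chance
#' nodes whose branch probabilities are drawn from the simplex (normalized
#' exponential draws, the Dirichlet(1,...,1) construction, with the last
#' probability set to one minus the rest so sums are exact), and leaves
#' carry payoffs drawn uniformly from the cost and effect ranges. The
#' expected payoff computed by path enumeration ([enumerate_paths()]) is
#' returned alongside the tree as an oracle.
#'
#' @param depth Tree depth (1 = a single terminal).
#' @param branching Maximum branches per chance node (each node draws
#'   between 2 and `branching`).
#' @param seed Integer seed; the same seed reproduces the same tree.
#' @param cost_range,effect_range Terminal payoff ranges; defaults mirror
#'   the knee-OA scale (costs in \[0, 10000\] USD, effects in \[0, 1\]).
#' @return List with `node` (the tree), `oracle` (list `cost`, `effect`)
#'   and `n_paths`.
#' @examples
#' g <- gen_tree(depth = 3, branching = 3, seed = 11)
#' rb <- rollback(g$node, values = list())
#' all.equal(rb$cost, g$oracle$cost)
#' @export
gen_tree <- function(depth, branching = 3L, seed = 1L,
                     cost_range = c(0, 10000), effect_range = c(0, 1)) {
  stopifnot(depth >= 1, branching >= 2)
  set.seed(seed)
  counter <- 0L
  build <- function(d) {
    counter <<- counter + 1L
    if (d == 1L) {
      return(terminal_node(
        paste0("leaf_", counter),
        cost = stats::runif(1, cost_range[1], cost_range[2]),
        effect = stats::runif(1, effect_range[1], effect_range[2])))
    }
    k <- sample(2:branching, 1L)
    draws <- stats::rexp(k)
    p <- draws / sum(draws)
    p[k] <- 1 - sum(p[-k])  # exact unit sum
    branches <- lapply(seq_len(k), function(i) build(d - 1L))
    chance_node(paste0("chance_", counter), branches = branches,
                probs = as.list(p))
  }
  node <- build(depth)
  oracle <- enumerate_paths(node)
  list(node = node, oracle = list(cost = oracle$cost,
                                  effect = oracle$effect),
       n_paths = oracle$n_paths)
}

#' Generate a two-strategy model with a closed-form cost difference
#'
#' Builds a minimal `cea_model` whose incremental cost is exactly
#' `intercept + sum(coefficients * x)` in the named parameters, so the
#' break-even threshold of parameter `x_j` has the closed form
#' `-(intercept + sum_{i != j} coef_i * base_i) / coef_j` and the tornado
#' swing of `x_j` is `|coef_j| * (high_j - low_j)`. Both closed forms are
#' returned as oracle functions.
#'
#' @param coefficients Named numeric vector: USD change in the cost
#'   difference per unit of each parameter. At least one must be nonzero.
#' @param intercept Cost difference when all parameters are zero.
#' @param seed Seed for the random parameter bases.
#' @param base_range Range the parameter bases are drawn from (unit-width
#'   low/high ranges are centred on each base).
#' @return List with `model` (a `cea_model`), `delta_cost_fn(values)` (the
#'   closed form), `threshold_fn(parameter)` (analytic break-even with the
#'   other parameters at base) and `swing_fn(parameter)`.
#' @examples
#' g <- gen_linear_model(c(x = -2), intercept = 100, seed = 1)
#' g$threshold_fn("x")  # 50
#' @export
gen_linear_model <- function(coefficients, intercept = 0, seed = 1L,
                             base_range = c(1, 9)) {
  if (length(coefficients) == 0L || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop("coefficients must be a named numeric vector", call. = FALSE)
  }
  if (all(coefficients == 0)) {
    stop("at least one coefficient must be nonzero", call. = FALSE)
  }
  set.seed(seed)
  nms <- names(coefficients)
  bases <- stats::runif(length(coefficients), base_range[1], base_range[2])
  names(bases) <- nms
  params <- lapply(nms, function(nm) {
    new_parameter(nm, base = bases[[nm]], low = bases[[nm]] - 0.5,
                  high = bases[[nm]] + 0.5, role = "count")
  })
  terms <- paste(
    vapply(nms, function(nm) {
      paste0(format(coefficients[[nm]], digits = 17), " * ", nm)
    }, character(1)),
    collapse = " + ")
  alt_cost <- paste0(format(intercept, digits = 17), " + ", terms)
  tree <- decision_node("linear synthetic", strategies = list(
    alternative = terminal_node("alt", cost = alt_cost, effect = 0.6),
    reference = terminal_node("ref", cost = 0, effect = 0.4)
  ))
  model <- new_cea_model(params, tree, name = "linear_synthetic")

  delta_cost_fn <- function(values) {
    vals <- bases
    vals[names(values)] <- unlist(values)
    intercept + sum(coefficients * vals[nms])
  }
  threshold_fn <- function(parameter) {
    stopifnot(parameter %in% nms)
    cj <- coefficients[[parameter]]
    if (cj == 0) return(NA_real_)
    others <- setdiff(nms, parameter)
    -(intercept + sum(coefficients[others] * bases[others])) / cj
  }
  swing_fn <- function(parameter) {
    stopifnot(parameter %in% nms)
    abs(coefficients[[parameter]]) * 1  # unit-width low/high range
  }
  list(model = model, delta_cost_fn = delta_cost_fn,
       threshold_fn = threshold_fn, swing_fn = swing_fn, bases = bases)
}
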