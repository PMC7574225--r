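# Probabilistic sensitivity analysis: seeded joint sampling of parameters
# from point/uniform/triangular distributions, vectorised rollback of every
# draw, and cost-effectiveness plane summaries (quadrant proportions,
# centroid, net monetary benefit, acceptability curve).

#' Distribution specification for a parameter
#'
#' @param kind `"point"`, `"uniform"`, or `"triangular"`.
#' @param value Point mass location (kind `"point"`).
#' @param low,high Support endpoints (uniform/triangular; `low < high` for
#'   uniform, `low <= mode <= high` for triangular).
#' @param mode Mode of the triangular distribution.
#' @return A `dist_spec` list.
#' @examples
#' dist_spec("triangular", low = 2000, mode = 4635, high = 6000)
#' dist_spec("uniform", low = 0.55, high = 0.85)
#' @export
dist_spec <- function(kind = c("point", "uniform", "triangular"),
                      value = NULL, low = NULL, high = NULL, mode = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    point = {
      if (is.null(value)) stop("point distribution needs 'value'",
                               call. = FALSE)
      list(kind = "point", value = as.numeric(value))
    },
    uniform = {
      if (is.null(low) || is.null(high)) {
        stop("uniform distribution needs 'low' and 'high'", call. = FALSE)
      }
      if (!(low < high)) stop("uniform requires low < high", call. = FALSE)
      list(kind = "uniform", low = as.numeric(low), high = as.numeric(high))
    },
    triangular = {
      if (is.null(low) || is.null(mode) || is.null(high)) {
        stop("triangular distribution needs 'low', 'mode' and 'high'",
             call. = FALSE)
      }
      if (!(low <= mode && mode <= high)) {
        stop("triangular requires low <= mode <= high", call. = FALSE)
      }
      list(kind = "triangular", low = as.numeric(low),
           mode = as.numeric(mode), high = as.numeric(high))
    })
  class(out) <- "dist_spec"
  out
}

#' Coerce a plain list (e.g. from a model file) to a `dist_spec`
#' @param x A `dist_spec` or a list with a `kind` field.
#' @return A `dist_spec`.
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (!is.list(x) || is.null(x$kind)) {
    stop("distribution spec needs a 'kind' field", call. = FALSE)
  }
  dist_spec(x$kind, value = x$value, low = x$low, high = x$high,
            mode = x$mode)
}

.dist_support <- function(d) {
  switch(d$kind,
    point = c(d$value, d$value),
    uniform = c(d$low, d$high),
    triangular = c(d$low, d$high))
}

.dist_mean <- function(d) {
  switch(d$kind,
    point = d$value,
    uniform = (d$low + d$high) / 2,
    triangular = (d$low + d$mode + d$high) / 3)
}

.check_dist_bounds <- function(d, role, name) {
  s <- .dist_support(d)
  if (role == "probability" && (s[1] < 0 || s[2] > 1)) {
    stop("distribution for probability parameter '", name,
         "' must have support within [0, 1] (no clipping is applied)",
         call. = FALSE)
  }
  if (role %in% c("cost", "count") && s[1] < 0) {
    stop("distribution for ", role, " parameter '", name,
         "' must have non-negative support", call. = FALSE)
  }
  invisible(TRUE)
}

# Inverse-CDF triangular sampler (no triangular distribution in base R).
.qtri <- function(u, low, mode, high) {
  if (high == low) return(rep(low, length(u)))
  fc <- (mode - low) / (high - low)
  ifelse(u < fc,
         low + sqrt(u * (high - low) * (mode - low)),
         high - sqrt((1 - u) * (high - low) * (high - mode)))
}

.sample_dist <- function(d, n) {
  switch(d$kind,
    point = rep(d$value, n),
    uniform = stats::runif(n, d$low, d$high),
    triangular = .qtri(stats::runif(n), d$low, d$mode, d$high))
}

# One RNG sub-stream per parameter, derived from the root seed and the
# parameter's declaration index, so adding a parameter to a model does not
# perturb the draws of the ones already there. Derived seeds stay < 2^31.
.derive_seed <- function(seed, index) {
  (as.numeric(seed) %% 1e6) * 2048 + 7919 * index
}

#' Sample a parameter set for probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter vectors. Each parameter uses its own RNG
#' sub-stream derived from `seed` and its declaration index, so draws are
#' reproducible per-parameter and independent across parameters.
#'
#' @param model A `cea_model`.
#' @param dists Optional named list of [dist_spec()]s overriding (or
#'   supplying) per-parameter distributions; parameters without a spec here
#'   or in the model fall back to a point mass at base.
#' @param n Number of draws.
#' @param seed Integer root seed.
#' @return Named list of numeric vectors of length `n`, in declaration
#'   order.
#' @export
sample_parameters <- function(model, dists = NULL, n, seed) {
  stopifnot(inherits(model, "cea_model"), n >= 1)
  draws <- list()
  for (i in seq_along(model$parameters)) {
    p <- model$parameters[[i]]
    d <- if (!is.null(dists) && p$name %in% names(dists)) {
      as_dist_spec(dists[[p$name]])
    } else if (!is.null(p$dist)) {
      p$dist
    } else {
      dist_spec("point", value = p$base)
    }
    .check_dist_bounds(d, p$role, p$name)
    set.seed(.derive_seed(seed, i))
    draws[[p$name]] <- .sample_dist(d, n)
  }
  draws
}

#' Run a probabilistic sensitivity analysis
#'
#' Samples `n` joint parameter draws, rolls the tree back once (vectorised)
#' for both strategies of the comparison, and summarizes the cloud of
#' incremental (cost, effect) pairs on the cost-effectiveness plane.
#'
#' @param model A `cea_model`.
#' @param dists Optional distribution overrides, see [sample_parameters()].
#' @param n Number of iterations (the reference analysis uses 1000).
#' @param seed Integer root seed; results are reproducible given `(n, seed)`.
#' @param comparison Comparison pair, as in [incremental()].
#' @return An object of class `cea_psa`: `iterations`, `seed`, `pairs`
#'   (data frame `iteration`, `delta_cost`, `delta_effect`),
#'   `quadrant_proportions`, `centroid` (named vector) and the comparison
#'   labels.
#' @examples
#' m <- knee_oa_model()
#' p <- run_psa(m, n = 500, seed = 7)
#' p$centroid
#' @export
run_psa <- function(model, dists = NULL, n = 1000L, seed = 1L,
                    comparison = 1L) {
  stopifnot(n >= 1)
  pair <- resolve_comparison(model, comparison)
  draws <- sample_parameters(model, dists = dists, n = n, seed = seed)
  payoffs <- rollback(model$tree, draws)
  pn <- payoffs[[pair[["new"]]]]
  ps <- payoffs[[pair[["standard"]]]]
  delta_cost <- rep_len(pn$cost - ps$cost, n)
  delta_effect <- rep_len(pn$effect - ps$effect, n)
  structure(
    list(iterations = as.integer(n), seed = as.integer(seed),
         new = pair[["new"]], standard = pair[["standard"]],
         pairs = data.frame(iteration = seq_len(n), delta_cost = delta_cost,
                            delta_effect = delta_effect),
         quadrant_proportions = quadrant_summary(delta_cost, delta_effect),
         centroid = c(delta_cost = mean(delta_cost),
                      delta_effect = mean(delta_effect))),
    class = "cea_psa"
  )
}

#' Quadrant proportions on the cost-effectiveness plane
#'
#' Counts incremental pairs per sign pattern and divides by the total.
#' Quadrants follow the plane convention (x = incremental effect,
#' y = incremental cost): `NE` more effective & more costly, `SE` more
#' effective & less costly (dominant), `NW` less effective & more costly
#' (dominated), `SW` less effective & less costly. Pairs with an exactly
#' zero component fall into the boundary categories `zero_cost`,
#' `zero_effect` or `origin` (measure-zero for continuous distributions).
#'
#' @param delta_cost,delta_effect Equal-length numeric vectors.
#' @return Named numeric vector of proportions over
#'   `c(NE, NW, SE, SW, zero_cost, zero_effect, origin)`; sums to 1.
#' @examples
#' quadrant_summary(c(1, -1), c(1, -1))
#' @export
quadrant_summary <- function(delta_cost, delta_effect) {
  if (length(delta_cost) == 0L || length(delta_cost) != length(delta_effect)) {
    stop("delta_cost and delta_effect must be non-empty and equal length",
         call. = FALSE)
  }
  sc <- sign(delta_cost); se <- sign(delta_effect)
  lab <- character(length(sc))
  lab[sc > 0 & se > 0] <- "NE"
  lab[sc > 0 & se < 0] <- "NW"
  lab[sc < 0 & se > 0] <- "SE"
  lab[sc < 0 & se < 0] <- "SW"
  lab[sc == 0 & se != 0] <- "zero_cost"
  lab[sc != 0 & se == 0] <- "zero_effect"
  lab[sc == 0 & se == 0] <- "origin"
  levels <- c("NE", "NW", "SE", "SW", "zero_cost", "zero_effect", "origin")
  counts <- table(factor(lab, levels = levels))
  out <- as.numeric(counts) / length(lab)
  names(out) <- levels
  out
}

#' Net monetary benefit
#'
#' `NMB(lambda) = lambda * delta_effect - delta_cost`. For a positive
#' incremental effect, `NMB > 0` at willingness-to-pay `lambda` is
#' equivalent to `ICER < lambda`.
#'
#' @param wtp Willingness to pay (USD per unit effect size), non-negative.
#' @param delta_cost,delta_effect Incremental cost (USD) and effect.
#' @return Numeric vector of net monetary benefit in USD.
#' @examples
#' net_monetary_benefit(50000, 2359, 0.13)  # 4141
#' @export
net_monetary_benefit <- function(wtp, delta_cost, delta_effect) {
  stopifnot(is.numeric(wtp))
  if (any(wtp < 0)) stop("willingness to pay must be non-negative",
                         call. = FALSE)
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with positive net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param psa A `cea_psa` result.
#' @param wtp Numeric vector of willingness-to-pay values (USD per unit
#'   effect size).
#' @return Data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp) {
  stopifnot(inherits(psa, "cea_psa"), is.numeric(wtp))
  prob <- vapply(wtp, function(l) {
    mean(net_monetary_benefit(l, psa$pairs$delta_cost,
                              psa$pairs$delta_effect) > 0)
  }, numeric(1))
  data.frame(wtp = wtp, prob_cost_effective = prob)
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("PSA: %s vs %s, %d iterations (seed %d)\n", x$new, x$standard,
              x$iterations, x$seed))
  cat(sprintf("  centroid: delta cost = %.2f USD, delta effect = %.4f\n",
              x$centroid[["delta_cost"]], x$centroid[["delta_effect"]]))
  q <- x$quadrant_proportions
  q <- q[q > 0]
  cat("  quadrants:", paste(sprintf("%s %.1f%%", names(q), 100 * q),
                            collapse = ", "), "\n")
  invisible(x)
}
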