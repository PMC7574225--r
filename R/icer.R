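#' Incremental cost-effectiveness ratio
#'
#' ICER = (cost of the new strategy minus cost of the standard strategy)
#' divided by (effectiveness of the new strategy minus effectiveness of the
#' standard strategy), in USD per unit of effect size. Undefined when the
#' two strategies are equally effective; dominance or cost-minimization
#' should be reported instead, and this function stops with that advice.
#'
#' @param cost_new,cost_std Expected costs (USD) of the new and standard
#'   strategies.
#' @param eff_new,eff_std Expected effectiveness (dimensionless effect size).
#' @return Full-precision ICER (USD per unit effect size). Use
#'   [truncate_dollars()] for the whole-dollar reporting convention.
#' @examples
#' compute_icer(8641, 6282, 0.52, 0.39)           # 18146.15...
#' truncate_dollars(compute_icer(8641, 6282, 0.52, 0.39))
#' @seealso [classify_dominance()], [net_monetary_benefit()]
#' @export
compute_icer <- function(cost_new, cost_std, eff_new, eff_std) {
  stopifnot(is.numeric(cost_new), is.numeric(cost_std),
            is.numeric(eff_new), is.numeric(eff_std))
  if (any(eff_new == eff_std)) {
    stop("ICER is undefined when the strategies are equally effective ",
         "(delta effect = 0); report dominance or compare costs directly",
         call. = FALSE)
  }
  (cost_new - cost_std) / (eff_new - eff_std)
}

#' Truncate a dollar amount toward zero
#'
#' Reporting convention for ICERs: whole dollars, truncated toward zero
#' (e.g. 18146.15 -> 18146; 15576.67 -> 15576). Full precision should be
#' kept internally and truncated only for presentation.
#'
#' @param x Numeric vector of dollar amounts.
#' @return `x` truncated toward zero to whole dollars.
#' @export
truncate_dollars <- function(x) trunc(x)

#' Classify an incremental (cost, effect) pair
#'
#' Maps the sign pattern of the incremental pair — new strategy minus
#' standard — onto the cost-effectiveness plane:
#'
#' * `dominant` — cheaper and more effective (Δcost < 0, Δeffect > 0);
#' * `dominated` — costlier and less effective;
#' * `NE` — costlier and more effective (the usual trade-off quadrant);
#' * `SW` — cheaper and less effective;
#' * `equal_cost` — Δcost exactly 0, effects differ;
#' * `equal_effect` — Δeffect exactly 0, costs differ;
#' * `equal` — both components exactly 0.
#'
#' Exact zeroes get dedicated categories rather than being folded into a
#' quadrant, so the classification is exhaustive and mutually exclusive
#' over all nine sign patterns.
#'
#' @param delta_cost,delta_effect Numeric vectors (recycled to a common
#'   length) of incremental cost (USD) and effect.
#' @return Character vector of classifications.
#' @examples
#' classify_dominance(2359, 0.13)   # "NE"
#' classify_dominance(-1, 0.1)      # "dominant"
#' @export
classify_dominance <- function(delta_cost, delta_effect) {
  n <- max(length(delta_cost), length(delta_effect))
  delta_cost <- rep_len(delta_cost, n)
  delta_effect <- rep_len(delta_effect, n)
  out <- character(n)
  sc <- sign(delta_cost); se <- sign(delta_effect)
  out[sc == 0 & se == 0] <- "equal"
  out[sc == 0 & se != 0] <- "equal_cost"
  out[sc != 0 & se == 0] <- "equal_effect"
  out[sc < 0 & se > 0] <- "dominant"
  out[sc > 0 & se < 0] <- "dominated"
  out[sc > 0 & se > 0] <- "NE"
  out[sc < 0 & se < 0] <- "SW"
  out
}

#' Convert a Medicare payment rate to a commercial rate
#'
#' Medicare rates are taken to be 75% of the commercial private-payer rate,
#' so the commercial rate is the Medicare rate divided by 0.75 (the exact
#' ratio; the familiar "x 1.33" multiplier is this ratio rounded to cents).
#'
#' @param medicare_rate Non-negative payment rate(s) in USD.
#' @return Commercial-equivalent rate(s) in USD.
#' @examples
#' commercial_rate(75)    # 100
#' round(commercial_rate(1), 2)  # 1.33
#' @export
commercial_rate <- function(medicare_rate) {
  stopifnot(is.numeric(medicare_rate))
  if (any(medicare_rate < 0)) {
    stop("medicare_rate must be non-negative", call. = FALSE)
  }
  medicare_rate / 0.75
}

#' Incremental comparison of two strategies
#'
#' Rolls back the model at given parameter values (base case by default) and
#' forms the incremental result for one comparison pair: Δcost, Δeffect,
#' full-precision and truncated ICER, and the dominance classification. The
#' ICER is `NA` when Δeffect is zero.
#'
#' @param model A `cea_model`.
#' @param comparison Either an index into `model$comparisons` or a character
#'   vector `c(new, standard)` of strategy labels.
#' @param values Optional named list of parameter values; defaults to the
#'   base case.
#' @return An object of class `cea_increment`.
#' @examples
#' m <- knee_oa_model()
#' incremental(m)                 # SAM vs SOC, base case
#' incremental(m, comparison = 2) # later-stage pathway pair
#' @export
incremental <- function(model, comparison = 1L, values = NULL) {
  stopifnot(inherits(model, "cea_model"))
  pair <- resolve_comparison(model, comparison)
  if (is.null(values)) values <- base_values(model)
  payoffs <- rollback(model$tree, values)
  pn <- payoffs[[pair[["new"]]]]
  ps <- payoffs[[pair[["standard"]]]]
  delta_cost <- pn$cost - ps$cost
  delta_effect <- pn$effect - ps$effect
  icer <- ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
  structure(
    list(new = pair[["new"]], standard = pair[["standard"]],
         cost_new = pn$cost, cost_std = ps$cost,
         effect_new = pn$effect, effect_std = ps$effect,
         delta_cost = delta_cost, delta_effect = delta_effect,
         icer = icer, icer_truncated = truncate_dollars(icer),
         classification = classify_dominance(delta_cost, delta_effect)),
    class = "cea_increment"
  )
}

resolve_comparison <- function(model, comparison) {
  strategies <- names(model$tree$strategies)
  if (is.numeric(comparison)) {
    if (comparison < 1L || comparison > length(model$comparisons)) {
      stop("model declares ", length(model$comparisons),
           " comparison(s); index ", comparison, " out of range",
           call. = FALSE)
    }
    pair <- model$comparisons[[comparison]]
  } else if (is.character(comparison) && length(comparison) == 2L) {
    pair <- list(new = comparison[[1L]], standard = comparison[[2L]])
  } else {
    stop("comparison must be an index or c(new, standard) labels",
         call. = FALSE)
  }
  missing <- setdiff(unlist(pair), strategies)
  if (length(missing) > 0L) {
    stop("unknown strategy label(s): ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
  c(new = pair$new, standard = pair$standard)
}

#' @export
print.cea_increment <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s\n", x$new, x$standard))
  cat(sprintf("  %-14s cost = %10.2f   effect = %6.4f\n", x$new,
              x$cost_new[1], x$effect_new[1]))
  cat(sprintf("  %-14s cost = %10.2f   effect = %6.4f\n", x$standard,
              x$cost_std[1], x$effect_std[1]))
  cat(sprintf("  delta cost   = %10.2f USD\n", x$delta_cost[1]))
  cat(sprintf("  delta effect = %10.4f\n", x$delta_effect[1]))
  if (is.na(x$icer[1])) {
    cat("  ICER undefined (equal effectiveness); classification: ",
        x$classification[1], "\n", sep = "")
  } else {
    cat(sprintf("  ICER = %.2f USD per unit effect (reported: $%d)\n",
                x$icer[1], as.integer(x$icer_truncated[1])))
    cat("  classification: ", x$classification[1], "\n", sep = "")
  }
  invisible(x)
}
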