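# Restricted arithmetic expression language for branch probabilities and
# terminal payoffs: +, -, * (unary minus allowed), numeric constants and
# parameter references. Deliberately no division, powers or function calls --
# linear cost accumulation (device price + per-session cost x session count)
# is all a sequential-therapy tree needs, and the restriction keeps model
# files auditable and rollback differentiable by inspection.

.allowed_ops <- c("+", "-", "*", "(")

#' Parse a model expression
#'
#' Parses a probability or payoff expression from a model file and verifies
#' that it only uses the restricted arithmetic grammar: addition, subtraction,
#' multiplication, parentheses, numeric constants and parameter names.
#'
#' @param x A single character string (e.g. `"1 - p_success"`,
#'   `"device_cost + pt_cost * n_sessions"`) or a numeric scalar.
#' @return An object of class `model_expr`: the parsed R expression with the
#'   original source text attached.
#' @examples
#' parse_model_expr("device_cost + 41.80 * n_sessions")
#' parse_model_expr(0.5)
#' @export
parse_model_expr <- function(x) {
  if (inherits(x, "model_expr")) {
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    e <- as.numeric(x)
    out <- list(expr = e, text = format(x, digits = 17L))
    class(out) <- "model_expr"
    return(out)
  }
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("model expressions must be a single string or a numeric scalar, got: ",
         deparse(substitute(x)), call. = FALSE)
  }
  parsed <- tryCatch(parse(text = x, keep.source = FALSE),
                     error = function(e) {
                       stop("cannot parse model expression '", x, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
  if (length(parsed) != 1L) {
    stop("model expression must be a single expression: '", x, "'",
         call. = FALSE)
  }
  e <- parsed[[1L]]
  .check_expr_ast(e, source = x)
  out <- list(expr = e, text = x)
  class(out) <- "model_expr"
  out
}

.check_expr_ast <- function(e, source) {
  if (is.numeric(e) || is.name(e)) {
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% .allowed_ops) {
      stop("operator or function '", op, "' is not allowed in model ",
           "expression '", source, "' (allowed: +, -, *, parentheses, ",
           "numbers, parameter names)", call. = FALSE)
    }
    for (i in seq_along(e)[-1L]) .check_expr_ast(e[[i]], source)
    return(invisible(TRUE))
  }
  stop("disallowed token '", deparse(e), "' in model expression '", source,
       "'", call. = FALSE)
}

#' @export
print.model_expr <- function(x, ...) {
  cat("<model_expr> ", x$text, "\n", sep = "")
  invisible(x)
}

#' List the parameter names referenced by a model expression
#'
#' @param x A `model_expr` (or something [parse_model_expr()] accepts).
#' @return Character vector of parameter names (empty for constants).
#' @export
expr_parameters <- function(x) {
  x <- parse_model_expr(x)
  if (is.numeric(x$expr)) character(0) else all.vars(x$expr)
}

#' Evaluate a model expression against parameter values
#'
#' Values may be scalars or equal-length vectors (one element per Monte-Carlo
#' draw); the expression is evaluated element-wise, which is what makes a
#' whole probabilistic sensitivity analysis a single vectorised rollback.
#'
#' @param x A `model_expr` or expression source.
#' @param values Named list (or named numeric vector) of parameter values.
#' @return Numeric scalar or vector.
#' @export
eval_model_expr <- function(x, values) {
  x <- parse_model_expr(x)
  if (is.numeric(x$expr)) {
    return(x$expr)
  }
  needed <- all.vars(x$expr)
  missing <- setdiff(needed, names(values))
  if (length(missing) > 0L) {
    stop("unbound parameter(s) ", paste0("'", missing, "'", collapse = ", "),
         " in expression '", x$text, "'", call. = FALSE)
  }
  eval(x$expr, envir = as.list(values), enclos = baseenv())
}
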