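# Model files are YAML with three sections:
#
#   name, horizon                       (optional metadata)
#   parameters: [{name, base, low, high, role, dist: {kind, low, mode, high},
#                 note}]
#   tree: nested nodes --
#     decision: {kind: decision, label, strategies: [{label, node}]}
#     chance:   {kind: chance, label, branches: [{prob, node}]}
#     terminal: {kind: terminal, label, cost, effect}
#   comparisons: [{new, standard}]      (optional; defaults to first two
#                                        strategies)
#
# Probabilities, costs and effects are expressions in the restricted
# arithmetic language (see parse_model_expr). read_model() validates the
# whole structure and reports the failing path in its error messages.

#' Read a model definition file
#'
#' @param path Path to a YAML model file (see the package vignette for the
#'   format).
#' @return A validated `cea_model`.
#' @examples
#' path <- system.file("extdata", "knee_oa_2020.yaml", package = "ceatree")
#' m <- read_model(path)
#' evaluate_strategies(m)
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  model_from_list(raw, source = path)
}

#' Build a model from a plain-list representation
#'
#' The list form mirrors the YAML file structure; [read_model()] is
#' `model_from_list(yaml::read_yaml(path))`.
#'
#' @param raw Nested list as produced by parsing a model file.
#' @param source Label used in error messages.
#' @return A validated `cea_model`.
#' @export
model_from_list <- function(raw, source = "model definition") {
  fail <- function(path, msg) {
    stop("invalid ", source, " at ", path, ": ", msg, call. = FALSE)
  }
  if (!is.list(raw)) fail("$", "top level must be a mapping")
  if (is.null(raw$parameters)) fail("$parameters", "section missing")
  if (is.null(raw$tree)) fail("$tree", "section missing")

  params <- lapply(seq_along(raw$parameters), function(i) {
    p <- raw$parameters[[i]]
    at <- paste0("$parameters[[", i, "]]")
    if (!is.list(p) || is.null(p$name)) fail(at, "needs a 'name'")
    for (f in c("base", "role")) {
      if (is.null(p[[f]])) fail(paste0(at, " (", p$name, ")"),
                                paste0("needs '", f, "'"))
    }
    tryCatch(
      new_parameter(p$name, base = p$base,
                    low = if (is.null(p$low)) p$base else p$low,
                    high = if (is.null(p$high)) p$base else p$high,
                    role = p$role, dist = p$dist, note = p$note),
      error = function(e) fail(paste0(at, " (", p$name, ")"),
                               conditionMessage(e))
    )
  })

  tree <- .node_from_list(raw$tree, path = "$tree", fail = fail)
  comparisons <- raw$comparisons
  if (!is.null(comparisons)) {
    comparisons <- lapply(comparisons, function(cmp) {
      if (!is.list(cmp) || is.null(cmp$new) || is.null(cmp$standard)) {
        fail("$comparisons", "each entry needs 'new' and 'standard'")
      }
      list(new = cmp$new, standard = cmp$standard)
    })
  }
  new_cea_model(parameters = params, tree = tree, comparisons = comparisons,
                name = if (is.null(raw$name)) "model" else raw$name,
                horizon = raw$horizon)
}

.node_from_list <- function(x, path, fail) {
  if (!is.list(x) || is.null(x$kind)) {
    fail(path, "node needs a 'kind' (decision/chance/terminal)")
  }
  label <- if (is.null(x$label)) x$kind else x$label
  switch(as.character(x$kind),
    terminal = {
      if (is.null(x$cost) || is.null(x$effect)) {
        fail(path, paste0("terminal '", label, "' needs 'cost' and 'effect'"))
      }
      tryCatch(terminal_node(label, cost = x$cost, effect = x$effect),
               error = function(e) fail(path, conditionMessage(e)))
    },
    chance = {
      if (is.null(x$branches) || length(x$branches) == 0L) {
        fail(path, paste0("chance '", label, "' needs non-empty 'branches'"))
      }
      probs <- list(); branches <- list()
      for (i in seq_along(x$branches)) {
        b <- x$branches[[i]]
        bp <- paste0(path, "$branches[[", i, "]]")
        if (is.null(b$prob)) fail(bp, "chance branch needs 'prob'")
        if (is.null(b$node)) fail(bp, "chance branch needs 'node'")
        probs[[i]] <- tryCatch(parse_model_expr(b$prob),
                               error = function(e) fail(bp, conditionMessage(e)))
        branches[[i]] <- .node_from_list(b$node, paste0(bp, "$node"), fail)
      }
      chance_node(label, branches = branches, probs = probs)
    },
    decision = {
      if (is.null(x$strategies) || length(x$strategies) == 0L) {
        fail(path, "decision node needs non-empty 'strategies'")
      }
      strat <- list()
      for (i in seq_along(x$strategies)) {
        s <- x$strategies[[i]]
        sp <- paste0(path, "$strategies[[", i, "]]")
        if (is.null(s$label)) fail(sp, "strategy needs a 'label'")
        if (is.null(s$node)) fail(sp, "strategy needs a 'node'")
        strat[[s$label]] <- .node_from_list(s$node, paste0(sp, "$node"), fail)
      }
      decision_node(label, strategies = strat)
    },
    fail(path, paste0("unknown node kind '", x$kind, "'"))
  )
}

#' Write a model definition file
#'
#' Serializes a `cea_model` back to the YAML format read by [read_model()];
#' reading the written file reproduces the model (expressions round-trip as
#' their source text, numeric fields at full precision).
#'
#' @param model A `cea_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cea_model"))
  raw <- list(name = model$name)
  if (!is.null(model$horizon)) raw$horizon <- model$horizon
  raw$parameters <- lapply(model$parameters, function(p) {
    out <- list(name = p$name, base = p$base, low = p$low, high = p$high,
                role = p$role)
    if (!is.null(p$dist)) out$dist <- unclass(p$dist)
    if (!is.null(p$note)) out$note <- p$note
    out
  })
  raw$tree <- .node_to_list(model$tree)
  raw$comparisons <- model$comparisons
  yaml::write_yaml(raw, path, precision = 17L)
  invisible(path)
}

.node_to_list <- function(node) {
  switch(node$kind,
    terminal = list(kind = "terminal", label = node$label,
                    cost = node$payoff$cost$text,
                    effect = node$payoff$effect$text),
    chance = list(kind = "chance", label = node$label,
                  branches = lapply(seq_along(node$branches), function(i) {
                    list(prob = node$probs[[i]]$text,
                         node = .node_to_list(node$branches[[i]]))
                  })),
    decision = list(kind = "decision", label = node$label,
                    strategies = lapply(names(node$strategies), function(nm) {
                      list(label = nm,
                           node = .node_to_list(node$strategies[[nm]]))
                    }))
  )
}
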