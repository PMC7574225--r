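# Shared fixtures, built in code.

# Two-strategy model whose incremental cost is exactly 100 - 2x.
toy_linear_100_minus_2x <- function() {
  gen_linear_model(c(x = -2), intercept = 100, seed = 101)
}

# Minimal two-branch chance arm used by expression/tree unit tests.
coin_tree <- function(p = 0.5, a = c(100, 0.2), b = c(300, 0.4)) {
  chance_node("toss",
              branches = list(terminal_node("a", a[1], a[2]),
                              terminal_node("b", b[1], b[2])),
              probs = list(p, if (is.character(p)) paste("1 -", p) else 1 - p))
}

# Symmetric triangular specs centred at each base value, half-width the
# largest symmetric range inside [low, high]; point-mass parameters are
# left alone.
symmetric_triangular_specs <- function(model) {
  specs <- list()
  for (p in model$parameters) {
    h <- min(p$base - p$low, p$high - p$base)
    if (h > 0) {
      specs[[p$name]] <- dist_spec("triangular", low = p$base - h,
                                   mode = p$base, high = p$base + h)
    } else {
      specs[[p$name]] <- dist_spec("point", value = p$base)
    }
  }
  specs
}
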