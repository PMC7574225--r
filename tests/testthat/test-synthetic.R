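test_that("depth-1 generation yields a single terminal whose oracle is its payoff", {
  g <- gen_tree(depth = 1, seed = 5)
  expect_equal(g$node$kind, "terminal")
  expect_equal(g$n_paths, 1L)
  rb <- rollback(g$node, list())
  expect_equal(rb$cost, g$oracle$cost)
  expect_equal(rb$effect, g$oracle$effect)
})

test_that("generation is deterministic given the seed", {
  a <- gen_tree(depth = 3, branching = 3, seed = 77)
  b <- gen_tree(depth = 3, branching = 3, seed = 77)
  expect_identical(a, b)
  c <- gen_tree(depth = 3, branching = 3, seed = 78)
  expect_false(identical(a$oracle, b$oracle) && identical(a, c))
})

test_that("generated chance-node probabilities sum to one within 1e-12", {
  check_sums <- function(node) {
    if (node$kind == "chance") {
      s <- sum(vapply(node$probs, function(p) p$expr, numeric(1)))
      expect_lt(abs(s - 1), 1e-12)
      lapply(node$branches, check_sums)
    }
    invisible(NULL)
  }
  for (seed in 1:10) check_sums(gen_tree(depth = 4, seed = seed)$node)
})

test_that("oracle path totals account for the whole probability mass", {
  for (seed in 1:10) {
    g <- gen_tree(depth = 3, seed = seed)
    en <- enumerate_paths(g$node)
    expect_equal(en$total_prob, 1, tolerance = 1e-12)
    expect_gte(en$n_paths, 1L)
  }
})

test_that("generated payoffs respect the requested ranges", {
  g <- gen_tree(depth = 3, seed = 12, cost_range = c(100, 200),
                effect_range = c(0.4, 0.6))
  leaves <- function(node) {
    if (node$kind == "terminal") return(list(node))
    unlist(lapply(node$branches, leaves), recursive = FALSE)
  }
  for (lf in leaves(g$node)) {
    cost <- lf$payoff$cost$expr
    effect <- lf$payoff$effect$expr
    expect_true(cost >= 100 && cost <= 200)
    expect_true(effect >= 0.4 && effect <= 0.6)
  }
})

test_that("linear-model generation exposes exact closed forms", {
  g <- gen_linear_model(c(x = -2), intercept = 100, seed = 1)
  expect_equal(g$threshold_fn("x"), 50)
  expect_equal(g$swing_fn("x"), 2)
  inc <- incremental(g$model)
  expect_equal(inc$delta_cost, g$delta_cost_fn(list()), tolerance = 1e-12)

  g2 <- gen_linear_model(c(a = 2, b = -5), intercept = 0, seed = 2)
  expect_equal(g2$swing_fn("a"), 2)
  expect_equal(g2$swing_fn("b"), 5)
})

test_that("degenerate coefficient sets are rejected", {
  expect_error(gen_linear_model(c(x = 0)), "nonzero")
  expect_error(gen_linear_model(numeric(0)), "named")
  expect_error(gen_linear_model(c(1, 2)), "named")
})
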