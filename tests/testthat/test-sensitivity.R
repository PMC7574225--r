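test_that("sweeping an unreferenced parameter gives constant incrementals", {
  g <- toy_linear_100_minus_2x()
  m <- g$model
  # add a parameter no strategy references
  m2 <- new_cea_model(c(m$parameters,
                        list(new_parameter("idle", 5, 0, 10, "count"))),
                      m$tree, m$comparisons, name = m$name)
  sw <- sweep_parameter(m2, "idle", c(0, 5, 10))
  expect_equal(length(unique(sw$delta_cost)), 1L)
  expect_equal(length(unique(sw$delta_effect)), 1L)
})

test_that("sweep recovers a linear closed-form cost difference", {
  g <- toy_linear_100_minus_2x()
  sw <- sweep_parameter(g$model, "x", c(0, 50, 100))
  expect_equal(sw$delta_cost, c(100, 0, -100))
})

test_that("sweep at the base value reproduces the base-case increment exactly", {
  m <- knee_oa_model()
  base_inc <- incremental(m)
  for (nm in c("sam_device_cost", "pt_session_cost", "p_sam_success")) {
    b <- base_values(m)[[nm]]
    sw <- sweep_parameter(m, nm, b)
    expect_identical(sw$delta_cost, base_inc$delta_cost)
    expect_identical(sw$delta_effect, base_inc$delta_effect)
  }
})

test_that("sweep validates its inputs", {
  m <- knee_oa_model()
  expect_error(sweep_parameter(m, "no_such", c(1, 2)), "unknown parameter")
  expect_error(sweep_parameter(m, "p_sam_success", numeric(0)), "empty")
  expect_error(sweep_parameter(m, "p_sam_success", c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bisection matches analytic roots of linear models to a cent", {
  set.seed(7)
  for (i in 1:20) {
    coef <- round(runif(1, -8, 8), 2)
    if (abs(coef) < 0.1) coef <- 1.5
    icpt <- round(runif(1, -300, 300), 2)
    g <- gen_linear_model(c(x = coef), intercept = icpt, seed = i)
    root <- g$threshold_fn("x")
    bracket <- sort(c(root - 57, root + 43))
    th <- find_threshold(g$model, "x", bracket)
    expect_equal(th$threshold, root, tolerance = 0.01 / abs(coef) + 1e-8)
    expect_lte(abs(th$delta_cost_at_threshold), 0.01)
    expect_true(th$bracket[1] <= th$threshold && th$threshold <= th$bracket[2])
  }
})

test_that("threshold direction reflects which side makes the new strategy cheaper", {
  g <- toy_linear_100_minus_2x()  # delta cost falls in x
  th <- find_threshold(g$model, "x", c(0, 100))
  expect_equal(th$threshold, 50, tolerance = 0.01)
  expect_equal(th$direction, "above_makes_new_cheaper")

  g2 <- gen_linear_model(c(x = 2), intercept = -100, seed = 3)
  th2 <- find_threshold(g2$model, "x", c(0, 100))
  expect_equal(th2$direction, "below_makes_new_cheaper")
})

test_that("a bracket with no sign change is a reported error", {
  g <- gen_linear_model(c(x = 0, y = 1), intercept = 100, seed = 5)
  # delta cost does not depend on x, so no root in x
  expect_error(find_threshold(g$model, "x", c(0, 100)), "same sign")
})

test_that("tornado swings equal |coefficient| x range on linear models", {
  g <- gen_linear_model(c(a = 2, b = -5), intercept = 10, seed = 11)
  tor <- tornado(g$model)
  expect_equal(tor$parameter, c("b", "a"))  # |−5| outranks |2|
  expect_equal(tor$swing, c(5, 2), tolerance = 1e-9)
})

test_that("tornado swing is invariant under reversal of low/high and degenerate for fixed parameters", {
  m <- knee_oa_model()
  tor <- tornado(m)
  # invariance: swing is |delta(high) - delta(low)|, recompute reversed
  for (i in seq_len(nrow(tor))) {
    expect_equal(tor$swing[i],
                 abs(tor$delta_cost_at_low[i] - tor$delta_cost_at_high[i]))
  }
  # a low = high parameter has zero swing
  tor0 <- tornado(m, parameters = "pt_util_sam")
  expect_equal(tor0$swing, 0)
})

test_that("tornado breaks swing ties alphabetically", {
  g <- gen_linear_model(c(zeta = 3, alpha = -3), intercept = 0, seed = 13)
  tor <- tornado(g$model)
  expect_equal(tor$parameter, c("alpha", "zeta"))
})
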