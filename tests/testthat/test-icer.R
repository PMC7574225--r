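test_that("ICER reproduces the published pathway values after truncation", {
  expect_equal(truncate_dollars(compute_icer(8641, 6282, 0.52, 0.39)), 18146)
  expect_equal(truncate_dollars(compute_icer(13967, 9294, 0.77, 0.47)), 15576)
  # full precision is kept internally
  expect_equal(compute_icer(8641, 6282, 0.52, 0.39), 2359 / 0.13)
})

test_that("ICER handles zero incremental cost and behaves under perspective swaps", {
  expect_equal(compute_icer(5000, 5000, 0.6, 0.4), 0)
  set.seed(42)
  for (i in 1:50) {
    c1 <- runif(1, 0, 1e4); c2 <- runif(1, 0, 1e4)
    e1 <- runif(1); e2 <- runif(1)
    if (e1 == e2) next
    # reversing the whole comparison leaves the ratio unchanged ...
    expect_equal(compute_icer(c1, c2, e1, e2),
                 compute_icer(c2, c1, e2, e1))
    # ... while swapping only the cost arguments negates it
    expect_equal(compute_icer(c1, c2, e1, e2),
                 -compute_icer(c2, c1, e1, e2))
  }
})

test_that("equal effectiveness is an undefined-ICER error, not a number", {
  expect_error(compute_icer(100, 50, 0.4, 0.4), "dominance")
})

test_that("dominance classification covers all nine sign patterns exactly once", {
  expect_equal(classify_dominance(2359, 0.13), "NE")
  expect_equal(classify_dominance(-1, 0.1), "dominant")
  expect_equal(classify_dominance(1, -0.1), "dominated")
  expect_equal(classify_dominance(-1, -0.1), "SW")
  expect_equal(classify_dominance(0, 0), "equal")
  expect_equal(classify_dominance(0, 0.1), "equal_cost")
  expect_equal(classify_dominance(5, 0), "equal_effect")

  grid <- expand.grid(dc = c(-1, 0, 1), de = c(-0.1, 0, 0.1))
  cls <- classify_dominance(grid$dc, grid$de)
  expect_true(all(nzchar(cls)))                       # exhaustive
  expect_equal(length(unique(paste(sign(grid$dc), sign(grid$de)))),
               length(cls))                           # one label per pattern
  expect_length(cls, 9L)
})

test_that("Medicare-to-commercial conversion uses the exact 1/0.75 ratio", {
  expect_equal(commercial_rate(75), 100)
  expect_equal(commercial_rate(0), 0)
  expect_equal(round(commercial_rate(1), 2), 1.33)
  expect_error(commercial_rate(-1), "non-negative")
})

test_that("incremental() reports NA ICER and equal classification for identical arms", {
  tree <- decision_node("root", strategies = list(
    a = terminal_node("a", 100, 0.5),
    b = terminal_node("b", 100, 0.5)))
  m <- new_cea_model(list(), tree)
  inc <- incremental(m)
  expect_true(is.na(inc$icer))
  expect_equal(inc$classification, "equal")
})
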