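test_that("point-mass PSA reproduces the base case exactly, all mass in one quadrant", {
  m <- knee_oa_model()
  specs <- lapply(base_values(m), function(b) dist_spec("point", value = b))
  p <- run_psa(m, dists = specs, n = 10, seed = 3)
  base_inc <- incremental(m)
  expect_equal(unique(p$pairs$delta_cost), base_inc$delta_cost)
  expect_equal(unique(p$pairs$delta_effect), base_inc$delta_effect)
  expect_equal(unname(p$quadrant_proportions["NE"]), 1)
  expect_equal(unname(p$centroid),
               c(base_inc$delta_cost, base_inc$delta_effect))
})

test_that("the same seed and n reproduce an identical PSA result", {
  m <- knee_oa_model()
  a <- run_psa(m, n = 200, seed = 99)
  b <- run_psa(m, n = 200, seed = 99)
  expect_identical(a, b)
  c <- run_psa(m, n = 200, seed = 100)
  expect_false(identical(a$pairs, c$pairs))
})

test_that("per-parameter RNG streams are unchanged when a parameter is added", {
  g <- gen_linear_model(c(a = 2, b = -1), intercept = 5, seed = 21)
  m <- g$model
  d1 <- sample_parameters(m, dists = list(
    a = dist_spec("uniform", low = 0, high = 1),
    b = dist_spec("uniform", low = 0, high = 1)), n = 50, seed = 17)
  m2 <- new_cea_model(c(m$parameters,
                        list(new_parameter("c_new", 1, 0, 2, "count"))),
                      m$tree, m$comparisons, name = m$name)
  d2 <- sample_parameters(m2, dists = list(
    a = dist_spec("uniform", low = 0, high = 1),
    b = dist_spec("uniform", low = 0, high = 1),
    c_new = dist_spec("uniform", low = 0, high = 2)), n = 50, seed = 17)
  expect_identical(d1$a, d2$a)
  expect_identical(d1$b, d2$b)
})

test_that("quadrant proportions sum to one and match a brute-force recount", {
  m <- knee_oa_model()
  p <- run_psa(m, dists = symmetric_triangular_specs(m), n = 10000,
               seed = 2024)
  q <- p$quadrant_proportions
  expect_equal(sum(q), 1, tolerance = 1e-9)
  dc <- p$pairs$delta_cost; de <- p$pairs$delta_effect
  expect_equal(unname(q["NE"]), mean(dc > 0 & de > 0))
  expect_equal(unname(q["SE"]), mean(dc < 0 & de > 0))
  # permutation invariance
  idx <- sample(length(dc))
  expect_equal(quadrant_summary(dc[idx], de[idx]), q)
})

test_that("symmetric distributions centre the PSA cloud on the base-case increment", {
  m <- knee_oa_model()
  n <- 10000
  p <- run_psa(m, dists = symmetric_triangular_specs(m), n = n, seed = 31)
  se_cost <- sd(p$pairs$delta_cost) / sqrt(n)
  se_eff <- sd(p$pairs$delta_effect) / sqrt(n)
  expect_lt(abs(p$centroid[["delta_cost"]] - 2359), 3 * se_cost)
  expect_lt(abs(p$centroid[["delta_effect"]] - 0.13), 3 * se_eff)
})

test_that("a distribution violating a parameter's role bounds is rejected before sampling", {
  m <- knee_oa_model()
  bad <- list(p_sam_success = dist_spec("uniform", low = 0.5, high = 1.2))
  expect_error(run_psa(m, dists = bad, n = 10, seed = 1), "\\[0, 1\\]")
  bad2 <- list(sam_device_cost = dist_spec("triangular", low = -10,
                                           mode = 0, high = 10))
  expect_error(run_psa(m, dists = bad2, n = 10, seed = 1), "non-negative")
})

test_that("net monetary benefit matches its closed form and the ICER rule", {
  expect_equal(net_monetary_benefit(50000, 2359, 0.13), 4141)
  expect_equal(net_monetary_benefit(0, 123, 0.4), -123)
  expect_error(net_monetary_benefit(-1, 1, 1), "non-negative")

  set.seed(606)
  dc <- runif(1000, -5000, 5000)
  de <- runif(1000, 1e-4, 1)          # positive incremental effect
  wtp <- runif(1000, 0, 1e5)
  nmb_pos <- net_monetary_benefit(wtp, dc, de) > 0
  icer_below <- mapply(function(a, e, l) compute_icer(a, 0, e, 0) < l,
                       dc, de, wtp)
  expect_identical(nmb_pos, unname(icer_below))
})

test_that("the acceptability curve is non-decreasing when all effects are positive", {
  m <- knee_oa_model()
  # vary only the cost-side parameters so the incremental effect stays at
  # its (positive) base value in every iteration
  specs <- symmetric_triangular_specs(m)
  tab <- parameter_table(m$parameters)
  for (nm in tab$name[tab$role %in% c("probability", "effect")]) {
    specs[[nm]] <- dist_spec("point", value = base_values(m)[[nm]])
  }
  p <- run_psa(m, dists = specs, n = 2000, seed = 8)
  expect_true(all(p$pairs$delta_effect > 0))
  cv <- ceac(p, wtp = seq(0, 1e5, by = 5000))
  expect_true(all(diff(cv$prob_cost_effective) >= 0))
})
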