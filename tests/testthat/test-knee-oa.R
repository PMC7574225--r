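test_that("the calibrated model reproduces the published strategy totals", {
  m <- knee_oa_model()
  tab <- evaluate_strategies(m)
  targets <- knee_oa_targets()
  for (i in seq_len(nrow(tab))) {
    tgt <- targets[[tab$strategy[i]]]
    expect_lt(abs(tab$cost[i] - tgt[["cost"]]), 1)
    expect_lt(abs(tab$effect[i] - tgt[["effect"]]), 0.005)
  }
})

test_that("base-case and later-pathway increments match the published figures", {
  m <- knee_oa_model()
  inc1 <- incremental(m, 1)
  expect_lt(abs(inc1$delta_cost - 2359), 1)
  expect_lt(abs(inc1$delta_effect - 0.13), 0.005)
  expect_equal(inc1$icer_truncated, 18146)
  expect_equal(inc1$classification, "NE")

  inc2 <- incremental(m, 2)
  expect_lt(abs(inc2$delta_cost - 4673), 1)
  expect_lt(abs(inc2$delta_effect - 0.30), 0.005)
  expect_equal(inc2$icer_truncated, 15576)
})

test_that("the bundled model file and the programmatic builder agree", {
  from_file <- evaluate_strategies(knee_oa_model())
  from_code <- evaluate_strategies(build_knee_oa_model())
  expect_equal(from_file, from_code)
})

test_that("pricing the device at the break-even equalises the strategy costs", {
  m <- knee_oa_model()
  tab <- evaluate_strategies(m, overrides = list(sam_device_cost = 2276))
  costs <- setNames(tab$cost, tab$strategy)
  expect_lt(abs(costs[["SAM"]] - costs[["SOC"]]), 1)
})

test_that("device-price sweep shifts the cost difference dollar-for-dollar", {
  m <- knee_oa_model()
  sw <- sweep_parameter(m, "sam_device_cost", c(2000, 4635))
  expect_equal(sw$delta_cost, c(-276, 2359), tolerance = 1e-6)
})

test_that("published break-evens emerge from the calibrated model", {
  m <- knee_oa_model()
  expect_equal(round(find_threshold(m, "sam_device_cost",
                                    c(0, 4635))$threshold), 2276)
  expect_equal(round(find_threshold(m, "pt_session_cost",
                                    c(25, 200))$threshold), 88)
  expect_equal(round(find_threshold(m, "n_pt_sessions",
                                    c(48, 300))$threshold), 144)
})

test_that("the tornado ranks device price, PT session price, then session count", {
  m <- knee_oa_model()
  tor <- tornado(m)
  expect_equal(tor$parameter[1:3],
               c("sam_device_cost", "pt_session_cost", "n_pt_sessions"))
})

test_that("zero success probabilities collapse both arms to their escalation terminals", {
  m <- knee_oa_model()
  tab <- evaluate_strategies(m, overrides = list(p_sam_success = 0,
                                                 p_soc_success = 0))
  v <- base_values(m)
  v$p_sam_success <- 0; v$p_soc_success <- 0
  sam_fail <- rollback(m$tree$strategies[["SAM"]]$branches[[2]], v)
  expect_equal(tab$cost[tab$strategy == "SAM"], sam_fail$cost)
  expect_equal(tab$effect[tab$strategy == "SAM"], sam_fail$effect)
})

test_that("calibration is a fixed point and responds linearly to target shifts", {
  m0 <- build_knee_oa_model(calibrated = FALSE)
  m1 <- calibrate_model(m0, knee_oa_targets(), knee_oa_residual_params())
  cal1 <- attr(m1, "calibration")

  # recalibrating to the model's own rollback leaves all residuals unchanged
  tab <- evaluate_strategies(m1)
  own <- lapply(seq_len(nrow(tab)),
                function(i) c(cost = tab$cost[i], effect = tab$effect[i]))
  names(own) <- tab$strategy
  m2 <- calibrate_model(m1, own, knee_oa_residual_params())
  cal2 <- attr(m2, "calibration")
  expect_equal(cal2$value, cal1$value, tolerance = 1e-9)

  # +100 on one target cost shifts exactly that residual by +100
  bumped <- knee_oa_targets()
  bumped[["SAM"]]["cost"] <- bumped[["SAM"]]["cost"] + 100
  m3 <- calibrate_model(m0, bumped, knee_oa_residual_params())
  cal3 <- attr(m3, "calibration")
  pick <- function(cal, p) cal$value[cal$parameter == p]
  expect_equal(pick(cal3, "resid_cost_sam"),
               pick(cal1, "resid_cost_sam") + 100)
  expect_equal(pick(cal3, "resid_cost_soc"), pick(cal1, "resid_cost_soc"))
})

test_that("targets below the fixed stage costs are an infeasible-calibration error", {
  m0 <- build_knee_oa_model(calibrated = FALSE)
  bad <- knee_oa_targets()
  bad[["SAM"]]["cost"] <- 100   # below the device price alone
  expect_error(calibrate_model(m0, bad, knee_oa_residual_params()),
               "infeasible")
})

test_that("every reconstructed quantity is flagged in the bundled model file", {
  m <- knee_oa_model()
  tab <- parameter_table(m$parameters)
  recon <- grepl("reconstructed|calibrated", tab$note)
  # published anchors that need no flag
  anchors <- c("sam_device_cost", "pt_session_cost",
               "e_sam_pt_late", "e_soc_pt_late")
  expect_true(all(recon | tab$name %in% anchors))
})
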