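test_that("the base-case report carries both published comparisons", {
  bc <- run_base_case(knee_oa_model())
  expect_s3_class(bc, "cea_base_case")
  expect_equal(nrow(bc$strategies), 4L)
  expect_equal(vapply(bc$comparisons, `[[`, numeric(1), "icer_truncated"),
               c(18146, 15576))
  expect_output(print(bc), "18146")
})

test_that("the full analysis writes a complete, internally consistent bundle", {
  out <- withr::local_tempdir()
  res <- run_full_analysis(
    knee_oa_model(), out_dir = out, n = 400, seed = 11,
    wtp = c(50000, 100000),
    thresholds = list(sam_device_cost = c(0, 4635),
                      pt_session_cost = c(25, 200)))
  files <- c("base_case.json", "tornado.csv", "thresholds.csv", "psa.csv",
             "psa_summary.json", "model.yaml", "manifest.json")
  expect_true(all(file.exists(file.path(out, files))))

  thr <- read.csv(file.path(out, "thresholds.csv"))
  expect_equal(thr$threshold_dollars[thr$parameter == "sam_device_cost"],
               2276)

  summ <- jsonlite::read_json(file.path(out, "psa_summary.json"),
                              simplifyVector = TRUE)
  expect_equal(sum(unlist(summ$quadrant_proportions)), 1, tolerance = 1e-9)
  expect_equal(summ$iterations, 400)

  # JSON round-trips the base case at full precision
  bcj <- jsonlite::read_json(file.path(out, "base_case.json"),
                             simplifyVector = TRUE)
  expect_equal(bcj$comparisons$icer[1], res$base_case$comparisons[[1]]$icer,
               tolerance = 1e-12)

  # per-iteration CSV round-trips NMB within write precision
  psa_tab <- read.csv(file.path(out, "psa.csv"))
  expect_equal(nrow(psa_tab), 400)
  expect_equal(psa_tab$nmb_50000,
               net_monetary_benefit(50000, psa_tab$delta_cost,
                                    psa_tab$delta_effect),
               tolerance = 1e-6)
})

test_that("reruns with the same manifest inputs are byte-identical", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  m <- knee_oa_model()
  run_full_analysis(m, out_dir = out1, n = 100, seed = 5,
                    thresholds = list(sam_device_cost = c(0, 4635)))
  run_full_analysis(m, out_dir = out2, n = 100, seed = 5,
                    thresholds = list(sam_device_cost = c(0, 4635)))
  for (f in c("base_case.json", "tornado.csv", "thresholds.csv", "psa.csv",
              "psa_summary.json", "model.yaml")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  expect_identical(m1$model_md5, m2$model_md5)
  expect_identical(m1$seed, m2$seed)
})

test_that("a failing stage removes partial outputs", {
  out <- withr::local_tempdir()
  expect_error(run_full_analysis(
    knee_oa_model(), out_dir = out, n = 50, seed = 1,
    thresholds = list(escalation_cost = c(500, 1500))),  # no sign change
    "same sign")
  expect_false(any(file.exists(file.path(
    out, c("base_case.json", "tornado.csv", "psa.csv")))))
})
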