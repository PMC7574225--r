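# Reconstructed 6-month knee osteoarthritis model: sustained acoustic
# medicine (SAM, wearable long-duration therapeutic ultrasound) versus the
# standard-of-care (SOC) sequence of ACR-guideline conservative therapies.
#
# Published anchors used directly: SAM device price $4,635 (average
# reimbursement); physical therapy $41.80 per 15-minute session with 2-4
# sessions per visit; strategy totals (cost, effect size) of (8641, 0.52)
# for SAM vs (6282, 0.39) for SOC in the initial pathway and (13967, 0.77)
# vs (9294, 0.47) in the later-stage pathway. Everything else (stage-level
# success probabilities, per-stage effect sizes, PT utilization multipliers,
# residual arm costs) is a documented reconstruction calibrated so the
# rollback reproduces those totals; such parameters carry a
# "reconstructed"/"calibrated" note in the model file.

#' Published calibration targets for the knee OA model
#'
#' Expected (cost in USD, effect size) per strategy over the 6-month
#' horizon: initial pathway SAM (8641, 0.52) vs SOC (6282, 0.39), and
#' later-stage pathway SAM+PT (13967, 0.77) vs NSAID+PT (9294, 0.47).
#'
#' @return Named list of `c(cost, effect)` per strategy label.
#' @export
knee_oa_targets <- function() {
  list(
    "SAM" = c(cost = 8641, effect = 0.52),
    "SOC" = c(cost = 6282, effect = 0.39),
    "SAM+PT (later)" = c(cost = 13967, effect = 0.77),
    "NSAID+PT (later)" = c(cost = 9294, effect = 0.47)
  )
}

#' Residual-parameter map for calibrating the knee OA model
#'
#' @return Named list mapping each strategy to its residual cost/effect
#'   parameter names, in the form [calibrate_model()] expects.
#' @export
knee_oa_residual_params <- function() {
  list(
    "SAM" = list(cost = "resid_cost_sam", effect = "resid_effect_sam"),
    "SOC" = list(cost = "resid_cost_soc", effect = "resid_effect_soc"),
    "SAM+PT (later)" = list(cost = "resid_cost_sam_late", effect = NULL),
    "NSAID+PT (later)" = list(cost = "resid_cost_soc_late", effect = NULL)
  )
}

#' Build the knee osteoarthritis SAM-vs-SOC model programmatically
#'
#' Constructs the four-strategy decision tree (initial pathway SAM vs SOC,
#' later-stage pathway SAM+PT vs NSAID+PT) with its parameter set and, by
#' default, calibrates the per-arm residual constants against
#' [knee_oa_targets()]. The bundled model file
#' `system.file("extdata", "knee_oa_2020.yaml", package = "ceatree")` is
#' this function's calibrated output, and [knee_oa_model()] loads it.
#'
#' Reconstruction choices (full rationale in the package vignette):
#' * the SAM device price enters the SAM arms at certainty (coefficient 1),
#'   which is what makes the break-even device price equal base price minus
#'   base incremental cost;
#' * the net PT-utilization differential between the initial arms is fixed
#'   at 2359 / (88 - 41.80) ≈ 51.06 15-minute sessions so that the
#'   session-price break-even lands at $88/session; with 68.4 expected
#'   sessions at base (≈ 2.85 sessions/visit over 24 weekly visits, inside
#'   the published 2–4 per visit) the session-count break-even then lands
#'   at 144 sessions. These two break-evens are consistency checks of the
#'   reconstruction, not independent results.
#'
#' @param calibrated If `TRUE` (default), residual constants are solved via
#'   [calibrate_model()]; if `FALSE` they are left at 0 so the calibration
#'   step can be exercised explicitly.
#' @return A `cea_model` with comparisons `SAM vs SOC` (initial) and
#'   `SAM+PT (later) vs NSAID+PT (later)`.
#' @examples
#' m <- build_knee_oa_model()
#' evaluate_strategies(m)
#' @export
build_knee_oa_model <- function(calibrated = TRUE) {
  tri <- function(low, mode, high) dist_spec("triangular", low = low,
                                             mode = mode, high = high)
  unif <- function(low, high) dist_spec("uniform", low = low, high = high)

  # Net PT-session differential between arms chosen so the PT price
  # break-even is $88/session; base expected sessions 68.4 then puts the
  # session-count break-even at 144 (reconstructed, see vignette).
  base_delta_cost <- 8641 - 6282
  pt_util_sam <- 0.9
  pt_util_soc <- pt_util_sam + (base_delta_cost / (88 - 41.80)) / 68.4

  params <- list(
    new_parameter("sam_device_cost", 4635, 2000, 6000, "cost",
                  dist = tri(2000, 4635, 6000),
                  note = "average reimbursement price of the SAM unit"),
    new_parameter("pt_session_cost", 41.80, 25, 60, "cost",
                  dist = tri(25, 41.80, 60),
                  note = "cost per 15-min PT session"),
    new_parameter("n_pt_sessions", 68.4, 48, 96, "count",
                  dist = tri(48, 68.4, 96),
                  note = paste("expected 15-min PT sessions over 6 months;",
                               "2-4 sessions/visit (reconstructed)")),
    new_parameter("p_sam_success", 0.70, 0.55, 0.85, "probability",
                  dist = unif(0.55, 0.85),
                  note = "P(pain relief on SAM sufficient to start PT) (reconstructed)"),
    new_parameter("p_soc_success", 0.55, 0.40, 0.70, "probability",
                  dist = unif(0.40, 0.70),
                  note = "P(pain relief on first-line topical NSAID) (reconstructed)"),
    new_parameter("soc_first_line_cost", 240, 120, 360, "cost",
                  dist = tri(120, 240, 360),
                  note = "6-month topical NSAID supply + visits (reconstructed)"),
    new_parameter("escalation_cost", 900, 500, 1500, "cost",
                  dist = tri(500, 900, 1500),
                  note = "steroid/HA injections + visits for non-responders (reconstructed)"),
    new_parameter("e_sam_pt", 0.61, 0.45, 0.75, "effect",
                  dist = tri(0.45, 0.61, 0.75),
                  note = "effect size, SAM responder with PT (reconstructed)"),
    new_parameter("e_sam_no_pt", 0.31, 0.20, 0.42, "effect",
                  dist = tri(0.20, 0.31, 0.42),
                  note = "effect size, SAM non-responder (reconstructed)"),
    new_parameter("e_soc_pt", 0.48, 0.35, 0.61, "effect",
                  dist = tri(0.35, 0.48, 0.61),
                  note = "effect size, SOC responder with PT (reconstructed)"),
    new_parameter("e_soc_no_pt", 0.28, 0.18, 0.38, "effect",
                  dist = tri(0.18, 0.28, 0.38),
                  note = "effect size, SOC non-responder (reconstructed)"),
    new_parameter("pt_util_sam", pt_util_sam, role = "count",
                  note = "PT utilization multiplier, SAM arm (reconstructed)"),
    new_parameter("pt_util_soc", pt_util_soc, role = "count",
                  note = paste("PT utilization multiplier, SOC arm;",
                               "reverse-engineered from the $88 session-price",
                               "break-even (reconstructed)")),
    new_parameter("pt_util_sam_late", 2.0, role = "count",
                  note = "PT utilization multiplier, later SAM+PT arm (reconstructed)"),
    new_parameter("pt_util_soc_late", 2.5, role = "count",
                  note = "PT utilization multiplier, later NSAID+PT arm (reconstructed)"),
    new_parameter("e_sam_pt_late", 0.77, 0.65, 0.89, "effect",
                  dist = tri(0.65, 0.77, 0.89),
                  note = "effect size, later-stage SAM+PT pathway"),
    new_parameter("e_soc_pt_late", 0.47, 0.35, 0.59, "effect",
                  dist = tri(0.35, 0.47, 0.59),
                  note = "effect size, later-stage NSAID+PT pathway"),
    new_parameter("resid_cost_sam", 0, role = "cost",
                  note = "residual 6-month arm cost, SAM (calibrated)"),
    new_parameter("resid_cost_soc", 0, role = "cost",
                  note = "residual 6-month arm cost, SOC (calibrated)"),
    new_parameter("resid_cost_sam_late", 0, role = "cost",
                  note = "residual 6-month arm cost, later SAM+PT (calibrated)"),
    new_parameter("resid_cost_soc_late", 0, role = "cost",
                  note = "residual 6-month arm cost, later NSAID+PT (calibrated)"),
    new_parameter("resid_effect_sam", 0, low = -1, high = 1, role = "effect",
                  note = "residual arm effect, SAM (calibrated)"),
    new_parameter("resid_effect_soc", 0, low = -1, high = 1, role = "effect",
                  note = "residual arm effect, SOC (calibrated)")
  )

  sam_pt_block <- "pt_session_cost * n_pt_sessions * pt_util_sam"
  soc_pt_block <- "pt_session_cost * n_pt_sessions * pt_util_soc"

  sam_arm <- chance_node(
    "pain response to SAM",
    branches = list(
      terminal_node(
        "SAM responder: PT initiated",
        cost = paste("sam_device_cost +", sam_pt_block, "+ resid_cost_sam"),
        effect = "e_sam_pt + resid_effect_sam"),
      terminal_node(
        "SAM non-responder: escalation, delayed PT",
        cost = paste("sam_device_cost +", sam_pt_block,
                     "+ escalation_cost + resid_cost_sam"),
        effect = "e_sam_no_pt + resid_effect_sam")
    ),
    probs = list("p_sam_success", "1 - p_sam_success")
  )

  soc_arm <- chance_node(
    "pain response to first-line topical NSAID",
    branches = list(
      terminal_node(
        "SOC responder: PT initiated",
        cost = paste("soc_first_line_cost +", soc_pt_block,
                     "+ resid_cost_soc"),
        effect = "e_soc_pt + resid_effect_soc"),
      terminal_node(
        "SOC non-responder: escalation, delayed PT",
        cost = paste("soc_first_line_cost +", soc_pt_block,
                     "+ escalation_cost + resid_cost_soc"),
        effect = "e_soc_no_pt + resid_effect_soc")
    ),
    probs = list("p_soc_success", "1 - p_soc_success")
  )

  sam_late <- terminal_node(
    "later-stage: SAM responder continuing PT",
    cost = paste("sam_device_cost +",
                 "pt_session_cost * n_pt_sessions * pt_util_sam_late",
                 "+ resid_cost_sam_late"),
    effect = "e_sam_pt_late")

  soc_late <- terminal_node(
    "later-stage: NSAID responder continuing PT",
    cost = paste("soc_first_line_cost +",
                 "pt_session_cost * n_pt_sessions * pt_util_soc_late",
                 "+ resid_cost_soc_late"),
    effect = "e_soc_pt_late")

  tree <- decision_node("knee OA 6-month management", strategies = list(
    "SAM" = sam_arm,
    "SOC" = soc_arm,
    "SAM+PT (later)" = sam_late,
    "NSAID+PT (later)" = soc_late
  ))

  model <- new_cea_model(
    parameters = params, tree = tree,
    comparisons = list(
      list(new = "SAM", standard = "SOC"),
      list(new = "SAM+PT (later)", standard = "NSAID+PT (later)")
    ),
    name = "knee_oa_2020", horizon = "6 months (no discounting)")

  if (calibrated) {
    model <- calibrate_model(model, knee_oa_targets(),
                             knee_oa_residual_params())
  }
  model
}

#' Load the bundled knee osteoarthritis model
#'
#' Reads the versioned, calibrated model file shipped with the package
#' (`inst/extdata/knee_oa_2020.yaml`). Identical, up to serialization
#' round-trip, to `build_knee_oa_model()`.
#'
#' @return A `cea_model`.
#' @examples
#' m <- knee_oa_model()
#' incremental(m)
#' @export
knee_oa_model <- function() {
  path <- system.file("extdata", "knee_oa_2020.yaml", package = "ceatree")
  if (!nzchar(path)) {
    stop("bundled model file not found; is ceatree installed?", call. = FALSE)
  }
  read_model(path)
}
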