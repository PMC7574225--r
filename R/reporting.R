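# Report drivers tying the stages together: the base-case report and the
# full analysis bundle (base case + tornado + thresholds + PSA) written to
# an output directory with a reproducibility manifest.

#' Base-case report for a model
#'
#' Rolls back the model at base values and assembles, for every declared
#' comparison pair, the incremental result (Δcost, Δeffect, full and
#' truncated ICER, dominance classification).
#'
#' @param model A `cea_model`, or the path of a model file.
#' @return An object of class `cea_base_case`: `strategies` (data frame)
#'   and `comparisons` (list of `cea_increment`).
#' @examples
#' run_base_case(knee_oa_model())
#' @export
run_base_case <- function(model) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "cea_model"))
  structure(
    list(model_name = model$name,
         strategies = evaluate_strategies(model),
         comparisons = lapply(seq_along(model$comparisons), incremental,
                              model = model)),
    class = "cea_base_case"
  )
}

#' @export
print.cea_base_case <- function(x, ...) {
  cat("Base case:", x$model_name, "\n\n")
  tab <- x$strategies
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-20s cost = $%8.0f   effect size = %.2f\n",
                tab$strategy[i], tab$cost[i], tab$effect[i]))
  }
  cat("\n")
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

.base_case_list <- function(bc) {
  list(
    model = bc$model_name,
    strategies = bc$strategies,
    comparisons = lapply(bc$comparisons, function(cmp) {
      list(new = cmp$new, standard = cmp$standard,
           cost_new = cmp$cost_new, cost_std = cmp$cost_std,
           effect_new = cmp$effect_new, effect_std = cmp$effect_std,
           delta_cost = cmp$delta_cost, delta_effect = cmp$delta_effect,
           icer = cmp$icer, icer_truncated = cmp$icer_truncated,
           classification = cmp$classification)
    })
  )
}

#' Full analysis bundle
#'
#' Runs the complete pipeline for one comparison — base case, tornado,
#' break-even thresholds, and probabilistic sensitivity analysis with net
#' monetary benefit at each willingness-to-pay value — and writes the
#' results to `out_dir`:
#'
#' * `base_case.json` — strategy totals and all incremental results;
#' * `tornado.csv` — one row per parameter, sorted by swing;
#' * `thresholds.csv` — one row per requested break-even search;
#' * `psa.csv` — per-iteration incremental pairs and NMB columns;
#' * `psa_summary.json` — quadrant proportions, centroid, CEAC points;
#' * `manifest.json` — seed, iteration count, package version and the MD5
#'   hash of the model file written alongside (`model.yaml`), so a run can
#'   be reproduced byte-for-byte from its manifest.
#'
#' On error, partial outputs are removed.
#'
#' @param model A `cea_model` or model-file path.
#' @param out_dir Output directory (created if needed).
#' @param n PSA iterations.
#' @param seed Root seed for the PSA.
#' @param wtp Numeric vector of willingness-to-pay values (USD per unit
#'   effect size) for NMB/CEAC reporting.
#' @param thresholds Named list: parameter name -> `c(low, high)` bracket
#'   for the break-even search. Empty list skips threshold analysis.
#' @param comparison Comparison pair for the sensitivity/PSA stages.
#' @return Invisibly, a list with all in-memory results and `out_dir`.
#' @export
run_full_analysis <- function(model, out_dir, n = 1000L, seed = 1L,
                              wtp = c(50000, 100000), thresholds = list(),
                              comparison = 1L) {
  if (is.character(model)) model <- read_model(model)
  stopifnot(inherits(model, "cea_model"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    path <- file.path(out_dir, name)
    written <<- c(written, path)
    path
  }
  tryCatch({
    bc <- run_base_case(model)
    jsonlite::write_json(.base_case_list(bc), emit("base_case.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    torn <- tornado(model, comparison = comparison)
    utils::write.csv(as.data.frame(torn), emit("tornado.csv"),
                     row.names = FALSE)

    thr_rows <- lapply(names(thresholds), function(nm) {
      th <- find_threshold(model, nm, thresholds[[nm]],
                           comparison = comparison)
      data.frame(parameter = nm, threshold = th$threshold,
                 threshold_dollars = round(th$threshold),
                 direction = th$direction,
                 bracket_low = th$bracket[1], bracket_high = th$bracket[2])
    })
    thr <- if (length(thr_rows) > 0) do.call(rbind, thr_rows) else
      data.frame(parameter = character(0), threshold = numeric(0),
                 threshold_dollars = numeric(0), direction = character(0),
                 bracket_low = numeric(0), bracket_high = numeric(0))
    utils::write.csv(thr, emit("thresholds.csv"), row.names = FALSE)

    psa <- run_psa(model, n = n, seed = seed, comparison = comparison)
    psa_tab <- psa$pairs
    for (l in wtp) {
      psa_tab[[sprintf("nmb_%g", l)]] <-
        net_monetary_benefit(l, psa$pairs$delta_cost, psa$pairs$delta_effect)
    }
    utils::write.csv(psa_tab, emit("psa.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(iterations = psa$iterations, seed = psa$seed,
           new = psa$new, standard = psa$standard,
           quadrant_proportions = as.list(psa$quadrant_proportions),
           centroid = as.list(psa$centroid),
           ceac = ceac(psa, wtp)),
      emit("psa_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)

    model_path <- emit("model.yaml")
    write_model(model, model_path)
    jsonlite::write_json(
      list(model = model$name, seed = as.integer(seed), n = as.integer(n),
           wtp = wtp, comparison = comparison,
           package_version = as.character(utils::packageVersion("ceatree")),
           model_md5 = unname(tools::md5sum(model_path))),
      emit("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

    invisible(list(base_case = bc, tornado = torn, thresholds = thr,
                   psa = psa, out_dir = out_dir))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
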