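#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 1000 joint draws from the model's
# parameter distributions (triangular over low/base/high for costs, counts
# and effects; uniform for success probabilities), rolled back per draw,
# summarized on the cost-effectiveness plane with NMB at $50k and $100k
# willingness-to-pay.
#
# Finding: across iterations SAM is predominantly more effective AND more
# costly than SOC (NE quadrant share ~90%+ under the reconstructed
# distributions; the share depends on the spread choices documented in the
# vignette), with the cloud centred near the base-case increment. At a
# $50,000 willingness-to-pay per unit effect size, SAM is cost-effective in
# the overwhelming majority of iterations.

suppressPackageStartupMessages(library(ceatree))

seed <- 2020L
model <- knee_oa_model()
psa <- run_psa(model, n = 1000L, seed = seed)
print(psa)

cv <- ceac(psa, wtp = seq(0, 100000, by = 10000))
print(cv)

dir.create("results", showWarnings = FALSE)
tab <- psa$pairs
tab$nmb_50000 <- net_monetary_benefit(50000, tab$delta_cost, tab$delta_effect)
tab$nmb_100000 <- net_monetary_benefit(100000, tab$delta_cost, tab$delta_effect)
write.csv(tab, "results/psa_iterations.csv", row.names = FALSE)
jsonlite::write_json(
  list(iterations = psa$iterations, seed = psa$seed,
       quadrant_proportions = as.list(psa$quadrant_proportions),
       centroid = as.list(psa$centroid), ceac = cv),
  "results/psa_summary.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("written: results/psa_iterations.csv, results/psa_summary.json\n")
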