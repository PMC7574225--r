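#!/usr/bin/env Rscript
# Tornado analysis: which parameters move the SAM-vs-SOC cost difference
# the most over their plausible ranges?
#
# Finding: the SAM device price dominates (swing $4,000 over its
# $2,000-$6,000 range), followed by the PT price per 15-min session and the
# expected number of PT sessions — the same top three the deterministic
# sensitivity analysis then takes to break-even in 03_thresholds.R. Success
# probabilities and escalation costs are an order of magnitude weaker.

suppressPackageStartupMessages(library(ceatree))

model <- knee_oa_model()
tor <- tornado(model)
print(tor)

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(tor), "results/tornado.csv", row.names = FALSE)
cat("written: results/tornado.csv\n")
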