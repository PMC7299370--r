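#!/usr/bin/env Rscript
# Step 5: current-voltage families (-80 to +80 mV in 20 mV steps, 30 sweeps
# per voltage) and the rectification index |I(+60)|/|I(-60)| per condition.
#
# Finds: the calibrated outward-block factor reproduces the graded RI of
# the CP conditions (0.056 / 0.128 / 0.274) while the CI heteromers stay
# linear (RI ~ 1, classified heteromer-dominated at the 0.7 cut point).

library(ampanoise)

dir.create("results", showWarnings = FALSE)

rows <- lapply(ampar_conditions(), function(cc) {
  m <- ampar_preset(cc)
  fam <- simulate_iv(m, n_sweeps = 30, seed = 21)
  cv <- build_iv(iv_peaks(fam))
  truth <- preset_truth()
  data.frame(condition = cc,
             ri_target = truth$ri[truth$condition == cc],
             ri_hat = round(cv$ri, 4),
             class = classify_rectification(cv$ri))
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/rectification.csv", row.names = FALSE)
cat("Rectification indices (seed 21):\n")
print(tab, row.names = FALSE)
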