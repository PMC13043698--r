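#!/usr/bin/env Rscript
# Step 3 — correlation of Q-LUS features with oxygenation.
#
# Aggregates the 8 zone-level feature sets into one Q-LUS value per
# infant, computes each infant's oxygenation indices (OSI when MAP is
# available — for CPAP the set pressure is the MAP — and S/F for all),
# and builds the study-style correlation table: Spearman's rho with
# bootstrap 95% CIs, overall and per ultrasound machine, non-significant
# cells rendered NS. Also writes scatter plots and index histograms.

library(qlus)

cfg <- qlus_config(seed = 20260301L)
res <- suppressMessages(qlus_correlate_files(
  "results/features.csv", "results/cohort/clinical.csv",
  config = cfg, out_dir = "results/correlations", make_plots = TRUE))

cat(sprintf("subject table: %d infants (%d with OSI)\n",
            nrow(res$subjects), sum(!is.na(res$subjects$osi))))
cat("\nwide correlation table (NS = not significant at p < 0.05):\n")
print(as.data.frame(res$wide), right = FALSE)
sig <- res$long[!is.na(res$long$significant) & res$long$significant, ]
cat(sprintf("\n%d of %d cells significant; strongest: %s vs %s (%s), rho = %.2f\n",
            nrow(sig), nrow(res$long),
            sig$feature[which.max(abs(sig$rho))],
            sig$index[which.max(abs(sig$rho))],
            sig$subgroup[which.max(abs(sig$rho))],
            sig$rho[which.max(abs(sig$rho))]))
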