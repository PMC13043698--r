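#!/usr/bin/env Rscript
# Step 4 — Monte-Carlo validation of the pipeline's directional finding.
#
# Repeats the whole study (simulate -> analyse -> aggregate -> correlate)
# 200 times and records how often the pipeline recovers the built-in link:
# brighter pleural/subpleural ROIs (higher MGV) ranking with lower OSI and
# higher S/F. A second run with the aeration-oxygenation link severed
# shows the same statistic at chance level. Writes
# results/sign_recovery.csv. Allow ~10 minutes on one core.

library(qlus)

seed <- 20260301L

rate <- sign_recovery_experiment(n_subjects = 70, n_reps = 200, seed = seed)
cat(sprintf("sign recovery under the default generator: %.3f (200 reps)\n",
            as.numeric(rate)))

null_rate <- sign_recovery_experiment(n_subjects = 70, n_reps = 200,
                                      params = null_params(), seed = seed)
cat(sprintf("joint-sign rate with the link severed:     %.3f (200 reps)\n",
            as.numeric(null_rate)))
s <- attr(null_rate, "signs")
cat(sprintf("null dependence between the two rhos (they share FiO2/SpO2): r = %.2f\n",
            cor(s[, 1], s[, 2])))

dir.create("results", showWarnings = FALSE)
utils::write.csv(
  data.frame(condition = c("default", "no_link"),
             joint_sign_rate = c(as.numeric(rate), as.numeric(null_rate)),
             n_reps = 200),
  "results/sign_recovery.csv", row.names = FALSE)
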