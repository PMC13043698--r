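#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Generates a 70-infant synthetic cohort (8 lung-ultrasound frames per
# infant, one per zone; two ultrasound-machine subgroups; clinical records
# with support mode, MAP, FiO2 and SpO2 linked to a latent aeration level)
# and writes frames, ground-truth ROI specs, the clinical table and the
# latent-truth table under results/cohort/.

library(qlus)

seed <- 20260301L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- qlus_simulate_to_dir(out, n_subjects = 70, seed = seed)

cat(sprintf("wrote %d frames for %d subjects to %s\n",
            length(cohort$frames), nrow(cohort$clinical), out))
cat(sprintf("machines: %s\n",
            paste(capture.output(print(table(cohort$clinical$machine_id))),
                  collapse = " ")))
cat(sprintf("MAP available for %d of %d infants\n",
            sum(!is.na(cohort$clinical$map_cmH2O)), nrow(cohort$clinical)))
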