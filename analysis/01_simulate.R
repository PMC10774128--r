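#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multicohort study.
#
# Eight cohorts of unequal size (three cross-sectional, five longitudinal,
# ~2,100 children in total) with site-specific covariate prevalences, mean
# shifts and residual noise; seven regional volume series following the
# asymptotic growth model and five Mullen raw-score series following the
# linear-in-age model. Writes the two long tables under results/data/.

library(subcortgrowth)

seed <- 20240901
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohorts <- default_cohorts()
truth <- default_truth()

vols <- simulate_volumes(cohorts, truth, seed = seed)
cogs <- simulate_cognition(cohorts, truth, seed = seed + 1)

write_long_table(vols, file.path(out, "volumes.csv"))
write_long_table(cogs, file.path(out, "cognition.csv"))

cat(sprintf("volumes:   %6d rows, %d subjects, %d regions\n",
            nrow(vols), length(unique(vols$subject_id)),
            length(unique(vols$region))))
cat(sprintf("cognition: %6d rows, %d subjects, %d scales\n",
            nrow(cogs), length(unique(cogs$subject_id)),
            length(unique(cogs$scale))))
print(table(subject_table(vols)$cohort))
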