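#!/usr/bin/env Rscript
# Stage 3: linear mixed models for the five Mullen raw-score scales.
#
# Per scale: overall mean, shared age slope, covariate and cohort fixed
# effects, subject random intercept, cohort-specific residual variances.
# Also runs the covariate-by-age interaction tests (likelihood ratio, with
# the Wald z of the interaction coefficient alongside) and tabulates the
# interindividual-variation summary.

library(subcortgrowth)

cogs <- read_long_table("results/data/cognition.csv", "cognition")
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

scales <- unique(cogs$scale)
covs <- c("male", "preterm", "low_bw", "low_medu", "low_income")
thr <- bonferroni_threshold(25)   # 5 scales x 5 covariates
cat(sprintf("Bonferroni threshold (25 tests): %g\n\n", thr))

fits <- list()
rows <- list(); irows <- list()
for (s in scales) {
  f <- fit_lmm(cogs, lmm_spec(), outcome = s)
  fits[[s]] <- f
  co <- f$coefficients
  co$significant <- ifelse(co$term %in% covs & co$p < thr, "**",
                           ifelse(co$term %in% covs & co$p < 0.05, "*", ""))
  co$scale <- s
  rows[[s]] <- co
  cat(sprintf("%-20s n=%4d subjects=%4d  slope=%.4f  IIV=%5.2f%%\n",
              s, f$n_obs, f$n_subjects,
              co$estimate[co$term == "age"], interindividual_variation(f)))
  for (k in covs) {
    fw <- fit_lmm(cogs, lmm_spec(interactions = k), outcome = s)
    lrt <- interaction_test(fw, f)
    wald <- fw$coefficients[fw$coefficients$term == paste0(k, ":age"), ]
    irows[[paste(s, k)]] <- data.frame(
      scale = s, covariate = k,
      lrt_stat = lrt$statistic, lrt_p = lrt$p_value,
      wald_estimate = wald$estimate, wald_p = wald$p,
      significant = lrt$p_value < thr)
  }
}
saveRDS(fits, "scratch/cognitive_fits.rds")

write.table(do.call(rbind, rows), "results/cognitive_effects.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(do.call(rbind, irows), "results/age_interactions.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

iiv <- data.frame(scale = scales,
                  interindividual_variation_pct = round(vapply(
                    fits, interindividual_variation, 0), 2))
write.table(iiv, "results/interindividual_variation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nInterindividual variation (%):\n")
print(iiv, row.names = FALSE)
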