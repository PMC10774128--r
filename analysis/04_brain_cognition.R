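#!/usr/bin/env Rscript
# Stage 4: brain-cognition correlations at age 2.
#
# Builds the panel of subject-specific predictions (fixed effects + BLUPs)
# at 730.5 days from the cached growth and cognitive fits, computes
# Pearson correlation matrices separately for full-term and preterm
# children with the Bonferroni flag at 0.05/35, and bootstrap confidence
# intervals for the full-term minus preterm difference of every
# volume-score correlation.

library(subcortgrowth)

growth_fits <- readRDS("scratch/growth_fits.rds")
cognitive_fits <- readRDS("scratch/cognitive_fits.rds")
vols <- read_long_table("results/data/volumes.csv", "volumes")
seed <- 20240904
B <- 2000

panel <- build_panel(growth_fits, cognitive_fits, subject_table(vols))
cat(sprintf("panel: %d subjects (%d full term, %d preterm)\n",
            nrow(panel), sum(panel$stratum == "full_term"),
            sum(panel$stratum == "preterm")))
write.csv(panel, "results/panel_age2.csv", row.names = FALSE, quote = FALSE)

cms <- lapply(c(full_term = "full_term", preterm = "preterm"),
              function(st) correlation_matrix(panel, st))
for (st in names(cms)) {
  write.table(round(cms[[st]]$r, 4),
              sprintf("results/correlations_%s.tsv", st),
              sep = "\t", quote = FALSE, col.names = NA)
}
cat(sprintf("Bonferroni threshold (35 tests): %g\n", cms$full_term$threshold))

pairs <- expand.grid(volume = cms$full_term$volumes,
                     score = cms$full_term$scores,
                     stringsAsFactors = FALSE)
ft <- panel[panel$stratum == "full_term", ]
pt <- panel[panel$stratum == "preterm", ]
long <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  v <- pairs$volume[i]; s <- pairs$score[i]
  bt <- bootstrap_corr_difference(ft[[v]], ft[[s]], pt[[v]], pt[[s]],
                                  B = B, seed = seed + i)
  data.frame(volume = v, score = s,
             r_fullterm = bt$r1, p_fullterm = cms$full_term$p[v, s],
             sig_fullterm = cms$full_term$significant[v, s],
             r_preterm = bt$r2, p_preterm = cms$preterm$p[v, s],
             sig_preterm = cms$preterm$significant[v, s],
             diff = bt$difference, ci_low = bt$ci[1], ci_high = bt$ci[2],
             diff_significant = bt$significant)
}))
write.table(long, "results/correlation_pairs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("\nLargest |full term - preterm| correlation differences:\n")
long <- long[order(-abs(long$diff)), ]
print(head(long[, c("volume", "score", "r_fullterm", "r_preterm",
                    "diff", "ci_low", "ci_high", "diff_significant")], 5),
      row.names = FALSE, digits = 3)
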