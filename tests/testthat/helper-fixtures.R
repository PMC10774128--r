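# Shared fixtures: small cohort layouts and noise-controlled truths.

two_cohorts <- function(n1 = 120, n2 = 80) {
  list(cohort_spec("alpha", n1, c(2L, 3L), c(5, 2000), 1.0,
                   c(male = 0.5, preterm = 0.25, low_bw = 0.25,
                     low_medu = 0.3, low_income = 0.3)),
       cohort_spec("beta", n2, c(1L, 2L), c(5, 1500), 1.5,
                   c(male = 0.5, preterm = 0.25, low_bw = 0.25,
                     low_medu = 0.3, low_income = 0.3),
                   cohort_shift_intercept = 0.02,
                   cohort_shift_asymptote = 0.01))
}

one_cohort <- function(n = 100, visits = c(3L, 3L), window = c(5, 2000),
                       prev = 0.3) {
  list(cohort_spec("solo", n, visits, window, 1.0,
                   c(male = 0.5, preterm = prev, low_bw = prev,
                     low_medu = prev, low_income = prev)))
}

# Truth with noise and random effects scaled (or zeroed) for one region.
quiet_truth <- function(region = "amygdala", sd_u = 0, sd_e = 0) {
  tr <- default_truth()
  tr$volumes[[region]]$sd_u_asym <- sd_u * tr$volumes[[region]]$params$asymptote
  tr$volumes[[region]]$sd_u_int <- sd_u * tr$volumes[[region]]$params$intercept
  tr$volumes[[region]]$sd_e <- sd_e * tr$volumes[[region]]$params$asymptote
  tr
}

quiet_cog_truth <- function(sd_u = 0, sd_e = 0) {
  tr <- default_truth()
  for (s in names(tr$cognition)) {
    tr$cognition[[s]]$sd_u <- sd_u
    tr$cognition[[s]]$sd_e <- sd_e
  }
  tr
}
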