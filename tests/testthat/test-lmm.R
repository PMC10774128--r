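test_that("one observation per subject without random intercept reduces to OLS", {
  cg <- suppressMessages(simulate_cognition(
    one_cohort(120, visits = c(1L, 1L), window = c(75, 1200)),
    default_truth(), seed = 2, scales = "gross_motor"))
  spec <- lmm_spec(random_intercept = FALSE, heteroscedastic = FALSE)
  f <- fit_lmm(cg, spec)
  ols <- lm(value ~ age_days + male + preterm + low_bw + low_medu + low_income,
            data = cg)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
})

test_that("the age slope is recovered from noise-free linear scores", {
  tr <- quiet_cog_truth(sd_u = 0, sd_e = 1e-9)
  cg <- suppressMessages(simulate_cognition(
    one_cohort(60, visits = c(2L, 2L), window = c(75, 1200)),
    tr, seed = 3, scales = "gross_motor"))
  f <- fit_lmm(cg, lmm_spec())
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(est[["age"]], 0.03, tolerance = 1e-6)
  expect_equal(est[["(intercept)"]], 7.65, tolerance = 1e-4)
})

test_that("two identical cohorts with noise sds 1 and 2 give variance ratio near 4", {
  tr <- quiet_cog_truth(sd_u = 1, sd_e = 1)
  specs <- list(
    cohort_spec("lo", 250, c(2L, 2L), c(75, 1200), 1,
                c(male = .5, preterm = .2, low_bw = .2, low_medu = .3,
                  low_income = .3)),
    cohort_spec("hi", 250, c(2L, 2L), c(75, 1200), 2,
                c(male = .5, preterm = .2, low_bw = .2, low_medu = .3,
                  low_income = .3)))
  cg <- suppressMessages(simulate_cognition(specs, tr, seed = 5,
                                            scales = "gross_motor"))
  f <- fit_lmm(cg, lmm_spec())
  # ratios are relative to the (alphabetically) first cohort; compare the pair
  ratio <- f$cohort_var_ratios[["hi"]] / f$cohort_var_ratios[["lo"]]
  expect_lt(abs(ratio - 4), 1.2)
})

test_that("likelihood never decreases when a fixed effect is added", {
  cg <- suppressMessages(simulate_cognition(
    two_cohorts(80, 60), default_truth(), seed = 7, scales = "gross_motor"))
  f0 <- fit_lmm(cg, lmm_spec(covariates = c("male", "preterm", "low_bw",
                                            "low_medu")))
  f1 <- suppressMessages(fit_lmm(cg, lmm_spec()))
  # refit the smaller model on the larger model's complete cases
  cc <- complete.cases(cg[, c("low_income")])
  f0cc <- fit_lmm(cg[cc, ], lmm_spec(covariates = c("male", "preterm",
                                                    "low_bw", "low_medu")))
  expect_gte(f1$loglik, f0cc$loglik - 1e-6)
})

test_that("ICV-scaled response is invariant to a common rescaling of all volumes", {
  v <- simulate_volumes(two_cohorts(60, 40), default_truth(), seed = 9,
                        regions = c("ICV", "hippocampus"))
  spec <- lmm_spec(response = "icv_scaled", age_slope = FALSE)
  f1 <- fit_lmm(v, spec, outcome = "hippocampus")
  v2 <- v; v2$value <- v2$value * 3.7
  f2 <- fit_lmm(v2, spec, outcome = "hippocampus")
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
})

test_that("visits lacking a same-visit ICV measurement are dropped with a count", {
  v <- simulate_volumes(one_cohort(40), default_truth(), seed = 11,
                        regions = c("ICV", "hippocampus"))
  icv_rows <- which(v$region == "ICV")
  v <- v[-icv_rows[1:5], ]
  expect_message(fit_lmm(v, lmm_spec(response = "icv_scaled", age_slope = FALSE),
                         outcome = "hippocampus"),
                 "5 visits dropped")
})

test_that("identical nested models give LR statistic 0 and p-value 1", {
  cg <- suppressMessages(simulate_cognition(
    one_cohort(60, window = c(75, 1200)), default_truth(), seed = 13,
    scales = "gross_motor"))
  f <- fit_lmm(cg, lmm_spec())
  out <- interaction_test(f, f)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 0)
  expect_equal(out$p_value, 1)
  f2 <- fit_lmm(cg, lmm_spec(interactions = "preterm"))
  expect_error(interaction_test(f, f2), "nested")
})

test_that("null interaction p-values are approximately uniform", {
  # scores generated with zero interaction; LRT p across seeds ~ U(0,1)
  specs <- one_cohort(70, visits = c(2L, 2L), window = c(75, 1200))
  ps <- vapply(1:120, function(s) {
    cg <- suppressMessages(simulate_cognition(specs, default_truth(), seed = s,
                                              scales = "gross_motor"))
    fw <- fit_lmm(cg, lmm_spec(interactions = "preterm"))
    fo <- fit_lmm(cg, lmm_spec())
    interaction_test(fw, fo)$p_value
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a strong injected interaction is detected at the corrected threshold", {
  specs <- one_cohort(150, visits = c(2L, 2L), window = c(75, 1200))
  thr <- bonferroni_threshold(25)
  hits <- vapply(1:20, function(s) {
    cg <- suppressMessages(simulate_cognition(specs, default_truth(), seed = s,
                                              scales = "gross_motor"))
    cg$value <- cg$value + 0.01 * cg$age_days * cg$preterm  # big interaction
    fw <- fit_lmm(cg, lmm_spec(interactions = "preterm"))
    fo <- fit_lmm(cg, lmm_spec())
    interaction_test(fw, fo)$p_value < thr
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("interindividual variation matches its analytic value", {
  # var(u) = 1, residual = 4, homoscedastic: share = 20%
  tr <- quiet_cog_truth(sd_u = 1, sd_e = 2)
  cg <- suppressMessages(simulate_cognition(
    one_cohort(1200, visits = c(2L, 2L), window = c(75, 1200)),
    tr, seed = 17, scales = "gross_motor"))
  f <- fit_lmm(cg, lmm_spec(heteroscedastic = FALSE))
  expect_equal(interindividual_variation(f), 20, tolerance = 0.15)
  f0 <- fit_lmm(cg, lmm_spec(random_intercept = FALSE, heteroscedastic = FALSE))
  expect_equal(interindividual_variation(f0), 0)
})

test_that("homoscedastic data drive the cohort variance ratios toward 1", {
  tr <- quiet_cog_truth(sd_u = 1, sd_e = 2)
  specs <- list(
    cohort_spec("c1", 200, c(2L, 2L), c(75, 1200), 1,
                c(male = .5, preterm = .2, low_bw = .2, low_medu = .3,
                  low_income = .3)),
    cohort_spec("c2", 200, c(2L, 2L), c(75, 1200), 1,
                c(male = .5, preterm = .2, low_bw = .2, low_medu = .3,
                  low_income = .3)))
  cg <- suppressMessages(simulate_cognition(specs, tr, seed = 19,
                                            scales = "gross_motor"))
  f <- fit_lmm(cg, lmm_spec())
  expect_lt(abs(f$cohort_var_ratios[["c2"]] - 1), 0.25)
})
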