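test_that("noise-free data with no random effects recover the generating curve", {
  tr <- quiet_truth("amygdala", sd_u = 0, sd_e = 1e-8)
  v <- simulate_volumes(one_cohort(60), tr, seed = 7, regions = "amygdala")
  f <- fit_growth(v, growth_model_spec(random_effects = FALSE,
                                       heteroscedastic = FALSE))
  expect_equal(f$params$asymptote, 2082.93, tolerance = 1e-4)
  expect_equal(f$params$intercept, 398.78, tolerance = 1e-4)
  expect_equal(f$log_rate, -5.60, tolerance = 1e-4)
  expect_true(f$convergence)
})

test_that("inner solve with random effects off coincides with weighted least squares", {
  set.seed(3)
  v <- simulate_volumes(two_cohorts(60, 40), default_truth(), seed = 3,
                        regions = "amygdala")
  spec <- growth_model_spec(random_effects = FALSE)
  f <- fit_growth(v, spec)
  # WLS oracle on the transformed linear design at the fitted rate constant
  w <- exp(-exp(f$log_rate) * v$age_days)
  Xb <- subcortgrowth:::base_design(v, spec$covariates, TRUE)
  X <- cbind((1 - w) * Xb, w * Xb)
  lam <- f$cohort_var_ratios[as.character(v$cohort)]
  wls <- lm.wfit(X, v$value, 1 / lam)
  est <- f$coefficients$estimate[seq_len(ncol(X))]
  expect_equal(est, unname(wls$coefficients), tolerance = 1e-8)
})

test_that("profiled likelihood is unimodal near the truth on generated data", {
  v <- simulate_volumes(one_cohort(80), default_truth(), seed = 19,
                        regions = "amygdala")
  spec <- growth_model_spec()
  grid <- seq(-6.6, -4.6, by = 0.2)
  Xb <- subcortgrowth:::base_design(v, spec$covariates, TRUE)
  subj <- factor(v$subject_id)
  ll <- vapply(grid, function(t3) {
    w <- exp(-exp(t3) * v$age_days)
    X <- cbind((1 - w) * Xb, w * Xb)
    colnames(X) <- paste0("c", seq_len(ncol(X)))
    hetlmm(v$value, X, cbind(1 - w, w), subj)$loglik
  }, 0)
  i <- which.max(ll)
  expect_true(i > 1 && i < length(grid))
  expect_true(all(diff(ll[seq_len(i)]) > 0))
  expect_true(all(diff(ll[i:length(grid)]) < 0))
})

test_that("log marginal likelihood is invariant to row order and relabeling", {
  v <- simulate_volumes(two_cohorts(40, 30), default_truth(), seed = 23,
                        regions = "amygdala")
  f1 <- fit_growth(v, growth_model_spec())
  set.seed(2); v2 <- v[sample(nrow(v)), ]
  v2$subject_id <- paste0("relabeled_", v2$subject_id)
  f2 <- fit_growth(v2, growth_model_spec())
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-5)
  expect_equal(f1$params$asymptote, f2$params$asymptote, tolerance = 1e-4)
})

test_that("population predictions interpolate between fitted intercept and asymptote", {
  v <- simulate_volumes(one_cohort(80), default_truth(), seed = 29,
                        regions = "amygdala")
  f <- fit_growth(v, growth_model_spec())
  expect_equal(predict_volume(f, list(), 0), f$params$intercept)
  expect_equal(predict_volume(f, list(), 1e7), f$params$asymptote,
               tolerance = 1e-8)
  # covariate effects shift the curve additively
  male_late <- predict_volume(f, list(male = 1), 1e7)
  est <- setNames(f$coefficients$estimate, f$coefficients$term)
  expect_equal(male_late - f$params$asymptote, est[["asym:male"]],
               tolerance = 1e-8)
  expect_error(predict_volume(f, list(), 100, subject_id = "nobody"), "unknown")
})

test_that("subject BLUPs move predictions in the direction of injected effects", {
  tr <- default_truth()
  v <- simulate_volumes(one_cohort(150), tr, seed = 31, regions = "amygdala")
  f <- fit_growth(v, growth_model_spec())
  # subjects with the largest positive asymptote BLUP must predict above
  # the population curve at late ages
  top <- rownames(f$blups)[which.max(f$blups[, 1])]
  sub <- subject_table(v)
  cv <- as.list(sub[top, c("male", "preterm", "low_bw", "low_medu", "low_income")])
  expect_gt(predict_volume(f, cv, 2200, subject_id = top),
            predict_volume(f, cv, 2200))
  # BLUP asymptote deviations correlate with the subject's late-age residuals
  late <- v[v$age_days > 1000, ]
  if (nrow(late) > 30) {
    pop <- vapply(seq_len(nrow(late)), function(i) {
      cvi <- as.list(late[i, c("male", "preterm", "low_bw", "low_medu", "low_income")])
      predict_volume(f, cvi, late$age_days[i])
    }, 0)
    dev <- tapply(late$value - pop, late$subject_id, mean)
    expect_gt(cor(f$blups[names(dev), 1], dev), 0.5)
  }
})

test_that("constant covariates and single-age data are rejected", {
  v <- simulate_volumes(one_cohort(30), default_truth(), seed = 37,
                        regions = "amygdala")
  v$male <- 1L
  expect_error(fit_growth(v, growth_model_spec()), "male")
  v2 <- simulate_volumes(one_cohort(30), default_truth(), seed = 37,
                         regions = "amygdala")
  v2$age_days <- 100
  v2 <- v2[!duplicated(v2$subject_id), ]
  expect_error(fit_growth(v2, growth_model_spec()), "distinct ages")
})

test_that("the no-income sensitivity variant drops exactly the income term", {
  spec <- growth_model_variant("no-income")
  expect_false("low_income" %in% spec$covariates)
  expect_setequal(spec$covariates, c("male", "preterm", "low_bw", "low_medu"))
  v <- simulate_volumes(one_cohort(60), default_truth(), seed = 41,
                        regions = "amygdala")
  f <- fit_growth(v, spec)
  expect_false(any(grepl("low_income", f$coefficients$term)))
})

test_that("incomplete covariate rows are dropped and counted", {
  v <- simulate_volumes(one_cohort(50), default_truth(), seed = 43,
                        regions = "amygdala")
  v$low_income[1:10] <- NA
  expect_message(f <- fit_growth(v, growth_model_spec()), "10 rows dropped")
  expect_equal(f$n_obs + f$n_dropped, nrow(v))
})
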