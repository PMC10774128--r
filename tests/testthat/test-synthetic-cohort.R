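test_that("noise-free generation reproduces the deterministic curve exactly", {
  tr <- quiet_truth("amygdala")
  specs <- one_cohort(40)
  v <- simulate_volumes(specs, tr, seed = 3, regions = "amygdala")
  p <- tr$volumes$amygdala$params
  expected <- vapply(seq_len(nrow(v)), function(i) {
    covs <- unlist(v[i, c("male", "preterm", "low_bw", "low_medu", "low_income")])
    asy <- p$asymptote + sum(covs * tr$volumes$amygdala$effects_asymptote)
    int <- p$intercept + sum(covs * tr$volumes$amygdala$effects_intercept)
    asy + (int - asy) * exp(-exp(p$log_rate) * v$age_days[i])
  }, 0)
  expect_equal(v$value, expected, tolerance = 1e-12)
})

test_that("noise-free reference subject at age 0 sits at the printed intercept", {
  tr <- quiet_truth("amygdala")
  spec <- cohort_spec("c", 5, c(1L, 1L), c(0, 1), 1,
                      c(male = 0, preterm = 0, low_bw = 0,
                        low_medu = 0, low_income = 0))
  # force age 0 by an almost-degenerate window, then evaluate directly
  v <- simulate_volumes(list(spec), tr, seed = 5, regions = "amygdala")
  v0 <- v[v$age_days == 0, ]
  expect_true(nrow(v0) >= 1)
  expect_equal(unique(round(v0$value, 2)), 398.78)
})

test_that("simulation is byte-identical for a repeated seed and differs across seeds", {
  specs <- two_cohorts(30, 20)
  a <- simulate_volumes(specs, default_truth(), seed = 99, regions = c("ICV", "amygdala"))
  b <- simulate_volumes(specs, default_truth(), seed = 99, regions = c("ICV", "amygdala"))
  expect_identical(a, b)
  c2 <- simulate_volumes(specs, default_truth(), seed = 100, regions = c("ICV", "amygdala"))
  expect_false(identical(a$value, c2$value))
  ca <- suppressMessages(simulate_cognition(specs, default_truth(), seed = 99))
  cb <- suppressMessages(simulate_cognition(specs, default_truth(), seed = 99))
  expect_identical(ca, cb)
})

test_that("tables respect the declared invariants", {
  specs <- two_cohorts(50, 40)
  v <- simulate_volumes(specs, default_truth(), seed = 12)
  expect_true(all(v$value > 0))
  expect_false(anyDuplicated(paste(v$subject_id, v$age_days, v$region)) > 0)
  st <- subject_table(v)          # errors if covariates vary within subject
  expect_equal(nrow(st), length(unique(v$subject_id)))
  cg <- suppressMessages(simulate_cognition(specs, default_truth(), seed = 12))
  win <- scale_age_windows()
  for (s in names(win)) {
    ages <- cg$age_days[cg$scale == s]
    expect_true(all(ages >= win[[s]][1] & ages <= win[[s]][2]))
  }
})

test_that("cognition rows outside a scale's validity window are omitted and counted", {
  spec <- cohort_spec("late", 30, c(1L, 1L), c(1400, 1700), 1,
                      c(male = .5, preterm = .2, low_bw = .2,
                        low_medu = .3, low_income = .3))
  expect_message(
    cg <- simulate_cognition(list(spec), default_truth(), seed = 4,
                             scales = c("gross_motor", "fine_motor")),
    "omitted")
  expect_false("gross_motor" %in% cg$scale)   # window ends at 1275 d
  expect_equal(sum(cg$scale == "fine_motor"), 30)
  expect_equal(attr(cg, "n_omitted"), 30L)
})

test_that("empirical covariate prevalences converge to the specified probabilities", {
  spec <- cohort_spec("big", 3000, c(1L, 1L), c(5, 2000), 1,
                      c(male = 0.52, preterm = 0.21, low_bw = 0.17,
                        low_medu = 0.31, low_income = 0.29))
  v <- simulate_volumes(list(spec), default_truth(), seed = 8, regions = "amygdala")
  st <- subject_table(v)
  for (k in c("male", "preterm", "low_bw", "low_medu", "low_income")) {
    p <- spec$covariate_prevalences[[k]]
    tol <- 4 * sqrt(p * (1 - p) / 3000)
    expect_lt(abs(mean(st[[k]]) - p), tol)
  }
})

test_that("variance at birth decomposes into subject and residual components", {
  tr <- default_truth()
  tr$volumes$amygdala$sd_u_asym <- 0
  spec <- cohort_spec("v", 2500, c(1L, 1L), c(0, 1), 1,
                      c(male = 0, preterm = 0, low_bw = 0,
                        low_medu = 0, low_income = 0))
  v <- simulate_volumes(list(spec), tr, seed = 31, regions = "amygdala")
  v0 <- v[v$age_days == 0, ]
  truev <- tr$volumes$amygdala$sd_u_int^2 + tr$volumes$amygdala$sd_e^2
  expect_equal(var(v0$value), truev, tolerance = 0.12)
})

test_that("invalid cohort specifications are rejected naming the field", {
  expect_error(cohort_spec("x", 0), "n_subjects")
  expect_error(cohort_spec("x", 5, age_window_days = c(10, 10)), "age_window")
  expect_error(cohort_spec("x", 5, residual_sd_scale = 0), "residual_sd_scale")
  expect_error(cohort_spec("x", 5, covariate_prevalences =
    c(male = 1.2, preterm = .1, low_bw = .1, low_medu = .1, low_income = .1)),
    "male")
})

test_that("generator defaults carry the printed reference parameters", {
  tr <- default_truth()
  expect_equal(unclass(tr$volumes$thalamus$params)[c("asymptote", "intercept", "log_rate")],
               list(asymptote = 13292.35, intercept = 8924.17, log_rate = -6.64))
  expect_equal(tr$volumes$ICV$effects_asymptote[["male"]], 112624.10)
  expect_equal(tr$cognition$gross_motor$intercept, 7.65)
  expect_equal(tr$cognition$gross_motor$slope, 0.03)
})

test_that("linear cognitive mean evaluates as intercept plus slope times age", {
  tr <- quiet_cog_truth()
  spec <- cohort_spec("c", 20, c(1L, 1L), c(99, 101), 1,
                      c(male = 0, preterm = 0, low_bw = 0,
                        low_medu = 0, low_income = 0))
  cg <- simulate_cognition(list(spec), tr, seed = 2, scales = "gross_motor")
  r100 <- cg[cg$age_days == 100, ]
  expect_true(nrow(r100) >= 1)
  expect_equal(unique(round(r100$value, 10)), 7.65 + 0.03 * 100)  # 10.65
})
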