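fit_panel_inputs <- function(seed = 51, n1 = 120, n2 = 60) {
  specs <- list(
    cohort_spec("p1", n1, c(2L, 2L), c(75, 1200), 1,
                c(male = .5, preterm = .3, low_bw = .2, low_medu = .3,
                  low_income = .3)),
    cohort_spec("p2", n2, c(1L, 2L), c(75, 1500), 1.3,
                c(male = .5, preterm = .3, low_bw = .2, low_medu = .3,
                  low_income = .3)))
  vols <- simulate_volumes(specs, default_truth(), seed = seed,
                           regions = c("ICV", "hippocampus"))
  cogs <- suppressMessages(simulate_cognition(specs, default_truth(),
                                              seed = seed + 1,
                                              scales = c("gross_motor",
                                                         "visual_reception")))
  gf <- lapply(setNames(c("ICV", "hippocampus"), c("ICV", "hippocampus")),
               function(r) suppressMessages(fit_growth(vols, growth_model_spec(),
                                                       region = r)))
  cf <- lapply(setNames(c("gross_motor", "visual_reception"),
                        c("gross_motor", "visual_reception")),
               function(s) suppressMessages(fit_lmm(cogs, lmm_spec(),
                                                    outcome = s)))
  list(vols = vols, cogs = cogs, gf = gf, cf = cf)
}

test_that("panel rows are population curves for reference subjects without BLUPs", {
  inp <- fit_panel_inputs()
  sub <- subject_table(inp$vols)
  panel <- suppressMessages(build_panel(inp$gf, inp$cf, sub,
                                        include_blups = FALSE))
  expect_equal(nrow(panel), nrow(sub))
  i <- which(sub$male == 0 & sub$preterm == 0 & sub$low_bw == 0 &
               sub$low_medu == 0 & sub$low_income == 0 &
               sub$cohort == "p1")[1]
  skip_if(is.na(i), "no reference-covariate subject in draw")
  expect_equal(panel$ICV[panel$subject_id == sub$subject_id[i]],
               predict_volume(inp$gf$ICV, list(), 730.5))
  expect_equal(panel$gross_motor[panel$subject_id == sub$subject_id[i]],
               predict_lmm(inp$cf$gross_motor, list(), 730.5))
})

test_that("subject-specific panel respects model membership and stratum labels", {
  inp <- fit_panel_inputs()
  sub <- subject_table(inp$vols)
  panel <- suppressMessages(build_panel(inp$gf, inp$cf, sub))
  nmax <- min(vapply(c(inp$gf, inp$cf), function(f) f$n_subjects, 0L))
  expect_lte(nrow(panel), nmax)
  expect_setequal(unique(panel$stratum), c("full_term", "preterm"))
  pre <- sub$subject_id[sub$preterm == 1]
  expect_true(all(panel$subject_id[panel$stratum == "preterm"] %in% pre))
  expect_true(all(is.finite(as.matrix(panel[, -(1:2)]))))
})

test_that("correlation matrix reproduces hand-computed Pearson r and basic cases", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 9)
  panel <- data.frame(subject_id = paste0("s", 1:5),
                      stratum = "full_term",
                      ICV = x, gross_motor = y,
                      stringsAsFactors = FALSE)
  panel2 <- panel; panel2$stratum <- "preterm"
  cm <- correlation_matrix(rbind(panel, panel2), "full_term",
                           volumes = "ICV", scores = "gross_motor")
  # hand covariance-formula oracle, frozen: r = 0.993883734674
  expect_equal(cm$r["ICV", "gross_motor"], 0.993883734674, tolerance = 1e-10)
  expect_equal(diag(cm$r), c(ICV = 1, gross_motor = 1))
  expect_true(isSymmetric(cm$r))
  panel$gross_motor <- -panel$ICV
  cm2 <- correlation_matrix(rbind(panel, panel2), "full_term",
                            volumes = "ICV", scores = "gross_motor")
  expect_equal(cm2$r["ICV", "gross_motor"], -1)
})

test_that("correlations are invariant to affine rescaling of a column", {
  set.seed(61)
  panel <- data.frame(subject_id = paste0("s", 1:40),
                      stratum = rep(c("full_term", "preterm"), 20),
                      ICV = rnorm(40), hippocampus = rnorm(40),
                      gross_motor = rnorm(40), stringsAsFactors = FALSE)
  cm1 <- correlation_matrix(panel, "full_term", volumes = c("ICV", "hippocampus"),
                            scores = "gross_motor")
  panel$ICV <- 1000 * panel$ICV - 77
  cm2 <- correlation_matrix(panel, "full_term", volumes = c("ICV", "hippocampus"),
                            scores = "gross_motor")
  expect_equal(cm1$r, cm2$r, tolerance = 1e-12)
  expect_equal(cm1$p, cm2$p, tolerance = 1e-12)
})

test_that("the Bonferroni flag marks only volume-score cells below alpha/35", {
  set.seed(63)
  n <- 200
  v <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, subcortgrowth:::.regions))
  s <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, subcortgrowth:::.scales))
  s[, 1] <- v[, 1] * 2 + rnorm(n, 0, 0.5)   # one strong pair
  panel <- data.frame(subject_id = paste0("s", 1:n), stratum = "full_term",
                      v, s, stringsAsFactors = FALSE)
  panel$stratum[1:4] <- "preterm"
  cm <- correlation_matrix(panel, "full_term")
  expect_equal(cm$threshold, 0.05 / 35)
  expect_true(cm$significant["ICV", "gross_motor"])
  expect_false(any(cm$significant[subcortgrowth:::.regions,
                                  subcortgrowth:::.regions]))
})

test_that("bootstrap difference is reproducible, zero for identical strata", {
  set.seed(65)
  x <- rnorm(50); y <- x + rnorm(50)
  b1 <- bootstrap_corr_difference(x, y, x, y, B = 300, seed = 5)
  b2 <- bootstrap_corr_difference(x, y, x, y, B = 300, seed = 5)
  expect_identical(b1$ci, b2$ci)
  expect_equal(b1$difference, 0)
  b3 <- bootstrap_corr_difference(x, y, x, y, B = 300, seed = 6)
  expect_false(identical(b1$ci, b3$ci))
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(n)
    x1 <- rnorm(n); y1 <- 0.5 * x1 + rnorm(n)
    x2 <- rnorm(n); y2 <- 0.5 * x2 + rnorm(n)
    b <- bootstrap_corr_difference(x1, y1, x2, y2, B = 400, seed = 1)
    diff(b$ci)
  }, 0)
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1] / 2)
})

test_that("clearly different population correlations are detected", {
  set.seed(67)
  n <- 300
  x1 <- rnorm(n); y1 <- 0.6 * x1 + rnorm(n, 0, sqrt(1 - 0.36))
  x2 <- rnorm(n); y2 <- rnorm(n)
  b <- bootstrap_corr_difference(x1, y1, x2, y2, B = 500, seed = 2)
  expect_true(b$significant)
  expect_gt(b$ci[1], 0)
})
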