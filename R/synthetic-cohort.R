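#' Specify one cohort of a synthetic multicohort study
#'
#' Describes a contributing site: its size, visit schedule, age window,
#' covariate prevalences, mean offsets relative to the pooled reference
#' curve, and how noisy its measurements are relative to the base residual
#' sd. Cross-sectional cohorts are expressed with `visits_per_subject =
#' c(1, 1)`.
#'
#' @param cohort_id Cohort label.
#' @param n_subjects Number of subjects (>= 1).
#' @param visits_per_subject Integer range `c(min, max)` of visits.
#' @param age_window_days Interval `c(lo, hi)` within [5, 2250] postnatal
#'   days from which visit ages are drawn.
#' @param residual_sd_scale Positive multiplier on the base residual sd
#'   (cohort-specific measurement noise).
#' @param covariate_prevalences Named probabilities for `male`, `preterm`,
#'   `low_bw`, `low_medu`, `low_income`.
#' @param cohort_shift_intercept,cohort_shift_asymptote Cohort mean shifts
#'   expressed as fractions of the region's reference intercept/asymptote
#'   (dimensionless, so one number serves regions whose volumes span three
#'   orders of magnitude).
#' @param missing_income_prob Probability that the observed family-income
#'   indicator is masked to `NA` (the truth still drives generation).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, n_subjects,
                        visits_per_subject = c(1L, 1L),
                        age_window_days = c(5, 2250),
                        residual_sd_scale = 1,
                        covariate_prevalences = c(male = 0.5, preterm = 0.1,
                                                  low_bw = 0.1, low_medu = 0.25,
                                                  low_income = 0.3),
                        cohort_shift_intercept = 0,
                        cohort_shift_asymptote = 0,
                        missing_income_prob = 0) {
  cov_names <- c("male", "preterm", "low_bw", "low_medu", "low_income")
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("invalid n_subjects: must be >= 1")
  if (length(visits_per_subject) != 2L || any(visits_per_subject < 1) ||
      visits_per_subject[1] > visits_per_subject[2])
    stop("invalid visits_per_subject: need c(min, max) with 1 <= min <= max")
  if (length(age_window_days) != 2L || age_window_days[1] >= age_window_days[2])
    stop("invalid age_window_days: window is empty")
  if (!is.numeric(residual_sd_scale) || residual_sd_scale <= 0)
    stop("invalid residual_sd_scale: must be > 0")
  p <- covariate_prevalences
  if (!all(cov_names %in% names(p)))
    stop("covariate_prevalences must name: ", paste(cov_names, collapse = ", "))
  p <- p[cov_names]
  if (any(p < 0 | p > 1))
    stop("invalid covariate_prevalences: probabilities must lie in [0, 1] (",
         paste(cov_names[p < 0 | p > 1], collapse = ", "), ")")
  if (missing_income_prob < 0 || missing_income_prob > 1)
    stop("invalid missing_income_prob: must lie in [0, 1]")
  structure(list(cohort_id = as.character(cohort_id),
                 n_subjects = as.integer(n_subjects),
                 visits_per_subject = as.integer(visits_per_subject),
                 age_window_days = age_window_days,
                 residual_sd_scale = residual_sd_scale,
                 covariate_prevalences = p,
                 cohort_shift_intercept = cohort_shift_intercept,
                 cohort_shift_asymptote = cohort_shift_asymptote,
                 missing_income_prob = missing_income_prob),
            class = "cohort_spec")
}

#' Default eight-cohort layout of the synthetic study
#'
#' Emulates a global multicohort infant-imaging consortium: eight cohorts
#' of unequal size, three of them cross-sectional (a neonatal cohort
#' scanned in the first weeks, an early-infancy cohort, and a preschool
#' cohort scanned at 3-6 years), the rest longitudinal with mixed visit
#' schedules; covariate prevalences differ markedly between sites (e.g. a
#' low-SES birth cohort versus low-risk volunteer samples), and sites
#' differ in mean offsets and residual noise.
#'
#' @return A list of [cohort_spec()] objects.
#' @export
default_cohorts <- function() {
  list(
    cohort_spec("site_A", 172, c(1L, 3L), c(5, 1825), 1.0,
                c(male = 0.465, preterm = 0.012, low_bw = 0.006,
                  low_medu = 0.029, low_income = 0.083),
                0.010, 0.008, missing_income_prob = 0.023),
    cohort_spec("site_B", 130, c(1L, 2L), c(120, 2000), 1.1,
                c(male = 0.508, preterm = 0.023, low_bw = 0.046,
                  low_medu = 0.023, low_income = 0.077),
                -0.012, -0.006, missing_income_prob = 0.10),
    cohort_spec("site_C", 135, c(1L, 1L), c(14, 40), 1.4,
                c(male = 0.519, preterm = 0.067, low_bw = 0.037,
                  low_medu = 0.948, low_income = 0.333),
                0.015, 0.010, missing_income_prob = 0),
    cohort_spec("site_D", 1013, c(1L, 3L), c(5, 2250), 1.0,
                c(male = 0.531, preterm = 0.379, low_bw = 0.315,
                  low_medu = 0.346, low_income = 0.433),
                0, 0, missing_income_prob = 0.065),
    cohort_spec("site_E", 357, c(1L, 2L), c(5, 1825), 0.9,
                c(male = 0.493, preterm = 0.059, low_bw = 0.070,
                  low_medu = 0.367, low_income = 0.205),
                -0.008, 0.012, missing_income_prob = 0.07),
    cohort_spec("site_F", 86, c(1L, 3L), c(180, 730), 0.8,
                c(male = 0.547, preterm = 0.012, low_bw = 0.012,
                  low_medu = 0.02, low_income = 0.143),
                0.006, -0.010, missing_income_prob = 0.023),
    cohort_spec("site_G", 127, c(1L, 1L), c(1100, 2250), 1.2,
                c(male = 0.575, preterm = 0.079, low_bw = 0.031,
                  low_medu = 0.039, low_income = 0.30),
                -0.005, 0.005, missing_income_prob = 0.30),
    cohort_spec("site_H", 88, c(1L, 1L), c(5, 60), 1.3,
                c(male = 0.590, preterm = 0.068, low_bw = 0.045,
                  low_medu = 0.330, low_income = 0.571),
                0.008, -0.008, missing_income_prob = 0.045)
  )
}

.regions <- c("ICV", "thalamus", "hippocampus", "amygdala",
              "caudate", "putamen", "pallidum")
.scales <- c("gross_motor", "visual_reception", "fine_motor",
             "receptive_language", "expressive_language")
.covariates <- c("male", "preterm", "low_bw", "low_medu", "low_income")

#' Cognitive-scale validity windows (postnatal days)
#'
#' Raw Mullen scores are informative only within scale-specific age
#' ranges: gross motor 75-1,275 d; fine motor and visual reception
#' 75-1,776 d; receptive and expressive language 75-2,963 d.
#'
#' @return A named list of `c(lo, hi)` windows, one per scale.
#' @export
scale_age_windows <- function() {
  list(gross_motor = c(75, 1275),
       visual_reception = c(75, 1776),
       fine_motor = c(75, 1776),
       receptive_language = c(75, 2963),
       expressive_language = c(75, 2963))
}

#' Ground-truth parameters of the synthetic study
#'
#' Returns the generative parameters: for each of the seven volumetric
#' outcomes (ICV and six subcortical structures) the reference growth
#' triple (asymptote, intercept, log-rate), the additive effects of the
#' five binary covariates on asymptote and on intercept, and the
#' random-effect / residual standard deviations; for each of the five
#' cognitive scales the reference intercept, the common age slope
#' (raw-score points per day), covariate effects, and variance components.
#'
#' Curve and effect values are the fitted estimates reported for a large
#' multicohort study of 2,108 children; variance components are not
#' reported there and are set to defaults documented in the methods
#' vignette (random-effect sds 5% of the reference parameter they perturb,
#' base residual sd 2% of the reference asymptote; cognitive total sd 3
#' raw-score points split to match the tabulated interindividual-variation
#' percentages).
#'
#' @return A list of class `truth_params` with elements `volumes` (per
#'   region: `params`, `effects_asymptote`, `effects_intercept`, `sd_u_asym`,
#'   `sd_u_int`, `sd_e`) and `cognition` (per scale: `intercept`, `slope`,
#'   `effects`, `sd_u`, `sd_e`, `age_window`).
#' @export
default_truth <- function() {
  ref_asy <- c(ICV = 1285208.00, thalamus = 13292.35, hippocampus = 5159.63,
               amygdala = 2082.93, caudate = 6947.72, putamen = 8535.24,
               pallidum = 2114.39)
  ref_int <- c(ICV = 402952.30, thalamus = 8924.17, hippocampus = 2190.29,
               amygdala = 398.78, caudate = 3711.22, putamen = 3345.64,
               pallidum = 1141.27)
  ref_lrate <- c(ICV = -5.66, thalamus = -6.64, hippocampus = -6.02,
                 amygdala = -5.60, caudate = -6.26, putamen = -6.01,
                 pallidum = -6.16)
  # rows: covariates, columns: regions
  eff_int <- rbind(
    male       = c(19177.04, 423.13, 80.27, 19.84, 114.07, 226.31, 40.48),
    preterm    = c(-48142.85, -282.32, -179.79, -109.84, -82.43, -218.48, -71.87),
    low_bw     = c(-45116.71, -295.56, -176.08, -74.96, -185.32, -385.05, -96.05),
    low_medu   = c(-16269.64, -186.31, -4.71, 7.27, -120.10, 383.86, 205.47),
    low_income = c(4526.54, -92.39, -58.86, -13.37, 10.61, -254.62, -51.61))
  eff_asy <- rbind(
    male       = c(112624.10, 990.70, 365.18, 190.05, 325.09, 671.36, 182.94),
    preterm    = c(17063.40, -184.55, -93.51, -41.81, -143.08, -56.33, -34.43),
    low_bw     = c(-26109.07, -110.19, -87.64, -24.73, -146.68, -165.53, -69.30),
    low_medu   = c(-45624.15, -394.91, -106.46, -88.94, -298.09, -260.66, -92.64),
    low_income = c(-14994.01, -398.43, -162.85, -45.89, -233.97, -336.27, -85.68))
  colnames(eff_int) <- colnames(eff_asy) <- .regions

  volumes <- lapply(stats::setNames(.regions, .regions), function(r) {
    list(params = growth_params(ref_asy[[r]], ref_int[[r]], ref_lrate[[r]]),
         effects_asymptote = eff_asy[, r],
         effects_intercept = eff_int[, r],
         sd_u_asym = 0.05 * ref_asy[[r]],
         sd_u_int = 0.05 * ref_int[[r]],
         sd_e = 0.02 * ref_asy[[r]])
  })

  cog_int <- c(gross_motor = 7.65, visual_reception = 6.13, fine_motor = 7.5,
               receptive_language = 5.76, expressive_language = 5.52)
  cog_eff <- rbind(
    male       = c(-0.19, -0.51, -0.30, -0.40, -0.40),
    preterm    = c(-0.92, -0.88, -0.91, -1.32, -1.28),
    low_bw     = c(-0.26, -0.64, -0.52, -0.06, -0.18),
    low_medu   = c(0.16, -0.74, -0.34, -0.46, -0.27),
    low_income = c(0.01, -0.60, -0.11, -0.80, -0.53))
  colnames(cog_eff) <- .scales
  # random-intercept share of total variance per scale
  iiv <- c(gross_motor = 21.5, visual_reception = 10.37, fine_motor = 6.07,
           receptive_language = 13.12, expressive_language = 19.05) / 100
  total_var <- 3^2
  windows <- scale_age_windows()
  cognition <- lapply(stats::setNames(.scales, .scales), function(s) {
    list(intercept = cog_int[[s]], slope = 0.03, effects = cog_eff[, s],
         sd_u = sqrt(iiv[[s]] * total_var),
         sd_e = sqrt((1 - iiv[[s]]) * total_var),
         age_window = windows[[s]])
  })

  structure(list(volumes = volumes, cognition = cognition),
            class = "truth_params")
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "truth_params"))
  for (r in names(truth$volumes)) {
    tr <- truth$volumes[[r]]
    if (!(tr$params$asymptote > tr$params$intercept && tr$params$intercept > 0))
      stop("region ", r, ": need asymptote > intercept > 0")
    if (tr$sd_u_asym < 0 || tr$sd_u_int < 0 || tr$sd_e < 0)
      stop("region ", r, ": negative sd")
  }
  for (s in names(truth$cognition)) {
    tc <- truth$cognition[[s]]
    if (tc$sd_u < 0 || tc$sd_e < 0) stop("scale ", s, ": negative sd")
  }
  invisible(truth)
}

# Draw covariates, visit counts and ages for every subject of one cohort.
# Covariates are constant within subject; visit ages are unique integer days
# within the cohort window.
draw_subjects <- function(spec, id_offset) {
  n <- spec$n_subjects
  p <- spec$covariate_prevalences
  cov <- sapply(.covariates, function(k) stats::rbinom(n, 1L, p[[k]]))
  cov <- matrix(cov, nrow = n, dimnames = list(NULL, .covariates))
  miss <- stats::runif(n) < spec$missing_income_prob
  nv <- if (spec$visits_per_subject[1] == spec$visits_per_subject[2])
    rep(spec$visits_per_subject[1], n)
  else
    sample(seq(spec$visits_per_subject[1], spec$visits_per_subject[2]),
           n, replace = TRUE)
  lo <- ceiling(spec$age_window_days[1]); hi <- floor(spec$age_window_days[2])
  ages <- lapply(nv, function(k) {
    pool <- lo:hi
    sort(if (length(pool) >= k) sample(pool, k) else pool)
  })
  list(subject_id = sprintf("%s_s%04d", spec$cohort_id, id_offset + seq_len(n)),
       cov = cov, income_missing = miss, ages = ages)
}

#' Simulate a long-format table of regional brain volumes
#'
#' Generates volumes under the hierarchical asymptotic growth model: each
#' subject's asymptote and intercept are the reference values plus additive
#' covariate effects, a cohort mean shift and independent zero-mean normal
#' subject effects; observations add normal noise whose sd is the base
#' residual sd times the cohort's `residual_sd_scale`. The rate constant is
#' shared. Deterministic for a fixed seed (cohorts processed in list order,
#' subjects in id order).
#'
#' @param cohort_specs List of [cohort_spec()] objects.
#' @param truth A `truth_params` object, e.g. [default_truth()].
#' @param seed Integer seed.
#' @param regions Regions to generate; default all seven.
#' @return A data.frame with columns `subject_id, cohort, age_days, male,
#'   preterm, low_bw, low_medu, low_income, region, value` (volume in mm3).
#' @export
simulate_volumes <- function(cohort_specs, truth = default_truth(), seed,
                             regions = names(truth$volumes)) {
  stopifnot(all(vapply(cohort_specs, inherits, TRUE, "cohort_spec")))
  validate_truth(truth)
  stopifnot(all(regions %in% names(truth$volumes)))
  set.seed(as.integer(seed))
  out <- vector("list", length(cohort_specs))
  for (ci in seq_along(cohort_specs)) {
    spec <- cohort_specs[[ci]]
    subj <- draw_subjects(spec, 0L)
    n <- spec$n_subjects
    rows <- vector("list", length(regions))
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      tr <- truth$volumes[[r]]
      u1 <- stats::rnorm(n, 0, tr$sd_u_asym)
      u2 <- stats::rnorm(n, 0, tr$sd_u_int)
      asy <- tr$params$asymptote * (1 + spec$cohort_shift_asymptote) +
        drop(subj$cov %*% tr$effects_asymptote) + u1
      int <- tr$params$intercept * (1 + spec$cohort_shift_intercept) +
        drop(subj$cov %*% tr$effects_intercept) + u2
      nv <- lengths(subj$ages)
      idx <- rep(seq_len(n), nv)
      age <- unlist(subj$ages)
      w <- exp(-exp(tr$params$log_rate) * age)
      mu <- asy[idx] + (int[idx] - asy[idx]) * w
      vol <- mu + stats::rnorm(length(mu), 0, tr$sd_e * spec$residual_sd_scale)
      bad <- which(vol <= 0)
      while (length(bad)) {   # volumes are physical; redraw rare nonpositive noise
        vol[bad] <- mu[bad] +
          stats::rnorm(length(bad), 0, tr$sd_e * spec$residual_sd_scale)
        bad <- bad[vol[bad] <= 0]
      }
      inc <- subj$cov[idx, "low_income"]
      inc[subj$income_missing[idx]] <- NA_integer_
      rows[[ri]] <- data.frame(
        subject_id = subj$subject_id[idx], cohort = spec$cohort_id,
        age_days = age,
        male = subj$cov[idx, "male"], preterm = subj$cov[idx, "preterm"],
        low_bw = subj$cov[idx, "low_bw"], low_medu = subj$cov[idx, "low_medu"],
        low_income = inc, region = r, value = vol,
        stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a long-format table of cognitive raw scores
#'
#' Scores follow a linear-in-age model per scale: reference intercept plus
#' age slope, additive covariate effects, a subject random intercept and
#' heteroscedastic cohort noise. Visit ages outside a scale's validity
#' window are omitted (a message reports the count).
#'
#' @inheritParams simulate_volumes
#' @param scales Scales to generate; default all five.
#' @return A data.frame with columns `subject_id, cohort, age_days, male,
#'   preterm, low_bw, low_medu, low_income, scale, value` (raw score).
#' @export
simulate_cognition <- function(cohort_specs, truth = default_truth(), seed,
                               scales = names(truth$cognition)) {
  stopifnot(all(vapply(cohort_specs, inherits, TRUE, "cohort_spec")))
  validate_truth(truth)
  stopifnot(all(scales %in% names(truth$cognition)))
  set.seed(as.integer(seed))
  out <- vector("list", length(cohort_specs))
  n_omitted <- 0L
  for (ci in seq_along(cohort_specs)) {
    spec <- cohort_specs[[ci]]
    subj <- draw_subjects(spec, 0L)
    n <- spec$n_subjects
    rows <- vector("list", length(scales))
    for (si in seq_along(scales)) {
      s <- scales[[si]]
      tc <- truth$cognition[[s]]
      u <- stats::rnorm(n, 0, tc$sd_u)
      nv <- lengths(subj$ages)
      idx <- rep(seq_len(n), nv)
      age <- unlist(subj$ages)
      keep <- age >= tc$age_window[1] & age <= tc$age_window[2]
      n_omitted <- n_omitted + sum(!keep)
      idx <- idx[keep]; age <- age[keep]
      if (!length(idx)) { rows[[si]] <- NULL; next }
      mu <- tc$intercept + tc$slope * age +
        drop(subj$cov %*% tc$effects)[idx] + u[idx]
      sc <- mu + stats::rnorm(length(mu), 0, tc$sd_e * spec$residual_sd_scale)
      inc <- subj$cov[idx, "low_income"]
      inc[subj$income_missing[idx]] <- NA_integer_
      rows[[si]] <- data.frame(
        subject_id = subj$subject_id[idx], cohort = spec$cohort_id,
        age_days = age,
        male = subj$cov[idx, "male"], preterm = subj$cov[idx, "preterm"],
        low_bw = subj$cov[idx, "low_bw"], low_medu = subj$cov[idx, "low_medu"],
        low_income = inc, scale = s, value = sc,
        stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (n_omitted > 0)
    message(n_omitted, " visit-scale rows omitted (age outside scale validity window)")
  attr(res, "n_omitted") <- n_omitted
  res
}
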