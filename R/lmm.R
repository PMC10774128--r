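#' Specify a linear mixed model for scaled volumes or cognitive scores
#'
#' Two response families are supported: cognitive raw scores modeled with
#' an overall mean, a single shared age slope, covariate and cohort fixed
#' effects; and ICV-scaled volumes (`volume / ICV * 1000`) modeled without
#' an age slope. Both carry a subject random intercept and cohort-specific
#' residual variances. Covariate-by-age interactions may be added when an
#' age slope is present.
#'
#' @param response `"raw"` (use `value` as is) or `"icv_scaled"`
#'   (`value / same-visit ICV * 1000`).
#' @param age_slope Include a linear age term (days).
#' @param covariates Binary covariate columns to adjust for.
#' @param interactions Subset of `covariates` whose interaction with age
#'   is included; requires `age_slope = TRUE`.
#' @param cohort_effects Include cohort mean dummies.
#' @param heteroscedastic Cohort-specific residual variances.
#' @param random_intercept Subject random intercept (`FALSE` reduces the
#'   model to generalized least squares).
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response = c("raw", "icv_scaled"),
                     age_slope = TRUE,
                     covariates = c("male", "preterm", "low_bw",
                                    "low_medu", "low_income"),
                     interactions = character(0),
                     cohort_effects = TRUE,
                     heteroscedastic = TRUE,
                     random_intercept = TRUE) {
  response <- match.arg(response)
  if (length(interactions) && !age_slope)
    stop("interactions with age require age_slope = TRUE")
  if (!all(interactions %in% covariates))
    stop("interactions must be a subset of covariates")
  structure(list(response = response, age_slope = age_slope,
                 covariates = covariates, interactions = interactions,
                 cohort_effects = cohort_effects,
                 heteroscedastic = heteroscedastic,
                 random_intercept = random_intercept),
            class = "lmm_spec")
}

#' Fit a heteroscedastic linear mixed model to a long table
#'
#' Maximum-likelihood fit of
#' `y_ij = mu + (age slope) + sum_k beta_k x_jk + u_j + e_ij`,
#' with subject random intercept `u_j` and residual variances differing by
#' cohort, via [hetlmm()]. For ICV-scaled volumes the response is
#' `volume / same-visit ICV * 1000`; visits lacking an ICV measurement are
#' dropped with a logged count. Cohorts contributing fewer than 3
#' observations cannot support their own variance and are pooled with the
#' reference cohort.
#'
#' @param data Long table from [simulate_volumes()] or
#'   [simulate_cognition()] (or read with [read_long_table()]).
#' @param spec An [lmm_spec()].
#' @param outcome Which `region` or `scale` to fit when several are present.
#' @return An object of class `lmm_fit` with the coefficient table,
#'   `var_u`, `cohort_var_ratios` (residual variance ratios),
#'   `sigma2` (reference residual variance), `loglik`,
#'   `interindividual_variation` (percent), BLUPs and row accounting.
#' @export
fit_lmm <- function(data, spec = lmm_spec(), outcome = NULL) {
  stopifnot(inherits(spec, "lmm_spec"))
  key <- if ("scale" %in% names(data)) "scale" else "region"
  if (spec$response == "icv_scaled") {
    if (!"region" %in% names(data)) stop("icv_scaled response needs a volume table")
    if (is.null(outcome) || outcome == "ICV")
      stop("icv_scaled response needs a non-ICV outcome region")
    icv <- data[data$region == "ICV", c("subject_id", "age_days", "value")]
    names(icv)[3] <- "icv"
    if (!nrow(icv)) stop("no ICV rows available for scaling")
    n0 <- sum(data$region == outcome)
    dat <- merge(data[data$region == outcome, , drop = FALSE], icv,
                 by = c("subject_id", "age_days"))
    n_no_icv <- n0 - nrow(dat)
    if (n_no_icv > 0) message(n_no_icv, " visits dropped (no same-visit ICV)")
    dat$value <- dat$value / dat$icv * 1000
    data <- dat
  } else {
    if (!is.null(outcome)) data <- data[data[[key]] == outcome, , drop = FALSE]
    if (length(unique(data[[key]])) > 1L)
      stop("data holds multiple ", key, "s; pass `outcome`")
    n0 <- nrow(data)
  }

  keep <- stats::complete.cases(data[, c("subject_id", "cohort", "age_days",
                                         spec$covariates, "value")])
  data <- data[keep, , drop = FALSE]
  n_dropped <- n0 - nrow(data)
  if (n_dropped > 0) message(n_dropped, " rows dropped (incomplete cases)")

  # pool cohorts too small to carry their own residual variance
  vgrp <- NULL
  if (spec$heteroscedastic && length(unique(data$cohort)) > 1L) {
    coh <- factor(data$cohort)
    small <- names(which(table(coh) < 3L))
    if (length(small)) {
      message("cohort(s) pooled with reference for variance estimation: ",
              paste(small, collapse = ", "))
      lv <- levels(coh)
      coh <- factor(ifelse(as.character(coh) %in% small, lv[1],
                           as.character(coh)))
    }
    vgrp <- coh
  }

  X <- cbind(`(intercept)` = rep(1, nrow(data)))
  if (spec$age_slope) X <- cbind(X, age = data$age_days)
  for (k in spec$covariates) {
    if (length(unique(data[[k]])) < 2L) stop("covariate constant in data: ", k)
    X <- cbind(X, data[[k]]); colnames(X)[ncol(X)] <- k
  }
  if (spec$cohort_effects && length(unique(data$cohort)) > 1L) {
    coh <- factor(data$cohort)
    for (lv in levels(coh)[-1L]) {
      X <- cbind(X, as.numeric(coh == lv))
      colnames(X)[ncol(X)] <- paste0("cohort:", lv)
    }
  }
  for (k in spec$interactions) {
    X <- cbind(X, data[[k]] * data$age_days)
    colnames(X)[ncol(X)] <- paste0(k, ":age")
  }

  subj <- factor(data$subject_id)
  Z <- if (spec$random_intercept) cbind(intercept = rep(1, nrow(data))) else NULL
  fit <- hetlmm(data$value, X, Z, subj, vgrp)

  est <- fit$coefficients
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(fit$se),
                      z = unname(est / fit$se),
                      p = 2 * stats::pnorm(-abs(unname(est / fit$se))),
                      stringsAsFactors = FALSE)
  var_u <- if (spec$random_intercept) fit$D[1, 1] else 0

  # count-weighted average residual variance across cohorts
  resvar <- fit$sigma2 * fit$var_group_ratios
  wts <- if (is.null(vgrp)) length(data$value) else as.numeric(table(vgrp))
  mean_resvar <- sum(resvar * wts) / sum(wts)
  iiv <- if (var_u + mean_resvar == 0) 0 else
    100 * var_u / (var_u + mean_resvar)

  structure(list(
    coefficients = coefs, var_u = var_u, sigma2 = fit$sigma2,
    cohort_var_ratios = fit$var_group_ratios,
    mean_residual_variance = mean_resvar,
    interindividual_variation = iiv,
    loglik = fit$loglik, convergence = fit$convergence,
    iterations = fit$iterations,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects, n_dropped = n_dropped,
    blups = fit$blups, spec = spec,
    outcome = unique(data[[if (key %in% names(data)) key else "region"]])[1]
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed fit [%s]: %d observations, %d subjects\n",
              x$outcome, x$n_obs, x$n_subjects))
  print(x$coefficients, digits = 4)
  cat(sprintf("  var(u) %.4g, interindividual variation %.2f%%, logLik %.2f\n",
              x$var_u, x$interindividual_variation, x$loglik))
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' Compares two ML fits of nested fixed-effect structures on the same data
#' (e.g. with and without covariate-by-age interactions) using the
#' chi-square reference with degrees of freedom equal to the difference in
#' fixed-effect counts.
#'
#' @param fit_with,fit_without `lmm_fit` objects; `fit_with` must nest
#'   `fit_without`.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
interaction_test <- function(fit_with, fit_without) {
  stopifnot(inherits(fit_with, "lmm_fit"), inherits(fit_without, "lmm_fit"))
  if (fit_with$n_obs != fit_without$n_obs)
    stop("fits are not on the same data (observation counts differ)")
  t1 <- fit_with$coefficients$term; t0 <- fit_without$coefficients$term
  if (!all(t0 %in% t1))
    stop("models are not nested (larger model must contain all smaller-model terms)")
  stat <- max(0, 2 * (fit_with$loglik - fit_without$loglik))
  df <- length(t1) - length(t0)
  list(statistic = stat, df = df,
       p_value = if (df == 0L) 1 else
         stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Interindividual variation explained by the subject random intercept
#'
#' The share of total variance attributable to stable between-subject
#' differences: `100 * var(u) / (var(u) + mean residual variance)`, the
#' residual variance averaged over cohorts with observation-count weights.
#'
#' @param fit An `lmm_fit`.
#' @return Percentage in [0, 100].
#' @export
interindividual_variation <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  fit$interindividual_variation
}
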