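#' Specify the hierarchical growth model
#'
#' Defines which binary covariates carry fixed effects on the asymptote and
#' intercept, whether cohort enters as fixed mean shifts on both, whether
#' residual variances are cohort-specific, and the random-effect structure.
#' The rate constant is a single fixed scalar: it carries no covariate or
#' random effects, by construction.
#'
#' @param covariates Character vector of binary covariate columns; the
#'   `"full"` variant uses all five sociodemographic factors, the
#'   `"no-income"` sensitivity variant drops `low_income` (kept separate
#'   because family income and maternal education are highly correlated).
#' @param cohort_effects Include cohort dummies on asymptote and intercept.
#' @param heteroscedastic Estimate cohort-specific residual variance ratios.
#' @param random_effects Subject-specific asymptote and intercept effects
#'   (`TRUE`), or none (`FALSE`, reduces to weighted least squares).
#' @param unstructured_re Estimate the correlation between the two subject
#'   effects; independent by default.
#' @param log_rate_bracket Search interval for the log rate constant.
#' @return An object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(covariates = c("male", "preterm", "low_bw",
                                             "low_medu", "low_income"),
                              cohort_effects = TRUE,
                              heteroscedastic = TRUE,
                              random_effects = TRUE,
                              unstructured_re = FALSE,
                              log_rate_bracket = c(-9, -3)) {
  stopifnot(length(log_rate_bracket) == 2L,
            log_rate_bracket[1] < log_rate_bracket[2])
  structure(list(covariates = covariates, cohort_effects = cohort_effects,
                 heteroscedastic = heteroscedastic,
                 random_effects = random_effects,
                 unstructured_re = unstructured_re,
                 log_rate_bracket = log_rate_bracket),
            class = "growth_model_spec")
}

#' @rdname growth_model_spec
#' @param variant Shorthand: `"full"` or `"no-income"`.
#' @export
growth_model_variant <- function(variant = c("full", "no-income")) {
  variant <- match.arg(variant)
  covs <- c("male", "preterm", "low_bw", "low_medu", "low_income")
  if (variant == "no-income") covs <- setdiff(covs, "low_income")
  growth_model_spec(covariates = covs)
}

# Build the base (per-parameter) design: intercept column, covariates,
# cohort dummies with the first cohort level as reference.
base_design <- function(dat, covariates, cohort_effects) {
  X <- cbind(`(ref)` = rep(1, nrow(dat)))
  for (k in covariates) {
    xk <- dat[[k]]
    if (length(unique(xk)) < 2L)
      stop("covariate constant in data: ", k)
    X <- cbind(X, xk)
    colnames(X)[ncol(X)] <- k
  }
  if (cohort_effects && length(unique(dat$cohort)) > 1L) {
    coh <- factor(dat$cohort)
    for (lv in levels(coh)[-1L]) {
      X <- cbind(X, as.numeric(coh == lv))
      colnames(X)[ncol(X)] <- paste0("cohort:", lv)
    }
  }
  X
}

#' Fit the hierarchical asymptotic growth model
#'
#' Maximizes the marginal likelihood of the nonlinear mixed model
#' `y_ij = f(x_ij; theta_j) + e_ij` with
#' `f(x; theta) = theta1 + (theta2 - theta1) exp(-exp(theta3) x)`, where
#' asymptote and intercept carry covariate fixed effects, cohort mean
#' shifts and independent subject random effects, and residual variances
#' are cohort-specific. Exploits that for fixed `theta3` the model is
#' linear in all remaining parameters with weights
#' `w = exp(-exp(theta3) x)`: the scalar `theta3` is profiled over its
#' bracket by one-dimensional optimization, the inner heteroscedastic
#' linear mixed problem being solved by [hetlmm()] (itself exact in the
#' fixed effects and residual scale). Standard errors are Wald, from the
#' observed information of the joint design augmented with the gradient of
#' the mean in `theta3`; p-values use the standard normal reference.
#'
#' @param data A long volume table (one region) as from
#'   [simulate_volumes()]; columns `subject_id, cohort, age_days`, the
#'   model covariates, and `value`.
#' @param spec A [growth_model_spec()].
#' @param region If `data` holds several regions, which one to fit.
#' @return An object of class `growth_fit`: coefficient table
#'   (`estimate`, `se`, `z`, `p` per term), reference [growth_params()],
#'   random-effect variances, cohort variance ratios, log-likelihood,
#'   convergence metadata, BLUPs, and row-accounting.
#' @export
fit_growth <- function(data, spec = growth_model_spec(), region = NULL) {
  stopifnot(inherits(spec, "growth_model_spec"))
  if (!is.null(region)) data <- data[data$region == region, , drop = FALSE]
  if ("region" %in% names(data) && length(unique(data$region)) > 1L)
    stop("data holds multiple regions; pass `region`")
  n0 <- nrow(data)
  keep <- stats::complete.cases(data[, c("subject_id", "cohort", "age_days",
                                         spec$covariates, "value")])
  data <- data[keep, , drop = FALSE]
  n_dropped <- n0 - nrow(data)
  if (n_dropped > 0)
    message(n_dropped, " rows dropped (incomplete covariates)")
  if (length(unique(data$age_days)) < 2L)
    stop("need at least 2 distinct ages to identify the growth curve")

  Xb <- base_design(data, spec$covariates, spec$cohort_effects)
  pb <- ncol(Xb)
  age <- data$age_days
  subj <- factor(data$subject_id)
  vgrp <- if (spec$heteroscedastic) factor(data$cohort) else NULL
  y <- data$value

  inner_cache <- new.env(parent = emptyenv())
  inner_cache$start <- NULL
  inner <- function(theta3, minimal = TRUE) {
    w <- exp(-exp(theta3) * age)
    X <- cbind((1 - w) * Xb, w * Xb)
    colnames(X) <- c(paste0("asym:", colnames(Xb)), paste0("int:", colnames(Xb)))
    Z <- if (spec$random_effects) cbind(asym = 1 - w, int = w) else NULL
    fit <- hetlmm(y, X, Z, subj, vgrp, unstructured = spec$unstructured_re,
                  start = inner_cache$start, minimal = minimal)
    if (is.finite(fit$loglik)) inner_cache$start <- fit$phi
    fit
  }
  profile_ll <- function(theta3) inner(theta3)$loglik

  # coarse grid, then golden-section refinement in the best sub-bracket
  grid <- seq(spec$log_rate_bracket[1], spec$log_rate_bracket[2], length.out = 13)
  ll_grid <- vapply(grid, profile_ll, 0)
  i <- which.max(ll_grid)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (!any(is.finite(ll_grid)))
    stop("profile likelihood is degenerate over the whole rate bracket")
  opt <- stats::optimize(profile_ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  theta3 <- opt$maximum
  fit <- inner(theta3, minimal = FALSE)

  # joint Wald covariance over (beta, theta3): augment with d mu / d theta3
  w <- exp(-exp(theta3) * age)
  a_lin <- drop(Xb %*% fit$coefficients[seq_len(pb)])
  b_lin <- drop(Xb %*% fit$coefficients[pb + seq_len(pb)])
  g <- (b_lin - a_lin) * (-age * exp(theta3) * w)
  V <- hetlmm_info_vcov(fit, extra = cbind(log_rate = g))
  est <- c(fit$coefficients, log_rate = theta3)
  se <- sqrt(diag(V))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p = 2 * stats::pnorm(-abs(unname(z))),
                      stringsAsFactors = FALSE)

  ref <- growth_params(est[["asym:(ref)"]], est[["int:(ref)"]], theta3)
  structure(list(
    coefficients = coefs,
    params = ref,
    log_rate = theta3,
    var_u = if (spec$random_effects)
      c(asym = fit$D[1, 1], int = fit$D[2, 2]) else c(asym = 0, int = 0),
    re_cov = fit$D,
    sigma2 = fit$sigma2,
    cohort_var_ratios = fit$var_group_ratios,
    loglik = fit$loglik,
    convergence = fit$convergence,
    iterations = fit$iterations,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects,
    n_dropped = n_dropped,
    blups = fit$blups,
    spec = spec,
    region = if (!is.null(region)) region else
      if ("region" %in% names(data)) unique(data$region) else NA_character_,
    base_terms = colnames(Xb)
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Asymptotic growth fit%s: %d observations, %d subjects\n",
              if (is.na(x$region)) "" else paste0(" [", x$region, "]"),
              x$n_obs, x$n_subjects))
  cat(sprintf("  asymptote %.2f, intercept %.2f, log-rate %.4f (maturation %.1f y)\n",
              x$params$asymptote, x$params$intercept, x$log_rate,
              days_to_years(maturation_age(x$params))))
  cat(sprintf("  logLik %.2f, converged: %s\n", x$loglik, x$convergence))
  invisible(x)
}

#' Predict volume from a growth fit
#'
#' Population prediction from the fixed effects at given covariate values
#' and age; optionally adds a subject's empirical-Bayes (BLUP) random
#' effects to give a subject-specific curve.
#'
#' @param fit A `growth_fit`.
#' @param covariates Named list/vector of binary covariate values (defaults
#'   to the reference level, 0, for any omitted) and optionally `cohort`.
#' @param age_days Age(s) in days.
#' @param subject_id Optional subject identifier whose BLUPs to add.
#' @return Predicted volume(s) in mm3.
#' @export
predict_volume <- function(fit, covariates = list(), age_days,
                           subject_id = NULL) {
  stopifnot(inherits(fit, "growth_fit"))
  if (any(age_days < 0)) stop("age_days must be non-negative")
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  xb <- stats::setNames(rep(0, length(fit$base_terms)), fit$base_terms)
  xb["(ref)"] <- 1
  for (k in names(covariates)) {
    if (k == "cohort") {
      col <- paste0("cohort:", covariates[[k]])
      if (col %in% names(xb)) xb[col] <- 1
      # reference cohort: no dummy column
    } else {
      if (!k %in% names(xb)) stop("unknown covariate: ", k)
      xb[k] <- as.numeric(covariates[[k]])
    }
  }
  asy <- sum(est[paste0("asym:", names(xb))] * xb)
  int <- sum(est[paste0("int:", names(xb))] * xb)
  if (!is.null(subject_id)) {
    if (is.null(fit$blups) || !subject_id %in% rownames(fit$blups))
      stop("unknown subject_id: ", subject_id)
    asy <- asy + fit$blups[subject_id, 1]
    int <- int + fit$blups[subject_id, 2]
  }
  w <- exp(-exp(fit$log_rate) * age_days)
  asy + (int - asy) * w
}
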