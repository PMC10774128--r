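#' Predict a cognitive score from a linear mixed fit
#'
#' Population prediction from the fixed effects at given covariate values
#' and age, optionally adding a subject's BLUP random intercept.
#'
#' @param fit An `lmm_fit`.
#' @param covariates Named list of binary covariate values and optionally
#'   `cohort`; omitted covariates sit at the reference level 0.
#' @param age_days Age(s) in days (ignored if the fit has no age slope).
#' @param subject_id Optional subject whose random intercept to add.
#' @return Predicted response value(s).
#' @export
predict_lmm <- function(fit, covariates = list(), age_days = 0,
                        subject_id = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  mu <- est[["(intercept)"]]
  if ("age" %in% names(est)) mu <- mu + est[["age"]] * age_days
  for (k in names(covariates)) {
    if (k == "cohort") {
      col <- paste0("cohort:", covariates[[k]])
      if (col %in% names(est)) mu <- mu + est[[col]]
    } else if (k %in% names(est)) {
      mu <- mu + est[[k]] * as.numeric(covariates[[k]])
      ia <- paste0(k, ":age")
      if (ia %in% names(est))
        mu <- mu + est[[ia]] * as.numeric(covariates[[k]]) * age_days
    } else stop("unknown covariate: ", k)
  }
  if (!is.null(subject_id)) {
    if (is.null(fit$blups) || !subject_id %in% rownames(fit$blups))
      stop("unknown subject_id: ", subject_id)
    mu <- mu + fit$blups[subject_id, 1]
  }
  unname(mu)
}

#' One row of covariates per subject from a long table
#'
#' @param data Long table with subject-constant covariate columns.
#' @return A data.frame keyed by `subject_id` with `cohort` and the five
#'   binary covariates.
#' @export
subject_table <- function(data) {
  cols <- c("subject_id", "cohort", "male", "preterm", "low_bw",
            "low_medu", "low_income")
  out <- unique(data[, intersect(cols, names(data)), drop = FALSE])
  if (anyDuplicated(out$subject_id))
    stop("covariates vary within subject; long table is malformed")
  rownames(out) <- out$subject_id
  out
}

#' Panel of subject-level predictions at a common age
#'
#' Builds one row per subject holding predicted volumes from each growth
#' fit and predicted cognitive scores from each linear mixed fit, all
#' evaluated at the same age (default 730.5 days = age 2, chosen because
#' data are densest there), plus the preterm/full-term stratum. By default
#' predictions are subject-specific (fixed effects plus BLUPs); subjects
#' absent from any of the fits are dropped with a logged count. A
#' population-only mode (`include_blups = FALSE`) keeps every subject and
#' uses fixed effects alone.
#'
#' @param growth_fits Named list of `growth_fit` objects (one per region).
#' @param cognitive_fits Named list of `lmm_fit` objects (one per scale).
#' @param subjects Subject covariate table from [subject_table()].
#' @param age_days Common prediction age; default 730.5.
#' @param include_blups Add empirical-Bayes subject effects (default TRUE).
#' @return A data.frame (class `predicted_panel`): `subject_id`, `stratum`,
#'   one column per region and per scale.
#' @export
build_panel <- function(growth_fits, cognitive_fits, subjects,
                        age_days = 730.5, include_blups = TRUE) {
  stopifnot(all(vapply(growth_fits, inherits, TRUE, "growth_fit")),
            all(vapply(cognitive_fits, inherits, TRUE, "lmm_fit")))
  ids <- subjects$subject_id
  if (include_blups) {
    for (f in c(growth_fits, cognitive_fits))
      ids <- intersect(ids, rownames(f$blups))
    n_drop <- length(subjects$subject_id) - length(ids)
    if (n_drop > 0)
      message(n_drop, " subjects dropped (absent from at least one model)")
  }
  if (!length(ids)) stop("no subjects present in all models")
  sub <- subjects[match(ids, subjects$subject_id), , drop = FALSE]
  covnames <- setdiff(names(sub), "subject_id")
  panel <- data.frame(subject_id = ids,
                      stratum = ifelse(sub$preterm == 1, "preterm", "full_term"),
                      stringsAsFactors = FALSE)
  for (r in names(growth_fits)) {
    f <- growth_fits[[r]]
    panel[[r]] <- vapply(seq_along(ids), function(i) {
      cv <- as.list(sub[i, covnames])
      predict_volume(f, cv, age_days,
                     subject_id = if (include_blups) ids[i] else NULL)
    }, 0)
  }
  for (s in names(cognitive_fits)) {
    f <- cognitive_fits[[s]]
    panel[[s]] <- vapply(seq_along(ids), function(i) {
      cv <- as.list(sub[i, covnames])
      predict_lmm(f, cv, age_days,
                  subject_id = if (include_blups) ids[i] else NULL)
    }, 0)
  }
  if (!all(is.finite(as.matrix(panel[, -(1:2)]))))
    stop("non-finite predictions in panel")
  for (st in c("full_term", "preterm"))
    if (!any(panel$stratum == st)) stop("empty stratum: ", st)
  class(panel) <- c("predicted_panel", "data.frame")
  panel
}

#' Correlation matrix of predicted volumes and scores within a stratum
#'
#' Pearson correlations among all panel measures within one stratum, with
#' two-sided p-values from the t transform and a Bonferroni flag applied
#' to the volume-score cells (a family of `n_volumes * n_scores` tests,
#' 35 for the full panel).
#'
#' @param panel A [build_panel()] result.
#' @param stratum `"full_term"` or `"preterm"`.
#' @param volumes,scores Column names of the two measure families; default
#'   all seven regions and all five scales present.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return A list (class `corr_matrix`): `r`, `p`, `significant` matrices,
#'   `threshold`, `n`, `stratum`; zero-variance columns yield `NA`
#'   correlations and are reported in `degenerate`.
#' @export
correlation_matrix <- function(panel, stratum,
                               volumes = intersect(.regions, names(panel)),
                               scores = intersect(.scales, names(panel)),
                               alpha = 0.05) {
  stopifnot(stratum %in% panel$stratum)
  dat <- as.matrix(panel[panel$stratum == stratum, c(volumes, scores)])
  n <- nrow(dat)
  if (n < 4L) stop("stratum too small for correlation (n < 4): ", stratum)
  sds <- apply(dat, 2, stats::sd)
  degenerate <- colnames(dat)[sds == 0]
  if (length(degenerate))
    message("zero-variance column(s), correlations undefined: ",
            paste(degenerate, collapse = ", "))
  r <- suppressWarnings(stats::cor(dat))
  r[degenerate, ] <- NA; r[, degenerate] <- NA
  diag(r) <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- 0
  thr <- bonferroni_threshold(length(volumes) * length(scores), alpha)
  sig <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  sig[volumes, scores] <- p[volumes, scores] < thr
  sig[scores, volumes] <- p[scores, volumes] < thr
  structure(list(r = r, p = p, significant = sig, threshold = thr,
                 n = n, stratum = stratum, volumes = volumes,
                 scores = scores, degenerate = degenerate),
            class = "corr_matrix")
}

#' Bootstrap confidence interval for a difference of correlations
#'
#' Percentile bootstrap CI for `cor(x1, y1) - cor(x2, y2)` between two
#' independent strata: each bootstrap replicate resamples cases within
#' each stratum independently and recomputes the two correlations.
#' Degenerate resamples (zero variance in any column) are redrawn.
#'
#' @param x1,y1 Paired observations of stratum 1.
#' @param x2,y2 Paired observations of stratum 2.
#' @param B Number of bootstrap replicates (>= 200).
#' @param seed Integer seed; results are reproducible given `seed` and `B`.
#' @param conf Confidence level, default 0.95.
#' @return A list: `difference` (point estimate `r1 - r2`), `r1`, `r2`,
#'   `ci` (percentile interval), `significant` (CI excludes 0), `B`,
#'   `seed`, `n_redrawn`.
#' @export
bootstrap_corr_difference <- function(x1, y1, x2, y2, B = 2000, seed,
                                      conf = 0.95) {
  stopifnot(length(x1) == length(y1), length(x2) == length(y2),
            length(x1) >= 4L, length(x2) >= 4L, B >= 200)
  set.seed(as.integer(seed))
  r1 <- stats::cor(x1, y1); r2 <- stats::cor(x2, y2)
  n1 <- length(x1); n2 <- length(x2)
  diffs <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      i1 <- sample.int(n1, replace = TRUE)
      i2 <- sample.int(n2, replace = TRUE)
      ok <- stats::sd(x1[i1]) > 0 && stats::sd(y1[i1]) > 0 &&
        stats::sd(x2[i2]) > 0 && stats::sd(y2[i2]) > 0
      if (ok) break
      n_redrawn <- n_redrawn + 1L
    }
    diffs[b] <- stats::cor(x1[i1], y1[i1]) - stats::cor(x2[i2], y2[i2])
  }
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(diffs, c(a, 1 - a)))
  list(difference = r1 - r2, r1 = r1, r2 = r2, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0, B = B, seed = seed,
       conf = conf, n_redrawn = n_redrawn)
}
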