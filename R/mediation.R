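#' Mediation analysis by product of coefficients with bootstrap intervals
#'
#' Tests whether a continuous mediator (e.g. a predicted brain volume at
#' age 2) transmits part of the effect of a binary exposure (e.g. low
#' maternal education) on a continuous outcome (e.g. a cognitive score).
#' Two ordinary least-squares models are fitted:
#' mediator ~ treatment + covariates (coefficient `a`) and
#' outcome ~ treatment + mediator + covariates (coefficients `c'` and `b`).
#' The indirect effect (ACME) is `a * b`, the direct effect (ADE) is `c'`,
#' and the total effect is their sum, which for these linear models equals
#' the treatment coefficient of outcome ~ treatment + covariates exactly.
#' Percentile confidence intervals come from nonparametric case resampling.
#'
#' @param treatment Binary (0/1) exposure vector.
#' @param mediator Numeric mediator.
#' @param outcome Numeric outcome.
#' @param covariates Optional data.frame / matrix of adjustment covariates.
#' @param B Bootstrap replicates; default 10000.
#' @param seed Integer seed.
#' @param conf Confidence level, default 0.95.
#' @return A list of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated` (NA when |total| is negligible), each with a
#'   percentile CI (`acme_ci`, `ade_ci`, `total_ci`, `prop_ci`), plus
#'   `B`, `seed`, `n`.
#' @export
mediate <- function(treatment, mediator, outcome, covariates = NULL,
                    B = 10000, seed, conf = 0.95) {
  n <- length(treatment)
  stopifnot(length(mediator) == n, length(outcome) == n, B >= 1)
  if (n < 20) stop("mediation needs n >= 20")
  if (!all(treatment %in% c(0, 1))) stop("treatment must be binary 0/1")
  if (length(unique(treatment)) < 2L) stop("treatment must have both levels")
  if (stats::sd(mediator) == 0) stop("mediator is constant")
  Xc <- NULL
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)
    for (j in seq_len(ncol(Xc))) {
      cn <- colnames(Xc)[j]
      if (stats::sd(Xc[, j]) == 0)
        stop("covariate is constant (separation): ", cn)
    }
  }
  ok <- stats::complete.cases(cbind(treatment, mediator, outcome, Xc))
  treatment <- treatment[ok]; mediator <- mediator[ok]; outcome <- outcome[ok]
  if (!is.null(Xc)) Xc <- Xc[ok, , drop = FALSE]
  n <- length(treatment)

  point <- function(tr, me, oc, Xc) {
    Xm <- cbind(1, tr, Xc)
    Xo <- cbind(1, tr, me, Xc)
    a <- stats::.lm.fit(Xm, me)$coefficients[2]
    co <- stats::.lm.fit(Xo, oc)$coefficients
    cprime <- co[2]; bcoef <- co[3]
    c(acme = a * bcoef, ade = cprime, total = a * bcoef + cprime)
  }
  est <- point(treatment, mediator, outcome, Xc)
  prop <- if (abs(est["total"]) < 1e-10) NA_real_ else
    unname(est["acme"] / est["total"])

  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, B, 3)
  for (b in seq_len(B)) {
    i <- sample.int(n, replace = TRUE)
    Xci <- if (is.null(Xc)) NULL else Xc[i, , drop = FALSE]
    bad <- length(unique(treatment[i])) < 2L ||
      (!is.null(Xci) && any(apply(Xci, 2, stats::sd) == 0))
    while (bad) {
      i <- sample.int(n, replace = TRUE)
      Xci <- if (is.null(Xc)) NULL else Xc[i, , drop = FALSE]
      bad <- length(unique(treatment[i])) < 2L ||
        (!is.null(Xci) && any(apply(Xci, 2, stats::sd) == 0))
    }
    boot[b, ] <- point(treatment[i], mediator[i], outcome[i], Xci)
  }
  a2 <- (1 - conf) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(a2, 1 - a2))
  propb <- ifelse(abs(boot[, 3]) < 1e-10, NA_real_, boot[, 1] / boot[, 3])
  prop_ci <- if (all(is.na(propb))) c(NA_real_, NA_real_) else
    unname(stats::quantile(propb, c(a2, 1 - a2), na.rm = TRUE))

  structure(list(
    acme = unname(est["acme"]), ade = unname(est["ade"]),
    total = unname(est["total"]), prop_mediated = prop,
    acme_ci = unname(qs[, 1]), ade_ci = unname(qs[, 2]),
    total_ci = unname(qs[, 3]), prop_ci = prop_ci,
    B = B, seed = seed, conf = conf, n = n
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(e, ci) sprintf("%.4g [%.4g, %.4g]%s", e, ci[1], ci[2],
                                 if (ci[1] > 0 || ci[2] < 0) " *" else "")
  cat("Mediation (", x$B, " bootstrap resamples, n = ", x$n, ")\n", sep = "")
  cat("  ACME (indirect):", fmt(x$acme, x$acme_ci), "\n")
  cat("  ADE  (direct):  ", fmt(x$ade, x$ade_ci), "\n")
  cat("  Total effect:   ", fmt(x$total, x$total_ci), "\n")
  cat("  Prop. mediated: ",
      if (is.na(x$prop_mediated)) "undefined (total ~ 0)"
      else sprintf("%.3f", x$prop_mediated), "\n")
  invisible(x)
}
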