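# Marginal maximum-likelihood engine for linear mixed models with
# per-subject random effects (q = 0, 1 or 2 columns) and residual variances
# that differ by group (cohort). Fixed effects and the overall residual
# scale are profiled out in closed form; the remaining variance parameters
# (random-effect sds relative to the residual sd, optional correlation,
# and group sd ratios) are optimized numerically.
#
# All per-subject algebra uses the Woodbury identity with q x q inner
# matrices, vectorized across subjects via rowsum(), so a likelihood
# evaluation costs O(N p) regardless of the number of subjects.

# Evaluate the profiled log-likelihood and GLS solution for one setting of
# the variance parameters phi. Returns the pieces needed both for
# optimization and for the final fit summary.
hetlmm_eval <- function(phi, y, X, Z, subj, grp, q, G, unstructured) {
  n <- length(y)
  p <- ncol(X)
  # unpack phi: q log-taus, optional atanh(rho), G-1 log sd ratios
  tau <- exp(phi[seq_len(q)])
  idx <- q
  if (unstructured && q == 2L) {
    rho <- tanh(phi[idx + 1L]); idx <- idx + 1L
  } else rho <- 0
  lam <- rep(1, G)
  if (G > 1L) lam[-1L] <- exp(phi[idx + seq_len(G - 1L)])
  v <- (lam^2)[grp]                      # relative residual variances per row

  Xv <- X / v
  A <- crossprod(X, Xv)                  # X' W X
  b <- crossprod(Xv, y)                  # X' W y
  logdet <- sum(log(v))

  if (q > 0L) {
    # Gamma = D / sigma^2 (random-effect covariance relative to residual)
    if (q == 1L) {
      Gmat <- matrix(tau[1]^2, 1, 1)
    } else {
      Gmat <- matrix(c(tau[1]^2, rho * tau[1] * tau[2],
                       rho * tau[1] * tau[2], tau[2]^2), 2, 2)
    }
    Gi <- solve(Gmat)
    Zv <- Z / v
    # per-subject Z' W Z (J x q(q+1)/2 distinct entries), Z' W y, X' W Z
    d <- rowsum(Zv * y, subj, reorder = FALSE)          # J x q
    if (q == 1L) {
      a11 <- rowsum(Zv[, 1] * Z[, 1], subj, reorder = FALSE)[, 1]
      M11 <- Gi[1, 1] + a11
      logdetM <- log(M11)
      Minv11 <- 1 / M11
      C1 <- rowsum(Xv * Z[, 1], subj, reorder = FALSE)  # J x p
      # corrections
      A <- A - crossprod(C1, C1 * Minv11)
      b <- b - crossprod(C1, Minv11 * d[, 1])
      logdet <- logdet + nrow(d) * determinant(Gmat, logarithm = TRUE)$modulus +
        sum(logdetM)
      Minv <- cbind(Minv11)
    } else {
      a11 <- rowsum(Zv[, 1] * Z[, 1], subj, reorder = FALSE)[, 1]
      a12 <- rowsum(Zv[, 1] * Z[, 2], subj, reorder = FALSE)[, 1]
      a22 <- rowsum(Zv[, 2] * Z[, 2], subj, reorder = FALSE)[, 1]
      M11 <- Gi[1, 1] + a11; M12 <- Gi[1, 2] + a12; M22 <- Gi[2, 2] + a22
      detM <- M11 * M22 - M12^2
      if (any(detM <= 0)) return(NULL)
      Minv11 <- M22 / detM; Minv22 <- M11 / detM; Minv12 <- -M12 / detM
      C1 <- rowsum(Xv * Z[, 1], subj, reorder = FALSE)
      C2 <- rowsum(Xv * Z[, 2], subj, reorder = FALSE)
      A <- A - crossprod(C1, C1 * Minv11) - crossprod(C2, C2 * Minv22) -
        crossprod(C1, C2 * Minv12) - crossprod(C2, C1 * Minv12)
      h1 <- Minv11 * d[, 1] + Minv12 * d[, 2]
      h2 <- Minv12 * d[, 1] + Minv22 * d[, 2]
      b <- b - crossprod(C1, h1) - crossprod(C2, h2)
      logdet <- logdet + nrow(d) * determinant(Gmat, logarithm = TRUE)$modulus +
        sum(log(detM))
      Minv <- cbind(Minv11, Minv12, Minv22)
    }
  } else {
    Gmat <- NULL; Minv <- NULL; d <- NULL
  }

  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  # residual quadratic form r' Vs^{-1} r computed from the residuals
  # directly (stable even when a variance ratio becomes very small)
  r <- y - drop(X %*% beta)
  rss <- sum(r^2 / v)
  if (q > 0L) {
    e <- rowsum((Z / v) * r, subj, reorder = FALSE)
    rss <- rss - if (q == 1L) sum(Minv[, 1] * e[, 1]^2) else
      sum(Minv[, 1] * e[, 1]^2 + 2 * Minv[, 2] * e[, 1] * e[, 2] +
            Minv[, 3] * e[, 2]^2)
  }
  if (!is.finite(rss)) return(NULL)
  if (rss <= 0) rss <- .Machine$double.eps * max(sum(y^2 / v), 1)
  sigma2 <- rss / n
  ll <- -0.5 * (n * (log(2 * pi) + 1 + log(sigma2)) + as.numeric(logdet))
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2, A = A,
       Gamma = Gmat, tau = tau, rho = rho, lambda = lam, v = v,
       Minv = Minv, d = d)
}

#' Fit a heteroscedastic linear mixed model by marginal maximum likelihood
#'
#' The workhorse behind [fit_growth()] (at fixed rate constant) and
#' [fit_lmm()]. The model is `y = X beta + Z_j u_j + e`, with per-subject
#' random effects `u_j ~ N(0, D)` (diagonal by default) and residuals
#' `e_i ~ N(0, sigma^2 * lambda_g(i)^2)` where `g` indexes residual-variance
#' groups (the first group is the reference with ratio 1). Estimation is ML,
#' not REML, so fits with different fixed-effect structures are comparable
#' by likelihood ratio.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (with column names).
#' @param Z Random-effect design matrix with 1 or 2 columns, or `NULL` for
#'   a model with no random effects (generalized least squares).
#' @param subject Factor (or coercible) identifying subjects.
#' @param var_group Factor identifying residual-variance groups; `NULL` for
#'   homoscedastic residuals.
#' @param unstructured If `TRUE` and `Z` has 2 columns, estimate the
#'   random-effect correlation; default independent effects.
#' @param start Optional start values for the variance parameters.
#' @param minimal If `TRUE`, return only what a profile-likelihood search
#'   needs (parameters and log-likelihood; a singular design yields
#'   `loglik = -Inf` instead of an error) and skip the covariance, BLUP
#'   and residual summaries.
#' @return A list of class `hetlmm` with elements `coefficients`, `se`,
#'   `vcov`, `sigma2`, `D`, `var_group_ratios` (variance ratios),
#'   `loglik`, `blups`, `fitted`, `residuals`, `convergence`, `iterations`,
#'   `n_obs`, `n_subjects`.
#' @export
hetlmm <- function(y, X, Z = NULL, subject, var_group = NULL,
                   unstructured = FALSE, start = NULL, minimal = FALSE) {
  stopifnot(length(y) == nrow(X))
  subj <- factor(subject)
  q <- if (is.null(Z)) 0L else ncol(Z)
  stopifnot(q <= 2L)
  if (q > 0L) stopifnot(nrow(Z) == length(y))
  grp <- if (is.null(var_group)) factor(rep(1L, length(y))) else factor(var_group)
  G <- nlevels(grp)
  grp <- as.integer(grp)

  if (!minimal && qr(X)$rank < ncol(X)) {
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("fixed-effect design is singular; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  nphi <- q + (G - 1L) + as.integer(unstructured && q == 2L)
  obj <- function(phi) {
    ev <- hetlmm_eval(phi, y, X, Z, subj, grp, q, G, unstructured)
    if (is.null(ev) || !is.finite(ev$loglik)) return(1e10)
    -ev$loglik
  }
  if (nphi > 0L) {
    warm <- !is.null(start) && length(start) == nphi && any(start != 0)
    opt <- stats::nlminb(if (warm) start else rep(0, nphi), obj,
                         lower = rep(-8, nphi), upper = rep(8, nphi))
    if (warm) {
      # a warm start from a neighbouring fit can settle in a poor local
      # basin (or trip "false convergence" when it sits at the optimum);
      # always confirm against a neutral start and keep the better optimum
      opt0 <- stats::nlminb(rep(0, nphi), obj,
                            lower = rep(-8, nphi), upper = rep(8, nphi))
      if (opt0$objective < opt$objective) {
        opt <- opt0
      } else if (opt$convergence != 0 && opt0$convergence == 0 &&
                 opt0$objective <= opt$objective + 1e-6 * abs(opt$objective)) {
        opt$convergence <- 0L
      }
    }
    phi <- opt$par
    convergence <- opt$convergence == 0
    iterations <- opt$iterations
  } else {
    phi <- numeric(0); convergence <- TRUE; iterations <- 0L
  }
  ev <- hetlmm_eval(phi, y, X, Z, subj, grp, q, G, unstructured)
  if (minimal) {
    if (is.null(ev))
      return(structure(list(loglik = -Inf, phi = phi, convergence = FALSE),
                       class = "hetlmm"))
    return(structure(list(
      coefficients = stats::setNames(ev$beta, colnames(X)),
      sigma2 = ev$sigma2,
      D = if (q > 0L) ev$sigma2 * ev$Gamma else NULL,
      var_group_ratios = stats::setNames(ev$lambda^2,
        if (is.null(var_group)) "all" else levels(factor(var_group))),
      loglik = ev$loglik, phi = phi, convergence = convergence,
      iterations = iterations,
      n_obs = length(y), n_subjects = nlevels(subj)
    ), class = "hetlmm"))
  }
  if (is.null(ev)) stop("mixed-model likelihood evaluation failed at the optimum")

  vcov_beta <- ev$sigma2 * solve_equilibrated(ev$A)
  se <- sqrt(pmax(diag(vcov_beta), 0))
  names(ev$beta) <- colnames(X); names(se) <- colnames(X)
  fitted_fix <- drop(X %*% ev$beta)
  r <- y - fitted_fix

  blups <- NULL
  if (q > 0L) {
    # u_j = M_j^{-1} e_j with e_j = Z_j' W r_j (scaled); D = sigma^2 Gamma
    v <- ev$v
    e <- rowsum((Z / v) * r, subj, reorder = FALSE)
    if (q == 1L) {
      u <- cbind(ev$Minv[, 1] * e[, 1])
    } else {
      u <- cbind(ev$Minv[, 1] * e[, 1] + ev$Minv[, 2] * e[, 2],
                 ev$Minv[, 2] * e[, 1] + ev$Minv[, 3] * e[, 2])
    }
    rownames(u) <- levels(subj)[unique(as.integer(subj))]
    # rowsum with reorder = FALSE keeps first-appearance order of levels
    blups <- u
  }

  structure(list(
    coefficients = ev$beta, se = se, vcov = vcov_beta,
    sigma2 = ev$sigma2,
    D = if (q > 0L) ev$sigma2 * ev$Gamma else NULL,
    var_group_ratios = stats::setNames(ev$lambda^2,
      if (is.null(var_group)) "all" else levels(factor(var_group))),
    loglik = ev$loglik, phi = phi,
    blups = blups, fitted = fitted_fix, residuals = r,
    y = y, X = X, Z = Z, subject = subj, v = ev$v,
    convergence = convergence, iterations = iterations,
    n_obs = length(y), n_subjects = nlevels(subj)
  ), class = "hetlmm")
}

#' @export
logLik.hetlmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              length(object$phi) + 1L, class = "logLik")
}

# Invert a symmetric positive-definite information matrix after diagonal
# equilibration; columns of the underlying design can differ in scale by
# many orders of magnitude (e.g. a rate-constant gradient next to 0/1
# dummies), which defeats a raw solve().
solve_equilibrated <- function(A) {
  s <- sqrt(pmax(diag(A), .Machine$double.xmin))
  Ai <- solve(A / tcrossprod(s))
  Ai / tcrossprod(s)
}

# Observed-information covariance for an augmented design [X, extra] at the
# fitted variance parameters; used by fit_growth for the rate-constant SE.
hetlmm_info_vcov <- function(fit, extra = NULL) {
  X <- if (is.null(extra)) fit$X else cbind(fit$X, extra)
  v <- fit$v
  Xv <- X / v
  A <- crossprod(X, Xv)
  if (!is.null(fit$Z)) {
    q <- ncol(fit$Z)
    Zv <- fit$Z / v
    subj <- fit$subject
    Gamma <- fit$D / fit$sigma2
    Gi <- solve(Gamma)
    if (q == 1L) {
      a11 <- rowsum(Zv[, 1] * fit$Z[, 1], subj, reorder = FALSE)[, 1]
      Minv11 <- 1 / (Gi[1, 1] + a11)
      C1 <- rowsum(Xv * fit$Z[, 1], subj, reorder = FALSE)
      A <- A - crossprod(C1, C1 * Minv11)
    } else {
      a11 <- rowsum(Zv[, 1] * fit$Z[, 1], subj, reorder = FALSE)[, 1]
      a12 <- rowsum(Zv[, 1] * fit$Z[, 2], subj, reorder = FALSE)[, 1]
      a22 <- rowsum(Zv[, 2] * fit$Z[, 2], subj, reorder = FALSE)[, 1]
      M11 <- Gi[1, 1] + a11; M12 <- Gi[1, 2] + a12; M22 <- Gi[2, 2] + a22
      detM <- M11 * M22 - M12^2
      Minv11 <- M22 / detM; Minv22 <- M11 / detM; Minv12 <- -M12 / detM
      C1 <- rowsum(Xv * fit$Z[, 1], subj, reorder = FALSE)
      C2 <- rowsum(Xv * fit$Z[, 2], subj, reorder = FALSE)
      A <- A - crossprod(C1, C1 * Minv11) - crossprod(C2, C2 * Minv22) -
        crossprod(C1, C2 * Minv12) - crossprod(C2, C1 * Minv12)
    }
  }
  fit$sigma2 * solve_equilibrated(A)
}
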