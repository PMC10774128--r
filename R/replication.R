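#' Split-sample replication of a mixed-model analysis
#'
#' Repeatedly halves the subjects (50/50, stratified by cohort so both
#' folds retain every site), refits the model in each fold, and tallies
#' per effect how often the two folds agree in sign and how often they
#' agree in sign with both folds significant at the Bonferroni threshold.
#' Splitting is by subject, never by observation, so repeated measures of
#' a child stay in one fold. Splits where a fold loses a covariate level
#' are redrawn (logged); repeats where a fold fit fails to converge are
#' excluded from the denominators.
#'
#' @param data A long volume or cognition table (single region or scale).
#' @param model_spec A [growth_model_spec()] or [lmm_spec()].
#' @param n_repeats Number of random splits; default 100.
#' @param seed Integer seed.
#' @param terms Effects to tally; default the model covariates.
#' @param threshold Per-test significance threshold; default the Bonferroni
#'   threshold for 35 tests at alpha 0.05.
#' @return A list of class `replication_summary`: data.frame `summary`
#'   (term, prop_same_sign, prop_same_sign_significant), `n_repeats`,
#'   `n_used`, `n_resplits`, `seed`, `threshold`.
#' @export
split_replicate <- function(data, model_spec, n_repeats = 100, seed,
                            terms = NULL,
                            threshold = bonferroni_threshold(35)) {
  is_growth <- inherits(model_spec, "growth_model_spec")
  if (!is_growth) stopifnot(inherits(model_spec, "lmm_spec"))
  covs <- model_spec$covariates
  if (is.null(terms)) terms <- covs
  set.seed(as.integer(seed))

  subj <- subject_table(data)
  fit_fold <- function(dat) {
    f <- tryCatch(suppressMessages(
      if (is_growth) fit_growth(dat, model_spec) else fit_lmm(dat, model_spec)),
      error = function(e) NULL)
    if (is.null(f) || !f$convergence) return(NULL)
    f$coefficients
  }
  extract <- function(co, term) {
    # growth fits report asym:/int: effects; tally both parameters per term
    rows <- co[co$term %in% c(term, paste0("asym:", term), paste0("int:", term)),
               , drop = FALSE]
    rows
  }

  same_sign <- stats::setNames(numeric(length(terms)), terms)
  both_sig <- stats::setNames(numeric(length(terms)), terms)
  n_used <- 0L; n_resplits <- 0L
  for (rep_i in seq_len(n_repeats)) {
    for (attempt in 1:50) {
      fold1_ids <- unlist(lapply(split(subj$subject_id, subj$cohort),
                                 function(ids) {
                                   k <- floor(length(ids) / 2)
                                   if (k == 0) character(0) else sample(ids, k)
                                 }), use.names = FALSE)
      d1 <- data[data$subject_id %in% fold1_ids, , drop = FALSE]
      d2 <- data[!data$subject_id %in% fold1_ids, , drop = FALSE]
      okcov <- all(vapply(covs, function(k)
        length(unique(stats::na.omit(d1[[k]]))) == 2L &&
          length(unique(stats::na.omit(d2[[k]]))) == 2L, TRUE))
      if (okcov) break
      n_resplits <- n_resplits + 1L
    }
    if (!okcov) next
    c1 <- fit_fold(d1); c2 <- fit_fold(d2)
    if (is.null(c1) || is.null(c2)) next
    n_used <- n_used + 1L
    for (tm in terms) {
      r1 <- extract(c1, tm); r2 <- extract(c2, tm)
      agree <- all(sign(r1$estimate) == sign(r2$estimate))
      same_sign[tm] <- same_sign[tm] + agree
      both_sig[tm] <- both_sig[tm] +
        (agree && all(r1$p < threshold) && all(r2$p < threshold))
    }
  }
  if (n_used == 0L) stop("no split produced two convergent fold fits")
  structure(list(
    summary = data.frame(term = terms,
                         prop_same_sign = unname(same_sign / n_used),
                         prop_same_sign_significant = unname(both_sig / n_used),
                         stringsAsFactors = FALSE),
    n_repeats = n_repeats, n_used = n_used, n_resplits = n_resplits,
    seed = seed, threshold = threshold
  ), class = "replication_summary")
}

#' Drop all but one subject from each sibling/twin group
#'
#' Sensitivity utility mirroring the removal of one twin per pair from a
#' family-structured cohort: of every listed group, the subject with the
#' lexicographically smallest id is retained and all observations of the
#' others removed.
#'
#' @param data Long table with a `subject_id` column.
#' @param sibling_map List of character vectors, each a group of related
#'   subject ids.
#' @return The filtered table.
#' @export
drop_relatives <- function(data, sibling_map) {
  if (!length(sibling_map)) return(data)
  all_ids <- unique(data$subject_id)
  unknown <- setdiff(unlist(sibling_map), all_ids)
  if (length(unknown))
    stop("unknown subject(s) in sibling_map: ", paste(unknown, collapse = ", "))
  drop <- unlist(lapply(sibling_map, function(g) sort(g)[-1L]))
  data[!data$subject_id %in% drop, , drop = FALSE]
}
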