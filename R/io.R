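#' Write a long-format table as CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal; the on-disk schema is
#' `subject_id, cohort, age_days, male, preterm, low_bw, low_medu,
#' low_income, region|scale, value`.
#'
#' @param data Long table from the simulators or a fit stage.
#' @param path Output file path.
#' @export
write_long_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read and validate a long-format table
#'
#' Parses a CSV written by [write_long_table()] (tolerates CRLF endings
#' and quoted fields), checks the schema, and rejects malformed rows with
#' their line numbers: non-numeric or negative ages, nonpositive volumes,
#' duplicate (subject, age, region/scale) keys, covariates varying within
#' subject.
#'
#' @param path CSV path.
#' @param kind `"volumes"` or `"cognition"`.
#' @return A validated data.frame.
#' @export
read_long_table <- function(path, kind = c("volumes", "cognition")) {
  kind <- match.arg(kind)
  key <- if (kind == "volumes") "region" else "scale"
  dat <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  want <- c("subject_id", "cohort", "age_days", "male", "preterm", "low_bw",
            "low_medu", "low_income", key, "value")
  missing_cols <- setdiff(want, names(dat))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  dat <- dat[, want]
  line <- seq_len(nrow(dat)) + 1L   # header is line 1

  bad <- !is.finite(dat$age_days) | dat$age_days < 0
  if (any(bad)) stop("invalid age_days at line(s): ",
                     paste(utils::head(line[bad], 10), collapse = ", "))
  bad <- !is.finite(dat$value) | (kind == "volumes" & dat$value <= 0)
  if (any(bad)) stop("invalid value (must be ",
                     if (kind == "volumes") "positive volume" else "finite score",
                     ") at line(s): ", paste(utils::head(line[bad], 10), collapse = ", "))
  for (k in c("male", "preterm", "low_bw", "low_medu")) {
    bad <- !dat[[k]] %in% c(0L, 1L)
    if (any(bad)) stop("non-binary ", k, " at line(s): ",
                       paste(utils::head(line[bad], 10), collapse = ", "))
  }
  bad <- !(dat$low_income %in% c(0L, 1L) | is.na(dat$low_income))
  if (any(bad)) stop("non-binary low_income at line(s): ",
                     paste(utils::head(line[bad], 10), collapse = ", "))
  keystr <- paste(dat$subject_id, dat$age_days, dat[[key]])
  dup <- duplicated(keystr)
  if (any(dup)) stop("duplicate (subject, age, ", key, ") key at line(s): ",
                     paste(utils::head(line[dup], 10), collapse = ", "))
  for (k in c("cohort", "male", "preterm", "low_bw", "low_medu", "low_income")) {
    nvals <- tapply(dat[[k]], dat$subject_id,
                    function(v) length(unique(v[!is.na(v)])))
    if (any(nvals > 1L, na.rm = TRUE))
      stop(k, " varies within subject(s): ",
           paste(utils::head(names(nvals)[nvals > 1L], 5), collapse = ", "))
  }
  dat
}

#' Pipeline configuration
#'
#' Collects paths, model variant, test-family sizes, bootstrap sizes and
#' the seed driving every stage. All sub-seeds are derived from `seed` in
#' a fixed order so a full rerun with the same config is identical.
#'
#' @param out_dir Directory for stage outputs.
#' @param variant `"full"` or `"no-income"`.
#' @param seed Master integer seed.
#' @param n_tests_volumes,n_tests_cognitive,n_tests_correlations
#'   Bonferroni family sizes (7x5 = 35, 5x5 = 25, 7x5 = 35).
#' @param boot_corr,boot_mediation Bootstrap replicate counts.
#' @param n_repeats Split-replication repeats.
#' @param age2_days Prediction age for the panel; default 730.5.
#' @param regions,scales Outcomes to run; defaults keep runtime modest
#'   while exercising every stage.
#' @param cohorts Cohort layout; default [default_cohorts()].
#' @param truth Generative truth; default [default_truth()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("pipeline"),
                            variant = c("full", "no-income"),
                            seed = 1L,
                            n_tests_volumes = 35L,
                            n_tests_cognitive = 25L,
                            n_tests_correlations = 35L,
                            boot_corr = 2000L,
                            boot_mediation = 10000L,
                            n_repeats = 100L,
                            age2_days = 730.5,
                            regions = c("ICV", "hippocampus", "amygdala"),
                            scales = c("gross_motor", "visual_reception"),
                            cohorts = default_cohorts(),
                            truth = default_truth()) {
  variant <- match.arg(variant)
  stopifnot(seed > 0, boot_corr > 0, boot_mediation > 0, n_repeats > 0)
  structure(list(out_dir = out_dir, variant = variant, seed = as.integer(seed),
                 n_tests_volumes = n_tests_volumes,
                 n_tests_cognitive = n_tests_cognitive,
                 n_tests_correlations = n_tests_correlations,
                 boot_corr = boot_corr, boot_mediation = boot_mediation,
                 n_repeats = n_repeats, age2_days = age2_days,
                 regions = regions, scales = scales,
                 cohorts = cohorts, truth = truth),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] (seed, variant, bootstrap sizes,
#' family sizes, output directory, regions, scales) may be supplied in a
#' YAML key-value file; unset keys fall back to the defaults, and the
#' cohort layout and generative truth stay at their package defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a YAML config requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  allowed <- c("out_dir", "variant", "seed", "n_tests_volumes",
               "n_tests_cognitive", "n_tests_correlations", "boot_corr",
               "boot_mediation", "n_repeats", "age2_days", "regions",
               "scales")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate the multicohort study, fit the growth model per region and
#' tabulate maturation ages, fit the cognitive linear mixed models, build
#' the age-2 prediction panel, compute stratified brain-cognition
#' correlations with a bootstrap comparison, run one mediation analysis
#' per (exposure, region, scale) triple requested, and run split-sample
#' replication. Stage outputs are written as TSV/CSV under
#' `config$out_dir`; per-stage sub-seeds are derived from the master seed
#' and recorded, and per-cohort residual summaries accompany each fit.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result (`volumes`,
#'   `cognition`, `growth_fits`, `maturation`, `cognitive_fits`, `panel`,
#'   `correlations`, `corr_difference`, `mediation`, `replication`,
#'   `seeds`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seed + c(simulate = 1L, cognition = 2L, boot = 3L,
                           mediation = 4L, replication = 5L)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  spec <- growth_model_variant(config$variant)
  lspec <- lmm_spec(covariates = spec$covariates)

  vols <- stage("simulate", simulate_volumes(config$cohorts, config$truth,
                                             seed = seeds[["simulate"]],
                                             regions = config$regions))
  cogs <- stage("simulate", suppressMessages(
    simulate_cognition(config$cohorts, config$truth,
                       seed = seeds[["cognition"]], scales = config$scales)))
  write_long_table(vols, file.path(config$out_dir, "volumes.csv"))
  write_long_table(cogs, file.path(config$out_dir, "cognition.csv"))

  growth_fits <- stage("fit-growth", lapply(
    stats::setNames(config$regions, config$regions), function(r)
      suppressMessages(fit_growth(vols, spec, region = r))))
  maturation <- data.frame(
    region = config$regions,
    maturation_days = vapply(growth_fits, function(f)
      maturation_age(f$params), 0),
    stringsAsFactors = FALSE)
  maturation$maturation_years <- days_to_years(maturation$maturation_days, 1)
  utils::write.table(maturation, file.path(config$out_dir, "maturation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  cognitive_fits <- stage("fit-lmm", lapply(
    stats::setNames(config$scales, config$scales), function(s)
      suppressMessages(fit_lmm(cogs, lspec, outcome = s))))

  # growth/lmm report tables and per-cohort residual diagnostics
  report <- do.call(rbind, lapply(config$regions, function(r) {
    co <- growth_fits[[r]]$coefficients; co$region <- r; co
  }))
  utils::write.table(report, file.path(config$out_dir, "growth_effects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  resid_summary <- do.call(rbind, lapply(config$regions, function(r) {
    f <- growth_fits[[r]]
    data.frame(region = r, cohort = names(f$cohort_var_ratios),
               var_ratio = unname(f$cohort_var_ratios))
  }))
  utils::write.table(resid_summary,
                     file.path(config$out_dir, "cohort_variance_ratios.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  panel <- stage("panel", suppressMessages(
    build_panel(growth_fits, cognitive_fits, subject_table(vols),
                age_days = config$age2_days)))
  correlations <- stage("correlate", lapply(
    stats::setNames(c("full_term", "preterm"), c("full_term", "preterm")),
    function(st) correlation_matrix(panel, st,
                                    volumes = config$regions,
                                    scores = config$scales)))
  ft <- panel[panel$stratum == "full_term", ]
  pt <- panel[panel$stratum == "preterm", ]
  r1 <- config$regions[1]; s1 <- config$scales[1]
  corr_diff <- stage("correlate", bootstrap_corr_difference(
    ft[[r1]], ft[[s1]], pt[[r1]], pt[[s1]],
    B = config$boot_corr, seed = seeds[["boot"]]))

  med_cov <- setdiff(spec$covariates, "low_medu")
  sub <- subject_table(vols)
  sub <- sub[match(panel$subject_id, sub$subject_id), ]
  cc <- stats::complete.cases(sub[, med_cov])
  med <- stage("mediate", mediate(
    treatment = sub$low_medu[cc], mediator = panel[[r1]][cc],
    outcome = panel[[s1]][cc],
    covariates = sub[cc, med_cov],
    B = config$boot_mediation, seed = seeds[["mediation"]]))

  repl <- stage("replicate", suppressMessages(split_replicate(
    cogs[cogs$scale == s1, ], lspec, n_repeats = config$n_repeats,
    seed = seeds[["replication"]],
    threshold = bonferroni_threshold(config$n_tests_cognitive))))
  utils::write.table(repl$summary,
                     file.path(config$out_dir, "replication.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  note("pipeline complete; sub-seeds: ",
       paste(names(seeds), seeds, sep = "=", collapse = ", "))

  invisible(list(volumes = vols, cognition = cogs,
                 growth_fits = growth_fits, maturation = maturation,
                 cognitive_fits = cognitive_fits, panel = panel,
                 correlations = correlations, corr_difference = corr_diff,
                 mediation = med, replication = repl,
                 seeds = seeds, log = log))
}
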