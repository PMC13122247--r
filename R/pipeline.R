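# End-to-end orchestration: simulate (or load) -> validate -> accuracy
# GLMMs -> two-stage transfer -> confidence LMMs -> metacognition, in the
# fixed analysis order, with one run seed and serializable report tables.

#' Pipeline run configuration
#'
#' @param seed single run seed; every random draw derives from it.
#' @param generator a [generator_config()] (synthetic mode).
#' @param trials,subjects in-memory tables (file/frame mode); when supplied,
#'   the generator is ignored.
#' @param random_structure random-effects policy for the inferential fits:
#'   `"diagonal"` (default) or `"maximal"`; the per-subject coefficient
#'   stages require random slopes, so intercept-only is not offered here.
#' @param mahalanobis_alpha chi-square tail for the outlier screen.
#' @param alpha significance threshold recorded in the report (two-sided).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, generator = generator_config(),
                       trials = NULL, subjects = NULL,
                       random_structure = c("diagonal", "maximal"),
                       mahalanobis_alpha = 0.025, alpha = 0.05) {
  random_structure <- match.arg(random_structure)
  if (xor(is.null(trials), is.null(subjects))) {
    stop("file mode needs both trials and subjects", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), generator = generator,
                 trials = trials, subjects = subjects,
                 input_mode = if (is.null(trials)) "synthetic" else "files",
                 random_structure = random_structure,
                 mahalanobis_alpha = mahalanobis_alpha, alpha = alpha),
            class = "run_config")
}

coef_tbl <- function(fit) fit$coefficients

#' Run the full analysis pipeline
#'
#' Stage order mirrors the analysis plan: design validation and accuracy
#' summaries; implicit and explicit accuracy GLMMs (base, AQ-score, AQ-group
#' variants); two-stage transfer of per-subject implicit interaction
#' coefficients into the explicit model; paired comparison of implicit
#' interaction vs explicit congruency subject coefficients; confidence LMMs
#' per task; AUROC2 metacognition with outlier screening, Spearman
#' correlations and AQ median split. Implicit accuracy/confidence analyses
#' use object-present trials only; continuous predictors are z-scored.
#'
#' @param config a [run_config()].
#' @return Object of class `gaze_report` (nested list of tables/results).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  if (config$input_mode == "synthetic") {
    sim <- simulate_experiment(config$generator, config$seed)
    trials <- sim$trials
    subjects <- sim$subjects
  } else {
    trials <- validate_trials(config$trials)
    subjects <- validate_subjects(config$subjects)
  }
  rs <- config$random_structure
  imp_all <- trials[trials$task == "implicit", ]
  expl <- trials[trials$task == "explicit", ]
  imp <- filter_present_trials(imp_all)

  design <- validate_design(
    trials,
    trials_per_implicit_cell =
      if (config$input_mode == "synthetic")
        config$generator$trials_per_implicit_cell else 12L,
    trials_per_explicit_condition =
      if (config$input_mode == "synthetic")
        config$generator$trials_per_explicit_condition else 48L)

  summaries <- list(
    implicit_present = summarize_accuracy(imp),
    implicit_absent = summarize_accuracy(imp_all[!imp_all$object_present, ]),
    implicit_overall = summarize_accuracy(imp_all),
    implicit_cells = summarize_accuracy(
      imp, by = c("gaze_validity", "body_head_congruency")),
    explicit_overall = summarize_accuracy(expl),
    explicit_cells = summarize_accuracy(expl, by = "body_head_congruency"))

  fit_implicit <- fit_implicit_accuracy(imp, random = rs)
  fit_explicit <- fit_explicit_accuracy(expl, random = rs)
  fit_explicit_aq <- fit_explicit_accuracy(expl, subjects, aq = "score",
                                           random = rs)
  fit_implicit_aq <- fit_implicit_accuracy(imp, subjects, aq = "score",
                                           random = rs)
  fit_implicit_group <- fit_implicit_accuracy(imp, subjects, aq = "group",
                                              random = rs)

  transfer <- fit_transfer(fit_implicit, expl, random = rs)
  eff_imp <- extract_subject_effects(fit_implicit, "gv_x_cong")
  eff_exp <- extract_subject_effects(fit_explicit, "congruent")
  # The paired comparison needs nonzero between-subject spread; when the
  # diagonal fits truncate the slope variances to zero, fall back to the
  # maximal (correlated) structure for this stage.
  coef_comparison <- tryCatch(
    compare_subject_effects(eff_imp, eff_exp),
    error = function(e) NULL)
  if (is.null(coef_comparison)) {
    eff_imp <- extract_subject_effects(
      fit_implicit_accuracy(imp, random = "maximal"), "gv_x_cong")
    eff_exp <- extract_subject_effects(
      fit_explicit_accuracy(expl, random = "maximal"), "congruent")
    coef_comparison <- tryCatch(
      compare_subject_effects(eff_imp, eff_exp),
      error = function(e) list(mean_a = mean(eff_imp$effect),
                               se_a = NA_real_,
                               mean_b = mean(eff_exp$effect),
                               se_b = NA_real_, t = NA_real_,
                               df = nrow(eff_imp) - 1L, p = NA_real_))
  }

  conf_implicit <- fit_confidence_lmm(imp, subjects, random = rs)
  conf_explicit <- fit_confidence_lmm(expl, subjects, random = rs)
  conf_design <- fit_confidence_design_lmm(imp, subjects, random = rs)

  metacog <- list(
    implicit = metacog_analysis(imp, subjects,
                                alpha = config$mahalanobis_alpha),
    explicit = metacog_analysis(expl, subjects,
                                alpha = config$mahalanobis_alpha))

  report <- list(
    seed = config$seed,
    input_mode = config$input_mode,
    coding = paste("gaze_valid: 1 = valid, 0 = invalid;",
                   "congruent: 1 = body-head congruent, 0 = incongruent;",
                   "AQ z-scored within sample; confidence z-scored"),
    alpha = config$alpha,
    design = design,
    summaries = summaries,
    models = list(
      implicit_accuracy = coef_tbl(fit_implicit),
      explicit_accuracy = coef_tbl(fit_explicit),
      explicit_accuracy_aq = coef_tbl(fit_explicit_aq),
      implicit_accuracy_aq = coef_tbl(fit_implicit_aq),
      implicit_accuracy_aq_group = coef_tbl(fit_implicit_group),
      confidence_implicit = coef_tbl(conf_implicit),
      confidence_explicit = coef_tbl(conf_explicit),
      confidence_implicit_design = coef_tbl(conf_design),
      transfer = coef_tbl(transfer)),
    converged = c(
      implicit_accuracy = fit_implicit$converged,
      explicit_accuracy = fit_explicit$converged,
      explicit_accuracy_aq = fit_explicit_aq$converged,
      implicit_accuracy_aq = fit_implicit_aq$converged,
      implicit_accuracy_aq_group = fit_implicit_group$converged,
      confidence_implicit = conf_implicit$converged,
      confidence_explicit = conf_explicit$converged,
      confidence_implicit_design = conf_design$converged,
      transfer = transfer$converged),
    coefficient_comparison = coef_comparison,
    metacognition = metacog,
    subject_effects = list(implicit_interaction = eff_imp,
                           explicit_congruency = eff_exp),
    r_version = as.character(getRversion()),
    lme4_version = as.character(utils::packageVersion("lme4")),
    elapsed_s = proc.time()[["elapsed"]] - t0)
  class(report) <- "gaze_report"
  report
}

#' @export
print.gaze_report <- function(x, ...) {
  cat("gaze perception analysis report (seed", x$seed, ",", x$input_mode,
      "input)\n")
  cat(length(x$design$violations), "design violation(s)\n")
  cat("implicit accuracy model:\n")
  print(round(x$models$implicit_accuracy[, -1], 3))
  mc <- x$metacognition$explicit$cor_excluded
  cat(sprintf("explicit AUROC2 ~ AQ: rho = %.3f, t(%d) = %.2f, p = %.3g\n",
              mc$rho, mc$df, mc$t, mc$p))
  mc <- x$metacognition$implicit$cor_excluded
  cat(sprintf("implicit AUROC2 ~ AQ: rho = %.3f, t(%d) = %.2f, p = %.3g\n",
              mc$rho, mc$df, mc$t, mc$p))
  invisible(x)
}

fmt_model_table <- function(tbl, title) {
  has_z <- "z" %in% names(tbl)
  lines <- c(title, strrep("-", nchar(title)),
             sprintf("%-28s %14s %8s %8s",
                     "Predictor", "Estimate (SEM)",
                     if (has_z) "z" else "t", "p"))
  for (i in seq_len(nrow(tbl))) {
    stat <- if (has_z) tbl$z[i] else tbl$t[i]
    lines <- c(lines, sprintf("%-28s %7.2f (%.2f) %8.2f %8.3g",
                              tbl$term[i], tbl$estimate[i], tbl$se[i],
                              stat, tbl$p[i]))
  }
  lines
}

#' Write report artifacts to a directory
#'
#' One plain-text table per model (estimate (SE), z/t, p in the standard
#' layout) plus the full report serialized as JSON.
#'
#' @param report a `gaze_report`.
#' @param dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  stopifnot(inherits(report, "gaze_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$models)) {
    p <- file.path(dir, paste0(nm, ".txt"))
    writeLines(fmt_model_table(report$models[[nm]], nm), p)
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), jp, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}

# JSON-serializable view of the report (design tables flattened).
report_to_list <- function(report) {
  out <- unclass(report)
  out$design <- list(task_counts = as.list(report$design$task_counts),
                     violations = report$design$violations)
  out$metacognition <- lapply(report$metacognition, function(m) {
    m$auroc2 <- m$auroc2
    m
  })
  out
}

#' Run the pipeline on deposited data files
#'
#' Manual reproduction path for an archived dataset: point at the trial and
#' subject CSVs (package schema, see [read_trials()]) and the full pipeline
#' runs in file mode.
#'
#' @param trials_path,subjects_path CSV paths.
#' @param ... passed to [run_config()] (e.g. `random_structure`).
#' @return A `gaze_report`.
#' @export
reproduce_from_files <- function(trials_path, subjects_path, ...) {
  x <- read_trials(trials_path, subjects_path)
  run_pipeline(run_config(trials = x$trials, subjects = x$subjects, ...))
}
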