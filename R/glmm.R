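# Hierarchical accuracy (logistic) and confidence (linear) models.
#
# Estimation is delegated to lme4 (Laplace approximation; adaptive
# Gauss-Hermite via nAGQ for intercept-only models) and lmerTest
# (Satterthwaite denominator df for the confidence LMMs). This module owns
# the design coding, the random-effects structure policy, per-subject
# coefficient extraction (fixed effect + conditional mode), the two-stage
# transfer analysis and the paired coefficient comparison.

#' Build the numeric model frame for the accuracy/confidence models
#'
#' Applies the factor coding used throughout: `gaze_valid` (1 = valid,
#' 0 = invalid), `congruent` (1 = body-head congruent, 0 = incongruent),
#' their product `gv_x_cong`, and `aq_z`, AQ z-scored within the analysis
#' sample. Continuous covariates with zero variance are rejected.
#'
#' @param trials validated trial table (single task).
#' @param subjects optional subject table (required when AQ enters a model).
#' @return data.frame with the original columns plus numeric codes.
#' @export
make_model_frame <- function(trials, subjects = NULL) {
  trials <- validate_trials(trials)
  if (length(unique(trials$task)) != 1L) {
    stop("model frame must contain a single task", call. = FALSE)
  }
  if (any(trials$gaze_validity == "not_applicable")) {
    stop("object-absent rows cannot be coded for the accuracy models; ",
         "apply filter_present_trials() first", call. = FALSE)
  }
  trials$gaze_valid <- as.integer(trials$gaze_validity == "valid")
  trials$congruent <- as.integer(trials$body_head_congruency == "congruent")
  trials$gv_x_cong <- trials$gaze_valid * trials$congruent
  if (!is.null(subjects)) {
    subjects <- add_aq_group(subjects)
    idx <- match(trials$subject_id, subjects$subject_id)
    if (anyNA(idx)) {
      missing <- unique(trials$subject_id[is.na(idx)])
      stop("subjects missing from subject table: ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    aq <- subjects$aq_score[idx]
    trials$aq_z <- zscore(aq, "aq_score")
    trials$aq_high <- as.integer(subjects$aq_group[idx] == "high")
  }
  trials
}

#' z-transform a covariate within the analysis sample
#'
#' @param x numeric vector.
#' @param name label used in the zero-variance error.
#' @return `(x - mean(x)) / sd(x)`.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("covariate '", name, "' has zero variance and cannot be z-scored",
         call. = FALSE)
  }
  (x - mean(x)) / s
}

random_part <- function(slopes, random) {
  switch(random,
    none = NULL,
    intercept = "(1 | subject_id)",
    diagonal = if (length(slopes)) {
      sprintf("(1 + %s || subject_id)", paste(slopes, collapse = " + "))
    } else "(1 | subject_id)",
    maximal = if (length(slopes)) {
      sprintf("(1 + %s | subject_id)", paste(slopes, collapse = " + "))
    } else "(1 | subject_id)",
    stop("unknown random structure: ", random, call. = FALSE)
  )
}

# Separation guard: Wald inference is meaningless once coefficients diverge
# on the logit scale.
check_separation <- function(beta, limit = 15) {
  if (any(abs(beta) > limit)) {
    stop("coefficient(s) diverged beyond |beta| > ", limit,
         " on the logit scale; data are (quasi-)separated: ",
         paste(names(beta)[abs(beta) > limit], collapse = ", "),
         call. = FALSE)
  }
}

new_gaze_fit <- function(model, coef_table, ranef_modes, family, formula,
                         converged, singular, n_obs, n_subjects) {
  structure(list(model = model, coefficients = coef_table,
                 ranef_modes = ranef_modes, family = family,
                 formula = formula, converged = converged,
                 singular = singular, n_obs = n_obs,
                 n_subjects = n_subjects),
            class = "gaze_fit")
}

#' @export
print.gaze_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed model (%s): %s\n", x$family, x$formula))
  cat(sprintf("%d observations, %d subjects%s%s\n", x$n_obs, x$n_subjects,
              if (!x$converged) "; NOT CONVERGED" else "",
              if (isTRUE(x$singular)) "; singular random-effects fit" else ""))
  print(round(x$coefficients[, setdiff(names(x$coefficients), "term")],
              digits))
  invisible(x)
}

# Conditional modes: with double-bar (diagonal) random terms lme4 returns one
# block per uncorrelated term, all grouped by subject; merge them into one
# subject x term data.frame.
collect_ranef <- function(model) {
  re <- lme4::ranef(model)
  blocks <- re[names(re) == "subject_id"]
  out <- do.call(cbind, lapply(blocks, as.data.frame))
  names(out) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  out
}

fit_glmm_engine <- function(resp, fixed, slopes, data, family, random, nAGQ) {
  rhs <- paste(fixed, collapse = " + ")
  if (random == "none") {
    return(fit_pinned_glmm(resp, fixed, data, family))
  }
  fml <- stats::as.formula(
    paste(resp, "~", rhs, "+", random_part(slopes, random)))
  if (family == "binomial") {
    if (random != "intercept") nAGQ <- 1L  # AGQ only for a single scalar RE
    model <- suppressMessages(lme4::glmer(
      fml, data = data, family = stats::binomial(), nAGQ = nAGQ,
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
    beta <- lme4::fixef(model)
    check_separation(beta)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    z <- beta / se
    ct <- data.frame(term = names(beta), estimate = unname(beta),
                     se = unname(se), z = unname(z),
                     p = 2 * stats::pnorm(-abs(unname(z))),
                     stringsAsFactors = FALSE)
  } else {
    model <- suppressMessages(lmerTest::lmer(
      fml, data = data, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    sm <- stats::coef(summary(model))  # Satterthwaite df
    ct <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], df = sm[, "df"],
                     t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                     stringsAsFactors = FALSE)
  }
  conv <- length(model@optinfo$conv$lme4) == 0L &&
    (is.null(model@optinfo$conv$opt) || model@optinfo$conv$opt == 0L)
  re <- collect_ranef(model)
  rownames(ct) <- NULL
  new_gaze_fit(model, ct, re, family,
               paste(deparse(fml), collapse = " "), conv,
               lme4::isSingular(model), nrow(data),
               length(unique(data$subject_id)))
}

# Degenerate fit with every random-effect variance pinned at zero, computed
# through the mixed-model deviance machinery (theta fixed at 0), not by
# re-routing to glm/lm. Used for the zero-variance equivalence checks.
fit_pinned_glmm <- function(resp, fixed, data, family) {
  rhs <- paste(fixed, collapse = " + ")
  fml <- stats::as.formula(paste(resp, "~", rhs, "+ (1 | subject_id)"))
  if (family == "binomial") {
    parsed <- lme4::glFormula(fml, data = data, family = stats::binomial())
    devfun <- do.call(lme4::mkGlmerDevfun, parsed)
    devfun <- lme4::updateGlmerDevfun(devfun, parsed$reTrms)
    nth <- length(parsed$reTrms$theta)
    start <- stats::coef(stats::glm(
      stats::as.formula(paste(resp, "~", rhs)), data = data,
      family = stats::binomial()))
    check_separation(start)
    obj <- function(beta) devfun(c(rep(0, nth), beta))
    opt <- stats::optim(start, obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    beta <- opt$par
    check_separation(beta)
    # Wald covariance at the pinned optimum; devfun is -2 logLik, so the
    # observed information is Hessian(devfun) / 2.
    H <- stats::optimHess(beta, obj)
    se <- sqrt(diag(solve(H / 2)))
    z <- beta / se
    ct <- data.frame(term = names(beta), estimate = unname(beta),
                     se = unname(se), z = unname(z),
                     p = 2 * stats::pnorm(-abs(unname(z))),
                     stringsAsFactors = FALSE)
    conv <- opt$convergence == 0L
  } else {
    parsed <- lme4::lFormula(fml, data = data, REML = FALSE)
    devfun <- do.call(lme4::mkLmerDevfun, parsed)
    devfun(rep(0, length(parsed$reTrms$theta)))  # beta profiled out at theta=0
    pp <- environment(devfun)$pp
    beta <- pp$beta(1)
    names(beta) <- colnames(parsed$X)
    ols <- stats::lm(stats::as.formula(paste(resp, "~", rhs)), data = data)
    se <- sqrt(diag(stats::vcov(ols)))
    tt <- beta / se
    dfr <- ols$df.residual
    ct <- data.frame(term = names(beta), estimate = unname(beta),
                     se = unname(se), df = dfr, t = unname(tt),
                     p = 2 * stats::pt(-abs(unname(tt)), dfr),
                     stringsAsFactors = FALSE)
    conv <- TRUE
  }
  # all variances are pinned at zero, so every conditional mode is zero
  subj <- sort(unique(as.character(data$subject_id)))
  re <- as.data.frame(matrix(0, length(subj), nrow(ct),
                             dimnames = list(subj, ct$term)))
  rownames(ct) <- NULL
  new_gaze_fit(NULL, ct, re, family,
               paste(resp, "~", rhs, "+ pinned zero-variance RE"),
               conv, TRUE, nrow(data), length(subj))
}

#' Fit the implicit-task accuracy GLMM
#'
#' Logistic mixed model of binary correctness on gaze validity, body-head
#' congruency and their interaction (object-present trials only), optionally
#' extended with standardized AQ (all AQ interactions) or a median-split AQ
#' group factor. Factor coding: 1 = gaze valid, 1 = congruent.
#'
#' @param trials implicit object-present trials ([filter_present_trials()]).
#' @param subjects subject table; required unless `aq = "none"`.
#' @param aq `"none"` (validity x congruency model), `"score"` (adds z-scored
#'   AQ and its interactions up to the three-way term) or `"group"` (adds the
#'   median-split low/high factor instead).
#' @param random random-effects structure: `"diagonal"` (default; random
#'   intercept plus uncorrelated slopes for the within-subject terms),
#'   `"intercept"`, `"maximal"` (correlated slopes), or `"none"` (all
#'   variances pinned at zero).
#' @param nAGQ adaptive Gauss-Hermite nodes for intercept-only fits
#'   (Laplace = 1); ignored when slopes are present.
#' @return A `gaze_fit`.
#' @export
fit_implicit_accuracy <- function(trials, subjects = NULL,
                                  aq = c("none", "score", "group"),
                                  random = c("diagonal", "intercept",
                                             "maximal", "none"),
                                  nAGQ = 1L) {
  aq <- match.arg(aq)
  random <- match.arg(random)
  if (aq != "none" && is.null(subjects)) {
    stop("subject table required for AQ models", call. = FALSE)
  }
  d <- make_model_frame(trials, subjects)
  if (unique(d$task) != "implicit") stop("expected implicit-task trials",
                                         call. = FALSE)
  slopes <- c("gaze_valid", "congruent", "gv_x_cong")
  fixed <- switch(aq,
    none = slopes,
    score = c(slopes, "aq_z", "gaze_valid:aq_z", "congruent:aq_z",
              "gv_x_cong:aq_z"),
    group = c(slopes, "aq_high", "gaze_valid:aq_high", "congruent:aq_high",
              "gv_x_cong:aq_high"))
  fit_glmm_engine("correct", fixed, slopes, d, "binomial", random, nAGQ)
}

#' Fit the explicit-task accuracy GLMM
#'
#' Logistic mixed model of correctness on body-head congruency (all explicit
#' trials are gaze-valid), optionally with standardized AQ and the
#' congruency x AQ interaction, and/or a standardized per-subject covariate
#' from the implicit task (two-stage transfer).
#'
#' @param trials explicit-task trials.
#' @param subjects subject table; required when `aq = "score"`.
#' @param aq `"none"` or `"score"`.
#' @param implicit_effect optional named numeric vector (names = subject ids)
#'   of per-subject implicit interaction coefficients; it is z-scored and
#'   entered as the fixed-effect covariate `implicit_accuracy`.
#' @inheritParams fit_implicit_accuracy
#' @return A `gaze_fit`.
#' @export
fit_explicit_accuracy <- function(trials, subjects = NULL,
                                  aq = c("none", "score"),
                                  implicit_effect = NULL,
                                  random = c("diagonal", "intercept",
                                             "maximal", "none"),
                                  nAGQ = 1L) {
  aq <- match.arg(aq)
  random <- match.arg(random)
  d <- make_model_frame(trials, if (aq == "score") subjects else NULL)
  if (unique(d$task) != "explicit") stop("expected explicit-task trials",
                                         call. = FALSE)
  fixed <- "congruent"
  if (aq == "score") fixed <- c(fixed, "aq_z", "congruent:aq_z")
  if (!is.null(implicit_effect)) {
    missing <- setdiff(unique(d$subject_id), names(implicit_effect))
    if (length(missing)) {
      stop("implicit_effect is missing subject(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    eff <- implicit_effect[as.character(d$subject_id)]
    d$implicit_accuracy <- zscore(unname(eff), "implicit_effect")
    fixed <- c(fixed, "implicit_accuracy")
  }
  fit_glmm_engine("correct", fixed, "congruent", d, "binomial", random, nAGQ)
}

#' Fit the confidence linear mixed model
#'
#' Confidence ratings are z-standardized within task, then regressed on
#' accuracy (0/1), z-scored AQ and their interaction, with a random intercept
#' and (by default) an uncorrelated random accuracy slope per subject. REML
#' estimates, t statistics with Satterthwaite df (via lmerTest). Implicit
#' trials should be pre-filtered to object-present rows to match the
#' accuracy analyses.
#'
#' @param trials single-task trial table with confidence filled.
#' @param subjects subject table (AQ).
#' @param random `"diagonal"` (default), `"intercept"`, `"maximal"`, or
#'   `"none"` (pinned zero-variance; equals OLS).
#' @param standardize_confidence z-score the response within the analysis
#'   sample (default TRUE).
#' @return A `gaze_fit` (family gaussian).
#' @export
fit_confidence_lmm <- function(trials, subjects,
                               random = c("diagonal", "intercept",
                                          "maximal", "none"),
                               standardize_confidence = TRUE) {
  random <- match.arg(random)
  d <- make_model_frame(trials, subjects)
  d$conf <- if (standardize_confidence) {
    zscore(as.numeric(d$confidence), "confidence")
  } else as.numeric(d$confidence)
  fit_glmm_engine("conf", c("correct", "aq_z", "correct:aq_z"), "correct",
                  d, "gaussian", random, 1L)
}

#' Fit the implicit confidence model with the design factors
#'
#' Control analysis: standardized confidence on gaze validity, congruency,
#' z-scored AQ and their interactions (object-present implicit trials).
#'
#' @inheritParams fit_confidence_lmm
#' @return A `gaze_fit`.
#' @export
fit_confidence_design_lmm <- function(trials, subjects,
                                      random = c("diagonal", "intercept",
                                                 "maximal", "none")) {
  random <- match.arg(random)
  d <- make_model_frame(trials, subjects)
  if (unique(d$task) != "implicit") stop("expected implicit-task trials",
                                         call. = FALSE)
  d$conf <- zscore(as.numeric(d$confidence), "confidence")
  slopes <- c("gaze_valid", "congruent", "gv_x_cong")
  fixed <- c(slopes, "aq_z", "gaze_valid:aq_z", "congruent:aq_z",
             "gv_x_cong:aq_z")
  fit_glmm_engine("conf", fixed, slopes, d, "gaussian", random, 1L)
}

#' Per-subject coefficients for a model term
#'
#' Subject-level coefficient = fixed-effect estimate + the subject's
#' conditional mode (BLUP) for the matching random slope. Requires the term
#' to carry a random slope in the fit.
#'
#' @param fit a `gaze_fit`.
#' @param term model term name (e.g. `"gv_x_cong"`, `"congruent"`).
#' @return data.frame with `subject_id` and `effect`.
#' @export
extract_subject_effects <- function(fit, term) {
  stopifnot(inherits(fit, "gaze_fit"))
  if (!term %in% fit$coefficients$term) {
    stop("term '", term, "' is not a fixed effect of this fit", call. = FALSE)
  }
  if (!term %in% colnames(fit$ranef_modes)) {
    stop("term '", term, "' has no random slope in this fit; ",
         "refit with random = 'diagonal' or 'maximal'", call. = FALSE)
  }
  fixed <- fit$coefficients$estimate[fit$coefficients$term == term]
  data.frame(subject_id = rownames(fit$ranef_modes),
             effect = fixed + fit$ranef_modes[[term]],
             stringsAsFactors = FALSE)
}

#' Two-stage transfer of implicit coefficients into the explicit model
#'
#' Extracts per-subject gaze-validity x congruency interaction coefficients
#' from the implicit accuracy fit, z-scores them, and refits the explicit
#' accuracy model with this `implicit_accuracy` covariate. Subject ids must
#' align between stages.
#'
#' @param implicit_fit implicit `gaze_fit` with a random interaction slope.
#' @param explicit_trials explicit-task trials.
#' @param term implicit term to transfer (default the interaction).
#' @inheritParams fit_explicit_accuracy
#' @return A `gaze_fit` containing the `implicit_accuracy` row.
#' @export
fit_transfer <- function(implicit_fit, explicit_trials,
                         term = "gv_x_cong",
                         random = c("diagonal", "intercept",
                                    "maximal", "none")) {
  random <- match.arg(random)
  eff <- extract_subject_effects(implicit_fit, term)
  v <- stats::setNames(eff$effect, eff$subject_id)
  fit_explicit_accuracy(explicit_trials, implicit_effect = v, random = random)
}

#' Paired comparison of per-subject coefficient vectors
#'
#' Paired t test on the per-subject differences between two coefficient
#' vectors (e.g. the implicit interaction vs the explicit congruency
#' coefficients), df = n - 1.
#'
#' @param effects_a,effects_b data.frames from [extract_subject_effects()]
#'   with matching `subject_id` sets.
#' @return list with `mean_a`, `se_a`, `mean_b`, `se_b`, `t`, `df`, `p`.
#' @export
compare_subject_effects <- function(effects_a, effects_b) {
  if (!setequal(effects_a$subject_id, effects_b$subject_id) ||
      nrow(effects_a) != nrow(effects_b)) {
    stop("subject sets differ between the two coefficient vectors",
         call. = FALSE)
  }
  a <- effects_a$effect
  b <- effects_b$effect[match(effects_a$subject_id, effects_b$subject_id)]
  n <- length(a)
  if (n < 2L) stop("need at least 2 paired subjects", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  # shrinkage can truncate the between-subject variance to (numerically)
  # zero, in which case the paired t is not identified
  if (sd_d <= 1e-6 * max(1, abs(mean(d)))) {
    if (mean(d) == 0) {
      tstat <- 0
    } else {
      stop("zero variance in paired differences with nonzero mean; ",
           "t statistic undefined", call. = FALSE)
    }
  } else {
    tstat <- mean(d) / (sd_d / sqrt(n))
  }
  list(mean_a = mean(a), se_a = stats::sd(a) / sqrt(n),
       mean_b = mean(b), se_b = stats::sd(b) / sqrt(n),
       t = tstat, df = n - 1L,
       p = 2 * stats::pt(-abs(tstat), n - 1L))
}
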