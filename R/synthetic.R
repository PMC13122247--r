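# Seeded synthetic generator for the gaze-perception design.
#
# Defaults reproduce the study conditions: 64 subjects; implicit task
# 96 trials (48 object-present, 12 per gaze-validity x congruency cell,
# 48 object-absent fillers); explicit task 96 gaze-valid trials, 48 per
# congruency level; integer AQ with mean 16.1, SD 6.08, truncated to [2, 27].
# Accuracy follows a random-intercept logistic model; confidence follows a
# latent type-2 model whose accuracy coupling weakens with AQ in the
# explicit task only.

#' Generator configuration
#'
#' All simulation parameters for the synthetic gaze-perception experiment.
#' Fixed-effect defaults are on the log-odds scale with 0/1 factor coding
#' (1 = gaze valid, 1 = body-head congruent) and AQ standardized by the
#' configured moments.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_implicit_cell object-present trials per gaze-validity x
#'   congruency cell in the implicit task (absent fillers are matched so the
#'   task totals twice the present count).
#' @param trials_per_explicit_condition explicit trials per congruency level.
#' @param implicit_fixed named log-odds coefficients `(intercept,
#'   gaze_validity, congruency, interaction)` of implicit object-present
#'   accuracy.
#' @param explicit_fixed named log-odds coefficients `(intercept, congruency,
#'   aq, congruency_aq)` of explicit accuracy; `aq` multiplies standardized AQ.
#' @param random_intercept_sd per-task SD of the subject accuracy random
#'   intercept.
#' @param random_slope_sd per-task named SDs of subject random slopes on the
#'   log-odds scale: implicit `(gaze_validity, congruency, interaction)`,
#'   explicit `(congruency)`. These give subjects genuinely different
#'   condition effects, which the per-subject coefficient extraction and the
#'   two-stage transfer rely on.
#' @param transfer_coupling log-odds change in explicit accuracy per SD of a
#'   subject's implicit interaction-slope deviation (0 = the tasks share no
#'   subject trait beyond AQ).
#' @param absent_accuracy fixed correct-rejection probability on implicit
#'   object-absent filler trials.
#' @param aq_mean,aq_sd,aq_range moments and truncation bounds of the
#'   rounded-Gaussian AQ draw.
#' @param confidence list of latent confidence-model parameters, per task:
#'   `mu0` latent intercept, `type2_slope` accuracy coupling (type-2
#'   sensitivity), `type2_aq_slope` change of that coupling per SD of AQ
#'   (negative in the explicit task only), `type2_slope_sd` between-subject SD
#'   of the coupling, `intercept_sd` between-subject SD of baseline
#'   confidence, `noise_sd` trial-level latent noise, and `cuts`, the 10
#'   strictly increasing latent cut points mapping to the 11-point 0-100
#'   rating grid.
#' @return An object of class `gaze_config`.
#' @export
generator_config <- function(
    n_subjects = 64L,
    trials_per_implicit_cell = 12L,
    trials_per_explicit_condition = 48L,
    implicit_fixed = c(intercept = 1.01, gaze_validity = 0.96,
                       congruency = 0.99, interaction = -1.04),
    explicit_fixed = c(intercept = 1.72, congruency = 0.07,
                       aq = -0.20, congruency_aq = 0),
    random_intercept_sd = c(implicit = 0.5, explicit = 0.5),
    random_slope_sd = list(
      implicit = c(gaze_validity = 0.3, congruency = 0.3,
                   interaction = 0.5),
      explicit = c(congruency = 0.2)),
    transfer_coupling = 0,
    absent_accuracy = 0.95,
    aq_mean = 16.1, aq_sd = 6.08, aq_range = c(2L, 27L),
    confidence = list(
      mu0 = c(implicit = -1.38, explicit = -1.00),
      type2_slope = c(implicit = 1.66, explicit = 1.17),
      type2_aq_slope = c(implicit = 0, explicit = -0.25),
      type2_slope_sd = c(implicit = 0.3, explicit = 0.3),
      intercept_sd = c(implicit = 0.3, explicit = 0.3),
      noise_sd = c(implicit = 0.72, explicit = 0.85),
      cuts = seq(-2.25, 2.25, by = 0.5)
    )) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    trials_per_implicit_cell = as.integer(trials_per_implicit_cell),
    trials_per_explicit_condition = as.integer(trials_per_explicit_condition),
    implicit_fixed = implicit_fixed,
    explicit_fixed = explicit_fixed,
    random_intercept_sd = random_intercept_sd,
    random_slope_sd = random_slope_sd,
    transfer_coupling = transfer_coupling,
    absent_accuracy = absent_accuracy,
    aq_mean = aq_mean, aq_sd = aq_sd, aq_range = as.integer(aq_range),
    confidence = confidence
  )
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (cfg$aq_sd <= 0) stop("aq_sd must be > 0", call. = FALSE)
  if (cfg$aq_range[1] > cfg$aq_range[2]) {
    stop("aq_range must be non-decreasing", call. = FALSE)
  }
  if (absent_accuracy <= 0 || absent_accuracy >= 1) {
    stop("absent_accuracy must lie in (0, 1)", call. = FALSE)
  }
  cuts <- cfg$confidence$cuts
  if (length(cuts) != 10L || any(diff(cuts) <= 0)) {
    stop("confidence$cuts must be 10 strictly increasing latent bounds",
         call. = FALSE)
  }
  if (!all(c("gaze_validity", "congruency", "interaction") %in%
             names(cfg$random_slope_sd$implicit)) ||
      !"congruency" %in% names(cfg$random_slope_sd$explicit)) {
    stop("random_slope_sd must name the implicit ",
         "(gaze_validity, congruency, interaction) and explicit ",
         "(congruency) slopes", call. = FALSE)
  }
  needed <- c("mu0", "type2_slope", "type2_aq_slope", "type2_slope_sd",
              "intercept_sd", "noise_sd")
  for (p in needed) {
    if (!all(TASKS %in% names(cfg$confidence[[p]]))) {
      stop("confidence$", p, " must be named per task", call. = FALSE)
    }
  }
  class(cfg) <- "gaze_config"
  cfg
}

# Per-subject RNG streams: every draw for subject i comes from a seed derived
# from (base seed, i, stream), so adding subjects never perturbs earlier
# subjects' tables. Kept below 2^31.
derive_seed <- function(seed, subject, stream) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(subject) * 30269 +
                as.double(stream) * 9973) %% 2147483647)
}

# AQ is z-scored with the configured moments (not the realized sample) so
# generated probabilities are prefix-stable in n_subjects.
aq_z_config <- function(cfg, aq) (aq - cfg$aq_mean) / cfg$aq_sd

#' Sample synthetic subjects and their random effects
#'
#' AQ scores are rounded truncated-normal draws; subject random effects
#' (accuracy intercepts per task, confidence intercepts and type-2 slope
#' deviations per task) are Gaussian with the configured SDs. Each subject
#' uses a private RNG stream derived from `seed`.
#'
#' @param config a [generator_config()].
#' @param seed integer base seed.
#' @return data.frame with `subject_id`, `aq_score` and random-effect columns
#'   `b_acc_implicit`, `b_acc_explicit`, `b_conf_implicit`, `b_conf_explicit`,
#'   `u_slope_implicit`, `u_slope_explicit`.
#' @export
sample_subjects <- function(config, seed) {
  stopifnot(inherits(config, "gaze_config"))
  n <- config$n_subjects
  rows <- lapply(seq_len(n), function(i) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, i, 1L))
    repeat {
      aq <- as.integer(round(stats::rnorm(1, config$aq_mean, config$aq_sd)))
      if (aq >= config$aq_range[1] && aq <= config$aq_range[2]) break
    }
    cc <- config$confidence
    rs <- config$random_slope_sd
    data.frame(
      subject_id = sprintf("S%03d", i),
      aq_score = aq,
      b_acc_implicit = stats::rnorm(1, 0, config$random_intercept_sd[["implicit"]]),
      b_acc_explicit = stats::rnorm(1, 0, config$random_intercept_sd[["explicit"]]),
      u_imp_gv = stats::rnorm(1, 0, rs$implicit[["gaze_validity"]]),
      u_imp_cong = stats::rnorm(1, 0, rs$implicit[["congruency"]]),
      u_imp_int = stats::rnorm(1, 0, rs$implicit[["interaction"]]),
      u_exp_cong = stats::rnorm(1, 0, rs$explicit[["congruency"]]),
      b_conf_implicit = stats::rnorm(1, 0, cc$intercept_sd[["implicit"]]),
      b_conf_explicit = stats::rnorm(1, 0, cc$intercept_sd[["explicit"]]),
      u_slope_implicit = stats::rnorm(1, 0, cc$type2_slope_sd[["implicit"]]),
      u_slope_explicit = stats::rnorm(1, 0, cc$type2_slope_sd[["explicit"]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate correctness for one task
#'
#' Implicit task: for each subject, 12 (configurable) object-present trials
#' per gaze-validity x congruency cell with
#' `logit p = intercept + b_gv*valid + b_cong*congruent +
#' b_int*valid*congruent + b_subject`, plus matched object-absent filler
#' trials at the fixed correct-rejection rate. Explicit task: 48 gaze-valid
#' trials per congruency level with
#' `logit p = intercept + b_cong*congruent + b_aq*z(AQ) +
#' b_cong_aq*congruent*z(AQ) + b_subject`. Trial order is shuffled per
#' subject; correctness is Bernoulli.
#'
#' @param config a [generator_config()].
#' @param subjects output of [sample_subjects()].
#' @param task `"implicit"` or `"explicit"`.
#' @param seed integer base seed (use the same seed as for
#'   [sample_subjects()] for one coherent experiment).
#' @return Trial table in the package schema, `confidence` initialized to 0
#'   until [simulate_confidence()] fills it.
#' @export
simulate_task <- function(config, subjects, task, seed) {
  stopifnot(inherits(config, "gaze_config"))
  task <- match.arg(task, TASKS)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(seed, i, if (task == "implicit") 2L else 3L))
    if (task == "implicit") {
      k <- config$trials_per_implicit_cell
      pres <- expand.grid(gaze_validity = c("valid", "invalid"),
                          body_head_congruency = CONGRUENCY_LEVELS,
                          rep = seq_len(k), stringsAsFactors = FALSE)
      b <- config$implicit_fixed
      gv <- as.integer(pres$gaze_validity == "valid")
      cg <- as.integer(pres$body_head_congruency == "congruent")
      eta <- b[["intercept"]] + (b[["gaze_validity"]] + s$u_imp_gv) * gv +
        (b[["congruency"]] + s$u_imp_cong) * cg +
        (b[["interaction"]] + s$u_imp_int) * gv * cg +
        s$b_acc_implicit
      pres_df <- data.frame(
        subject_id = s$subject_id, task = task,
        gaze_validity = pres$gaze_validity,
        body_head_congruency = pres$body_head_congruency,
        object_present = TRUE,
        correct = stats::rbinom(nrow(pres), 1, stats::plogis(eta)),
        stringsAsFactors = FALSE
      )
      n_abs <- 4L * k
      abs_df <- data.frame(
        subject_id = s$subject_id, task = task,
        gaze_validity = "not_applicable",
        body_head_congruency = rep(CONGRUENCY_LEVELS, each = n_abs %/% 2L,
                                   length.out = n_abs),
        object_present = FALSE,
        correct = stats::rbinom(n_abs, 1, config$absent_accuracy),
        stringsAsFactors = FALSE
      )
      out <- rbind(pres_df, abs_df)
    } else {
      k <- config$trials_per_explicit_condition
      b <- config$explicit_fixed
      cg <- rep(c(1L, 0L), each = k)
      z <- aq_z_config(config, s$aq_score)
      int_sd <- config$random_slope_sd$implicit[["interaction"]]
      trait <- if (int_sd > 0) s$u_imp_int / int_sd else 0
      eta <- b[["intercept"]] + (b[["congruency"]] + s$u_exp_cong) * cg +
        b[["aq"]] * z + b[["congruency_aq"]] * cg * z +
        config$transfer_coupling * trait + s$b_acc_explicit
      out <- data.frame(
        subject_id = s$subject_id, task = task,
        gaze_validity = "valid",
        body_head_congruency = ifelse(cg == 1L, "congruent", "incongruent"),
        object_present = TRUE,
        correct = stats::rbinom(length(cg), 1, stats::plogis(eta)),
        stringsAsFactors = FALSE
      )
    }
    out <- out[sample.int(nrow(out)), ]
    out$trial_index <- seq_len(nrow(out))
    out$confidence <- 0L
    rownames(out) <- NULL
    out[, trial_columns]
  })
  do.call(rbind, rows)
}

#' Fill in confidence ratings from the latent type-2 model
#'
#' Latent confidence is
#' `mu0 + (s0 + s_AQ * z(AQ) + u_subject) * correct + b_subject + noise`,
#' discretized to the 11-point 0-100 grid by the fixed cut points. With the
#' default negative `s_AQ` in the explicit task, the coupling between
#' confidence and accuracy -- and hence downstream AUROC2 -- declines with
#' AQ there, while the implicit task's coupling is AQ-independent.
#'
#' @inheritParams simulate_task
#' @param trials trial table with correctness already assigned.
#' @return `trials` with `confidence` filled.
#' @export
simulate_confidence <- function(config, trials, subjects, seed) {
  stopifnot(inherits(config, "gaze_config"))
  cc <- config$confidence
  idx <- match(trials$subject_id, subjects$subject_id)
  if (anyNA(idx)) stop("trials reference unknown subjects", call. = FALSE)
  conf <- integer(nrow(trials))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    for (task in intersect(TASKS, unique(trials$task))) {
      sel <- which(idx == i & trials$task == task)
      if (!length(sel)) next
      old <- .Random.seed_save()
      set.seed(derive_seed(seed, i, if (task == "implicit") 4L else 5L))
      slope <- cc$type2_slope[[task]] +
        cc$type2_aq_slope[[task]] * aq_z_config(config, s$aq_score) +
        s[[paste0("u_slope_", task)]]
      latent <- cc$mu0[[task]] + slope * trials$correct[sel] +
        s[[paste0("b_conf_", task)]] +
        stats::rnorm(length(sel), 0, cc$noise_sd[[task]])
      conf[sel] <- 10L * findInterval(latent, cc$cuts)
      .Random.seed_restore(old)
    }
  }
  trials$confidence <- conf
  trials
}

#' Simulate a complete two-task experiment
#'
#' Convenience wrapper: samples subjects, simulates both tasks and fills
#' confidence. Identical `(config, seed)` yields byte-identical tables.
#'
#' @inheritParams simulate_task
#' @return list with `subjects` (public columns only), `trials` (both tasks)
#'   and `truth` (subjects including random effects, for recovery studies).
#' @export
simulate_experiment <- function(config = generator_config(), seed = 1L) {
  subjects <- sample_subjects(config, seed)
  trials <- rbind(simulate_task(config, subjects, "implicit", seed),
                  simulate_task(config, subjects, "explicit", seed))
  trials <- simulate_confidence(config, trials, subjects, seed)
  list(subjects = subjects[, c("subject_id", "aq_score")],
       trials = validate_trials(trials),
       truth = subjects)
}
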