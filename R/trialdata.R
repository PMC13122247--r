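#' @keywords internal
"_PACKAGE"

# Confidence must lie on the 11-point scale used by both tasks.
CONFIDENCE_GRID <- seq(0L, 100L, by = 10L)

TASKS <- c("implicit", "explicit")
GAZE_LEVELS <- c("valid", "invalid", "not_applicable")
CONGRUENCY_LEVELS <- c("congruent", "incongruent")

trial_columns <- c(
  "subject_id", "task", "trial_index", "gaze_validity",
  "body_head_congruency", "object_present", "correct", "confidence"
)
subject_columns <- c("subject_id", "aq_score")

norm_enum <- function(x, levels, column, rows = NULL) {
  out <- levels[match(tolower(trimws(as.character(x))), levels)]
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    where <- if (is.null(rows)) bad else rows[bad]
    stop(sprintf("invalid %s value(s) in row(s) %s: %s", column,
                 paste(utils::head(where, 5L), collapse = ", "),
                 paste(utils::head(unique(x[bad]), 5L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

#' Validate a trial table against the design schema
#'
#' Checks column presence, enum levels, the 11-point confidence grid and the
#' task-level structural invariants (explicit trials are gaze-valid and
#' object-present; implicit object-absent trials carry no gaze validity).
#' Called by [read_trials()] and usable directly on in-memory tables.
#'
#' @param trials data.frame of trials (one row per trial).
#' @return The validated, normalized data.frame (enum labels lower-case,
#'   `object_present` logical, `correct` integer 0/1).
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- as.data.frame(trials)[, trial_columns]
  rows <- seq_len(nrow(trials))
  trials$subject_id <- as.character(trials$subject_id)
  trials$task <- norm_enum(trials$task, TASKS, "task", rows)
  trials$gaze_validity <- norm_enum(trials$gaze_validity, GAZE_LEVELS,
                                    "gaze_validity", rows)
  trials$body_head_congruency <- norm_enum(trials$body_head_congruency,
                                           CONGRUENCY_LEVELS,
                                           "body_head_congruency", rows)
  trials$trial_index <- as.integer(trials$trial_index)
  if (any(is.na(trials$trial_index)) || any(trials$trial_index < 1L)) {
    stop("trial_index must be an integer >= 1", call. = FALSE)
  }
  if (is.character(trials$object_present)) {
    trials$object_present <- tolower(trimws(trials$object_present)) %in%
      c("true", "t", "1", "yes")
  }
  trials$object_present <- as.logical(trials$object_present)
  trials$correct <- as.integer(trials$correct)
  bad <- which(!trials$correct %in% c(0L, 1L))
  if (length(bad)) {
    stop("correct must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  trials$confidence <- as.integer(trials$confidence)
  bad <- which(!trials$confidence %in% CONFIDENCE_GRID)
  if (length(bad)) {
    stop("confidence must be on the 0-100 grid in steps of 10; ",
         "offending row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  expl <- trials$task == "explicit"
  bad <- which(expl & (trials$gaze_validity != "valid" | !trials$object_present))
  if (length(bad)) {
    stop("explicit-task rows must be gaze-valid and object-present; ",
         "offending row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!expl & !trials$object_present &
                 trials$gaze_validity != "not_applicable")
  if (length(bad)) {
    stop("implicit object-absent rows must have gaze_validity ",
         "'not_applicable'; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- which(!expl & trials$object_present &
                 trials$gaze_validity == "not_applicable")
  if (length(bad)) {
    stop("implicit object-present rows must be gaze valid or invalid; ",
         "offending row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  trials
}

#' Validate a subject table
#'
#' @param subjects data.frame with at least `subject_id` and `aq_score`
#'   (Autism-Spectrum Quotient total, instrument range 0-50).
#' @return Normalized data.frame.
#' @export
validate_subjects <- function(subjects) {
  missing <- setdiff(subject_columns, names(subjects))
  if (length(missing)) {
    stop("subject table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  subjects <- as.data.frame(subjects)
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$aq_score <- as.integer(subjects$aq_score)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id in subject table", call. = FALSE)
  }
  bad <- which(is.na(subjects$aq_score) | subjects$aq_score < 0L |
                 subjects$aq_score > 50L)
  if (length(bad)) {
    stop("aq_score must lie in the AQ instrument range [0, 50]; ",
         "offending row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  subjects
}

#' Read trial and subject tables from CSV
#'
#' One UTF-8 comma-separated trial file (columns `subject_id, task,
#' trial_index, gaze_validity, body_head_congruency, object_present, correct,
#' confidence`) and optionally one subject file (`subject_id, aq_score`,
#' optional `age`, `gender`). Enum labels are matched case-insensitively.
#'
#' @param path path to the trial CSV.
#' @param subjects_path optional path to the subject CSV.
#' @param sep field delimiter (default comma).
#' @return A list with elements `trials` and (if requested) `subjects`.
#' @export
read_trials <- function(path, subjects_path = NULL, sep = ",") {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  trials <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  trials <- validate_trials(trials)
  out <- list(trials = trials)
  if (!is.null(subjects_path)) {
    if (!file.exists(subjects_path)) {
      stop("subject file not found: ", subjects_path, call. = FALSE)
    }
    subj <- utils::read.table(subjects_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
    out$subjects <- validate_subjects(subj)
  }
  out
}

#' Write trial / subject tables as CSV
#'
#' Writes the documented schema so that `read_trials(write_trials(x))`
#' round-trips field-for-field.
#'
#' @param trials,subjects data.frames in the package schema.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  utils::write.table(trials, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials
#' @export
write_subjects <- function(subjects, path) {
  subjects <- validate_subjects(subjects)
  utils::write.table(subjects, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Check design balance per subject
#'
#' The implicit task contributes 96 trials per subject, half object-present,
#' the present half split 12/12/12/12 over gaze validity x body-head
#' congruency; the explicit task contributes 96 gaze-valid trials split 48/48
#' over congruency. Violations are returned as data, not raised.
#'
#' @param trials validated trial table (may mix tasks).
#' @param trials_per_implicit_cell,trials_per_explicit_condition expected cell
#'   sizes; defaults are the design's (12 and 48).
#' @return An object of class `design_report`: list with `task_counts`,
#'   `cell_counts` and character vector `violations` (empty iff balanced).
#' @export
validate_design <- function(trials, trials_per_implicit_cell = 12L,
                            trials_per_explicit_condition = 48L) {
  violations <- character(0)
  if (nrow(trials) == 0L) {
    rep <- list(task_counts = table(character(0)),
                cell_counts = NULL, violations = "no trials")
    class(rep) <- "design_report"
    return(rep)
  }
  trials <- validate_trials(trials)
  k_imp <- trials_per_implicit_cell
  k_exp <- trials_per_explicit_condition
  cells <- list()
  for (task in intersect(TASKS, unique(trials$task))) {
    tt <- trials[trials$task == task, ]
    for (s in unique(tt$subject_id)) {
      st <- tt[tt$subject_id == s, ]
      if (task == "implicit") {
        expected_total <- 8L * k_imp
        if (nrow(st) != expected_total) {
          violations <- c(violations, sprintf(
            "subject %s: implicit trial count %d != %d", s, nrow(st),
            expected_total))
        }
        pres <- st[st$object_present, ]
        if (nrow(pres) != 4L * k_imp) {
          violations <- c(violations, sprintf(
            "subject %s: implicit object-present count %d != %d", s,
            nrow(pres), 4L * k_imp))
        }
        tab <- table(pres$gaze_validity, pres$body_head_congruency)
        for (gv in c("valid", "invalid")) {
          for (cg in CONGRUENCY_LEVELS) {
            n <- if (gv %in% rownames(tab) && cg %in% colnames(tab)) {
              tab[gv, cg]
            } else 0L
            if (n != k_imp) {
              violations <- c(violations, sprintf(
                "subject %s: implicit cell %s x %s has %d trials, expected %d",
                s, gv, cg, n, k_imp))
            }
          }
        }
        cells[[paste0("implicit.", s)]] <- tab
      } else {
        if (nrow(st) != 2L * k_exp) {
          violations <- c(violations, sprintf(
            "subject %s: explicit trial count %d != %d", s, nrow(st),
            2L * k_exp))
        }
        tab <- table(st$body_head_congruency)
        for (cg in CONGRUENCY_LEVELS) {
          n <- if (cg %in% names(tab)) tab[[cg]] else 0L
          if (n != k_exp) {
            violations <- c(violations, sprintf(
              "subject %s: explicit condition %s has %d trials, expected %d",
              s, cg, n, k_exp))
          }
        }
        cells[[paste0("explicit.", s)]] <- tab
      }
    }
  }
  rep <- list(task_counts = table(trials$task),
              cell_counts = cells, violations = violations)
  class(rep) <- "design_report"
  rep
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report\n")
  print(x$task_counts)
  if (length(x$violations) == 0L) {
    cat("No balance violations.\n")
  } else {
    cat(length(x$violations), "violation(s):\n")
    cat(paste0("  - ", utils::head(x$violations, 20L)), sep = "\n")
    if (length(x$violations) > 20L) cat("  ...\n")
  }
  invisible(x)
}

#' Restrict implicit trials to object-present rows
#'
#' The object-detection analyses consider only trials in which the cued
#' object was present (half of all implicit trials); object-absent fillers
#' are dropped. Idempotent; row order is preserved.
#'
#' @param trials implicit-task trial table.
#' @return The object-present subset.
#' @export
filter_present_trials <- function(trials) {
  if (nrow(trials) == 0L) return(trials)
  if (any(trials$task != "implicit")) {
    stop("filter_present_trials applies to implicit-task trials only",
         call. = FALSE)
  }
  trials[trials$object_present, , drop = FALSE]
}

#' Summarize accuracy by condition
#'
#' Means are aggregated per subject first; the standard error of a group is
#' the sample SD of per-subject means divided by the square root of the
#' number of subjects.
#'
#' @param trials trial table.
#' @param by character vector of grouping columns (e.g.
#'   `c("gaze_validity", "body_head_congruency")`); may be empty for an
#'   overall summary.
#' @param percent report means/SEs on the 0-100 scale (default) rather than
#'   proportions.
#' @return data.frame with group columns, `n_trials`, `n_subjects`,
#'   `mean_accuracy`, `se`.
#' @export
summarize_accuracy <- function(trials, by = character(0), percent = TRUE) {
  if (nrow(trials) == 0L) stop("no trials to summarize", call. = FALSE)
  stopifnot(all(by %in% names(trials)))
  key <- if (length(by)) interaction(trials[by], drop = TRUE, sep = "\r")
         else factor(rep("all", nrow(trials)))
  out <- lapply(levels(key), function(g) {
    gt <- trials[key == g, , drop = FALSE]
    per_subj <- tapply(gt$correct, gt$subject_id, mean)
    m <- mean(gt$correct)
    se <- if (length(per_subj) > 1L) {
      stats::sd(per_subj) / sqrt(length(per_subj))
    } else NA_real_
    labels <- if (length(by)) {
      stats::setNames(as.data.frame(as.list(strsplit(g, "\r", fixed = TRUE)[[1]]),
                                    col.names = by), by)
    } else data.frame(group = "all")
    cbind(labels,
          data.frame(n_trials = nrow(gt), n_subjects = length(per_subj),
                     mean_accuracy = if (percent) 100 * m else m,
                     se = if (percent) 100 * se else se))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median-split AQ scores into low/high groups
#'
#' Scores at or below the sample median form the low group (ties at the
#' median go to the low group).
#'
#' @param subjects subject table with `aq_score`.
#' @return `subjects` with columns `aq_group` (factor low/high) and
#'   `aq_median` attribute.
#' @export
add_aq_group <- function(subjects) {
  subjects <- validate_subjects(subjects)
  med <- stats::median(subjects$aq_score)
  subjects$aq_group <- factor(ifelse(subjects$aq_score <= med, "low", "high"),
                              levels = c("low", "high"))
  attr(subjects, "aq_median") <- med
  subjects
}
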