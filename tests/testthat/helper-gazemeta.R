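# Shared fixtures, built in code.

# Reduced-size configuration for fast structural tests; the acceptance tests
# use the full study-size defaults.
small_config <- function(n_subjects = 8L, ...) {
  generator_config(n_subjects = n_subjects, ...)
}

# A deterministic 4-row valid trial table covering both tasks.
tiny_trials <- function() {
  data.frame(
    subject_id = c("S1", "S1", "S2", "S2"),
    task = c("implicit", "implicit", "explicit", "explicit"),
    trial_index = c(1L, 2L, 1L, 2L),
    gaze_validity = c("valid", "not_applicable", "valid", "valid"),
    body_head_congruency = c("congruent", "incongruent",
                             "congruent", "incongruent"),
    object_present = c(TRUE, FALSE, TRUE, TRUE),
    correct = c(1L, 0L, 1L, 1L),
    confidence = c(80L, 40L, 100L, 60L),
    stringsAsFactors = FALSE
  )
}

# Noise-free generator: no random effects, no AQ slope on accuracy.
flat_config <- function(n_subjects = 4L, ...) {
  generator_config(
    n_subjects = n_subjects,
    random_intercept_sd = c(implicit = 0, explicit = 0),
    random_slope_sd = list(
      implicit = c(gaze_validity = 0, congruency = 0, interaction = 0),
      explicit = c(congruency = 0)),
    ...
  )
}
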