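test_that("identical config and seed reproduce identical tables", {
  a <- simulate_experiment(small_config(5L), seed = 42)
  b <- simulate_experiment(small_config(5L), seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
  c <- simulate_experiment(small_config(5L), seed = 43)
  expect_false(identical(a$trials$correct, c$trials$correct))
})

test_that("adding subjects never perturbs earlier subjects' tables", {
  small <- simulate_experiment(small_config(5L), seed = 7)
  large <- simulate_experiment(small_config(9L), seed = 7)
  keep <- unique(small$trials$subject_id)
  reset_rn <- function(d) { rownames(d) <- NULL; d }
  expect_identical(
    reset_rn(small$trials),
    reset_rn(large$trials[large$trials$subject_id %in% keep, ]))
  expect_identical(reset_rn(small$subjects),
                   reset_rn(large$subjects[1:5, ]))
})

test_that("AQ draws respect the truncation range and the truncated mean", {
  subj <- sample_subjects(generator_config(), seed = 1)
  expect_true(all(subj$aq_score >= 2 & subj$aq_score <= 27))
  expect_true(all(subj$aq_score == round(subj$aq_score)))

  expect_error(generator_config(aq_sd = 0), "aq_sd")

  # large-sample mean against the closed-form truncated-normal oracle
  # (rounding then accepting in [2, 27] truncates the latent at [1.5, 27.5])
  big <- sample_subjects(generator_config(n_subjects = 4000L), seed = 2)
  a <- (1.5 - 16.1) / 6.08
  b <- (27.5 - 16.1) / 6.08
  trunc_mean <- 16.1 - 6.08 * (dnorm(b) - dnorm(a)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(big$aq_score) - trunc_mean), 0.2)
})

test_that("simulated cell accuracies match the inverse-logit linear predictor", {
  # no random effects, huge cell counts: empirical rates hit the closed form
  cfg <- flat_config(n_subjects = 2L, trials_per_implicit_cell = 4000L)
  subj <- sample_subjects(cfg, seed = 1)
  tr <- simulate_task(cfg, subj, "implicit", seed = 1)
  pres <- filter_present_trials(tr)
  cell <- function(gv, cg) {
    mean(pres$correct[pres$gaze_validity == gv &
                        pres$body_head_congruency == cg])
  }
  expect_lt(abs(cell("invalid", "incongruent") - plogis(1.01)), 0.02)
  expect_lt(abs(cell("valid", "incongruent") - plogis(1.01 + 0.96)), 0.02)
  expect_lt(abs(cell("invalid", "congruent") - plogis(1.01 + 0.99)), 0.02)
  expect_lt(abs(cell("valid", "congruent") -
                  plogis(1.01 + 0.96 + 0.99 - 1.04)), 0.02)
  expect_lt(abs(mean(tr$correct[!tr$object_present]) - 0.95), 0.02)

  # all effects zero: long-run accuracy is 50%
  cfg0 <- flat_config(
    n_subjects = 2L, trials_per_implicit_cell = 2000L,
    implicit_fixed = c(intercept = 0, gaze_validity = 0, congruency = 0,
                       interaction = 0))
  tr0 <- filter_present_trials(
    simulate_task(cfg0, sample_subjects(cfg0, 1), "implicit", seed = 1))
  expect_lt(abs(mean(tr0$correct) - 0.5), 0.02)
})

test_that("generated data are balanced and schema-valid", {
  sim <- simulate_experiment(small_config(6L), seed = 12)
  expect_length(validate_design(sim$trials)$violations, 0)
  expect_silent(validate_trials(sim$trials))
  expl <- sim$trials[sim$trials$task == "explicit", ]
  expect_true(all(expl$gaze_validity == "valid" & expl$object_present))
})

test_that("confidence model produces the configured accuracy coupling", {
  # vanishing noise and no slope heterogeneity: perfect type-2 separation
  cfg <- flat_config(n_subjects = 3L)
  cfg$confidence$noise_sd[] <- 1e-6
  cfg$confidence$type2_slope_sd[] <- 0
  cfg$confidence$intercept_sd[] <- 0
  sim <- simulate_experiment(cfg, seed = 4)
  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])
  tab <- subject_auroc2(imp)
  expect_true(all(tab$auroc2[tab$defined] == 1))

  # zero coupling: confidence independent of accuracy, AUROC2 near chance
  cfg0 <- flat_config(n_subjects = 40L)
  cfg0$confidence$type2_slope[] <- 0
  cfg0$confidence$type2_aq_slope[] <- 0
  cfg0$confidence$type2_slope_sd[] <- 0
  sim0 <- simulate_experiment(cfg0, seed = 5)
  expl0 <- sim0$trials[sim0$trials$task == "explicit", ]
  tab0 <- subject_auroc2(expl0)
  expect_lt(abs(mean(tab0$auroc2[tab0$defined]) - 0.5), 0.03)

  expect_error(generator_config(confidence = list(
    mu0 = c(implicit = 0, explicit = 0),
    type2_slope = c(implicit = 1, explicit = 1),
    type2_aq_slope = c(implicit = 0, explicit = 0),
    type2_slope_sd = c(implicit = 0, explicit = 0),
    intercept_sd = c(implicit = 0, explicit = 0),
    noise_sd = c(implicit = 1, explicit = 1),
    cuts = rep(0, 10))), "strictly increasing")
})

test_that("explicit type-2 AQ slope induces a negative AUROC2-AQ correlation", {
  sim <- simulate_experiment(generator_config(), seed = 31)
  expl <- sim$trials[sim$trials$task == "explicit", ]
  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])
  tab_e <- merge(subject_auroc2(expl), sim$subjects)
  tab_i <- merge(subject_auroc2(imp), sim$subjects)
  tab_e <- tab_e[tab_e$defined, ]
  tab_i <- tab_i[tab_i$defined, ]
  expect_lt(spearman_test(tab_e$auroc2, tab_e$aq_score)$rho, 0)
  expect_lt(abs(spearman_test(tab_i$auroc2, tab_i$aq_score)$rho), 0.3)
})
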