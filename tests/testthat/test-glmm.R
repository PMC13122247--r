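test_that("factor coding enumerates the four design cells correctly", {
  d <- expand.grid(gaze_validity = c("valid", "invalid"),
                   body_head_congruency = c("congruent", "incongruent"),
                   stringsAsFactors = FALSE)
  d$subject_id <- "S1"; d$task <- "implicit"; d$trial_index <- 1:4
  d$object_present <- TRUE; d$correct <- 1L; d$confidence <- 50L
  mf <- make_model_frame(d)
  expect_equal(mf$gaze_valid, as.integer(d$gaze_validity == "valid"))
  expect_equal(mf$congruent,
               as.integer(d$body_head_congruency == "congruent"))
  # interaction column is 1 only in the valid-congruent cell
  expect_equal(mf$gv_x_cong, as.integer(d$gaze_validity == "valid" &
                                          d$body_head_congruency == "congruent"))
})

test_that("covariate standardization centers and scales, rejecting constants", {
  z <- zscore(c(2, 7, 13, 27))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_error(zscore(rep(16, 4), "aq_score"), "aq_score.*zero variance")
})

test_that("zero-variance mixed fits equal their fixed-effects counterparts", {
  sim <- simulate_experiment(flat_config(8L), seed = 21)
  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])
  d <- make_model_frame(imp)

  pinned <- fit_implicit_accuracy(imp, random = "none")
  pooled <- glm(correct ~ gaze_valid + congruent + gv_x_cong,
                binomial, d)
  expect_lt(max(abs((pinned$coefficients$estimate - coef(pooled)) /
                      coef(pooled))), 1e-6)

  pl <- fit_confidence_lmm(imp, sim$subjects, random = "none")
  ds <- make_model_frame(imp, sim$subjects)
  ds$conf <- zscore(as.numeric(ds$confidence))
  ols <- lm(conf ~ correct + aq_z + correct:aq_z, ds)
  expect_lt(max(abs((pl$coefficients$estimate - coef(ols)) /
                      coef(ols))), 1e-6)
})

test_that("single-seed fixed-effect recovery lands within 2 reported SEs", {
  cfg <- generator_config()
  subj <- sample_subjects(cfg, seed = 101)
  imp <- filter_present_trials(simulate_task(cfg, subj, "implicit", 101))
  fit <- fit_implicit_accuracy(imp, random = "intercept")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(est[["gaze_valid"]] - 0.96), 2 * 0.15)
  expect_lt(abs(est[["congruent"]] - 0.99), 2 * 0.16)
  expect_lt(abs(est[["gv_x_cong"]] - (-1.04)), 2 * 0.23)
  expect_true(fit$converged)
})

test_that("confidence LMM recovers the generator's type-2 coupling", {
  cfg <- generator_config()
  sim <- simulate_experiment(cfg, seed = 55)
  expl <- sim$trials[sim$trials$task == "explicit", ]
  fit <- fit_confidence_lmm(expl, sim$subjects)
  ct <- fit$coefficients
  acc <- ct[ct$term == "correct", ]
  # the 11-point grid spans 20 rating points per latent unit, so on the
  # z-scored response the estimand is 20 * s0 / sd(confidence)
  target <- 20 * 1.17 / sd(as.numeric(expl$confidence))
  expect_gt(acc$estimate, 0)
  expect_lt(abs(acc$estimate - target), 2 * acc$se)
  # AQ weakens the coupling in the explicit task
  int <- ct[ct$term == "correct:aq_z", ]
  expect_lt(int$estimate, 0)

  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])
  fit_i <- fit_confidence_lmm(imp, sim$subjects)
  int_i <- fit_i$coefficients[fit_i$coefficients$term == "correct:aq_z", ]
  # implicit coupling is AQ-independent by construction
  expect_lt(abs(int_i$estimate), 2 * int_i$se + 0.05)
})

test_that("per-subject coefficients combine fixed effects and modes", {
  sim <- simulate_experiment(flat_config(6L), seed = 33)
  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])

  fit0 <- fit_implicit_accuracy(imp, random = "none")
  eff0 <- extract_subject_effects(fit0, "gv_x_cong")
  fixed0 <- fit0$coefficients$estimate[fit0$coefficients$term == "gv_x_cong"]
  expect_equal(eff0$effect, rep(fixed0, 6))  # zero variance: all equal fixed

  fit <- fit_implicit_accuracy(imp, random = "diagonal")
  eff <- extract_subject_effects(fit, "gv_x_cong")
  fixed <- fit$coefficients$estimate[fit$coefficients$term == "gv_x_cong"]
  expect_lt(abs(mean(eff$effect) - fixed), 0.05)  # modes average to ~0

  fit_int <- fit_implicit_accuracy(imp, random = "intercept")
  expect_error(extract_subject_effects(fit_int, "gv_x_cong"),
               "no random slope")
  expect_error(extract_subject_effects(fit, "not_a_term"), "not a fixed")
})

test_that("subjects with stronger simulated effects rank higher", {
  # many trials per cell so the conditional modes track the truth
  cfg <- generator_config(
    n_subjects = 16L, trials_per_implicit_cell = 60L,
    random_slope_sd = list(
      implicit = c(gaze_validity = 0.6, congruency = 0.3, interaction = 0.6),
      explicit = c(congruency = 0.2)))
  subj <- sample_subjects(cfg, seed = 77)
  imp <- filter_present_trials(simulate_task(cfg, subj, "implicit", 77))
  fit <- fit_implicit_accuracy(imp, random = "diagonal")
  eff <- extract_subject_effects(fit, "gaze_valid")
  truth <- 0.96 + subj$u_imp_gv[match(eff$subject_id, subj$subject_id)]
  expect_gt(spearman_test(eff$effect, truth)$rho, 0.5)
})

test_that("paired coefficient comparison matches the textbook formula", {
  a <- data.frame(subject_id = paste0("S", 1:5),
                  effect = c(0.5, 0.2, -0.1, 0.4, 0.3))
  b <- data.frame(subject_id = paste0("S", 1:5),
                  effect = c(0.1, 0.0, -0.2, 0.2, 0.1))
  res <- compare_subject_effects(a, b)
  # hand computation: d = (.4,.2,.1,.2,.2), mean .22, sd .1095445,
  # t = .22 / (.1095445/sqrt(5)) = 4.490731
  expect_equal(res$t, 4.490731, tolerance = 1e-6)
  expect_equal(res$df, 4L)
  expect_equal(res$p, 2 * pt(-4.490731, 4), tolerance = 1e-6)
  # independent route through stats::t.test
  tt <- t.test(a$effect, b$effect, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)

  expect_equal(compare_subject_effects(a, a)$t, 0)
  shifted <- a; shifted$effect <- a$effect + 1
  expect_error(compare_subject_effects(shifted, a), "zero variance")
  expect_error(compare_subject_effects(a, b[1:4, ]), "subject sets differ")
})

test_that("two-stage transfer recovers null and induced coupling", {
  # default generator: tasks share no trait, transfer coefficient ~ 0
  sim <- simulate_experiment(generator_config(), seed = 13)
  imp <- filter_present_trials(sim$trials[sim$trials$task == "implicit", ])
  expl <- sim$trials[sim$trials$task == "explicit", ]
  fi <- fit_implicit_accuracy(imp, random = "diagonal")
  tr <- fit_transfer(fi, expl)
  b <- tr$coefficients[tr$coefficients$term == "implicit_accuracy", ]
  expect_lt(abs(b$estimate), 3 * b$se)

  # induced coupling: positive, clearly nonzero coefficient
  cfg <- generator_config(transfer_coupling = 0.4)
  sim2 <- simulate_experiment(cfg, seed = 7)
  imp2 <- filter_present_trials(sim2$trials[sim2$trials$task == "implicit", ])
  expl2 <- sim2$trials[sim2$trials$task == "explicit", ]
  fi2 <- fit_implicit_accuracy(imp2, random = "diagonal")
  tr2 <- fit_transfer(fi2, expl2)
  b2 <- tr2$coefficients[tr2$coefficients$term == "implicit_accuracy", ]
  expect_gt(b2$estimate, 0)
  expect_lt(b2$p, 0.05)

  # misaligned subject ids abort before fitting
  eff <- extract_subject_effects(fi, "gv_x_cong")
  v <- setNames(eff$effect, eff$subject_id)
  names(v)[1] <- "GHOST"
  expect_error(fit_explicit_accuracy(expl, implicit_effect = v),
               "missing subject")
})

test_that("fixed effects agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  for (seed in 1:5) {
    cfg <- small_config(24L)
    subj <- sample_subjects(cfg, seed)
    imp <- filter_present_trials(simulate_task(cfg, subj, "implicit", seed))
    ours <- fit_implicit_accuracy(imp, random = "intercept")
    d <- make_model_frame(imp)
    alt <- glmmTMB::glmmTMB(
      correct ~ gaze_valid + congruent + gv_x_cong + (1 | subject_id),
      data = d, family = binomial())
    est_alt <- glmmTMB::fixef(alt)$cond
    expect_lt(max(abs(ours$coefficients$estimate - est_alt)), 0.05,
              label = sprintf("max |lme4 - glmmTMB| at seed %d", seed))
  }
})

test_that("separation triggers the diagnostic guard", {
  d <- tiny_trials()[rep(1:2, each = 6), ]
  d$trial_index <- 1:12
  d$subject_id <- rep(c("S1", "S2"), 6)
  d$gaze_validity <- "valid"; d$object_present <- TRUE
  d$task <- "implicit"
  d$body_head_congruency <- rep(c("congruent", "incongruent"), each = 6)
  d$correct <- as.integer(d$body_head_congruency == "congruent")
  expect_error(
    suppressWarnings(fit_implicit_accuracy(d, random = "none")),
    "separat")
})
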