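test_that("noise-free parameter recovery for generated encodings", {
  # forces generated under exact average encoding, gain 0.8,
  # distinct-velocity (evident-style) conditions
  prof_avg <- make_encoding_profiles(omega = 0.5, alpha = 0.8)
  fit <- fit_encoding_model(prof_avg, "weighted")
  expect_equal(fit$omega, 0.5, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.8, tolerance = 1e-6)
  expect_true(fit$converged)

  # pure right-hand encoding -> omega = 1
  prof_r <- make_encoding_profiles(omega = 1, alpha = 0.8)
  fit_r <- fit_encoding_model(prof_r, "weighted")
  expect_equal(fit_r$omega, 1, tolerance = 1e-6)

  # one-parameter models recover their gain exactly on their own encoding
  expect_equal(fit_encoding_model(prof_r, "right")$alpha, 0.8,
               tolerance = 1e-9)
  expect_equal(fit_encoding_model(prof_avg, "average")$alpha, 0.8,
               tolerance = 1e-9)
})

test_that("weighted model SSE is nested below the single-weight models", {
  set.seed(51)
  for (om in c(0.2, 0.6, 0.95)) {
    prof <- make_encoding_profiles(omega = om, alpha = 0.7, noise_sd = 0.4)
    sses <- vapply(c("right", "left", "average", "weighted"), function(m)
      fit_encoding_model(prof, m)$sse, numeric(1))
    expect_lte(sses[["weighted"]], min(sses[c("right", "left", "average")]))
  }
})

test_that("identical hand velocities collapse the models and trip the omega warning", {
  # matched-speed (ambiguous-style) conditions with v_left == v_right
  vel <- condition_velocity_templates(c("b_ss", "b_mm", "b_ff"),
                                      kinematics_config(right_lead_ms = 0))
  prof <- tibble::tibble(
    participant = 1L, condition = vel$condition,
    force = purrr::map(vel$v_right, ~ 0.8 * 13 * .x),
    v_left = vel$v_right, v_right = vel$v_right,
    padded = purrr::map(vel$v_right, ~ rep(FALSE, length(.x)))
  )
  sses <- vapply(c("right", "left", "average"), function(m)
    fit_encoding_model(prof, m)$sse, numeric(1))
  expect_true(all(abs(sses - sses[1]) < 1e-9))
  expect_warning(fitw <- fit_encoding_model(prof, "weighted"),
                 class = "curladapt_identifiability")
  expect_false(fitw$identifiable)
  expect_lt(abs(fitw$sse - sses[[1]]), 1e-12)
})

test_that("BIC follows the Gaussian least-squares formula", {
  # equal SSE, one extra parameter at n = 800 costs log(800)
  expect_equal(compute_bic(10, 800, 2) - compute_bic(10, 800, 1), log(800))
  # halving the SSE at fixed k drops BIC by n log 2
  expect_equal(compute_bic(5, 800, 1) - compute_bic(10, 800, 1),
               -800 * log(2))
  # k = 0 has no parameter penalty
  expect_equal(compute_bic(10, 100, 0), 100 * log(10 / 100))
  expect_error(compute_bic(0, 100, 1), class = "curladapt_degenerate_sse")
  expect_error(compute_bic(10, 2, 2), class = "curladapt_invalid_parameter")
})

test_that("the pooled reference gain averages parametric fits and supports override", {
  set.seed(61)
  prof <- make_encoding_profiles(omega = 0.5, alpha = 0.8, noise_sd = 0.2)
  fits <- fit_encoding_models(prof)
  expect_equal(reference_alpha(fits), mean(fits$alpha))

  ref <- nonparametric_reference(prof, fits = fits)
  expect_equal(ref$model, "nonparametric")
  expect_equal(ref$k, 0L)
  # reference SSE is at least the best parametric SSE (nested optimum)
  expect_gte(ref$sse, min(fits$sse))

  ref822 <- nonparametric_reference(prof, alpha = 0.822)
  expect_equal(ref822$alpha, 0.822)

  expect_error(reference_alpha(fits[0, ]), class = "curladapt_empty_fit")
})

test_that("generalization predictions follow the fitted encoding", {
  prof <- make_encoding_profiles(omega = 1, alpha = 0.8)
  fit_r <- fit_encoding_model(prof, "weighted")
  vel <- condition_velocity_templates()
  preds <- predict_generalization(fit_r, vel)
  expect_equal(nrow(preds), 12)

  # right-encoding fit predicts zero force on unimanual conditions
  uni <- preds[startsWith(preds$condition, "u_"), ]
  expect_true(all(abs(uni$peak_force_pred) < 1e-6))
  expect_true(all(is.na(uni$fc_pred)))

  # in-sample identity: trained-condition prediction equals the fitted force
  b_mm_pred <- preds$force[[which(preds$condition == "b_mm")]]
  expect_equal(b_mm_pred,
               prof$force[[which(prof$condition == "b_mm")]],
               tolerance = 1e-5)

  # bimanual predicted FC of a right-encoding fit is 100 * alpha
  bi <- preds[startsWith(preds$condition, "b_"), ]
  expect_equal(bi$fc_pred, rep(80, 9), tolerance = 1e-4)
})

test_that("prediction MSE compares overlapping untrained conditions", {
  obs <- tibble::tibble(condition = c("b_ss", "b_sm", "b_sf", "b_mm"),
                        fc = c(40, 55, 70, 60))
  pred <- tibble::tibble(condition = c("b_ss", "b_sm", "b_sf", "b_mm"),
                         fc_pred = c(42, 50, 70, 65))
  # spreadsheet oracle: mean of squared differences
  expect_equal(prediction_mse(pred, obs), mean(c(4, 25, 0, 25)))
  expect_equal(prediction_mse(pred, obs, exclude = "b_mm"),
               mean(c(4, 25, 0)))
  # identical predictions -> 0; constant offset d -> d^2
  expect_equal(prediction_mse(obs, obs), 0)
  off <- dplyr::mutate(obs, fc = fc + 3)
  expect_equal(prediction_mse(off, obs), 9)
  expect_error(prediction_mse(pred, obs, exclude = obs$condition),
               class = "curladapt_no_overlap")
})

test_that("weight trajectory tracks constant and drifting ground truth", {
  lrn <- learner_config(omega = 0.5, noise_sd = 0.05)
  dat <- simulate_experiment("evident", n_participants = 1, seed = 13,
                             learner = lrn, keep = "clamp")
  prof <- align_profiles(dat)
  traj <- fit_weight_trajectory(prof)
  expect_true(all(traj$fitted))
  expect_equal(nrow(traj), 20)
  # exposure: 2 clamps x 3 conditions x 2 blocks; generalization: 12 x 2
  expect_equal(traj$n_profiles, rep(c(12L, 24L), each = 10))
  expect_equal(mean(traj$omega), 0.5, tolerance = 0.05)
  expect_lt(stats::sd(traj$omega), 0.1)

  # ramping omega 0.5 -> 0.9 across exposure: rising, then high plateau
  lrn2 <- learner_config(omega = 0.9, omega_start = 0.5, noise_sd = 0.05)
  dat2 <- simulate_experiment("evident", n_participants = 1, seed = 14,
                              learner = lrn2, keep = "clamp")
  traj2 <- fit_weight_trajectory(align_profiles(dat2))
  n <- nrow(traj2)
  expect_gt(mean(traj2$omega[(n - 4):n]), mean(traj2$omega[1:5]))
  expect_equal(mean(traj2$omega[(n - 4):n]), 0.9, tolerance = 0.05)
})

test_that("tidy and glance summarise encoding fits broom-style", {
  prof <- make_encoding_profiles(omega = 0.5, alpha = 0.8, noise_sd = 0)
  fit <- fit_encoding_model(prof, "weighted")
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "omega"))
  expect_equal(td$estimate, c(0.8, 0.5), tolerance = 1e-5)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("model", "alpha", "omega", "sse", "bic", "r2") %in%
                    names(gl)))
  # noise-free fit: SSE at round-off level, so R^2 is essentially 1 and the
  # BIC (if the SSE is not exactly zero) is strongly negative
  expect_equal(gl$r2, 1, tolerance = 1e-9)
  expect_true(is.na(gl$bic) || gl$bic < 0)
})
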