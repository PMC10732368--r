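test_that("curl field maps right-hand velocity to left-hand force", {
  # stationary driving hand -> no force
  f0 <- apply_force_field(data.frame(vx = numeric(5), vy = numeric(5)))
  expect_true(all(f0$fx == 0) && all(f0$fy == 0))

  # forward movement pushes leftward: vy = 0.5 -> Fx = -6.5 N
  f1 <- apply_force_field(data.frame(vx = 0, vy = 0.5))
  expect_equal(f1$fx, -6.5)
  expect_equal(f1$fy, 0)

  # matrix multiply oracle for a general velocity
  f2 <- apply_force_field(data.frame(vx = 0.1, vy = 0.6))
  expect_equal(c(f2$fx, f2$fy), c(-7.8, 1.3))

  # linearity in the velocity
  v <- data.frame(vx = runif(10, -1, 1), vy = runif(10, -1, 1))
  f <- apply_force_field(v)
  f3 <- apply_force_field(3 * v)
  expect_equal(as.matrix(f3), 3 * as.matrix(f))
})

test_that("learner gain follows the single-rate recursion", {
  mk_state <- function(...) {
    c(list(alpha = 0, omega = 1, noise_sd = 0, clamp_update = FALSE),
      list(...))
  }
  vl <- rep(0.5, 10)
  vr <- rep(0.4, 10)

  # no learning: rate 0, alpha stays 0 and commanded force is identically 0
  st <- mk_state(retention = 1, rate = 0)
  for (i in 1:5) {
    out <- simulate_learner_trial(st, vl, vr, "force_field")
    st <- out$state
    expect_equal(out$commanded, numeric(10))
  }
  expect_equal(st$alpha, 0)

  # perfect retention: closed form alpha_t = 1 - (1 - b)^t
  b <- 0.1
  st <- mk_state(retention = 1, rate = b)
  alphas <- numeric(20)
  for (t in 1:20) {
    st <- simulate_learner_trial(st, vl, vr, "force_field")$state
    alphas[t] <- st$alpha
  }
  expect_equal(alphas, 1 - (1 - b)^(1:20), tolerance = 1e-12)
  expect_true(all(diff(alphas) > 0))

  # clamp trials hold the gain
  st2 <- simulate_learner_trial(st, vl, vr, "clamp")$state
  expect_equal(st2$alpha, st$alpha)

  # pure right-hand encoding commands nothing when the right hand is still
  st3 <- mk_state(retention = 1, rate = 0)
  st3$alpha <- 0.8
  out <- simulate_learner_trial(st3, vl, numeric(10), "clamp")
  expect_equal(out$commanded, numeric(10))
})

test_that("simulated experiment has the full schedule and is reproducible", {
  dat <- simulate_experiment("evident", n_participants = 1, seed = 5,
                             keep = "none")
  expect_equal(nrow(dat), 2208)
  expect_equal(unname(table(dat$phase)[c("baseline", "exposure",
                                         "generalization")]),
               c(288L, 960L, 960L), ignore_attr = TRUE)
  dat2 <- simulate_experiment("evident", n_participants = 1, seed = 5,
                              keep = "none")
  expect_identical(dat, dat2)

  # learner converges towards the configured asymptote b / (1 - a + b) = 0.8
  late <- dat$alpha[dat$phase == "generalization"]
  expect_equal(mean(late), 0.8, tolerance = 0.01)
})

test_that("matched condition with zero lead and no noise gives identical hands", {
  dat <- simulate_experiment(
    "ambiguous", n_participants = 1, seed = 2,
    learner = learner_config(noise_sd = 0),
    kinematics = kinematics_config(noise_cv = 0, right_lead_ms = 0),
    keep = "clamp"
  )
  clamp_mm <- dat[dat$condition == "b_mm" & dat$field_type == "clamp", ]
  s <- clamp_mm$series[[1]]
  expect_equal(s$vyl, s$vyr)
  # unimanual trials: right hand identically stationary
  uni <- dat[startsWith(dat$condition, "u_") & dat$field_type == "clamp", ]
  expect_true(all(purrr::map_lgl(uni$series, ~ all(.x$vyr == 0))))
})

test_that("clamp-trial force compensation converges to the learner asymptote", {
  lrn <- learner_config(retention = 0.99, rate = 0.04, noise_sd = 0.1)
  dat <- simulate_experiment("evident", n_participants = 1, seed = 9,
                             learner = lrn, keep = "clamp")
  prof <- align_profiles(dat)
  fc <- fc_table(prof)
  late <- fc$fc[fc$phase == "generalization"]
  a_inf <- lrn$rate / (1 - lrn$retention + lrn$rate)
  expect_equal(mean(late), 100 * a_inf, tolerance = 3)
})

test_that("the lateral plant produces leftward error that shrinks with adaptation", {
  dat <- simulate_experiment(
    "evident", n_participants = 1, seed = 4,
    kinematics = kinematics_config(plant = TRUE),
    keep = "all"
  )
  mpe <- mpe_table(dat)
  ff <- dplyr::arrange(mpe[mpe$field_type == "force_field" &
                             mpe$phase == "exposure", ], trial)
  # adaptation is fast (near-asymptotic within the first block), so "early"
  # means the first few perturbed trials
  early <- head(ff$mpe_cm, 6)
  late <- tail(ff$mpe_cm, 60)
  expect_gt(mean(early), 0) # curl field pushes leftward
  expect_lt(mean(late), mean(early) / 2)
})
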