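test_that("zero-phase Butterworth filter has unit DC gain and no lag", {
  # constant series passes through unchanged
  x <- rep(2.5, 600)
  expect_equal(lowpass_filter(x), x, tolerance = 1e-9)

  # a 2 Hz sinusoid keeps its peak time (zero lag) and amplitude;
  # restrict to one cycle so there is a unique maximum
  t <- seq(0, 1.999, by = 1e-3)
  s <- sin(2 * pi * 2 * t)
  y <- lowpass_filter(s)
  expect_equal(which.max(y[1:500]), which.max(s[1:500]), tolerance = 2)
  expect_equal(max(y[100:1900]), 1, tolerance = 1e-3)

  # a 100 Hz sinusoid (2.5x cutoff) is attenuated below 1%:
  # squared 5th-order Butterworth magnitude 1/(1 + 2.5^10) ~ 1e-4
  h <- sin(2 * pi * 100 * t)
  yh <- lowpass_filter(h)
  expect_lt(max(abs(yh[100:1900])), 0.01)

  expect_error(lowpass_filter(rep(1, 10)),
               class = "curladapt_series_too_short")
})

test_that("drift correction subtracts the pre-onset window mean and is idempotent", {
  n <- 1000
  onset <- 300
  expect_equal(remove_force_drift(numeric(n), onset), numeric(n))
  expect_equal(remove_force_drift(rep(4, n), onset), numeric(n))

  # linear drift f = k t: window mean is k * (onset - 175 ms)
  k <- 0.01
  f <- k * (0:(n - 1))
  corrected <- remove_force_drift(f, onset)
  expect_equal(corrected, f - k * (onset - 175))

  # idempotent
  expect_equal(remove_force_drift(corrected, onset), corrected)

  expect_error(remove_force_drift(numeric(n), 100),
               class = "curladapt_insufficient_baseline")
})

test_that("movement onset is the first 5%-of-peak crossing", {
  # noise-free minimum-jerk reach embedded at 300 ms: compare with the
  # analytic root of 16 tau^2 (1-tau)^2 = threshold
  prof <- generate_velocity_profile("fast", noise_cv = 0)
  T_s <- attr(prof, "duration")
  v <- c(numeric(300), prof$v)
  onset <- detect_movement_onset(v)
  tau_star <- uniroot(function(tau) 16 * tau^2 * (1 - tau)^2 - 0.05,
                      c(1e-6, 0.5), tol = 1e-12)$root
  expect_equal(onset, 300 + tau_star * T_s * 1000, tolerance = 1.5)

  # step-to-constant speed: first non-zero sample
  expect_equal(detect_movement_onset(c(numeric(10), rep(1, 10))), 10)

  expect_error(detect_movement_onset(numeric(100)),
               class = "curladapt_no_movement")
})

test_that("alignment centres an 801-sample window on the reference peak", {
  n <- 1200
  vyr <- numeric(n)
  vyr[601] <- 1 # right-hand peak at 600 ms
  vyl <- numeric(n); vyl[550:700] <- 0.5
  s <- make_trial_series(vyl, vyr, fxl = seq_len(n) * 0.01)
  al <- align_to_peak_velocity(s)
  expect_equal(al$ref_hand, "right")
  expect_equal(al$centre_ms, 600)
  expect_length(al$force, 801)
  expect_equal(al$force, s$fxl[201:1001]) # window spans 200..1000 ms
  expect_false(any(al$padded))

  # plateau: earliest maximal sample wins
  vyr2 <- numeric(n); vyr2[500:520] <- 1
  s2 <- make_trial_series(vyl, vyr2)
  expect_equal(align_to_peak_velocity(s2)$centre_ms, 499)

  # unimanual trial aligns to the left hand; right-hand reference errors
  s3 <- make_trial_series(vyl)
  expect_equal(align_to_peak_velocity(s3)$ref_hand, "left")
  expect_error(align_to_peak_velocity(s3, reference_hand = "right"),
               class = "curladapt_invalid_reference")

  # out-of-range window samples are padded with boundary values and flagged
  vyr3 <- numeric(n); vyr3[200] <- 1
  s4 <- make_trial_series(vyl, vyr3, fxl = rep(2, n))
  al4 <- align_to_peak_velocity(s4)
  expect_true(any(al4$padded))
  expect_equal(al4$force, rep(2, 801))
})

test_that("peak force averages a 20 ms window around the centre", {
  expect_equal(peak_force(rep(3, 801)), 3)
  expect_equal(peak_force(numeric(801)), 0)

  # symmetric triangle, apex A at centre, half-width 100 ms:
  # oracle = direct mean over the 21 centre samples
  A <- 5
  lag <- -400:400
  tri <- pmax(0, A * (1 - abs(lag) / 100))
  expect_equal(peak_force(tri), mean(tri[abs(lag) <= 10]))
  expect_equal(peak_force(tri), 0.95 * A, tolerance = 0.01)
})

test_that("filtering and aligning commute for in-range windows", {
  set.seed(21)
  n <- 1400
  vyr <- numeric(n); vyr[701] <- 1
  f <- as.numeric(stats::filter(rnorm(n), rep(1 / 30, 30), sides = 2))
  f[is.na(f)] <- 0
  s <- make_trial_series(numeric(n) + 0.1, vyr, fxl = f)

  filter_then_align <- {
    s2 <- s; s2$fxl <- lowpass_filter(s2$fxl)
    align_to_peak_velocity(s2)$force
  }
  align_then_filter <- lowpass_filter(align_to_peak_velocity(s)$force)
  # identical away from the window edges (shift-invariant linear operation;
  # edge-padding transients decay towards the window interior)
  expect_equal(filter_then_align[301:501], align_then_filter[301:501],
               tolerance = 1e-6)
})

test_that("align_profiles conditions and aligns clamp trials from a dataset", {
  dat <- simulate_experiment("evident", n_participants = 1, seed = 8,
                             keep = "clamp")
  prof <- align_profiles(dat)
  expect_true(all(prof$field_type == "clamp"))
  expect_true(all(lengths(prof$force) == 801))
  expect_setequal(unique(prof$ref_hand[startsWith(prof$condition, "u_")]),
                  "left")
  expect_setequal(unique(prof$ref_hand[startsWith(prof$condition, "b_")]),
                  "right")

  avg <- average_profiles(prof[prof$phase == "generalization", ])
  expect_equal(nrow(avg), 12)
  expect_true(all(avg$n_trials == 20))
})
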