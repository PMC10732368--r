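#' Curl-field force from the driving hand's velocity
#'
#' The perturbation applied to the left hand is a velocity-dependent,
#' counter-clockwise curl field driven by the *right* hand:
#' `F = [[0, -B], [B, 0]] %*% (vx, vy)`, so a forward right-hand movement
#' (`vy > 0`) pushes the left hand leftward (`Fx < 0`).
#'
#' @param velocity Data frame (or 2-column matrix) of right-hand velocity
#'   with columns `vx`, `vy` in m/s.
#' @param B Curl gain, N.s/m (default 13, i.e. 0.13 N per cm/s).
#' @return A tibble with columns `fx`, `fy` (N), one row per sample.
#' @export
#' @examples
#' apply_force_field(data.frame(vx = 0, vy = 0.5)) # fx = -6.5 N
apply_force_field <- function(velocity, B = DEFAULT_B) {
  v <- as.data.frame(velocity)
  if (is.null(colnames(v)) || !all(c("vx", "vy") %in% colnames(v))) {
    colnames(v) <- c("vx", "vy")[seq_len(ncol(v))]
  }
  if (!all(is.finite(v$vx)) || !all(is.finite(v$vy))) {
    abort("velocity series must be finite", class = "curladapt_invalid_parameter")
  }
  tibble::tibble(fx = -B * v$vy, fy = B * v$vx)
}

#' Learner configuration
#'
#' Parameters of the simulated adaptive learner. The compensation gain
#' `alpha` follows a single-rate update on every force-field trial,
#' `alpha' = retention * alpha + rate * (1 - alpha)`, approaching the
#' asymptote `rate / (1 - retention + rate)` (0.8 at the defaults). The
#' learner's predictive lateral force is
#' `alpha * B * (omega * v_right + (1 - omega) * v_left)` plus execution
#' noise, where `omega` is the ground-truth encoding weight (1 = pure
#' right-hand encoding, 0 = pure left-hand).
#'
#' @param alpha0 Initial compensation gain (default 0: naive).
#' @param omega Ground-truth encoding weight; `NULL` lets
#'   [simulate_experiment()] pick the group default (0.9 evident,
#'   0.4 ambiguous).
#' @param retention Retention factor `a` in (0, 1].
#' @param rate Error-driven learning rate `b >= 0`.
#' @param noise_sd Execution noise on commanded force, N per sample.
#' @param clamp_update Update `alpha` on clamp trials too (default `FALSE`:
#'   the channel clamps the error to ~0, so no update).
#' @param omega_start If non-`NULL`, `omega` ramps linearly from
#'   `omega_start` to `omega` across the exposure phase and stays at `omega`
#'   afterwards (mimicking a drifting encoding weight).
#' @return A list of class `learner_config`.
#' @export
learner_config <- function(alpha0 = 0, omega = NULL, retention = 0.99,
                           rate = 0.04, noise_sd = 0.3,
                           clamp_update = FALSE, omega_start = NULL) {
  if (retention <= 0 || retention > 1 || rate < 0 || noise_sd < 0) {
    abort("need 0 < retention <= 1, rate >= 0, noise_sd >= 0",
          class = "curladapt_invalid_parameter")
  }
  structure(
    list(alpha0 = alpha0, omega = omega, retention = retention, rate = rate,
         noise_sd = noise_sd, clamp_update = clamp_update,
         omega_start = omega_start),
    class = "learner_config"
  )
}

#' Kinematics configuration
#'
#' Trial-level kinematic settings of the simulator: peak-speed variability,
#' the small temporal lead of the right (dominant) hand, the pre-movement
#' rest and total recording length, and the optional lateral point-mass
#' plant used to produce kinematic errors on force-field trials.
#'
#' @param noise_cv Coefficient of variation of peak speed per hand per trial
#'   (default 0.05, which keeps ~95% of reaches inside the +/-10%
#'   compliance band).
#' @param right_lead_ms Temporal lead of the right hand in bimanual trials,
#'   ms (default 20).
#' @param pre_ms Rest period before left-hand movement onset, ms.
#' @param total_ms Total recording length per trial, ms.
#' @param plant Simulate lateral trajectory deviations on force-field trials
#'   with a viscous point-mass plant (needed for perpendicular-error
#'   analyses; default `FALSE`).
#' @param plant_mass Effective lateral mass, kg.
#' @param plant_damping Viscous damping, N.s/m.
#' @return A list of class `kinematics_config`.
#' @export
kinematics_config <- function(noise_cv = 0.05, right_lead_ms = 20,
                              pre_ms = 300, total_ms = 1400,
                              plant = FALSE, plant_mass = 1.5,
                              plant_damping = 50) {
  if (noise_cv < 0 || right_lead_ms < 0 || pre_ms < 200 || total_ms <= pre_ms) {
    abort("invalid kinematics configuration (need noise_cv >= 0, lead >= 0, pre_ms >= 200, total_ms > pre_ms)",
          class = "curladapt_invalid_parameter")
  }
  structure(
    list(noise_cv = noise_cv, right_lead_ms = right_lead_ms, pre_ms = pre_ms,
         total_ms = total_ms, plant = plant, plant_mass = plant_mass,
         plant_damping = plant_damping),
    class = "kinematics_config"
  )
}

# Embed a movement speed profile into the trial grid starting at onset_ms.
embed_profile <- function(v, onset_ms, n) {
  out <- numeric(n)
  i0 <- onset_ms + 1L
  len <- min(length(v), n - i0 + 1L)
  if (len > 0) out[i0:(i0 + len - 1L)] <- v[seq_len(len)]
  out
}

#' Simulate one trial of the adaptive learner
#'
#' Given the learner's current state and the trial's forward-speed series
#' for both hands, computes the commanded (predictive) lateral force,
#' the measured lateral force, and the updated state. On force-field trials
#' the gain updates by the single-rate rule; on clamp trials the channel
#' clamps the error so the gain is held (unless `clamp_update` is set) and
#' the measured force equals the commanded force pressed into the channel
#' wall. On null and force-field trials the measured handle force mirrors
#' the robot-applied field (zero in the null field).
#'
#' @param state A list with at least `alpha` and `omega` plus the
#'   [learner_config()] fields `retention`, `rate`, `noise_sd`,
#'   `clamp_update`.
#' @param v_left,v_right Forward-speed series of the two hands, m/s, on a
#'   common 1 kHz grid (`v_right` all zero for unimanual trials).
#' @param field_type `"null"`, `"force_field"` or `"clamp"`.
#' @param B Curl gain, N.s/m.
#' @return A list with `commanded` (N), `measured` (N, lateral), and
#'   `state` (updated).
#' @export
simulate_learner_trial <- function(state, v_left, v_right, field_type, B = DEFAULT_B) {
  n <- length(v_left)
  stopifnot(length(v_right) == n)
  noise <- if (state$noise_sd > 0) rnorm(n, 0, state$noise_sd) else numeric(n)
  commanded <- state$alpha * B *
    (state$omega * v_right + (1 - state$omega) * v_left) + noise
  measured <- switch(field_type,
    clamp = commanded,
    force_field = -B * v_right,
    null = numeric(n),
    abort(paste0("unknown field_type '", field_type, "'"),
          class = "curladapt_invalid_parameter")
  )
  update <- field_type == "force_field" ||
    (field_type == "clamp" && isTRUE(state$clamp_update))
  if (update) {
    state$alpha <- state$retention * state$alpha + state$rate * (1 - state$alpha)
  }
  list(commanded = commanded, measured = measured, state = state)
}

# Lateral point-mass plant: m x'' = F - c x', integrated at 1 kHz with a
# first-order recursion (stats::filter, method = "recursive").
plant_lateral <- function(force, mass, damping, dt = DT) {
  a <- 1 - damping * dt / mass
  vx <- as.numeric(stats::filter(force * dt / mass, a, method = "recursive"))
  x <- cumsum(vx) * dt
  list(x = x, vx = vx)
}

simulate_participant <- function(schedule, group, participant, learner,
                                 kinematics, keep, B) {
  n <- kinematics$total_ms + 1L
  grid <- condition_grid()
  cond_info <- setNames(
    split(grid, seq_len(nrow(grid))),
    grid$label
  )
  n_expo <- sum(schedule$phase == "exposure")
  state <- list(alpha = learner$alpha0, omega = learner$omega,
                retention = learner$retention, rate = learner$rate,
                noise_sd = learner$noise_sd,
                clamp_update = learner$clamp_update)

  n_trials <- nrow(schedule)
  phase_v <- schedule$phase
  cond_v <- schedule$condition
  field_v <- schedule$field_type
  series_l <- vector("list", n_trials)
  alpha_v <- numeric(n_trials)
  omega_v <- numeric(n_trials)
  expo_seen <- 0L
  for (i in seq_len(n_trials)) {
    info <- cond_info[[cond_v[i]]]
    if (is.null(info)) {
      abort(paste0("unknown condition '", cond_v[i], "'"),
            class = "curladapt_invalid_parameter")
    }
    if (phase_v[i] == "exposure") expo_seen <- expo_seen + 1L
    if (!is.null(learner$omega_start)) {
      frac <- if (phase_v[i] == "baseline") 0 else
        if (phase_v[i] == "exposure") expo_seen / n_expo else 1
      state$omega <- learner$omega_start +
        frac * (learner$omega - learner$omega_start)
    }

    keep_series <- keep == "all" || (keep == "clamp" && field_v[i] == "clamp")
    if (keep_series) {
      prof_l <- generate_velocity_profile(info$left_class,
                                          noise_cv = kinematics$noise_cv)
      vyl <- embed_profile(prof_l$v, kinematics$pre_ms, n)
      if (info$bimanual) {
        prof_r <- generate_velocity_profile(info$right_class,
                                            noise_cv = kinematics$noise_cv)
        onset_r <- max(kinematics$pre_ms - kinematics$right_lead_ms, 0L)
        vyr <- embed_profile(prof_r$v, onset_r, n)
      } else {
        vyr <- numeric(n)
      }
      sim <- simulate_learner_trial(state, vyl, vyr, field_v[i], B)
      state <- sim$state

      vxl <- numeric(n)
      xl <- numeric(n)
      if (kinematics$plant && field_v[i] == "force_field") {
        net <- -B * vyr + sim$commanded
        pl <- plant_lateral(net, kinematics$plant_mass, kinematics$plant_damping)
        vxl <- pl$vx
        xl <- pl$x
      }
      series_l[[i]] <- tibble::tibble(
        t_ms = 0:(n - 1L),
        xl = xl, yl = cumsum(vyl) * DT, vxl = vxl, vyl = vyl,
        fxl = sim$measured, fyl = 0,
        xr = 0, yr = cumsum(vyr) * DT, vxr = 0, vyr = vyr
      )
    } else {
      # learner state still advances on force-field trials
      if (field_v[i] == "force_field") {
        state$alpha <- state$retention * state$alpha +
          state$rate * (1 - state$alpha)
      }
    }
    alpha_v[i] <- state$alpha
    omega_v[i] <- state$omega
  }
  tibble::tibble(
    participant = participant, group = group,
    trial = schedule$trial, phase = phase_v, block = schedule$block,
    condition = cond_v, field_type = field_v,
    alpha = alpha_v, omega_true = omega_v,
    series = series_l
  )
}

#' Simulate a full synthetic experiment
#'
#' Simulates `n_participants` synthetic participants of one training group
#' through the complete 2208-trial schedule: per-trial minimum-jerk reach
#' kinematics with peak-speed noise and a right-hand temporal lead, the
#' coupled curl-field / channel dynamics, and a single-rate adaptive learner
#' with a ground-truth encoding weight. Each participant gets an independent
#' sub-seed derived from `seed`, and an independently shuffled schedule.
#'
#' Time-series are materialized only for the trials selected by `keep`
#' (`"clamp"` keeps channel trials — all that the encoding analysis needs —
#' `"all"` keeps every trial, e.g. for perpendicular-error analyses with the
#' plant enabled, `"none"` keeps only the trial ledger and learner state).
#'
#' @param group `"evident"` or `"ambiguous"`.
#' @param n_participants Number of synthetic participants (>= 1).
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   dataset exactly.
#' @param learner A [learner_config()].
#' @param kinematics A [kinematics_config()].
#' @param keep Which trials to keep time-series for (see above).
#' @param B Curl gain, N.s/m.
#' @return A tibble with one row per trial: `participant`, `group`, `trial`,
#'   `phase`, `block`, `condition`, `field_type`, `alpha` (learner gain
#'   after the trial), `omega_true`, and a `series` list-column of per-trial
#'   1 kHz tibbles (`t_ms`, `xl`, `yl`, `vxl`, `vyl`, `fxl`, `fyl`, `xr`,
#'   `yr`, `vxr`, `vyr`; `NULL` where not kept).
#' @export
#' @examples
#' \donttest{
#' dat <- simulate_experiment("evident", n_participants = 1, seed = 1)
#' nrow(dat) # 2208
#' }
simulate_experiment <- function(group = c("evident", "ambiguous"),
                                n_participants = 1, seed = 1L,
                                learner = learner_config(),
                                kinematics = kinematics_config(),
                                keep = c("clamp", "all", "none"),
                                B = DEFAULT_B) {
  gd <- group_design(group)
  keep <- match.arg(keep)
  if (!is.numeric(n_participants) || n_participants < 1) {
    abort("`n_participants` must be >= 1", class = "curladapt_invalid_parameter")
  }
  if (is.null(learner$omega)) {
    learner$omega <- if (gd$group == "evident") 0.9 else 0.4
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)

  out <- purrr::map(seq_len(n_participants), function(p) {
    pseed <- (as.integer(seed) * 1009L + p) %% .Machine$integer.max
    sched <- build_schedule(gd, seed = pseed)
    set.seed(pseed)
    simulate_participant(sched, gd$group, p, learner, kinematics, keep, B)
  })
  purrr::list_rbind(out)
}

#' Noise-free aligned velocity templates per condition
#'
#' Builds the deterministic (noise-free, default-lead) forward-speed series
#' of both hands for each requested condition, aligned on the reference
#' hand's peak speed exactly as measured profiles are (801-sample window,
#' -400 to +400 ms). Used to generate model predictions for conditions and
#' for analytic transfer calculations.
#'
#' @param conditions Character vector of condition labels (default: all 12).
#' @param kinematics A [kinematics_config()]; its `noise_cv` is ignored
#'   (profiles are noise-free).
#' @param half_window_ms Half-width of the alignment window, ms.
#' @return A tibble with columns `condition` and list-columns `v_left`,
#'   `v_right` (m/s, length `2 * half_window_ms + 1`).
#' @export
condition_velocity_templates <- function(conditions = condition_grid()$label,
                                         kinematics = kinematics_config(),
                                         half_window_ms = 400) {
  grid <- condition_grid()
  n <- kinematics$total_ms + 1L
  purrr::map(conditions, function(lab) {
    info <- grid[grid$label == lab, ]
    if (nrow(info) != 1L) {
      abort(paste0("unknown condition '", lab, "'"),
            class = "curladapt_invalid_parameter")
    }
    vyl <- embed_profile(generate_velocity_profile(info$left_class, 0)$v,
                         kinematics$pre_ms, n)
    if (info$bimanual) {
      onset_r <- max(kinematics$pre_ms - kinematics$right_lead_ms, 0L)
      vyr <- embed_profile(generate_velocity_profile(info$right_class, 0)$v,
                           onset_r, n)
      centre <- which.max(vyr)
    } else {
      vyr <- numeric(n)
      centre <- which.max(vyl)
    }
    wl <- align_window(vyl, centre, half_window_ms)
    wr <- align_window(vyr, centre, half_window_ms)
    tibble::tibble(condition = lab, v_left = list(wl$values),
                   v_right = list(wr$values))
  }) |> purrr::list_rbind()
}
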