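# Synthetic aligned-profile tables built directly from the deterministic
# condition velocity templates, with forces generated under a known encoding.
# Shaped like align_profiles()/average_profiles() output.
make_encoding_profiles <- function(omega, alpha,
                                   conditions = c("b_sf", "b_mm", "b_fs"),
                                   noise_sd = 0, participant = 1L, B = 13) {
  vel <- condition_velocity_templates(conditions)
  force <- purrr::map2(vel$v_left, vel$v_right, function(vl, vr) {
    f <- alpha * B * (omega * vr + (1 - omega) * vl)
    if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
    f
  })
  tibble::tibble(
    participant = participant,
    condition = vel$condition,
    force = force,
    v_left = vel$v_left,
    v_right = vel$v_right,
    padded = purrr::map(vel$v_left, ~ rep(FALSE, length(.x)))
  )
}

# Brute-force grid search over (alpha, omega) for the weighted model,
# evaluated through the exact quadratic expansion of the SSE.
grid_search_weighted <- function(f, vl, vr, B = 13,
                                 alphas = seq(0, 2, by = 0.001),
                                 omegas = seq(-0.5, 1.5, by = 0.001)) {
  Suu <- sum(vr^2) * B^2
  Sww <- sum(vl^2) * B^2
  Suw <- sum(vr * vl) * B^2
  SFu <- sum(f * vr) * B
  SFw <- sum(f * vl) * B
  FF <- sum(f^2)
  SFm <- omegas * SFu + (1 - omegas) * SFw
  Smm <- omegas^2 * Suu + 2 * omegas * (1 - omegas) * Suw + (1 - omegas)^2 * Sww
  sse <- outer(alphas^2, Smm) - 2 * outer(alphas, SFm) + FF
  idx <- arrayInd(which.min(sse), dim(sse))
  list(alpha = alphas[idx[1]], omega = omegas[idx[2]], sse = min(sse))
}

# A minimal single-trial series tibble on the simulator grid.
make_trial_series <- function(vyl, vyr = NULL, fxl = NULL, t_ms = NULL) {
  n <- length(vyl)
  if (is.null(vyr)) vyr <- numeric(n)
  if (is.null(fxl)) fxl <- numeric(n)
  if (is.null(t_ms)) t_ms <- seq_len(n) - 1L
  tibble::tibble(
    t_ms = t_ms, xl = 0, yl = cumsum(vyl) * 1e-3, vxl = 0, vyl = vyl,
    fxl = fxl, fyl = 0, xr = 0, yr = cumsum(vyr) * 1e-3, vxr = 0, vyr = vyr
  )
}
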