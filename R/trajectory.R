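#' Minimum-jerk speed profile
#'
#' Tangential speed of a minimum-jerk point-to-point reach of length
#' `distance` and duration `duration`:
#' `v(t) = 30 d/T tau^2 (1 - tau)^2` with `tau = t/T`, peaking at
#' `1.875 d/T` at mid-movement. Zero outside `[0, T]`.
#'
#' @param t Time, seconds (vector).
#' @param distance Reach length, metres.
#' @param duration Movement duration, seconds.
#' @return Speed in m/s at each `t`.
#' @export
min_jerk_speed <- function(t, distance, duration) {
  if (!is.numeric(distance) || distance <= 0 ||
      !is.numeric(duration) || duration <= 0) {
    abort("`distance` and `duration` must be positive",
          class = "curladapt_invalid_parameter")
  }
  tau <- t / duration
  v <- 30 * distance / duration * tau^2 * (1 - tau)^2
  v[tau < 0 | tau > 1] <- 0
  v
}

#' Generate a reach velocity profile for a speed class
#'
#' Produces a bell-shaped (minimum-jerk) forward-speed profile for one reach
#' of the given speed class. Peak speed, not duration, is the controlled
#' quantity: the movement duration is rescaled to `1.875 d / v_peak` so the
#' noise-free peak speed equals the class's desired peak while the time
#' integral of speed equals the reach distance. With noise, the realized
#' peak speed is the desired peak multiplied by a Gaussian draw centred on 1
#' with standard deviation `noise_cv` (duration rescales accordingly, so the
#' distance is preserved).
#'
#' @param speed_class `"slow"`, `"medium"` or `"fast"` (or a one-row tibble
#'   as returned by [speed_classes()]).
#' @param noise_cv Coefficient of variation of the peak-speed draw
#'   (fraction; 0 = deterministic).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param dt Sampling interval, seconds (default 1 kHz).
#' @return A tibble with columns `t_ms` (time since movement onset) and
#'   `v` (forward speed, m/s), plus attributes `peak_speed` (m/s),
#'   `duration` (s) and `distance` (m).
#' @export
#' @examples
#' prof <- generate_velocity_profile("fast", noise_cv = 0)
#' max(prof$v) # 0.75 m/s
generate_velocity_profile <- function(speed_class, noise_cv = 0, seed = NULL,
                                      dt = DT) {
  row <- if (is.character(speed_class)) speed_class_row(speed_class) else speed_class
  distance <- row$distance_cm / 100
  desired_peak <- row$peak_speed_cm_s / 100
  if (distance <= 0 || desired_peak <= 0) {
    abort("distance and desired peak speed must be positive",
          class = "curladapt_invalid_parameter")
  }
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  mult <- if (noise_cv > 0) 1 + noise_cv * rnorm(1L) else 1
  mult <- max(mult, 0.2) # guard against absurd draws at high cv
  peak <- desired_peak * mult
  duration <- 1.875 * distance / peak
  t <- seq(0, ceiling(duration / dt) * dt, by = dt)
  v <- min_jerk_speed(t, distance, duration)
  out <- tibble::tibble(t_ms = round(t * 1000), v = v)
  attr(out, "peak_speed") <- peak
  attr(out, "duration") <- duration
  attr(out, "distance") <- distance
  out
}
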