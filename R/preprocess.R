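#' Zero-phase Butterworth low-pass filter
#'
#' Filters a series with a Butterworth low-pass applied forward and backward
#' (zero phase lag, squared magnitude response, DC gain 1). The series is
#' extended by odd reflection at both ends before filtering to suppress edge
#' transients, then trimmed back.
#'
#' @param x Numeric series (1 kHz samples by default).
#' @param order Filter order (default 5).
#' @param cutoff Cut-off frequency, Hz (default 40).
#' @param fs Sampling rate, Hz (default 1000).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' all.equal(lowpass_filter(rep(2, 100)), rep(2, 100))
lowpass_filter <- function(x, order = 5, cutoff = 40, fs = 1000) {
  n <- length(x)
  if (n <= 3 * order) {
    abort("series too short to filter (need length > 3 * order)",
          class = "curladapt_series_too_short")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1L, 500L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  ext <- c(head_pad, x, tail_pad)
  y <- signal::filtfilt(bf, ext)
  y[(pad + 1L):(pad + n)]
}

#' Remove slow force drift from a clamp-trial force series
#'
#' Subtracts the mean lateral force measured 200 ms to 150 ms before
#' movement onset from the whole series, removing slow offsets of the force
#' transducer (e.g. from inconsistent arm-support position). Idempotent.
#'
#' @param force Lateral force series, N, on a 1 kHz grid starting at 0 ms.
#' @param onset_ms Movement onset time, ms (must be >= 200 ms into the
#'   recording so the baseline window exists).
#' @return The drift-corrected series.
#' @export
remove_force_drift <- function(force, onset_ms) {
  if (onset_ms < 200) {
    abort("need at least 200 ms of pre-onset samples for drift correction",
          class = "curladapt_insufficient_baseline")
  }
  idx <- seq.int(onset_ms - 200, onset_ms - 150) + 1L
  if (max(idx) > length(force)) {
    abort("force series shorter than the drift-correction window",
          class = "curladapt_insufficient_baseline")
  }
  force - mean(force[idx])
}

#' Detect movement onset from a speed series
#'
#' Onset is the first sample at which hand speed exceeds a fraction
#' (default 5%) of that trial's peak speed, searching forward from the
#' start of the recording.
#'
#' @param speed Speed series, m/s, 1 kHz grid starting at 0 ms.
#' @param threshold Fraction of peak speed (default 0.05); must be > 0.
#' @return Onset time in ms.
#' @export
detect_movement_onset <- function(speed, threshold = 0.05) {
  if (threshold <= 0) {
    abort("`threshold` must be positive", class = "curladapt_invalid_parameter")
  }
  peak <- max(speed)
  if (peak <= 0) {
    abort("speed series is identically zero; no movement to detect",
          class = "curladapt_no_movement")
  }
  idx <- which(speed > threshold * peak)[1]
  idx - 1L
}

# Extract a symmetric window around centre_idx, padding out-of-range samples
# with the boundary value and flagging them.
align_window <- function(x, centre_idx, half_window_ms = 400) {
  idx <- (centre_idx - half_window_ms):(centre_idx + half_window_ms)
  padded <- idx < 1L | idx > length(x)
  idx_clamped <- pmin(pmax(idx, 1L), length(x))
  list(values = x[idx_clamped], padded = padded)
}

#' Align a clamp trial's force profile to peak velocity
#'
#' Clips the left-hand lateral force (and both hands' forward-speed series)
#' to a window from 400 ms before to 400 ms after the reference hand's peak
#' speed: the right hand for bimanual trials, the left hand for unimanual
#' trials (`reference_hand = "auto"`). Ties in peak speed are broken by the
#' earliest sample. Out-of-range samples are padded with the boundary value
#' and flagged so downstream fits can exclude them.
#'
#' @param series A per-trial series tibble as produced by
#'   [simulate_experiment()] (columns `vyl`, `vyr`, `fxl`).
#' @param reference_hand `"auto"`, `"right"` or `"left"`.
#' @param half_window_ms Half-width of the window, ms (default 400;
#'   window length `2 * half_window_ms + 1` samples).
#' @return A list with `force`, `v_left`, `v_right` (numeric, window grid),
#'   `padded` (logical), `lag_ms` (window time axis, -400..400),
#'   `ref_hand`, and `centre_ms` (peak-speed time in trial time).
#' @export
align_to_peak_velocity <- function(series, reference_hand = c("auto", "right", "left"),
                                   half_window_ms = 400) {
  reference_hand <- match.arg(reference_hand)
  bimanual <- any(series$vyr != 0)
  if (reference_hand == "auto") {
    reference_hand <- if (bimanual) "right" else "left"
  }
  if (reference_hand == "right" && !bimanual) {
    abort("cannot align to the right hand on a unimanual trial",
          class = "curladapt_invalid_reference")
  }
  ref <- if (reference_hand == "right") series$vyr else series$vyl
  centre <- which.max(ref) # earliest maximal sample on ties
  wf <- align_window(series$fxl, centre, half_window_ms)
  wl <- align_window(series$vyl, centre, half_window_ms)
  wr <- align_window(series$vyr, centre, half_window_ms)
  list(
    force = wf$values, v_left = wl$values, v_right = wr$values,
    padded = wf$padded, lag_ms = -half_window_ms:half_window_ms,
    ref_hand = reference_hand, centre_ms = series$t_ms[centre]
  )
}

#' Peak force of an aligned profile
#'
#' Mean lateral force over a 20 ms window (+/-10 ms) centred on the
#' profile's centre sample, i.e. on the reference hand's peak-speed time.
#'
#' @param force Aligned force profile (odd length; centre = peak speed), or
#'   the list returned by [align_to_peak_velocity()].
#' @param window_ms Total window width, ms (default 20).
#' @return Mean force over the window, N.
#' @export
peak_force <- function(force, window_ms = 20) {
  if (is.list(force) && !is.null(force$force)) force <- force$force
  centre <- (length(force) + 1L) %/% 2L
  half <- round(window_ms / 2)
  idx <- (centre - half):(centre + half)
  idx <- idx[idx >= 1L & idx <= length(force)]
  mean(force[idx])
}

#' Extract aligned clamp-trial profiles from a dataset
#'
#' The standard conditioning pipeline for channel trials: low-pass filter
#' the measured lateral force (zero-phase Butterworth, 5th order, 40 Hz),
#' remove pre-movement drift, and align force and both hands' forward-speed
#' series on the reference hand's peak speed.
#'
#' @param data A trial dataset from [simulate_experiment()] or
#'   [read_dataset()] (rows with `field_type == "clamp"` and a non-`NULL`
#'   `series` are used).
#' @param half_window_ms Half-width of the alignment window, ms.
#' @param filter_cutoff,filter_order Butterworth settings.
#' @param drift_correct Apply pre-onset drift removal (default `TRUE`).
#' @return A tibble with one row per clamp trial: the trial labels plus
#'   `ref_hand`, `centre_ms` and list-columns `force`, `v_left`, `v_right`,
#'   `padded`.
#' @export
align_profiles <- function(data, half_window_ms = 400, filter_cutoff = 40,
                           filter_order = 5, drift_correct = TRUE) {
  keep <- data$field_type == "clamp" & !purrr::map_lgl(data$series, is.null)
  rows <- data[keep, ]
  if (nrow(rows) == 0L) {
    abort("no clamp trials with time-series found",
          class = "curladapt_no_clamp_trials")
  }
  prof <- purrr::map(rows$series, function(s) {
    f <- lowpass_filter(s$fxl, order = filter_order, cutoff = filter_cutoff)
    if (drift_correct) {
      onset <- detect_movement_onset(s$vyl)
      f <- remove_force_drift(f, onset)
    }
    s2 <- s
    s2$fxl <- f
    align_to_peak_velocity(s2, half_window_ms = half_window_ms)
  })
  out <- rows[, intersect(c("participant", "group", "trial", "phase", "block",
                            "condition", "field_type", "alpha", "omega_true"),
                          names(rows))]
  out$ref_hand <- purrr::map_chr(prof, "ref_hand")
  out$centre_ms <- purrr::map_dbl(prof, "centre_ms")
  out$force <- purrr::map(prof, "force")
  out$v_left <- purrr::map(prof, "v_left")
  out$v_right <- purrr::map(prof, "v_right")
  out$padded <- purrr::map(prof, "padded")
  tibble::as_tibble(out)
}

#' Average aligned profiles within condition
#'
#' Collapses aligned clamp-trial profiles to one mean profile per
#' participant and condition (the convention used for encoding-model fits),
#' averaging force and velocity sample-wise. A sample is flagged padded in
#' the mean if it was padded in any contributing trial.
#'
#' @param profiles Output of [align_profiles()], optionally pre-filtered
#'   (e.g. to one phase).
#' @return A tibble with one row per participant x condition and the same
#'   list-columns as the input.
#' @export
average_profiles <- function(profiles) {
  profiles |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("participant", "group", "condition")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      ref_hand = .data$ref_hand[1],
      force = list(rowMeans(do.call(cbind, .data$force))),
      v_left = list(rowMeans(do.call(cbind, .data$v_left))),
      v_right = list(rowMeans(do.call(cbind, .data$v_right))),
      padded = list(Reduce(`|`, .data$padded)),
      .groups = "drop"
    )
}
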