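#' Signed maximum perpendicular error of a reach path
#'
#' The signed largest perpendicular distance between the hand path and the
#' straight line joining the centres of the start and end targets, taken at
#' the sample with the largest absolute deviation. For a forward reach the
#' sign convention is positive = leftward of the travel direction (the curl
#' field pushes the hand leftward, so unadapted force-field trials have
#' positive MPE).
#'
#' @param x,y Hand path coordinates, metres.
#' @param start,target Numeric length-2 centres of the start and end
#'   targets, metres.
#' @return Signed maximum perpendicular error in cm.
#' @export
#' @examples
#' max_perpendicular_error(c(0, -0.02, 0), c(0, 0.1, 0.2), target = c(0, 0.2))
max_perpendicular_error <- function(x, y, start = c(0, 0), target) {
  d <- c(target[1] - start[1], target[2] - start[2])
  len <- sqrt(sum(d^2))
  if (len == 0) {
    abort("start and target coincide; perpendicular error undefined",
          class = "curladapt_degenerate_path")
  }
  # signed perpendicular distance; left of the direction of travel positive
  s <- (d[1] * (y - start[2]) - d[2] * (x - start[1])) / len
  s[which.max(abs(s))] * 100
}

#' Perfect-compensation force profile
#'
#' The lateral force that would exactly oppose the curl field on a bimanual
#' trial: `+B * vy_right(t)` (the field pushes `-B * vy_right`). Undefined
#' for unimanual trials, where no field is ever applied.
#'
#' @param v_right Right-hand forward-speed series, m/s.
#' @param B Curl gain, N.s/m.
#' @return Lateral force series, N.
#' @export
perfect_compensation_profile <- function(v_right, B = DEFAULT_B) {
  if (all(v_right == 0)) {
    abort("right hand is stationary: no field is applied and the compensation target is undefined",
          class = "curladapt_undefined_compensation")
  }
  B * v_right
}

#' Force compensation of a measured channel-trial profile
#'
#' Force compensation is 100 times the slope of a linear regression of the
#' measured lateral force on the perfect-compensation profile. By default
#' the regression goes through the origin (drift is removed upstream);
#' set `intercept = TRUE` for the with-intercept variant.
#'
#' @param measured Measured lateral force, N.
#' @param perfect Perfect-compensation profile, N (same length, not all
#'   zero).
#' @param intercept Include an intercept in the regression.
#' @return Force compensation in percent (100 = complete adaptation).
#' @export
#' @examples
#' v <- sin(seq(0, pi, length.out = 100))
#' force_compensation(6.5 * v, 13 * v) # 50
force_compensation <- function(measured, perfect, intercept = FALSE) {
  if (length(measured) != length(perfect)) {
    abort("profiles must have equal length", class = "curladapt_invalid_parameter")
  }
  if (all(perfect == 0)) {
    abort("perfect-compensation profile is identically zero; force compensation undefined",
          class = "curladapt_undefined_compensation")
  }
  slope <- if (intercept) {
    stats::coef(stats::lm(measured ~ perfect))[["perfect"]]
  } else {
    sum(measured * perfect) / sum(perfect^2)
  }
  100 * slope
}

#' Bin a per-trial series into consecutive means
#'
#' Averages an ordered per-trial metric over non-overlapping consecutive
#' bins (default 12 trials, the convention for plotting adaptation curves).
#' A trailing partial bin is averaged and flagged.
#'
#' @param values Numeric per-trial values, in trial order.
#' @param bin Bin width in trials.
#' @return A tibble with `bin`, `mean`, `n` and `partial`.
#' @export
bin_series <- function(values, bin = 12) {
  if (bin < 1) abort("`bin` must be >= 1", class = "curladapt_invalid_parameter")
  idx <- ceiling(seq_along(values) / bin)
  tibble::tibble(
    bin = unique(idx),
    mean = as.numeric(tapply(values, idx, mean)),
    n = as.integer(tapply(values, idx, length))
  ) |>
    dplyr::mutate(partial = .data$n < bin)
}

#' Per-trial force compensation table
#'
#' Computes force compensation for every bimanual clamp trial in an aligned
#' profile table, regressing the measured force on the perfect-compensation
#' profile built from that trial's aligned right-hand speed. Padded samples
#' are excluded from the regression. Unimanual trials (no field, no defined
#' compensation target) are skipped.
#'
#' @param profiles Output of [align_profiles()].
#' @param B Curl gain, N.s/m.
#' @param intercept Passed to [force_compensation()].
#' @return A tibble of trial labels plus `fc` (percent).
#' @export
fc_table <- function(profiles, B = DEFAULT_B, intercept = FALSE) {
  rows <- profiles[profiles$ref_hand == "right", ]
  rows$fc <- purrr::pmap_dbl(
    list(rows$force, rows$v_right, rows$padded),
    function(f, vr, pad) {
      ok <- !pad
      force_compensation(f[ok], perfect_compensation_profile(vr[ok], B),
                         intercept = intercept)
    }
  )
  dplyr::select(rows, -dplyr::any_of(c("force", "v_left", "v_right", "padded")))
}

#' Per-trial maximum perpendicular error table
#'
#' Computes the signed MPE for every null and force-field trial that has a
#' stored path (requires a dataset simulated with `keep = "all"`, and the
#' lateral plant enabled for deviations to exist), using each condition's
#' reach distance for the target position.
#'
#' @param data A trial dataset with `series` time-series.
#' @return A tibble of trial labels plus `mpe_cm`.
#' @export
mpe_table <- function(data) {
  grid <- condition_grid()
  dist_m <- setNames(speed_classes()$distance_cm / 100, speed_classes()$class)
  left_class <- setNames(grid$left_class, grid$label)
  keep <- data$field_type %in% c("null", "force_field") &
    !purrr::map_lgl(data$series, is.null)
  rows <- data[keep, ]
  if (nrow(rows) == 0L) {
    abort("no null/force-field trials with time-series found",
          class = "curladapt_no_kinematic_trials")
  }
  rows$mpe_cm <- purrr::map2_dbl(rows$series, rows$condition, function(s, cond) {
    max_perpendicular_error(s$xl, s$yl,
                            start = c(0, 0),
                            target = c(0, dist_m[[left_class[[cond]]]]))
  })
  dplyr::select(rows, -"series")
}
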