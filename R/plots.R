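#' Plot the force-compensation learning curve
#'
#' Clamp-trial force compensation across the experiment, binned and averaged
#' across participants, split by group if present.
#'
#' @param fc An [fc_table()] result (optionally with a `group` column).
#' @param bin Bin width in clamp trials.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(fc, bin = 12) {
  grp <- "group" %in% names(fc)
  fc <- dplyr::arrange(fc, .data$trial)
  keys <- c(if (grp) "group", "participant")
  binned <- fc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ bin_series(.x$fc, bin = bin)) |>
    dplyr::ungroup() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(if (grp) "group", "bin")))) |>
    dplyr::summarise(fc = mean(.data$mean), .groups = "drop")
  p <- ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$fc)) +
    ggplot2::geom_hline(yintercept = c(0, 100), linetype = "dotted") +
    ggplot2::geom_line(if (grp) ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = paste0("clamp-trial bin (", bin, " trials)"),
                  y = "force compensation (%)") +
    ggplot2::theme_minimal()
  p
}

#' Plot mean aligned force profiles per condition
#'
#' @param profiles [align_profiles()] output (typically one phase).
#' @return A ggplot object.
#' @export
plot_force_profiles <- function(profiles) {
  long <- profiles |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(force = list(rowMeans(do.call(cbind, .data$force))),
                     .groups = "drop") |>
    dplyr::mutate(lag_ms = list(seq(-400, 400))) |>
    tidyr::unnest(c("force", "lag_ms"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lag_ms, y = .data$force,
                                     colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from peak speed (ms)", y = "lateral force (N)") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs observed generalization per condition
#'
#' Bar chart of observed per-condition force compensation with each encoding
#' model's prediction overlaid as points.
#'
#' @param predictions Prediction table (`condition`, `model`, `fc_pred`),
#'   e.g. from [run_pipeline()].
#' @param observed Observed per-condition FC (`condition`, `fc`).
#' @return A ggplot object.
#' @export
plot_generalization <- function(predictions, observed) {
  obs <- observed |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(fc = mean(.data$fc), .groups = "drop")
  pred <- predictions |>
    dplyr::group_by(.data$condition, .data$model) |>
    dplyr::summarise(fc_pred = mean(.data$fc_pred), .groups = "drop")
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$condition)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$fc), fill = "grey80") +
    ggplot2::geom_point(data = pred,
                        ggplot2::aes(y = .data$fc_pred, colour = .data$model)) +
    ggplot2::labs(x = NULL, y = "force compensation (%)") +
    ggplot2::theme_minimal()
}

#' Plot the encoding-weight trajectory
#'
#' Fitted weight per 96-trial window, averaged across participants, with
#' the pure right-hand (1), average (0.5) and left-hand (0) encodings as
#' reference lines.
#'
#' @param weights A [fit_weight_trajectory()] result (optionally with a
#'   `group` column).
#' @return A ggplot object.
#' @export
plot_weight_trajectory <- function(weights) {
  grp <- "group" %in% names(weights)
  avg <- weights |>
    dplyr::filter(.data$fitted) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(if (grp) "group", "window")))) |>
    dplyr::summarise(omega = mean(.data$omega), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$window, y = .data$omega)) +
    ggplot2::geom_hline(yintercept = c(0, 0.5, 1), linetype = "dotted") +
    ggplot2::geom_line(if (grp) ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = "96-trial window", y = "encoding weight") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of an encoding-model fit
#'
#' Observed vs model-predicted lateral force samples with the identity line.
#'
#' @param object An `encoding_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.encoding_fit <- function(object, ...) {
  d <- tibble::tibble(observed = object$observed, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::labs(
      x = "model force (N)", y = "measured force (N)",
      title = paste0(object$model, " encoding (R² = ",
                     format(object$r2, digits = 3), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
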