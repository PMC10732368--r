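DATASET_COLS <- c("participant", "group", "trial", "phase", "block",
                  "condition", "field_type", "hand", "t_ms",
                  "x", "y", "vx", "vy", "fx", "fy")

#' Write a trial dataset to a delimited file
#'
#' Serializes a trial dataset to the tidy long format: one row per sample
#' per hand with columns `participant, group, trial, phase, block,
#' condition, field_type, hand, t_ms, x, y, vx, vy, fx, fy` (forces are
#' recorded on the left hand only; right-hand rows carry `NA`). Trials
#' without stored time-series are skipped. Values are written at full
#' double precision, so a write/read round trip is lossless.
#'
#' @param data A trial dataset from [simulate_experiment()].
#' @param path Output file (CSV, UTF-8, header row).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  keep <- !purrr::map_lgl(data$series, is.null)
  rows <- data[keep, ]
  long <- purrr::map2(seq_len(nrow(rows)), rows$series, function(i, s) {
    lab <- rows[i, c("participant", "group", "trial", "phase", "block",
                     "condition", "field_type")]
    left <- tibble::tibble(hand = "left", t_ms = s$t_ms, x = s$xl, y = s$yl,
                           vx = s$vxl, vy = s$vyl, fx = s$fxl, fy = s$fyl)
    right <- tibble::tibble(hand = "right", t_ms = s$t_ms, x = s$xr, y = s$yr,
                            vx = s$vxr, vy = s$vyr,
                            fx = NA_real_, fy = NA_real_)
    dplyr::bind_cols(lab[rep(1, 2 * nrow(s)), ], dplyr::bind_rows(left, right))
  }) |> purrr::list_rbind()
  if (is.null(long) || ncol(long) == 0L) {
    long <- tibble::as_tibble(setNames(
      rep(list(logical(0)), length(DATASET_COLS)), DATASET_COLS))
  }
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' Read a trial dataset written by [write_dataset()]
#'
#' @param path CSV file in the long format documented in [write_dataset()].
#' @return A trial dataset tibble (one row per trial, `series` list-column),
#'   matching the shape produced by [simulate_experiment()] (without the
#'   simulator-only `alpha`/`omega_true` columns).
#' @export
read_dataset <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(DATASET_COLS, names(long))
  if (length(missing) > 0L) {
    abort(paste0("dataset file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "curladapt_schema_error")
  }
  if (nrow(long) == 0L) {
    return(tibble::tibble(
      participant = integer(), group = character(), trial = integer(),
      phase = character(), block = integer(), condition = character(),
      field_type = character(), series = list()
    ))
  }
  long |>
    dplyr::group_by(.data$participant, .data$group, .data$trial, .data$phase,
                    .data$block, .data$condition, .data$field_type) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(series = purrr::map(.data$data, function(d) {
      l <- d[d$hand == "left", ]
      r <- d[d$hand == "right", ]
      tibble::tibble(t_ms = l$t_ms, xl = l$x, yl = l$y, vxl = l$vx,
                     vyl = l$vy, fxl = l$fx, fyl = l$fy,
                     xr = r$x, yr = r$y, vxr = r$vx, vyr = r$vy)
    })) |>
    dplyr::select(-"data") |>
    dplyr::arrange(.data$participant, .data$trial)
}

#' Build a run configuration
#'
#' Bundles everything needed to reproduce an analysis run: the group
#' designs, learner and kinematics parameters, seed, analysis options, and
#' sample size. Serializable to YAML with [write_run_config()].
#'
#' @param groups Character vector of groups to simulate.
#' @param n_participants Participants per group.
#' @param seed Base integer seed.
#' @param learner,kinematics Parameter lists ([learner_config()],
#'   [kinematics_config()]); `learner$omega` may be a named list/vector with
#'   per-group ground-truth weights.
#' @param B Curl gain, N.s/m.
#' @param keep Which trials to keep series for (see
#'   [simulate_experiment()]).
#' @param half_window_ms,onset_threshold,fc_intercept Analysis options:
#'   alignment half-window (ms), movement-onset threshold (fraction of peak
#'   speed), with-intercept force-compensation regression flag.
#' @param reference_alpha Optional fixed non-parametric gain override.
#' @return A list of class `run_config`.
#' @export
run_config <- function(groups = c("evident", "ambiguous"), n_participants = 8,
                       seed = 1L, learner = learner_config(),
                       kinematics = kinematics_config(), B = DEFAULT_B,
                       keep = "clamp", half_window_ms = 400,
                       onset_threshold = 0.05, fc_intercept = FALSE,
                       reference_alpha = NULL) {
  if (onset_threshold <= 0) {
    abort("`onset_threshold` must be positive",
          class = "curladapt_invalid_config")
  }
  for (g in groups) group_design(g) # validates
  structure(
    list(groups = groups, n_participants = n_participants, seed = seed,
         learner = learner, kinematics = kinematics, B = B, keep = keep,
         half_window_ms = half_window_ms, onset_threshold = onset_threshold,
         fc_intercept = fc_intercept, reference_alpha = reference_alpha),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(lapply(config, function(x)
    if (is.list(x)) unclass(x) else x)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lc <- do.call(learner_config, raw$learner %||% list())
  kc <- do.call(kinematics_config, raw$kinematics %||% list())
  do.call(run_config, c(
    raw[setdiff(names(raw), c("learner", "kinematics"))],
    list(learner = lc, kinematics = kc)
  ))
}

group_omega <- function(learner, group) {
  om <- learner$omega
  if (is.list(om) || (length(om) > 1 && !is.null(names(om)))) {
    learner$omega <- om[[group]]
  }
  learner
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> metrics -> models for every group in
#' the configuration: simulates the synthetic participants, aligns the
#' channel-trial force profiles, computes per-trial force compensation (and
#' perpendicular error where kinematic series are available), fits the four
#' encoding models per participant on the condition-averaged
#' generalization-phase profiles of the trained conditions, fits the pooled
#' non-parametric reference, computes BIC improvements, and produces
#' per-condition generalization predictions with out-of-sample mean squared
#' errors.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV together with a `run_log.yaml` recording the
#'   configuration and seeds in force.
#' @return A list of class `curladapt_run` with tibbles `data` (trial
#'   ledger without series), `fc`, `mpe` (`NULL` without kinematic series),
#'   `fits`, `reference`, `bic`, `weights`, `predictions`, `mse`, and the
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  datasets <- purrr::map(config$groups, function(g) {
    simulate_experiment(
      g, n_participants = config$n_participants,
      seed = (as.integer(config$seed) + match(g, config$groups) * 131071L) %%
        .Machine$integer.max,
      learner = group_omega(config$learner, g),
      kinematics = config$kinematics, keep = config$keep, B = config$B
    )
  })
  names(datasets) <- config$groups

  per_group <- purrr::imap(datasets, function(dat, g) {
    trained <- group_design(g)$trained_conditions
    prof <- align_profiles(dat, half_window_ms = config$half_window_ms)
    fc <- fc_table(prof, B = config$B, intercept = config$fc_intercept)
    mpe <- if (any(dat$field_type != "clamp" &
                   !purrr::map_lgl(dat$series, is.null))) {
      mpe_table(dat)
    } else {
      NULL
    }
    gen_mean <- average_profiles(prof[prof$phase == "generalization", ])
    fits <- suppressWarnings(
      fit_encoding_models(gen_mean, conditions = trained, B = config$B)
    )
    ref <- nonparametric_reference(gen_mean, fits = fits,
                                   alpha = config$reference_alpha,
                                   conditions = trained, B = config$B)
    bic <- bic_improvement(fits, ref)

    # observed per-condition FC in generalization (clamp trials, bimanual)
    obs_fc <- fc[fc$phase == "generalization", ] |>
      dplyr::group_by(.data$participant, .data$condition) |>
      dplyr::summarise(fc = mean(.data$fc), .groups = "drop")
    vel <- gen_mean |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        v_left = list(rowMeans(do.call(cbind, .data$v_left))),
        v_right = list(rowMeans(do.call(cbind, .data$v_right))),
        .groups = "drop"
      )
    preds <- fits |>
      dplyr::mutate(preds = purrr::map(.data$fit, predict_generalization,
                                       velocities = vel, B = config$B)) |>
      dplyr::select("participant", "preds") |>
      tidyr::unnest("preds") |>
      dplyr::select(-"force")
    mse <- preds |>
      dplyr::group_by(.data$participant, .data$model) |>
      dplyr::group_modify(function(d, key) {
        obs <- obs_fc[obs_fc$participant == key$participant, ]
        tibble::tibble(
          mse_untrained = prediction_mse(
            d[, c("condition", "fc_pred")], obs, exclude = trained),
          mse_all_bimanual = prediction_mse(
            d[, c("condition", "fc_pred")], obs)
        )
      }) |>
      dplyr::ungroup()
    weights <- suppressWarnings(fit_weight_trajectory(prof, B = config$B))
    list(fc = fc, mpe = mpe, fits = fits, reference = ref, bic = bic,
         predictions = preds, mse = mse, weights = weights)
  })

  bind_group <- function(field) {
    purrr::imap(per_group, function(res, g) {
      if (is.null(res[[field]])) return(NULL)
      dplyr::mutate(res[[field]], group = g, .before = 1)
    }) |> purrr::list_rbind()
  }
  out <- list(
    data = purrr::list_rbind(purrr::map(datasets, dplyr::select, -"series")),
    fc = bind_group("fc"),
    mpe = if (all(purrr::map_lgl(per_group, ~ is.null(.x$mpe)))) NULL
          else bind_group("mpe"),
    fits = bind_group("fits") |> dplyr::select(-"fit"),
    reference = bind_group("reference") |> dplyr::select(-"fit"),
    bic = bind_group("bic"),
    weights = bind_group("weights"),
    predictions = bind_group("predictions"),
    mse = bind_group("mse"),
    config = config
  )
  class(out) <- "curladapt_run"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tbls <- c("data", "fc", "mpe", "fits", "reference", "bic", "weights",
              "predictions", "mse")
    for (nm in tbls) {
      if (!is.null(out[[nm]])) {
        readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                         progress = FALSE)
      }
    }
    log <- list(
      package_version = as.character(utils::packageVersion("curladapt")),
      r_version = R.version.string,
      seed = config$seed,
      groups = config$groups,
      n_participants = config$n_participants,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

#' @export
print.curladapt_run <- function(x, ...) {
  cat("<curladapt_run>\n")
  cat("  groups:", paste(x$config$groups, collapse = ", "),
      " participants/group:", x$config$n_participants, "\n")
  cat("  trials:", nrow(x$data), "  clamp FC rows:", nrow(x$fc), "\n")
  cat("  fits:", nrow(x$fits), " model fits;  predictions:",
      nrow(x$predictions), "\n")
  invisible(x)
}
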