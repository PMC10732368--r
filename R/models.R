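ENCODING_MODELS <- c("right", "left", "average", "weighted")

# Mixture weight on right-hand velocity implied by each model.
model_weight <- function(model, omega = NA_real_) {
  switch(model,
    right = 1, left = 0, average = 0.5, nonparametric = 1,
    weighted = omega,
    abort(paste0("unknown model '", model, "'"),
          class = "curladapt_invalid_parameter")
  )
}

# Concatenate list-column profiles into flat vectors, dropping padded samples.
flatten_profiles <- function(profiles) {
  pad <- unlist(profiles$padded)
  keep <- if (is.null(pad)) TRUE else !pad
  list(
    f = unlist(profiles$force)[keep],
    vl = unlist(profiles$v_left)[keep],
    vr = unlist(profiles$v_right)[keep]
  )
}

# SSE of the best alpha for a fixed mixture weight w (closed-form gain,
# residuals summed directly to avoid cancellation for near-perfect fits).
best_alpha_sse <- function(f, vl, vr, w, B) {
  m <- B * (w * vr + (1 - w) * vl)
  smm <- sum(m^2)
  if (smm == 0) return(sum(f^2))
  sum((f - (sum(f * m) / smm) * m)^2)
}

#' Fit an encoding model to channel-trial force profiles
#'
#' Fits one of the four parametric encoding models of the predictive force
#' (or the fixed-gain non-parametric reference) to aligned channel-trial
#' force profiles by least squares. The models express the commanded
#' lateral force as a gain `alpha` times a velocity predictor scaled by the
#' curl gain `B`:
#'
#' * `right`: `alpha * B * v_right`
#' * `left`: `alpha * B * v_left`
#' * `average`: `alpha * B * (v_left + v_right) / 2`
#' * `weighted`: `alpha * B * (omega * v_right + (1 - omega) * v_left)`,
#'   with `omega` free (initialized at 0.5, unbounded) and `alpha`
#'   initialized at 1
#' * `nonparametric`: `alpha_fixed * B * v_right` with no free parameter
#'
#' Profiles are concatenated across the rows of `profiles` (padded samples
#' excluded). The weighted fit minimizes the summed squared residual with
#' BFGS and analytic gradients (relative objective tolerance 1e-8); the
#' one-parameter models have closed-form through-origin solutions. When the
#' left and right velocity profiles are (near-)identical the weight is not
#' identifiable: the fit is still returned, with a warning, when the
#' relative change of the optimal-gain SSE across `omega` in [0, 1] is
#' below 1e-6.
#'
#' @param profiles Aligned profiles (one or more rows of [align_profiles()]
#'   or [average_profiles()] output).
#' @param model One of `"right"`, `"left"`, `"average"`, `"weighted"`,
#'   `"nonparametric"`.
#' @param B Curl gain, N.s/m.
#' @param alpha_fixed Fixed gain for the non-parametric model.
#' @return An object of class `encoding_fit`: a list with `model`, `alpha`,
#'   `omega`, `sse`, `n`, `k`, `bic` (`NA` for a degenerate noise-free fit
#'   with zero SSE), `r2`, `converged`, `identifiable`, `B`, and the
#'   `observed`/`fitted` vectors.
#' @export
#' @seealso [fit_encoding_models()], [compute_bic()], [predict_generalization()]
fit_encoding_model <- function(profiles, model = c("weighted", "right", "left",
                                                   "average", "nonparametric"),
                               B = DEFAULT_B, alpha_fixed = NULL) {
  model <- match.arg(model)
  if (nrow(profiles) == 0L) {
    abort("no profiles to fit", class = "curladapt_empty_fit")
  }
  dat <- flatten_profiles(profiles)
  f <- dat$f; vl <- dat$vl; vr <- dat$vr
  n <- length(f)
  converged <- TRUE
  identifiable <- TRUE
  omega <- NA_real_

  if (model == "nonparametric") {
    if (is.null(alpha_fixed)) {
      abort("`alpha_fixed` is required for the non-parametric model",
            class = "curladapt_invalid_parameter")
    }
    alpha <- alpha_fixed
    k <- 0L
    pred <- alpha * B * vr
  } else if (model %in% c("right", "left", "average")) {
    w <- model_weight(model)
    m <- B * (w * vr + (1 - w) * vl)
    if (all(m == 0)) {
      abort("velocity predictor is identically zero; gain undefined",
            class = "curladapt_undefined_fit")
    }
    alpha <- sum(f * m) / sum(m^2)
    k <- 1L
    pred <- alpha * m
  } else { # weighted
    obj <- function(par) {
      m <- B * (par[2] * vr + (1 - par[2]) * vl)
      sum((f - par[1] * m)^2)
    }
    grad <- function(par) {
      m <- B * (par[2] * vr + (1 - par[2]) * vl)
      r <- f - par[1] * m
      c(-2 * sum(r * m), -2 * par[1] * B * sum(r * (vr - vl)))
    }
    opt <- optim(c(alpha = 1, omega = 0.5), obj, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-8))
    converged <- opt$convergence == 0L
    if (!converged) {
      warn(paste0("weighted fit did not converge (optim code ",
                  opt$convergence, ", ", opt$counts[["function"]],
                  " objective evaluations)"),
           class = "curladapt_nonconvergence")
    }
    alpha <- opt$par[["alpha"]]
    omega <- opt$par[["omega"]]
    k <- 2L
    pred <- alpha * B * (omega * vr + (1 - omega) * vl)

    prof_sse <- vapply(seq(0, 1, by = 0.1), function(w)
      best_alpha_sse(f, vl, vr, w, B), numeric(1))
    # scale against both the SSE level and the signal power, so exact
    # noise-free fits (SSE at round-off level) still register as flat
    denom <- max(max(prof_sse), 1e-12 * sum(f^2), .Machine$double.eps)
    rel_change <- (max(prof_sse) - min(prof_sse)) / denom
    if (rel_change < 1e-6) {
      identifiable <- FALSE
      warn("left and right velocity profiles are nearly identical: the encoding weight omega is not identifiable",
           class = "curladapt_identifiability")
    }
  }

  sse <- sum((f - pred)^2)
  tss <- sum((f - mean(f))^2)
  structure(
    list(
      model = model, alpha = alpha, omega = omega, sse = sse, n = n, k = k,
      bic = if (sse > 0) compute_bic(sse, n, k) else NA_real_,
      r2 = if (tss > 0) 1 - sse / tss else NA_real_,
      converged = converged, identifiable = identifiable, B = B,
      observed = f, fitted = pred
    ),
    class = "encoding_fit"
  )
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat("<encoding_fit> model:", x$model, "\n")
  cat("  alpha:", format(x$alpha, digits = 4))
  if (!is.na(x$omega)) cat("  omega:", format(x$omega, digits = 4))
  cat("\n  SSE:", format(x$sse, digits = 4), " n:", x$n, " k:", x$k,
      " BIC:", format(x$bic, digits = 6), " R2:", format(x$r2, digits = 4), "\n")
  if (!x$identifiable) cat("  (omega not identifiable)\n")
  invisible(x)
}

#' Fit all encoding models per participant
#'
#' Convenience wrapper fitting each requested encoding model to each
#' participant's profiles (optionally restricted to a condition set, e.g.
#' the trained conditions).
#'
#' @param profiles Aligned (usually condition-averaged) profiles.
#' @param models Character vector of models to fit.
#' @param conditions Optional condition labels to restrict to.
#' @param B Curl gain, N.s/m.
#' @return A tibble with one row per participant x model: `participant`,
#'   `model`, `alpha`, `omega`, `sse`, `n`, `k`, `bic`, `r2`, `converged`,
#'   `identifiable` and a `fit` list-column of `encoding_fit` objects.
#' @export
fit_encoding_models <- function(profiles, models = ENCODING_MODELS,
                                conditions = NULL, B = DEFAULT_B) {
  if (!is.null(conditions)) {
    profiles <- profiles[profiles$condition %in% conditions, ]
  }
  if (!"participant" %in% names(profiles)) profiles$participant <- 1L
  by_p <- split(profiles, factor(profiles$participant,
                                 levels = unique(profiles$participant)))
  purrr::map(by_p, function(pp) {
    purrr::map(models, function(mod) {
      fit <- fit_encoding_model(pp, model = mod, B = B)
      dplyr::bind_cols(
        tibble::tibble(participant = pp$participant[1]),
        glance(fit),
        tibble::tibble(fit = list(fit))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Pooled reference gain from parametric fits
#'
#' The mean fitted gain `alpha` across the four parametric encoding models
#' and all participants (pooled across groups), used as the fixed gain of
#' the non-parametric reference model.
#'
#' @param fits A fit table from [fit_encoding_models()].
#' @return A single numeric gain.
#' @export
reference_alpha <- function(fits) {
  rows <- fits[fits$model %in% ENCODING_MODELS, ]
  if (nrow(rows) == 0L) {
    abort("no parametric fits available to pool a reference gain from",
          class = "curladapt_empty_fit")
  }
  mean(rows$alpha)
}

#' Fit the non-parametric reference model
#'
#' Fits the zero-parameter reference model (fixed gain times right-hand
#' velocity times `B`) to each participant's profiles. The gain is the
#' pooled mean of the parametric fits ([reference_alpha()]) unless
#' overridden via `alpha` (e.g. 0.822, the published pooled value).
#'
#' @param profiles Aligned profiles (as passed to [fit_encoding_models()]).
#' @param fits Parametric fit table used to pool the gain (ignored when
#'   `alpha` is given).
#' @param alpha Optional fixed gain override.
#' @param conditions Optional condition labels to restrict to.
#' @param B Curl gain, N.s/m.
#' @return A fit table (same shape as [fit_encoding_models()]) with
#'   `model = "nonparametric"`; the gain used is in the `alpha` column.
#' @export
nonparametric_reference <- function(profiles, fits = NULL, alpha = NULL,
                                    conditions = NULL, B = DEFAULT_B) {
  if (is.null(alpha)) {
    if (is.null(fits)) {
      abort("supply either `fits` to pool a gain from, or a fixed `alpha`",
            class = "curladapt_invalid_parameter")
    }
    alpha <- reference_alpha(fits)
  }
  if (!is.null(conditions)) {
    profiles <- profiles[profiles$condition %in% conditions, ]
  }
  if (!"participant" %in% names(profiles)) profiles$participant <- 1L
  by_p <- split(profiles, factor(profiles$participant,
                                 levels = unique(profiles$participant)))
  purrr::map(by_p, function(pp) {
    fit <- fit_encoding_model(pp, model = "nonparametric", B = B,
                              alpha_fixed = alpha)
    dplyr::bind_cols(
      tibble::tibble(participant = pp$participant[1]),
      glance(fit),
      tibble::tibble(fit = list(fit))
    )
  }) |> purrr::list_rbind()
}

#' Bayesian information criterion for a least-squares fit
#'
#' Gaussian-likelihood BIC for a model with `k` free parameters fitted to
#' `n` samples with summed squared error `sse`:
#' `BIC = n * log(sse / n) + k * log(n)`.
#'
#' @param sse Summed squared error (> 0).
#' @param n Number of samples (> `k`).
#' @param k Number of free parameters (>= 0).
#' @return The BIC value (lower is better).
#' @export
#' @examples
#' compute_bic(10, 800, 2) - compute_bic(10, 800, 1) # log(800)
compute_bic <- function(sse, n, k) {
  if (!is.numeric(sse) || sse <= 0) {
    abort("`sse` must be positive (a zero-SSE fit is degenerate; add noise or skip the BIC)",
          class = "curladapt_degenerate_sse")
  }
  if (n <= k || k < 0) {
    abort("need n > k >= 0", class = "curladapt_invalid_parameter")
  }
  n * log(sse / n) + k * log(n)
}

#' BIC improvement over the non-parametric reference
#'
#' Joins a parametric fit table with the non-parametric reference fits and
#' reports, per participant and model, the BIC improvement
#' `delta_bic = bic_reference - bic_model` (positive = the model beats the
#' reference).
#'
#' @param fits Parametric fit table.
#' @param reference Non-parametric fit table ([nonparametric_reference()]).
#' @return A tibble `participant`, `model`, `bic`, `delta_bic`, `r2`.
#' @export
bic_improvement <- function(fits, reference) {
  ref <- dplyr::select(reference, "participant", bic_ref = "bic")
  fits |>
    dplyr::inner_join(ref, by = "participant") |>
    dplyr::mutate(delta_bic = .data$bic_ref - .data$bic) |>
    dplyr::select("participant", "model", "bic", "delta_bic", "r2")
}

#' Predict generalization from a fitted encoding model
#'
#' Applies a fitted model's gain (and weight) to each condition's velocity
#' profiles to predict the channel-trial force profile, force compensation
#' and peak force that the learner should express in that condition —
#' including the unimanual conditions, where the right-hand velocity is
#' identically zero (so a pure right-hand encoding predicts zero force).
#' Predicted force compensation is the through-origin regression slope of
#' the predicted force on the perfect-compensation profile (undefined, `NA`,
#' for unimanual conditions where no field is ever applied).
#'
#' @param fit An `encoding_fit` (typically fitted on the trained conditions
#'   only).
#' @param velocities A tibble with `condition` and list-columns `v_left`,
#'   `v_right` on the aligned grid — observed condition means
#'   (e.g. from [average_profiles()]) or noise-free templates
#'   ([condition_velocity_templates()]).
#' @param B Curl gain (defaults to the fit's).
#' @return A tibble `condition`, `model`, `force` (list), `fc_pred` (%),
#'   `peak_force_pred` (N).
#' @export
predict_generalization <- function(fit, velocities, B = NULL) {
  B <- B %||% fit$B
  w <- model_weight(fit$model, fit$omega)
  purrr::pmap(
    list(velocities$condition, velocities$v_left, velocities$v_right),
    function(cond, vl, vr) {
      pred <- fit$alpha * B * (w * vr + (1 - w) * vl)
      fc <- if (any(vr != 0)) {
        force_compensation(pred, perfect_compensation_profile(vr, B))
      } else {
        NA_real_
      }
      tibble::tibble(condition = cond, model = fit$model, force = list(pred),
                     fc_pred = fc, peak_force_pred = peak_force(pred))
    }
  ) |> purrr::list_rbind()
}

#' Mean squared prediction error across conditions
#'
#' Mean squared difference between predicted and observed per-condition
#' values (force compensation by default), over the overlapping conditions
#' after excluding a set (conventionally the trained conditions, so the MSE
#' measures out-of-sample generalization).
#'
#' @param predicted,observed Data frames with a `condition` column and one
#'   numeric value column each (the first numeric column is used), or named
#'   numeric vectors.
#' @param exclude Condition labels to drop (e.g. the trained set).
#' @param include Optional condition labels to restrict to (applied before
#'   `exclude`); e.g. all bimanual, or the unimanual set.
#' @return The mean squared error (single number).
#' @export
prediction_mse <- function(predicted, observed, exclude = NULL, include = NULL) {
  as_named <- function(x) {
    if (is.data.frame(x)) {
      num <- names(x)[vapply(x, is.numeric, logical(1)) & names(x) != "condition"]
      if (!"condition" %in% names(x) || length(num) == 0L) {
        abort("data frame needs a `condition` column and a numeric value column",
              class = "curladapt_invalid_parameter")
      }
      setNames(x[[num[1]]], x$condition)
    } else {
      x
    }
  }
  p <- as_named(predicted)
  o <- as_named(observed)
  conds <- intersect(names(p), names(o))
  if (!is.null(include)) conds <- intersect(conds, include)
  conds <- setdiff(conds, exclude)
  conds <- conds[!is.na(p[conds]) & !is.na(o[conds])]
  if (length(conds) == 0L) {
    abort("no overlapping conditions between predictions and observations",
          class = "curladapt_no_overlap")
  }
  mean((p[conds] - o[conds])^2)
}

#' Encoding-weight trajectory across the experiment
#'
#' Refits the weighted encoding model on consecutive windows of
#' `block_size` trials through the exposure and generalization phases,
#' per participant, tracking how the fitted weight `omega` develops as the
#' learner accumulates experience.
#'
#' @param profiles Per-trial aligned clamp profiles ([align_profiles()]) of
#'   the full dataset; only exposure and generalization trials are used.
#' @param block_size Window length in trials (default 96).
#' @param B Curl gain, N.s/m.
#' @return A tibble `participant`, `window`, `trial_start`, `trial_end`,
#'   `n_profiles`, `alpha`, `omega`, `fitted` (FALSE, with `NA` estimates,
#'   for windows containing no clamp trials).
#' @export
fit_weight_trajectory <- function(profiles, block_size = 96, B = DEFAULT_B) {
  rows <- profiles[profiles$phase %in% c("exposure", "generalization"), ]
  if (nrow(rows) == 0L) {
    abort("no exposure/generalization clamp profiles found",
          class = "curladapt_no_clamp_trials")
  }
  # snap the first window onto the block grid counted from trial 1, so
  # windows tile the experiment (with 96 = two schedule blocks, window 1
  # starts exactly at the first exposure trial)
  first_trial <- ((min(rows$trial) - 1L) %/% block_size) * block_size + 1L
  last_trial <- max(rows$trial)
  n_win <- ceiling((last_trial - first_trial + 1) / block_size)
  rows$window <- (rows$trial - first_trial) %/% block_size + 1L
  if (!"participant" %in% names(rows)) rows$participant <- 1L

  tidyr::expand_grid(participant = unique(rows$participant),
                     window = seq_len(n_win)) |>
    purrr::pmap(function(participant, window) {
      pp <- rows[rows$participant == participant & rows$window == window, ]
      base <- tibble::tibble(
        participant = participant, window = window,
        trial_start = first_trial + (window - 1L) * block_size,
        trial_end = min(first_trial + window * block_size - 1L, last_trial),
        n_profiles = nrow(pp)
      )
      if (nrow(pp) == 0L) {
        return(dplyr::mutate(base, alpha = NA_real_, omega = NA_real_,
                             fitted = FALSE))
      }
      fit <- suppressWarnings(fit_encoding_model(pp, "weighted", B = B))
      dplyr::mutate(base, alpha = fit$alpha, omega = fit$omega, fitted = TRUE)
    }) |>
    purrr::list_rbind()
}
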