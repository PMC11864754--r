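# Model-level pipeline: weights -> mixture compensation profile -> comparison
# statistics (RMSE, phase shift, decay, BIC).

#' Frame weights for a test workspace under a weighting model
#'
#' Convenience dispatcher over [redyn_weights()], [energy_weights()] and
#' [smoothness_weights()] using an experiment configuration.
#'
#' @param config A [experiment_config()].
#' @param ws `"test1"` or `"test2"`.
#' @param model Weighting model.
#' @param noise A [noise_spec()] (Re-Dyn model only).
#' @param dt Movement sampling interval, s.
#' @return A `frame_weights` data frame.
#' @export
predict_weights <- function(config, ws, model = c("redyn", "energy", "smoothness"),
                            noise = noise_spec(), dt = 0.002) {
  model <- match.arg(model)
  if (model == "redyn") {
    redyn_weights(config$geometry, config$workspaces$training,
                  config$workspaces[[ws]], config$field, noise = noise,
                  dt = dt, hand_in_train = config$hand_in_train,
                  rotation = config$rotations[[ws]])
  } else {
    fc <- frame_compensation(config, ws, dt = dt)
    if (model == "energy") energy_weights(fc$lateral, fc$directions)
    else smoothness_weights(fc$lateral, fc$directions)
  }
}

#' Mixture compensation profile from frame weights
#'
#' The mixture force is linear in the frame forces, and the compensation
#' slope is linear in the recorded force, so the mixture compensation curve
#' is the per-direction weighted sum of the frame compensation curves.
#'
#' @param weights A `frame_weights` data frame.
#' @param frame_slopes D x 3 matrix of frame compensation slopes
#'   (cartesian, joint, object), as produced by [frame_compensation()].
#' @param workspace Workspace label for the result.
#' @return A `compensation_profile`.
#' @export
mixture_profile <- function(weights, frame_slopes, workspace = NA_character_) {
  wm <- as.matrix(weights[, c("cartesian", "joint", "object")])
  if (nrow(wm) == 1L) wm <- wm[rep(1L, nrow(frame_slopes)), , drop = FALSE]
  stopifnot(nrow(wm) == nrow(frame_slopes))
  as_compensation_profile(rowSums(wm * frame_slopes), weights$direction,
                          workspace)
}

#' Compensation profile of the learned field itself
#'
#' The reference curve all phase shifts are measured against: the
#' compensation profile of the scaled field in the training workspace
#' (approximately `cos(2 alpha)`).
#'
#' @inheritParams predict_weights
#' @return A `compensation_profile`.
#' @export
field_profile <- function(config, dt = 0.002) {
  fc <- frame_compensation(config, "training", dt = dt)
  as_compensation_profile(fc$slopes[, "cartesian"], fc$directions, "field")
}

#' Compare weighting models against experimental compensation profiles
#'
#' For each test workspace and each model, builds the predicted mixture
#' compensation curve, scales it by the decay factor (the fitted-optimal
#' model absorbs decay in its weights instead), and reports RMSE, the phase
#' error between prediction and data, and the decay factor.  Residuals are
#' pooled across workspaces per model for the BIC comparison against the
#' zero-force (no generalization) null; degrees of freedom are 1 for the
#' predictive models (the decay factor) and 3 for the fitted-optimal model.
#'
#' @param config A [experiment_config()].
#' @param profiles Named list of experimental `compensation_profile`s for
#'   `"test1"` and/or `"test2"`.
#' @param noise A [noise_spec()] for the Re-Dyn weights.
#' @param models Models to include.
#' @param dt Movement sampling interval, s.
#' @param bic_n Number of data points used in the BIC penalty; defaults to
#'   the pooled residual count (pass 128 to reproduce the pooled
#'   four-experiment accounting).
#' @return List with `table` (one row per model x workspace: rmse,
#'   phase_error, lambda), `bic` (one row per model: k, n, bic,
#'   bic_improvement), `residuals` (named list of pooled residual vectors)
#'   and `predictions` (per workspace per model `compensation_profile`s,
#'   decay-scaled).
#' @export
model_comparison <- function(config, profiles, noise = noise_spec(),
                             models = c("redyn", "energy", "smoothness", "optimal"),
                             dt = 0.002, bic_n = NULL) {
  k_map <- c(redyn = 1L, energy = 1L, smoothness = 1L, optimal = 3L)
  models <- match.arg(models, several.ok = TRUE)
  ws_names <- intersect(c("test1", "test2"), names(profiles))
  if (!length(ws_names)) stop("profiles must be named 'test1'/'test2'")
  rows <- list(); residuals <- stats::setNames(vector("list", length(models)), models)
  observed_all <- c(); predictions <- list()
  for (ws in ws_names) {
    fc <- frame_compensation(config, ws, dt = dt)
    y <- .profile_values(profiles[[ws]])
    observed_all <- c(observed_all, y)
    for (m in models) {
      if (m == "optimal") {
        fit <- fit_optimal_weights(y, fc$slopes)
        pred <- as.numeric(fc$slopes %*% fit$weights)
        lambda <- NA_real_
      } else {
        w <- predict_weights(config, ws, model = m, noise = noise, dt = dt)
        mix <- mixture_profile(w, fc$slopes, ws)
        lambda <- decay_factor(y, mix)
        pred <- lambda * .profile_values(mix)
      }
      res <- y - pred
      residuals[[m]] <- c(residuals[[m]], res)
      predictions[[ws]][[m]] <- as_compensation_profile(pred, fc$directions, ws)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, workspace = ws,
        rmse = sqrt(mean(res^2)),
        phase_error = phase_shift(pred, y),
        lambda = lambda)
    }
  }
  n <- if (is.null(bic_n)) length(observed_all) else bic_n
  bic <- do.call(rbind, lapply(models, function(m) {
    data.frame(model = m, k = k_map[[m]], n = n,
               bic = model_bic(residuals[[m]], k_map[[m]], n),
               bic_improvement = bic_improvement(residuals[[m]], k_map[[m]],
                                                 observed_all, n))
  }))
  list(table = do.call(rbind, rows), bic = bic,
       residuals = residuals, observed = observed_all,
       predictions = predictions)
}
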