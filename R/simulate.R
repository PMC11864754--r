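# Synthetic participants: force-channel forces generated from a configurable
# ground-truth frame mixture, standing in for behavioural recordings.

#' Ground truth for a synthetic participant
#'
#' The generative model the synthetic experiment assumes: in the test
#' workspaces the predictive lateral force on channel trials is
#' `lambda * (w_c F_cart + w_j F_joint + w_o F_obj)` plus i.i.d. Gaussian
#' noise per sample; in the training workspace it is the undecayed learned
#' field plus the same noise.
#'
#' @param weights Frame mixture: length-3 `c(w_c, w_j, w_o)` applied in all
#'   directions, or a `frame_weights` data frame for per-direction weights.
#' @param lambda Named decay factors `c(test1 = , test2 = )`.
#' @param noise_sd Per-sample channel-force noise SD in N.  Default 10% of
#'   the peak perfect-compensation force (0.1 * gain * peak speed).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(weights = c(1, 0, 0),
                         lambda = c(test1 = 1, test2 = 1),
                         noise_sd = NULL) {
  if (inherits(weights, "frame_weights")) {
    wm <- as.matrix(weights[, c("cartesian", "joint", "object")])
    dirs <- weights$direction
  } else {
    if (length(weights) != 3L || any(weights < 0)) {
      stop("weights must be three non-negative values or a frame_weights object")
    }
    wm <- matrix(weights, nrow = 1L,
                 dimnames = list(NULL, c("cartesian", "joint", "object")))
    dirs <- NULL
  }
  structure(list(weights = wm, directions = dirs,
                 lambda = lambda, noise_sd = noise_sd),
            class = "ground_truth")
}

.gt_weights_for <- function(gt, direction) {
  if (is.null(gt$directions)) return(gt$weights[1L, ])
  i <- which.min(abs(wrap180(gt$directions - direction)))
  gt$weights[i, ]
}

#' Simulate a participant of one generalization experiment
#'
#' Builds the full trial schedule and fills every force-channel trial with a
#' time-sampled hand velocity (ideal minimum-jerk) and a lateral force
#' generated from the ground-truth frame mixture.  Generalization-phase
#' channel trials in the test workspaces carry the decayed mixture force;
#' training-workspace channel trials carry the undecayed learned field;
#' pre-exposure channel trials carry noise only (no adaptation yet).
#' Null-field and force-field trials carry kinematics metadata only (no
#' perturbation dynamics are simulated).
#'
#' @param config A [experiment_config()].
#' @param truth A [ground_truth()].
#' @param seed Integer seed (drives both the schedule and the force noise).
#' @param dt,radius,peak_speed Movement sampling parameters.
#' @return An object of class `redyn_participant`: list with `schedule` (see
#'   [build_schedule()]) and `samples` (one row per time sample of each FC
#'   trial: `trial`, `phase`, `workspace`, `condition`, `direction`, `rep`,
#'   `t`, `vx`, `vy`, `lateral`).
#' @export
simulate_participant <- function(config, truth = ground_truth(),
                                 seed = 1L, dt = 0.002,
                                 radius = 0.05, peak_speed = 0.5) {
  stopifnot(inherits(config, "redyn_experiment"), inherits(truth, "ground_truth"))
  sched <- build_schedule(config$id, seed)
  noise_sd <- if (is.null(truth$noise_sd)) 0.1 * 0.16 * peak_speed else truth$noise_sd
  dirs <- standard_directions()

  # template lateral-force series per workspace x direction
  templates <- list()
  velocities <- list()
  for (ws in .WORKSPACES) {
    for (d in dirs) {
      key <- paste(ws, d)
      fp <- frame_profiles(config, ws, d, dt, radius, peak_speed)
      velocities[[key]] <- fp$movement$velocity
      if (ws == "training") {
        templates[[key]] <- fp$lateral[, "cartesian"]
      } else {
        w <- .gt_weights_for(truth, d)
        lam <- truth$lambda[[ws]]
        templates[[key]] <- lam * as.numeric(fp$lateral %*% w)
      }
    }
  }

  fc_idx <- which(sched$condition == "FC")
  samples <- vector("list", length(fc_idx))
  for (j in seq_along(fc_idx)) {
    i <- fc_idx[j]
    key <- paste(sched$workspace[i], sched$direction[i])
    vel <- velocities[[key]]
    n <- nrow(vel)
    base <- if (sched$phase[i] == "pre_exposure") numeric(n) else templates[[key]]
    lat <- base + stats::rnorm(n, 0, noise_sd)
    samples[[j]] <- data.frame(trial = sched$trial[i], phase = sched$phase[i],
                               workspace = sched$workspace[i],
                               condition = "FC",
                               direction = sched$direction[i],
                               rep = sched$rep[i],
                               t = (seq_len(n) - 1L) * dt,
                               vx = vel[, 1], vy = vel[, 2], lateral = lat)
  }
  structure(list(schedule = sched, samples = do.call(rbind, samples)),
            class = "redyn_participant",
            experiment = config$id, seed = as.integer(seed),
            noise_sd = noise_sd, truth = truth)
}

#' Force-compensation profiles of a simulated (or recorded) participant
#'
#' Computes the per-trial compensation slope of every generalization-phase
#' force-channel trial and averages repetitions into one
#' [compensation_profile()] per workspace.
#'
#' @param samples A `redyn_participant` or its long-format `samples` data
#'   frame.
#' @param phase Phase to analyse.
#' @return Named list of `compensation_profile`s (`training`, `test1`,
#'   `test2`).
#' @export
participant_profiles <- function(samples, phase = "generalization") {
  if (inherits(samples, "redyn_participant")) samples <- samples$samples
  samples <- samples[samples$phase == phase & samples$condition == "FC", ]
  if (!nrow(samples)) stop(sprintf("no force-channel samples in phase '%s'", phase))
  out <- list()
  for (ws in intersect(.WORKSPACES, unique(samples$workspace))) {
    sub <- samples[samples$workspace == ws, ]
    trials <- unique(sub$trial)
    slope <- numeric(length(trials)); direction <- numeric(length(trials))
    for (j in seq_along(trials)) {
      tr <- sub[sub$trial == trials[j], ]
      slope[j] <- force_compensation(tr$lateral, cbind(tr$vx, tr$vy))
      direction[j] <- tr$direction[1]
    }
    out[[ws]] <- compensation_profile(direction, slope, workspace = ws)
  }
  out
}
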