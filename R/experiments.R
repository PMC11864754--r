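#' Workspace configurations of the four generalization experiments
#'
#' Returns the arm geometry, training and test workspaces, force field and
#' frame-prediction plumbing for one of the four experiments.  Workspace
#' centres are set by the printed joint angles; the shoulder is placed so
#' that the training-workspace centre sits at the device origin, mirroring
#' the calibration procedure.
#'
#' Experiment 3 reuses the experiment 2 workspaces but movements are
#' executed by the hand in the training workspace while the controlled
#' point is the tip of a rigid virtual pole reaching into the test
#' workspace; the object rotation is then set by the pole direction
#' ([pole_rotation()]) and the joint-frame prediction collapses to the
#' Cartesian one.
#'
#' @param id Experiment id, 1 to 4.
#' @param upper_arm,forearm Arm segment lengths in metres.
#' @return An object of class `redyn_experiment`: list with `id`, `geometry`,
#'   `workspaces` (named list `training`, `test1`, `test2`), `field`,
#'   `hand_in_train` flag and per-test-workspace object `rotations` (deg).
#' @export
experiment_config <- function(id, upper_arm = 0.33, forearm = 0.34) {
  if (!id %in% 1:4) stop(sprintf("unknown experiment id '%s' (must be 1..4)", id))
  q <- switch(id,
    `1` = list(training = c(50, 90), test1 = c(50, 55), test2 = c(75, 45)),
    `2` = list(training = c(40, 70), test1 = c(75, 85), test2 = c(75, 50)),
    `3` = list(training = c(40, 70), test1 = c(75, 85), test2 = c(75, 50)),
    `4` = list(training = c(55, 75), test1 = c(30, 100), test2 = c(80, 50)))
  # place the shoulder so the training centre is at the origin
  rel <- forward_kinematics(arm_geometry(upper_arm, forearm), q$training)
  geom <- arm_geometry(upper_arm, forearm, shoulder = -rel)
  ws <- lapply(names(q), function(nm) workspace(geom, nm, q[[nm]]))
  names(ws) <- names(q)
  hand_in_train <- id == 3
  rot <- if (hand_in_train) {
    c(test1 = pole_rotation(geom, ws$training, ws$test1),
      test2 = pole_rotation(geom, ws$training, ws$test2))
  } else {
    c(test1 = object_rotation(geom, ws$training, ws$test1),
      test2 = object_rotation(geom, ws$training, ws$test2))
  }
  structure(list(id = as.integer(id), geometry = geom, workspaces = ws,
                 field = scaled_curl_field(), hand_in_train = hand_in_train,
                 rotations = rot),
            class = "redyn_experiment")
}

#' @export
print.redyn_experiment <- function(x, ...) {
  cat(sprintf("Generalization experiment %d%s\n", x$id,
              if (x$hand_in_train) " (virtual-pole: hand stays in the training workspace)" else ""))
  for (ws in x$workspaces) print(ws)
  cat(sprintf("Object rotations: test1 %+.1f deg, test2 %+.1f deg\n",
              x$rotations["test1"], x$rotations["test2"]))
  invisible(x)
}

#' The 16 movement directions of the experimental protocol
#' @return Numeric vector of 16 equally spaced directions, degrees.
#' @export
standard_directions <- function() seq(0, 360 - 22.5, by = 22.5)

#' Per-frame generalized force profiles for one test-workspace movement
#'
#' Computes the Cartesian, joint and object frame predictions for a single
#' movement direction in a test workspace of an experiment.
#'
#' @param config A [experiment_config()].
#' @param ws `"test1"`, `"test2"` or `"training"` (in the training workspace
#'   all three frames coincide with the learned field).
#' @param direction Movement direction, degrees.
#' @param dt Sampling interval, s.
#' @param radius,peak_speed Movement geometry, m and m/s.
#' @return List with `movement` and n x 2 force matrices `cartesian`,
#'   `joint`, `object`, plus `lateral` (n x 3 signed lateral components,
#'   columns cartesian/joint/object).
#' @export
frame_profiles <- function(config, ws, direction, dt = 0.002,
                           radius = 0.05, peak_speed = 0.5) {
  wsp <- config$workspaces[[ws]]
  if (is.null(wsp)) stop(sprintf("unknown workspace '%s'", ws))
  mv <- min_jerk_movement(wsp$center, direction, radius, peak_speed, dt)
  cart <- cartesian_prediction(mv, config$field)
  if (ws == "training") {
    joint <- cart
    object <- cart
  } else if (config$hand_in_train) {
    # hand kinematics are identical to training-workspace kinematics
    joint <- cart
    object <- object_prediction(config$rotations[[ws]], mv, config$field)
  } else {
    joint <- joint_prediction(config$geometry, config$workspaces$training,
                              wsp, mv, config$field)
    object <- object_prediction(config$rotations[[ws]], mv, config$field)
  }
  lateral <- cbind(cartesian = signed_lateral_component(cart, direction),
                   joint = signed_lateral_component(joint, direction),
                   object = signed_lateral_component(object, direction))
  list(movement = mv, cartesian = cart, joint = joint, object = object,
       lateral = lateral)
}

#' Per-frame compensation slopes across all movement directions
#'
#' For every direction, regresses each frame's predicted lateral force
#' against the perfect-compensation signal ([force_compensation()]), giving
#' the model force-compensation curves of the three frames.
#'
#' @inheritParams frame_profiles
#' @param directions Movement directions, degrees.
#' @return List with `slopes` (length(directions) x 3 matrix), `directions`,
#'   and `lateral` (list of three n x D lateral-force matrices used by the
#'   energy and smoothness weighting models).
#' @export
frame_compensation <- function(config, ws, directions = standard_directions(),
                               dt = 0.002, radius = 0.05, peak_speed = 0.5) {
  D <- length(directions)
  slopes <- matrix(NA_real_, D, 3L,
                   dimnames = list(NULL, c("cartesian", "joint", "object")))
  lat <- NULL
  for (i in seq_len(D)) {
    fp <- frame_profiles(config, ws, directions[i], dt, radius, peak_speed)
    if (is.null(lat)) {
      lat <- list(cartesian = matrix(NA_real_, nrow(fp$lateral), D),
                  joint = matrix(NA_real_, nrow(fp$lateral), D),
                  object = matrix(NA_real_, nrow(fp$lateral), D))
    }
    for (k in 1:3) {
      slopes[i, k] <- force_compensation(fp$lateral[, k], fp$movement$velocity)
      lat[[k]][, i] <- fp$lateral[, k]
    }
  }
  list(slopes = slopes, directions = directions, lateral = lat, dt = dt)
}
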