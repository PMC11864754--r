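# Literature scenarios: per-frame generalized force patterns and Re-Dyn
# weights for four classic force-field generalization designs.
#
# The source papers do not all print their workspace joint angles; the
# angles below are estimates reconstructed from each study's figures and are
# shipped as editable presets (see the scenario's `estimated` flag).

#' Prior-study generalization scenario
#'
#' Arm geometry, training/test workspaces and viscous field for one of four
#' classic studies.  `"criscimagna2003"` is the inter-limb (mirror) design:
#' the test workspace is the same spatial location reached with the mirrored
#' (left) arm, built with a reflected [arm_geometry()]; its centre posture
#' keeps the hand-segment orientation at 90 degrees so the object frame
#' coincides with the Cartesian one.  `"berniker2014"` places the two
#' workspaces symmetrically about a near-midline axis.  All joint angles are
#' estimates (the original geometries are only sketched), and all fields are
#' unscaled viscous matrices ([prior_study_field()]).
#'
#' @param study Scenario name.
#' @param upper_arm,forearm Segment lengths, metres.
#' @return An object of class `study_scenario`: list with `name`,
#'   `geometry`, `test_geom`, `train_ws`, `test_ws`, `field`, `mirror`,
#'   `estimated`.
#' @export
study_scenario <- function(study = c("shadmehr1994", "malfait2002",
                                     "criscimagna2003", "berniker2014"),
                           upper_arm = 0.33, forearm = 0.34) {
  study <- match.arg(study)
  q <- switch(study,
    shadmehr1994    = list(train = c(15, 90), test = c(60, 90)),
    malfait2002     = list(train = c(20, 80), test = c(65, 80)),
    criscimagna2003 = list(train = c(30, 60), test = c(30, 60)),
    berniker2014    = list(train = c(50, 90), test = c(38, 90)))
  geom <- arm_geometry(upper_arm, forearm)
  train_ws <- workspace(geom, "training", q$train)
  mirror <- study == "criscimagna2003"
  if (mirror) {
    # left arm: shoulder reflected about the vertical through the workspace
    # centre, so the same spatial centre is reached at the mirrored posture
    cx <- train_ws$center[1]
    test_geom <- arm_geometry(upper_arm, forearm,
                              shoulder = c(2 * cx - geom$shoulder[1],
                                           geom$shoulder[2]),
                              reflect = TRUE)
    test_ws <- workspace(test_geom, "test", q$test)
  } else {
    test_geom <- geom
    test_ws <- workspace(geom, "test", q$test)
  }
  structure(list(name = study, geometry = geom, test_geom = test_geom,
                 train_ws = train_ws, test_ws = test_ws,
                 field = prior_study_field(study), mirror = mirror,
                 estimated = TRUE),
            class = "study_scenario")
}

#' Per-frame generalized force patterns of a prior-study scenario
#'
#' For each movement direction, the time-mean generalized force vector at
#' the test workspace under each coordinate frame.
#'
#' @param scenario A [study_scenario()].
#' @param directions Movement directions, degrees (8 by default, matching
#'   the classic centre-out designs).
#' @param radius,peak_speed,dt Movement parameters.
#' @return List of three D x 2 matrices (`cartesian`, `joint`, `object`) of
#'   mean force vectors (N), plus `directions`.
#' @export
study_force_patterns <- function(scenario, directions = seq(0, 315, by = 45),
                                 radius = 0.05, peak_speed = 0.5, dt = 0.002) {
  stopifnot(inherits(scenario, "study_scenario"))
  rot <- object_rotation(scenario$geometry, scenario$train_ws,
                         scenario$test_ws, scenario$test_geom)
  out <- list(cartesian = NULL, joint = NULL, object = NULL)
  for (d in directions) {
    mv <- min_jerk_movement(scenario$test_ws$center, d, radius, peak_speed, dt)
    cart <- cartesian_prediction(mv, scenario$field)
    joint <- joint_prediction(scenario$geometry, scenario$train_ws,
                              scenario$test_ws, mv, scenario$field,
                              test_geom = scenario$test_geom)
    object <- object_prediction(rot, mv, scenario$field)
    out$cartesian <- rbind(out$cartesian, colMeans(cart))
    out$joint <- rbind(out$joint, colMeans(joint))
    out$object <- rbind(out$object, colMeans(object))
  }
  out$directions <- directions
  out
}

#' Re-Dyn weights for a prior-study scenario
#'
#' @inheritParams study_force_patterns
#' @param noise A [noise_spec()].
#' @return A `frame_weights` data frame.
#' @export
study_weights <- function(scenario, noise = noise_spec(),
                          directions = seq(0, 315, by = 45),
                          radius = 0.05, peak_speed = 0.5, dt = 0.002) {
  stopifnot(inherits(scenario, "study_scenario"))
  redyn_weights(scenario$geometry, scenario$train_ws, scenario$test_ws,
                scenario$field, noise = noise, directions = directions,
                radius = radius, peak_speed = peak_speed, dt = dt,
                test_geom = scenario$test_geom)
}
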