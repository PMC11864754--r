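# Per-frame predictions of how a learned force field generalizes to a test
# workspace.  Force profiles are plain n x 2 matrices (N), one row per
# movement sample.
#
# The internal .*_force_xy functions operate on conformable arrays of
# positions/velocities so the Monte-Carlo weighting code can evaluate
# thousands of perturbed movements in one vectorized pass.

# Cartesian frame: forces depend on velocity only, so the learned field is
# simply replayed on the test movement.
.cartesian_force_xy <- function(field, vx, vy) .field_force_xy(field, vx, vy)

# Joint frame: learned torques tau(thetadot) transferred through the test
# configuration,
#   F = Jtest^-T Jtrain^T B(Jtrain Jtest^-1 v) Jtrain Jtest^-1 v,
# with the Jacobians evaluated at the instantaneous postures of the test
# path and of the geometrically matched training path.
.joint_force_xy <- function(field, train_geom, test_geom,
                            train_x, train_y, test_x, test_y, vx, vy) {
  qt <- .ik_rad(test_geom, test_x, test_y)
  qr <- .ik_rad(train_geom, train_x, train_y)
  Jt <- .jac_rad(test_geom, qt$ts, qt$te)
  Jr <- .jac_rad(train_geom, qr$ts, qr$te)
  Jti <- m22_inverse(Jt$a11, Jt$a12, Jt$a21, Jt$a22)
  thetadot <- m22_apply(Jti$a11, Jti$a12, Jti$a21, Jti$a22, vx, vy)
  vt <- m22_apply(Jr$a11, Jr$a12, Jr$a21, Jr$a22, thetadot$x, thetadot$y)
  Bf <- .field_force_xy(field, vt$x, vt$y)
  tau <- m22_apply(Jr$a11, Jr$a21, Jr$a12, Jr$a22, Bf$x, Bf$y)      # Jr^T
  m22_apply(Jti$a11, Jti$a21, Jti$a12, Jti$a22, tau$x, tau$y)       # Jt^-T
}

# Object frame: rotate velocities back by theta, apply the learned field,
# rotate the forces forward.  theta in radians, conformable with vx/vy.
.object_force_xy <- function(field, theta, vx, vy) {
  ct <- cos(theta); st <- sin(theta)
  vrx <- ct * vx + st * vy
  vry <- -st * vx + ct * vy
  F0 <- .field_force_xy(field, vrx, vry)
  list(x = ct * F0$x - st * F0$y, y = st * F0$x + ct * F0$y)
}

#' Cartesian-frame generalized force prediction
#'
#' Under an extrinsic (Cartesian) representation the learned forces are
#' invariant to arm posture, so the prediction is the learned field applied
#' to the test movement's velocities.
#'
#' @param movement A [min_jerk_movement()].
#' @param field A [field_spec()].
#' @return n x 2 matrix of forces (N).
#' @export
cartesian_prediction <- function(movement, field) {
  field_force(field, movement$velocity)
}

#' Joint-frame generalized force prediction
#'
#' The field is learned as a map from joint velocities to joint torques at
#' the training posture and replayed through the test-arm Jacobians.  With
#' `evaluate = "instantaneous"` (default) the Jacobians follow the
#' instantaneous postures along the test path and along the geometrically
#' matched training path (same direction and time-normalized samples,
#' translated to the training workspace); `evaluate = "center"` freezes both
#' at the workspace-centre postures for sensitivity analysis.
#'
#' @param geom Training-arm [arm_geometry()].
#' @param train_ws,test_ws [workspace()] objects.
#' @param movement Test-workspace [min_jerk_movement()].
#' @param field A [field_spec()].
#' @param test_geom Test-arm geometry; defaults to `geom` (same arm).  Pass a
#'   mirrored geometry for inter-limb transfer scenarios.
#' @param evaluate Jacobian evaluation mode.
#' @return n x 2 matrix of forces (N).
#' @export
joint_prediction <- function(geom, train_ws, test_ws, movement, field,
                             test_geom = geom,
                             evaluate = c("instantaneous", "center")) {
  evaluate <- match.arg(evaluate)
  v <- movement$velocity
  if (evaluate == "instantaneous") {
    px <- movement$position[, 1]; py <- movement$position[, 2]
    tx <- px - test_ws$center[1] + train_ws$center[1]
    ty <- py - test_ws$center[2] + train_ws$center[2]
    f <- .joint_force_xy(field, geom, test_geom, tx, ty, px, py, v[, 1], v[, 2])
  } else {
    qtr <- deg2rad(train_ws$q); qte <- deg2rad(test_ws$q)
    ptr <- .fk_rad(geom, qtr[1], qtr[2]); pte <- .fk_rad(test_geom, qte[1], qte[2])
    f <- .joint_force_xy(field, geom, test_geom,
                         rep(ptr$x, nrow(v)), rep(ptr$y, nrow(v)),
                         rep(pte$x, nrow(v)), rep(pte$y, nrow(v)),
                         v[, 1], v[, 2])
  }
  cbind(f$x, f$y)
}

#' Object-frame generalized force prediction
#'
#' Forces belong to the hand-held object: the velocity is rotated back to
#' the training orientation, the learned field applied, and the force
#' rotated forward by the change in object orientation `rotation`.
#'
#' @param rotation Object rotation between training and test workspace,
#'   degrees (see [object_rotation()]).
#' @inheritParams cartesian_prediction
#' @return n x 2 matrix of forces (N).
#' @export
object_prediction <- function(rotation, movement, field) {
  f <- .object_force_xy(field, deg2rad(rotation),
                        movement$velocity[, 1], movement$velocity[, 2])
  cbind(f$x, f$y)
}

#' Object rotation angle between two workspaces
#'
#' The change in hand-segment orientation between the workspace-centre
#' postures ([hand_segment_orientation()]); this is the single rotation the
#' object frame applies to the learned forces.
#'
#' @inheritParams joint_prediction
#' @return Angle in degrees, wrapped to (-180, 180].
#' @export
object_rotation <- function(geom, train_ws, test_ws, test_geom = geom) {
  wrap180(hand_segment_orientation(test_geom, test_ws$q) -
            hand_segment_orientation(geom, train_ws$q))
}

#' Object rotation for a virtual-pole (tool-tip) workspace
#'
#' When movements are executed in the training workspace but the controlled
#' point is the tip of a rigid virtual pole, the object orientation in the
#' test workspace is the pole direction: the vector joining the training and
#' test workspace centres.  The rotation is that direction minus the
#' training hand-segment orientation.
#'
#' @inheritParams joint_prediction
#' @return Angle in degrees, wrapped to (-180, 180].
#' @export
pole_rotation <- function(geom, train_ws, test_ws) {
  d <- test_ws$center - train_ws$center
  if (sqrt(sum(d^2)) < 1e-12) return(0)
  wrap180(rad2deg(atan2(d[2], d[1])) - hand_segment_orientation(geom, train_ws$q))
}

#' Weighted mixture of frame predictions
#'
#' Sample-wise weighted sum `w_c * cart + w_j * joint + w_o * object`.
#'
#' @param weights Numeric length-3 `c(w_c, w_j, w_o)`.
#' @param cart,joint,object n x 2 force matrices sampled identically.
#' @return n x 2 matrix of forces (N).
#' @export
mixture_prediction <- function(weights, cart, joint, object) {
  if (length(weights) != 3L) stop("weights must be c(w_c, w_j, w_o)")
  if (!all(dim(cart) == dim(joint)) || !all(dim(cart) == dim(object))) {
    stop("frame force profiles must be sampled identically")
  }
  weights[1] * cart + weights[2] * joint + weights[3] * object
}
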