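#' Planar two-link arm geometry
#'
#' Describes the arm model used throughout the package: an upper arm of length
#' `upper_arm` and a forearm (elbow-to-handle) of length `forearm`, rooted at
#' `shoulder`.  The shoulder angle is measured counter-clockwise from the +x
#' axis and the elbow angle is the flexion between the upper-arm and forearm
#' directions, so the forearm points along `shoulder_angle + elbow_angle`.
#' All angles at the API surface are in degrees.
#'
#' `reflect = TRUE` builds the mirror-image (left) arm: positions relative to
#' the shoulder are reflected about the vertical axis.  This is used for
#' inter-limb transfer scenarios.
#'
#' @param upper_arm Upper-arm length in metres (default 0.33).
#' @param forearm Forearm length in metres (default 0.34).
#' @param shoulder Shoulder position, metres, length-2 numeric.
#' @param reflect Logical; mirror the arm about the vertical through the
#'   shoulder.
#' @return An object of class `arm_geometry`.
#' @examples
#' geom <- arm_geometry()
#' forward_kinematics(geom, c(50, 90))
#' @export
arm_geometry <- function(upper_arm = 0.33, forearm = 0.34,
                         shoulder = c(0, 0), reflect = FALSE) {
  if (!is.numeric(upper_arm) || upper_arm <= 0 || !is.numeric(forearm) || forearm <= 0) {
    stop("segment lengths must be strictly positive")
  }
  structure(
    list(upper_arm = as.numeric(upper_arm), forearm = as.numeric(forearm),
         shoulder = .assert_point(shoulder, "shoulder"),
         reflect = isTRUE(reflect)),
    class = "arm_geometry")
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat(sprintf("Two-link planar arm: L1 = %.3f m, L2 = %.3f m, shoulder = (%.3f, %.3f)%s\n",
              x$upper_arm, x$forearm, x$shoulder[1], x$shoulder[2],
              if (x$reflect) " [mirrored]" else ""))
  invisible(x)
}

.check_joint_state <- function(q) {
  if (!is.numeric(q) || length(q) != 2L || any(!is.finite(q))) {
    stop("joint state must be numeric c(shoulder_angle, elbow_angle) in degrees")
  }
  as.numeric(q)
}

# Vectorized forward kinematics, radians in, world coordinates out.
.fk_rad <- function(geom, ts, te) {
  sgn <- if (geom$reflect) -1 else 1
  x <- geom$upper_arm * cos(ts) + geom$forearm * cos(ts + te)
  y <- geom$upper_arm * sin(ts) + geom$forearm * sin(ts + te)
  list(x = geom$shoulder[1] + sgn * x, y = geom$shoulder[2] + y)
}

#' Forward kinematics of the two-link arm
#'
#' Hand (handle-centre) position for a joint configuration.
#'
#' @param geom An [arm_geometry()].
#' @param q Joint state `c(shoulder_angle, elbow_angle)` in degrees.
#' @return Hand position, metres, length-2 numeric.
#' @export
forward_kinematics <- function(geom, q) {
  q <- .check_joint_state(q)
  p <- .fk_rad(geom, deg2rad(q[1]), deg2rad(q[2]))
  c(p$x, p$y)
}

# Vectorized inverse kinematics on world coordinates; returns radians.
# Always selects the elbow-flexed branch, elbow in (0, pi).
.ik_rad <- function(geom, x, y, tol = 1e-9) {
  sgn <- if (geom$reflect) -1 else 1
  rx <- sgn * (x - geom$shoulder[1])
  ry <- y - geom$shoulder[2]
  L1 <- geom$upper_arm; L2 <- geom$forearm
  r <- sqrt(rx^2 + ry^2)
  if (any(r > L1 + L2 + tol) || any(r < abs(L1 - L2) - tol)) {
    stop(sprintf(
      "point at distance %.6f m from the shoulder is unreachable (limits [%.6f, %.6f] m)",
      max(r), abs(L1 - L2), L1 + L2))
  }
  c2 <- pmin(1, pmax(-1, (r^2 - L1^2 - L2^2) / (2 * L1 * L2)))
  te <- acos(c2)
  ts <- atan2(ry, rx) - atan2(L2 * sin(te), L1 + L2 * cos(te))
  list(ts = ts, te = te)
}

#' Inverse kinematics of the two-link arm
#'
#' Joint angles that place the hand at `p`, on the elbow-flexed branch
#' (elbow angle in (0, 180) degrees).  Errors if `p` lies outside the annulus
#' of reachable points (radial tolerance 1e-9 m).
#'
#' @inheritParams forward_kinematics
#' @param p Hand position, metres.
#' @return `c(shoulder_angle, elbow_angle)` in degrees.
#' @export
inverse_kinematics <- function(geom, p) {
  p <- .assert_point(p, "p")
  q <- .ik_rad(geom, p[1], p[2])
  c(rad2deg(q$ts) %% 360, rad2deg(q$te))
}

# Jacobian entries at (ts, te) radians, vectorized.  World-frame: the mirror
# reflection premultiplies by diag(-1, 1), i.e. negates the first row.
.jac_rad <- function(geom, ts, te) {
  L1 <- geom$upper_arm; L2 <- geom$forearm
  s1 <- sin(ts); c1 <- cos(ts); s12 <- sin(ts + te); c12 <- cos(ts + te)
  sgn <- if (geom$reflect) -1 else 1
  list(a11 = sgn * (-L1 * s1 - L2 * s12), a12 = sgn * (-L2 * s12),
       a21 = L1 * c1 + L2 * c12,          a22 = L2 * c12)
}

#' Arm Jacobian
#'
#' The 2x2 map from joint angular velocity (rad/s) to hand velocity (m/s),
#' i.e. the analytic partial derivatives of [forward_kinematics()] with
#' respect to the joint angles in radians.
#'
#' @inheritParams forward_kinematics
#' @return A 2x2 numeric matrix (m/rad).
#' @export
jacobian <- function(geom, q) {
  q <- .check_joint_state(q)
  j <- .jac_rad(geom, deg2rad(q[1]), deg2rad(q[2]))
  matrix(c(j$a11, j$a21, j$a12, j$a22), 2L, 2L)
}

#' Shoulder-to-hand orientation
#'
#' Planar angle of the vector from the shoulder to the hand, degrees in
#' (-180, 180].  Invariant to uniform scaling of both segment lengths.
#'
#' @inheritParams forward_kinematics
#' @return Angle in degrees.
#' @export
hand_orientation <- function(geom, q) {
  p <- forward_kinematics(geom, q) - geom$shoulder
  if (sqrt(sum(p^2)) < 1e-12) stop("hand coincides with the shoulder; orientation undefined")
  wrap180(rad2deg(atan2(p[2], p[1])))
}

#' Hand-segment (forearm) orientation
#'
#' World-frame direction of the forearm/handle segment, `shoulder_angle +
#' elbow_angle` for a right arm (reflected for a mirrored arm), degrees in
#' (-180, 180].  This is the orientation the object-centred frame rotates
#' with: a hand-held object keeps a fixed angle to the hand segment, so the
#' rotation applied to generalized forces is the change in this angle between
#' workspaces.
#'
#' @inheritParams forward_kinematics
#' @return Angle in degrees.
#' @export
hand_segment_orientation <- function(geom, q) {
  q <- .check_joint_state(q)
  ang <- q[1] + q[2]
  if (geom$reflect) ang <- 180 - ang
  wrap180(ang)
}

# vectorized variant on radians, used by the Monte-Carlo internals
.segment_orientation_rad <- function(geom, ts, te) {
  ang <- ts + te
  if (geom$reflect) ang <- pi - ang
  ang
}

#' Workspace defined by its centre posture
#'
#' A named workspace whose centre is where the hand sits at the given joint
#' configuration; the centre position is derived through
#' [forward_kinematics()].
#'
#' @inheritParams forward_kinematics
#' @param name Workspace label.
#' @return An object of class `redyn_workspace` with fields `name`, `q`
#'   (degrees) and `center` (metres).
#' @export
workspace <- function(geom, name, q) {
  q <- .check_joint_state(q)
  structure(list(name = as.character(name), q = q,
                 center = forward_kinematics(geom, q)),
            class = "redyn_workspace")
}

#' @export
print.redyn_workspace <- function(x, ...) {
  cat(sprintf("Workspace '%s': shoulder %.1f deg, elbow %.1f deg, centre (%.4f, %.4f) m\n",
              x$name, x$q[1], x$q[2], x$center[1], x$center[2]))
  invisible(x)
}
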