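#' Velocity-dependent force-field specification
#'
#' A planar viscous field `F = s(v) * B %*% v` with `B` a 2x2 viscosity
#' matrix (N s/m).  When `direction_scaled` is `TRUE` the field is the
#' direction-scaled curl field: the scaling factor `s` is
#' `cos(2 * direction(v))`, so rightward/leftward motion gets `s = +1`,
#' motion along the y axis gets `s = -1`, and motion at 45 degrees feels no
#' force.
#'
#' @param viscosity 2x2 numeric viscosity matrix, N s/m.
#' @param direction_scaled Logical; apply the `cos(2 alpha)` scaling.
#' @param name Optional label.
#' @return An object of class `field_spec`.
#' @seealso [scaled_curl_field()], [prior_study_field()]
#' @export
field_spec <- function(viscosity, direction_scaled = FALSE, name = "field") {
  viscosity <- matrix(as.numeric(viscosity), 2L, 2L)
  if (any(!is.finite(viscosity))) stop("viscosity matrix entries must be finite")
  structure(list(viscosity = viscosity,
                 direction_scaled = isTRUE(direction_scaled),
                 name = as.character(name)),
            class = "field_spec")
}

#' The direction-scaled curl field used in the generalization experiments
#'
#' `B = [[0, g], [-g, 0]]` with gain `g = 0.16` N s/m, scaled by
#' `cos(2 alpha)` where `alpha` is the instantaneous movement direction.
#'
#' @param gain Curl viscosity, N s/m.
#' @return A [field_spec()].
#' @export
scaled_curl_field <- function(gain = 0.16) {
  field_spec(rbind(c(0, gain), c(-gain, 0)), direction_scaled = TRUE,
             name = "scaled_curl")
}

#' Unscaled curl field
#' @param gain Curl viscosity, N s/m.
#' @return A [field_spec()].
#' @export
curl_field <- function(gain = 0.16) {
  field_spec(rbind(c(0, gain), c(-gain, 0)), direction_scaled = FALSE,
             name = "curl")
}

#' Viscosity matrices of classic generalization studies
#'
#' Named presets for the viscous fields of four earlier force-field
#' generalization studies (units N s/m); none of them is direction scaled.
#'
#' @param study One of `"shadmehr1994"`, `"malfait2002"`, `"criscimagna2003"`,
#'   `"berniker2014"`.
#' @return A [field_spec()].
#' @export
prior_study_field <- function(study = c("shadmehr1994", "malfait2002",
                                        "criscimagna2003", "berniker2014")) {
  study <- match.arg(study)
  B <- switch(study,
    shadmehr1994    = rbind(c(-10.1, -11.2), c(-11.2, 11.1)),
    malfait2002     = rbind(c(-20, -20), c(0, 0)),
    criscimagna2003 = rbind(c(0, 13), c(-13, 0)),
    berniker2014    = rbind(c(-10.1, -11.2), c(-11.2, 11.1)))
  field_spec(B, direction_scaled = FALSE, name = study)
}

# internal: field force on velocity components given as arrays
.field_force_xy <- function(spec, vx, vy) {
  B <- spec$viscosity
  s <- 1
  if (spec$direction_scaled) {
    s <- cos(2 * atan2(vy, vx))
    # at zero velocity the direction is undefined but B %*% 0 = 0 regardless
    s[vx == 0 & vy == 0] <- 1
  }
  list(x = s * (B[1, 1] * vx + B[1, 2] * vy),
       y = s * (B[2, 1] * vx + B[2, 2] * vy))
}

#' Force exerted by a field
#'
#' @param spec A [field_spec()].
#' @param velocity Hand velocity: length-2 numeric or an n x 2 matrix of
#'   per-sample velocities (m/s).
#' @return Force in N, same shape as `velocity`.
#' @export
field_force <- function(spec, velocity) {
  if (is.matrix(velocity)) {
    f <- .field_force_xy(spec, velocity[, 1], velocity[, 2])
    cbind(f$x, f$y)
  } else {
    velocity <- .assert_point(velocity, "velocity")
    f <- .field_force_xy(spec, velocity[1], velocity[2])
    c(f$x, f$y)
  }
}

#' Perfect-compensation force series
#'
#' The force needed to exactly oppose an unscaled curl field along a velocity
#' series: `B0 %*% v` per sample with `B0 = [[0, gain], [-gain, 0]]`.  Used
#' as the regression reference for force-compensation slopes; its signed
#' lateral component equals `gain * speed` and is positive in every
#' direction.
#'
#' @param velocity n x 2 matrix of velocities (m/s).
#' @param gain Curl viscosity, N s/m.
#' @return n x 2 matrix of forces (N).
#' @export
perfect_compensation_force <- function(velocity, gain = 0.16) {
  if (!is.matrix(velocity)) velocity <- matrix(velocity, ncol = 2L)
  field_force(curl_field(gain), velocity)
}

#' Signed lateral force component
#'
#' Projects planar forces onto the unit vector 90 degrees clockwise of the
#' movement direction, so clockwise-perturbing forces are positive and
#' counter-clockwise forces negative.  This is the sign convention under
#' which the mean lateral force of the scaled curl field traces
#' `+cos(2 alpha)`.
#'
#' @param force n x 2 matrix (or length-2 vector) of forces, N.
#' @param direction Movement direction `alpha`, degrees.
#' @return Numeric vector of signed lateral forces, N.
#' @export
signed_lateral_component <- function(force, direction) {
  a <- deg2rad(direction)
  if (!is.matrix(force)) force <- matrix(force, ncol = 2L)
  as.numeric(force[, 1] * sin(a) - force[, 2] * cos(a))
}
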