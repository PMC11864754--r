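# Minimum-jerk point-to-point movements on the workspace circle.

# fifth-order minimum-jerk position / velocity shape on normalized time
.mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
.mj_vel <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4  # peak 1.875 at tau = 0.5

#' Minimum-jerk reaching movement
#'
#' Builds a straight-line fifth-order minimum-jerk reach across the diameter
#' of the workspace circle: from `center + R * (cos(a+180), sin(a+180))` to
#' `center + R * (cos a, sin a)`.  The duration solves
#' `peak_speed = (15/8) * 2R / T`, so the default 10 cm reach at 50 cm/s peak
#' lasts 0.375 s.  The time grid always has an even number of steps so the
#' commanded peak speed is attained exactly at the midpoint sample.
#'
#' @param center Workspace centre, metres.
#' @param direction Movement direction `alpha`, degrees.
#' @param radius Circle radius R, metres (default 0.05: a 10 cm diameter).
#' @param peak_speed Commanded peak speed, m/s (default 0.5).
#' @param dt Sampling interval, seconds (default 0.002).
#' @return An object of class `redyn_movement` with fields `start`, `target`,
#'   `center`, `direction`, `radius`, `t`, `dt`, `position` (n x 2) and
#'   `velocity` (n x 2).
#' @export
min_jerk_movement <- function(center = c(0, 0), direction = 0, radius = 0.05,
                              peak_speed = 0.5, dt = 0.002) {
  if (radius <= 0 || peak_speed <= 0 || dt <= 0) {
    stop("radius, peak_speed and dt must be strictly positive")
  }
  center <- .assert_point(center, "center")
  a <- deg2rad(direction)
  start <- center + radius * c(cos(a + pi), sin(a + pi))
  target <- center + radius * c(cos(a), sin(a))
  d <- 2 * radius
  T <- 1.875 * d / peak_speed
  nstep <- max(2L, 2L * ceiling(T / (2 * dt)))
  t <- seq(0, T, length.out = nstep + 1L)
  tau <- t / T
  u <- c(cos(a), sin(a))
  pos <- cbind(start[1] + u[1] * d * .mj_pos(tau),
               start[2] + u[2] * d * .mj_pos(tau))
  speed <- (d / T) * .mj_vel(tau)
  vel <- cbind(u[1] * speed, u[2] * speed)
  structure(list(start = start, target = target, center = center,
                 direction = as.numeric(direction), radius = radius,
                 peak_speed = peak_speed, t = t, dt = t[2] - t[1],
                 position = pos, velocity = vel),
            class = "redyn_movement")
}

#' @export
print.redyn_movement <- function(x, ...) {
  cat(sprintf(
    "Minimum-jerk reach: direction %.1f deg, %.0f mm, %d samples over %.3f s, peak %.2f m/s\n",
    x$direction, 2000 * x$radius, length(x$t), max(x$t), max(sqrt(rowSums(x$velocity^2)))))
  invisible(x)
}
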