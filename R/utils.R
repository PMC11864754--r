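# Internal numeric helpers. All public APIs take angles in degrees; everything
# here works in radians unless the name says otherwise.

.DEG <- pi / 180

deg2rad <- function(x) x * .DEG
rad2deg <- function(x) x / .DEG

# wrap an angle in degrees to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# 2x2 counter-clockwise rotation matrix, angle in degrees
rotation2 <- function(theta_deg) {
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

# elementwise 2x2 linear map applied to row-wise vectors (vx, vy):
# returns list(x=, y=) with x = a11*vx + a12*vy etc.  Entries and vectors may
# be scalars or conformable arrays; this is what keeps the Monte-Carlo loops
# vectorized over samples x replicates.
m22_apply <- function(a11, a12, a21, a22, vx, vy) {
  list(x = a11 * vx + a12 * vy, y = a21 * vx + a22 * vy)
}

m22_inverse <- function(a11, a12, a21, a22) {
  det <- a11 * a22 - a12 * a21
  if (any(abs(det) < 1e-12)) {
    stop("singular 2x2 map encountered (arm posture at or near a kinematic singularity)")
  }
  list(a11 = a22 / det, a12 = -a12 / det, a21 = -a21 / det, a22 = a11 / det)
}

.assert_point <- function(p, name = "point") {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))) {
    stop(sprintf("'%s' must be a finite numeric vector of length 2", name))
  }
  as.numeric(p)
}

# FNV-1a over a serialized R object; used to stamp output files with a
# reproducible configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
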