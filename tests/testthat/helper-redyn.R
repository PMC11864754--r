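# Shared fixtures for the test suite.

default_geom <- function() arm_geometry(0.33, 0.34, c(0, 0))

# small Monte-Carlo budget for unit tests; acceptance checks use the default
quick_noise <- function(replicates = 200, seed = 42L) {
  noise_spec(angular_sd = 1, replicates = replicates, seed = seed)
}

# independent central-difference Jacobian oracle
fd_jacobian <- function(geom, q, h = 1e-6) {
  hdeg <- h * 180 / pi
  J <- matrix(NA_real_, 2, 2)
  for (j in 1:2) {
    dq <- c(0, 0); dq[j] <- hdeg
    J[, j] <- (forward_kinematics(geom, q + dq) -
                 forward_kinematics(geom, q - dq)) / (2 * h)
  }
  J
}

expect_weights_simplex <- function(w, tol = 1e-9) {
  wm <- as.matrix(w[, c("cartesian", "joint", "object")])
  expect_true(all(wm >= -tol))
  expect_equal(unname(rowSums(wm)), rep(1, nrow(wm)), tolerance = 1e-9)
}
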