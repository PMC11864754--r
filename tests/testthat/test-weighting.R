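test_that("the arc-length rule converts angular to linear noise", {
  expect_equal(1000 * arc_length_sd(0.1, 1), 1.745, tolerance = 1e-3)
  expect_equal(arc_length_sd(0.2, 1), 2 * arc_length_sd(0.1, 1))
})

test_that("perturbed endpoints follow the per-frame noise scheme", {
  center <- c(0.02, -0.01); R <- 0.05; a <- 30
  nominal <- list(start = center + R * c(cos(pi * 210 / 180), sin(pi * 210 / 180)),
                  target = center + R * c(cos(pi * 30 / 180), sin(pi * 30 / 180)))
  for (fr in c("cartesian", "joint", "object")) {
    pe <- perturbed_endpoints(fr, center, R, a, c(0, 0, 0, 0))
    expect_equal(pe$start, nominal$start, tolerance = 1e-12)
    expect_equal(pe$target, nominal$target, tolerance = 1e-12)
  }
  # cartesian draws add arc-length-equivalent linear offsets outside the
  # trig terms; the printed calibration makes 1 degree about 1.7 mm
  pe <- perturbed_endpoints("cartesian", center, R, a, c(1, 0, 0, 0))
  expect_equal(pe$start - nominal$start, c(arc_length_sd(0.1, 1), 0),
               tolerance = 1e-12)
  expect_equal(1000 * (pe$start - nominal$start)[1], 1.745, tolerance = 1e-3)
  # angular draw on the target x-angle rotates the target along the circle
  pe <- perturbed_endpoints("joint", center, R, a, c(0, 0, 1, 0))
  expect_equal(pe$target[1], center[1] + R * cos(pi * 31 / 180), tolerance = 1e-12)
  expect_equal(pe$target[2], nominal$target[2])
})

test_that("inverse-variance weights follow the closed form", {
  expect_equal(unname(inverse_variance_weights(c(1, 2, 2))), c(0.5, 0.25, 0.25))
  expect_equal(unname(inverse_variance_weights(c(1, 1, 1))), rep(1, 3) / 3)
  # zero-variance frame takes the full weight
  expect_equal(unname(inverse_variance_weights(c(0, 1, 2))), c(1, 0, 0))
  expect_equal(unname(inverse_variance_weights(c(0, 0, 2))), c(0.5, 0.5, 0))
})

test_that("energy weights invert the mean-force magnitudes", {
  lat <- list(cartesian = matrix(1, 8, 2), joint = matrix(2, 8, 2),
              object = matrix(-2, 8, 2))
  w <- energy_weights(lat, directions = c(0, 180))
  expect_equal(w$cartesian, c(0.5, 0.5))
  expect_equal(w$joint, c(0.25, 0.25))
  expect_equal(w$object, c(0.25, 0.25))  # |mean| used, sign irrelevant
  expect_weights_simplex(w)
})

test_that("smoothness weights invert the mean absolute third difference", {
  i <- 0:9
  mk <- function(c3) matrix((c3 / 6) * i^3, ncol = 1)  # third difference == c3
  w <- smoothness_weights(list(cartesian = mk(1), joint = mk(1), object = mk(2)),
                          directions = 0)
  expect_equal(unname(as.matrix(w[, 2:4])[1, ]), c(0.4, 0.4, 0.2),
               tolerance = 1e-12)
  # identical profiles share the weight equally
  w2 <- smoothness_weights(list(cartesian = mk(3), joint = mk(3), object = mk(3)),
                           directions = 0)
  expect_equal(unname(as.matrix(w2[, 2:4])[1, ]), rep(1, 3) / 3)
  expect_error(smoothness_weights(list(cartesian = mk(1)[1:3, , drop = FALSE],
                                       joint = mk(1)[1:3, , drop = FALSE],
                                       object = mk(1)[1:3, , drop = FALSE]),
                                  directions = 0), "4 samples")
})

test_that("a cubic force profile has a constant third difference", {
  dt <- 0.002; t <- seq(0, 0.1, by = dt)
  a3 <- 7
  f <- a3 * t^3 - 2 * t + 0.5
  d3 <- diff(f, differences = 3)
  # heavy cancellation: the third difference is ~3e-7 against values ~0.5
  expect_equal(d3, rep(6 * a3 * dt^3, length(d3)), tolerance = 1e-6)
})

test_that("only the pooled cartesian+joint weight matters when predictions coincide", {
  # experiment 3: the hand never leaves the training workspace, so the
  # cartesian and joint predictions are identical and only the SUM of their
  # weights is identifiable -- reallocating weight between them leaves the
  # mixture unchanged (the reason those two weights are reported pooled)
  cfg <- experiment_config(3)
  w <- predict_weights(cfg, "test1", "redyn", quick_noise(300))
  expect_weights_simplex(w)
  fc <- frame_compensation(cfg, "test1")
  pooled <- w
  pooled$cartesian <- (w$cartesian + w$joint) / 2
  pooled$joint <- pooled$cartesian
  expect_equal(mixture_profile(pooled, fc$slopes)$compensation,
               mixture_profile(w, fc$slopes)$compensation, tolerance = 1e-12)
  # the object weight alternates with direction (strong near the diagonal
  # directions where the rotated pattern is flatter, weak at the cardinals)
  expect_gt(max(w$object), 0.4)
  expect_lt(min(w$object), 0.15)
})

test_that("Re-Dyn weights are reproducible under a fixed seed", {
  cfg <- experiment_config(1)
  ns <- quick_noise(80)
  w1 <- predict_weights(cfg, "test1", "redyn", ns)
  w2 <- predict_weights(cfg, "test1", "redyn", ns)
  expect_identical(w1$cartesian, w2$cartesian)
  expect_identical(attr(w1, "sigma2"), attr(w2, "sigma2"))
  w3 <- predict_weights(cfg, "test1", "redyn", quick_noise(80, seed = 7L))
  expect_false(identical(w1$cartesian, w3$cartesian))
  expect_weights_simplex(w1)
})

test_that("Monte-Carlo weight scatter shrinks as one over sqrt(replicates)", {
  cfg <- experiment_config(1)
  wc_at <- function(reps, seed) {
    w <- redyn_weights(cfg$geometry, cfg$workspaces$training,
                       cfg$workspaces$test1, cfg$field,
                       noise_spec(replicates = reps, seed = seed),
                       directions = 90)
    w$cartesian
  }
  seeds <- 1:30
  sd_small <- sd(vapply(seeds, function(s) wc_at(30, s), numeric(1)))
  sd_large <- sd(vapply(seeds, function(s) wc_at(1000, s), numeric(1)))
  ratio <- sd_small / sd_large   # ideal sqrt(1000/30) = 5.77
  expect_gt(ratio, 3)
  expect_lt(ratio, 9)
})

test_that("fitted optimal weights recover a known mixture exactly", {
  cfg <- experiment_config(1)
  fc <- frame_compensation(cfg, "test1")
  truth <- c(0.2, 0.3, 0.5)
  y <- as.numeric(fc$slopes %*% truth)
  fit <- fit_optimal_weights(y, fc$slopes)
  expect_equal(unname(fit$weights), truth, tolerance = 1e-6)
  expect_false(fit$nonunique)
  # pure cartesian data
  fit_c <- fit_optimal_weights(fc$slopes[, 1], fc$slopes)
  expect_equal(unname(fit_c$weights), c(1, 0, 0), tolerance = 1e-6)
  # zero data: the zero triple is admissible and optimal
  fit_0 <- fit_optimal_weights(rep(0, 16), fc$slopes)
  expect_equal(unname(fit_0$weights), c(0, 0, 0))
})

test_that("optimal weights respect the simplex inequality constraints", {
  cfg <- experiment_config(1)
  fc <- frame_compensation(cfg, "test1")
  set.seed(5)
  for (i in 1:10) {
    y <- as.numeric(fc$slopes %*% runif(3, 0, 1.2)) + rnorm(16, 0, 0.2)
    fit <- fit_optimal_weights(y, fc$slopes)
    expect_true(all(fit$weights >= 0))
    expect_lte(sum(fit$weights), 1 + 1e-9)
  }
})

test_that("collinear frame profiles are flagged non-unique", {
  p <- cos(2 * standard_directions() * pi / 180)
  P <- cbind(p, p, p)
  fit <- fit_optimal_weights(0.6 * p, P)
  expect_true(fit$nonunique)
  expect_equal(as.numeric(P %*% fit$weights), 0.6 * p, tolerance = 1e-8)
})
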