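test_that("minimum-jerk movements satisfy their boundary conditions", {
  mv <- min_jerk_movement(center = c(0.1, 0.2), direction = 60)
  expect_equal(mv$position[1, ], mv$start, tolerance = 1e-12)
  expect_equal(mv$position[nrow(mv$position), ], mv$target, tolerance = 1e-12)
  expect_equal(max(mv$t), 0.375, tolerance = 1e-12)  # (15/8)*0.1/0.5
  expect_equal(max(sqrt(rowSums(mv$velocity^2))), 0.5, tolerance = 1e-6)
  expect_equal(mv$velocity[1, ], c(0, 0))
  expect_equal(mv$velocity[nrow(mv$velocity), ], c(0, 0), tolerance = 1e-12)
  # endpoints sit on the circle diameter
  expect_equal(mv$start, mv$center + 0.05 * c(cos(pi * 240 / 180), sin(pi * 240 / 180)),
               tolerance = 1e-12)
})

test_that("all frame predictions collapse when test equals train", {
  g <- default_geom()
  tr <- workspace(g, "training", c(50, 90))
  mv <- min_jerk_movement(tr$center, 75)
  f <- scaled_curl_field()
  cart <- cartesian_prediction(mv, f)
  expect_equal(joint_prediction(g, tr, tr, mv, f), cart, tolerance = 1e-9)
  expect_equal(object_prediction(0, mv, f), cart, tolerance = 1e-12)
  expect_equal(object_rotation(g, tr, tr), 0)
})

test_that("cartesian prediction is workspace invariant and zero at 45 degrees", {
  cfg <- experiment_config(1)
  f <- cfg$field
  mv_tr <- min_jerk_movement(cfg$workspaces$training$center, 10)
  mv_t1 <- min_jerk_movement(cfg$workspaces$test1$center, 10)
  expect_equal(cartesian_prediction(mv_tr, f), cartesian_prediction(mv_t1, f),
               tolerance = 1e-12)
  mv45 <- min_jerk_movement(cfg$workspaces$test1$center, 45)
  expect_equal(cartesian_prediction(mv45, f),
               matrix(0, nrow(mv45$velocity), 2), tolerance = 1e-12)
})

test_that("object prediction circularly shifts the compensation curve", {
  f <- scaled_curl_field()
  dirs <- standard_directions()
  slope_for <- function(rot, a) {
    mv <- min_jerk_movement(direction = a)
    lat <- signed_lateral_component(object_prediction(rot, mv, f), a)
    force_compensation(lat, mv$velocity)
  }
  base <- vapply(dirs, function(a) slope_for(0, a), numeric(1))
  shifted <- vapply(dirs, function(a) slope_for(22.5, a), numeric(1))
  # brute-force shift oracle: value at a under rotation t equals the
  # training-curve value at a - t
  expect_equal(shifted, base[c(16, 1:15)], tolerance = 1e-9)
})

test_that("a pure curl field is rotation invariant in the object frame", {
  f <- curl_field()
  mv <- min_jerk_movement(direction = 30)
  cart <- cartesian_prediction(mv, f)
  for (th in c(-120, 15, 90)) {
    expect_equal(object_prediction(th, mv, f), cart, tolerance = 1e-12)
  }
})

test_that("joint prediction shifts leftward for experiment 1 workspace 1", {
  cfg <- experiment_config(1)
  fc <- frame_compensation(cfg, "test1")
  shift <- phase_shift(fc$slopes[, "joint"], field_profile(cfg))
  expect_lt(shift, 0)
})

test_that("joint prediction propagates kinematic errors", {
  g <- default_geom()
  tr <- workspace(g, "training", c(50, 90))
  # test workspace beyond reach
  far <- structure(list(name = "far", q = c(0, 0), center = c(0.9, 0)),
                   class = "redyn_workspace")
  mv <- min_jerk_movement(far$center, 0)
  expect_error(joint_prediction(g, tr, far, mv, scaled_curl_field()),
               "unreachable")
})

test_that("frame predictions are continuous near non-singular postures", {
  g <- default_geom()
  tr <- workspace(g, "training", c(50, 90))
  f <- scaled_curl_field()
  base_q <- c(60, 80)
  ws1 <- workspace(g, "a", base_q)
  ws2 <- workspace(g, "b", base_q + c(0.01, 0.01))
  m1 <- min_jerk_movement(ws1$center, 30)
  m2 <- min_jerk_movement(ws2$center, 30)
  d_joint <- max(abs(joint_prediction(g, tr, ws1, m1, f) -
                       joint_prediction(g, tr, ws2, m2, f)))
  expect_lt(d_joint, 1e-2)
  d_obj <- max(abs(object_prediction(object_rotation(g, tr, ws1), m1, f) -
                     object_prediction(object_rotation(g, tr, ws2), m2, f)))
  expect_lt(d_obj, 1e-2)
})

test_that("mixture prediction is the sample-wise weighted sum", {
  set.seed(4)
  a <- matrix(rnorm(20), 10); b <- matrix(rnorm(20), 10); c0 <- matrix(rnorm(20), 10)
  expect_equal(mixture_prediction(c(1, 0, 0), a, b, c0), a)
  expect_equal(mixture_prediction(c(1, 1, 1) / 3, a, a, a), a)
  expect_equal(mixture_prediction(c(0.2, 0.3, 0.5), a, b, c0),
               0.2 * a + 0.3 * b + 0.5 * c0)
  expect_error(mixture_prediction(c(0.5, 0.5, 0), a, b[1:5, ], c0),
               "sampled identically")
})

test_that("experiment 3 and 4 frame identities hold", {
  cfg3 <- experiment_config(3)
  fc3 <- frame_compensation(cfg3, "test1")
  expect_equal(fc3$slopes[, "joint"], fc3$slopes[, "cartesian"])
  cfg4 <- experiment_config(4)
  for (ws in c("test1", "test2")) {
    fc4 <- frame_compensation(cfg4, ws)
    expect_equal(fc4$slopes[, "object"], fc4$slopes[, "cartesian"],
                 tolerance = 1e-9)
  }
  # experiment 4 keeps the hand-segment orientation constant by design
  expect_equal(unname(cfg4$rotations), c(0, 0), tolerance = 1e-12)
})

test_that("experiment configurations carry the printed joint angles", {
  expect_equal(experiment_config(1)$workspaces$training$q, c(50, 90))
  expect_equal(experiment_config(1)$workspaces$test2$q, c(75, 45))
  expect_equal(experiment_config(4)$workspaces$test1$q, c(30, 100))
  cfg2 <- experiment_config(2); cfg3 <- experiment_config(3)
  for (ws in names(cfg2$workspaces)) {
    expect_equal(cfg3$workspaces[[ws]]$q, cfg2$workspaces[[ws]]$q)
  }
  expect_error(experiment_config(7), "unknown experiment")
  # training workspace centred at the device origin
  expect_equal(experiment_config(2)$workspaces$training$center, c(0, 0),
               tolerance = 1e-12)
})
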