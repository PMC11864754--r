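test_that("schedules reproduce the protocol counts for every experiment", {
  sched <- build_schedule(1, seed = 11)
  counts <- table(sched$phase)
  expect_equal(unname(counts[c("familiarization", "pre_exposure", "exposure",
                               "generalization")]),
               c(16L, 384L, 240L, 1920L), ignore_attr = TRUE)
  expect_equal(nrow(sched), 2560L)
  # exposure: 15 repetitions x 16 directions, all in the training workspace
  expo <- sched[sched$phase == "exposure", ]
  expect_true(all(expo$workspace == "training" & expo$condition == "FF"))
  expect_equal(unname(table(expo$direction)), rep(15L, 16L), ignore_attr = TRUE)
  # generalization: 1536 FF (training only) and 384 FC (8 x 16 x 3)
  gen <- sched[sched$phase == "generalization", ]
  expect_equal(sum(gen$condition == "FF"), 1536L)
  expect_equal(sum(gen$condition == "FC"), 384L)
  expect_true(all(gen$workspace[gen$condition == "FF"] == "training"))
  fc <- gen[gen$condition == "FC", ]
  expect_equal(unname(table(fc$workspace, fc$direction)),
               matrix(8L, 3, 16), ignore_attr = TRUE)
  # pre-exposure: 4 NF + 4 FC per direction per workspace
  pre <- sched[sched$phase == "pre_exposure", ]
  expect_equal(unname(table(pre$condition, pre$workspace)),
               matrix(64L, 2, 3), ignore_attr = TRUE)
})

test_that("channel trials interleave 4:1 within the generalization phase", {
  sched <- build_schedule(2, seed = 3)
  gen <- sched[sched$phase == "generalization", ]
  expect_equal(sum(gen$condition == "FF") / sum(gen$condition == "FC"), 4)
  # exactly one channel trial within each series of five
  series <- matrix(gen$condition, nrow = 5)
  expect_true(all(colSums(series == "FC") == 1))
})

test_that("schedule counts are seed invariant but ordering is not", {
  s1 <- build_schedule(1, seed = 1); s2 <- build_schedule(1, seed = 2)
  expect_equal(table(s1$phase, s1$condition), table(s2$phase, s2$condition))
  expect_false(identical(s1$direction, s2$direction))
  expect_identical(s1, build_schedule(1, seed = 1))
})

test_that("a noiseless Cartesian ground truth reproduces the training profile", {
  cfg <- experiment_config(1)
  sim <- simulate_participant(cfg, ground_truth(c(1, 0, 0),
                                                c(test1 = 1, test2 = 1),
                                                noise_sd = 1e-15),
                              seed = 2)
  pr <- participant_profiles(sim)
  expect_equal(pr$test1$compensation, pr$training$compensation, tolerance = 1e-6)
  expect_equal(pr$test2$compensation, pr$training$compensation, tolerance = 1e-6)
  # the training profile is the field's cos(2a) compensation curve
  expect_equal(pr$training$compensation,
               cos(2 * standard_directions() * pi / 180), tolerance = 1e-6)
})

test_that("simulated participants are bit-identical under a fixed seed", {
  cfg <- experiment_config(2)
  s1 <- simulate_participant(cfg, ground_truth(), seed = 5)
  s2 <- simulate_participant(cfg, ground_truth(), seed = 5)
  expect_identical(s1$samples, s2$samples)
})

test_that("optimal-weight fitting recovers the decayed ground-truth mixture", {
  cfg <- experiment_config(1)
  truth <- c(0.2, 0.3, 0.5)
  sim <- simulate_participant(cfg, ground_truth(truth,
                                                c(test1 = 0.4, test2 = 0.7),
                                                noise_sd = 1e-15),
                              seed = 4)
  pr <- participant_profiles(sim)
  fc <- frame_compensation(cfg, "test1")
  fit <- fit_optimal_weights(pr$test1$compensation, fc$slopes)
  expect_equal(unname(fit$weights), 0.4 * truth, tolerance = 1e-6)
  fc2 <- frame_compensation(cfg, "test2")
  fit2 <- fit_optimal_weights(pr$test2$compensation, fc2$slopes)
  expect_equal(unname(fit2$weights), 0.7 * truth, tolerance = 1e-6)
})

test_that("the pipeline closes: simulated profiles carry the mixture's phase", {
  cfg <- experiment_config(1)
  truth <- c(0.2, 0.3, 0.5)
  fc <- frame_compensation(cfg, "test1")
  target <- as.numeric(fc$slopes %*% truth)
  # default channel noise (10% of peak perfect-compensation force)
  sim <- simulate_participant(cfg, ground_truth(truth, c(test1 = 0.6, test2 = 0.6)),
                              seed = 6)
  pr <- participant_profiles(sim)
  expect_lt(abs(phase_shift(pr$test1, target)), 2)
})
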