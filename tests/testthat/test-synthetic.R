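test_that("simulation is bit-identical for a fixed seed", {
  spec <- SceneSpec(n_frames = 12L, seed = 9L)
  a <- simulateSequence(spec)
  b <- simulateSequence(spec)
  expect_identical(a$frames, b$frames)
  expect_identical(a$tracks, b$tracks)
  c <- simulateSequence(SceneSpec(n_frames = 12L, seed = 10L))
  expect_false(identical(a$frames, c$frames))
})

test_that("blob centroids recover the true locations on noise-free frames", {
  # well-separated blobs so windowed centroids see a single keypoint
  spec <- SceneSpec(n_frames = 6L, n_keypoints = 3L, amplitude = c(6, 4, 5),
                    noise_sigma = 0, texture_amp = 0,
                    background_level = 0, seed = 2L)
  sim <- simulateSequence(spec)
  for (f in c(1, 4, 6)) {
    img <- sim$frames[[f]]
    tr <- sim$tracks[sim$tracks$frame == f - 1, ]
    for (p in seq_len(nrow(tr))) {
      # isolate the blob in a window around the truth before centroiding
      x0 <- round(tr$x[p]); y0 <- round(tr$y[p])
      win <- img[(y0 - 5):(y0 + 7), (x0 - 5):(x0 + 7)]
      cen <- blobCentroid(win)
      expect_lt(abs(cen[["x"]] - 6 - (tr$x[p] - x0)), 0.5)
      expect_lt(abs(cen[["y"]] - 6 - (tr$y[p] - y0)), 0.5)
    }
  }
})

test_that("zero-amplitude scenes are static", {
  spec <- SceneSpec(n_frames = 5L, amplitude = 0, noise_sigma = 0, seed = 1L)
  sim <- simulateSequence(spec)
  for (f in 2:5) expect_identical(sim$frames[[f]], sim$frames[[1]])
  # one fixed location per keypoint across all frames
  expect_identical(nrow(unique(sim$tracks[, c("keypoint", "x", "y")])), 4L)
})

test_that("occlusion episode counts sit inside Poisson bounds", {
  spec <- SceneSpec(n_frames = 500L, occlusion_rate = 2,
                    occlusion_run_length = 1, seed = 4L)
  sim <- simulateSequence(spec)
  n_eps <- nrow(sim$episodes)
  # expectation 2/100 * 500 * 4 = 40; 99% Poisson bounds
  expect_gte(n_eps, stats::qpois(0.005, 40))
  expect_lte(n_eps, stats::qpois(0.995, 40))
  # visibility flags agree with the episode table
  occl_frames <- sum(!sim$tracks$visible)
  expect_identical(occl_frames, as.integer(sum(sim$episodes$length)))
})

test_that("occluded keypoints are covered by the masking rectangle", {
  spec <- SceneSpec(n_frames = 60L, occlusion_rate = 10,
                    occlusion_run_length = 3, noise_sigma = 0, seed = 6L)
  sim <- simulateSequence(spec)
  hid <- sim$tracks[!sim$tracks$visible, ][1, ]
  img <- sim$frames[[hid$frame + 1]]
  # the pixel at the blob centre shows the occluder, not the blob peak
  expect_equal(img[round(hid$y) + 1, round(hid$x) + 1], 0.55,
               tolerance = 1e-9)
})

test_that("the two views share x exactly and are otherwise independent", {
  tv <- simulateTwoViews(SceneSpec(n_frames = 20L, occlusion_rate = 5,
                                   seed = 3L))
  expect_identical(tv$side$tracks$x, tv$bottom$tracks$x)
  expect_false(identical(tv$side$tracks$y, tv$bottom$tracks$y))
  expect_false(identical(tv$side$tracks$visible, tv$bottom$tracks$visible))
  # reproducible
  tv2 <- simulateTwoViews(SceneSpec(n_frames = 20L, occlusion_rate = 5,
                                    seed = 3L))
  expect_identical(tv$side$frames, tv2$side$frames)
  expect_identical(tv$bottom$frames, tv2$bottom$frames)
})

test_that("scenario presets are validated, seeded and non-adjacent", {
  expect_error(standardScenarios("nonsense"), "arg")
  st <- standardScenarios("static", 0L)
  expect_identical(max(abs(st$scene@amplitude)), 0)
  g1 <- standardScenarios("gait", 0L)
  g2 <- standardScenarios("gait", 0L)
  expect_identical(g1$scene, g2$scene)
  iso <- standardScenarios("isolated-errors", 2L)
  expect_identical(iso$schedule$run_length, 1L)
  expect_equal(iso$mock@error_prob, 0.15)
  expect_equal(iso$mock@error_displacement, 40)
  sched <- makeErrorSchedule(iso$scene@n_frames, iso$scene@n_keypoints,
                             iso$schedule$prob, iso$schedule$run_length,
                             iso$schedule$min_gap, 2L)
  for (p in 1:4) {
    hits <- which(sched[, p])
    if (length(hits) > 1) expect_true(all(diff(hits) >= 2))
  }
  runs <- standardScenarios("error-runs", 0L)
  expect_identical(runs$schedule$run_length, 9L)
})

test_that("trajectories escaping the frame are rejected at spec validation", {
  expect_error(SceneSpec(width = 32L, height = 32L, amplitude = 30),
               "margin|escape")
})
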