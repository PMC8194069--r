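test_that("window indices follow the t +/- k*s rule with edge clamping", {
  expect_identical(buildWindow(10, FrameWindowSpec(2, 3), 100),
                   as.integer(seq(4, 16, by = 2)))
  expect_identical(buildWindow(5, FrameWindowSpec(3, 0), 100), 5L)
  expect_identical(buildWindow(1, FrameWindowSpec(1, 4), 100),
                   c(0L, 0L, 0L, 0L, 1L, 2L, 3L, 4L, 5L))
  expect_identical(buildWindow(98, FrameWindowSpec(1, 4), 100),
                   c(94L, 95L, 96L, 97L, 98L, 99L, 99L, 99L, 99L))
  w <- buildWindow(50, FrameWindowSpec(1, 4), 100)
  expect_length(w, 9)
  expect_identical(w[5], 50L)
  expect_error(buildWindow(100, FrameWindowSpec(1, 4), 100), "outside")
  expect_error(buildWindow(-1, FrameWindowSpec(1, 4), 100), "outside")
})

test_that("dense flow recovers null motion and known shifts", {
  ref <- texturedFrame(96, 96, seed = 10)
  # null motion
  fl0 <- denseFlow(ref, ref)
  mag <- sqrt(flowU(fl0)^2 + flowV(fl0)^2)
  expect_lt(stats::quantile(mag, 0.95), 0.5)
  # content shifted +5 px along x
  src <- matrix(0, 96, 96)
  src[, 6:96] <- ref[, 1:91]
  fl <- denseFlow(ref, src)
  expect_lt(abs(stats::median(flowU(fl)) - 5), 1)
  expect_lt(abs(stats::median(flowV(fl))), 1)
  # blank frames stay finite (validity enforces it on construction)
  blank <- matrix(0.5, 64, 64)
  expect_s4_class(denseFlow(blank, blank), "FlowField")
  expect_error(denseFlow(ref, matrix(0, 10, 10)), "dimensions")
})

test_that("warping is identity under zero flow and shifts under integer flow", {
  anns <- data.frame(frame_id = "f", keypoint = c("a", "b"),
                     x = c(10, 20), y = c(12, 6), box_w = 7, box_h = 7)
  st <- stackLabels(anns, c("a", "b"), 32, 24)
  zero <- FlowField(matrix(0, 24, 32), matrix(0, 24, 32))
  expect_identical(heatmapArray(warpHeatmap(st, zero)), heatmapArray(st))
  # constant integer flow u = 3: columns shift left by 3 with zero fill
  fl <- FlowField(matrix(3, 24, 32), matrix(0, 24, 32))
  warped <- heatmapArray(warpHeatmap(st, fl))
  g <- heatmapArray(st)
  shifted <- array(0, dim(g))
  shifted[, 1:29, ] <- g[, 4:32, ]   # manual shift oracle
  expect_equal(warped, shifted, tolerance = 1e-12)
  # flow sending everything out of bounds empties the stack
  far <- FlowField(matrix(100, 24, 32), matrix(0, 24, 32))
  expect_identical(max(heatmapArray(warpHeatmap(st, far))), 0)
})

test_that("morphing a static window preserves peaks and the centre member", {
  frame <- texturedFrame(64, 64, seed = 11)
  anns <- data.frame(frame_id = "f", keypoint = "a", x = 30, y = 25,
                     box_w = 9, box_h = 9)
  st <- stackLabels(anns, "a", 64, 64)
  frames <- rep(list(frame), 5)
  stacks <- rep(list(st), 5)
  morphed <- morphWindow(frames, stacks)
  expect_length(morphed, 5)
  expect_identical(heatmapArray(morphed[[3]]), heatmapArray(st))  # centre
  for (m in morphed)
    expect_identical(argmaxLocation(keypointGrid(m, "a")), c(x = 30, y = 25))
  expect_error(morphWindow(frames, stacks[1:3]), "misaligned")
})

test_that("aggregation is the pixelwise weighted sum, linear before clipping", {
  anns <- data.frame(frame_id = "f", keypoint = c("a", "b"),
                     x = c(8, 16), y = c(8, 4), box_w = 5, box_h = 5)
  st <- stackLabels(anns, c("a", "b"), 24, 16)
  stacks <- rep(list(st), 3)
  onehot <- AggregatorWeights(matrix(c(0, 1, 0, 0, 1, 0), 2, 3,
                                     byrow = TRUE), c("a", "b"), -1:1)
  expect_identical(heatmapArray(aggregateStacks(stacks, onehot)),
                   heatmapArray(st))
  unif <- AggregatorWeights(matrix(1 / 3, 2, 3), c("a", "b"), -1:1)
  expect_equal(heatmapArray(aggregateStacks(stacks, unif)),
               heatmapArray(st), tolerance = 1e-12)
  # linearity on random stacks
  set.seed(12)
  rnd <- function() HeatmapStack(array(runif(24 * 16 * 2), c(16, 24, 2)),
                                 c("a", "b"))
  A <- list(rnd(), rnd(), rnd()); B <- list(rnd(), rnd(), rnd())
  w <- AggregatorWeights(matrix(rnorm(6), 2, 3), c("a", "b"), -1:1)
  AB <- lapply(1:3, function(k)
    HeatmapStack(2 * heatmapArray(A[[k]]) + 3 * heatmapArray(B[[k]]),
                 c("a", "b")))
  lhs <- heatmapArray(aggregateStacks(AB, w))
  rhs <- 2 * heatmapArray(aggregateStacks(A, w)) +
    3 * heatmapArray(aggregateStacks(B, w))
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_error(aggregateStacks(stacks[1:2], onehot), "window length")
})

test_that("least squares recovers a known mixing vector exactly", {
  sim <- simulateSequence(SceneSpec(n_frames = 40L, seed = 3L))
  stacks <- mockPredictSequence(sim$tracks, sim$keypoints, 96, 96,
                                MockPredictorConfig(seed = 3L))
  win <- FrameWindowSpec(1, 2)
  wstar <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  windows <- lapply(c(5L, 12L, 20L, 28L, 34L), function(t) {
    idx <- buildWindow(t, win, 40L)
    morphed <- morphWindow(sim$frames[idx + 1], stacks[idx + 1], 3L)
    mix <- Reduce(`+`, lapply(1:5, function(k)
      wstar[k] * heatmapArray(morphed[[k]])))
    list(morphed = morphed, label = HeatmapStack(mix, sim$keypoints))
  })
  fit <- fitWeights(windows, "ls")
  expect_lt(max(abs(sweep(weightMatrix(fit), 2, wstar))), 1e-6)
  # labels equal to the centre stack: one-hot centre weights
  windows2 <- lapply(windows, function(w)
    list(morphed = w$morphed, label = w$morphed[[3]]))
  fit2 <- fitWeights(windows2, "ls")
  target <- matrix(rep(c(0, 0, 1, 0, 0), each = 4), 4, 5)
  expect_lt(max(abs(weightMatrix(fit2) - target)), 1e-6)
})

test_that("a single 1x1-grid window reduces to scalar regression", {
  morphed <- lapply(c(2, 5), function(v)
    HeatmapStack(array(v, c(1, 1, 1)), "a"))
  label <- HeatmapStack(array(3, c(1, 1, 1)), "a")
  fit <- suppressWarnings(
    fitWeights(list(list(morphed = morphed, label = label)), "ls",
               offsets = c(-1L, 1L)))
  w <- weightMatrix(fit)
  # any exact solution of 2*w1 + 5*w2 = 3 has zero residual
  expect_equal(2 * w[1, 1] + 5 * w[1, 2], 3, tolerance = 1e-9)
})

test_that("degenerate static windows fall back to a minimum-norm solution", {
  st <- HeatmapStack(array(runif(64), c(8, 8, 1)), "a")
  windows <- list(list(morphed = rep(list(st), 3), label = st))
  expect_warning(fit <- fitWeights(windows, "ls"), "rank-deficient")
  expect_equal(sum(weightMatrix(fit)), 1, tolerance = 1e-6)
})

test_that("aggregated decoding corrects an isolated injected error", {
  sim <- simulateSequence(SceneSpec(n_frames = 30L, seed = 5L))
  sched <- matrix(FALSE, 30, 4); sched[15, 2] <- TRUE
  stacks <- mockPredictSequence(sim$tracks, sim$keypoints, 96, 96,
                                MockPredictorConfig(error_displacement = 40,
                                                    seed = 5L), sched)
  win <- FrameWindowSpec(1, 4)
  unif <- AggregatorWeights(matrix(1 / 9, 4, 9), sim$keypoints, -4:4)
  res <- predictTarget(sim$frames, stacks, 14L, win, unif)
  truth <- sim$tracks[sim$tracks$frame == 14 & sim$tracks$keypoint == "kp2", ]
  base_loc <- argmaxLocation(keypointGrid(stacks[[15]], "kp2"))
  expect_gt(sqrt(sum((base_loc - c(truth$x, truth$y))^2)), 30)  # base is off
  expect_lt(sqrt(sum((res$locations["kp2", ] - c(truth$x, truth$y))^2)), 4)
  # f = 0 degenerates to the base prediction
  res0 <- predictTarget(sim$frames, stacks, 14L, FrameWindowSpec(1, 0),
                        AggregatorWeights(matrix(1, 4, 1), sim$keypoints, 0L))
  expect_identical(res0$locations["kp2", ],
                   c(x = base_loc[["x"]], y = base_loc[["y"]]))
})

test_that("aggregator weights round-trip through JSON", {
  w <- AggregatorWeights(matrix(rnorm(12), 3, 4), c("a", "b", "c"),
                         c(-2L, -1L, 1L, 2L))
  f <- tempfile(fileext = ".json")
  writeWeights(w, f)
  back <- readWeights(f)
  expect_identical(keypointNames(back), keypointNames(w))
  expect_identical(back@offsets, w@offsets)
  expect_equal(weightMatrix(back), weightMatrix(w), tolerance = 1e-12)
})
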