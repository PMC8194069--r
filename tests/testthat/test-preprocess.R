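test_that("dataset splits are sized, disjoint, exhaustive and deterministic", {
  ids <- sprintf("f%03d", 1:500)
  sp <- splitDataset(ids, seed = 7)
  expect_identical(lengths(sp), c(train = 300L, validation = 100L,
                                  test = 100L))
  expect_identical(sort(unlist(sp, use.names = FALSE)), sort(ids))
  expect_identical(splitDataset(ids, seed = 7), sp)
  expect_false(identical(splitDataset(ids, seed = 8), sp))
})

test_that("video-grouped splits keep every video whole", {
  ids <- as.vector(outer(sprintf("vid%d", 1:5), sprintf("%03d", 1:100),
                         paste, sep = "_"))
  sp <- splitDataset(ids, group_by = "video", seed = 1)
  vids <- lapply(sp, function(v) unique(sub("_[^_]*$", "", v)))
  expect_length(unlist(vids), 5)          # no video spans two splits
  expect_identical(sort(unlist(sp, use.names = FALSE)), sort(ids))
  expect_error(splitDataset(c("a_1", "a_2"), group_by = "video"),
               "fewer videos")
})

test_that("rotation maps labels exactly like the image", {
  frame <- texturedFrame(20, 20, seed = 2)
  anns <- data.frame(frame_id = "f", keypoint = "kp", x = 3, y = 5,
                     box_w = 3, box_h = 3)
  # identity
  r0 <- rotateWithLabels(frame, anns, 0)
  expect_equal(r0$frame, frame, tolerance = 1e-12)
  expect_equal(r0$anns$x, 3)
  # quarter turn on a square frame: (x, y) -> (W-1-y, x)
  r90 <- rotateWithLabels(frame, anns, 90)
  expect_equal(dim(r90$frame), dim(frame))
  expect_equal(r90$anns$x, 20 - 1 - 5, tolerance = 1e-9)
  expect_equal(r90$anns$y, 3, tolerance = 1e-9)
  # image pixels follow the same map: out(W-1-y, x) == in(x, y)
  for (pt in list(c(3, 5), c(10, 2), c(17, 16))) {
    x <- pt[1]; y <- pt[2]
    expect_equal(r90$frame[x + 1, (20 - 1 - y) + 1], frame[y + 1, x + 1],
                 tolerance = 1e-6)
  }
})

test_that("rotated blobs are re-detected at the mapped annotation", {
  for (i in 1:20) {
    set.seed(8000 + i)
    x <- runif(1, 20, 43); y <- runif(1, 20, 43)
    ang <- runif(1, -45, 45)
    frame <- poseflow:::renderBlob(64, 64, x, y, 2.5)
    anns <- data.frame(frame_id = "f", keypoint = "kp", x = x, y = y,
                       box_w = 5, box_h = 5)
    rot <- rotateWithLabels(frame, anns, ang)
    cen <- blobCentroid(rot$frame)
    expect_lt(abs(cen["x"] - rot$anns$x), 1)
    expect_lt(abs(cen["y"] - rot$anns$y), 1)
  }
})

test_that("flips mirror coordinates and honour swap maps", {
  frame <- texturedFrame(10, 10, seed = 3)
  anns <- data.frame(frame_id = "f", keypoint = c("L", "R"),
                     x = c(3, 7), y = c(5, 2), box_w = 3, box_h = 3)
  fl <- flipWithLabels(frame, anns, "y")
  expect_equal(fl$anns$x, c(6, 2))   # x -> W-1-x
  expect_equal(fl$anns$y, c(5, 2))
  # double flip is the identity
  fl2 <- flipWithLabels(fl$frame, fl$anns, "y")
  expect_equal(fl2$frame, frame)
  expect_equal(fl2$anns$x, anns$x)
  # swap map exchanges names
  fs <- flipWithLabels(frame, anns, "y", swap = c(L = "R", R = "L"))
  expect_identical(fs$anns$keypoint, c("R", "L"))
  expect_error(flipWithLabels(frame, anns, "y", swap = c(L = "R", R = "R")),
               "bijection")
  # xy flip mirrors both axes
  fxy <- flipWithLabels(frame, anns, "xy")
  expect_equal(fxy$anns$x, c(6, 2))
  expect_equal(fxy$anns$y, c(4, 7))
})

test_that("area resizing averages exactly and scales labels linearly", {
  # 2x2 checkerboard -> single pixel mean
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  r <- resizeAreaWithLabels(cb, data.frame(x = 0, y = 0), 1, 1)
  expect_equal(r$frame[1, 1], 0.5)
  # constants survive any resize
  const <- matrix(0.37, 11, 7)
  r <- resizeAreaWithLabels(const, data.frame(x = 1, y = 1), 5, 3)
  expect_equal(max(abs(r$frame - 0.37)), 0, tolerance = 1e-12)
  r <- resizeAreaWithLabels(const, data.frame(x = 1, y = 1), 13, 20)
  expect_equal(max(abs(r$frame - 0.37)), 0, tolerance = 1e-12)
  # linear coordinate scaling
  frame <- texturedFrame(200, 100, seed = 4)  # W=200, H=100
  anns <- data.frame(frame_id = "f", keypoint = "kp", x = 60, y = 30,
                     box_w = 8L, box_h = 8L)
  r <- resizeAreaWithLabels(frame, anns, 100, 50)
  expect_equal(r$anns$x, 30)
  expect_equal(r$anns$y, 15)
  expect_identical(r$anns$box_w, 4L)
  expect_error(resizeAreaWithLabels(frame, anns, 0, 10))
})

test_that("resized blobs are re-detected at the mapped annotation", {
  for (i in 1:15) {
    set.seed(8500 + i)
    x <- runif(1, 20, 43); y <- runif(1, 20, 43)
    sc <- runif(2, 0.5, 1.6)
    frame <- poseflow:::renderBlob(64, 64, x, y, 2.5)
    anns <- data.frame(frame_id = "f", keypoint = "kp", x = x, y = y,
                       box_w = 5, box_h = 5)
    r <- resizeAreaWithLabels(frame, anns, round(64 * sc[1]),
                              round(64 * sc[2]))
    cen <- blobCentroid(r$frame)
    expect_lt(abs(cen["x"] - r$anns$x), 1)
    expect_lt(abs(cen["y"] - r$anns$y), 1)
  }
})

test_that("augmentation commutes with label generation at the argmax", {
  frame <- texturedFrame(48, 48, seed = 5)
  spec <- AugmentSpec(flip_mode = "y_axis", seed = 3L)
  for (i in 1:10) {
    set.seed(8700 + i)
    anns <- data.frame(frame_id = "f", keypoint = "kp",
                       x = runif(1, 12, 35), y = runif(1, 12, 35),
                       box_w = 9L, box_h = 9L)
    aug <- augmentWithLabels(frame, anns, spec, index = i)
    h <- generateHeatmap(aug$anns$x, aug$anns$y, 9, 9,
                         ncol(aug$frame), nrow(aug$frame))
    peak <- argmaxLocation(h)
    expect_lte(abs(peak["x"] - aug$anns$x), 1)
    expect_lte(abs(peak["y"] - aug$anns$y), 1)
    # reproducible per (seed, index)
    aug2 <- augmentWithLabels(frame, anns, spec, index = i)
    expect_identical(aug$angle, aug2$angle)
    expect_identical(aug$frame, aug2$frame)
  }
})

test_that("training targets are peak-scaled stage copies", {
  anns <- data.frame(frame_id = "f", keypoint = "kp", x = 8, y = 8,
                     box_w = 5, box_h = 5)
  st <- stackLabels(anns, "kp", 16, 16)
  tt <- makeTrainingTarget(st, peak = 16, stages = 2L)
  expect_length(tt, 2)
  expect_identical(max(heatmapArray(tt[[1]])), 16)
  expect_identical(heatmapArray(tt[[1]]), heatmapArray(tt[[2]]))
  id <- makeTrainingTarget(st, peak = 1)[[1]]
  expect_identical(heatmapArray(id), heatmapArray(st))
})
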