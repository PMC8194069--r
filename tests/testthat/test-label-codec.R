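test_that("generated labels match the brute-force per-pixel oracle", {
  for (i in 1:25) {
    ann <- randomAnnotation(32, 32, 1000 + i)
    got <- generateHeatmap(ann$x, ann$y, ann$box_w, ann$box_h, 32, 32)
    want <- oracleHeatmap(ann$x, ann$y, ann$box_w, ann$box_h, 32, 32)
    expect_lt(max(abs(got - want)), 1e-9)
  }
  # the spec'd large-box case: nonzero count agrees with the oracle
  got <- generateHeatmap(16, 16, 21, 21, 40, 40)
  want <- oracleHeatmap(16, 16, 21, 21, 40, 40)
  expect_identical(sum(got > 0), sum(want > 0))
})

test_that("label invariants hold on randomized annotations", {
  for (i in 1:60) {
    ann <- randomAnnotation(28, 24, 2000 + i)
    g <- generateHeatmap(ann$x, ann$y, ann$box_w, ann$box_h, 28, 24)
    expect_identical(max(g), 1)                  # exact max 1.0
    expect_true(all(g[g > 0] >= 0.1))            # nothing in (0, 0.1)
    # support confined to the clipped box
    cx <- floor(ann$x + 0.5); cy <- floor(ann$y + 0.5)
    left <- cx - (ann$box_w - 1) %/% 2
    top <- cy - (ann$box_h - 1) %/% 2
    nz <- which(g > 0, arr.ind = TRUE)
    expect_true(all(nz[, 2] - 1 >= left & nz[, 2] - 1 <= left + ann$box_w - 1))
    expect_true(all(nz[, 1] - 1 >= top & nz[, 1] - 1 <= top + ann$box_h - 1))
  }
})

test_that("centre pixel, threshold floor and symmetry behave as specified", {
  g <- generateHeatmap(10, 10, 9, 9, 32, 32)
  expect_identical(g[11, 11], 1)
  expect_gte(min(g[g > 0]), 0.1)
  # integer-centred annotation: reflection symmetry about centre row/column
  block <- g[(11 - 4):(11 + 4), (11 - 4):(11 + 4)]
  expect_equal(block, block[9:1, ], tolerance = 1e-12)
  expect_equal(block, block[, 9:1], tolerance = 1e-12)
})

test_that("annotations outside the image are rejected; edge boxes clip", {
  expect_error(generateHeatmap(-1, 5, 3, 3, 16, 16), "outside")
  expect_error(generateHeatmap(5, 16, 3, 3, 16, 16), "outside")
  # box centred at a corner pixel survives partially and still peaks at 1
  g <- generateHeatmap(0, 0, 9, 9, 16, 16)
  expect_identical(g[1, 1], 1)
  expect_true(all(which(g > 0, arr.ind = TRUE) <= 5))
})

test_that("support mask is exactly the positive region", {
  g <- generateHeatmap(8, 8, 7, 7, 16, 16)
  m <- supportMask(g)
  expect_identical(m, g > 0)
  expect_identical(sum(m), sum(g > 0))
  expect_false(any(supportMask(matrix(0, 4, 4))))
  one <- matrix(0, 8, 8); one[6, 6] <- 1
  expect_identical(which(supportMask(one)), which(one == 1))
})

test_that("stacking labels preserves order, flags missing keypoints", {
  anns <- data.frame(frame_id = "f0",
                     keypoint = c("a", "b", "d"),
                     x = c(5, 9, 12), y = c(5, 9, 12),
                     box_w = 5, box_h = 5)
  st <- stackLabels(anns, c("a", "b", "c", "d"), 20, 20)
  expect_identical(keypointNames(st), c("a", "b", "c", "d"))
  expect_identical(unname(st@metadata$present), c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(max(keypointGrid(st, "c")), 0)
  # per-grid maxima equal the single-call results
  for (k in c("a", "b", "d")) {
    i <- match(k, anns$keypoint)
    single <- generateHeatmap(anns$x[i], anns$y[i], 5, 5, 20, 20)
    expect_identical(keypointGrid(st, k), single)
  }
  # empty annotation set: all zero, all flagged
  st0 <- stackLabels(anns[0, ], c("a", "b"), 20, 20)
  expect_true(all(heatmapArray(st0) == 0))
  expect_false(any(st0@metadata$present))
  # duplicates are named in the error
  expect_error(stackLabels(rbind(anns, anns[1, ]), c("a", "b", "c", "d"),
                           20, 20), "duplicate.*'a'.*'f0'")
})

test_that("annotation serialization round-trips through CSV and JSON", {
  anns <- data.frame(frame_id = c("f0", "f0", "f1"),
                     keypoint = c("a", "b", "a"),
                     x = c(1.234567, 10.5, 3.000001),
                     y = c(4.7654321, 2, 8.25),
                     box_w = c(5L, 7L, 5L), box_h = c(5L, 3L, 5L))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  writeAnnotations(anns, csv)
  writeAnnotations(anns, json)
  for (path in c(csv, json)) {
    back <- readAnnotations(path)
    expect_identical(back$frame_id, anns$frame_id)
    expect_identical(back$keypoint, anns$keypoint)
    expect_equal(back$x, anns$x, tolerance = 1e-6)
    expect_equal(back$y, anns$y, tolerance = 1e-6)
    expect_equal(back$box_w, anns$box_w)
  }
  # malformed inputs are rejected with the offending row
  bad <- anns; bad$box_w[2] <- 0
  f <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(readAnnotations(f), "row 2")
  nocol <- anns[, -3]
  utils::write.csv(nocol, f, row.names = FALSE)
  expect_error(readAnnotations(f), "missing column")
})

test_that("heatmap stacks round-trip through TIFF and CSV", {
  anns <- data.frame(frame_id = "f0", keypoint = c("a", "b"),
                     x = c(6, 14), y = c(8, 3), box_w = 5, box_h = 7)
  st <- stackLabels(anns, c("a", "b"), 24, 16)
  tif <- tempfile(fileext = ".tiff"); csv <- tempfile(fileext = ".csv")
  writeHeatmapStack(st, tif)
  writeHeatmapStack(st, csv)
  for (path in c(tif, csv)) {
    back <- readHeatmapStack(path)
    expect_identical(keypointNames(back), keypointNames(st))
    expect_equal(heatmapArray(back), heatmapArray(st), tolerance = 1e-6)
  }
})
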