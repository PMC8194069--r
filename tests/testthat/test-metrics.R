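test_that("argmax decoding matches a full scan and breaks ties row-major", {
  one <- matrix(0, 10, 10); one[3, 8] <- 1
  expect_identical(argmaxLocation(one), c(x = 7, y = 2))
  expect_identical(argmaxLocation(matrix(1, 5, 5)), c(x = 0, y = 0))
  for (i in 1:20) {
    set.seed(3000 + i)
    g <- matrix(sample(0:9, 48, replace = TRUE) / 9, 6, 8)  # forces ties
    expect_identical(argmaxLocation(g), oracleArgmax(g))
  }
  expect_error(argmaxLocation(matrix(NaN, 3, 3)), "NaN")
})

test_that("aPCK correctness follows the label support, incl. the 0.1 edge", {
  g <- generateHeatmap(8, 8, 7, 7, 16, 16)
  expect_true(isCorrectApck(c(8, 8), g))
  # a pixel just outside the box is incorrect
  expect_false(isCorrectApck(c(13, 8), g))
  # outside the image counts as incorrect
  expect_false(isCorrectApck(c(-2, 5), g))
  expect_false(isCorrectApck(c(5, 16), g))
  # a support-boundary pixel holding exactly the threshold value is correct
  edge <- matrix(0, 8, 8); edge[4, 4] <- 1; edge[4, 5] <- 0.1
  expect_true(isCorrectApck(c(4, 3), edge))
  # float predictions snap to the nearest pixel
  expect_true(isCorrectApck(c(3.6, 3.4), edge))
})

test_that("aPCK error table equals exhaustive counting with absent keypoints", {
  # 5-frame hand-counted fixture, 2 keypoints, one absent in two frames
  kps <- c("a", "b")
  labels <- list(); preds <- array(0, c(5, 2, 2))
  set.seed(42)
  for (f in 1:5) {
    anns <- data.frame(frame_id = "f", keypoint = "a",
                       x = 8, y = 8, box_w = 5, box_h = 5)
    if (f <= 3)  # b present only in frames 1..3
      anns <- rbind(anns, data.frame(frame_id = "f", keypoint = "b",
                                     x = 3, y = 12, box_w = 3, box_h = 3))
    labels[[f]] <- stackLabels(anns, kps, 16, 16)
  }
  preds[, 1, 1] <- c(8, 8, 0, 8, 7)   # a: correct, correct, miss, correct, correct
  preds[, 1, 2] <- c(8, 9, 0, 8, 8)
  preds[, 2, 1] <- c(3, 0, 3, 5, 5)   # b: correct, miss, correct (f4, f5 absent)
  preds[, 2, 2] <- c(12, 0, 12, 5, 5)
  tab <- apckErrorTable(preds, labels)
  expect_identical(tab$n, c(5L, 3L, 8L))
  expect_identical(tab$n_correct, c(4L, 2L, 6L))
  expect_equal(tab$apck_error[1:2], c(1 / 5, 1 / 3))
  expect_equal(tab$apck_error[3], mean(c(1 / 5, 1 / 3)))
})

test_that("aPCK equals brute-force counting on randomized pairs", {
  n <- 250
  labels <- vector("list", n)
  preds <- array(0, c(n, 1, 2))
  correct <- logical(n)
  for (i in 1:n) {
    ann <- randomAnnotation(16, 16, 5000 + i)
    st <- stackLabels(ann, "kp", 16, 16)
    labels[[i]] <- st
    set.seed(6000 + i)
    preds[i, 1, ] <- runif(2, 0, 15.99)
    correct[i] <- oracleApckCorrect(preds[i, 1, ], keypointGrid(st, 1))
  }
  tab <- apckErrorTable(preds, labels)
  expect_identical(tab$n_correct[1], sum(correct))
  expect_equal(tab$apck_error[1], 1 - mean(correct))
})

test_that("shrinking the label box never decreases the aPCK error", {
  for (i in 1:15) {
    ann <- randomAnnotation(24, 24, 7000 + i)
    ann$box_w <- max(ann$box_w, 5); ann$box_h <- max(ann$box_h, 5)
    small <- ann; small$box_w <- ann$box_w - 2; small$box_h <- ann$box_h - 2
    set.seed(7100 + i)
    pred <- array(runif(2, 0, 23), c(1, 1, 2))
    big_err <- apckErrorTable(pred, list(stackLabels(ann, "kp", 24, 24)))
    small_err <- apckErrorTable(pred, list(stackLabels(small, "kp", 24, 24)))
    expect_gte(small_err$apck_error[1], big_err$apck_error[1])
  }
})

test_that("RMSE reduces to the direct formula", {
  gt <- array(0, c(4, 2, 2))
  gt[, 1, ] <- cbind(c(2, 4, 6, 8), c(1, 3, 5, 7))
  gt[, 2, ] <- cbind(c(10, 10, 10, 10), c(4, 4, 4, 4))
  preds <- gt
  preds[, 1, 1] <- gt[, 1, 1] + 3  # constant (3, 4) offset: RMSE 5
  preds[, 1, 2] <- gt[, 1, 2] + 4
  tab <- rmseTable(preds, gt, c("a", "b"))
  expect_equal(tab$rmse[1], 5)
  expect_equal(tab$rmse[2], 0)
  # random fixture vs direct recomputation
  set.seed(11)
  preds[, 2, ] <- gt[, 2, ] + matrix(rnorm(8), 4, 2)
  tab <- rmseTable(preds, gt, c("a", "b"))
  d <- preds[, 2, ] - gt[, 2, ]
  expect_equal(tab$rmse[2], sqrt(mean(d[, 1]^2 + d[, 2]^2)))
})

test_that("paired keypoint comparison is a paired t-test", {
  a <- c(0.10, 0.12, 0.09, 0.15, 0.11)
  b <- c(0.14, 0.15, 0.12, 0.18, 0.16)
  ht <- pairedKeypointTest(a, b)
  expect_equal(unname(ht$estimate), mean(a - b))
  expect_equal(ht$p.value, stats::t.test(a - b)$p.value)
})
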