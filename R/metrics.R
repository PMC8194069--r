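#' Decode a heatmap by its global maximum
#'
#' Returns the 0-based (x, y) pixel of the grid's maximum value; ties are
#' broken by the smallest row-major index (scan rows top to bottom, each row
#' left to right).
#'
#' @param grid numeric matrix (finite; all-NaN grids are rejected).
#' @return named numeric vector `c(x =, y =)`.
#' @export
argmaxLocation <- function(grid) {
  if (all(is.na(grid))) stop("cannot decode an all-NaN grid")
  m <- max(grid, na.rm = TRUE)
  idx <- which(grid == m, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])[1]  # row-major: by row, then column
  c(x = unname(idx[o, 2]) - 1, y = unname(idx[o, 1]) - 1)
}

#' aPCK correctness of one prediction
#'
#' A prediction is correct iff it lands inside the nonzero support of the
#' ground-truth label heatmap. Float coordinates are snapped to the nearest
#' pixel (round half up); predictions outside the image are incorrect.
#'
#' @param pred numeric (x, y) predicted location, 0-based pixels.
#' @param gt_grid ground-truth heatmap label matrix.
#' @return logical.
#' @export
isCorrectApck <- function(pred, gt_grid) {
  px <- roundHalfUp(pred[[1]]); py <- roundHalfUp(pred[[2]])
  if (px < 0 || px >= ncol(gt_grid) || py < 0 || py >= nrow(gt_grid))
    return(FALSE)
  gt_grid[py + 1, px + 1] > 0
}

#' aPCK error-rate table
#'
#' Per-keypoint adjusted-PCK error rates: error = 1 - n_correct / n_evaluated,
#' where a prediction is evaluated against the label stack of its frame via
#' [isCorrectApck()]. Frames whose label grid is all zero for a keypoint
#' (absent keypoint) are excluded from that keypoint's denominator. The
#' summary row `MEAN` holds the unweighted mean (and the attribute `"sd"` the
#' SD) across keypoints with at least one evaluated frame.
#'
#' @param preds numeric array n_frames x P x 2 (last dim: x, y), or a list of
#'   P x 2 matrices, aligned with `labels`.
#' @param labels list of [HeatmapStack-class] label stacks, one per frame,
#'   all sharing the same keypoint order.
#' @return data.frame (keypoint, n, n_correct, apck_error) with a MEAN row.
#' @export
apckErrorTable <- function(preds, labels) {
  stopifnot(length(labels) >= 1)
  kps <- keypointNames(labels[[1]])
  P <- length(kps)
  if (is.list(preds)) {
    preds <- array(unlist(lapply(preds, as.numeric)), c(P, 2, length(preds)))
    preds <- aperm(preds, c(3, 1, 2))
  }
  stopifnot(dim(preds)[1] == length(labels), dim(preds)[2] == P)
  n_eval <- integer(P); n_corr <- integer(P)
  for (f in seq_along(labels)) {
    g <- heatmapArray(labels[[f]])
    for (p in seq_len(P)) {
      grid <- g[, , p]
      if (max(grid) == 0) next  # absent keypoint: not evaluated
      n_eval[p] <- n_eval[p] + 1L
      if (isCorrectApck(preds[f, p, ], grid)) n_corr[p] <- n_corr[p] + 1L
    }
  }
  err <- ifelse(n_eval > 0, 1 - n_corr / n_eval, NA_real_)
  out <- data.frame(keypoint = kps, n = n_eval, n_correct = n_corr,
                    apck_error = err, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(keypoint = "MEAN", n = sum(n_eval),
                               n_correct = sum(n_corr),
                               apck_error = mean(err, na.rm = TRUE)))
  attr(out, "sd") <- stats::sd(err[!is.na(err)])
  out
}

#' RMSE table
#'
#' Per-keypoint root-mean-square Euclidean distance (pixels) between
#' predicted and ground-truth point coordinates. Frames with missing ground
#' truth (NA coordinates) are excluded per keypoint.
#'
#' @param preds as in [apckErrorTable()].
#' @param gt_points numeric array n_frames x P x 2 of true (x, y), NA where
#'   the keypoint is absent.
#' @param keypoints keypoint names (length P).
#' @return data.frame (keypoint, n, rmse) with a MEAN row.
#' @export
rmseTable <- function(preds, gt_points, keypoints) {
  P <- length(keypoints)
  if (is.list(preds)) {
    preds <- array(unlist(lapply(preds, as.numeric)), c(P, 2, length(preds)))
    preds <- aperm(preds, c(3, 1, 2))
  }
  stopifnot(identical(dim(preds), dim(gt_points)))
  n <- integer(P); rmse <- numeric(P)
  for (p in seq_len(P)) {
    ok <- !is.na(gt_points[, p, 1]) & !is.na(gt_points[, p, 2])
    n[p] <- sum(ok)
    d2 <- (preds[ok, p, 1] - gt_points[ok, p, 1])^2 +
      (preds[ok, p, 2] - gt_points[ok, p, 2])^2
    rmse[p] <- if (n[p] > 0) sqrt(mean(d2)) else NA_real_
  }
  out <- data.frame(keypoint = keypoints, n = n, rmse = rmse,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(keypoint = "MEAN", n = sum(n),
                        rmse = mean(rmse, na.rm = TRUE)))
}

#' Paired comparison of two models' per-keypoint error rates
#'
#' Paired t-test, paired by keypoint, between two vectors of per-keypoint
#' error rates (e.g. the `apck_error` columns of two [apckErrorTable()]
#' reports without their MEAN rows).
#'
#' @param err_a,err_b numeric vectors of per-keypoint error rates.
#' @return the `htest` object from [stats::t.test()].
#' @export
pairedKeypointTest <- function(err_a, err_b) {
  stopifnot(length(err_a) == length(err_b))
  stats::t.test(err_a, err_b, paired = TRUE)
}

#' Write an evaluation report as CSV
#'
#' @param report data.frame from [apckErrorTable()] or [rmseTable()].
#' @param path output CSV path.
#' @export
writeEvalReport <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
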