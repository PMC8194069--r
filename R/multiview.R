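#' Local maxima of a confidence map
#'
#' Candidate peak detection for multi-view correction: the grid is smoothed
#' with a Gaussian filter of `smooth_sigma`, then every pixel strictly
#' greater than all of its 8 neighbours (missing neighbours at borders are
#' ignored) and at least `min_rel` times the global maximum is returned,
#' sorted by descending score. The global maximum itself is always included
#' (row-major tie-break on plateaus).
#'
#' @param grid numeric H x W heatmap matrix.
#' @param smooth_sigma Gaussian smoothing sigma in pixels (>= 0; 0 skips
#'   smoothing).
#' @param min_rel minimum peak height relative to the global max, in (0, 1].
#' @return data.frame (x, y, score), 0-based pixel coordinates; empty for an
#'   all-zero grid.
#' @export
localMaxima <- function(grid, smooth_sigma = 3, min_rel = 0.1) {
  stopifnot(smooth_sigma >= 0, min_rel > 0, min_rel <= 1)
  if (max(grid) <= 0)
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  sm <- if (smooth_sigma > 0) .gauss_smooth(grid, smooth_sigma) else grid
  H <- nrow(sm); W <- ncol(sm)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- sm
  is_peak <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2:(H + 1)) + dy, (2:(W + 1)) + dx]
    # -Inf border neighbours are vacuously smaller
    is_peak <- is_peak & (sm > nb | !is.finite(nb))
  }
  gmax <- max(sm)
  keep <- which(is_peak & sm >= min_rel * gmax, arr.ind = TRUE)
  gm <- argmaxLocation(sm)
  xs <- keep[, 2] - 1; ys <- keep[, 1] - 1
  if (!any(xs == gm["x"] & ys == gm["y"])) {
    xs <- c(xs, gm[["x"]]); ys <- c(ys, gm[["y"]])
  }
  score <- sm[cbind(ys + 1, xs + 1)]
  o <- order(-score, ys, xs)
  data.frame(x = xs[o], y = ys[o], score = score[o])
}

#' Correct keypoint locations using a paired orthogonal view
#'
#' For camera pairs sharing the x-axis, the better-predicted reference view
#' constrains the corrected view: for each paired keypoint, candidate peaks
#' are gathered from its heatmap in the corrected view and its location is
#' replaced by the candidate whose x-coordinate differs least from the
#' reference-view x for the same keypoint. Ties on |dx| go to the higher
#' score, then the smaller row-major index. Unpaired keypoints are untouched;
#' a keypoint with no candidates keeps its original location and is flagged.
#'
#' @param side_stack [HeatmapStack-class] of corrected-view predictions.
#' @param side_locs P x 2 matrix (x, y) of current corrected-view locations,
#'   rows named or ordered by the stack's keypoints.
#' @param bottom_locs named matrix / data.frame of reference-view locations
#'   with columns x, y and rownames the reference keypoint names.
#' @param pairing a [ViewPairing-class].
#' @param smooth_sigma,min_rel candidate detection, see [localMaxima()].
#' @return data.frame (keypoint, x, y, corrected, flagged); `corrected` is
#'   TRUE where the location was replaced by a different candidate.
#' @export
correctKeypoints <- function(side_stack, side_locs, bottom_locs, pairing,
                             smooth_sigma = 3, min_rel = 0.1) {
  stopifnot(is(side_stack, "HeatmapStack"), is(pairing, "ViewPairing"))
  kps <- keypointNames(side_stack)
  if (is.null(rownames(side_locs))) rownames(side_locs) <- kps
  out <- data.frame(keypoint = kps,
                    x = side_locs[kps, 1], y = side_locs[kps, 2],
                    corrected = FALSE, flagged = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(pairing@side)) {
    kp <- pairing@side[i]
    ref_kp <- pairing@bottom[i]
    p <- match(kp, kps)
    if (is.na(p)) next
    x_ref <- if (is.data.frame(bottom_locs)) bottom_locs[ref_kp, "x"]
             else bottom_locs[ref_kp, 1]
    if (is.na(x_ref)) next
    cand <- localMaxima(heatmapArray(side_stack)[, , p], smooth_sigma, min_rel)
    if (nrow(cand) == 0) {
      out$flagged[p] <- TRUE
      next
    }
    dx <- abs(cand$x - x_ref)
    o <- order(dx, -cand$score, cand$y, cand$x)
    best <- cand[o[1], ]
    if (best$x != out$x[p] || best$y != out$y[p]) out$corrected[p] <- TRUE
    out$x[p] <- best$x; out$y[p] <- best$y
  }
  out
}

#' Read / write a view pairing as JSON
#'
#' The JSON holds `reference_view` and an array of `[side, bottom]` keypoint
#' name pairs.
#'
#' @param path JSON path.
#' @export
readPairing <- function(path) {
  o <- jsonlite::fromJSON(path)
  pairs <- o$pairs
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  ViewPairing(pairs[, 1], pairs[, 2],
              if (!is.null(o$reference_view)) o$reference_view else "bottom")
}

#' @rdname readPairing
#' @param pairing a [ViewPairing-class].
#' @export
writePairing <- function(pairing, path) {
  jsonlite::write_json(
    list(reference_view = pairing@reference_view,
         pairs = cbind(pairing@side, pairing@bottom)),
    path, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
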