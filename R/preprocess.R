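#' AugmentSpec: keypoint-consistent augmentation parameters
#'
#' @slot rotation_range numeric length 2, degrees (default (-10, 10)).
#' @slot flip_mode one of "none", "y_axis", "all_axes".
#' @slot seed integer.
#' @export
setClass("AugmentSpec",
  representation(rotation_range = "numeric", flip_mode = "character",
                 seed = "integer"))

setValidity("AugmentSpec", function(object) {
  if (length(object@rotation_range) != 2L ||
      object@rotation_range[1] > object@rotation_range[2])
    return("rotation_range must be an ordered pair of degrees")
  if (!object@flip_mode %in% c("none", "y_axis", "all_axes"))
    return("flip_mode must be none, y_axis or all_axes")
  TRUE
})

#' @rdname AugmentSpec-class
#' @param rotation_range,flip_mode,seed see slot documentation.
#' @export
AugmentSpec <- function(rotation_range = c(-10, 10), flip_mode = "none",
                        seed = 0L) {
  new("AugmentSpec", rotation_range = rotation_range, flip_mode = flip_mode,
      seed = as.integer(seed))
}

#' Split frame ids into train / validation / test sets
#'
#' Deterministic seeded split with sizes matching the ratios (largest
#' remainder rounding; the default 0.6/0.2/0.2 realises the 3:1:1 split).
#' With `group_by = "video"` ids of the form `<video>_<frame>` (or any prefix
#' before the last underscore) are kept whole: no video spans two splits, and
#' group sizes are balanced greedily towards the target frame counts.
#'
#' @param ids character vector of frame ids.
#' @param ratios three non-negative numbers summing to 1.
#' @param group_by `NULL` (frame-level) or `"video"`.
#' @param seed integer seed.
#' @return named list of id vectors: `train`, `validation`, `test`.
#' @export
splitDataset <- function(ids, ratios = c(0.6, 0.2, 0.2), group_by = NULL,
                         seed = 0L) {
  stopifnot(length(ids) > 0, length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  ids <- as.character(ids)
  if (is.null(group_by)) {
    n <- length(ids)
    sizes <- largestRemainder(n * ratios)
    perm <- withSeed(seed, sample.int(n))
    bins <- rep.int(1:3, sizes)
    out <- split(ids[perm], bins)
  } else {
    if (!identical(group_by, "video"))
      stop("group_by must be NULL or 'video'")
    vids <- sub("_[^_]*$", "", ids)
    groups <- split(ids, vids)
    if (length(groups) < sum(ratios > 0))
      stop("fewer videos than nonzero splits; cannot group by video")
    ord <- withSeed(seed, sample(names(groups)))
    target <- length(ids) * ratios
    assigned <- numeric(3)
    out <- list(character(0), character(0), character(0))
    for (g in ord) {
      deficit <- target - assigned
      k <- which.max(deficit)
      out[[k]] <- c(out[[k]], groups[[g]])
      assigned[k] <- assigned[k] + length(groups[[g]])
    }
  }
  names(out) <- c("train", "validation", "test")
  lapply(out, unname)
}

largestRemainder <- function(x) {
  fl <- floor(x)
  rem <- sum(round(sum(x))) - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# forward affine map of 0-based coords for a rotation about the image centre
# onto an expanded canvas; returns function(x, y) -> list(x, y) plus dims
rotationMap <- function(width, height, angle) {
  th <- angle * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  W2 <- as.integer(ceiling(width * abs(c_) + height * abs(s_) - 1e-9))
  H2 <- as.integer(ceiling(width * abs(s_) + height * abs(c_) - 1e-9))
  cx <- (width - 1) / 2; cy <- (height - 1) / 2
  cx2 <- (W2 - 1) / 2; cy2 <- (H2 - 1) / 2
  list(
    width = W2, height = H2,
    forward = function(x, y) {
      list(x = c_ * (x - cx) - s_ * (y - cy) + cx2,
           y = s_ * (x - cx) + c_ * (y - cy) + cy2)
    },
    inverse = function(x, y) {
      list(x = c_ * (x - cx2) + s_ * (y - cy2) + cx,
           y = -s_ * (x - cx2) + c_ * (y - cy2) + cy)
    })
}

#' Rotate a frame together with its keypoint annotations
#'
#' Rotates about the image centre onto an expanded canvas (the axis-aligned
#' bounding box of the rotated image) padded with zeros, so no content is
#' cropped. The image is resampled bilinearly; annotation coordinates are
#' mapped exactly by the same rotation-plus-translation. Box sizes are
#' unchanged. Positive angles rotate clockwise on screen (y axis pointing
#' down).
#'
#' @param frame H x W numeric matrix.
#' @param anns annotation data.frame (columns x, y at least).
#' @param angle rotation angle in degrees.
#' @return list with elements `frame` and `anns`.
#' @export
rotateWithLabels <- function(frame, anns, angle) {
  m <- rotationMap(ncol(frame), nrow(frame), angle)
  xs <- rep(0:(m$width - 1), each = m$height)
  ys <- rep(0:(m$height - 1), times = m$width)
  src <- m$inverse(xs, ys)
  out <- matrix(bilinearSample(frame, src$x, src$y),
                nrow = m$height, ncol = m$width)
  if (nrow(anns) > 0) {
    mapped <- m$forward(anns$x, anns$y)
    anns$x <- mapped$x; anns$y <- mapped$y
  }
  list(frame = out, anns = anns)
}

#' Mirror a frame together with its keypoint annotations
#'
#' @param frame H x W numeric matrix.
#' @param anns annotation data.frame.
#' @param axis `"y"` (left-right mirror, x -> W-1-x), `"x"` (top-bottom,
#'   y -> H-1-y) or `"xy"` (both).
#' @param swap optional named character vector mapping keypoint names to
#'   their mirror partners (e.g. `c(L = "R", R = "L")`); must be a bijection.
#' @return list with elements `frame` and `anns`.
#' @export
flipWithLabels <- function(frame, anns, axis = c("y", "x", "xy"),
                           swap = NULL) {
  axis <- match.arg(axis)
  W <- ncol(frame); H <- nrow(frame)
  if (axis %in% c("y", "xy")) {
    frame <- frame[, W:1, drop = FALSE]
    if (nrow(anns) > 0) anns$x <- W - 1 - anns$x
  }
  if (axis %in% c("x", "xy")) {
    frame <- frame[H:1, , drop = FALSE]
    if (nrow(anns) > 0) anns$y <- H - 1 - anns$y
  }
  if (!is.null(swap) && nrow(anns) > 0) {
    if (anyDuplicated(unname(swap)) || anyDuplicated(names(swap)) ||
        !setequal(names(swap), unname(swap)))
      stop("keypoint swap map must be a bijection")
    hit <- anns$keypoint %in% names(swap)
    anns$keypoint[hit] <- unname(swap[anns$keypoint[hit]])
  }
  list(frame = frame, anns = anns)
}

# 1D resampling weight matrix: pixel-area relation when shrinking
# (each output pixel averages its exact coverage interval), bilinear when
# enlarging; rows sum to 1
resampleWeights <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  if (n_out <= n_in) {
    scale <- n_in / n_out
    for (o in seq_len(n_out)) {
      lo <- (o - 1) * scale; hi <- o * scale
      i0 <- floor(lo); i1 <- ceiling(hi) - 1
      for (i in i0:i1) {
        cover <- min(hi, i + 1) - max(lo, i)
        if (cover > 0) A[o, i + 1] <- cover
      }
    }
  } else {
    for (o in seq_len(n_out)) {
      src <- (o - 0.5) * n_in / n_out - 0.5
      i0 <- floor(src); w <- src - i0
      i0c <- min(max(i0, 0), n_in - 1)
      i1c <- min(max(i0 + 1, 0), n_in - 1)
      A[o, i0c + 1] <- A[o, i0c + 1] + (1 - w)
      A[o, i1c + 1] <- A[o, i1c + 1] + w
    }
  }
  A / rowSums(A)
}

#' Resize a frame with pixel-area relation, mapping labels consistently
#'
#' Downsampling uses the pixel-area relation (each output pixel is the exact
#' area average of the input region it covers, the preferred resampler for
#' decimation); upsampling uses bilinear interpolation. Annotation
#' coordinates are scaled by `out_w / W` and `out_h / H`; box dimensions are
#' scaled the same way and kept >= 1.
#'
#' @param frame H x W numeric matrix.
#' @param anns annotation data.frame.
#' @param out_w,out_h target dimensions (>= 1).
#' @return list with elements `frame` and `anns`.
#' @export
resizeAreaWithLabels <- function(frame, anns, out_w, out_h) {
  stopifnot(out_w >= 1, out_h >= 1)
  Ay <- resampleWeights(nrow(frame), out_h)
  Ax <- resampleWeights(ncol(frame), out_w)
  out <- Ay %*% frame %*% t(Ax)
  if (nrow(anns) > 0) {
    sx <- out_w / ncol(frame); sy <- out_h / nrow(frame)
    anns$x <- anns$x * sx
    anns$y <- anns$y * sy
    if ("box_w" %in% names(anns)) {
      anns$box_w <- pmax(1L, as.integer(round(anns$box_w * sx)))
      anns$box_h <- pmax(1L, as.integer(round(anns$box_h * sy)))
    }
  }
  list(frame = out, anns = anns)
}

#' Randomly augment one frame with its annotations
#'
#' Draws a rotation angle uniformly from the spec's range and applies each
#' admissible flip with probability 0.5. All randomness comes from the spec
#' seed combined with `index` so each sample is independently reproducible.
#'
#' @param frame H x W numeric matrix.
#' @param anns annotation data.frame.
#' @param spec an [AugmentSpec-class].
#' @param index sample index used to derive the substream.
#' @param swap optional keypoint swap map forwarded to [flipWithLabels()].
#' @return list with elements `frame`, `anns`, `angle`, `flips`.
#' @export
augmentWithLabels <- function(frame, anns, spec, index = 1L, swap = NULL) {
  stopifnot(is(spec, "AugmentSpec"))
  draws <- withSeed(hash31(paste0("augment:", spec@seed, ":", index)), {
    list(angle = stats::runif(1, spec@rotation_range[1],
                              spec@rotation_range[2]),
         flip = stats::runif(3))
  })
  out <- rotateWithLabels(frame, anns, draws$angle)
  flips <- character(0)
  axes <- switch(spec@flip_mode, none = character(0), y_axis = "y",
                 all_axes = c("x", "y", "xy"))
  for (i in seq_along(axes)) {
    if (draws$flip[i] < 0.5) {
      out <- flipWithLabels(out$frame, out$anns, axes[i], swap = swap)
      flips <- c(flips, axes[i])
    }
  }
  list(frame = out$frame, anns = out$anns, angle = draws$angle, flips = flips)
}

#' Build training targets from a label stack
#'
#' Multiplies every grid by the training peak value (contrast between label
#' region and background; evaluation-side heatmaps are never scaled) and
#' replicates the scaled stack once per supervision stage.
#'
#' @param stack a [HeatmapStack-class] label stack.
#' @param peak positive scale factor (default 16).
#' @param stages number of supervision stages (copies), >= 1.
#' @return list of `stages` scaled [HeatmapStack-class] objects.
#' @export
makeTrainingTarget <- function(stack, peak = 16, stages = 1L) {
  stopifnot(is(stack, "HeatmapStack"), peak > 0, stages >= 1)
  scaled <- HeatmapStack(stack@grids * peak, stack@keypoints, stack@metadata)
  rep(list(scaled), stages)
}
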