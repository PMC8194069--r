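#' Temporal window indices around a target frame
#'
#' For a target frame t, skip ratio s and frame range f, the window holds the
#' 2f + 1 indices t + k * s for k = -f..f. At sequence edges indices are
#' clamped into [0, n_frames - 1] (boundary frames are replicated rather than
#' dropped, so every frame has a full window). Frame indices are 0-based.
#'
#' @param t target frame index (0-based).
#' @param spec a [FrameWindowSpec-class].
#' @param n_frames sequence length.
#' @return integer vector of 2f + 1 frame indices; the centre element is t.
#' @examples
#' buildWindow(10, FrameWindowSpec(skip_ratio = 2, frame_range = 3), 100)
#' @export
buildWindow <- function(t, spec, n_frames) {
  stopifnot(is(spec, "FrameWindowSpec"))
  if (t < 0 || t >= n_frames)
    stop(sprintf("target index %d outside [0, %d]", t, n_frames - 1))
  k <- -spec@frame_range:spec@frame_range
  idx <- as.integer(t) + k * spec@skip_ratio
  as.integer(pmin(pmax(idx, 0L), n_frames - 1L))
}

#' Dense optical flow between two frames
#'
#' Farneback dense flow: quadratic polynomial expansion over a Gaussian
#' applicability, coarse-to-fine over an image pyramid, with a windowed
#' normal-equation solve per pixel. The flow is estimated with the target
#' frame as reference so that, for each target pixel p, `src` at p + (u, v)
#' corresponds to `ref` at p (backward mapping; warping by it leaves no
#' holes). Multi-channel frames are reduced to Rec.601 luminance first.
#'
#' @param ref target (reference) frame, H x W matrix or H x W x 3 array.
#' @param src source frame of the same dimensions.
#' @param params a [FarnebackParams-class].
#' @return a [FlowField-class].
#' @export
denseFlow <- function(ref, src, params = FarnebackParams()) {
  stopifnot(is(params, "FarnebackParams"))
  ref <- luminance(ref); src <- luminance(src)
  if (!identical(dim(ref), dim(src)))
    stop("ref and src frames must share dimensions")
  fl <- .fb_flow(ref, src, params@window_size, params@pyramid_scale,
                 params@levels, params@iterations, params@poly_n,
                 params@poly_sigma)
  FlowField(fl$u, fl$v)
}

#' Warp a heatmap stack through a flow field
#'
#' Backward bilinear sampling: morphed(p) = h(p + (u, v)(p)); samples falling
#' outside the grid contribute 0 (confidence mass is never fabricated at the
#' borders). Applied identically to all keypoint grids.
#'
#' @param stack a [HeatmapStack-class].
#' @param flow a [FlowField-class] of matching dimensions.
#' @return the morphed [HeatmapStack-class].
#' @export
warpHeatmap <- function(stack, flow) {
  stopifnot(is(stack, "HeatmapStack"), is(flow, "FlowField"))
  HeatmapStack(.warp_cube(heatmapArray(stack), flowU(flow), flowV(flow)),
               keypointNames(stack), stack@metadata)
}

#' Morph a window of heatmap stacks onto the target frame
#'
#' For each window member k, computes the dense flow from the target frame to
#' frame k and warps that member's heatmaps onto the target coordinates. The
#' centre member is the target itself and is returned unmodified.
#'
#' @param frames list of 2f + 1 frames aligned with a [buildWindow()] output.
#' @param stacks list of 2f + 1 [HeatmapStack-class] predictions, aligned
#'   with `frames`.
#' @param t_pos 1-based position of the target frame within the window
#'   (default the centre).
#' @param params a [FarnebackParams-class].
#' @return list of 2f + 1 morphed [HeatmapStack-class] objects.
#' @export
morphWindow <- function(frames, stacks, t_pos = (length(frames) + 1L) %/% 2L,
                        params = FarnebackParams()) {
  if (length(frames) != length(stacks))
    stop("frames and stacks lists are misaligned")
  ref <- luminance(frames[[t_pos]])
  others <- setdiff(seq_along(frames), t_pos)
  # the reference pyramid and its polynomial expansions are shared across
  # all window members
  flows <- .fb_flow_batch(ref, lapply(frames[others], luminance),
                          params@window_size, params@pyramid_scale,
                          params@levels, params@iterations, params@poly_n,
                          params@poly_sigma)
  out <- vector("list", length(frames))
  out[[t_pos]] <- stacks[[t_pos]]
  for (i in seq_along(others)) {
    k <- others[i]
    out[[k]] <- HeatmapStack(
      .warp_cube(heatmapArray(stacks[[k]]), flows[[i]]$u, flows[[i]]$v),
      keypointNames(stacks[[k]]), stacks[[k]]@metadata)
  }
  out
}

#' Aggregate morphed heatmaps with per-keypoint window weights
#'
#' The trainable 1 x 1 convolution of the temporal model: for keypoint p the
#' output grid is the pixelwise weighted sum over window offsets,
#' y_p = sum_k w[p, k] * o_k_p, with no bias and no nonlinearity. Negative
#' values are clipped to 0 only when `clip = TRUE` (decoding/serialisation);
#' raw values are retained for training.
#'
#' @param morphed list of 2f + 1 morphed [HeatmapStack-class] objects.
#' @param weights an [AggregatorWeights-class] with one column per member.
#' @param clip clip negative values at 0 (default FALSE).
#' @return the aggregated [HeatmapStack-class].
#' @export
aggregateStacks <- function(morphed, weights, clip = FALSE) {
  stopifnot(is(weights, "AggregatorWeights"))
  K <- length(morphed)
  if (K != ncol(weights@w))
    stop(sprintf("window length %d does not match %d weight columns",
                 K, ncol(weights@w)))
  d <- dim(heatmapArray(morphed[[1]]))
  out <- array(0, d)
  for (k in seq_len(K)) {
    g <- heatmapArray(morphed[[k]])
    for (p in seq_len(d[3])) out[, , p] <- out[, , p] + weights@w[p, k] * g[, , p]
  }
  if (clip) out[out < 0] <- 0
  new("HeatmapStack", grids = out, keypoints = keypointNames(morphed[[1]]),
      metadata = list())
}

# per-keypoint normal-equation accumulator for streaming least squares:
# A[p] += X'X, b[p] += X'y over the pixels of one window
accumulateNormalEq <- function(acc, morphed, label) {
  K <- length(morphed); d <- dim(heatmapArray(label))
  if (is.null(acc)) {
    acc <- list(A = rep(list(matrix(0, K, K)), d[3]),
                b = rep(list(numeric(K)), d[3]),
                yty = numeric(d[3]), n = 0)
  }
  cubes <- lapply(morphed, heatmapArray)
  lab <- heatmapArray(label)
  npx <- d[1] * d[2]
  for (p in seq_len(d[3])) {
    X <- vapply(cubes, function(g) as.numeric(g[, , p]), numeric(npx))
    if (!is.matrix(X)) X <- matrix(X, nrow = npx)
    y <- as.numeric(lab[, , p])
    acc$A[[p]] <- acc$A[[p]] + crossprod(X)
    acc$b[[p]] <- acc$b[[p]] + drop(crossprod(X, y))
    acc$yty[p] <- acc$yty[p] + sum(y * y)
  }
  acc$n <- acc$n + npx
  acc
}

solveNormalEq <- function(acc, keypoints, offsets) {
  K <- length(offsets)
  w <- matrix(0, length(keypoints), K)
  mse <- numeric(length(keypoints))
  for (p in seq_along(keypoints)) {
    A <- acc$A[[p]]; b <- acc$b[[p]]
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) {
      warning(sprintf(
        "rank-deficient system for keypoint '%s'; using minimum-norm solution",
        keypoints[p]))
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      sol <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
      sol <- drop(sol)
    }
    w[p, ] <- sol
    mse[p] <- (acc$yty[p] - 2 * sum(sol * b) +
                 drop(t(sol) %*% A %*% sol)) / acc$n
  }
  list(weights = AggregatorWeights(w, keypoints, offsets),
       mse = pmax(mse, 0))
}

#' Fit aggregator weights from training windows
#'
#' Minimises the pixelwise mean squared error between the aggregated window
#' and the (peak-scaled) label stack. Two solvers are available: exact
#' per-keypoint linear least squares (`"ls"`, the default; streaming normal
#' equations, minimum-norm fallback with a warning when rank-deficient) and
#' stochastic gradient descent (`"gd"`: ADAM with beta1 0.9 / beta2 0.999,
#' learning rate 1e-4, 30 epochs, one update per training window per epoch,
#' weights initialised uniformly at 1 / (2f + 1)).
#'
#' @param windows list of training windows; each element is a list with
#'   `morphed` (list of 2f + 1 morphed [HeatmapStack-class]) and `label`
#'   (the target-frame label [HeatmapStack-class], scaled like training
#'   targets).
#' @param method `"ls"` or `"gd"`.
#' @param offsets integer window offsets (defaults to -f..f).
#' @param lr,epochs,beta1,beta2 ADAM hyperparameters for `"gd"`.
#' @param seed seed for the `"gd"` window shuffling.
#' @return an [AggregatorWeights-class]; the achieved training MSE per
#'   keypoint is in the attribute `"mse"`.
#' @export
fitWeights <- function(windows, method = c("ls", "gd"), offsets = NULL,
                       lr = 1e-4, epochs = 30L, beta1 = 0.9, beta2 = 0.999,
                       seed = 0L) {
  method <- match.arg(method)
  stopifnot(length(windows) >= 1)
  K <- length(windows[[1]]$morphed)
  keypoints <- keypointNames(windows[[1]]$label)
  if (is.null(offsets)) offsets <- seq_len(K) - 1L - (K - 1L) %/% 2L
  if (method == "ls") {
    acc <- NULL
    for (wnd in windows) acc <- accumulateNormalEq(acc, wnd$morphed, wnd$label)
    fit <- solveNormalEq(acc, keypoints, offsets)
    out <- fit$weights
    attr(out, "mse") <- fit$mse
    return(out)
  }
  # ADAM, one stochastic update per window per epoch
  P <- length(keypoints)
  w <- matrix(1 / K, P, K)
  m <- matrix(0, P, K); v <- matrix(0, P, K)
  step <- 0L
  Xs <- lapply(windows, function(wnd) {
    lab <- heatmapArray(wnd$label)
    npx <- prod(dim(lab)[1:2])
    lapply(seq_len(P), function(p) {
      X <- vapply(wnd$morphed, function(s) as.numeric(heatmapArray(s)[, , p]),
                  numeric(npx))
      if (!is.matrix(X)) X <- matrix(X, nrow = npx)
      list(X = X, y = as.numeric(lab[, , p]))
    })
  })
  for (e in seq_len(epochs)) {
    ord <- withSeed(hash31(paste("gd", seed, e, sep = ":")),
                    sample.int(length(windows)))
    for (j in ord) {
      step <- step + 1L
      for (p in seq_len(P)) {
        X <- Xs[[j]][[p]]$X; y <- Xs[[j]][[p]]$y
        r <- drop(X %*% w[p, ]) - y
        g <- drop(crossprod(X, r)) * (2 / length(y))
        m[p, ] <- beta1 * m[p, ] + (1 - beta1) * g
        v[p, ] <- beta2 * v[p, ] + (1 - beta2) * g^2
        mh <- m[p, ] / (1 - beta1^step)
        vh <- v[p, ] / (1 - beta2^step)
        w[p, ] <- w[p, ] - lr * mh / (sqrt(vh) + 1e-8)
      }
    }
  }
  mse <- vapply(seq_len(P), function(p) {
    tot <- 0; n <- 0
    for (j in seq_along(windows)) {
      r <- drop(Xs[[j]][[p]]$X %*% w[p, ]) - Xs[[j]][[p]]$y
      tot <- tot + sum(r^2); n <- n + length(r)
    }
    tot / n
  }, numeric(1))
  out <- AggregatorWeights(w, keypoints, offsets)
  attr(out, "mse") <- mse
  out
}

#' Aggregated prediction for one target frame
#'
#' Composes the full temporal step for a single target frame: gathers the
#' window, morphs the supplied per-frame base predictions onto the target,
#' aggregates them with the fitted weights (negative values clipped for
#' decoding) and decodes each keypoint at the global maximum.
#'
#' @param frames list of all frames of the sequence (0-based order).
#' @param stacks list of base-model [HeatmapStack-class] predictions aligned
#'   with `frames`.
#' @param t target frame index (0-based).
#' @param spec a [FrameWindowSpec-class].
#' @param weights an [AggregatorWeights-class].
#' @param params a [FarnebackParams-class].
#' @return list with `stack` (aggregated [HeatmapStack-class]) and
#'   `locations` (P x 2 matrix of decoded x, y).
#' @export
predictTarget <- function(frames, stacks, t, spec, weights,
                          params = FarnebackParams()) {
  idx <- buildWindow(t, spec, length(frames))
  morphed <- morphWindow(frames[idx + 1L], stacks[idx + 1L],
                         t_pos = spec@frame_range + 1L, params = params)
  agg <- aggregateStacks(morphed, weights, clip = TRUE)
  g <- heatmapArray(agg)
  locs <- t(vapply(seq_len(dim(g)[3]),
                   function(p) argmaxLocation(g[, , p]), numeric(2)))
  rownames(locs) <- keypointNames(agg)
  colnames(locs) <- c("x", "y")
  list(stack = agg, locations = locs)
}

#' Persist / load aggregator weights as JSON
#'
#' @param weights an [AggregatorWeights-class].
#' @param path JSON path.
#' @export
writeWeights <- function(weights, path) {
  jsonlite::write_json(
    list(keypoints = weights@keypoints, offsets = weights@offsets,
         w = weights@w),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeWeights
#' @return `readWeights`: an [AggregatorWeights-class].
#' @export
readWeights <- function(path) {
  o <- jsonlite::fromJSON(path)
  w <- o$w
  if (is.list(w)) w <- do.call(rbind, w)
  if (!is.matrix(w)) w <- matrix(w, nrow = 1)
  AggregatorWeights(w, o$keypoints, o$offsets)
}
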