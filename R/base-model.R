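#' Validate a base-model prediction stack against the predictor contract
#'
#' Any single-frame predictor can feed the temporal aggregator as long as it
#' returns one finite, non-negative, image-sized heatmap per keypoint in the
#' dataset's keypoint order. This check is applied before stacks enter the
#' flow module.
#'
#' @param stack a [HeatmapStack-class].
#' @param width,height expected frame dimensions.
#' @param keypoints expected keypoint order.
#' @return the stack, invisibly; errors describe the first violation.
#' @export
validatePredictions <- function(stack, width, height, keypoints) {
  if (!is(stack, "HeatmapStack")) stop("predictions must be a HeatmapStack")
  d <- dim(heatmapArray(stack))
  if (d[1] != height || d[2] != width)
    stop(sprintf("prediction grids are %d x %d px, expected %d x %d",
                 d[2], d[1], width, height))
  if (!identical(keypointNames(stack), as.character(keypoints)))
    stop("prediction keypoint order does not match the dataset order")
  if (min(heatmapArray(stack)) < 0)
    stop("prediction grids must be non-negative")
  invisible(stack)
}

# seeded draw for one (frame, keypoint): jitter, error flag, error direction
mockDraws <- function(cfg, frame_id, keypoint) {
  withSeed(hash31(paste("mock", cfg@seed, frame_id, keypoint, sep = ":")), {
    list(jitter = stats::rnorm(2, 0, max(cfg@loc_noise_sigma, 1e-12)),
         err_u = stats::runif(1),
         angles = stats::runif(64, 0, 2 * pi))
  })
}

# displace (x, y) by dist at the first seeded angle that stays inside the
# image; falls back to coordinate clamping
displaceInside <- function(x, y, dist, angles, width, height) {
  for (a in angles) {
    nx <- x + dist * cos(a); ny <- y + dist * sin(a)
    if (nx >= 0 && nx <= width - 1 && ny >= 0 && ny <= height - 1)
      return(c(nx, ny))
  }
  a <- angles[1]
  c(min(max(x + dist * cos(a), 0), width - 1),
    min(max(y + dist * sin(a), 0), height - 1))
}

#' Mock base-model prediction for one frame
#'
#' Emulates a trained single-frame predictor, including its failure mode
#' under temporary obstruction: for every visible keypoint a Gaussian peak is
#' rendered at the true location jittered by `loc_noise_sigma`; with
#' probability `error_prob` -- and always when the keypoint is occluded --
#' the peak is instead displaced by `error_displacement` pixels in a seeded
#' random direction (kept inside the image). Absent keypoints (all-zero
#' truth) yield all-zero grids. Identical (seed, frame_id, keypoint) always
#' produce identical output.
#'
#' @param truth ground-truth [HeatmapStack-class] for the frame (peaks are
#'   re-rendered at its per-keypoint argmax), or a P x 2 matrix of true
#'   (x, y) locations with NA rows for absent keypoints plus a `keypoints`
#'   attribute-free companion argument.
#' @param occluded logical vector (length P) of occlusion flags.
#' @param cfg a [MockPredictorConfig-class].
#' @param frame_id frame identifier entering the per-frame substream.
#' @param force_error optional logical vector overriding the Bernoulli error
#'   draw (from [makeErrorSchedule()]); occlusion still forces an error.
#' @param keypoints keypoint names when `truth` is a coordinate matrix.
#' @return a [HeatmapStack-class] of mock predictions; the realised peak
#'   locations and error flags are in `metadata$locations` / `metadata$error`.
#' @export
mockPredict <- function(truth, occluded, cfg, frame_id = "0",
                        force_error = NULL, keypoints = NULL) {
  stopifnot(is(cfg, "MockPredictorConfig"))
  if (is(truth, "HeatmapStack")) {
    g <- heatmapArray(truth)
    keypoints <- keypointNames(truth)
    locs <- t(vapply(seq_len(dim(g)[3]), function(p) {
      if (max(g[, , p]) == 0) c(NA_real_, NA_real_)
      else argmaxLocation(g[, , p])
    }, numeric(2)))
    height <- dim(g)[1]; width <- dim(g)[2]
  } else {
    locs <- truth
    stopifnot(!is.null(keypoints), !is.null(attr(locs, "dim")))
    width <- attr(locs, "width"); height <- attr(locs, "height")
    if (is.null(width) || is.null(height))
      stop("coordinate-matrix truth needs width/height attributes")
  }
  P <- length(keypoints)
  occluded <- rep_len(occluded, P)
  if (is.null(force_error)) force_error <- rep(NA, P)
  grids <- array(0, c(height, width, P))
  out_locs <- matrix(NA_real_, P, 2)
  err <- logical(P)
  for (p in seq_len(P)) {
    if (is.na(locs[p, 1])) next
    d <- mockDraws(cfg, frame_id, keypoints[p])
    x <- locs[p, 1] + d$jitter[1] * (cfg@loc_noise_sigma > 0)
    y <- locs[p, 2] + d$jitter[2] * (cfg@loc_noise_sigma > 0)
    x <- min(max(x, 0), width - 1); y <- min(max(y, 0), height - 1)
    bern <- if (is.na(force_error[p])) d$err_u < cfg@error_prob
            else isTRUE(force_error[p])
    err[p] <- bern || occluded[p]
    if (err[p]) {
      xy <- displaceInside(x, y, cfg@error_displacement, d$angles,
                           width, height)
      x <- xy[1]; y <- xy[2]
    }
    grids[, , p] <- renderBlob(width, height, x, y, cfg@render_sigma,
                               amp = cfg@peak)
    out_locs[p, ] <- c(x, y)
  }
  HeatmapStack(grids, keypoints,
               metadata = list(locations = out_locs, error = err,
                               frame_id = frame_id))
}

#' Seeded gross-error schedule with controlled run lengths
#'
#' Lays out error episodes of length `run_length` so that, per keypoint, the
#' expected fraction of error frames is close to `prob` and consecutive
#' episodes are separated by at least `min_gap` clean frames (with
#' `run_length = 1, min_gap = 1` errors are isolated single frames, pairwise
#' non-adjacent).
#'
#' @param n_frames,n_keypoints schedule dimensions.
#' @param prob target per-frame error probability.
#' @param run_length episode length in frames.
#' @param min_gap minimum clean frames between episodes.
#' @param seed integer seed.
#' @return logical n_frames x n_keypoints matrix.
#' @export
makeErrorSchedule <- function(n_frames, n_keypoints, prob, run_length = 1L,
                              min_gap = 1L, seed = 0L) {
  sched <- matrix(FALSE, n_frames, n_keypoints)
  p_start <- prob / run_length
  for (p in seq_len(n_keypoints)) {
    u <- withSeed(hash31(paste("errsched", seed, p, sep = ":")),
                  stats::runif(n_frames))
    t <- 1L
    while (t <= n_frames) {
      if (u[t] < p_start) {
        sched[t:min(t + run_length - 1L, n_frames), p] <- TRUE
        t <- t + run_length + min_gap
      } else t <- t + 1L
    }
  }
  sched
}

#' Mock predictions for a whole sequence
#'
#' @param tracks data.frame from [simulateSequence()] (columns frame,
#'   keypoint, x, y, visible).
#' @param keypoints keypoint order.
#' @param width,height frame dimensions.
#' @param cfg a [MockPredictorConfig-class].
#' @param error_schedule optional matrix from [makeErrorSchedule()].
#' @return list of [HeatmapStack-class], one per frame (0-based frame order).
#' @export
mockPredictSequence <- function(tracks, keypoints, width, height, cfg,
                                error_schedule = NULL) {
  frames <- sort(unique(tracks$frame))
  lapply(seq_along(frames), function(i) {
    f <- frames[i]
    sub <- tracks[tracks$frame == f, ]
    locs <- matrix(NA_real_, length(keypoints), 2)
    occ <- logical(length(keypoints))
    m <- match(keypoints, sub$keypoint)
    locs[!is.na(m), 1] <- sub$x[m[!is.na(m)]]
    locs[!is.na(m), 2] <- sub$y[m[!is.na(m)]]
    occ[!is.na(m)] <- !sub$visible[m[!is.na(m)]]
    attr(locs, "width") <- width; attr(locs, "height") <- height
    fe <- if (is.null(error_schedule)) NULL else error_schedule[i, ]
    mockPredict(locs, occ, cfg, frame_id = as.character(f),
                force_error = fe, keypoints = keypoints)
  })
}

#' Validate a full-scale base-model configuration
#'
#' The deep single-frame predictor used at full scale (ResNet-backed encoder
#' cut after a chosen Conv block, three transposed-convolution layers with
#' 13 x 13 kernels, final filter count equal to the number of keypoints,
#' optional intermediate supervision) is configuration-only here: this
#' validates the schema so an external implementation can be slotted in
#' behind the predictor contract.
#'
#' @param cfg named list or YAML path with fields `backbone_cut`
#'   (Conv1..Conv5), `deconv_filters` (3 integers, last = n_keypoints),
#'   `n_keypoints`, optional `intermediate_supervision_after`, and training
#'   fields `learning_rate` (default 1e-4), `epochs` (50), `batch_size` (10),
#'   `adam_beta1` (0.9), `adam_beta2` (0.999), `peak` (16).
#' @return the validated config list with defaults filled in.
#' @export
readBaselineConfig <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  defaults <- list(backbone_cut = "Conv4", deconv_filters = c(64, 64, NA),
                   n_keypoints = NULL, intermediate_supervision_after = NULL,
                   learning_rate = 1e-4, epochs = 50L, batch_size = 10L,
                   adam_beta1 = 0.9, adam_beta2 = 0.999, peak = 16,
                   deconv_kernel = 13L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0)
    stop("unknown base-model config field(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$n_keypoints)) stop("n_keypoints is required")
  if (!cfg$backbone_cut %in% paste0("Conv", 1:5))
    stop("backbone_cut must be one of Conv1..Conv5")
  if (length(cfg$deconv_filters) != 3)
    stop("deconv_filters must list 3 filter counts")
  if (is.na(cfg$deconv_filters[3]))
    cfg$deconv_filters[3] <- cfg$n_keypoints
  if (cfg$deconv_filters[3] != cfg$n_keypoints)
    stop("the final deconvolution layer must have one filter per keypoint")
  if (cfg$deconv_kernel != 13L)
    stop("deconv_kernel is fixed at 13")
  cfg
}
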