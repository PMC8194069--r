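# trajectory synthesis: sinusoidal swing along x (gait-like) with a smaller
# quadrature bob along y, optional linear drift; bounds-checked against a
# 3-sigma blob margin
sceneTrajectories <- function(spec) {
  P <- spec@n_keypoints; n <- spec@n_frames
  t <- 0:(n - 1)
  margin <- 3 * spec@blob_sigma
  cx <- rep((spec@width - 1) / 2, P)
  cy <- margin + 0.6 * max(spec@amplitude) +
    (seq_len(P) - 0.5) / P *
      (spec@height - 1 - 2 * (margin + 0.6 * max(spec@amplitude)))
  x <- matrix(0, n, P); y <- matrix(0, n, P)
  for (p in seq_len(P)) {
    ph <- 2 * pi * t / spec@period[p] + spec@phase[p]
    x[, p] <- cx[p] + spec@amplitude[p] * sin(ph) + spec@drift[1] * t
    y[, p] <- cy[p] + 0.6 * spec@amplitude[p] * sin(ph + pi / 2) +
      spec@drift[2] * t
  }
  if (min(x) < margin || max(x) > spec@width - 1 - margin ||
      min(y) < margin || max(y) > spec@height - 1 - margin)
    stop("trajectories escape the 3-sigma safety margin of the frame")
  list(x = x, y = y)
}

# seeded occlusion episodes for one view; returns visibility matrix and an
# episode table
drawOcclusions <- function(spec, tag) {
  n <- spec@n_frames; P <- spec@n_keypoints
  visible <- matrix(TRUE, n, P)
  eps <- list()
  if (spec@occlusion_rate > 0) {
    p_start <- spec@occlusion_rate / 100
    for (p in seq_len(P)) {
      draws <- withSeed(hash31(paste("occl", spec@seed, tag, p, sep = ":")), {
        list(u = stats::runif(n), g = stats::rgeom(n, 1 /
               max(spec@occlusion_run_length, 1)) + 1)
      })
      t <- 1L
      while (t <= n) {
        if (draws$u[t] < p_start) {
          len <- if (spec@occlusion_geometric) draws$g[t]
                 else as.integer(spec@occlusion_run_length)
          end <- min(t + len - 1L, n)
          visible[t:end, p] <- FALSE
          eps[[length(eps) + 1]] <- data.frame(keypoint = p, start = t - 1L,
                                               length = end - t + 1L)
          t <- end + 2L  # at least one visible frame between episodes
        } else t <- t + 1L
      }
    }
  }
  episodes <- if (length(eps) > 0) do.call(rbind, eps)
              else data.frame(keypoint = integer(0), start = integer(0),
                              length = integer(0))
  list(visible = visible, episodes = episodes)
}

# render one view given trajectories; all randomness from spec seed + tag
renderScene <- function(spec, traj, tag = "main") {
  W <- spec@width; H <- spec@height; n <- spec@n_frames
  P <- spec@n_keypoints
  texture <- withSeed(hash31(paste("texture", spec@seed, tag, sep = ":")),
                      matrix(stats::runif(H * W, -1, 1), H, W))
  texture <- .gauss_smooth(texture, 1.2)
  texture <- spec@texture_amp * texture / max(abs(texture))
  background <- spec@background_level + texture
  occ <- drawOcclusions(spec, tag)
  half <- ceiling(3 * spec@blob_sigma)
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    img <- background
    for (p in seq_len(P))
      img <- img + renderBlob(W, H, traj$x[f, p], traj$y[f, p],
                              spec@blob_sigma, amp = 0.7)
    for (p in seq_len(P)) {
      if (!occ$visible[f, p]) {  # moving rectangle covering the keypoint
        x0 <- max(0, roundHalfUp(traj$x[f, p]) - half)
        x1 <- min(W - 1, roundHalfUp(traj$x[f, p]) + half)
        y0 <- max(0, roundHalfUp(traj$y[f, p]) - half)
        y1 <- min(H - 1, roundHalfUp(traj$y[f, p]) + half)
        img[(y0:y1) + 1, (x0:x1) + 1] <- 0.55
      }
    }
    if (spec@noise_sigma > 0) {
      img <- img + withSeed(hash31(paste("noise", spec@seed, tag, f,
                                         sep = ":")),
                            matrix(stats::rnorm(H * W, 0, spec@noise_sigma),
                                   H, W))
    }
    frames[[f]] <- pmin(pmax(img, 0), 1)
  }
  kps <- sprintf("kp%d", seq_len(P))
  tracks <- data.frame(
    frame = rep(0:(n - 1), each = P),
    keypoint = rep(kps, n),
    x = as.numeric(t(traj$x)), y = as.numeric(t(traj$y)),
    visible = as.logical(t(occ$visible)),
    stringsAsFactors = FALSE)
  box <- as.integer(round(4 * spec@blob_sigma))
  annotations <- data.frame(
    frame_id = sprintf("frame_%06d", tracks$frame),
    keypoint = tracks$keypoint, x = tracks$x, y = tracks$y,
    box_w = box, box_h = box, stringsAsFactors = FALSE)
  occ$episodes$keypoint <- kps[occ$episodes$keypoint]
  list(frames = frames, tracks = tracks, annotations = annotations,
       episodes = occ$episodes, keypoints = kps, spec = spec)
}

#' Simulate a seeded articulated-scene video
#'
#' Renders each keypoint as a Gaussian blob following a sinusoidal (plus
#' drift) trajectory over a weakly textured background with per-frame sensor
#' noise. During occlusion episodes the keypoint is covered by a moving grey
#' rectangle (photometrically plausible masking) and its visibility flag is
#' FALSE; the true location is still recorded. All randomness flows from the
#' spec seed; identical specs give bit-identical frames.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `frames` (list of H x W matrices in [0, 1]), `tracks`
#'   (data.frame frame, keypoint, x, y, visible), `annotations` (annotation
#'   records with a fixed box of 4 x blob_sigma), `episodes` (occlusion
#'   episode table) and `keypoints`.
#' @export
simulateSequence <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  renderScene(spec, sceneTrajectories(spec), tag = "main")
}

#' Simulate a paired side/bottom view sharing the x-axis
#'
#' Both views share identical per-keypoint x(t) (the common axis of the
#' mirror geometry); y trajectories are independent between views, as are
#' occlusion episodes and sensor noise.
#'
#' @param spec a [SceneSpec-class].
#' @return list with elements `side` and `bottom`, each as returned by
#'   [simulateSequence()].
#' @export
simulateTwoViews <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  traj_side <- sceneTrajectories(spec)
  spec_b <- spec
  spec_b@phase <- spec@phase + withSeed(
    hash31(paste("bottomphase", spec@seed, sep = ":")),
    stats::runif(spec@n_keypoints, 0.5, 2 * pi - 0.5))
  traj_b <- sceneTrajectories(spec_b)
  traj_bottom <- list(x = traj_side$x, y = traj_b$y)
  list(side = renderScene(spec, traj_side, tag = "side"),
       bottom = renderScene(spec, traj_bottom, tag = "bottom"))
}

#' Named scenario presets
#'
#' The standard synthetic study conditions used throughout the package's
#' validation:
#' \describe{
#'   \item{static}{zero motion, zero sensor noise; the null-motion control
#'     (120 frames).}
#'   \item{gait}{sinusoidal multi-keypoint motion, 96 x 96 px, 4 keypoints,
#'     500 frames, textured background and sensor noise.}
#'   \item{isolated-errors}{the gait scene paired with a mock predictor that
#'     commits isolated single-frame gross errors (per-frame probability
#'     0.15, displacement 40 px, run length 1, errors pairwise
#'     non-adjacent).}
#'   \item{error-runs}{as isolated-errors but with error runs of length 9,
#'     spanning the aggregation window.}
#'   \item{two-view-swap}{a 200-frame two-view scene; the corrected view
#'     receives injected x-displaced primary peaks that retain a truthful
#'     secondary peak (displacement 28 px, secondary score 0.7, injection
#'     probability 0.1).}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed merged into all component specs.
#' @return list with `scene` ([SceneSpec-class]), `mock`
#'   ([MockPredictorConfig-class]), `window` ([FrameWindowSpec-class]) and,
#'   depending on the scenario, `schedule` (error-schedule parameters) or
#'   `inject` (two-view injection parameters).
#' @export
standardScenarios <- function(name = c("static", "gait", "isolated-errors",
                                       "error-runs", "two-view-swap"),
                              seed = 0L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  gait <- SceneSpec(seed = seed)
  base <- switch(name,
    "static" = list(
      scene = SceneSpec(n_frames = 120L, amplitude = 0, noise_sigma = 0,
                        seed = seed),
      mock = MockPredictorConfig(seed = seed),
      window = FrameWindowSpec()),
    "gait" = list(
      scene = gait,
      mock = MockPredictorConfig(loc_noise_sigma = 0.5, seed = seed),
      window = FrameWindowSpec()),
    "isolated-errors" = list(
      scene = gait,
      mock = MockPredictorConfig(loc_noise_sigma = 0.5, error_prob = 0.15,
                                 error_displacement = 40, seed = seed),
      window = FrameWindowSpec(),
      schedule = list(prob = 0.15, run_length = 1L, min_gap = 1L)),
    "error-runs" = list(
      scene = gait,
      mock = MockPredictorConfig(loc_noise_sigma = 0.5, error_prob = 0.15,
                                 error_displacement = 40, seed = seed),
      window = FrameWindowSpec(),
      schedule = list(prob = 0.15, run_length = 9L, min_gap = 1L)),
    "two-view-swap" = list(
      scene = SceneSpec(n_frames = 200L, seed = seed),
      mock = MockPredictorConfig(seed = seed),
      window = FrameWindowSpec(),
      inject = list(prob = 0.1, displacement = 28, secondary_score = 0.7)))
  c(base, list(name = name, seed = seed))
}

#' Decode a list of heatmap stacks at their per-keypoint maxima
#'
#' @param stacks list of [HeatmapStack-class] (one per frame).
#' @return numeric array n_frames x P x 2 of decoded (x, y).
#' @export
decodeStacks <- function(stacks) {
  P <- nKeypoints(stacks[[1]])
  out <- array(NA_real_, c(length(stacks), P, 2))
  for (f in seq_along(stacks)) {
    g <- heatmapArray(stacks[[f]])
    for (p in seq_len(P)) {
      if (max(g[, , p]) <= 0) next
      out[f, p, ] <- argmaxLocation(g[, , p])
    }
  }
  out
}

#' Ground-truth label stacks for a simulated sequence
#'
#' @param sim result of [simulateSequence()].
#' @param sigma_frac see [generateHeatmap()].
#' @return list of [HeatmapStack-class] label stacks, one per frame.
#' @export
labelStacksFromSim <- function(sim, sigma_frac = 0.25) {
  W <- sim$spec@width; H <- sim$spec@height
  frames <- sort(unique(sim$tracks$frame))
  lapply(frames, function(f) {
    ann <- sim$annotations[sim$tracks$frame == f, ]
    stackLabels(ann, sim$keypoints, W, H, sigma_frac)
  })
}

#' True keypoint coordinates of a simulated sequence as an array
#'
#' @param sim result of [simulateSequence()].
#' @return numeric array n_frames x P x 2 of true (x, y).
#' @export
trueLocationArray <- function(sim) {
  n <- sim$spec@n_frames; P <- length(sim$keypoints)
  out <- array(NA_real_, c(n, P, 2))
  out[, , 1] <- matrix(sim$tracks$x, n, P, byrow = TRUE)
  out[, , 2] <- matrix(sim$tracks$y, n, P, byrow = TRUE)
  out
}
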