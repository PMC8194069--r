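#' End-to-end temporal-aggregation experiment on a synthetic scenario
#'
#' Runs the full occlusion-correction study on one scenario seed: simulate
#' the scene, produce mock base-model predictions with the scenario's error
#' schedule, fit per-keypoint window weights by streaming least squares on
#' evenly spaced training windows (labels scaled by the training peak), then
#' decode every frame with and without temporal aggregation and score both
#' against the ground-truth labels with aPCK.
#'
#' @param scenario `"isolated-errors"`, `"error-runs"`, `"static"` or
#'   `"gait"`.
#' @param seed integer scenario seed.
#' @param n_train number of training windows (default 60).
#' @param params a [FarnebackParams-class].
#' @return list with `base` and `aggregated` aPCK tables
#'   ([apckErrorTable()]), `weights`, `base_locs`, `agg_locs`, `sim` and the
#'   error `schedule`.
#' @export
runTemporalExperiment <- function(scenario = "isolated-errors", seed = 0L,
                                  n_train = 60L,
                                  params = FarnebackParams()) {
  sc <- standardScenarios(scenario, seed)
  sim <- simulateSequence(sc$scene)
  n <- sc$scene@n_frames
  P <- sc$scene@n_keypoints
  schedule <- if (!is.null(sc$schedule))
    makeErrorSchedule(n, P, sc$schedule$prob, sc$schedule$run_length,
                      sc$schedule$min_gap, seed)
  else matrix(FALSE, n, P)
  stacks <- mockPredictSequence(sim$tracks, sim$keypoints,
                                sc$scene@width, sc$scene@height,
                                sc$mock, schedule)
  labels <- labelStacksFromSim(sim)
  res <- flowPipeline(sim$frames, stacks, labels, sc$window, params,
                      peak = sc$mock@peak, n_train = n_train)
  base_locs <- decodeStacks(stacks)
  list(base = apckErrorTable(base_locs, labels),
       aggregated = apckErrorTable(res$locations, labels),
       weights = res$weights, base_locs = base_locs,
       agg_locs = res$locations, sim = sim, schedule = schedule,
       labels = labels, stacks = stacks)
}

# inject an x-displaced primary peak while keeping a truthful secondary peak
# (amplitude ratio `secondary_score`) into one keypoint grid
injectSwappedPeak <- function(grid, x_true, y_true, displacement,
                              secondary_score, render_sigma, peak, width,
                              height, direction) {
  x_bad <- x_true + direction * displacement
  if (x_bad < 0 || x_bad > width - 1) x_bad <- x_true - direction * displacement
  renderBlob(width, height, x_bad, y_true, render_sigma, amp = peak) +
    renderBlob(width, height, x_true, y_true, render_sigma,
               amp = peak * secondary_score)
}

#' End-to-end two-view correction experiment
#'
#' Simulates the paired side/bottom scene, renders clean mock predictions
#' for the side view, then injects, on a seeded subset of (frame, keypoint)
#' pairs, an x-displaced primary peak that retains a truthful secondary peak
#' (the paw-swap failure mode). The bottom-view reference locations are the
#' true bottom tracks (perfect reference sharing the x-axis). Corrections
#' use [correctKeypoints()] for every frame; aPCK is scored on the side view
#' before and after correction.
#'
#' @param seed integer scenario seed.
#' @param smooth_sigma,min_rel candidate detection, see [localMaxima()].
#' @return list with per-(frame, keypoint) injection records, pre/post aPCK
#'   tables over all frames, pre/post aPCK error on the injected pairs only,
#'   and the |x_side - x_ref| distances before/after correction.
#' @export
runTwoViewExperiment <- function(seed = 0L, smooth_sigma = 3,
                                 min_rel = 0.1) {
  sc <- standardScenarios("two-view-swap", seed)
  tv <- simulateTwoViews(sc$scene)
  side <- tv$side; bottom <- tv$bottom
  n <- sc$scene@n_frames; P <- sc$scene@n_keypoints
  W <- sc$scene@width; H <- sc$scene@height
  kps <- side$keypoints
  stacks <- mockPredictSequence(side$tracks, kps, W, H, sc$mock)
  truth_side <- trueLocationArray(side)
  truth_bottom <- trueLocationArray(bottom)

  inj <- withSeed(hash31(paste("inject", seed, sep = ":")), {
    hits <- matrix(stats::runif(n * P) < sc$inject$prob, n, P)
    dirs <- matrix(sample(c(-1, 1), n * P, replace = TRUE), n, P)
    list(hits = hits, dirs = dirs)
  })
  for (f in seq_len(n)) {
    g <- heatmapArray(stacks[[f]])
    changed <- FALSE
    for (p in seq_len(P)) {
      if (!inj$hits[f, p]) next
      g[, , p] <- injectSwappedPeak(g[, , p], truth_side[f, p, 1],
                                    truth_side[f, p, 2],
                                    sc$inject$displacement,
                                    sc$inject$secondary_score,
                                    sc$mock@render_sigma, sc$mock@peak,
                                    W, H, inj$dirs[f, p])
      changed <- TRUE
    }
    if (changed) stacks[[f]] <- HeatmapStack(g, kps)
  }

  pairing <- ViewPairing(kps, kps)
  pre_locs <- decodeStacks(stacks)
  post_locs <- pre_locs
  dx_pre <- matrix(NA_real_, n, P); dx_post <- matrix(NA_real_, n, P)
  for (f in seq_len(n)) {
    sl <- pre_locs[f, , , drop = TRUE]
    dim(sl) <- c(P, 2); rownames(sl) <- kps
    bl <- truth_bottom[f, , , drop = TRUE]
    dim(bl) <- c(P, 2); rownames(bl) <- kps
    corr <- correctKeypoints(stacks[[f]], sl, bl, pairing,
                             smooth_sigma, min_rel)
    post_locs[f, , 1] <- corr$x; post_locs[f, , 2] <- corr$y
    dx_pre[f, ] <- abs(sl[, 1] - bl[, 1])
    dx_post[f, ] <- abs(corr$x - bl[, 1])
  }

  labels <- labelStacksFromSim(side)
  hit_idx <- which(inj$hits)
  errRateOn <- function(locs) {
    wrong <- 0L
    for (i in hit_idx) {
      f <- ((i - 1) %% n) + 1L; p <- ((i - 1) %/% n) + 1L
      grid <- heatmapArray(labels[[f]])[, , p]
      if (!isCorrectApck(locs[f, p, ], grid)) wrong <- wrong + 1L
    }
    if (length(hit_idx) == 0) 0 else wrong / length(hit_idx)
  }
  list(pre = apckErrorTable(pre_locs, labels),
       post = apckErrorTable(post_locs, labels),
       injected_error_pre = errRateOn(pre_locs),
       injected_error_post = errRateOn(post_locs),
       n_injected = length(hit_idx),
       dx_pre = dx_pre, dx_post = dx_post,
       pre_locs = pre_locs, post_locs = post_locs,
       stacks = stacks, labels = labels)
}
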