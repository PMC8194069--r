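#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib poseflow, .registration = TRUE
NULL

#' HeatmapStack: per-keypoint confidence grids for one frame
#'
#' A stack of P image-sized confidence grids, one per keypoint, sharing a
#' fixed keypoint order. Ground-truth label stacks obey the label invariants
#' (maximum exactly 1 when the keypoint is visible, no value in (0, 0.1),
#' support confined to the annotation box); base-model output stacks must be
#' non-negative (enforced by [validatePredictions()]); raw aggregated stacks
#' may carry negative values until clipped for decoding. The class itself
#' requires only finiteness.
#'
#' Grids are stored as an H x W x P array; matrix row = y, column = x, with
#' 0-based pixel coordinates in the public interface (pixel (x, y) lives at
#' `grids[y + 1, x + 1, p]`).
#'
#' @slot grids numeric array, H x W x P, finite.
#' @slot keypoints character vector of length P, unique keypoint names.
#' @slot metadata list of optional annotations (e.g. `present` flags from
#'   [stackLabels()]).
#' @export
setClass("HeatmapStack",
  representation(grids = "array", keypoints = "character", metadata = "list"),
  prototype(metadata = list())
)

setValidity("HeatmapStack", function(object) {
  d <- dim(object@grids)
  if (length(d) != 3L) return("grids must be an H x W x P array")
  if (d[3] < 1L) return("at least one keypoint grid is required")
  if (length(object@keypoints) != d[3])
    return("length(keypoints) must equal the number of grids")
  if (anyDuplicated(object@keypoints))
    return("keypoint names must be unique")
  if (!all(is.finite(object@grids)))
    return("grids must be finite")
  TRUE
})

#' Construct a HeatmapStack
#'
#' @param grids H x W x P numeric array (a matrix is promoted to P = 1).
#' @param keypoints character vector of P keypoint names.
#' @param metadata optional list.
#' @return A [HeatmapStack-class] object.
#' @export
HeatmapStack <- function(grids, keypoints, metadata = list()) {
  if (is.matrix(grids)) grids <- array(grids, c(dim(grids), 1L))
  new("HeatmapStack", grids = grids, keypoints = as.character(keypoints),
      metadata = metadata)
}

#' FlowField: dense displacement field between two frames
#'
#' Per-pixel displacement (u along x, v along y) mapping each target-frame
#' pixel p to the corresponding location p + (u, v) in a source frame
#' (backward mapping, suitable for hole-free warping).
#'
#' @slot u numeric H x W matrix, displacement in pixels along x (columns).
#' @slot v numeric H x W matrix, displacement in pixels along y (rows).
#' @export
setClass("FlowField", representation(u = "matrix", v = "matrix"))

setValidity("FlowField", function(object) {
  if (!identical(dim(object@u), dim(object@v)))
    return("u and v must share dimensions")
  if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
    return("flow must be finite everywhere")
  TRUE
})

#' @rdname FlowField-class
#' @param u,v numeric matrices (see slots).
#' @export
FlowField <- function(u, v) new("FlowField", u = u, v = v)

#' FrameWindowSpec: temporal window geometry
#'
#' A window of 2f + 1 frames at indices t + k * s for k in -f..f, where s is
#' the skip ratio and f the frame range.
#'
#' @slot skip_ratio integer >= 1 (stride between window members).
#' @slot frame_range integer >= 0 (half-width of the window).
#' @export
setClass("FrameWindowSpec",
  representation(skip_ratio = "integer", frame_range = "integer"))

setValidity("FrameWindowSpec", function(object) {
  if (length(object@skip_ratio) != 1L || object@skip_ratio < 1L)
    return("skip_ratio must be a single integer >= 1")
  if (length(object@frame_range) != 1L || object@frame_range < 0L)
    return("frame_range must be a single integer >= 0")
  TRUE
})

#' @rdname FrameWindowSpec-class
#' @param skip_ratio,frame_range window stride and half-width
#'   (defaults 1 and 4, the values used throughout the pipeline).
#' @export
FrameWindowSpec <- function(skip_ratio = 1L, frame_range = 4L) {
  new("FrameWindowSpec", skip_ratio = as.integer(skip_ratio),
      frame_range = as.integer(frame_range))
}

#' FarnebackParams: dense optical-flow hyperparameters
#'
#' Defaults follow the standard configuration for heatmap morphing: averaging
#' window of 27 pixels, pyramid scale 0.5 with 5 levels and 8 iterations per
#' level, polynomial-expansion neighbourhood of 7 pixels with sigma 1.5.
#'
#' @slot window_size integer, averaging window in pixels.
#' @slot pyramid_scale numeric in (0, 1).
#' @slot levels integer >= 1, pyramid levels.
#' @slot iterations integer >= 1, iterations per level.
#' @slot poly_n integer, pixel neighbourhood for polynomial expansion.
#' @slot poly_sigma numeric, Gaussian sigma of the expansion applicability.
#' @export
setClass("FarnebackParams",
  representation(window_size = "integer", pyramid_scale = "numeric",
                 levels = "integer", iterations = "integer",
                 poly_n = "integer", poly_sigma = "numeric"))

setValidity("FarnebackParams", function(object) {
  if (object@pyramid_scale <= 0 || object@pyramid_scale >= 1)
    return("pyramid_scale must lie strictly between 0 and 1")
  if (object@levels < 1L) return("levels must be >= 1")
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@window_size < 3L) return("window_size must be >= 3")
  if (object@poly_n < 3L || object@poly_n %% 2L == 0L)
    return("poly_n must be an odd integer >= 3")
  if (object@poly_sigma <= 0) return("poly_sigma must be positive")
  TRUE
})

#' @rdname FarnebackParams-class
#' @param window_size,pyramid_scale,levels,iterations,poly_n,poly_sigma see
#'   slot documentation.
#' @export
FarnebackParams <- function(window_size = 27L, pyramid_scale = 0.5,
                            levels = 5L, iterations = 8L,
                            poly_n = 7L, poly_sigma = 1.5) {
  new("FarnebackParams", window_size = as.integer(window_size),
      pyramid_scale = pyramid_scale, levels = as.integer(levels),
      iterations = as.integer(iterations), poly_n = as.integer(poly_n),
      poly_sigma = poly_sigma)
}

#' AggregatorWeights: per-keypoint weights over window offsets
#'
#' The parameters of the 1 x 1 convolution that aggregates morphed heatmaps:
#' one weight vector per keypoint over the 2f + 1 window offsets. Fitted
#' values need not be normalised.
#'
#' @slot w numeric P x (2f + 1) matrix.
#' @slot keypoints character vector of P keypoint names.
#' @slot offsets integer vector of window offsets (-f..f).
#' @export
setClass("AggregatorWeights",
  representation(w = "matrix", keypoints = "character", offsets = "integer"))

setValidity("AggregatorWeights", function(object) {
  if (nrow(object@w) != length(object@keypoints))
    return("one weight row per keypoint is required")
  if (ncol(object@w) != length(object@offsets))
    return("one weight column per window offset is required")
  if (!all(is.finite(object@w))) return("weights must be finite")
  TRUE
})

#' @rdname AggregatorWeights-class
#' @param w,keypoints,offsets see slot documentation.
#' @export
AggregatorWeights <- function(w, keypoints, offsets) {
  new("AggregatorWeights", w = w, keypoints = as.character(keypoints),
      offsets = as.integer(offsets))
}

#' MockPredictorConfig: deterministic stand-in for a trained base model
#'
#' The mock predictor re-renders, for every keypoint, a Gaussian peak at the
#' true location jittered by `loc_noise_sigma`; with probability `error_prob`
#' (and always when the keypoint is occluded) the peak is displaced by
#' `error_displacement` pixels in a seeded random direction. Peaks are
#' rendered at amplitude `peak`, the scale of peak-multiplied training
#' targets. All draws are reproducible per (seed, frame_id, keypoint).
#'
#' @slot loc_noise_sigma numeric, pixel jitter SD of the rendered peak.
#' @slot error_prob numeric in [0, 1], per-frame gross-error probability.
#' @slot error_displacement numeric, gross-error displacement in pixels.
#' @slot peak numeric > 0, rendered peak amplitude (default 16).
#' @slot render_sigma numeric > 0, sigma of the rendered Gaussian peak.
#' @slot seed integer seed.
#' @export
setClass("MockPredictorConfig",
  representation(loc_noise_sigma = "numeric", error_prob = "numeric",
                 error_displacement = "numeric", peak = "numeric",
                 render_sigma = "numeric", seed = "integer"))

setValidity("MockPredictorConfig", function(object) {
  if (object@error_prob < 0 || object@error_prob > 1)
    return("error_prob must lie in [0, 1]")
  if (object@loc_noise_sigma < 0) return("loc_noise_sigma must be >= 0")
  if (object@error_displacement < 0) return("error_displacement must be >= 0")
  if (object@peak <= 0) return("peak must be positive")
  if (object@render_sigma <= 0) return("render_sigma must be positive")
  TRUE
})

#' @rdname MockPredictorConfig-class
#' @param loc_noise_sigma,error_prob,error_displacement,peak,render_sigma,seed
#'   see slot documentation.
#' @export
MockPredictorConfig <- function(loc_noise_sigma = 0, error_prob = 0,
                                error_displacement = 40, peak = 16,
                                render_sigma = 3, seed = 0L) {
  new("MockPredictorConfig", loc_noise_sigma = loc_noise_sigma,
      error_prob = error_prob, error_displacement = error_displacement,
      peak = peak, render_sigma = render_sigma, seed = as.integer(seed))
}

#' ViewPairing: keypoint correspondence between two views sharing the x-axis
#'
#' @slot side character vector of corrected-view keypoint names.
#' @slot bottom character vector of reference-view keypoint names (same
#'   length; pairing is positional and injective on each side).
#' @slot reference_view label of the reference view.
#' @export
setClass("ViewPairing",
  representation(side = "character", bottom = "character",
                 reference_view = "character"))

setValidity("ViewPairing", function(object) {
  if (length(object@side) != length(object@bottom))
    return("side and bottom keypoint lists must have equal length")
  if (anyDuplicated(object@side) || anyDuplicated(object@bottom))
    return("pairing must be injective on each side")
  TRUE
})

#' @rdname ViewPairing-class
#' @param side,bottom,reference_view see slot documentation.
#' @export
ViewPairing <- function(side, bottom, reference_view = "bottom") {
  new("ViewPairing", side = as.character(side), bottom = as.character(bottom),
      reference_view = reference_view)
}

#' SceneSpec: synthetic articulated-scene description
#'
#' Describes a seeded synthetic video: P keypoints rendered as Gaussian blobs
#' following sinusoidal trajectories (plus optional drift) over a weakly
#' textured background, with per-frame sensor noise and optional occlusion
#' episodes during which a moving rectangle covers a keypoint.
#'
#' @slot width,height integer frame dimensions in pixels.
#' @slot n_keypoints integer P >= 1.
#' @slot n_frames integer number of frames.
#' @slot amplitude numeric vector (recycled to P), sinusoid amplitude px.
#' @slot period numeric vector (recycled to P), sinusoid period in frames.
#' @slot phase numeric vector (recycled to P), phase in radians.
#' @slot drift numeric length 2, (vx, vy) drift in px/frame.
#' @slot blob_sigma numeric, Gaussian blob sigma in px.
#' @slot background_level numeric in [0, 1].
#' @slot texture_amp numeric, amplitude of the fixed background texture.
#' @slot noise_sigma numeric, per-frame Gaussian sensor noise SD.
#' @slot occlusion_rate numeric, episodes per keypoint per 100 frames.
#' @slot occlusion_run_length numeric, episode length (frames); mean length
#'   when `occlusion_geometric` is TRUE.
#' @slot occlusion_geometric logical, geometric vs fixed run lengths.
#' @slot seed integer master seed; all randomness flows from it.
#' @export
setClass("SceneSpec",
  representation(width = "integer", height = "integer",
                 n_keypoints = "integer", n_frames = "integer",
                 amplitude = "numeric", period = "numeric", phase = "numeric",
                 drift = "numeric", blob_sigma = "numeric",
                 background_level = "numeric", texture_amp = "numeric",
                 noise_sigma = "numeric", occlusion_rate = "numeric",
                 occlusion_run_length = "numeric",
                 occlusion_geometric = "logical", seed = "integer"))

setValidity("SceneSpec", function(object) {
  if (object@n_keypoints < 1L) return("n_keypoints must be >= 1")
  if (object@n_frames < 1L) return("n_frames must be >= 1")
  if (object@blob_sigma <= 0) return("blob_sigma must be positive")
  if (length(object@drift) != 2L) return("drift must be length 2 (vx, vy)")
  if (any(object@period <= 0)) return("period must be positive")
  if (object@occlusion_rate < 0) return("occlusion_rate must be >= 0")
  if (object@occlusion_run_length < 1) return("occlusion_run_length must be >= 1")
  # trajectory bound check: centres + excursion must stay >= 3 sigma inside
  tr <- try(sceneTrajectories(object), silent = TRUE)
  if (inherits(tr, "try-error"))
    return("trajectories escape the 3-sigma safety margin of the frame")
  TRUE
})

#' @rdname SceneSpec-class
#' @param width,height,n_keypoints,n_frames,amplitude,period,phase,drift,blob_sigma,background_level,texture_amp,noise_sigma,occlusion_rate,occlusion_run_length,occlusion_geometric,seed
#'   see slot documentation.
#' @export
SceneSpec <- function(width = 96L, height = 96L, n_keypoints = 4L,
                      n_frames = 500L, amplitude = c(12, 9, 14, 10),
                      period = c(45, 60, 75, 95), phase = NULL,
                      drift = c(0, 0), blob_sigma = 3,
                      background_level = 0.25, texture_amp = 0.1,
                      noise_sigma = 0.01, occlusion_rate = 0,
                      occlusion_run_length = 1, occlusion_geometric = FALSE,
                      seed = 0L) {
  P <- as.integer(n_keypoints)
  if (is.null(phase)) phase <- seq(0, 1.5 * pi, length.out = P)
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      n_keypoints = P, n_frames = as.integer(n_frames),
      amplitude = rep_len(amplitude, P), period = rep_len(period, P),
      phase = rep_len(phase, P), drift = drift, blob_sigma = blob_sigma,
      background_level = background_level, texture_amp = texture_amp,
      noise_sigma = noise_sigma, occlusion_rate = occlusion_rate,
      occlusion_run_length = occlusion_run_length,
      occlusion_geometric = occlusion_geometric, seed = as.integer(seed))
}
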