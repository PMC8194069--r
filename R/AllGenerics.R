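#' @describeIn HeatmapStack-class keypoint names, in stack order.
#' @param x object.
#' @export
setGeneric("keypointNames", function(x) standardGeneric("keypointNames"))

#' @describeIn HeatmapStack-class number of keypoints.
#' @export
setGeneric("nKeypoints", function(x) standardGeneric("nKeypoints"))

#' @describeIn HeatmapStack-class the underlying H x W x P array.
#' @export
setGeneric("heatmapArray", function(x) standardGeneric("heatmapArray"))

#' @describeIn FlowField-class displacement along x, as an H x W matrix.
#' @export
setGeneric("flowU", function(x) standardGeneric("flowU"))

#' @describeIn FlowField-class displacement along y, as an H x W matrix.
#' @export
setGeneric("flowV", function(x) standardGeneric("flowV"))

#' @describeIn AggregatorWeights-class weight matrix (P x window length).
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @export
setMethod("keypointNames", "HeatmapStack", function(x) x@keypoints)
#' @export
setMethod("nKeypoints", "HeatmapStack", function(x) dim(x@grids)[3])
#' @export
setMethod("heatmapArray", "HeatmapStack", function(x) x@grids)
#' @export
setMethod("keypointNames", "AggregatorWeights", function(x) x@keypoints)
#' @export
setMethod("flowU", "FlowField", function(x) x@u)
#' @export
setMethod("flowV", "FlowField", function(x) x@v)
#' @export
setMethod("weightMatrix", "AggregatorWeights", function(x) x@w)

#' Extract one keypoint grid from a stack
#'
#' @param x a [HeatmapStack-class].
#' @param keypoint keypoint name or integer index.
#' @return an H x W matrix.
#' @export
keypointGrid <- function(x, keypoint) {
  stopifnot(is(x, "HeatmapStack"))
  if (is.character(keypoint)) {
    i <- match(keypoint, x@keypoints)
    if (is.na(i)) stop("unknown keypoint: ", keypoint)
  } else i <- as.integer(keypoint)
  x@grids[, , i]
}

setMethod("show", "HeatmapStack", function(object) {
  d <- dim(object@grids)
  cat(sprintf("HeatmapStack: %d x %d px, %d keypoint(s)\n", d[2], d[1], d[3]))
  cat("  keypoints:", paste(object@keypoints, collapse = ", "), "\n")
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              min(object@grids), max(object@grids)))
})

setMethod("show", "FlowField", function(object) {
  mag <- sqrt(object@u^2 + object@v^2)
  cat(sprintf("FlowField: %d x %d px; |d| median %.3f, max %.3f px\n",
              ncol(object@u), nrow(object@u), stats::median(mag), max(mag)))
})

setMethod("show", "FrameWindowSpec", function(object) {
  cat(sprintf("FrameWindowSpec: skip ratio %d, frame range %d (window %d)\n",
              object@skip_ratio, object@frame_range,
              2L * object@frame_range + 1L))
})

setMethod("show", "AggregatorWeights", function(object) {
  cat(sprintf("AggregatorWeights: %d keypoint(s) x %d offset(s)\n",
              nrow(object@w), ncol(object@w)))
  m <- round(object@w, 4)
  dimnames(m) <- list(object@keypoints, object@offsets)
  print(m)
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, %d keypoints, %d frames, seed %d\n",
    object@width, object@height, object@n_keypoints, object@n_frames,
    object@seed))
  if (object@occlusion_rate > 0)
    cat(sprintf("  occlusions: %.2g per keypoint per 100 frames, run length %g (%s)\n",
                object@occlusion_rate, object@occlusion_run_length,
                if (object@occlusion_geometric) "geometric" else "fixed"))
})
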