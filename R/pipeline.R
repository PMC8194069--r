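#' Read and write frame sequences as numbered PNG files
#'
#' Frames are stored as `frame_%06d.png` (grayscale, values in [0, 1]),
#' numbered by 0-based frame index.
#'
#' @param frames list of H x W matrices.
#' @param dir output directory (created if needed).
#' @export
writeFrames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i - 1L)))
  invisible(dir)
}

#' @rdname writeFrames
#' @return `readFrames`: list of H x W matrices in frame order.
#' @export
readFrames <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir)
  lapply(files, function(f) luminance(png::readPNG(f)))
}

pipelineSchema <- list(
  seed = "integer",
  image = list(width = "integer", height = "integer",
               sigma_frac = "numeric", peak = "numeric"),
  split = list(ratios = "numeric", group_by = "character",
               seed = "integer"),
  augment = list(rotation_range = "numeric", flip_mode = "character",
                 seed = "integer"),
  window = list(skip_ratio = "integer", frame_range = "integer"),
  farneback = list(window_size = "integer", pyramid_scale = "numeric",
                   levels = "integer", iterations = "integer",
                   poly_n = "integer", poly_sigma = "numeric"),
  multiview = list(pairing = "character", reference = "character",
                   smooth_sigma = "numeric", min_rel = "numeric"),
  paths = list(frames = "character", annotations = "character",
               output = "character"))

#' Read and validate a pipeline configuration
#'
#' A single YAML file configures every pipeline stage (image geometry and
#' label parameters, split and augmentation specs, temporal window, optical
#' flow hyperparameters, multi-view pairing, seeds). The config is validated
#' against a schema before any stage runs; unknown keys are rejected
#' field-by-field.
#'
#' @param path YAML path, or a named list.
#' @return validated nested list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  checkKeys <- function(x, schema, prefix = "") {
    bad <- setdiff(names(x), names(schema))
    if (length(bad) > 0)
      stop("unknown config field(s): ",
           paste0(prefix, bad, collapse = ", "))
    for (k in names(x)) {
      if (is.list(schema[[k]])) {
        if (!is.list(x[[k]]))
          stop("config field ", prefix, k, " must be a mapping")
        checkKeys(x[[k]], schema[[k]], paste0(prefix, k, "."))
      }
    }
  }
  checkKeys(cfg, pipelineSchema)
  defaults <- list(
    seed = 0L,
    image = list(width = 96L, height = 96L, sigma_frac = 0.25, peak = 16),
    split = list(ratios = c(0.6, 0.2, 0.2), group_by = NULL, seed = 0L),
    augment = list(rotation_range = c(-10, 10), flip_mode = "none",
                   seed = 0L),
    window = list(skip_ratio = 1L, frame_range = 4L),
    farneback = list(window_size = 27L, pyramid_scale = 0.5, levels = 5L,
                     iterations = 8L, poly_n = 7L, poly_sigma = 1.5),
    multiview = list(pairing = NULL, reference = "bottom",
                     smooth_sigma = 3, min_rel = 0.1),
    paths = list(frames = NULL, annotations = NULL, output = NULL))
  utils::modifyList(defaults, cfg)
}

# one JSON line per completed stage: stage name, config hash, seed
logStage <- function(stage, cfg, seed, log_path = NULL) {
  entry <- list(stage = stage, seed = seed,
                config_hash = hash31(paste(deparse(cfg), collapse = "")),
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  message(sprintf("[poseflow] %s (seed %s)", stage, seed))
  if (!is.null(log_path))
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  invisible(entry)
}

#' Pipeline stage: simulate a scenario to disk
#'
#' Writes frames as numbered PNGs, ground-truth annotations as CSV, tracks
#' (with visibility) as CSV and occlusion episodes as a JSON sidecar.
#' Identical (scenario, seed) reruns produce identical output trees.
#'
#' @param scenario scenario name, see [standardScenarios()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param log_path optional JSON-lines run log.
#' @return the simulation list, invisibly.
#' @export
runSimulate <- function(scenario, seed, out_dir, log_path = NULL) {
  sc <- standardScenarios(scenario, seed)
  sim <- simulateSequence(sc$scene)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeFrames(sim$frames, file.path(out_dir, "frames"))
  writeAnnotations(sim$annotations, file.path(out_dir, "annotations.csv"))
  utils::write.csv(sim$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(sim$episodes, file.path(out_dir, "occlusions.json"),
                       dataframe = "rows")
  logStage(paste0("simulate:", scenario), sc, seed, log_path)
  invisible(sim)
}

#' Pipeline stage: convert annotations to heatmap label stacks
#'
#' @param annotations_path annotation CSV/JSON.
#' @param width,height image dimensions.
#' @param out_dir output directory (one TIFF stack per frame).
#' @param sigma_frac see [generateHeatmap()].
#' @param keypoint_order optional explicit keypoint order (default: sorted
#'   unique names).
#' @param log_path optional run log.
#' @return vector of written paths, invisibly.
#' @export
runMakeLabels <- function(annotations_path, width, height, out_dir,
                          sigma_frac = 0.25, keypoint_order = NULL,
                          log_path = NULL) {
  anns <- readAnnotations(annotations_path)
  if (is.null(keypoint_order)) keypoint_order <- sort(unique(anns$keypoint))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(unique(anns$frame_id), function(fid) {
    stack <- stackLabels(anns[anns$frame_id == fid, ], keypoint_order,
                         width, height, sigma_frac)
    p <- file.path(out_dir, paste0(fid, ".tiff"))
    writeHeatmapStack(stack, p)
    p
  }, character(1))
  logStage("make-labels", list(w = width, h = height, sf = sigma_frac),
           NA, log_path)
  invisible(paths)
}

#' Pipeline stage: split frame ids into manifests
#'
#' Writes `train.txt`, `validation.txt`, `test.txt` (one id per line).
#'
#' @param annotations_path annotation CSV/JSON whose frame ids are split.
#' @param out_dir output directory.
#' @param ratios,group_by,seed see [splitDataset()].
#' @param log_path optional run log.
#' @return the split list, invisibly.
#' @export
runSplit <- function(annotations_path, out_dir, ratios = c(0.6, 0.2, 0.2),
                     group_by = NULL, seed = 0L, log_path = NULL) {
  ids <- unique(readAnnotations(annotations_path)$frame_id)
  sp <- splitDataset(ids, ratios, group_by, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(sp))
    writeLines(sp[[k]], file.path(out_dir, paste0(k, ".txt")))
  logStage("split", list(ratios = ratios, group_by = group_by), seed,
           log_path)
  invisible(sp)
}

#' Pipeline stage: evaluate predicted locations against labels
#'
#' @param pred_path CSV of predictions (frame_id, keypoint, x, y).
#' @param annotations_path ground-truth annotation CSV/JSON.
#' @param width,height image dimensions.
#' @param out_path report CSV (aPCK error and RMSE per keypoint).
#' @param sigma_frac see [generateHeatmap()].
#' @param log_path optional run log.
#' @return the report data.frame, invisibly.
#' @export
runEvaluate <- function(pred_path, annotations_path, width, height,
                        out_path, sigma_frac = 0.25, log_path = NULL) {
  preds_df <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
  anns <- readAnnotations(annotations_path)
  kps <- sort(unique(anns$keypoint))
  fids <- sort(unique(anns$frame_id))
  labels <- lapply(fids, function(fid)
    stackLabels(anns[anns$frame_id == fid, ], kps, width, height,
                sigma_frac))
  preds <- array(NA_real_, c(length(fids), length(kps), 2))
  gt <- array(NA_real_, c(length(fids), length(kps), 2))
  fi <- match(preds_df$frame_id, fids); ki <- match(preds_df$keypoint, kps)
  preds[cbind(fi, ki, 1)] <- preds_df$x
  preds[cbind(fi, ki, 2)] <- preds_df$y
  ai <- match(anns$frame_id, fids); aki <- match(anns$keypoint, kps)
  gt[cbind(ai, aki, 1)] <- anns$x
  gt[cbind(ai, aki, 2)] <- anns$y
  apck <- apckErrorTable(preds, labels)
  rmse <- rmseTable(preds, gt, kps)
  report <- merge(apck, rmse[, c("keypoint", "rmse")], by = "keypoint",
                  sort = FALSE)
  writeEvalReport(report, out_path)
  logStage("evaluate", list(w = width, h = height), NA, log_path)
  invisible(report)
}

# shared streaming driver: fit aggregator weights on evenly spaced training
# windows (labels scaled by the training peak), then decode every frame
flowPipeline <- function(frames, stacks, labels, window, params,
                         peak = 16, n_train = 60L, fit = TRUE,
                         weights = NULL) {
  n <- length(frames)
  f <- window@frame_range; s <- window@skip_ratio
  kps <- keypointNames(stacks[[1]])
  if (fit) {
    lo <- min(f * s, n - 1L); hi <- max(n - 1L - f * s, 0L)
    centers <- unique(round(seq(lo, hi, length.out = min(n_train, hi - lo + 1L))))
    acc <- NULL
    for (t in centers) {
      idx <- buildWindow(t, window, n)
      morphed <- morphWindow(frames[idx + 1L], stacks[idx + 1L],
                             t_pos = f + 1L, params = params)
      lab <- makeTrainingTarget(labels[[t + 1L]], peak = peak)[[1]]
      acc <- accumulateNormalEq(acc, morphed, lab)
    }
    fitres <- solveNormalEq(acc, kps, (-f:f) * s)
    weights <- fitres$weights
    attr(weights, "mse") <- fitres$mse
  }
  locs <- array(NA_real_, c(n, length(kps), 2))
  for (t in 0:(n - 1)) {
    pt <- predictTarget(frames, stacks, t, window, weights, params)
    locs[t + 1L, , ] <- pt$locations
  }
  list(weights = weights, locations = locs)
}

#' Pipeline stage: fit aggregator weights from a simulated directory tree
#'
#' Loads frames, base-model prediction stacks and label stacks from
#' directories (as written by the other stages), fits the per-keypoint
#' window weights by streaming least squares and writes them as JSON.
#'
#' @param frames_dir directory of `frame_%06d.png`.
#' @param stacks_dir directory of per-frame prediction stacks
#'   (`frame_%06d.tiff`).
#' @param labels_dir directory of per-frame label stacks.
#' @param out_path output weights JSON.
#' @param skip_ratio,frame_range window geometry.
#' @param peak training peak value.
#' @param n_train number of training windows.
#' @param farneback a [FarnebackParams-class].
#' @param log_path optional run log.
#' @return the [AggregatorWeights-class], invisibly.
#' @export
runFlowTrain <- function(frames_dir, stacks_dir, labels_dir, out_path,
                         skip_ratio = 1L, frame_range = 4L, peak = 16,
                         n_train = 60L, farneback = FarnebackParams(),
                         log_path = NULL) {
  frames <- readFrames(frames_dir)
  stacks <- readStackDir(stacks_dir)
  labels <- readStackDir(labels_dir)
  window <- FrameWindowSpec(skip_ratio, frame_range)
  res <- flowPipeline(frames, stacks, labels, window, farneback,
                      peak = peak, n_train = n_train)
  writeWeights(res$weights, out_path)
  logStage("flow-train", list(s = skip_ratio, f = frame_range), NA, log_path)
  invisible(res$weights)
}

#' Pipeline stage: aggregated prediction for every frame
#'
#' @param frames_dir,stacks_dir as in [runFlowTrain()].
#' @param weights_path weights JSON from [runFlowTrain()].
#' @param out_path output CSV (frame_id, keypoint, x, y).
#' @param skip_ratio,frame_range,farneback,log_path as in [runFlowTrain()].
#' @return data.frame of decoded locations, invisibly.
#' @export
runFlowPredict <- function(frames_dir, stacks_dir, weights_path, out_path,
                           skip_ratio = 1L, frame_range = 4L,
                           farneback = FarnebackParams(), log_path = NULL) {
  frames <- readFrames(frames_dir)
  stacks <- readStackDir(stacks_dir)
  weights <- readWeights(weights_path)
  window <- FrameWindowSpec(skip_ratio, frame_range)
  res <- flowPipeline(frames, stacks, NULL, window, farneback,
                      fit = FALSE, weights = weights)
  kps <- keypointNames(stacks[[1]])
  df <- data.frame(
    frame_id = rep(sprintf("frame_%06d", 0:(length(frames) - 1)),
                   each = length(kps)),
    keypoint = rep(kps, length(frames)),
    x = as.numeric(t(res$locations[, , 1])),
    y = as.numeric(t(res$locations[, , 2])))
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  logStage("flow-predict", list(s = skip_ratio, f = frame_range), NA,
           log_path)
  invisible(df)
}

readStackDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0) stop("no heatmap stacks found in ", dir)
  lapply(files, readHeatmapStack)
}

#' Pipeline stage: multi-view correction of predicted locations
#'
#' @param side_stacks_dir directory of corrected-view prediction stacks.
#' @param side_pred_path CSV of corrected-view locations.
#' @param bottom_pred_path CSV of reference-view locations.
#' @param pairing_path pairing JSON, see [readPairing()].
#' @param out_path output CSV of corrected locations.
#' @param smooth_sigma,min_rel see [localMaxima()].
#' @param log_path optional run log.
#' @return data.frame of corrected locations, invisibly.
#' @export
runMultiviewCorrect <- function(side_stacks_dir, side_pred_path,
                                bottom_pred_path, pairing_path, out_path,
                                smooth_sigma = 3, min_rel = 0.1,
                                log_path = NULL) {
  stacks <- readStackDir(side_stacks_dir)
  side <- utils::read.csv(side_pred_path, stringsAsFactors = FALSE)
  bottom <- utils::read.csv(bottom_pred_path, stringsAsFactors = FALSE)
  pairing <- readPairing(pairing_path)
  fids <- sort(unique(side$frame_id))
  out <- vector("list", length(fids))
  for (i in seq_along(fids)) {
    fid <- fids[i]
    s <- side[side$frame_id == fid, ]
    b <- bottom[bottom$frame_id == fid, ]
    kps <- keypointNames(stacks[[i]])
    sl <- as.matrix(s[match(kps, s$keypoint), c("x", "y")])
    rownames(sl) <- kps
    bl <- as.matrix(b[, c("x", "y")])
    rownames(bl) <- b$keypoint
    corr <- correctKeypoints(stacks[[i]], sl, bl, pairing,
                             smooth_sigma, min_rel)
    corr$frame_id <- fid
    out[[i]] <- corr
  }
  df <- do.call(rbind, out)[, c("frame_id", "keypoint", "x", "y",
                                "corrected", "flagged")]
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  logStage("multiview-correct", list(sigma = smooth_sigma), NA, log_path)
  invisible(df)
}
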