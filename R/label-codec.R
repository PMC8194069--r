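#' Convert a keypoint annotation to a truncated-Gaussian heatmap label
#'
#' Renders the ground-truth confidence map for one keypoint: a 2D Gaussian
#' PDF evaluated at pixel centres inside the annotation's acceptance box
#' (hard zero outside), rescaled so its maximum is exactly 1.0, after which
#' every value strictly below 0.1 is set to 0. The nonzero support of the
#' result is the region in which a prediction counts as correct under aPCK.
#'
#' Coordinates are 0-based with x = column and y = row (origin top-left).
#' The box is centred on the nearest pixel to (x, y) and spans `box_w` x
#' `box_h` pixels (even sizes extend one pixel further right/down); it is
#' clipped to the image.
#'
#' @param x,y keypoint location in pixels (floats allowed).
#' @param box_w,box_h acceptance box size in pixels (integers >= 1).
#' @param width,height image dimensions in pixels.
#' @param sigma_frac Gaussian sigma as a fraction of the box dimension per
#'   axis (default 0.25, i.e. the box spans about +/- 2 sigma).
#' @return an H x W numeric matrix; the heatmap label grid.
#' @examples
#' g <- generateHeatmap(10, 10, 9, 9, 32, 32)
#' g[11, 11]            # exactly 1 at the (rounded) centre
#' range(g[g > 0])      # no value below the 0.1 cut
#' @export
generateHeatmap <- function(x, y, box_w, box_h, width, height,
                            sigma_frac = 0.25) {
  stopifnot(sigma_frac > 0, box_w >= 1, box_h >= 1)
  if (x < 0 || x >= width || y < 0 || y >= height)
    stop(sprintf("annotation (%.3f, %.3f) lies outside the %d x %d image",
                 x, y, width, height))
  grid <- matrix(0, nrow = height, ncol = width)
  cx <- roundHalfUp(x); cy <- roundHalfUp(y)
  left <- cx - (box_w - 1) %/% 2; right <- left + box_w - 1
  top <- cy - (box_h - 1) %/% 2; bottom <- top + box_h - 1
  l <- max(left, 0); r <- min(right, width - 1)
  t <- max(top, 0); b <- min(bottom, height - 1)
  if (l > r || t > b) {
    warning("annotation box entirely clipped away; returning an all-zero grid")
    return(grid)
  }
  sx <- box_w * sigma_frac; sy <- box_h * sigma_frac
  gx <- exp(-((l:r - x)^2) / (2 * sx^2))
  gy <- exp(-((t:b - y)^2) / (2 * sy^2))
  block <- gy %o% gx
  block <- block / max(block)
  block[block < 0.1] <- 0
  grid[(t:b) + 1, (l:r) + 1] <- block
  grid
}

#' Support mask of a heatmap label
#'
#' The boolean region in which an aPCK prediction counts as correct: TRUE
#' exactly where the label grid is positive. A pixel holding the threshold
#' value 0.1 itself is inside the support (only values strictly below 0.1
#' are zeroed during label generation).
#'
#' @param grid heatmap label matrix.
#' @return logical matrix of the same shape.
#' @export
supportMask <- function(grid) grid > 0

#' Build a heatmap label stack for one frame
#'
#' Generates one label grid per keypoint in `keypoint_order`. Keypoints with
#' no annotation in this frame yield all-zero grids and are flagged in the
#' stack metadata (`present`); such grids are excluded from aPCK denominators
#' during evaluation.
#'
#' @param anns data.frame of annotations for a single frame with columns
#'   `keypoint`, `x`, `y`, `box_w`, `box_h` (and optionally `frame_id`).
#' @param keypoint_order character vector fixing the stack order.
#' @param width,height image dimensions.
#' @param sigma_frac see [generateHeatmap()].
#' @return a [HeatmapStack-class] with `metadata$present` flags.
#' @export
stackLabels <- function(anns, keypoint_order, width, height,
                        sigma_frac = 0.25) {
  P <- length(keypoint_order)
  stopifnot(P >= 1)
  grids <- array(0, c(height, width, P))
  present <- logical(P)
  if (nrow(anns) > 0) {
    dup <- anns$keypoint[duplicated(anns$keypoint)]
    if (length(dup) > 0) {
      fid <- if ("frame_id" %in% names(anns)) anns$frame_id[1] else "<frame>"
      stop(sprintf("duplicate annotation for keypoint '%s' in frame '%s'",
                   dup[1], fid))
    }
  }
  for (p in seq_len(P)) {
    i <- if (nrow(anns) > 0) match(keypoint_order[p], anns$keypoint) else NA
    if (!is.na(i)) {
      grids[, , p] <- generateHeatmap(anns$x[i], anns$y[i],
                                      anns$box_w[i], anns$box_h[i],
                                      width, height, sigma_frac)
      present[p] <- TRUE
    }
  }
  HeatmapStack(grids, keypoint_order,
               metadata = list(present = stats::setNames(present,
                                                         keypoint_order)))
}

annotationColumns <- c("frame_id", "keypoint", "x", "y", "box_w", "box_h")

validateAnnotations <- function(df, where = "annotations") {
  missing <- setdiff(annotationColumns, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing column(s): %s", where,
                 paste(missing, collapse = ", ")))
  for (col in c("x", "y", "box_w", "box_h")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric %s at row %d", where, col, bad[1]))
    df[[col]] <- v
  }
  bad <- which(df$box_w < 1 | df$box_h < 1)
  if (length(bad) > 0)
    stop(sprintf("%s: box dimensions must be >= 1 (row %d)", where, bad[1]))
  df$frame_id <- as.character(df$frame_id)
  df$keypoint <- as.character(df$keypoint)
  df[annotationColumns]
}

#' Read / write keypoint annotations
#'
#' Annotations are records (frame_id, keypoint, x, y, box_w, box_h), stored
#' either as a UTF-8 CSV with that header or as a JSON array of equivalent
#' objects; the format is chosen by file extension. Round-tripping preserves
#' coordinates to at least 6 decimals.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return `readAnnotations`: a data.frame with the columns above.
#' @export
readAnnotations <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  validateAnnotations(df, where = path)
}

#' @rdname readAnnotations
#' @param anns annotation data.frame.
#' @export
writeAnnotations <- function(anns, path) {
  anns <- validateAnnotations(anns)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(anns, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE)
  } else {
    utils::write.csv(anns, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Persist / load heatmap stacks
#'
#' Two on-disk formats are supported, selected by extension: multi-page
#' 32-bit float TIFF (`.tif`/`.tiff`; keypoint names go to a small `.json`
#' sidecar next to the file) and a plain long CSV (`.csv`, columns keypoint,
#' y, x, value for nonzero entries plus a header row of dimensions).
#'
#' @param stack a [HeatmapStack-class].
#' @param path output path.
#' @export
writeHeatmapStack <- function(stack, path) {
  stopifnot(is(stack, "HeatmapStack"))
  ext <- tolower(tools::file_ext(path))
  g <- stack@grids
  if (ext %in% c("tif", "tiff")) {
    # float TIFF stores [0, 1]; peak-scaled stacks carry their scale in the
    # sidecar
    scale <- max(1, max(g))
    pages <- lapply(seq_len(dim(g)[3]), function(p) g[, , p] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(keypoints = stack@keypoints,
                              height = dim(g)[1], width = dim(g)[2],
                              scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "csv") {
    idx <- which(g != 0, arr.ind = TRUE)
    df <- data.frame(keypoint = stack@keypoints[idx[, 3]],
                     y = idx[, 1] - 1L, x = idx[, 2] - 1L,
                     value = g[idx])
    con <- file(path, "w")
    writeLines(sprintf("# height=%d width=%d keypoints=%s", dim(g)[1],
                       dim(g)[2], paste(stack@keypoints, collapse = ";")),
               con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  } else stop("unsupported heatmap stack format: ", ext)
  invisible(path)
}

#' @rdname writeHeatmapStack
#' @return `readHeatmapStack`: a [HeatmapStack-class].
#' @export
readHeatmapStack <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    meta <- jsonlite::fromJSON(paste0(path, ".json"))
    scale <- if (is.null(meta$scale)) 1 else meta$scale
    g <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
    for (p in seq_along(pages)) g[, , p] <- pages[[p]] * scale
    HeatmapStack(g, meta$keypoints)
  } else if (ext == "csv") {
    header <- readLines(path, n = 1)
    m <- regmatches(header,
                    regexec("height=(\\d+) width=(\\d+) keypoints=(.*)$",
                            header))[[1]]
    if (length(m) != 4) stop("malformed heatmap stack CSV header: ", path)
    h <- as.integer(m[2]); w <- as.integer(m[3])
    kps <- strsplit(m[4], ";", fixed = TRUE)[[1]]
    df <- utils::read.csv(path, skip = 1, stringsAsFactors = FALSE)
    g <- array(0, c(h, w, length(kps)))
    p <- match(df$keypoint, kps)
    g[cbind(df$y + 1L, df$x + 1L, p)] <- df$value
    HeatmapStack(g, kps)
  } else stop("unsupported heatmap stack format: ", ext)
}
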