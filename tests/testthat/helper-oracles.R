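# independent oracles used across the suite; deliberately written as plain
# double loops / direct formulas, not via the package's own code paths

# brute-force per-pixel heatmap label: evaluate the Gaussian PDF at every
# pixel of the (clipped) box, max-normalise, zero values below 0.1
oracleHeatmap <- function(x, y, box_w, box_h, width, height,
                          sigma_frac = 0.25) {
  cx <- floor(x + 0.5); cy <- floor(y + 0.5)
  left <- cx - (box_w - 1) %/% 2; right <- left + box_w - 1
  top <- cy - (box_h - 1) %/% 2; bottom <- top + box_h - 1
  g <- matrix(0, height, width)
  for (py in 0:(height - 1)) {
    for (px in 0:(width - 1)) {
      if (px >= left && px <= right && py >= top && py <= bottom)
        g[py + 1, px + 1] <- stats::dnorm(px, x, box_w * sigma_frac) *
          stats::dnorm(py, y, box_h * sigma_frac)
    }
  }
  if (max(g) > 0) {
    g <- g / max(g)
    g[g < 0.1] <- 0
  }
  g
}

# direct-scan argmax with row-major tie-break
oracleArgmax <- function(grid) {
  best <- -Inf; bx <- NA; by <- NA
  for (py in 0:(nrow(grid) - 1)) {
    for (px in 0:(ncol(grid) - 1)) {
      v <- grid[py + 1, px + 1]
      if (v > best) { best <- v; bx <- as.numeric(px); by <- as.numeric(py) }
    }
  }
  c(x = bx, y = by)
}

# direct correctness count: nearest-pixel lookup of the label grid
oracleApckCorrect <- function(pred, grid) {
  px <- floor(pred[1] + 0.5); py <- floor(pred[2] + 0.5)
  if (px < 0 || px >= ncol(grid) || py < 0 || py >= nrow(grid)) return(FALSE)
  grid[py + 1, px + 1] > 0
}

# intensity centroid of a single-blob image, 0-based coordinates
blobCentroid <- function(img) {
  tot <- sum(img)
  xs <- matrix(rep(0:(ncol(img) - 1), each = nrow(img)), nrow(img))
  ys <- matrix(rep(0:(nrow(img) - 1), ncol(img)), nrow(img))
  c(x = sum(img * xs) / tot, y = sum(img * ys) / tot)
}

# random in-bounds annotation on a width x height frame
randomAnnotation <- function(width, height, seed_i) {
  set.seed(seed_i)
  bw <- sample(3:min(11, (width - 2) %/% 2), 1)
  bh <- sample(3:min(11, (height - 2) %/% 2), 1)
  data.frame(frame_id = "f0", keypoint = "kp",
             x = runif(1, bw, width - 1 - bw),
             y = runif(1, bh, height - 1 - bh),
             box_w = bw, box_h = bh)
}

# textured frame for flow tests: fine plus coarse smoothed noise, so every
# pyramid level has gradients to lock onto
texturedFrame <- function(width = 96, height = 96, seed = 1) {
  set.seed(seed)
  fine <- poseflow:::.gauss_smooth(
    matrix(runif(height * width), height, width), 1.0)
  coarse <- poseflow:::.gauss_smooth(
    matrix(runif(height * width), height, width), 6.0)
  f <- fine + 4 * coarse
  (f - min(f)) / (max(f) - min(f))
}
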