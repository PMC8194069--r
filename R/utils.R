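# internal helpers: seeded evaluation, coordinate conventions, blob rendering

# evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (pixel snapping of non-negative coordinates)
roundHalfUp <- function(x) floor(x + 0.5)

# deterministic 31-bit hash of a string, for per-(seed, frame, keypoint)
# substream derivation
hash31 <- function(s) {
  v <- utf8ToInt(s)
  h <- 17
  for (c in v) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

# Gaussian blob with amplitude `amp`, centre (x, y) in 0-based pixel
# coordinates, rendered over the full H x W grid (separable outer product)
renderBlob <- function(width, height, x, y, sigma, amp = 1) {
  gy <- exp(-((seq_len(height) - 1 - y)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(width) - 1 - x)^2) / (2 * sigma^2))
  amp * (gy %o% gx)
}

# bilinear sampling of img (H x W matrix) at 0-based float coords;
# taps outside the grid contribute 0
bilinearSample <- function(img, xs, ys) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  wx <- xs - x0; wy <- ys - y0
  tap <- function(xi, yi) {
    ok <- xi >= 0 & xi <= W - 1 & yi >= 0 & yi <= H - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  (1 - wx) * (1 - wy) * tap(x0, y0) +
    wx * (1 - wy) * tap(x0 + 1, y0) +
    (1 - wx) * wy * tap(x0, y0 + 1) +
    wx * wy * tap(x0 + 1, y0 + 1)
}

# Rec.601 luminance reduction for multi-channel frames
luminance <- function(frame) {
  if (is.matrix(frame)) return(frame)
  stopifnot(length(dim(frame)) == 3)
  if (dim(frame)[3] == 1) return(frame[, , 1])
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}
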