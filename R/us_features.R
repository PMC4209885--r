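#' Interest-point grid for local gray-level features
#'
#' Features are computed at interest points placed on a regular lattice
#' inside the frame: at each point the windowed local mean gray level and,
#' optionally, first-order spatial gray-level differences along rows and
#' columns. The default geometry — 181 points (a 14 x 13 lattice with its
#' last point dropped) times three features per point — yields exactly 543
#' features, the dimensionality contract of the ultrasound pipeline; the
#' original extractor's geometry is not published, so the grid is fully
#' configurable and 543 is the only fixed quantity.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param n_points number of interest points actually used, taken in
#'   row-major order from the lattice (default `n_rows * n_cols`).
#' @param window half-width of the square local window, pixels.
#' @param feature_kinds subset of `c("mean", "grad_r", "grad_c")`.
#' @return an object of class `feature_grid` with an `n_features` field.
#' @export
#' @examples
#' g <- feature_grid()  # default: 181 points x 3 kinds = 543 features
#' g$n_features
feature_grid <- function(n_rows = 14L, n_cols = 13L,
                         n_points = NULL, window = 2L,
                         feature_kinds = c("mean", "grad_r", "grad_c")) {
  if (n_rows < 1 || n_cols < 1 || window < 1) {
    stop("Grid dimensions and window must be positive.", call. = FALSE)
  }
  if (is.null(n_points)) {
    n_points <- n_rows * n_cols
    if (n_rows == 14L && n_cols == 13L &&
        setequal(feature_kinds, c("mean", "grad_r", "grad_c"))) {
      n_points <- 181L  # default geometry pinned to the 543-feature contract
    }
  }
  if (n_points < 1 || n_points > n_rows * n_cols) {
    stop("`n_points` must lie in [1, n_rows * n_cols].", call. = FALSE)
  }
  feature_kinds <- match.arg(feature_kinds,
                             c("mean", "grad_r", "grad_c"), several.ok = TRUE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_points = as.integer(n_points), window = as.integer(window),
                 feature_kinds = feature_kinds,
                 n_features = as.integer(n_points * length(feature_kinds))),
            class = "feature_grid")
}

# lattice pixel coordinates, evenly spaced with a margin that keeps the
# window (and the shifted gradient windows) inside the frame
.grid_points <- function(grid, height, width) {
  m <- 2L * grid$window + 1L
  if (height < 2 * m || width < 2 * m) {
    stop(sprintf("Frame %d x %d too small for window half-width %d.",
                 height, width, grid$window), call. = FALSE)
  }
  rows <- round(seq(m + 1L, height - m, length.out = grid$n_rows))
  cols <- round(seq(m + 1L, width - m, length.out = grid$n_cols))
  pts <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  pts <- pts[order(pts$row, pts$col), ]
  pts[seq_len(grid$n_points), ]
}

#' Extract local gray-level features from one grayscale frame
#'
#' At every interest point: the mean gray level of the `(2w+1)^2` window,
#' and first-order spatial differences computed as the mean of the window
#' shifted by `+w` minus `-w` along each axis (a coarse local gradient of
#' the gray level). Deterministic in the frame content.
#'
#' @param frame numeric matrix, 8-bit (`0..255`) or float gray levels;
#'   values are used as given.
#' @param grid a [feature_grid()].
#' @return numeric vector of length `grid$n_features`, ordered point-major
#'   within each feature kind (`mean` block, then `grad_r`, then `grad_c`).
#' @export
extract_us_features <- function(frame, grid = feature_grid()) {
  frame <- as.matrix(frame)
  if (!is.numeric(frame)) stop("`frame` must be numeric.", call. = FALSE)
  pts <- .grid_points(grid, nrow(frame), ncol(frame))
  w <- grid$window
  win_mean <- function(r, c) {
    mean(frame[(r - w):(r + w), (c - w):(c + w)])
  }
  out <- numeric(0)
  for (kind in grid$feature_kinds) {
    v <- switch(kind,
      mean = mapply(win_mean, pts$row, pts$col),
      grad_r = mapply(function(r, c) win_mean(r + w, c) - win_mean(r - w, c),
                      pts$row, pts$col),
      grad_c = mapply(function(r, c) win_mean(r, c + w) - win_mean(r, c - w),
                      pts$row, pts$col))
    out <- c(out, v)
  }
  names(out) <- paste0(rep(grid$feature_kinds, each = grid$n_points), "_",
                       seq_len(grid$n_points))
  out
}

#' Extract features from a frame stack
#'
#' @param frames `height x width x n` array from [simulate_us_images()].
#' @param grid a [feature_grid()].
#' @return `n x n_features` matrix.
#' @export
extract_us_features_stack <- function(frames, grid = feature_grid()) {
  stopifnot(length(dim(frames)) == 3)
  t(apply(frames, 3, extract_us_features, grid = grid))
}

#' Read a grayscale PNG frame
#'
#' Convenience loader for image fixtures: reads a PNG and returns a
#' numeric gray-level matrix in `[0, 1]` (color images are averaged over
#' their channels).
#'
#' @param path PNG file path.
#' @return numeric matrix of gray levels.
#' @export
read_gray_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("Reading PNG frames requires the 'png' package.", call. = FALSE)
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
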