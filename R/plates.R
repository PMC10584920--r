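# Image stage: crop the plate, locate the 32 x 48 colony grid, segment
# colonies within grid cells, and measure per-colony area and
# background-removed intensity.

#' Preprocess a raw plate image into a normalized signal image
#'
#' Converts to a single channel (mean over channels), optionally inverts
#' (`signal = 1 - luminance`, for light plates with dark blue colonies), and
#' rescales intensities to `[0, 1]`. Constant images pass through unchanged
#' (the rescale is guarded against zero range).
#'
#' @param x numeric matrix, or 3-d array with channels in the third
#'   dimension. Larger values must mean stronger reporter signal after
#'   `invert` is applied.
#' @param invert logical; set `TRUE` for images where colonies are darker
#'   than the background.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
preprocess <- function(x, invert = FALSE) {
  if (length(x) == 0) stopf("empty image")
  if (is.array(x) && length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
  if (!is.matrix(x)) stopf("image must be a matrix or 3-channel array")
  x <- x / max(1, max(x))  # tolerate 8/16-bit integer scales
  if (isTRUE(invert)) x <- max(x) - x
  rng <- range(x)
  if (diff(rng) > 0) x <- (x - rng[1]) / diff(rng)
  x
}

#' Crop a plate image to its foreground bounding box
#'
#' Thresholds the image at a fixed value and restricts the region of interest
#' to the first and last foreground pixel encountered vertically and
#' horizontally.
#'
#' @param image preprocessed matrix (values in `[0, 1]`).
#' @param threshold fixed mask threshold in (0, 1).
#' @return list with `image` (cropped matrix) and `offset` = `c(row, col)`
#'   0-based offsets of the crop origin in the input image.
#' @export
crop_plate <- function(image, threshold = 0.1) {
  stopifnot(is.matrix(image), threshold > 0, threshold < 1)
  mask <- image > threshold
  if (!any(mask)) stopf("blank_plate")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(image = image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       offset = c(rows[1] - 1L, cols[1] - 1L))
}

# Background subtraction + contrast stretch + edge-enhanced binary mask used
# for grid detection. sigma ~ expected colony radius.
grid_mask <- function(image, sigma) {
  bg <- as_matrix_img(EBImage::gblur(image, sigma = 4 * sigma))
  y <- image - bg
  q <- quantile(y, c(0.01, 0.999), names = FALSE)
  if (q[2] - q[1] < 1e-6) stopf("no_grid_detected")
  # light smoothing suppresses pixel noise without eroding colonies; the
  # threshold is the smaller of the Otsu cut (dense, bright plates) and a
  # robust noise-scale cut (sparse plates whose weak colonies would fall
  # below an Otsu threshold dominated by a few strong colonies)
  ys <- as_matrix_img(EBImage::gblur(y, sigma = 1.5))
  ys01 <- matrix(pmin(1, pmax(0, (ys - q[1]) / (q[2] - q[1]))),
                 nrow(ys), ncol(ys))
  th_otsu <- q[1] + (q[2] - q[1]) *
    EBImage::otsu(EBImage::Image(ys01), range = c(0, 1))
  th_noise <- max(4 * mad(ys), 0.02 * (q[2] - q[1]))
  ys > min(th_otsu, th_noise)
}

# strip EBImage Image class back to a plain matrix
as_matrix_img <- function(x) {
  m <- EBImage::imageData(x)
  matrix(as.numeric(m), nrow(m), ncol(m))
}

# Peak finding on a smoothed 1-d projection via zero-crossings of the
# gradient (sign change of the first difference at a local maximum).
projection_peaks <- function(p, window) {
  window <- max(3L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(p, rep(1 / window, window), sides = 2)
  sm[is.na(sm)] <- 0
  d <- diff(sm)
  sgn <- sign(d)
  idx <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0) + 1L
  idx[sm[idx] > 0.1 * max(sm)]
}

# Fit an equidistant center sequence to detected peaks: assign integer grid
# indices from the median spacing, then least-squares for origin and spacing.
fit_equidistant <- function(peaks, n, extent) {
  if (length(peaks) < 2) stopf("no_grid_detected")
  sp0 <- median(diff(peaks))
  k <- round((peaks - peaks[1]) / sp0)
  for (it in 1:3) {
    fit <- stats::lm.fit(cbind(1, k), peaks)
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
    k <- round((peaks - a) / b)
  }
  fit <- stats::lm.fit(cbind(1, k), peaks)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b <= 0) stopf("no_grid_detected")
  # choose the window of n consecutive indices that best centres the grid
  # within the image extent (rows/cols at the borders may hold no colonies)
  s_lo <- max(k) - (n - 1L); s_hi <- min(k)
  if (s_lo > s_hi) stopf("no_grid_detected")
  best <- s_hi; best_cost <- Inf
  for (s in s_lo:s_hi) {
    first <- a + b * s; last <- a + b * (s + n - 1L)
    cost <- abs(first - (extent - last))  # margin imbalance
    if (first < 0.5 || last > extent + 0.5) cost <- cost + extent
    if (cost < best_cost) { best_cost <- cost; best <- s }
  }
  a + b * (best + 0L:(n - 1L))
}

#' Detect the 1536-colony grid in a cropped plate image
#'
#' Builds a binary colony mask (smoothing-based background subtraction,
#' dynamic contrast stretch, Otsu threshold), projects it horizontally and
#' vertically, finds projection peaks by gradient zero-crossing analysis, and
#' fits equidistant row/column centers by least squares, extrapolating
#' positions of missing colonies.
#'
#' @param image cropped, preprocessed plate matrix.
#' @param min_peaks minimum detected peaks per axis below which
#'   `"no_grid_detected"` is raised.
#' @return object of class `grid_spec`: list with `rows`, `cols`,
#'   `centers_y` (length 32), `centers_x` (length 48), `spacing` =
#'   `c(dy, dx)`, `origin` = first centers.
#' @export
detect_grid <- function(image, min_peaks = 10L) {
  stopifnot(is.matrix(image))
  sigma <- max(2, min(dim(image)) / (PLATE_ROWS * 4))
  mask <- grid_mask(image, sigma)
  py <- rowSums(mask); px <- colSums(mask)
  sp_guess_y <- nrow(image) / PLATE_ROWS
  sp_guess_x <- ncol(image) / PLATE_COLS
  peaks_y <- projection_peaks(py, sp_guess_y / 2)
  peaks_x <- projection_peaks(px, sp_guess_x / 2)
  if (length(peaks_y) < min_peaks || length(peaks_x) < min_peaks) {
    stopf("no_grid_detected")
  }
  cy <- fit_equidistant(peaks_y, PLATE_ROWS, nrow(image))
  cx <- fit_equidistant(peaks_x, PLATE_COLS, ncol(image))
  structure(list(rows = PLATE_ROWS, cols = PLATE_COLS,
                 centers_y = cy, centers_x = cx,
                 spacing = c(dy = unname(diff(cy[1:2])),
                             dx = unname(diff(cx[1:2]))),
                 origin = c(cy[1], cx[1])),
            class = "grid_spec")
}

# Pixel bounds of one grid cell (half-open around the centre, clipped).
cell_bounds <- function(grid, r, c, dims) {
  half_y <- grid$spacing["dy"] / 2; half_x <- grid$spacing["dx"] / 2
  y0 <- max(1L, as.integer(ceiling(grid$centers_y[r] - half_y)))
  y1 <- min(dims[1], as.integer(floor(grid$centers_y[r] + half_y)))
  x0 <- max(1L, as.integer(ceiling(grid$centers_x[c] - half_x)))
  x1 <- min(dims[2], as.integer(floor(grid$centers_x[c] + half_x)))
  c(y0, y1, x0, x1)
}

#' Segment colonies within grid cells
#'
#' Classical per-cell segmentation standing in for a learned model: within
#' each grid cell a lightly smoothed copy of the image is thresholded by the
#' cell-local Otsu value; the largest connected component is kept and its
#' holes filled. Cells whose candidate component is too small or whose
#' foreground/background contrast is below `min_contrast` are left empty
#' (missing colony). Touching colonies are split at cell boundaries by
#' construction.
#'
#' @param image cropped plate matrix.
#' @param grid a `grid_spec` from [detect_grid()].
#' @param min_area minimum component area in pixels.
#' @param min_contrast minimum mean(foreground) - mean(background) within the
#'   cell, on the preprocessed intensity scale.
#' @param smooth_sigma Gaussian sigma (pixels) of the copy used to derive the
#'   mask; measurement later uses the original pixels.
#' @return integer label matrix of `dim(image)`; label of cell (r, c) is
#'   `(r - 1) * 48 + c`, 0 = background.
#' @export
segment_colonies <- function(image, grid, min_area = 9L, min_contrast = 0.02,
                             smooth_sigma = 0.8) {
  stopifnot(inherits(grid, "grid_spec"))
  sm <- if (smooth_sigma > 0) {
    as_matrix_img(EBImage::gblur(image, sigma = smooth_sigma))
  } else image
  labels <- matrix(0L, nrow(image), ncol(image))
  for (r in seq_len(grid$rows)) {
    for (c in seq_len(grid$cols)) {
      b <- cell_bounds(grid, r, c, dim(image))
      if (b[2] - b[1] < 3 || b[4] - b[3] < 3) next
      cell <- sm[b[1]:b[2], b[3]:b[4]]
      rng <- range(cell)
      if (diff(rng) < min_contrast) next
      cell01 <- matrix(pmin(1, pmax(0, cell)), nrow(cell), ncol(cell))
      th <- EBImage::otsu(EBImage::Image(cell01), range = c(0, 1))
      bw <- cell > th
      if (!any(bw) || all(bw)) next
      # refine to the half-amplitude threshold so disk areas are unbiased
      th <- (mean(cell[bw]) + mean(cell[!bw])) / 2
      bw <- cell > th
      if (!any(bw)) next
      cc <- EBImage::bwlabel(EBImage::Image(bw * 1))
      tab <- tabulate(as.integer(EBImage::imageData(cc)))
      if (!length(tab)) next
      lab <- which.max(tab)
      comp <- EBImage::imageData(cc) == lab
      comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
      if (sum(comp) < min_area) next
      fg_mean <- mean(cell[comp]); bg_mean <- mean(cell[!comp])
      if (!is.finite(bg_mean) || fg_mean - bg_mean < min_contrast) next
      sub <- labels[b[1]:b[2], b[3]:b[4]]
      sub[comp] <- (r - 1L) * grid$cols + c
      labels[b[1]:b[2], b[3]:b[4]] <- sub
    }
  }
  labels
}

#' Measure per-colony area and background-removed intensity
#'
#' Area `A` is the pixel count of the colony's segmentation label. Intensity
#' `I` is the mean foreground pixel value minus the mean of the cell-local
#' background pixels (background removal), in signal units per pixel. Exactly
#' one measurement per grid position is returned; absent colonies are flagged
#' `missing` with `A = 0` and undefined `I`.
#'
#' @param image cropped plate matrix (original pixels).
#' @param labels label matrix from [segment_colonies()].
#' @param grid a `grid_spec`.
#' @return data.frame with 1536 rows: `row`, `col`, `A`, `I`, `missing`,
#'   `touching`, `low_confidence`.
#' @export
measure_colonies <- function(image, labels, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  out <- expand.grid(col = seq_len(grid$cols), row = seq_len(grid$rows))
  out <- out[, c("row", "col")]
  n <- nrow(out)
  A <- integer(n); I <- rep(NA_real_, n)
  missing <- logical(n); touching <- logical(n); lowconf <- logical(n)
  for (i in seq_len(n)) {
    r <- out$row[i]; c <- out$col[i]
    lab <- (r - 1L) * grid$cols + c
    b <- cell_bounds(grid, r, c, dim(image))
    cell_lab <- labels[b[1]:b[2], b[3]:b[4]]
    fg <- cell_lab == lab
    A[i] <- sum(fg)
    if (A[i] == 0L) { missing[i] <- TRUE; next }
    cell_img <- image[b[1]:b[2], b[3]:b[4]]
    bg_px <- cell_img[!fg & cell_lab == 0L]
    bg_mean <- if (length(bg_px)) mean(bg_px) else 0
    I[i] <- mean(cell_img[fg]) - bg_mean
    edge <- fg[1, , drop = FALSE]
    touching[i] <- any(fg[1, ]) || any(fg[nrow(fg), ]) ||
      any(fg[, 1]) || any(fg[, ncol(fg)])
    lowconf[i] <- A[i] < 2L * 9L
  }
  data.frame(row = out$row, col = out$col, A = A, I = I,
             missing = missing, touching = touching,
             low_confidence = lowconf)
}

#' Run the whole image stage on one plate
#'
#' Convenience wrapper: [preprocess()] (optional), [crop_plate()],
#' [detect_grid()], [segment_colonies()], [measure_colonies()], and a join
#' against the plate layout.
#'
#' @param image raw or preprocessed plate matrix.
#' @param layout data.frame mapping grid positions to strains
#'   ([plate_layout()] output or equivalent with `row`, `col`, `strain`,
#'   `class`).
#' @param crop_threshold fixed threshold for [crop_plate()].
#' @param invert passed to [preprocess()].
#' @param ... passed to [segment_colonies()].
#' @return data.frame of measurements with layout columns attached.
#' @export
quantify_plate <- function(image, layout = NULL, crop_threshold = 0.1,
                           invert = FALSE, ...) {
  img <- preprocess(image, invert = invert)
  cr <- crop_plate(img, threshold = crop_threshold)
  grid <- detect_grid(cr$image)
  labels <- segment_colonies(cr$image, grid, ...)
  meas <- measure_colonies(cr$image, labels, grid)
  if (!is.null(layout)) {
    meas <- merge(meas, layout[, c("row", "col", "strain", "class")],
                  by = c("row", "col"), sort = TRUE)
    meas <- meas[order(meas$row, meas$col), ]
    rownames(meas) <- NULL
  }
  attr(meas, "grid") <- grid
  attr(meas, "offset") <- cr$offset
  meas
}
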