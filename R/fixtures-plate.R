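# Synthetic plate generator: renders 1536-colony (32 x 48) agar plate images
# with known colony positions, areas and amplitudes, so the image stage can be
# tested against exact ground truth.

PLATE_ROWS <- 32L
PLATE_COLS <- 48L

STRAIN_CLASSES <- c("TF-pair", "TF1-empty", "empty-TF2", "empty-empty")

#' Build a 1536-position plate layout from strain quadruplicates
#'
#' Each strain occupies a 2 x 2 quadruplicate block of colonies; a full plate
#' holds 384 strain blocks arranged 16 x 24. Blocks are filled row-major in
#' the order given. Unused blocks are left empty (`NA` strain).
#'
#' @param strains character vector of strain ids (length <= 384).
#' @param classes strain class for each strain, one of `"TF-pair"`,
#'   `"TF1-empty"`, `"empty-TF2"`, `"empty-empty"`.
#' @param block_index optional integer vector assigning each strain to a
#'   specific block (1..384, row-major); defaults to `seq_along(strains)`.
#' @return data.frame with one row per grid position (1536 rows): `row`,
#'   `col` (1-based grid coordinates), `block`, `strain`, `class`.
#' @export
plate_layout <- function(strains, classes,
                         block_index = seq_along(strains)) {
  n_blocks <- (PLATE_ROWS / 2L) * (PLATE_COLS / 2L)
  if (length(strains) != length(classes)) {
    stopf("strains and classes must have equal length")
  }
  if (length(strains) > n_blocks) stopf("more than %d strains", n_blocks)
  if (anyDuplicated(block_index) || any(block_index < 1) ||
      any(block_index > n_blocks)) {
    stopf("block_index must be unique values in 1..%d", n_blocks)
  }
  bad <- setdiff(unique(classes), STRAIN_CLASSES)
  if (length(bad)) stopf("unknown strain class: %s", paste(bad, collapse = ", "))

  grid <- expand.grid(row = seq_len(PLATE_ROWS), col = seq_len(PLATE_COLS))
  block_row <- (grid$row + 1L) %/% 2L
  block_col <- (grid$col + 1L) %/% 2L
  grid$block <- (block_row - 1L) * (PLATE_COLS / 2L) + block_col
  slot <- rep(NA_integer_, n_blocks)
  slot[block_index] <- seq_along(strains)
  idx <- slot[grid$block]
  grid$strain <- ifelse(is.na(idx), NA_character_, strains[idx])
  grid$class <- ifelse(is.na(idx), NA_character_, classes[idx])
  grid[order(grid$row, grid$col), c("row", "col", "block", "strain", "class")]
}

#' Ground-truth description of one synthetic plate
#'
#' Couples a layout with per-colony planted amplitudes and radii plus noise
#' parameters. Amplitudes are reporter signal above the local background (on
#' the 0..1 intensity scale); the rendered colony is a flat-top disk with a
#' 1-pixel anti-aliased rim so its true pixel area is well defined.
#'
#' @param layout data.frame from [plate_layout()].
#' @param amplitude per-position planted amplitude (recycled; >= 0).
#' @param radius per-position colony radius in pixels (recycled; > 0; the default avoids half-maximum contours that hit exact integer-lattice distances).
#' @param present logical, colony present at each position (recycled).
#' @param gradient_frac amplitude of the smooth background gradient as a
#'   fraction of the maximum planted amplitude.
#' @param noise_sd standard deviation of i.i.d. Gaussian pixel noise.
#' @param spacing grid spacing in pixels.
#' @param margin blank margin around the grid in pixels.
#' @param base_level constant background pedestal intensity.
#' @param seed integer seed used when rendering.
#' @return object of class `plate_truth`.
#' @export
plate_truth <- function(layout, amplitude = 0, radius = 4.7, present = TRUE,
                        gradient_frac = 0.05, noise_sd = 0.02,
                        spacing = 14L, margin = 20L, base_level = 0.1,
                        seed = 1L) {
  n <- nrow(layout)
  if (n != PLATE_ROWS * PLATE_COLS) stopf("layout must have 1536 rows")
  amplitude <- rep_len(amplitude, n)
  radius <- rep_len(radius, n)
  present <- rep_len(present, n)
  present[is.na(layout$strain)] <- FALSE
  if (any(amplitude < 0)) stopf("amplitudes must be >= 0")
  if (any(radius[present] <= 0)) stopf("radii of present colonies must be > 0")
  structure(list(layout = layout, amplitude = amplitude, radius = radius,
                 present = present, gradient_frac = gradient_frac,
                 noise_sd = noise_sd, spacing = spacing, margin = margin,
                 base_level = base_level, seed = as.integer(seed)),
            class = "plate_truth")
}

# Pixel centers of the 32 x 48 grid for a given truth geometry (1-based).
truth_centers <- function(truth) {
  cy <- truth$margin + (seq_len(PLATE_ROWS) - 0.5) * truth$spacing
  cx <- truth$margin + (seq_len(PLATE_COLS) - 0.5) * truth$spacing
  list(y = cy, x = cx)
}

#' Render a synthetic plate image from its ground truth
#'
#' Colonies are radially symmetric flat-top disks (full amplitude up to the
#' planted radius, linear 1-pixel anti-aliased rim) centred on an equidistant
#' grid, added to a smooth low-order background gradient plus i.i.d. Gaussian
#' pixel noise. Identical `truth` (including its seed) yields an identical
#' image.
#'
#' @param truth a [plate_truth()] object.
#' @return list with `image` (numeric matrix, values in `[0, 1]`, larger =
#'   stronger reporter signal) and `truth_table` (data.frame with per-position
#'   `row`, `col`, `strain`, `class`, `cy`, `cx`, `amplitude`, `radius`,
#'   `present`, `true_area`). `true_area` is the number of pixels within
#'   `radius + 0.5` of the centre (the rendered mask at half amplitude).
#' @export
gen_plate <- function(truth) {
  stopifnot(inherits(truth, "plate_truth"))
  sp <- truth$spacing
  if (any(truth$radius[truth$present] + 1 > sp / 2)) stopf("layout_overflow")
  H <- as.integer(2 * truth$margin + PLATE_ROWS * sp)
  W <- as.integer(2 * truth$margin + PLATE_COLS * sp)
  ctr <- truth_centers(truth)

  max_amp <- if (any(truth$present)) max(truth$amplitude[truth$present], 0) else 0
  grad_amp <- truth$gradient_frac * max_amp
  u <- matrix(rep((seq_len(H) - 1) / (H - 1), W), H, W)
  v <- matrix(rep((seq_len(W) - 1) / (W - 1), each = H), H, W)
  img <- truth$base_level + grad_amp * (0.6 * u + 0.3 * v + 0.1 * u * v)

  with_seed(truth$seed, {
    if (truth$noise_sd > 0) {
      img <- img + matrix(rnorm(H * W, 0, truth$noise_sd), H, W)
    }
  })

  lay <- truth$layout
  true_area <- integer(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    if (!truth$present[i]) next
    r <- truth$radius[i]
    a <- truth$amplitude[i]
    cy <- ctr$y[lay$row[i]]
    cx <- ctr$x[lay$col[i]]
    yy <- seq.int(max(1L, floor(cy - r - 1)), min(H, ceiling(cy + r + 1)))
    xx <- seq.int(max(1L, floor(cx - r - 1)), min(W, ceiling(cx + r + 1)))
    d <- sqrt(outer((yy - cy)^2, (xx - cx)^2, `+`))
    w <- pmin(1, pmax(0, r + 1 - d))
    img[yy, xx] <- img[yy, xx] + a * w
    true_area[i] <- sum(d <= r + 0.5)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  tt <- data.frame(row = lay$row, col = lay$col, strain = lay$strain,
                   class = lay$class, cy = ctr$y[lay$row], cx = ctr$x[lay$col],
                   amplitude = truth$amplitude, radius = truth$radius,
                   present = truth$present, true_area = true_area,
                   stringsAsFactors = FALSE)
  list(image = img, truth_table = tt)
}

#' Write a plate image as 16-bit grayscale PNG
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(image, path) {
  EBImage::writeImage(EBImage::Image(t(image)), path, type = "png",
                      bits.per.sample = 16L)
  invisible(path)
}

#' Read a plate image from PNG/TIFF
#'
#' Returns a plain numeric matrix (rows = image rows); multi-channel images
#' are converted to grayscale by channel averaging.
#'
#' @param path image file path.
#' @return numeric matrix.
#' @export
read_plate_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- apply(dat, c(1, 2), mean)
  t(dat)
}
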