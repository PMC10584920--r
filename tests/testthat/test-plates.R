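# Image stage: preprocessing, cropping, grid detection, segmentation,
# measurement.

make_test_plate <- function(noise_sd = 0.02, absent_frac = 0, seed = 7,
                            n_strains = 96) {
  strains <- sprintf("S%02d", seq_len(n_strains))
  classes <- rep(c("TF-pair", "TF1-empty", "empty-TF2", "empty-empty"),
                 length.out = n_strains)
  lay <- plate_layout(strains, classes,
                      block_index = round(seq(1, 384, length.out = n_strains)))
  amp <- ifelse(is.na(lay$strain), 0,
                0.2 + 0.6 * (match(lay$strain, strains) %% 3) / 2)
  present <- !is.na(lay$strain)
  if (absent_frac > 0) {
    set.seed(seed)
    idx <- which(present)
    present[sample(idx, round(absent_frac * length(idx)))] <- FALSE
  }
  tr <- plate_truth(lay, amplitude = amp, present = present,
                    noise_sd = noise_sd, seed = seed)
  c(gen_plate(tr), list(truth = tr))
}

test_that("preprocess handles zero, constant and multi-channel images", {
  expect_equal(preprocess(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_equal(preprocess(matrix(0.5, 4, 4)), matrix(0.5, 4, 4))
  arr <- array(rep(c(0, 0.5, 1), each = 4), dim = c(2, 2, 3))
  expect_equal(dim(preprocess(arr)), c(2, 2))
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "empty image")
  # rank order of colony-center means preserved on a rendered plate
  pl <- make_test_plate(noise_sd = 0)
  img <- preprocess(pl$image)
  tt <- pl$truth_table[pl$truth_table$present, ]
  ord <- tapply(seq_len(nrow(tt)), tt$amplitude, function(i)
    mean(img[cbind(round(tt$cy[i]), round(tt$cx[i]))]))
  expect_false(is.unsorted(ord))
})

test_that("crop_plate finds the foreground bounding box and is idempotent", {
  img <- matrix(0, 30, 40)
  img[11, 21] <- 1
  cr <- crop_plate(img, 0.5)
  expect_equal(dim(cr$image), c(1, 1))
  expect_equal(cr$offset, c(10, 20))

  full <- matrix(1, 5, 5)
  crf <- crop_plate(full, 0.5)
  expect_equal(crf$offset, c(0, 0))
  expect_equal(dim(crf$image), c(5, 5))

  expect_error(crop_plate(matrix(0, 5, 5), 0.5), "blank_plate")

  pl <- make_test_plate(noise_sd = 0)
  cr1 <- crop_plate(preprocess(pl$image), 0.1)
  cr2 <- crop_plate(cr1$image, 0.1)
  expect_identical(cr1$image, cr2$image)
  expect_equal(cr2$offset, c(0, 0))
})

test_that("crop bounds equal the extreme planted colony pixels on a strong noise-free plate", {
  lay <- plate_layout(sprintf("S%d", 1:96), rep("TF-pair", 96))
  tr <- plate_truth(lay, amplitude = 0.8, gradient_frac = 0, noise_sd = 0,
                    seed = 1)
  pl <- gen_plate(tr)
  img <- preprocess(pl$image)
  cr <- crop_plate(img, 0.1)
  fg <- which(img > 0.1, arr.ind = TRUE)
  expect_equal(cr$offset, c(min(fg[, 1]) - 1, min(fg[, 2]) - 1))
  expect_equal(dim(cr$image), c(diff(range(fg[, 1])) + 1,
                                diff(range(fg[, 2])) + 1))
})

test_that("detect_grid recovers planted centers within 1 px (noise-free) and 2 px (default noise)", {
  for (noise in c(0, 0.02)) {
    pl <- make_test_plate(noise_sd = noise)
    img <- preprocess(pl$image)
    cr <- crop_plate(img, 0.1)
    g <- detect_grid(cr$image)
    truth_y <- sort(unique(pl$truth_table$cy)) - cr$offset[1]
    truth_x <- sort(unique(pl$truth_table$cx)) - cr$offset[2]
    tol <- if (noise == 0) 1 else 2
    expect_lt(max(abs(g$centers_y - truth_y)), tol)
    expect_lt(max(abs(g$centers_x - truth_x)), tol)
  }
})

test_that("detect_grid tolerates 10% missing colonies and rejects blank images", {
  pl <- make_test_plate(absent_frac = 0.1, n_strains = 384)
  cr <- crop_plate(preprocess(pl$image), 0.1)
  g <- detect_grid(cr$image)
  expect_length(g$centers_y, 32)
  expect_length(g$centers_x, 48)
  truth_y <- sort(unique(pl$truth_table$cy)) - cr$offset[1]
  expect_lt(max(abs(g$centers_y - truth_y)), 2)

  expect_error(detect_grid(matrix(0.5, 200, 300)), "no_grid_detected")
})

test_that("segment + measure recover area within 10% and amplitude ordering", {
  pl <- make_test_plate(noise_sd = 0.02)
  cr <- crop_plate(preprocess(pl$image), 0.1)
  g <- detect_grid(cr$image)
  labels <- segment_colonies(cr$image, g)
  meas <- measure_colonies(cr$image, labels, g)
  expect_equal(nrow(meas), 1536)
  m <- merge(meas, pl$truth_table, by = c("row", "col"))
  pres <- m[m$present, ]
  expect_true(all(!pres$missing))
  expect_true(all(abs(pres$A - pres$true_area) / pres$true_area <= 0.10))
  # empty cells flagged missing, A = 0, I undefined
  ab <- m[!m$present, ]
  expect_true(all(ab$missing))
  expect_true(all(ab$A == 0))
  expect_true(all(is.na(ab$I)))
  # planted amplitudes 0.2 < 0.5 < 0.8: measured mean I strictly increasing
  mi <- tapply(pres$I, pres$amplitude, mean)
  expect_false(is.unsorted(mi))
})

test_that("measure returns exact values for a uniform disk on zero background", {
  img <- matrix(0, 28, 28)
  cy <- 14.5; cx <- 14.5
  d <- sqrt(outer((1:28 - cy)^2, (1:28 - cx)^2, `+`))
  img[d <= 5.1] <- 0.6
  grid <- structure(list(rows = 1L, cols = 1L, centers_y = cy, centers_x = cx,
                         spacing = c(dy = 28, dx = 28), origin = c(cy, cx)),
                    class = "grid_spec")
  labels <- matrix(0L, 28, 28)
  labels[img > 0] <- 1L
  meas <- measure_colonies(img, labels, grid)
  expect_equal(meas$A, sum(d <= 5.1))
  expect_equal(meas$I, 0.6)
})
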