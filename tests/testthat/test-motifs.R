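# PWM scanning, exact p-values, core-motif merging, co-binding.

random_pwm <- function(k, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(4 * k) + 0.02, 4, k)
  new_pwm(sweep(m, 2, colSums(m), "/"), tf = paste0("T", seed))
}

test_that("low-specificity filter drops PWMs with no informative position", {
  keep <- matrix(0.25, 4, 6); keep[1, 3] <- 1; keep[2:4, 3] <- 0
  expect_true(filter_low_specificity(new_pwm(keep)))
  expect_false(filter_low_specificity(new_pwm(matrix(0.25, 4, 6))))
  boundary <- matrix((1 - 0.79) / 3, 4, 5); boundary[1, ] <- 0.79
  expect_false(filter_low_specificity(new_pwm(boundary)))
})

test_that("scan_pwm scores the right number of windows and the consensus score in closed form", {
  p <- random_pwm(10, 1)
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  hits_all <- scan_pwm(p, c(x = s), p_max = 1, both_strands = FALSE)
  expect_equal(nrow(hits_all), 91)  # |s| - k + 1 windows
  expect_equal(nrow(scan_pwm(p, c(x = substr(s, 1, 9)), p_max = 1)), 0)
  # window matching the per-position argmax: score = sum log2(max / 0.25)
  cons <- pwm_consensus(p)
  h <- scan_pwm(p, c(y = cons), p_max = 1, both_strands = FALSE)
  expect_equal(h$score, sum(log2(apply(p$matrix, 2, max) / 0.25)),
               tolerance = 1e-12)
})

test_that("reverse-strand hits are reported in forward coordinates", {
  fx <- gen_motif_set(1, c(p = 60), k = 8, seed = 3)
  p <- fx$pwms$TF1
  cons <- pwm_consensus(p)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  seqs <- c(pr = paste0(strrep("A", 20), rc, strrep("A", 32)))
  h <- scan_pwm(p, seqs, p_max = 1e-3)
  minus <- h[h$strand == "-", ]
  expect_true(nrow(minus) >= 1)
  expect_true(any(minus$start == 20 & minus$end == 28))
})

test_that("DP p-values equal exhaustive enumeration for k <= 8 and obey closed forms", {
  for (seed in 1:6) {
    k <- sample(3:8, 1)
    p <- random_pwm(k, seed)
    units <- round(p$logodds / 1e-4)
    # probe scores across the support, on the discretization grid
    probes <- (c(sum(apply(units, 2, min)),
                 sum(apply(units, 2, max)),
                 round(seq(sum(apply(units, 2, min)),
                           sum(apply(units, 2, max)), length.out = 9)))) * 1e-4
    expect_equal(pwm_score_pvalue(p, probes),
                 enumerate_pwm_pvalues(p, probes), tolerance = 1e-12)
  }
  # unique consensus -> p = 4^-k; below-minimum score -> p = 1
  p <- random_pwm(6, 99)
  cons_score <- sum(apply(p$logodds, 2, max))
  expect_equal(pwm_score_pvalue(p, cons_score), 4^-6)
  expect_equal(pwm_score_pvalue(p, -1e6), 1)
  expect_equal(pwm_score_pvalue(p, -Inf), 1)
})

test_that("p-value is monotone non-increasing in score", {
  p <- random_pwm(7, 5)
  sc <- seq(-20, 15, length.out = 200)
  pv <- pwm_score_pvalue(p, sc)
  expect_true(all(diff(pv) <= 1e-15))
})

test_that("core-motif merging reproduces the hand-traced examples", {
  # two identical hits -> one core equal to the hit
  h1 <- data.frame(start = c(10, 10), end = c(20, 20))
  expect_equal(merge_core_motifs(h1)[, c("start", "end")],
               data.frame(start = 10, end = 20))
  # 80% overlap boundary -> grouped; core = intersection
  h2 <- data.frame(start = c(0, 2), end = c(10, 12))
  expect_equal(merge_core_motifs(h2)[, c("start", "end")],
               data.frame(start = 2, end = 10))
  # chain whose full intersection is too short -> (n-1) fallback core
  h3 <- data.frame(start = c(0, 2, 8), end = c(10, 12, 18))
  out3 <- merge_core_motifs(h3)
  expect_true(any(out3$start == 2 & out3$end == 10))
  # n-1 contiguous-subset fallback inside a genuine >= 80% group
  h4 <- data.frame(start = c(0, 1, 2), end = c(5, 6, 7))
  out4 <- merge_core_motifs(h4)
  expect_equal(out4$start[1], 1)
  expect_equal(out4$end[1], 5)
})

test_that("cores are non-overlapping, >= 4 nt, and contained in member hits on random hit sets", {
  set.seed(42)
  for (rep in 1:300) {
    k <- sample(5:12, 1)
    n <- sample(1:8, 1)
    starts <- sort(sample(0:60, n, replace = TRUE))
    hits <- data.frame(start = starts, end = starts + k)
    cores <- merge_core_motifs(hits)
    if (!nrow(cores)) next
    expect_true(all(cores$end - cores$start >= 4))
    if (nrow(cores) > 1) {
      expect_true(all(cores$start[-1] >= cores$end[-nrow(cores)]))
    }
    # each core lies within at least one hit (containment in its members)
    for (i in seq_len(nrow(cores))) {
      expect_true(any(hits$start <= cores$start[i] &
                        hits$end >= cores$end[i]))
    }
  }
})

test_that("co-binding uses the edge-to-edge gap convention", {
  a <- data.frame(start = 100, end = 110)
  expect_equal(nrow(pair_cobinding(a, data.frame(start = 114, end = 124))), 1)
  expect_equal(pair_cobinding(a, data.frame(start = 114, end = 124))$gap, 4)
  expect_equal(nrow(pair_cobinding(a, data.frame(start = 121, end = 131))), 0)
  expect_equal(nrow(pair_cobinding(a, data.frame(start = 120, end = 130))), 1)
  ov <- pair_cobinding(a, data.frame(start = 105, end = 115))
  expect_equal(ov$gap, 0)
})

test_that("PWM text files round-trip", {
  fx <- gen_motif_set(3, c(p = 50), seed = 10)
  path <- tempfile(fileext = ".pwm")
  write_pwm_file(fx$pwms, path)
  back <- read_pwm_file(path)
  expect_equal(names(back), names(fx$pwms))
  for (nm in names(back)) {
    expect_equal(back[[nm]]$matrix, fx$pwms[[nm]]$matrix, tolerance = 1e-6)
  }
})
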