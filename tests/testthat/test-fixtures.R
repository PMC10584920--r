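# Synthetic-data generators: determinism, ground-truth consistency.

test_that("gen_plate is deterministic and renders the background alone at zero amplitude", {
  lay <- plate_layout(c("S1", "S2"), c("TF-pair", "empty-empty"))
  tr <- plate_truth(lay, amplitude = 0.6, seed = 3)
  expect_identical(gen_plate(tr)$image, gen_plate(tr)$image)

  tr0 <- plate_truth(lay, amplitude = 0, gradient_frac = 0, noise_sd = 0,
                     seed = 3)
  img0 <- gen_plate(tr0)$image
  expect_true(all(img0 == tr0$base_level))
})

test_that("rendered true area equals the half-amplitude mask pixel count", {
  lay <- plate_layout("S1", "TF-pair")
  tr <- plate_truth(lay, amplitude = 0.8, radius = 5, gradient_frac = 0,
                    noise_sd = 0, seed = 1)
  pl <- gen_plate(tr)
  tt <- pl$truth_table[pl$truth_table$present, ]
  for (i in seq_len(nrow(tt))) {
    fg <- pl$image >= tr$base_level + 0.5 * tt$amplitude[i]
    # count within this colony's cell only
    yy <- round(tt$cy[i]) + (-7:7); xx <- round(tt$cx[i]) + (-7:7)
    expect_equal(sum(fg[yy, xx]), tt$true_area[i])
  }
})

test_that("gen_plate rejects colonies that overflow their grid cell", {
  lay <- plate_layout("S1", "TF-pair")
  tr <- plate_truth(lay, amplitude = 0.5, radius = 6.5, seed = 1)
  expect_error(gen_plate(tr), "layout_overflow")
})

test_that("gen_screen amplitudes follow the planted event semantics", {
  ev <- data.frame(bait = "B", pair = c("P1", "P2", "P3"),
                   event = c("none", "TF1-antagonized", "obligate-cooperative"))
  sc <- gen_screen(screen_truth(ev, "2-AD"), seed = 2, colony_cv = 0)
  pt <- sc$plates[["B"]]
  amp_of <- function(strain) {
    unique(pt$amplitude[!is.na(pt$layout$strain) & pt$layout$strain == strain])
  }
  base <- amp_of("P1:pair")
  # none: all four strains at baseline amplitude
  expect_equal(amp_of("P1:tf1"), base)
  expect_equal(amp_of("P1:tf2"), base)
  expect_equal(amp_of("empty:01"), base)
  # TF1-antagonized: TF1-empty high, pair baseline
  expect_gt(amp_of("P2:tf1"), 10 * base)
  expect_equal(amp_of("P2:pair"), base)
  # obligate cooperative: pair high, singles baseline
  expect_gt(amp_of("P3:pair"), 10 * base)
  expect_equal(amp_of("P3:tf1"), base)
})

test_that("gen_screen emits one expected call per planted event, closed under the call vocabulary", {
  ev <- data.frame(bait = "B", pair = sprintf("P%03d", 1:100),
                   event = rep(c("obligate-cooperative", "enhanced-cooperative",
                                 "TF1-antagonized", "TF2-antagonized",
                                 "independent", "none"), length.out = 100))
  sc <- gen_screen(screen_truth(ev, "2-AD"), seed = 1)
  expect_equal(nrow(sc$expected), 100)
  expect_identical(sc$expected$event, ev$event)
  expect_true(all(sc$expected$expected_call %in%
                    c("cooperative", "antagonistic_TF1", "antagonistic_TF2",
                      "independent", "none")))
  expect_error(screen_truth(data.frame(bait = "B", pair = "P", event = "bogus")),
               "unknown event")
})

test_that("gen_motif_set plants consensus sites at the stated coordinates", {
  fx <- gen_motif_set(2, c(promA = 300), k = 8,
                      planted_sites = data.frame(tf = "TF1", promoter = "promA",
                                                 pos = 100), seed = 7)
  expect_equal(fx$sites,
               data.frame(tf = "TF1", promoter = "promA", start = 100,
                          end = 108, strand = "+", stringsAsFactors = FALSE))
  cons <- pwm_consensus(fx$pwms$TF1)
  expect_equal(substr(fx$promoters[["promA"]], 101, 108), cons)

  # zero planted sites -> empty truth
  fx0 <- gen_motif_set(1, c(p = 50), seed = 1)
  expect_equal(nrow(fx0$sites), 0)

  # two sites 4 nt apart for two TFs -> co-binding marked
  fx2 <- gen_motif_set(2, c(p = 200),
                       planted_sites = data.frame(tf = c("TF1", "TF2"),
                                                  promoter = "p",
                                                  pos = c(50, 62)), seed = 2)
  expect_equal(nrow(fx2$cobinding), 1)
  expect_equal(fx2$cobinding$gap, 4)

  expect_error(gen_motif_set(1, c(p = 50),
                             planted_sites = data.frame(tf = "TF1",
                                                        promoter = "p",
                                                        pos = 48), seed = 1),
               "exceeds promoter bounds")
})

test_that("gen_expression patterns have the promised structure", {
  fx <- gen_expression(4, 187, patterns = c("uniform", "exclusive", "dual",
                                            "random"), seed = 3)
  expect_true(all(fx$matrix[1, ] == fx$matrix[1, 1]))
  expect_equal(sum(fx$matrix[2, ] > 0), 1)
  expect_equal(sum(fx$matrix[3, ] > 0), 2)
  expect_identical(gen_expression(4, 187, seed = 3)$matrix,
                   gen_expression(4, 187, seed = 3)$matrix)
})

test_that("gen_alignments truth marks wells with dominant on-target reads confirmed", {
  wells <- data.frame(well = c("w1", "w2"), expected = c("TFA", "TFB"))
  fx <- gen_alignments(wells, targets = c("TFA", "TFB", "TFC"),
                       on_target = 0.95, seed = 4)
  expect_true(all(fx$truth$confirmed))
  # and a well dominated by off-target reads is not confirmed
  fx_bad <- gen_alignments(data.frame(well = "w1", expected = "TFA"),
                           targets = c("TFA", "TFB"), on_target = 0.02,
                           seed = 5)
  expect_false(fx_bad$truth$confirmed[1])
})

test_that("gen_network null fixture places evidence independently of edges", {
  fx <- gen_network(20, 8, enrichment = 0, seed = 6)
  expect_s3_class(fx$network, "bipartite_network")
  expect_false(fx$enriched)
  # same seed reproduces evidence exactly
  fx2 <- gen_network(20, 8, enrichment = 0, seed = 6)
  expect_identical(fx$evidence, fx2$evidence)
})
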