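# Degree-preserving randomization, overlap counting, proportion statistics.

test_that("the only legal swap of a two-edge network exchanges the targets", {
  edges <- data.frame(pair_id = c("a", "b"), tf1 = c("a1", "b1"),
                      tf2 = c("a2", "b2"), promoter = c("x", "y"))
  net <- bipartite_network(edges)
  r <- edge_switch_randomize(net, n_switches = 1, seed = 1)
  expect_equal(r$edges$promoter[r$edges$pair_id == "a"], "y")
  expect_equal(r$edges$promoter[r$edges$pair_id == "b"], "x")
})

test_that("a single-edge network is returned unchanged with a warning", {
  net <- bipartite_network(data.frame(pair_id = "a", tf1 = "t1", tf2 = "t2",
                                      promoter = "x"))
  expect_warning(r <- edge_switch_randomize(net, n_switches = 5, seed = 1,
                                            max_tries = 100),
                 "swaps possible")
  expect_equal(r$edges, net$edges)
})

test_that("randomization preserves every node degree and forbids duplicate edges", {
  fx <- gen_network(40, 10, enrichment = 0, seed = 3)
  deg0 <- network_degrees(fx$network)
  for (s in 1:5) {
    r <- edge_switch_randomize(fx$network, n_switches = 2000, seed = s)
    deg <- network_degrees(r)
    expect_equal(deg$source, deg0$source)
    expect_equal(deg$target, deg0$target)
    expect_equal(anyDuplicated(r$edges[c("pair_id", "promoter")]), 0L)
  }
})

test_that("overlap_count requires evidence for both TFs under each mode", {
  edges <- data.frame(pair_id = c("p1", "p2"), tf1 = c("A", "C"),
                      tf2 = c("B", "D"), promoter = c("x", "y"))
  net <- bipartite_network(edges)
  expect_equal(overlap_count(net, data.frame(tf = character(),
                                             promoter = character()),
                             mode = "chip_any_cell"), 0)
  ev_full <- data.frame(tf = c("A", "B", "C", "D"),
                        promoter = c("x", "x", "y", "y"))
  expect_equal(overlap_count(net, ev_full, "chip_any_cell"), 2)
  # only one TF covered on edge 2
  ev_half <- ev_full[-4, ]
  expect_equal(overlap_count(net, ev_half, "chip_any_cell"), 1)
  # same-cell mode needs a shared cell line
  ev_cell <- transform(ev_full, cell_line = c("c1", "c2", "c3", "c3"))
  expect_equal(overlap_count(net, ev_cell, "chip_same_cell"), 1)
  # summit proximity: within 50 bp counts, beyond does not
  ev_sum <- transform(ev_full, summit = c(100, 149, 100, 151))
  expect_equal(overlap_count(net, ev_sum, "chip_summits_50bp"), 1)
  expect_error(overlap_count(net, ev_full, "chip_same_cell"), "lacks fields")
  # hand-placed same-cell evidence on 3 of 10 edges
  fx <- gen_network(10, 4, enrichment = 0, seed = 5, base_p = 0)
  e <- fx$network$edges
  picks <- e[1:3, ]
  ev <- do.call(rbind, lapply(seq_len(3), function(i) {
    data.frame(tf = c(picks$tf1[i], picks$tf2[i]), promoter = picks$promoter[i],
               cell_line = "CL", summit = c(10, 20))
  }))
  expect_equal(overlap_count(fx$network, ev, "chip_same_cell"), 3)
})

test_that("null_significance matches the closed-form Z and p", {
  nulls <- c(10, 12, 14, 16, 18)
  r0 <- null_significance(mean(nulls), nulls)
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 1)
  r2 <- null_significance(mean(nulls) + 2 * sd(nulls), nulls)
  expect_equal(r2$z, 2)
  expect_equal(r2$p_value, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(r2$p_value, 0.0455, tolerance = 1e-3)
  expect_error(null_significance(5, c(3, 3, 3)), "degenerate_null")
})

test_that("sampled null overlap distribution matches exhaustive enumeration on a matching fixture", {
  # 4x4 perfect matching: every double-edge swap is valid, so the chain's
  # stationary distribution is uniform over the 24 matchings
  n <- 4
  edges <- data.frame(pair_id = paste0("m", 1:n),
                      tf1 = paste0("t", 1:n, "a"), tf2 = paste0("t", 1:n, "b"),
                      promoter = paste0("q", 1:n))
  net <- bipartite_network(edges)
  ev <- data.frame(tf = c("t1a", "t1b", "t1a", "t1b", "t2a", "t2b"),
                   promoter = c("q1", "q1", "q2", "q2", "q1", "q1"),
                   cell_line = "CL", summit = 1)
  set.seed(7)
  rt <- randomization_test(net, ev, mode = "chip_any_cell",
                           n_networks = 4000, n_switches = 60)
  expect_true(rt$degrees_preserved)
  sampled <- table(factor(rt$null_samples, levels = 0:n)) / 4000
  perms <- enumerate_matchings(n)
  ok <- matrix(FALSE, n, n)
  ok[1, 1] <- ok[1, 2] <- ok[2, 1] <- TRUE
  ov <- apply(perms, 1, function(pp) sum(ok[cbind(1:n, pp)]))
  exact <- table(factor(ov, levels = 0:n)) / nrow(perms)
  tv <- 0.5 * sum(abs(sampled - exact))
  expect_lt(tv, 0.05)
})

test_that("planted enrichment yields Z >= 3 and null fixtures stay near zero", {
  z_enr <- vapply(1:25, function(i) {
    fx <- gen_network(60, 10, enrichment = 5, seed = i, base_p = 0.12)
    randomization_test(fx$network, fx$evidence, "chip_any_cell",
                       n_networks = 200, n_switches = 1500, seed = i + 500)$z
  }, numeric(1))
  expect_gte(mean(z_enr >= 3), 0.9)
  z_null <- vapply(1:25, function(i) {
    fx <- gen_network(60, 10, enrichment = 0, seed = i, base_p = 0.12)
    randomization_test(fx$network, fx$evidence, "chip_any_cell",
                       n_networks = 200, n_switches = 1500, seed = i + 500)$z
  }, numeric(1))
  expect_gte(mean(abs(z_null) < 2), 0.9)
})

test_that("two-proportion test matches hand-computed standard errors and z", {
  r <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r$se1, 0.05)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  # pooled z, hand-computed closed form
  x1 <- 67; n1 <- 176; x2 <- 129; n2 <- 226
  r2 <- two_proportion_test(x1, n1, x2, n2)
  pp <- (x1 + x2) / (n1 + n2)
  z_hand <- (x1 / n1 - x2 / n2) /
    sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(r2$z, z_hand, tolerance = 1e-12)
  expect_equal(abs(r2$z), 3.78, tolerance = 0.01)
  expect_error(two_proportion_test(1, 0, 1, 2), "positive")
})
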