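# Degree-preserving randomization of the TF-pair -> promoter network,
# evidence-overlap counting, and proportion statistics.

#' Construct a bipartite TF-pair to promoter network
#'
#' Directed edges run from TF-pair source nodes to promoter target nodes.
#' Each pair node carries its two member TFs.
#'
#' @param edges data.frame with columns `pair_id`, `tf1`, `tf2`, `promoter`;
#'   one row per unique edge.
#' @return object of class `bipartite_network`.
#' @export
bipartite_network <- function(edges) {
  stopifnot(all(c("pair_id", "tf1", "tf2", "promoter") %in% names(edges)))
  if (anyDuplicated(edges[c("pair_id", "promoter")])) {
    stopf("duplicate edges in network")
  }
  pairs <- unique(edges[, c("pair_id", "tf1", "tf2")])
  if (anyDuplicated(pairs$pair_id)) {
    stopf("pair_id maps to more than one (tf1, tf2)")
  }
  promoters <- sort(unique(edges$promoter))
  structure(list(edges = edges, pairs = pairs, promoters = promoters),
            class = "bipartite_network")
}

#' Degree-preserving edge-switch randomization
#'
#' Performs `n_switches` successful double-edge swaps (two edges exchange
#' their promoter endpoints); proposals that would create a duplicate edge,
#' or that involve edges sharing an endpoint, are rejected and retried.
#' Source and target degree sequences are preserved exactly. If the retry
#' budget is exhausted before `n_switches` successes (e.g. a single-edge
#' network admits no swap) the current network is returned with a warning.
#'
#' @param net a [bipartite_network()].
#' @param n_switches number of successful swaps.
#' @param seed optional integer seed (`set.seed` is called when non-NULL).
#' @param max_tries proposal budget (default `100 * n_switches`).
#' @return a randomized `bipartite_network` with the same degree sequences.
#' @export
edge_switch_randomize <- function(net, n_switches = 20000, seed = NULL,
                                  max_tries = 100 * n_switches) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.null(seed)) set.seed(seed)
  src_lev <- net$pairs$pair_id
  tgt_lev <- net$promoters
  src <- match(net$edges$pair_id, src_lev)
  dst <- match(net$edges$promoter, tgt_lev)
  res <- edge_switch_cpp(src, dst, length(src_lev), length(tgt_lev),
                         n_switches, max_tries)
  if (res$n_done < n_switches) {
    warnf("only %d of %d swaps possible within the retry budget",
          res$n_done, n_switches)
  }
  edges <- net$edges
  edges$pair_id <- src_lev[res$src]
  edges$promoter <- tgt_lev[res$dst]
  edges$tf1 <- net$pairs$tf1[match(edges$pair_id, net$pairs$pair_id)]
  edges$tf2 <- net$pairs$tf2[match(edges$pair_id, net$pairs$pair_id)]
  bipartite_network(edges)
}

#' Node degrees of a bipartite network
#'
#' @param net a [bipartite_network()].
#' @return list with named integer vectors `source` and `target`.
#' @export
network_degrees <- function(net) {
  list(source = table(factor(net$edges$pair_id, levels = net$pairs$pair_id)),
       target = table(factor(net$edges$promoter, levels = net$promoters)))
}

# Logical pair-node x promoter matrix: does evidence support BOTH member TFs
# of the pair at that promoter under the given mode?
evidence_ok_matrix <- function(net, evidence, mode, max_summit_dist = 50,
                               max_motif_gap = 10) {
  pairs <- net$pairs
  proms <- net$promoters
  ok <- matrix(FALSE, nrow(pairs), length(proms),
               dimnames = list(pairs$pair_id, proms))
  chip_modes <- c("chip_any_cell", "chip_same_cell", "chip_summits_50bp")
  motif_modes <- c("motif_anywhere", "motif_within_10bp")
  if (mode %in% chip_modes) {
    need <- c("tf", "promoter",
              if (mode == "chip_same_cell") "cell_line",
              if (mode == "chip_summits_50bp") "summit")
    if (!all(need %in% names(evidence))) {
      stopf("evidence lacks fields for mode %s", mode)
    }
  } else if (mode %in% motif_modes) {
    need <- c("tf", "promoter",
              if (mode == "motif_within_10bp") c("start", "end"))
    if (!all(need %in% names(evidence))) {
      stopf("evidence lacks fields for mode %s", mode)
    }
  } else {
    stopf("unknown overlap mode: %s", mode)
  }
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_along(proms)) {
      e1 <- evidence[evidence$tf == pairs$tf1[i] &
                       evidence$promoter == proms[j], , drop = FALSE]
      e2 <- evidence[evidence$tf == pairs$tf2[i] &
                       evidence$promoter == proms[j], , drop = FALSE]
      if (!nrow(e1) || !nrow(e2)) next
      ok[i, j] <- switch(mode,
        chip_any_cell = TRUE,
        motif_anywhere = TRUE,
        chip_same_cell = length(intersect(e1$cell_line, e2$cell_line)) > 0,
        chip_summits_50bp = {
          min(abs(outer(e1$summit, e2$summit, `-`))) <= max_summit_dist
        },
        motif_within_10bp = {
          nrow(pair_cobinding(e1, e2, max_gap = max_motif_gap)) > 0
        })
    }
  }
  ok
}

#' Count network edges supported by evidence for both TFs
#'
#' An edge (TF1-TF2 -> promoter) counts if the evidence supports BOTH TFs at
#' that promoter under the requested mode: `chip_any_cell` (peaks in any
#' cell line), `chip_same_cell` (peaks in a shared cell line),
#' `chip_summits_50bp` (peak summits within 50 bp of each other),
#' `motif_anywhere` (core motifs of both TFs present), or
#' `motif_within_10bp` (core motifs within 10 nt of each other).
#'
#' @param net a [bipartite_network()].
#' @param evidence data.frame; ChIP modes need `tf`, `promoter` (+
#'   `cell_line`, `summit` where applicable); motif modes need `tf`,
#'   `promoter` (+ `start`, `end`).
#' @param mode one of the five modes above.
#' @param ... mode thresholds (`max_summit_dist`, `max_motif_gap`).
#' @return integer overlap count.
#' @export
overlap_count <- function(net, evidence, mode = "chip_any_cell", ...) {
  ok <- evidence_ok_matrix(net, evidence, mode, ...)
  src <- match(net$edges$pair_id, net$pairs$pair_id)
  dst <- match(net$edges$promoter, net$promoters)
  sum(ok[cbind(src, dst)])
}

#' Z-score and two-tailed p against a randomized null
#'
#' `Z = (observed - mean(null)) / sd(null)`; `p = 2 * (1 - Phi(|Z|))`.
#'
#' @param observed observed overlap count.
#' @param null_samples numeric vector of null overlaps (>= 2 values).
#' @return object of class `randomization_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_value`, `n_null`.
#' @export
null_significance <- function(observed, null_samples) {
  if (length(null_samples) < 2) stopf("need >= 2 null samples")
  mu <- mean(null_samples)
  sdev <- sd(null_samples)
  if (sdev == 0) stopf("degenerate_null")
  z <- (observed - mu) / sdev
  structure(list(observed = observed, null_mean = mu, null_sd = sdev,
                 z = z, p_value = 2 * pnorm(-abs(z)),
                 n_null = length(null_samples)),
            class = "randomization_result")
}

#' Full network randomization test
#'
#' Generates `n_networks` degree-preserving randomizations (each restarted
#' from the observed network, `n_switches` successful swaps each), counts the
#' evidence overlap of each, and compares the observed overlap with the null
#' distribution by Z-score. Degree preservation and edge uniqueness are
#' verified for every randomized network.
#'
#' @param net a [bipartite_network()].
#' @param evidence,mode,... as in [overlap_count()].
#' @param n_networks number of randomized networks.
#' @param n_switches successful swaps per network.
#' @param seed optional integer seed.
#' @return a `randomization_result` with the null sample attached as
#'   `null_samples` and the verification flag as `degrees_preserved`.
#' @export
randomization_test <- function(net, evidence, mode = "chip_any_cell",
                               n_networks = 10000, n_switches = 20000,
                               seed = NULL, ...) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.null(seed)) set.seed(seed)
  ok <- evidence_ok_matrix(net, evidence, mode, ...)
  src <- match(net$edges$pair_id, net$pairs$pair_id)
  dst <- match(net$edges$promoter, net$promoters)
  observed <- sum(ok[cbind(src, dst)])
  res <- randomize_overlap_cpp(src, dst, nrow(net$pairs),
                               length(net$promoters), ok, n_networks,
                               n_switches, 100 * n_switches)
  if (res$short_runs > 0) {
    warnf("%d of %d randomizations exhausted the retry budget",
          res$short_runs, n_networks)
  }
  out <- null_significance(observed, res$overlaps)
  out$null_samples <- res$overlaps
  out$degrees_preserved <- res$all_ok
  out
}

#' Two-proportion comparison test
#'
#' Standard errors per proportion are `sqrt(p * (1 - p) / n)`; the z
#' statistic uses the pooled-proportion normal approximation by default
#' (unpooled optional); the p-value is two-tailed.
#'
#' @param x1,n1,x2,n2 successes and sample sizes of the two groups.
#' @param pooled use the pooled variance estimate for z.
#' @return list with `p1`, `p2`, `se1`, `se2`, `z`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, pooled = TRUE) {
  if (n1 <= 0 || n2 <= 0) stopf("sample sizes must be positive")
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  se1 <- sqrt(p1 * (1 - p1) / n1)
  se2 <- sqrt(p2 * (1 - p2) / n2)
  if (pooled) {
    pp <- (x1 + x2) / (n1 + n2)
    se_diff <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  } else {
    se_diff <- sqrt(se1^2 + se2^2)
  }
  z <- if (se_diff == 0) 0 else (p1 - p2) / se_diff
  list(p1 = p1, p2 = p2, se1 = se1, se2 = se2, z = z,
       p_value = 2 * pnorm(-abs(z)))
}
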