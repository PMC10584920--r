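# Seeded generators for motif, expression, alignment and network fixtures,
# each returning ground truth alongside the generated data.

#' Generate promoters with planted PWM binding sites
#'
#' Builds information-rich PWMs (one dominant base per position), random
#' background promoters, and plants each PWM's consensus at the requested
#' positions. Site coordinates are 0-based half-open on the forward strand.
#'
#' @param n_pwms number of PWMs (TF ids `TF1..TFn`).
#' @param promoter_lengths named integer vector of promoter lengths.
#' @param planted_sites data.frame with `tf`, `promoter`, `pos` (0-based
#'   start); NULL for none.
#' @param k motif length (recycled per PWM).
#' @param dominant probability of the dominant base at each position.
#' @param seed integer seed.
#' @param cobind_gap gap (nt) used to mark planted co-binding pairs.
#' @return list: `pwms` (list of `pwm`), `promoters` (named character),
#'   `sites` (truth data.frame `tf`, `promoter`, `start`, `end`, `strand`),
#'   `cobinding` (truth data.frame of planted site pairs within
#'   `cobind_gap`).
#' @export
gen_motif_set <- function(n_pwms, promoter_lengths, planted_sites = NULL,
                          k = 8L, dominant = 0.9, seed = 1L,
                          cobind_gap = 10L) {
  stopifnot(n_pwms >= 1, all(promoter_lengths >= 1))
  if (is.null(names(promoter_lengths))) {
    names(promoter_lengths) <- paste0("prom", seq_along(promoter_lengths))
  }
  k <- rep_len(as.integer(k), n_pwms)
  with_seed(seed, {
    pwms <- lapply(seq_len(n_pwms), function(i) {
      m <- matrix((1 - dominant) / 3, 4, k[i])
      dom <- sample.int(4, k[i], replace = TRUE)
      m[cbind(dom, seq_len(k[i]))] <- dominant
      new_pwm(m, tf = paste0("TF", i))
    })
    names(pwms) <- vapply(pwms, `[[`, character(1), "tf")
    promoters <- vapply(promoter_lengths, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    sites <- data.frame(tf = character(), promoter = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    if (!is.null(planted_sites) && nrow(planted_sites)) {
      for (i in seq_len(nrow(planted_sites))) {
        tf <- planted_sites$tf[i]
        pr <- planted_sites$promoter[i]
        pos <- planted_sites$pos[i]
        cons <- pwm_consensus(pwms[[tf]])
        L <- nchar(promoters[[pr]])
        if (pos < 0 || pos + nchar(cons) > L) {
          stopf("planted site exceeds promoter bounds (%s at %d)", pr, pos)
        }
        substr(promoters[[pr]], pos + 1, pos + nchar(cons)) <- cons
        sites <- rbind(sites, data.frame(
          tf = tf, promoter = pr, start = pos, end = pos + nchar(cons),
          strand = "+", stringsAsFactors = FALSE))
      }
    }
    cobinding <- data.frame(tf_a = character(), tf_b = character(),
                            promoter = character(), gap = integer(),
                            stringsAsFactors = FALSE)
    if (nrow(sites) > 1) {
      for (i in 1:(nrow(sites) - 1)) {
        for (j in (i + 1):nrow(sites)) {
          if (sites$promoter[i] != sites$promoter[j]) next
          if (sites$tf[i] == sites$tf[j]) next
          gap <- max(0L, max(sites$start[i], sites$start[j]) -
                       min(sites$end[i], sites$end[j]))
          if (gap <= cobind_gap) {
            cobinding <- rbind(cobinding, data.frame(
              tf_a = sites$tf[i], tf_b = sites$tf[j],
              promoter = sites$promoter[i], gap = gap,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    list(pwms = pwms, promoters = promoters, sites = sites,
         cobinding = cobinding)
  })
}

#' Generate a cluster-level expression matrix with known specificity patterns
#'
#' Pattern semantics: `uniform` genes have identical totals in every
#' cluster; `exclusive` genes are non-zero in exactly one cluster; `dual`
#' genes are equal in exactly two clusters; `random` genes draw lognormal
#' values per cluster.
#'
#' @param n_genes,n_clusters matrix dimensions (`n_clusters >= 2`).
#' @param patterns character vector (recycled to `n_genes`) over
#'   `c("uniform", "exclusive", "dual", "random")`.
#' @param level base expression level (cpm-like units).
#' @param seed integer seed.
#' @return list: `matrix` (genes x clusters, pseudocount-free), `patterns`,
#'   `active_clusters` (list of the non-background clusters per gene).
#' @export
gen_expression <- function(n_genes, n_clusters, patterns = "random",
                           level = 100, seed = 1L) {
  stopifnot(n_genes >= 1, n_clusters >= 2)
  patterns <- rep_len(patterns, n_genes)
  bad <- setdiff(unique(patterns), c("uniform", "exclusive", "dual", "random"))
  if (length(bad)) stopf("unknown pattern: %s", paste(bad, collapse = ", "))
  with_seed(seed, {
    m <- matrix(0, n_genes, n_clusters,
                dimnames = list(paste0("gene", seq_len(n_genes)),
                                paste0("cluster", seq_len(n_clusters))))
    active <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      active[[i]] <- switch(patterns[i],
        uniform = {
          m[i, ] <- level
          seq_len(n_clusters)
        },
        exclusive = {
          cl <- sample.int(n_clusters, 1)
          m[i, cl] <- level * n_clusters
          cl
        },
        dual = {
          cl <- sample.int(n_clusters, 2)
          m[i, cl] <- level * n_clusters / 2
          sort(cl)
        },
        random = {
          m[i, ] <- exp(rnorm(n_clusters, log(level), 1))
          seq_len(n_clusters)
        })
    }
    list(matrix = m, patterns = patterns, active_clusters = active)
  })
}

#' Generate SWIM-seq alignment fixtures (SAM text) with confirmation truth
#'
#' Each well gets `n_reads` reads: a seeded binomial share aligns to the
#' well's expected target(s) (split evenly among them) with passing scores;
#' the rest align to decoy targets. A fraction of reads is rendered
#' filter-failing (low score or high mismatch count). The truth flag applies
#' the strict-top-count rule to the surviving reads by construction.
#'
#' @param wells data.frame with `well` and `expected` (list column or
#'   `;`-separated string of expected targets).
#' @param targets character vector of all alignable targets (decoys drawn
#'   from here).
#' @param n_reads reads per well.
#' @param on_target probability a read is on-target.
#' @param fail_rate fraction of reads that fail the alignment-quality
#'   filters.
#' @param read_length trimmed read length (nt).
#' @param seed integer seed.
#' @return list: `sam` (character vector of SAM lines), `truth` (data.frame
#'   `well`, `confirmed`), `expected` (named list well -> expected targets).
#' @export
gen_alignments <- function(wells, targets, n_reads = 80L, on_target = 0.95,
                           fail_rate = 0.05, read_length = 100L, seed = 1L) {
  stopifnot(nrow(wells) >= 1, n_reads >= 1)
  expected <- wells$expected
  if (!is.list(expected)) expected <- strsplit(expected, ";", fixed = TRUE)
  names(expected) <- wells$well
  with_seed(seed, {
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", targets, "\tLN:2000"))
    lines <- header
    truth <- data.frame(well = wells$well, confirmed = NA,
                        stringsAsFactors = FALSE)
    for (w in seq_len(nrow(wells))) {
      well <- wells$well[w]
      exp_t <- expected[[well]]
      n_on <- rbinom(1, n_reads, on_target)
      tgt <- c(sample(exp_t, n_on, replace = TRUE),
               sample(setdiff(targets, exp_t), n_reads - n_on,
                      replace = TRUE))
      fails <- runif(n_reads) < fail_rate
      surv_counts <- integer(0)
      for (r in seq_len(n_reads)) {
        if (fails[r]) {
          score <- round(read_length * runif(1, 0.5, 0.85))
          nm <- round(read_length * runif(1, 0.06, 0.15))
        } else {
          score <- round(read_length * runif(1, 0.92, 1.0))
          nm <- sample(0:3, 1)
        }
        seq <- paste(sample(DNA_BASES, read_length, replace = TRUE),
                     collapse = "")
        lines <- c(lines, paste(
          sprintf("%s_read%03d", well, r), "0", tgt[r], "1", "60",
          paste0(read_length, "M"), "*", "0", "0", seq,
          strrep("I", read_length),
          paste0("AS:i:", score), paste0("NM:i:", nm),
          paste0("RG:Z:", well), sep = "\t"))
        ok <- score >= 0.9 * read_length && nm < 0.05 * read_length
        if (ok) {
          surv_counts[tgt[r]] <- (if (tgt[r] %in% names(surv_counts))
            surv_counts[[tgt[r]]] else 0L) + 1L
        }
      }
      other <- setdiff(names(surv_counts), exp_t)
      other_max <- if (length(other)) max(unlist(surv_counts[other])) else 0L
      conf <- all(vapply(exp_t, function(t) {
        cnt <- if (t %in% names(surv_counts)) surv_counts[[t]] else 0L
        cnt >= 1L && cnt > other_max
      }, logical(1)))
      truth$confirmed[w] <- conf
    }
    list(sam = lines, truth = truth, expected = expected)
  })
}

#' Generate a bipartite network fixture with optional evidence enrichment
#'
#' Builds a random TF-pair to promoter network and a ChIP-like evidence
#' table. With `enrichment = 0` evidence is placed on (pair, promoter)
#' combinations independently of the edge set (null fixture); with
#' `enrichment > 0` true edges receive evidence with probability
#' `min(1, base_p * (1 + enrichment))` versus `base_p` elsewhere.
#'
#' @param n_pairs,n_baits numbers of TF-pair and promoter nodes.
#' @param enrichment evidence enrichment factor on true edges (>= 0).
#' @param seed integer seed.
#' @param mean_degree mean out-degree of pair nodes.
#' @param base_p background evidence probability per (pair, promoter).
#' @return list: `network` ([bipartite_network()]), `evidence` (data.frame
#'   `tf`, `promoter`, `cell_line`, `summit`), `enriched` flag.
#' @export
gen_network <- function(n_pairs, n_baits, enrichment = 0, seed = 1L,
                        mean_degree = 3, base_p = 0.15) {
  stopifnot(n_pairs >= 1, n_baits >= 1, enrichment >= 0)
  with_seed(seed, {
    proms <- paste0("prom", seq_len(n_baits))
    pairs <- data.frame(pair_id = paste0("pair", seq_len(n_pairs)),
                        tf1 = paste0("TF", 2 * seq_len(n_pairs) - 1),
                        tf2 = paste0("TF", 2 * seq_len(n_pairs)),
                        stringsAsFactors = FALSE)
    edges <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      d <- min(n_baits, 1 + rpois(1, max(0, mean_degree - 1)))
      data.frame(pair_id = pairs$pair_id[i], tf1 = pairs$tf1[i],
                 tf2 = pairs$tf2[i],
                 promoter = sample(proms, d), stringsAsFactors = FALSE)
    }))
    is_edge <- matrix(FALSE, n_pairs, n_baits,
                      dimnames = list(pairs$pair_id, proms))
    is_edge[cbind(match(edges$pair_id, pairs$pair_id),
                  match(edges$promoter, proms))] <- TRUE
    p_edge <- min(1, base_p * (1 + enrichment))
    ev <- list()
    for (i in seq_len(n_pairs)) {
      for (j in seq_len(n_baits)) {
        p <- if (is_edge[i, j]) p_edge else base_p
        if (runif(1) < p) {
          s1 <- sample.int(400, 1)
          ev[[length(ev) + 1]] <- data.frame(
            tf = c(pairs$tf1[i], pairs$tf2[i]), promoter = proms[j],
            cell_line = "CL1", summit = c(s1, s1 + sample.int(40, 1)),
            stringsAsFactors = FALSE)
        }
      }
    }
    evidence <- if (length(ev)) do.call(rbind, ev) else {
      data.frame(tf = character(), promoter = character(),
                 cell_line = character(), summit = integer(),
                 stringsAsFactors = FALSE)
    }
    list(network = bipartite_network(edges), evidence = evidence,
         enriched = enrichment > 0)
  })
}
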