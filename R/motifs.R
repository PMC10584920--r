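# PWM scanning with exact p-values, low-specificity filtering, core-motif
# merging and TF-pair co-binding detection.
#
# Scores are per-window sums of log2 odds against a uniform background
# (p = 0.25 per base). P-values are exact: the null score distribution over
# all 4^k words is computed by dynamic programming on a discretized score
# grid, so P(Score >= s) is a finite sum, not an approximation.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position probability matrix object
#'
#' @param matrix 4 x k numeric matrix of base probabilities, rows A, C, G, T
#'   (each column sums to 1).
#' @param tf TF identifier.
#' @param floor_bits lower bound applied to per-position log2 odds (guards
#'   zero probabilities; both scanning and the exact p-value use the floored
#'   matrix).
#' @return object of class `pwm`.
#' @export
new_pwm <- function(matrix, tf = "TF", floor_bits = -20) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 4, ncol(matrix) >= 1)
  if (any(matrix < 0)) stopf("probabilities must be >= 0")
  if (any(abs(colSums(matrix) - 1) > 1e-9)) {
    stopf("each PWM position must sum to 1")
  }
  rownames(matrix) <- DNA_BASES
  logodds <- pmax(log2(matrix / 0.25), floor_bits)
  structure(list(tf = tf, k = ncol(matrix), matrix = matrix,
                 logodds = logodds, background = rep(0.25, 4)),
            class = "pwm")
}

#' Read PWMs from a whitespace-delimited text file
#'
#' Format: a header line `>TF` followed by 4 rows (A, C, G, T) of k
#' probabilities each; multiple PWMs may be concatenated.
#'
#' @param path file path.
#' @return named list of `pwm` objects.
#' @export
read_pwm_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stopf("no PWM header ('>TF') found in %s", path)
  out <- list()
  for (i in seq_along(starts)) {
    tf <- sub("^>\\s*", "", lines[starts[i]])
    block <- lines[(starts[i] + 1):(starts[i] + 4)]
    m <- do.call(rbind, lapply(block, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    out[[tf]] <- new_pwm(m, tf = tf)
  }
  out
}

#' Write PWMs to the text format read by [read_pwm_file()]
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm_file <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf), con)
    for (b in 1:4) {
      writeLines(paste(format(p$matrix[b, ], digits = 8), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Drop low-specificity PWMs
#'
#' A PWM is dropped when the maximum base probability at every position is
#' below `min_prob` (no position is informative).
#'
#' @param pwm a `pwm` object.
#' @param min_prob specificity cutoff (default 0.8).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_low_specificity <- function(pwm, min_prob = 0.8) {
  stopifnot(inherits(pwm, "pwm"))
  any(apply(pwm$matrix, 2, max) >= min_prob)
}

# Encode a DNA string as integer codes 1..4 (A,C,G,T), NA for anything else.
encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], DNA_BASES)
  code
}

# Window scores of an encoded sequence under a log-odds matrix; windows
# containing non-ACGT letters are NA.
window_scores <- function(codes, logodds) {
  k <- ncol(logodds)
  n <- length(codes) - k + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(k)) {
    v <- logodds[cbind(codes[i:(i + n - 1)], i)]
    s <- s + v
  }
  s
}

# Exact null score distribution by dynamic programming on a discretized
# grid: returns integer score units and P(Score = u) for words drawn
# uniformly from {A,C,G,T}^k.
pwm_score_distribution <- function(pwm, granularity = 1e-4) {
  units <- round(pwm$logodds / granularity)
  k <- pwm$k
  lo <- sum(apply(units, 2, min))
  hi <- sum(apply(units, 2, max))
  dist <- numeric(hi - lo + 1)
  # running support starts at offset 0
  cur_lo <- 0
  dist_cur <- 1
  for (i in seq_len(k)) {
    u <- units[, i]
    new_lo <- cur_lo + min(u)
    new_hi <- cur_lo + length(dist_cur) - 1 + max(u)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      off <- cur_lo + u[b] - new_lo
      idx <- seq_along(dist_cur) + off
      new[idx] <- new[idx] + 0.25 * dist_cur
    }
    dist_cur <- new
    cur_lo <- new_lo
  }
  list(units = seq.int(cur_lo, length.out = length(dist_cur)),
       prob = dist_cur, granularity = granularity)
}

#' Exact p-value of a PWM score
#'
#' `P(Score(W) >= score)` for a word `W` uniform over the 4^k k-mers,
#' computed from the exact (discretized) null score distribution.
#' `pwm_score_pvalue(pwm, -Inf)` is 1.
#'
#' @param pwm a `pwm` object.
#' @param score numeric vector of scores (bits).
#' @param granularity score discretization in bits.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
pwm_score_pvalue <- function(pwm, score, granularity = 1e-4) {
  d <- pwm_score_distribution(pwm, granularity)
  sf <- rev(cumsum(rev(d$prob)))  # sf[i] = P(U >= units[i])
  n_u <- length(d$units)
  # a float score accumulates up to half a unit of rounding error per
  # position relative to the integer-unit grid, so queries within k units
  # above the maximum attainable score are the maximum score
  slack <- pwm$k
  vapply(score, function(s) {
    if (!is.finite(s)) return(if (s < 0) 1 else 0)
    u <- round(s / granularity)
    if (u <= d$units[1]) return(1)
    if (u > d$units[n_u]) {
      return(if (u - d$units[n_u] <= slack) sf[n_u] else 0)
    }
    sf[u - d$units[1] + 1]
  }, numeric(1))
}

#' Scan sequences with a PWM
#'
#' Scores every window of every sequence on both strands (sum of log2 odds
#' per window; exactly `|s| - k + 1` windows per strand; windows containing
#' non-ACGT letters are skipped), converts scores to exact p-values, and
#' reports hits with `p <= p_max`. Hit coordinates are 0-based half-open on
#' the forward strand.
#'
#' @param pwm a `pwm` object.
#' @param seqs named character vector of promoter sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param p_max p-value threshold for reported hits.
#' @param both_strands scan the reverse complement as well.
#' @param granularity score discretization in bits.
#' @return data.frame of hits: `tf`, `promoter`, `start`, `end`, `strand`,
#'   `score`, `pvalue`.
#' @export
scan_pwm <- function(pwm, seqs, p_max = 1e-4, both_strands = TRUE,
                     granularity = 1e-4) {
  stopifnot(inherits(pwm, "pwm"))
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  d <- pwm_score_distribution(pwm, granularity)
  sf <- rev(cumsum(rev(d$prob)))
  n_u <- length(d$units)
  pval_of <- function(s) {
    u <- round(s / granularity)
    ifelse(u <= d$units[1], 1,
           ifelse(u > d$units[n_u] + pwm$k, 0,
                  sf[pmax(1, pmin(n_u, u - d$units[1] + 1))]))
  }
  k <- pwm$k
  res <- list()
  for (nm in names(seqs)) {
    codes <- encode_dna(seqs[[nm]])
    L <- length(codes)
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      cd <- if (st == "+") codes else rev(5L - codes)
      sc <- window_scores(cd, pwm$logodds)
      if (!length(sc)) next
      ok <- which(!is.na(sc))
      if (!length(ok)) next
      pv <- pval_of(sc[ok])
      keep <- pv <= p_max
      if (!any(keep)) next
      t0 <- ok[keep] - 1L           # 0-based window start on scanned strand
      start <- if (st == "+") t0 else L - t0 - k
      res[[length(res) + 1]] <- data.frame(
        tf = pwm$tf, promoter = nm, start = start, end = start + k,
        strand = st, score = sc[ok][keep], pvalue = pv[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(tf = character(), promoter = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$promoter, out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# intersection of a set of [start, end) intervals
interval_intersection <- function(start, end) {
  c(max(start), min(end))
}

# Recursive core extraction for one group of overlapping hits (sorted by
# start): emit the widest contiguous-subset intersection >= min_core,
# preferring larger subsets; leftmost on ties; recurse on the remainder.
extract_cores <- function(iv, min_core) {
  n <- nrow(iv)
  if (n == 0) return(NULL)
  if (n == 1) {
    if (iv$end[1] - iv$start[1] >= min_core) return(iv[1, c("start", "end")])
    return(NULL)
  }
  for (m in n:2) {
    best <- NULL
    for (s in 1:(n - m + 1)) {
      sub <- iv[s:(s + m - 1), ]
      ix <- interval_intersection(sub$start, sub$end)
      len <- ix[2] - ix[1]
      if (len >= min_core && (is.null(best) || len > best$len)) {
        best <- list(s = s, m = m, start = ix[1], end = ix[2], len = len)
      }
    }
    if (!is.null(best)) {
      left <- if (best$s > 1) iv[1:(best$s - 1), , drop = FALSE] else NULL
      right <- if (best$s + best$m - 1 < n) {
        iv[(best$s + best$m):n, , drop = FALSE]
      } else NULL
      return(rbind(extract_cores(left %||% iv[0, ], min_core),
                   data.frame(start = best$start, end = best$end),
                   extract_cores(right %||% iv[0, ], min_core)))
    }
  }
  # no multi-member subset intersects widely enough: singleton cores
  do.call(rbind, lapply(seq_len(n), function(i) {
    extract_cores(iv[i, , drop = FALSE], min_core)
  }))
}

#' Merge overlapping motif hits of one TF into core motifs
#'
#' Consecutive hits (sorted by start) sharing at least `min_frac` of the
#' shorter hit's nucleotides are grouped transitively. For each group the
#' n-way intersection is emitted as a core motif if it is `min_core` or
#' longer; otherwise the process falls back to (n-1)-member contiguous
#' subsets (longest intersection wins, leftmost on ties) and the removed
#' members re-enter as their own (sub)groups. A final left-to-right pass
#' trims any residual overlap between cores of different groups and drops
#' cores shorter than `min_core`, so the output is always pairwise
#' non-overlapping.
#'
#' @param hits data.frame of hits of one TF on one promoter (`start`, `end`,
#'   0-based half-open; extra columns ignored).
#' @param min_frac grouping overlap fraction (of the shorter hit).
#' @param min_core minimum core length in nucleotides.
#' @return data.frame of cores: `start`, `end` (plus `tf`, `promoter` if
#'   present in `hits`).
#' @export
merge_core_motifs <- function(hits, min_frac = 0.8, min_core = 4L) {
  if (!nrow(hits)) return(data.frame(start = integer(), end = integer()))
  hits <- hits[order(hits$start, hits$end), , drop = FALSE]
  n <- nrow(hits)
  grp <- integer(n); grp[1] <- 1L
  if (n > 1) {
    for (i in 2:n) {
      ov <- min(hits$end[i - 1], hits$end[i]) -
        max(hits$start[i - 1], hits$start[i])
      shorter <- min(hits$end[i - 1] - hits$start[i - 1],
                     hits$end[i] - hits$start[i])
      grp[i] <- if (ov >= min_frac * shorter) grp[i - 1] else grp[i - 1] + 1L
    }
  }
  cores <- do.call(rbind, lapply(split(hits[, c("start", "end")], grp),
                                 extract_cores, min_core = min_core))
  if (is.null(cores) || !nrow(cores)) {
    return(data.frame(start = integer(), end = integer()))
  }
  cores <- cores[order(cores$start, cores$end), , drop = FALSE]
  # cross-group overlap trim (stands in for a manual-review step)
  keep <- logical(nrow(cores))
  last_end <- -Inf
  for (i in seq_len(nrow(cores))) {
    s <- max(cores$start[i], last_end)
    if (cores$end[i] - s >= min_core) {
      cores$start[i] <- s
      keep[i] <- TRUE
      last_end <- cores$end[i]
    }
  }
  cores <- cores[keep, , drop = FALSE]
  for (col in c("tf", "promoter")) {
    if (col %in% names(hits)) cores[[col]] <- hits[[col]][1]
  }
  rownames(cores) <- NULL
  cores
}

#' Detect co-binding core-motif pairs of two TFs on one promoter
#'
#' Two cores co-bind when their edge-to-edge gap is at most `max_gap`
#' nucleotides (overlapping cores have gap 0).
#'
#' @param cores_a,cores_b data.frames of core motifs (`start`, `end`) of the
#'   two TFs on the same promoter.
#' @param max_gap maximum gap in nucleotides.
#' @return data.frame of co-binding pairs: `start_a`, `end_a`, `start_b`,
#'   `end_b`, `gap`.
#' @export
pair_cobinding <- function(cores_a, cores_b, max_gap = 10L) {
  if (!nrow(cores_a) || !nrow(cores_b)) {
    return(data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer(),
                      gap = integer()))
  }
  idx <- expand.grid(i = seq_len(nrow(cores_a)), j = seq_len(nrow(cores_b)))
  gap <- pmax(0L, pmax(cores_a$start[idx$i], cores_b$start[idx$j]) -
                pmin(cores_a$end[idx$i], cores_b$end[idx$j]))
  keep <- gap <= max_gap
  data.frame(start_a = cores_a$start[idx$i][keep],
             end_a = cores_a$end[idx$i][keep],
             start_b = cores_b$start[idx$j][keep],
             end_b = cores_b$end[idx$j][keep],
             gap = gap[keep])
}

#' Consensus sequence of a PWM (per-position argmax base)
#'
#' @param pwm a `pwm` object.
#' @return character string of length k.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$matrix, 2, which.max)], collapse = "")
}
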