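# Amino-acid percent identity, homology-based TF-pair expansion, and Jaccard
# similarity of paralog partner-relationship profiles.

#' Percent amino-acid identity from a global pairwise alignment
#'
#' Needleman-Wunsch global alignment (affine gaps, BLOSUM62 by default via
#' Biostrings); identity is the number of identical aligned positions over
#' the alignment length (including gap columns) times 100, or over the
#' shorter sequence's length when `denominator = "shorter"`.
#'
#' @param seq_a,seq_b amino-acid sequences (character or `AAString`).
#' @param substitution_matrix name of the substitution matrix.
#' @param gap_opening,gap_extension affine gap penalties.
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return percent identity in `[0, 100]`.
#' @export
percent_identity <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                             gap_opening = 10, gap_extension = 0.5,
                             denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (!nzchar(seq_a) || !nzchar(seq_b)) stopf("sequences must be non-empty")
  valid <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
  if (!grepl(valid, seq_a) || !grepl(valid, seq_b)) {
    stopf("invalid amino-acid residues")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  denom <- switch(denominator,
                  alignment = length(p),
                  shorter = min(nchar(seq_a), nchar(seq_b)))
  100 * matches / denom
}

#' Pairwise percent-identity matrix for a set of TF sequences
#'
#' @param seqs named character vector or `AAStringSet` of TF sequences.
#' @param ... passed to [percent_identity()].
#' @return symmetric matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(seqs, ...) {
  if (methods::is(seqs, "AAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  n <- length(seqs)
  stopifnot(n >= 1, !is.null(names(seqs)))
  m <- diag(100, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- percent_identity(seqs[[i]], seqs[[j]], ...)
      }
    }
  }
  m
}

#' Expand known TF pairs by sequence homology
#'
#' For each known interacting pair (X, Y), every TF A highly similar to X
#' and every TF B highly similar to Y spawn candidate pairs (A, Y), (X, B)
#' and (A, B). "Highly similar" means percent identity at or above `cutoff`,
#' or, in percentile mode, at or above the given percentile of the
#' off-diagonal identity distribution. Pairs are unordered and deduplicated;
#' only `known`-provenance pairs act as seeds, so re-expanding the output
#' adds nothing.
#'
#' @param known_pairs data.frame with `tf1`, `tf2` (and optionally
#'   `provenance`; rows not marked `"known"` are kept but not expanded).
#' @param identities symmetric percent-identity matrix with TF dimnames
#'   covering all referenced TFs.
#' @param cutoff identity cutoff in percent (used when `percentile` is NULL).
#' @param percentile percentile (0-100, exclusive) of the off-diagonal
#'   upper-triangle identities from which to derive the cutoff.
#' @return data.frame `tf1`, `tf2`, `provenance` (`"known"` or
#'   `"homology"`), with the derived cutoff as attribute `"cutoff"`.
#' @export
homology_expand <- function(known_pairs, identities, cutoff = NULL,
                            percentile = NULL) {
  stopifnot(all(c("tf1", "tf2") %in% names(known_pairs)))
  tfs <- rownames(identities)
  refd <- unique(c(known_pairs$tf1, known_pairs$tf2))
  if (!all(refd %in% tfs)) stopf("identities must cover all referenced TFs")
  if (!is.null(percentile)) {
    if (percentile <= 0 || percentile >= 100) {
      stopf("percentile must be in (0, 100)")
    }
    offdiag <- identities[upper.tri(identities)]
    cutoff <- quantile(offdiag, percentile / 100, names = FALSE)
  }
  if (is.null(cutoff)) stopf("either cutoff or percentile is required")

  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  prov <- known_pairs$provenance %||% rep("known", nrow(known_pairs))
  seeds <- known_pairs[prov == "known", , drop = FALSE]
  out_tf1 <- known_pairs$tf1; out_tf2 <- known_pairs$tf2
  out_prov <- prov
  similar <- function(x) tfs[identities[x, ] >= cutoff & tfs != x]
  for (i in seq_len(nrow(seeds))) {
    x <- seeds$tf1[i]; y <- seeds$tf2[i]
    as_ <- similar(x); bs <- similar(y)
    new1 <- if (length(as_)) cbind(as_, y) else NULL
    new2 <- if (length(bs)) cbind(x, bs) else NULL
    new3 <- if (length(as_) && length(bs)) {
      g <- expand.grid(a = as_, b = bs, stringsAsFactors = FALSE)
      cbind(g$a, g$b)
    } else NULL
    new <- rbind(new1, new2, new3)
    if (!is.null(new)) {
      out_tf1 <- c(out_tf1, new[, 1]); out_tf2 <- c(out_tf2, new[, 2])
      out_prov <- c(out_prov, rep("homology", nrow(new)))
    }
  }
  k <- key(out_tf1, out_tf2)
  keep <- !duplicated(k) & out_tf1 != out_tf2
  # known provenance wins over homology for the same unordered pair
  ord <- order(out_prov != "known")
  k_ord <- k[ord]
  keep_ord <- !duplicated(k_ord) & out_tf1[ord] != out_tf2[ord]
  out <- data.frame(tf1 = out_tf1[ord][keep_ord],
                    tf2 = out_tf2[ord][keep_ord],
                    provenance = out_prov[ord][keep_ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Binary partner-relationship profile of a TF
#'
#' For an ordered list of shared partners, the profile is the vector
#' (P1_coop, P1_antag, P2_coop, P2_antag, ...): per partner, whether the TF
#' has at least one cooperative and at least one antagonistic event with it.
#'
#' @param events data.frame of called events with columns `tf`, `partner`,
#'   `event` (`"cooperative"` / `"antagonistic"`).
#' @param tf the TF whose profile to build.
#' @param partners ordered character vector of shared partners.
#' @return integer 0/1 vector of length `2 * length(partners)`.
#' @export
partner_profile <- function(events, tf, partners) {
  e <- events[events$tf == tf, , drop = FALSE]
  v <- integer(2 * length(partners))
  for (i in seq_along(partners)) {
    ep <- e[e$partner == partners[i], , drop = FALSE]
    v[2 * i - 1] <- as.integer(any(ep$event == "cooperative"))
    v[2 * i] <- as.integer(any(ep$event == "antagonistic"))
  }
  v
}

#' Jaccard index of two binary partner profiles
#'
#' Positions set in both vectors over positions set in either. Undefined
#' (NA) when neither vector has a set position.
#'
#' @param profile_a,profile_b 0/1 vectors over the identical partner
#'   ordering (equal length).
#' @return Jaccard index in `[0, 1]`, or NA when undefined.
#' @export
partner_jaccard <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) stopf("profile length mismatch")
  a <- as.logical(profile_a); b <- as.logical(profile_b)
  union_n <- sum(a | b)
  if (union_n == 0) return(NA_real_)
  sum(a & b) / union_n
}

#' Bin percent identity into low / medium / high
#'
#' Low: < 30%; medium: 30-50% (closed interval); high: > 50%.
#'
#' @param percent numeric vector in `[0, 100]`.
#' @return character vector of bins.
#' @export
identity_bins <- function(percent) {
  stopifnot(all(percent >= 0 & percent <= 100))
  ifelse(percent < 30, "low", ifelse(percent <= 50, "medium", "high"))
}
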