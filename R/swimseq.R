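# SWIM-seq strain confirmation: filter alignment records from barcoded-well
# amplicon sequencing and decide per-well and per-series confirmation.

#' Read a minimal subset of a SAM text file
#'
#' Parses QNAME, FLAG, RNAME, the read length (from SEQ), and the `AS:i:`
#' (alignment score), `NM:i:` (mismatches) and `RG:Z:` (well id) tags.
#' Demultiplexing and trimming are upstream; this reader consumes aligner
#' output only.
#'
#' @param path SAM file path.
#' @return data.frame: `qname`, `well`, `flag`, `target`, `primary`,
#'   `mapped`, `score`, `mismatches`, `read_length`.
#' @export
read_sam_minimal <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(qname = character(), well = character(),
                      flag = integer(), target = character(),
                      primary = logical(), mapped = logical(),
                      score = numeric(), mismatches = integer(),
                      read_length = integer(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag_value <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":"), f[-(1:11)], value = TRUE)
    if (length(hit)) sub(paste0("^", tag, ":[AifZHB]:"), "", hit[1])
    else NA_character_
  }
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  data.frame(
    qname = vapply(fields, `[`, character(1), 1),
    well = vapply(fields, tag_value, character(1), "RG"),
    flag = flag,
    target = vapply(fields, `[`, character(1), 3),
    primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    mapped = bitwAnd(flag, 0x4L) == 0L,
    score = as.numeric(vapply(fields, tag_value, character(1), "AS")),
    mismatches = as.integer(vapply(fields, tag_value, character(1), "NM")),
    read_length = vapply(fields, function(f) {
      if (f[10] == "*") NA_integer_ else nchar(f[10])
    }, integer(1)),
    stringsAsFactors = FALSE)
}

#' Filter alignment records for strain confirmation
#'
#' Keeps primary, mapped records whose alignment score is at least
#' `min_score_frac` of the trimmed read length and whose mismatch count is
#' strictly below `max_mismatch_frac` of the read length.
#'
#' @param records data.frame from [read_sam_minimal()].
#' @param min_score_frac minimum score as a fraction of read length.
#' @param max_mismatch_frac mismatch fraction bound (strict).
#' @return the surviving subset of `records`.
#' @export
filter_records <- function(records, min_score_frac = 0.9,
                           max_mismatch_frac = 0.05) {
  keep <- records$primary & records$mapped &
    !is.na(records$read_length) & !is.na(records$score) &
    !is.na(records$mismatches) &
    records$score >= min_score_frac * records$read_length &
    records$mismatches < max_mismatch_frac * records$read_length
  records[keep, , drop = FALSE]
}

#' Confirm the expected target(s) of one well
#'
#' Counts surviving reads per aligned target. An expected target is
#' confirmed when it has at least one read and strictly more reads than
#' every non-expected target (a tie with an unexpected target fails). The
#' well is confirmed when all expected targets are confirmed.
#'
#' @param records surviving records of one well ([filter_records()]).
#' @param expected character vector of expected target id(s).
#' @return list with `expected`, `counts` (named), `top_target`,
#'   `per_target` (named logical), `confirmed`.
#' @export
confirm_well <- function(records, expected) {
  stopifnot(length(expected) >= 1)
  counts <- table(records$target)
  cnt <- setNames(as.integer(counts), names(counts))
  get <- function(t) if (t %in% names(cnt)) cnt[[t]] else 0L
  other_max <- {
    others <- setdiff(names(cnt), expected)
    if (length(others)) max(cnt[others]) else 0L
  }
  per_target <- vapply(expected, function(t) {
    get(t) >= 1L && get(t) > other_max
  }, logical(1))
  top <- if (length(cnt)) names(cnt)[which.max(cnt)] else NA_character_
  list(expected = expected, counts = cnt, top_target = top,
       per_target = per_target, confirmed = all(per_target))
}

#' Confirm a TF-pair strain series from its three wells
#'
#' A TF-pair series is sequence-confirmed when both TFs are confirmed in the
#' TF1-TF2 well, TF1 and the empty AD2u vector are confirmed in the
#' TF1-empty well, and TF2 and the empty pGADT7 vector are confirmed in the
#' TF2-empty well (all six conditions).
#'
#' @param pair_well,tf1_well,tf2_well [confirm_well()] results for the
#'   TF1-TF2, TF1-empty and TF2-empty strains (pass `NULL` for a missing
#'   well).
#' @return list with `confirmed` and `reason` (`NA` when confirmed).
#' @export
confirm_series <- function(pair_well, tf1_well, tf2_well) {
  if (is.null(pair_well) || is.null(tf1_well) || is.null(tf2_well)) {
    return(list(confirmed = FALSE, reason = "missing_well"))
  }
  checks <- c(pair_well$per_target, tf1_well$per_target,
              tf2_well$per_target)
  if (length(checks) != 6L) {
    return(list(confirmed = FALSE, reason = "wrong_expected_targets"))
  }
  if (all(checks)) list(confirmed = TRUE, reason = NA_character_)
  else list(confirmed = FALSE, reason = "target_mismatch")
}
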