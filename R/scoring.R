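# Reporter signal scores and cooperativity/antagonism indices.
#
# Per colony the raw quantity is (I - I_min) * A, where I is the
# background-removed mean intensity, I_min the minimum non-zero colony
# intensity on the plate, and A the colony area. A strain's reporter signal
# RS is the quadruplicate aggregate of that quantity minus the plate's
# empty-empty baseline.

#' Plate-level normalization context
#'
#' Computes `I_min` (minimum intensity over colonies with `A > 0`) and the
#' empty-empty baseline (mean of per-colony `(I - I_min) * A` over all
#' empty-empty colonies on the plate).
#'
#' @param measurements data.frame from [quantify_plate()] (needs `A`, `I`,
#'   `class`).
#' @return object of class `plate_context`: list with `I_min`,
#'   `empty_baseline`, `n_empty_colonies`.
#' @export
plate_context <- function(measurements) {
  m <- measurements[measurements$A > 0 & !is.na(measurements$I), , drop = FALSE]
  if (!nrow(m)) stopf("no measurable colonies on plate")
  I_min <- min(m$I)
  emp <- m[!is.na(m$class) & m$class == "empty-empty", , drop = FALSE]
  if (!nrow(emp)) stopf("no_baseline")
  v_emp <- (emp$I - I_min) * emp$A
  structure(list(I_min = I_min,
                 empty_baseline = mean(v_emp),
                 empty_mad = mad(v_emp),
                 n_empty_colonies = nrow(emp)),
            class = "plate_context")
}

#' Reporter signal score of one strain quartet
#'
#' Per unflagged colony the value `(I - I_min) * A` is computed; the quartet
#' is aggregated (median by default, mean optionally) and the plate's
#' empty-empty baseline subtracted.
#'
#' @param quartet data.frame of the strain's colony measurements (up to 4
#'   rows; `A`, `I`, `missing`).
#' @param ctx a [plate_context()].
#' @param aggregate `"median"` (robust default) or `"mean"`.
#' @return list with `RS` (NA if no usable colony), `n_colonies`, `cv`
#'   (coefficient of variation of per-colony values), `status` (`"ok"` or
#'   `"inconclusive"`), `aggregate`.
#' @export
reporter_signal <- function(quartet, ctx, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(ctx, "plate_context"))
  ok <- !quartet$missing & quartet$A > 0 & !is.na(quartet$I)
  v <- (quartet$I[ok] - ctx$I_min) * quartet$A[ok]
  if (!length(v)) {
    return(list(RS = NA_real_, n_colonies = 0L, cv = NA_real_,
                status = "inconclusive", aggregate = aggregate))
  }
  agg <- if (aggregate == "median") median(v) else mean(v)
  # CV denominator floored so that colony spread within measurement noise
  # (sd below ~4 empty-colony MADs) never reads as non-uniform: baseline
  # strains have means near zero, where a plain CV is meaningless
  cv_floor <- max(abs(ctx$empty_baseline), 8 * (ctx$empty_mad %||% 0),
                  .Machine$double.eps)
  cv <- if (length(v) > 1) sd(v) / max(abs(mean(v)), cv_floor) else NA_real_
  list(RS = agg - ctx$empty_baseline, n_colonies = length(v), cv = cv,
       status = "ok", aggregate = aggregate)
}

#' Cooperativity and antagonism indices
#'
#' Exact differences of reporter signals: the cooperativity index is
#' `RS_pair - RS_TF1 - RS_TF2`; antagonism index 1 is `RS_TF1 - RS_pair`;
#' antagonism index 2 is `RS_TF2 - RS_pair`.
#'
#' @param rs_pair,rs_tf1,rs_tf2 finite reporter signal scores.
#' @return list with `cooperativity`, `antagonism1`, `antagonism2`.
#' @export
interaction_indices <- function(rs_pair, rs_tf1, rs_tf2) {
  stopifnot(is.finite(rs_pair), is.finite(rs_tf1), is.finite(rs_tf2))
  list(cooperativity = rs_pair - rs_tf1 - rs_tf2,
       antagonism1 = rs_tf1 - rs_pair,
       antagonism2 = rs_tf2 - rs_pair)
}

#' Score every strain on a plate
#'
#' Computes the plate context and one reporter signal per strain
#' (quadruplicate aggregation), returning a per-strain table.
#'
#' @param measurements data.frame from [quantify_plate()] with `strain` and
#'   `class` columns.
#' @param aggregate passed to [reporter_signal()].
#' @return data.frame: `strain`, `class`, `RS`, `n_colonies`, `cv`, `status`.
#' @export
score_plate <- function(measurements, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  ctx <- plate_context(measurements)
  strains <- unique(measurements$strain[!is.na(measurements$strain)])
  rows <- lapply(strains, function(s) {
    q <- measurements[!is.na(measurements$strain) &
                        measurements$strain == s, , drop = FALSE]
    rs <- reporter_signal(q, ctx, aggregate = aggregate)
    data.frame(strain = s, class = q$class[1], RS = rs$RS,
               n_colonies = rs$n_colonies, cv = rs$cv, status = rs$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "context") <- ctx
  out
}
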