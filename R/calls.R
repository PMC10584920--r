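# QC and event calling: quantize reporter activity relative to the plate's
# empty-empty distribution, apply the calling criteria, and classify binding
# modality under the 1-AD and 2-AD designs.

ACTIVITY_LEVELS <- c("none", "very_weak", "weak", "moderate", "strong")
EVENT_TYPES <- c("cooperative", "antagonistic_TF1", "antagonistic_TF2",
                 "antagonistic_mutual", "independent", "none", "inconclusive")
MODALITIES_1AD <- c("mutual_cooperativity", "recruitment_TF1_recruits_TF2",
                    "recruitment_TF2_recruits_TF1", "sequestration_of_TF1",
                    "sequestration_of_TF2", "competition", "independent",
                    "unclassified")

#' Quantize reporter signal into qualitative activity levels
#'
#' Computes a robust z-score of the strain's reporter signal against the
#' plate's empty-empty RS distribution (`z = (RS - median) / MAD`) and bins
#' it: `z < 2` very weak, `2 <= z < 4` weak, `4 <= z < 8` moderate, `z >= 8`
#' strong (bins configurable).
#'
#' @param rs numeric vector of reporter signals.
#' @param empty_rs reporter signals of the plate's empty-empty strains
#'   (length >= 3).
#' @param thresholds increasing z cutpoints for weak/moderate/strong.
#' @return character vector of levels, with the z-scores as attribute `"z"`.
#' @export
classify_activity <- function(rs, empty_rs, thresholds = c(2, 4, 8)) {
  if (length(empty_rs) < 3) stopf("need >= 3 empty-empty RS values")
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  ctr <- median(empty_rs)
  scale <- mad(empty_rs)
  if (scale == 0) {
    warnf("degenerate empty-empty distribution (MAD = 0); using epsilon scale")
    scale <- 1e-8 * max(1, abs(ctr))
  }
  z <- (rs - ctr) / scale
  lev <- cut(z, breaks = c(-Inf, thresholds, Inf),
             labels = c("very_weak", "weak", "moderate", "strong"),
             right = FALSE)
  out <- as.character(lev)
  attr(out, "z") <- z
  out
}

#' Quality-control a strain series
#'
#' A series is inconclusive if any of its strains lacks growth on the mating
#' selection plate, has fewer than `min_uniform` uniform quadruplicate
#' colonies (a colony quartet is uniform when >= `min_uniform` colonies were
#' detected and their per-colony value CV is <= `max_cv`), failed sequence
#' confirmation, or was contaminated.
#'
#' @param series data.frame with one row per strain: `growth` (logical),
#'   `n_colonies`, `cv`, and optionally `contaminated`, `seq_confirmed`.
#' @param min_uniform minimum uniform colonies out of 4.
#' @param max_cv maximum coefficient of variation among detected colonies.
#' @return list with `status` (`"pass"` or `"inconclusive"`) and `reason`.
#' @export
qc_series <- function(series, min_uniform = 3L, max_cv = 0.5) {
  if (!all(series$growth %||% TRUE)) {
    return(list(status = "inconclusive", reason = "no_growth"))
  }
  if (!is.null(series$contaminated) && any(series$contaminated)) {
    return(list(status = "inconclusive", reason = "contaminated"))
  }
  if (!is.null(series$seq_confirmed) && !all(series$seq_confirmed)) {
    return(list(status = "inconclusive", reason = "not_sequence_confirmed"))
  }
  non_uniform <- series$n_colonies < min_uniform |
    (!is.na(series$cv) & series$cv > max_cv)
  if (any(non_uniform)) {
    return(list(status = "inconclusive", reason = "non_uniform"))
  }
  list(status = "pass", reason = NA_character_)
}

#' Call the event type from a series' activity levels
#'
#' Cooperative: the TF-pair strain shows strong or moderate activity while
#' both single-TF strains show at most weak activity. Antagonistic: a
#' single-TF strain shows strong or moderate activity while the TF-pair
#' strain shows at most weak activity (mutual if both singles are active).
#' Independent: pair and at least one single active. None: nothing active.
#' The mapping is total over activity-level triples.
#'
#' @param pair,tf1,tf2 activity levels (values of `ACTIVITY_LEVELS`).
#' @return one of `"cooperative"`, `"antagonistic_TF1"`,
#'   `"antagonistic_TF2"`, `"antagonistic_mutual"`, `"independent"`,
#'   `"none"`.
#' @export
call_event <- function(pair, tf1, tf2) {
  stopifnot(all(c(pair, tf1, tf2) %in% ACTIVITY_LEVELS))
  active <- function(l) l %in% c("moderate", "strong")
  if (active(pair)) {
    if (!active(tf1) && !active(tf2)) return("cooperative")
    return("independent")
  }
  if (active(tf1) && active(tf2)) return("antagonistic_mutual")
  if (active(tf1)) return("antagonistic_TF1")
  if (active(tf2)) return("antagonistic_TF2")
  "none"
}

#' Classify the binding modality under the 1-AD design
#'
#' Truth-table lookup on the activity pattern of the four strains of a
#' reciprocal-orientation series: (TF1-AD alone, TF1-AD + TF2, TF2-AD alone,
#' TF2-AD + TF1), each active (`TRUE`) or inactive (`FALSE`).
#'
#' @param tf1_ad_alone,tf1_ad_pair,tf2_ad_alone,tf2_ad_pair logical activity
#'   of the four strains; any `NA` (missing orientation) yields
#'   `"unclassified"` with a warning.
#' @return one of the 1-AD modality labels.
#' @export
classify_modality_1ad <- function(tf1_ad_alone, tf1_ad_pair,
                                  tf2_ad_alone, tf2_ad_pair) {
  pat <- c(tf1_ad_alone, tf1_ad_pair, tf2_ad_alone, tf2_ad_pair)
  if (anyNA(pat)) {
    warnf("one orientation missing; modality unclassified")
    return("unclassified")
  }
  key <- paste(as.integer(pat), collapse = "")
  switch(key,
         "0101" = "mutual_cooperativity",
         "1101" = "recruitment_TF1_recruits_TF2",
         "0111" = "recruitment_TF2_recruits_TF1",
         "1000" = "sequestration_of_TF1",
         "0010" = "sequestration_of_TF2",
         "1011" = "competition",  # TF2 outcompetes TF1
         "1110" = "competition",  # TF1 outcompetes TF2
         "1111" = "independent",
         "unclassified")
}

#' Classify the binding modality under the 2-AD design
#'
#' The 2-AD design can only detect mutual cooperativity and sequestration;
#' independent binding is indistinguishable from recruitment or competition.
#'
#' @param event event type from [call_event()].
#' @return `"mutual_cooperativity"`, `"sequestration"`, or
#'   `"indistinguishable"`.
#' @export
classify_modality_2ad <- function(event) {
  if (event == "cooperative") return("mutual_cooperativity")
  if (event %in% c("antagonistic_TF1", "antagonistic_TF2",
                   "antagonistic_mutual")) {
    return("sequestration")
  }
  "indistinguishable"
}

# Map a 1-AD activity pattern to the event vocabulary.
event_from_modality_1ad <- function(modality, pattern) {
  if (all(!pattern)) return("none")
  switch(modality,
         "mutual_cooperativity" = "cooperative",
         "recruitment_TF1_recruits_TF2" = "cooperative",
         "recruitment_TF2_recruits_TF1" = "cooperative",
         "sequestration_of_TF1" = "antagonistic_TF1",
         "sequestration_of_TF2" = "antagonistic_TF2",
         # competition: the orientation whose pair strain lost activity is
         # the outcompeted (antagonized) TF
         "competition" = if (!pattern[2]) "antagonistic_TF1"
                         else "antagonistic_TF2",
         "independent" = "independent",
         "inconclusive")
}

#' Call all events of a screen from per-strain scores
#'
#' Joins the per-strain reporter signals with the strain metadata, quantizes
#' activity against the plate's empty-empty strains, applies QC, and calls
#' one event per (bait, pair) series, with modality.
#'
#' @param scores data.frame from [score_plate()] (per strain: `RS`,
#'   `n_colonies`, `cv`, `status`).
#' @param strains data.frame with `strain`, `bait`, `pair`, `role` (2-AD:
#'   `pair`/`tf1`/`tf2`; 1-AD: `o1_pair`/`o1_single`/`o2_pair`/`o2_single`),
#'   `class`; optionally `growth`, `contaminated`, `seq_confirmed`.
#' @param design `"2-AD"` or `"1-AD"`.
#' @param thresholds passed to [classify_activity()].
#' @param min_uniform,max_cv passed to [qc_series()].
#' @return data.frame with one row per (bait, pair): `bait`, `pair`,
#'   `event`, `modality`, `qc`, `qc_reason`, and the supporting activity
#'   levels.
#' @export
call_screen <- function(scores, strains, design = c("2-AD", "1-AD"),
                        thresholds = c(2, 4, 8), min_uniform = 3L,
                        max_cv = 0.5) {
  design <- match.arg(design)
  tab <- merge(strains, scores[, setdiff(names(scores), "class")],
               by = "strain", all.x = TRUE)
  empty_rs <- tab$RS[tab$class == "empty-empty" & !is.na(tab$RS)]
  series_keys <- unique(tab[!is.na(tab$pair), c("bait", "pair")])
  rows <- lapply(seq_len(nrow(series_keys)), function(i) {
    s <- tab[!is.na(tab$pair) & tab$bait == series_keys$bait[i] &
               tab$pair == series_keys$pair[i], , drop = FALSE]
    s$growth <- s$growth %||% rep(TRUE, nrow(s))
    qc <- qc_series(s, min_uniform = min_uniform, max_cv = max_cv)
    base <- data.frame(bait = series_keys$bait[i], pair = series_keys$pair[i],
                       stringsAsFactors = FALSE)
    if (qc$status != "pass" || anyNA(s$RS)) {
      reason <- if (qc$status != "pass") qc$reason else "missing_strain"
      return(cbind(base, data.frame(event = "inconclusive",
                                    modality = NA_character_, qc = "inconclusive",
                                    qc_reason = reason,
                                    level_pair = NA, level_tf1 = NA,
                                    level_tf2 = NA, stringsAsFactors = FALSE)))
    }
    lev <- setNames(classify_activity(s$RS, empty_rs, thresholds), s$role)
    if (design == "2-AD") {
      event <- call_event(lev[["pair"]], lev[["tf1"]], lev[["tf2"]])
      modality <- classify_modality_2ad(event)
      cbind(base, data.frame(event = event, modality = modality, qc = "pass",
                             qc_reason = NA_character_,
                             level_pair = lev[["pair"]],
                             level_tf1 = lev[["tf1"]],
                             level_tf2 = lev[["tf2"]],
                             stringsAsFactors = FALSE))
    } else {
      need <- c("o1_single", "o1_pair", "o2_single", "o2_pair")
      pattern <- lev[need] %in% c("moderate", "strong")
      modality <- classify_modality_1ad(pattern[1], pattern[2],
                                        pattern[3], pattern[4])
      event <- event_from_modality_1ad(modality, pattern)
      cbind(base, data.frame(event = event, modality = modality, qc = "pass",
                             qc_reason = NA_character_,
                             level_pair = lev[["o1_pair"]],
                             level_tf1 = lev[["o1_single"]],
                             level_tf2 = lev[["o2_single"]],
                             stringsAsFactors = FALSE))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
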