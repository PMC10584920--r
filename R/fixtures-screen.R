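# Synthetic screen generator: plants cooperative / antagonistic / independent
# events for (DNA-bait, TF-pair) combinations and emits one plate_truth per
# bait plus the expected interaction calls.

SCREEN_EVENTS <- c("obligate-cooperative", "enhanced-cooperative",
                   "TF1-antagonized", "TF2-antagonized",
                   "independent", "none")

#' Ground-truth description of a synthetic pY1H screen
#'
#' @param events data.frame with columns `bait`, `pair`, `event`; exactly one
#'   row per (bait, pair); `event` one of `"obligate-cooperative"`,
#'   `"enhanced-cooperative"`, `"TF1-antagonized"`, `"TF2-antagonized"`,
#'   `"independent"`, `"none"`.
#' @param design `"2-AD"` (both TFs carry the activation domain; one strain
#'   per pair) or `"1-AD"` (reciprocal AD orientations, two sub-series).
#' @return object of class `screen_truth`.
#' @export
screen_truth <- function(events, design = c("2-AD", "1-AD")) {
  design <- match.arg(design)
  stopifnot(all(c("bait", "pair", "event") %in% names(events)))
  bad <- setdiff(unique(events$event), SCREEN_EVENTS)
  if (length(bad)) stopf("unknown event type: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(events[c("bait", "pair")])) {
    stopf("each (bait, pair) must have exactly one planted event")
  }
  structure(list(events = events, design = design), class = "screen_truth")
}

# Map a planted event to the expected call vocabulary of the calls module.
expected_event_call <- function(event) {
  c("obligate-cooperative" = "cooperative",
    "enhanced-cooperative" = "cooperative",
    "TF1-antagonized" = "antagonistic_TF1",
    "TF2-antagonized" = "antagonistic_TF2",
    "independent" = "independent",
    "none" = "none")[event]
}

# Activity class ("baseline", "weak", "strong") per strain role for an event.
# 2-AD roles: pair, tf1, tf2. "weak" is only used by enhanced-cooperative
# singles (enhanced binding: some activity alone, much stronger together).
event_activity_2ad <- function(event) {
  switch(event,
    "obligate-cooperative" = c(pair = "strong", tf1 = "baseline", tf2 = "baseline"),
    "enhanced-cooperative" = c(pair = "strong", tf1 = "weak", tf2 = "weak"),
    "TF1-antagonized"      = c(pair = "baseline", tf1 = "strong", tf2 = "baseline"),
    "TF2-antagonized"      = c(pair = "baseline", tf1 = "baseline", tf2 = "strong"),
    "independent"          = c(pair = "strong", tf1 = "strong", tf2 = "strong"),
    "none"                 = c(pair = "baseline", tf1 = "baseline", tf2 = "baseline"),
    stopf("unknown event type: %s", event))
}

# 1-AD roles: o1_single (TF1-AD alone), o1_pair (TF1-AD + TF2),
#             o2_single (TF2-AD alone), o2_pair (TF2-AD + TF1).
event_activity_1ad <- function(event) {
  act <- function(a1, p1, a2, p2) {
    c(o1_single = a1, o1_pair = p1, o2_single = a2, o2_pair = p2)
  }
  switch(event,
    "obligate-cooperative" = act("baseline", "strong", "baseline", "strong"),
    "enhanced-cooperative" = act("weak", "strong", "weak", "strong"),
    "TF1-antagonized"      = act("strong", "baseline", "baseline", "baseline"),
    "TF2-antagonized"      = act("baseline", "baseline", "strong", "baseline"),
    "independent"          = act("strong", "strong", "strong", "strong"),
    "none"                 = act("baseline", "baseline", "baseline", "baseline"),
    stopf("unknown event type: %s", event))
}

#' Generate plate images and expected calls for a planted screen
#'
#' Every (bait, pair) event is expanded into its strain series (pair strain
#' plus single-TF controls for 2-AD; reciprocal AD-orientation sub-series for
#' 1-AD) and laid out on one plate per bait together with empty-empty control
#' strains spread across the plate. Planted colony amplitudes follow the
#' event semantics: `strong` for active strains, `baseline` for inactive
#' strains (empty-empty level), `weak` for the singles of
#' enhanced-cooperative events. Per-colony amplitudes get lognormal
#' colony-to-colony jitter.
#'
#' @param truth a [screen_truth()] object.
#' @param seed integer seed.
#' @param n_empty number of empty-empty control strains per plate.
#' @param amp named list of planted amplitudes: `baseline`, `weak`, `strong`.
#' @param colony_cv lognormal sdlog of per-colony amplitude jitter.
#' @param ... further arguments passed to [plate_truth()] (noise levels,
#'   geometry).
#' @return list with `plates` (named list of `plate_truth`, one per bait),
#'   `strains` (data.frame: `strain`, `bait`, `pair`, `role`, `class`,
#'   `orientation`), and `expected` (data.frame: `bait`, `pair`, `event`,
#'   `expected_call`).
#' @export
gen_screen <- function(truth, seed = 1L, n_empty = 84L,
                       amp = list(baseline = 0.05, weak = 0.056, strong = 0.85),
                       colony_cv = 0.05, ...) {
  stopifnot(inherits(truth, "screen_truth"))
  ev <- truth$events
  design <- truth$design
  roles <- if (design == "2-AD") {
    data.frame(role = c("pair", "tf1", "tf2"),
               class = c("TF-pair", "TF1-empty", "empty-TF2"),
               orientation = NA_character_, stringsAsFactors = FALSE)
  } else {
    data.frame(role = c("o1_pair", "o1_single", "o2_pair", "o2_single"),
               class = c("TF-pair", "TF1-empty", "TF-pair", "empty-TF2"),
               orientation = c("TF1-AD", "TF1-AD", "TF2-AD", "TF2-AD"),
               stringsAsFactors = FALSE)
  }
  n_roles <- nrow(roles)

  plates <- list()
  strains_all <- list()
  for (b in unique(ev$bait)) {
    evb <- ev[ev$bait == b, , drop = FALSE]
    n_strains <- nrow(evb) * n_roles + n_empty
    n_blocks <- (PLATE_ROWS / 2L) * (PLATE_COLS / 2L)
    if (n_strains > n_blocks) {
      stopf("bait %s needs %d strain blocks; plate holds %d",
            b, n_strains, n_blocks)
    }
    strain_df <- do.call(rbind, lapply(seq_len(nrow(evb)), function(i) {
      data.frame(strain = paste(evb$pair[i], roles$role, sep = ":"),
                 bait = b, pair = evb$pair[i], role = roles$role,
                 class = roles$class, orientation = roles$orientation,
                 event = evb$event[i], stringsAsFactors = FALSE)
    }))
    empty_df <- data.frame(strain = sprintf("empty:%02d", seq_len(n_empty)),
                           bait = b, pair = NA_character_, role = "empty",
                           class = "empty-empty", orientation = NA_character_,
                           event = NA_character_, stringsAsFactors = FALSE)
    # spread empties evenly across the occupied blocks
    empty_slots <- unique(round(seq(1, n_strains, length.out = n_empty)))
    while (length(empty_slots) < n_empty) {
      empty_slots <- union(empty_slots,
                           setdiff(seq_len(n_strains), empty_slots)[1])
    }
    all_df <- data.frame(matrix(nrow = n_strains, ncol = 0))
    order_idx <- integer(n_strains)
    order_idx[empty_slots] <- seq_len(n_empty)
    order_idx[setdiff(seq_len(n_strains), empty_slots)] <-
      n_empty + seq_len(nrow(strain_df))
    all_df <- rbind(empty_df, strain_df)[order_idx, , drop = FALSE]

    # spread strain blocks across the whole plate so sparse screens still
    # occupy every grid row/column region (as pinned arrays do)
    layout <- plate_layout(all_df$strain, all_df$class,
                           block_index = round(seq(1, n_blocks,
                                                   length.out = n_strains)))
    amp_class <- vapply(seq_len(nrow(all_df)), function(i) {
      if (all_df$role[i] == "empty") return("baseline")
      acts <- if (design == "2-AD") event_activity_2ad(all_df$event[i])
              else event_activity_1ad(all_df$event[i])
      unname(acts[all_df$role[i]])
    }, character(1))
    strain_amp <- unlist(amp[amp_class], use.names = FALSE)
    pos_amp <- strain_amp[match(layout$strain, all_df$strain)]
    plate_seed <- with_seed(seed, sample.int(.Machine$integer.max, 1L))
    pos_amp_jit <- with_seed(plate_seed, {
      pos_amp * exp(rnorm(length(pos_amp), 0, colony_cv))
    })
    pos_amp_jit[is.na(pos_amp_jit)] <- 0
    plates[[b]] <- plate_truth(layout, amplitude = pos_amp_jit,
                               seed = plate_seed, ...)
    strains_all[[b]] <- all_df
    seed <- seed + 1L  # distinct plate seeds, still fully determined
  }

  strains <- do.call(rbind, strains_all)
  rownames(strains) <- NULL
  expected <- data.frame(bait = ev$bait, pair = ev$pair, event = ev$event,
                         expected_call = unname(expected_event_call(ev$event)),
                         stringsAsFactors = FALSE)
  list(plates = plates,
       strains = strains[, c("strain", "bait", "pair", "role", "class",
                             "orientation")],
       expected = expected)
}
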