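# V-structures and patient timelines: the v-glyph groups a temporal anchor
# (TAP) with a left Problem wing, a right Action wing and attached Visit
# items; a timeline is the ordered sequence of v-structures for one patient.

#' Construct a v-structure
#'
#' One v-shaped glyph: a temporal anchor with the Problem events that
#' explain a hospital encounter on its left wing, the Actions taken on the
#' right wing, and administrative Visit items attached. Within a wing,
#' events are grouped by semantic type with groups (and events inside each
#' group) kept in appearance order — no internal order or temporal gap is
#' invented beyond what the source states.
#'
#' @param structure_id Identifier, unique within the timeline.
#' @param tap A `temporal_anchor` (see [parse_tap()]).
#' @param problems,actions,visits Lists of [clinical_event()]s.
#' @param visit_only Structures carrying only Visit items (e.g. an
#'   admission opening a record) are exempt from the nonempty-wing rule.
#' @return A `v_structure`.
#' @export
v_structure <- function(structure_id, tap, problems = list(),
                        actions = list(), visits = list(),
                        visit_only = FALSE) {
  structure(list(structure_id = structure_id, tap = tap,
                 problems = group_wing_by_type(problems),
                 actions = group_wing_by_type(actions),
                 visits = visits, visit_only = isTRUE(visit_only)),
            class = "v_structure")
}

# Stable regrouping: semantic-type groups in order of each type's first
# appearance; events inside a group in appearance order.
group_wing_by_type <- function(events) {
  if (length(events) <= 1L) return(events)
  idx <- order(vapply(events, `[[`, 0L, "appearance_index"))
  events <- events[idx]
  tags <- vapply(events, `[[`, "", "semantic_type")
  events[order(match(tags, unique(tags)))]
}

structure_events <- function(v) c(v$problems, v$actions, v$visits)

#' @export
print.v_structure <- function(x, ...) {
  fmt <- function(evs) paste(vapply(evs, function(e)
    sprintf("%s:%s", e$semantic_type, e$text), ""), collapse = "; ")
  cat(sprintf("<v %s> TAP \"%s\"\n", x$structure_id, x$tap$raw_text))
  if (length(x$problems)) cat("  P: ", fmt(x$problems), "\n", sep = "")
  if (length(x$actions))  cat("  A: ", fmt(x$actions), "\n", sep = "")
  if (length(x$visits))   cat("  V: ", fmt(x$visits), "\n", sep = "")
  invisible(x)
}

#' Construct a patient timeline
#'
#' @param patient_id Identifier.
#' @param structures Ordered list of [v_structure()]s, chronological where
#'   TAP intervals decide and in appearance order otherwise.
#' @param anchor_date Optional date used to resolve relative temporal
#'   expressions (e.g. the admission or dictation date).
#' @param cross_links Data frame of Problem-to-Action links that span
#'   structures (columns `problem_id`, `action_id`), as recorded by
#'   [link_problem_to_later_action()].
#' @return A `patient_timeline`.
#' @export
patient_timeline <- function(patient_id, structures = list(),
                             anchor_date = NULL,
                             cross_links = empty_cross_links()) {
  structure(list(patient_id = patient_id, structures = structures,
                 anchor_date = anchor_date, cross_links = cross_links),
            class = "patient_timeline")
}

empty_cross_links <- function() {
  data.frame(problem_id = character(0), action_id = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("<timeline %s> %d structure(s)\n", x$patient_id,
              length(x$structures)))
  for (v in x$structures) print(v)
  invisible(x)
}

#' Validate a patient timeline
#'
#' Checks every event, wing-position permissions against the taxonomy, the
#' nonempty-wing rule, appearance-index uniqueness, and that causal links
#' stay within the patient.
#'
#' @param timeline A [patient_timeline()].
#' @return Character vector of violations; empty when valid.
#' @export
validate_timeline <- function(timeline) {
  v <- character(0)
  all_ids <- character(0)
  all_idx <- integer(0)
  for (s in timeline$structures) {
    if (!s$visit_only && length(s$problems) + length(s$actions) == 0L) {
      v <- c(v, sprintf("%s: both wings empty", s$structure_id))
    }
    for (pos in c("Problem", "Action", "Visit")) {
      wing <- switch(pos, Problem = s$problems, Action = s$actions,
                     Visit = s$visits)
      for (e in wing) {
        ve <- validate_event(e)
        if (length(ve)) v <- c(v, paste0(s$structure_id, "/", ve))
        if (e$semantic_type %in% semantic_tags() &&
            !(pos %in% allowed_positions(e$semantic_type))) {
          v <- c(v, sprintf("%s/%s: tag %s not permitted on %s position",
                            s$structure_id, e$event_id, e$semantic_type, pos))
        }
        all_ids <- c(all_ids, e$event_id)
        all_idx <- c(all_idx, e$appearance_index)
      }
    }
  }
  if (anyDuplicated(all_ids)) {
    v <- c(v, sprintf("duplicate event_id: %s",
                      paste(unique(all_ids[duplicated(all_ids)]),
                            collapse = ", ")))
  }
  if (anyDuplicated(all_idx)) {
    v <- c(v, "appearance_index values are not unique within the patient")
  }
  for (s in timeline$structures) {
    for (e in structure_events(s)) {
      bad <- setdiff(e$causal_links, all_ids)
      if (length(bad)) {
        v <- c(v, sprintf("%s: causal link to unknown event(s) %s",
                          e$event_id, paste(bad, collapse = ", ")))
      }
    }
  }
  v
}

# Map event_id -> index of the structure containing it.
event_structure_map <- function(timeline) {
  out <- integer(0)
  for (i in seq_along(timeline$structures)) {
    ids <- vapply(structure_events(timeline$structures[[i]]), `[[`, "",
                  "event_id")
    out[ids] <- i
  }
  out
}

# All causal links of a timeline as a data.frame(from, to, from_structure,
# to_structure): event-level links plus recorded cross-structure links.
timeline_links <- function(timeline) {
  smap <- event_structure_map(timeline)
  from <- character(0); to <- character(0)
  for (s in timeline$structures) {
    for (e in structure_events(s)) {
      if (length(e$causal_links)) {
        from <- c(from, rep(e$event_id, length(e$causal_links)))
        to <- c(to, e$causal_links)
      }
    }
  }
  cl <- timeline$cross_links
  if (nrow(cl)) { from <- c(from, cl$problem_id); to <- c(to, cl$action_id) }
  keep <- to %in% names(smap) & from %in% names(smap)
  data.frame(from = from[keep], to = to[keep],
             from_structure = unname(smap[from[keep]]),
             to_structure = unname(smap[to[keep]]),
             stringsAsFactors = FALSE)
}

#' Extract context blocks from a timeline
#'
#' A context block is a maximal run of consecutive v-structures bound
#' together by evidence of shared context: a causal link crossing between
#' two neighbouring structures, or neighbouring structures carrying the
#' identical verbatim temporal expression (the multiple-cause case where
#' one expression is split into several v's). Successive causally related
#' events thus group into the unit used for pattern recognition; structures
#' with no such ties form singleton blocks.
#'
#' @param timeline A validated [patient_timeline()].
#' @return Ordered list of `context_block` objects partitioning the
#'   timeline: fields `block_id`, `structure_ids`, `structure_index`, and
#'   `link_evidence` (the links that bind the block).
#' @export
extract_context_blocks <- function(timeline) {
  n <- length(timeline$structures)
  if (n == 0L) return(list())
  links <- timeline_links(timeline)
  raw <- vapply(timeline$structures, function(s) s$tap$raw_text, "")
  bound <- logical(max(n - 1L, 0L))  # bound[i]: structures i and i+1 joined
  for (i in seq_len(n - 1L)) {
    spans <- (links$from_structure == i & links$to_structure == i + 1L) |
             (links$from_structure == i + 1L & links$to_structure == i)
    shared_tap <- nzchar(raw[i]) && identical(raw[i], raw[i + 1L])
    bound[i] <- any(spans) || shared_tap
  }
  run_id <- cumsum(c(1L, as.integer(!bound)))
  blocks <- list()
  for (b in unique(run_id)) {
    idx <- which(run_id == b)
    ev <- links[links$from_structure %in% idx & links$to_structure %in% idx &
                  links$from_structure != links$to_structure, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- structure(list(
      block_id = sprintf("%s-b%d", timeline$patient_id, length(blocks) + 1L),
      structure_ids = vapply(timeline$structures[idx], `[[`, "",
                             "structure_id"),
      structure_index = idx,
      link_evidence = ev), class = "context_block")
  }
  blocks
}

#' @export
print.context_block <- function(x, ...) {
  cat(sprintf("<block %s> structures: %s\n", x$block_id,
              paste(x$structure_ids, collapse = " -> ")))
  invisible(x)
}
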