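#' Construct a clinical event record
#'
#' One pre-annotated narrative event: its original text, a semantic tag
#' from [taxonomy()], the verbatim temporal expression accompanying it
#' (possibly empty), its order of appearance in the source document, and
#' any explicitly stated causal links from this event to events it caused
#' (Problem-to-Action direction, as in "due to cervix cancer, concurrent
#' chemo RT was done").
#'
#' @param event_id Opaque identifier, unique within the patient.
#' @param text The original event expression, e.g. `"NTR of tm."`.
#' @param semantic_type One of the 14 tags in [semantic_tags()].
#' @param raw_time Verbatim temporal expression string; `""` when the
#'   source gives none. Never normalized here: the verbatim string is what
#'   the timeline displays.
#' @param appearance_index Non-negative integer; order in the source
#'   document, unique per patient.
#' @param causal_links Character vector of event ids this event is a stated
#'   cause of.
#' @return An object of class `clinical_event`.
#' @export
clinical_event <- function(event_id, text, semantic_type, raw_time = "",
                           appearance_index = 0L,
                           causal_links = character(0)) {
  stopifnot(is.character(event_id), length(event_id) == 1L)
  ev <- structure(list(
    event_id = event_id,
    text = as.character(text),
    semantic_type = as.character(semantic_type),
    raw_time = if (length(raw_time) == 0L || is.na(raw_time)) "" else as.character(raw_time),
    appearance_index = as.integer(appearance_index),
    causal_links = as.character(causal_links)
  ), class = "clinical_event")
  ev
}

#' Validate a clinical event
#'
#' Checks the event against the taxonomy and field invariants. Violations
#' are returned, never raised, so callers can collect a full report.
#'
#' @param event A [clinical_event()].
#' @return Character vector of violations, each naming the offending field
#'   and rule; empty when the event is valid.
#' @examples
#' validate_event(clinical_event("e1", "dizziness", "Sx"))     # character(0)
#' validate_event(clinical_event("e1", "WBC 11.2", "Lab"))     # unknown tag
#' @export
validate_event <- function(event) {
  v <- character(0)
  if (!inherits(event, "clinical_event")) {
    return("event: not a clinical_event object")
  }
  if (is.na(event$event_id) || !nzchar(event$event_id)) {
    v <- c(v, "event_id: must be a nonempty string")
  }
  if (length(event$semantic_type) != 1L ||
      !(event$semantic_type %in% semantic_tags())) {
    v <- c(v, sprintf("semantic_type: unknown semantic tag '%s'",
                      paste(event$semantic_type, collapse = ",")))
  }
  if (length(event$appearance_index) != 1L || is.na(event$appearance_index) ||
      event$appearance_index < 0L) {
    v <- c(v, "appearance_index: must be a non-negative integer")
  }
  if (any(event$causal_links == event$event_id)) {
    v <- c(v, "causal_links: event cannot cause itself")
  }
  v
}

#' @export
print.clinical_event <- function(x, ...) {
  cat(sprintf("<event %s> [%s] \"%s\" @ \"%s\" (#%d)\n", x$event_id,
              x$semantic_type, x$text, x$raw_time, x$appearance_index))
  if (length(x$causal_links)) {
    cat("  causes:", paste(x$causal_links, collapse = ", "), "\n")
  }
  invisible(x)
}
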