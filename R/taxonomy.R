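#' Semantic type taxonomy of clinical events
#'
#' The model classifies every annotated event into one of 14 semantic
#' categories. Each category is permitted on a fixed subset of the three
#' structural positions: the Problem wing (why something was done), the
#' Action wing (what was done), or the Visit strip (administrative events).
#'
#' @return A data frame with one row per semantic type and columns
#'   `tag` (the notation used in event records), `description`, and
#'   `allowed_positions` (a list column of character vectors drawn from
#'   `"Problem"`, `"Action"`, `"Visit"`).
#' @examples
#' tax <- taxonomy()
#' nrow(tax)                                   # 14
#' tax$allowed_positions[[match("Dx", tax$tag)]]  # Problem and Action
#' @export
taxonomy <- function() {
  tab <- data.frame(
    tag = c("Purpose", "Sx", "Dx", "Finding", "Drug", "Op", "Other",
            "Plan", "Test", "Tx", "Adm", "Death", "Disch", "Visit"),
    description = c("Purpose", "Symptom", "Diagnosis", "Finding", "Drug",
                    "Operation", "Any other events", "Plan", "Test",
                    "Treatment", "Admission", "Death", "Discharge",
                    "Hospital/Department visit information"),
    stringsAsFactors = FALSE
  )
  tab$allowed_positions <- list(
    "Problem", "Problem",
    c("Problem", "Action"), c("Problem", "Action"),
    "Action", "Action", "Action", "Action", "Action", "Action",
    "Visit", "Visit", "Visit", "Visit"
  )
  tab
}

#' The 14 semantic tags
#'
#' @return Character vector of the valid `semantic_type` tags, in taxonomy
#'   order.
#' @export
semantic_tags <- function() taxonomy()$tag

#' Positions a semantic tag may occupy
#'
#' @param tag A semantic tag.
#' @return Character vector among `"Problem"`, `"Action"`, `"Visit"`;
#'   empty if the tag is unknown.
#' @export
allowed_positions <- function(tag) {
  tax <- taxonomy()
  i <- match(tag, tax$tag)
  if (is.na(i)) character(0) else tax$allowed_positions[[i]]
}
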