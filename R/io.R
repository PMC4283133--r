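# Interchange formats: a JSON document of per-patient annotated events
# (canonical), a flat TSV importer, timeline and rule serialization, and a
# YAML configuration covering the temporal dialect and rendering options.
# The schema is enforced field-by-field with located errors; the verbatim
# temporal expression strings are stored untouched.

SCHEMA_VERSION <- "1.0"

EVENT_FIELDS <- c("event_id", "text", "semantic_type", "raw_time",
                  "appearance_index", "causal_links")
EVENT_REQUIRED <- c("event_id", "semantic_type", "appearance_index")
PATIENT_FIELDS <- c("patient_id", "anchor_date", "events")

io_stop <- function(where, msg) {
  stop(sprintf("%s: %s", where, msg), call. = FALSE)
}

check_fields <- function(rec, allowed, required, where) {
  unknown <- setdiff(names(rec), allowed)
  if (length(unknown)) {
    io_stop(where, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(required, names(rec))
  if (length(missing)) {
    io_stop(where, paste0("missing required field(s): ",
                          paste(missing, collapse = ", ")))
  }
}

event_from_record <- function(rec, where) {
  check_fields(rec, EVENT_FIELDS, EVENT_REQUIRED, where)
  ev <- clinical_event(
    event_id = as.character(rec$event_id),
    text = if (is.null(rec$text)) "" else as.character(rec$text),
    semantic_type = as.character(rec$semantic_type),
    raw_time = if (is.null(rec$raw_time)) "" else as.character(rec$raw_time),
    appearance_index = as.integer(rec$appearance_index),
    causal_links = if (is.null(rec$causal_links)) character(0) else
      as.character(unlist(rec$causal_links)))
  viol <- validate_event(ev)
  if (length(viol)) io_stop(where, paste(viol, collapse = "; "))
  ev
}

#' Read an annotated-events document
#'
#' Canonical format is JSON: an object with `schema_version` and
#' `patients`, each patient holding `patient_id`, an optional ISO-8601
#' `anchor_date`, and its `events`. The TSV importer is a flat convenience
#' form with columns `patient_id`, `event_id`, `appearance_index`,
#' `semantic_type`, `text`, `raw_time`, `causal_links`
#' (semicolon-separated ids). Schema violations raise errors naming the
#' offending location; unknown fields are rejected.
#'
#' @param path File path.
#' @param format `"json"` or `"tsv"`.
#' @return An `interchange_document`: `schema_version` and `patients`
#'   (each with `patient_id`, `anchor_date`, `events`).
#' @export
read_events <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") read_events_json(path) else read_events_tsv(path)
}

read_events_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_fields(doc, c("schema_version", "patients"),
               c("schema_version", "patients"), "/")
  if (!identical(doc$schema_version, SCHEMA_VERSION)) {
    io_stop("/schema_version",
            sprintf("unsupported schema_version '%s' (expected '%s')",
                    doc$schema_version, SCHEMA_VERSION))
  }
  patients <- list()
  for (i in seq_along(doc$patients)) {
    p <- doc$patients[[i]]
    where <- sprintf("/patients/%d", i)
    check_fields(p, PATIENT_FIELDS, c("patient_id", "events"), where)
    events <- lapply(seq_along(p$events), function(j)
      event_from_record(p$events[[j]], sprintf("%s/events/%d", where, j)))
    ids <- vapply(events, `[[`, "", "event_id")
    if (anyDuplicated(ids)) {
      io_stop(where, paste0("duplicate event_id: ",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    patients[[length(patients) + 1L]] <- list(
      patient_id = as.character(p$patient_id),
      anchor_date = if (is.null(p$anchor_date)) NULL else
        as.character(p$anchor_date),
      events = events)
  }
  pids <- vapply(patients, `[[`, "", "patient_id")
  if (anyDuplicated(pids)) io_stop("/patients", "duplicate patient_id")
  structure(list(schema_version = SCHEMA_VERSION, patients = patients),
            class = "interchange_document")
}

read_events_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("patient_id", "event_id", "appearance_index", "semantic_type",
            "text", "raw_time", "causal_links")
  check_fields(stats::setNames(vector("list", ncol(tab)), names(tab)),
               need, need, "header")
  patients <- list()
  for (pid in unique(tab$patient_id)) {
    rows <- which(tab$patient_id == pid)
    events <- lapply(rows, function(r) {
      links <- tab$causal_links[r]
      event_from_record(list(
        event_id = tab$event_id[r], text = tab$text[r],
        semantic_type = tab$semantic_type[r], raw_time = tab$raw_time[r],
        appearance_index = as.integer(tab$appearance_index[r]),
        causal_links = if (nzchar(links))
          strsplit(links, ";", fixed = TRUE)[[1]] else character(0)),
        sprintf("row %d", r + 1L))
    })
    ids <- vapply(events, `[[`, "", "event_id")
    if (anyDuplicated(ids)) {
      io_stop(sprintf("patient %s", pid), "duplicate event_id")
    }
    patients[[length(patients) + 1L]] <- list(patient_id = pid,
                                              anchor_date = NULL,
                                              events = events)
  }
  structure(list(schema_version = SCHEMA_VERSION, patients = patients),
            class = "interchange_document")
}

event_to_record <- function(e) {
  list(event_id = e$event_id, text = e$text,
       semantic_type = e$semantic_type, raw_time = e$raw_time,
       appearance_index = e$appearance_index,
       causal_links = as.list(e$causal_links))
}

#' Write an annotated-events document
#'
#' @param document An `interchange_document` (or a list of patients).
#' @param path Output path.
#' @export
write_events <- function(document, path) {
  pats <- lapply(document$patients, function(p) {
    out <- list(patient_id = p$patient_id)
    if (!is.null(p$anchor_date)) out$anchor_date <- p$anchor_date
    out$events <- lapply(p$events, event_to_record)
    out
  })
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, patients = pats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

structure_to_record <- function(s) {
  list(structure_id = s$structure_id,
       raw_time = s$tap$raw_text,
       visit_only = s$visit_only,
       problems = lapply(s$problems, event_to_record),
       actions = lapply(s$actions, event_to_record),
       visits = lapply(s$visits, event_to_record))
}

#' Write a patient timeline to JSON
#'
#' The serialization is lossless: verbatim temporal expressions are stored
#' untouched and anchors are rebuilt deterministically on read, so a
#' round-trip compares equal field-by-field.
#'
#' @param timeline A [patient_timeline()].
#' @param path Output path.
#' @export
write_timeline <- function(timeline, path) {
  doc <- list(
    schema_version = SCHEMA_VERSION,
    patient_id = timeline$patient_id,
    anchor_date = if (is.null(timeline$anchor_date)) NULL else
      format(as.Date(timeline$anchor_date), "%Y-%m-%d"),
    structures = lapply(timeline$structures, structure_to_record),
    cross_links = if (nrow(timeline$cross_links))
      lapply(seq_len(nrow(timeline$cross_links)), function(i)
        list(problem_id = timeline$cross_links$problem_id[i],
             action_id = timeline$cross_links$action_id[i]))
    else list())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a patient timeline from JSON
#'
#' @param path File written by [write_timeline()].
#' @param lexicon,pivot Passed to [parse_tap()] when rebuilding anchors.
#' @return A [patient_timeline()].
#' @export
read_timeline <- function(path, lexicon = NULL, pivot = 30L) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    io_stop(path, paste0("parse error: ", conditionMessage(e))))
  check_fields(doc, c("schema_version", "patient_id", "anchor_date",
                      "structures", "cross_links"),
               c("schema_version", "patient_id", "structures"), "/")
  if (!identical(doc$schema_version, SCHEMA_VERSION)) {
    io_stop("/schema_version",
            sprintf("unsupported schema_version '%s' (expected '%s')",
                    doc$schema_version, SCHEMA_VERSION))
  }
  anchor_date <- if (is.null(doc$anchor_date)) NULL else
    as.Date(doc$anchor_date)
  structures <- lapply(seq_along(doc$structures), function(i) {
    s <- doc$structures[[i]]
    where <- sprintf("/structures/%d", i)
    check_fields(s, c("structure_id", "raw_time", "visit_only", "problems",
                      "actions", "visits"),
                 c("structure_id", "raw_time"), where)
    mk <- function(field) lapply(seq_along(s[[field]]), function(j)
      event_from_record(s[[field]][[j]],
                        sprintf("%s/%s/%d", where, field, j)))
    v_structure(s$structure_id,
                parse_tap(s$raw_time, anchor_date = anchor_date,
                          lexicon = lexicon, pivot = pivot),
                problems = mk("problems"), actions = mk("actions"),
                visits = mk("visits"), visit_only = isTRUE(s$visit_only))
  })
  cl <- empty_cross_links()
  for (l in doc$cross_links) {
    cl <- rbind(cl, data.frame(problem_id = l$problem_id,
                               action_id = l$action_id,
                               stringsAsFactors = FALSE))
  }
  patient_timeline(doc$patient_id, structures, anchor_date = anchor_date,
                   cross_links = cl)
}

rule_to_record <- function(rule) {
  list(include = as.list(rule$include$blocks),
       exclude_preceding = lapply(rule$exclude_preceding, function(e)
         as.list(e$blocks)),
       temporal_constraint = if (is.null(rule$temporal_constraint)) NULL else
         list(min_units = rule$temporal_constraint$min_units,
              max_units = rule$temporal_constraint$max_units,
              unit = rule$temporal_constraint$unit))
}

#' Write mined rules to JSON
#'
#' @param results List of `mining_result`s from [mine_rules()] (or bare
#'   [phenotype_rule()]s).
#' @param path Output path.
#' @export
write_rules <- function(results, path) {
  recs <- lapply(results, function(r) {
    if (inherits(r, "phenotype_rule")) {
      rule_to_record(r)
    } else {
      c(rule_to_record(r$rule),
        list(support_target = r$support_target,
             support_background = r$support_background,
             confusion = as.list(r$confusion)))
    }
  })
  jsonlite::write_json(list(schema_version = SCHEMA_VERSION, rules = recs),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read phenotype rules from JSON
#'
#' @param path File written by [write_rules()].
#' @return List of [phenotype_rule()]s.
#' @export
read_rules <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_fields(doc, c("schema_version", "rules"),
               c("schema_version", "rules"), "/")
  if (!identical(doc$schema_version, SCHEMA_VERSION)) {
    io_stop("/schema_version",
            sprintf("unsupported schema_version '%s'", doc$schema_version))
  }
  lapply(doc$rules, function(r) {
    tc <- NULL
    if (!is.null(r$temporal_constraint)) {
      tc <- structure(list(min_units = r$temporal_constraint$min_units,
                           max_units = r$temporal_constraint$max_units,
                           unit = r$temporal_constraint$unit),
                      class = "duration_bounds")
    }
    phenotype_rule(unlist(r$include),
                   lapply(r$exclude_preceding, unlist),
                   temporal_constraint = tc)
  })
}

#' Read a YAML configuration
#'
#' Recognized sections: `temporal` (`pivot`, `lexicon` as a name-to-date
#' map), `render` (any [render_config()] argument), and `mine`
#' (`min_support_target`, `max_len`, `mode`).
#'
#' @param path YAML file.
#' @return Named list with `temporal`, `render` and `mine` entries merged
#'   over defaults.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(temporal = list(pivot = 30L, lexicon = NULL),
              render = list(), mine = list(min_support_target = 0.8,
                                           max_len = 3L,
                                           mode = "semantic_type"))
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in names(user)) cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  if (!is.null(cfg$temporal$lexicon)) {
    cfg$temporal$lexicon <- unlist(cfg$temporal$lexicon)
    names(cfg$temporal$lexicon) <- tolower(names(cfg$temporal$lexicon))
  }
  cfg
}

render_config_from <- function(cfg) {
  do.call(render_config, cfg$render)
}
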