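# Assembles a flat list of annotated events into a timeline of
# v-structures: role assignment from the semantic tag (with the
# explicit-causality rule for diagnoses and findings), shared TAPs for
# events carrying the same verbatim temporal expression, one v-structure
# per distinct causal relationship within a shared expression, and
# chronological-then-appearance ordering.

#' Assign the structural role of an event
#'
#' Symptoms and purposes always model as Problems. Diagnoses and findings
#' model as Problems only when the text states the causality explicitly
#' ("due to cervix cancer, concurrent chemo RT was done"); the same event
#' without a causality expression is an Action. Every other clinical event
#' is an Action; administrative events are Visits.
#'
#' @param event A validated [clinical_event()].
#' @param has_explicit_cause_link Whether the source text states this event
#'   as the cause of another (in event records: a nonempty `causal_links`).
#' @return A `role_assignment`: `event_id`, `role` (Problem / Action /
#'   Visit) and `rule_fired` (audit label).
#' @export
assign_role <- function(event, has_explicit_cause_link = length(event$causal_links) > 0L) {
  tag <- event$semantic_type
  if (!(tag %in% semantic_tags())) {
    stop("unknown semantic tag '", tag, "'")
  }
  res <- switch(tag,
    Purpose = , Sx = c("Problem", "symptom/purpose is always a Problem"),
    Dx = , Finding = if (has_explicit_cause_link) {
      c("Problem", "explicit causality models Dx/Finding as a Problem")
    } else {
      c("Action", "Dx/Finding without causality expression is an Action")
    },
    Adm = , Death = , Disch = , Visit = c("Visit", "administrative event"),
    c("Action", "clinical event done for a problem is an Action"))
  structure(list(event_id = event$event_id, role = res[[1]],
                 rule_fired = res[[2]]), class = "role_assignment")
}

# Detect a cycle in the event-level causal graph; returns the cycle as a
# vector of ids, or NULL.
find_causal_cycle <- function(events) {
  ids <- vapply(events, `[[`, "", "event_id")
  adj <- lapply(events, function(e) intersect(e$causal_links, ids))
  names(adj) <- ids
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  path <- character(0)
  cycle <- NULL
  visit <- function(u) {
    if (!is.null(cycle)) return()
    state[[u]] <<- 1L
    path <<- c(path, u)
    for (w in adj[[u]]) {
      if (state[[w]] == 1L) {
        cycle <<- c(path[which(path == w)[1]:length(path)], w)
        return()
      }
      if (state[[w]] == 0L) visit(w)
      if (!is.null(cycle)) return()
    }
    state[[u]] <<- 2L
    path <<- path[-length(path)]
  }
  for (u in ids) if (state[[u]] == 0L) visit(u)
  cycle
}

#' Build a patient timeline from annotated events
#'
#' Events carrying the same verbatim temporal expression share one temporal
#' anchor. Within a shared expression, each distinct causal relationship —
#' a connected group of Problems and the Actions they are stated causes of —
#' becomes its own v-structure (so two independently caused tests at one
#' date render as two v's sharing the expression), and the remaining
#' unlinked events join a single residual structure. Events with no
#' temporal expression inherit the nearest preceding one, preserving the
#' order-of-appearance display principle. Structures are ordered
#' chronologically wherever the anchors' intervals decide the order, and by
#' earliest appearance otherwise; a resolvable anchor out of document order
#' is moved, with a warning, because the timeline is the product.
#'
#' @param events List of [clinical_event()]s for one patient.
#' @param anchor_date Optional date resolving relative expressions.
#' @param patient_id Identifier stored on the timeline.
#' @param lexicon,pivot Passed to [parse_tap()].
#' @return A [patient_timeline()].
#' @export
build_timeline <- function(events, anchor_date = NULL, patient_id = "p1",
                           lexicon = NULL, pivot = 30L) {
  if (length(events) == 0L) {
    return(patient_timeline(patient_id, anchor_date = anchor_date))
  }
  viol <- unlist(lapply(events, validate_event))
  if (length(viol)) stop("invalid events: ", paste(viol, collapse = "; "))
  ids <- vapply(events, `[[`, "", "event_id")
  if (anyDuplicated(ids)) stop("duplicate event_id within patient")
  idx <- vapply(events, `[[`, 0L, "appearance_index")
  if (anyDuplicated(idx)) stop("appearance_index values must be unique")
  unknown <- setdiff(unlist(lapply(events, `[[`, "causal_links")), ids)
  if (length(unknown)) {
    stop("causal link(s) reference events outside this patient: ",
         paste(unknown, collapse = ", "))
  }
  cyc <- find_causal_cycle(events)
  if (!is.null(cyc)) {
    stop("cyclic causal links: ", paste(cyc, collapse = " -> "))
  }

  events <- events[order(idx)]
  ids <- vapply(events, `[[`, "", "event_id")

  # TAP grouping: same verbatim raw_time shares a group; empty raw_time
  # inherits the nearest preceding group (leading untimed events form one).
  raw <- vapply(events, `[[`, "", "raw_time")
  group_key <- character(length(events))
  last <- ""
  for (i in seq_along(events)) {
    if (nzchar(trimws(raw[i]))) last <- raw[i]
    group_key[i] <- last
  }
  keys <- unique(group_key)
  taps <- lapply(keys, parse_tap, anchor_date = anchor_date,
                 lexicon = lexicon, pivot = pivot)
  names(taps) <- keys

  roles <- vapply(events, function(e)
    assign_role(e, length(e$causal_links) > 0L)$role, "")
  names(roles) <- ids

  structures <- list()
  group_order_key <- numeric(0)   # earliest appearance index per structure
  group_of_structure <- integer(0)
  sid <- 0L
  for (gi in seq_along(keys)) {
    key <- keys[gi]
    in_group <- events[group_key == key]
    gids <- vapply(in_group, `[[`, "", "event_id")
    grole <- roles[gids]

    # Bipartite problem-action link graph within the group: connected
    # components are the distinct causal relationships.
    comp <- stats::setNames(seq_along(gids), gids)
    linked <- stats::setNames(rep(FALSE, length(gids)), gids)
    for (e in in_group) {
      targets <- intersect(e$causal_links, gids)
      targets <- targets[roles[targets] == "Action"]
      if (roles[[e$event_id]] == "Problem" && length(targets)) {
        linked[[e$event_id]] <- TRUE
        for (t in targets) {
          linked[[t]] <- TRUE
          old <- comp[[t]]
          comp[comp == old] <- comp[[e$event_id]]
        }
      }
    }

    member_sets <- list()
    for (cid in unique(comp[linked])) {
      member_sets[[length(member_sets) + 1L]] <- gids[comp == cid & linked]
    }
    # order causal structures by earliest member appearance
    if (length(member_sets) > 1L) {
      first_idx <- vapply(member_sets, function(m)
        min(vapply(in_group[match(m, gids)], `[[`, 0L, "appearance_index")), 0L)
      member_sets <- member_sets[order(first_idx)]
    }
    residual <- gids[!linked & grole != "Visit"]
    if (length(residual)) member_sets <- c(member_sets, list(residual))
    visits <- in_group[grole[gids] == "Visit"]

    if (!length(member_sets)) {
      if (length(visits)) {
        sid <- sid + 1L
        structures[[sid]] <- v_structure(
          sprintf("%s-s%d", patient_id, sid), taps[[key]], visits = visits,
          visit_only = TRUE)
        group_order_key[sid] <- min(vapply(visits, `[[`, 0L,
                                           "appearance_index"))
        group_of_structure[sid] <- gi
      }
      next
    }
    for (mi in seq_along(member_sets)) {
      members <- in_group[match(member_sets[[mi]], gids)]
      mroles <- roles[member_sets[[mi]]]
      sid <- sid + 1L
      structures[[sid]] <- v_structure(
        sprintf("%s-s%d", patient_id, sid), taps[[key]],
        problems = members[mroles == "Problem"],
        actions = members[mroles == "Action"],
        visits = if (mi == 1L) visits else list())
      group_order_key[sid] <- min(vapply(members, `[[`, 0L,
                                         "appearance_index"))
      group_of_structure[sid] <- gi
    }
  }

  # Order TAP groups: appearance first, then correct chronological
  # inversions between groups whose anchors decide the order (stable
  # insertion pass; structures of one group move together, keeping their
  # internal appearance order).
  ord <- order_structure_groups(structures, group_of_structure,
                                group_order_key, taps, keys)
  structures <- structures[ord]
  # Visit events with no co-occurring Problem/Action attach to the nearest
  # following structure; a trailing visit-only group stays as its own
  # structure (an admission may open a record before any clinical event).
  i <- 1L
  while (i <= length(structures)) {
    if (structures[[i]]$visit_only && i < length(structures)) {
      structures[[i + 1L]]$visits <- c(structures[[i]]$visits,
                                       structures[[i + 1L]]$visits)
      structures[[i]] <- NULL
    } else {
      i <- i + 1L
    }
  }
  for (i in seq_along(structures)) {
    structures[[i]]$structure_id <- sprintf("%s-s%d", patient_id, i)
  }
  patient_timeline(patient_id, structures, anchor_date = anchor_date)
}

order_structure_groups <- function(structures, group_of_structure,
                                   group_order_key, taps, keys) {
  gis <- sort(unique(group_of_structure))
  gkey <- vapply(gis, function(g) min(group_order_key[group_of_structure == g]),
                 0)
  gis <- gis[order(gkey)]  # appearance order of groups
  # insertion sort on groups with the chronological comparator
  n <- length(gis)
  moved <- FALSE
  if (n > 1L) {
    for (i in 2L:n) {
      j <- i
      while (j > 1L) {
        rel <- qualitative_relation(taps[[keys[gis[j]]]],
                                    taps[[keys[gis[j - 1L]]]])
        if (rel == "before") {
          tmp <- gis[j]; gis[j] <- gis[j - 1L]; gis[j - 1L] <- tmp
          j <- j - 1L
          moved <- TRUE
        } else break
      }
    }
  }
  if (moved) {
    warning("temporal expressions out of document order; ",
            "chronological order applied")
  }
  unlist(lapply(gis, function(g)
    which(group_of_structure == g)[order(group_order_key[
      group_of_structure == g])]))
}

#' Link a Problem to a temporally separate later Action
#'
#' The opposite-directed wing pair lets a problem connect to action events
#' in a later structure — chief complaints starting in late July linked to
#' the workup done in August. The link is recorded on the timeline and
#' consumed by context-block extraction and rendering.
#'
#' @param timeline A [patient_timeline()].
#' @param problem_event_id,action_event_id Event ids present on the
#'   timeline; the action's structure must not precede the problem's.
#' @return The updated timeline.
#' @export
link_problem_to_later_action <- function(timeline, problem_event_id,
                                         action_event_id) {
  if (identical(problem_event_id, action_event_id)) {
    stop("self-link: an event cannot cause itself")
  }
  smap <- event_structure_map(timeline)
  for (id in c(problem_event_id, action_event_id)) {
    if (!(id %in% names(smap))) stop("unknown event '", id, "'")
  }
  pi <- smap[[problem_event_id]]
  ai <- smap[[action_event_id]]
  if (ai < pi) stop("action precedes its problem: structure ", ai,
                    " is before structure ", pi)
  timeline$cross_links <- rbind(
    timeline$cross_links,
    data.frame(problem_id = problem_event_id, action_id = action_event_id,
               stringsAsFactors = FALSE))
  timeline
}
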