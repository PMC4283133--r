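# Deterministic layout and SVG rendering of a patient timeline: v-shaped
# glyphs on a dynamically scaled baseline (equal spacing between temporal
# anchor marks regardless of elapsed time), red Problem wings up-left and
# blue Action wings up-right, color-coded semantic tag boxes heading each
# same-type run of events, Visit items in a strip below the baseline, and
# baseline arcs for Problem-to-Action links that span structures.

#' Rendering configuration
#'
#' @param unit_spacing Pixels between successive temporal anchor marks.
#'   The timeline is dynamically scaled: this spacing is constant and never
#'   proportional to elapsed time.
#' @param wing_angle Wing inclination from the baseline, degrees (15-75).
#' @param problem_color,action_color Hex fills of the semantic tag boxes
#'   (red for Problem events, blue for Action events).
#' @param visit_color Hex fill of Visit tag boxes.
#' @param font_size,char_width Font metrics used to size label boxes.
#' @param label_pitch Vertical distance between stacked labels on a wing.
#' @param wing_length Length of the drawn wing stroke.
#' @param margin Canvas margin on all sides.
#' @param show_blocks Draw enclosing rectangles around context blocks.
#'   Off by default: the rectangles are an explanatory aid, not part of the
#'   visualization itself.
#' @return A `render_config`.
#' @export
render_config <- function(unit_spacing = 170, wing_angle = 45,
                          problem_color = "#CC0000",
                          action_color = "#0033CC",
                          visit_color = "#666666",
                          font_size = 11, char_width = 6.6,
                          label_pitch = 16, wing_length = 34,
                          margin = 40, show_blocks = FALSE) {
  stopifnot(unit_spacing > 0)
  if (wing_angle < 15 || wing_angle > 75) {
    stop("wing_angle must be between 15 and 75 degrees")
  }
  for (col in c(problem_color, action_color, visit_color)) {
    if (!grepl("^#[0-9A-Fa-f]{6}$", col)) stop("colors must be hex #RRGGBB")
  }
  structure(list(unit_spacing = unit_spacing, wing_angle = wing_angle,
                 problem_color = problem_color, action_color = action_color,
                 visit_color = visit_color, font_size = font_size,
                 char_width = char_width, label_pitch = label_pitch,
                 wing_length = wing_length, margin = margin,
                 show_blocks = show_blocks),
            class = "render_config")
}

# Label slots of one wing: a tag box ahead of each same-type run of events,
# then the events, in wing order.
wing_slots <- function(events, side) {
  if (!length(events)) {
    return(data.frame(kind = character(0), text = character(0),
                      tag = character(0), stringsAsFactors = FALSE))
  }
  tags <- vapply(events, `[[`, "", "semantic_type")
  texts <- vapply(events, `[[`, "", "text")
  kind <- character(0); text <- character(0); tag <- character(0)
  prev <- ""
  for (i in seq_along(events)) {
    if (!identical(tags[i], prev)) {
      kind <- c(kind, "tag"); text <- c(text, tags[i]); tag <- c(tag, tags[i])
      prev <- tags[i]
    }
    kind <- c(kind, "event"); text <- c(text, texts[i]); tag <- c(tag, tags[i])
  }
  data.frame(kind = kind, text = text, tag = tag, side = side,
             stringsAsFactors = FALSE)
}

#' Compute the layout geometry of a timeline
#'
#' Pure and deterministic: identical inputs give identical coordinates.
#' Temporal anchor marks sit on a horizontal baseline at strictly
#' increasing, equally spaced x positions; each structure's Problem wing
#' extends up-left and its Action wing up-right; label boxes are sized so
#' that no two overlap; canvas height follows the largest wing, not the
#' number of distinct event concepts.
#'
#' @param timeline A [patient_timeline()].
#' @param config A [render_config()].
#' @return A `layout_geometry` with data-frame components `taps`, `wings`,
#'   `boxes`, `links`, `blocks` and a `canvas` list.
#' @export
layout_timeline <- function(timeline, config = render_config()) {
  n <- length(timeline$structures)
  sp <- config$unit_spacing
  pitch <- config$label_pitch
  ang <- config$wing_angle * pi / 180
  rise <- config$wing_length * sin(ang)
  run <- config$wing_length * cos(ang)
  box_h <- pitch - 4
  max_w <- (sp - 24) / 2

  labels <- render_tap_labels(timeline)
  xs <- config$margin + sp / 2 + (seq_len(max(n, 0L)) - 1) * sp

  slots <- lapply(timeline$structures, function(s)
    rbind(wing_slots(s$problems, "Problem"), wing_slots(s$actions, "Action")))
  max_slots <- if (n) max(c(0L, vapply(slots, function(d)
    max(c(0L, sum(d$side == "Problem"), sum(d$side == "Action"))), 0L))) else 0L
  max_visits <- if (n) max(vapply(timeline$structures, function(s)
    length(s$visits), 0L)) else 0L

  baseline <- config$margin + rise + max_slots * pitch + pitch
  smap <- event_structure_map(timeline)
  has_arcs <- nrow(timeline$cross_links) > 0L
  height <- baseline + 16 + pitch +            # tap label band
    max_visits * pitch + (if (has_arcs) 24 else 0) + config$margin
  width <- 2 * config$margin + max(n, 1L) * sp

  taps <- data.frame(structure_id = character(0), x = numeric(0),
                     y = numeric(0), label = character(0),
                     show_label = logical(0), stringsAsFactors = FALSE)
  wings <- data.frame(structure_id = character(0), side = character(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), stringsAsFactors = FALSE)
  boxes <- data.frame(structure_id = character(0), side = character(0),
                      kind = character(0), event_ref = character(0),
                      x = numeric(0), y = numeric(0), w = numeric(0),
                      h = numeric(0), text = character(0),
                      fill = character(0), stringsAsFactors = FALSE)

  # Structures sharing one verbatim expression show the label once,
  # centered under the run.
  show_label <- rep(TRUE, n)
  if (n > 1L) {
    for (i in 2L:n) {
      if (nzchar(labels[i]) && identical(labels[i], labels[i - 1L])) {
        show_label[i] <- FALSE
      }
    }
  }

  for (i in seq_len(n)) {
    s <- timeline$structures[[i]]
    taps <- rbind(taps, data.frame(
      structure_id = s$structure_id, x = xs[i], y = baseline,
      label = labels[i], show_label = show_label[i], stringsAsFactors = FALSE))
    for (side in c("Problem", "Action")) {
      sl <- slots[[i]][slots[[i]]$side == side, , drop = FALSE]
      dir <- if (side == "Problem") -1 else 1
      if (nrow(sl) || !s$visit_only) {
        wings <- rbind(wings, data.frame(
          structure_id = s$structure_id, side = side,
          x0 = xs[i], y0 = baseline, x1 = xs[i] + dir * run,
          y1 = baseline - rise, stringsAsFactors = FALSE))
      }
      if (!nrow(sl)) next
      base_fill <- if (side == "Problem") config$problem_color else
        config$action_color
      for (k in seq_len(nrow(sl))) {
        w <- min(nchar(sl$text[k]) * config$char_width + 6, max_w)
        y <- baseline - rise - k * pitch
        x <- if (side == "Problem") xs[i] - 8 - w else xs[i] + 8
        boxes <- rbind(boxes, data.frame(
          structure_id = s$structure_id, side = side, kind = sl$kind[k],
          event_ref = "", x = x, y = y, w = w, h = box_h, text = sl$text[k],
          fill = if (sl$kind[k] == "tag") base_fill else "none",
          stringsAsFactors = FALSE))
      }
    }
    if (length(s$visits)) {
      vtags <- vapply(s$visits, `[[`, "", "semantic_type")
      vtexts <- vapply(s$visits, `[[`, "", "text")
      for (k in seq_along(s$visits)) {
        txt <- sprintf("%s %s", vtags[k], vtexts[k])
        w <- min(nchar(txt) * config$char_width + 6, max_w)
        boxes <- rbind(boxes, data.frame(
          structure_id = s$structure_id, side = "Visit", kind = "visit",
          event_ref = s$visits[[k]]$event_id, x = xs[i] + 8,
          y = baseline + 16 + pitch + (k - 1) * pitch, w = w, h = box_h,
          text = txt, fill = config$visit_color, stringsAsFactors = FALSE))
      }
    }
  }

  # Verbatim temporal expression labels, centered; shared runs centered on
  # the run.
  tap_boxes <- data.frame(structure_id = character(0), side = character(0),
                          kind = character(0), event_ref = character(0),
                          x = numeric(0), y = numeric(0), w = numeric(0),
                          h = numeric(0), text = character(0),
                          fill = character(0), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && !show_label[j + 1L]) j <- j + 1L
    if (nzchar(labels[i])) {
      cx <- mean(xs[i:j])
      w <- min(nchar(labels[i]) * config$char_width + 6, sp * (j - i + 1) - 8)
      tap_boxes <- rbind(tap_boxes, data.frame(
        structure_id = timeline$structures[[i]]$structure_id, side = "TAP",
        kind = "tap", event_ref = "", x = cx - w / 2, y = baseline + 6,
        w = w, h = box_h, text = labels[i], fill = "none",
        stringsAsFactors = FALSE))
    }
    i <- j + 1L
  }
  boxes <- rbind(boxes, tap_boxes)

  links <- data.frame(from_structure = character(0),
                      to_structure = character(0), x0 = numeric(0),
                      x1 = numeric(0), y = numeric(0),
                      stringsAsFactors = FALSE)
  if (has_arcs) {
    arc_y <- height - config$margin - 4
    for (r in seq_len(nrow(timeline$cross_links))) {
      pi_ <- smap[[timeline$cross_links$problem_id[r]]]
      ai_ <- smap[[timeline$cross_links$action_id[r]]]
      links <- rbind(links, data.frame(
        from_structure = timeline$structures[[pi_]]$structure_id,
        to_structure = timeline$structures[[ai_]]$structure_id,
        x0 = xs[pi_], x1 = xs[ai_], y = baseline, stringsAsFactors = FALSE))
    }
  }

  blocks <- data.frame(block_id = character(0), x = numeric(0),
                       y = numeric(0), w = numeric(0), h = numeric(0),
                       stringsAsFactors = FALSE)
  if (config$show_blocks && n) {
    for (b in extract_context_blocks(timeline)) {
      idx <- b$structure_index
      blocks <- rbind(blocks, data.frame(
        block_id = b$block_id, x = min(xs[idx]) - sp / 2 + 6,
        y = config$margin / 2, w = diff(range(xs[idx])) + sp - 12,
        h = height - config$margin, stringsAsFactors = FALSE))
    }
  }

  structure(list(taps = taps, wings = wings, boxes = boxes, links = links,
                 blocks = blocks,
                 canvas = list(width = width, height = height,
                               baseline = baseline)),
            class = "layout_geometry")
}

#' Verbatim temporal anchor labels of a timeline
#'
#' Labels are the verbatim temporal expressions as written in the source —
#' never normalized calendar dates — so informal and proximity expressions
#' ("postop") keep their context. Structures without an expression get an
#' empty label.
#'
#' @param timeline A [patient_timeline()].
#' @return Character vector, one label per structure.
#' @export
render_tap_labels <- function(timeline) {
  vapply(timeline$structures, function(s) {
    r <- s$tap$raw_text
    if (is.null(r) || is.na(r)) "" else r
  }, "")
}

fmt_num <- function(x) {
  s <- sprintf("%.2f", x)
  sub("-0\\.00", "0.00", s)
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render layout geometry to an SVG document
#'
#' Output is a deterministic function of its inputs: identical geometry and
#' configuration produce byte-identical SVG, so rendered fixtures can be
#' compared by hash.
#'
#' @param geometry A [layout_timeline()] result.
#' @param config The [render_config()] used for the layout.
#' @return A single string holding an SVG 1.1 document.
#' @export
render_svg <- function(geometry, config = render_config()) {
  g <- geometry
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" viewBox="0 0 %s %s">'),
            fmt_num(g$canvas$width), fmt_num(g$canvas$height),
            fmt_num(g$canvas$width), fmt_num(g$canvas$height)),
    sprintf('<rect class="canvas" x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
            fmt_num(g$canvas$width), fmt_num(g$canvas$height)))
  if (nrow(g$blocks)) {
    out <- c(out, vapply(seq_len(nrow(g$blocks)), function(i) sprintf(
      '<rect class="context-block" x="%s" y="%s" width="%s" height="%s" fill="#DDDDDD" fill-opacity="0.5" stroke="#AAAAAA"/>',
      fmt_num(g$blocks$x[i]), fmt_num(g$blocks$y[i]),
      fmt_num(g$blocks$w[i]), fmt_num(g$blocks$h[i])), ""))
  }
  out <- c(out, sprintf(
    '<line class="baseline" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333333"/>',
    fmt_num(0), fmt_num(g$canvas$baseline), fmt_num(g$canvas$width),
    fmt_num(g$canvas$baseline)))
  if (nrow(g$links)) {
    out <- c(out, vapply(seq_len(nrow(g$links)), function(i) sprintf(
      '<path class="pa-link" d="M %s %s Q %s %s %s %s" fill="none" stroke="%s" stroke-dasharray="4 3"/>',
      fmt_num(g$links$x0[i]), fmt_num(g$links$y[i]),
      fmt_num((g$links$x0[i] + g$links$x1[i]) / 2),
      fmt_num(g$links$y[i] + 40),
      fmt_num(g$links$x1[i]), fmt_num(g$links$y[i]),
      config$problem_color), ""))
  }
  if (nrow(g$taps)) {
    out <- c(out, vapply(seq_len(nrow(g$taps)), function(i) sprintf(
      '<circle class="tap-mark" cx="%s" cy="%s" r="3" fill="#333333"/>',
      fmt_num(g$taps$x[i]), fmt_num(g$taps$y[i])), ""))
  }
  if (nrow(g$wings)) {
    out <- c(out, vapply(seq_len(nrow(g$wings)), function(i) sprintf(
      '<path class="wing wing-%s" d="M %s %s L %s %s" fill="none" stroke="%s" stroke-width="2"/>',
      tolower(g$wings$side[i]),
      fmt_num(g$wings$x0[i]), fmt_num(g$wings$y0[i]),
      fmt_num(g$wings$x1[i]), fmt_num(g$wings$y1[i]),
      if (g$wings$side[i] == "Problem") config$problem_color else
        config$action_color), ""))
  }
  if (nrow(g$boxes)) {
    for (i in seq_len(nrow(g$boxes))) {
      b <- g$boxes[i, ]
      if (b$fill != "none") {
        out <- c(out, sprintf(
          '<rect class="%s-box" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
          b$kind, fmt_num(b$x), fmt_num(b$y), fmt_num(b$w), fmt_num(b$h),
          b$fill))
      }
      color <- if (b$fill == "none") "#000000" else "#FFFFFF"
      out <- c(out, sprintf(
        '<text class="%s-label" x="%s" y="%s" font-size="%s" font-family="sans-serif" fill="%s">%s</text>',
        b$kind, fmt_num(b$x + 3), fmt_num(b$y + b$h - 3),
        fmt_num(config$font_size), color, svg_escape(b$text)))
    }
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Render a timeline straight to SVG
#'
#' Convenience wrapper: [layout_timeline()] then [render_svg()].
#'
#' @inheritParams layout_timeline
#' @return SVG document string.
#' @export
render_timeline <- function(timeline, config = render_config()) {
  render_svg(layout_timeline(timeline, config), config)
}
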