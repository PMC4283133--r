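# Temporal anchor points (TAPs): parsing of non-explicit temporal
# expressions into granularity-aware calendar intervals, and distance /
# qualitative reasoning over them. All calendar arithmetic is at minute
# resolution in UTC; interval endpoints are inclusive.

GRANULARITY_ORDER <- c(decade = 1L, year = 2L, month = 3L, day = 4L,
                       hour = 5L, minute = 6L, unknown = 0L)

NUMBER_WORDS <- c(a = 1L, an = 1L, one = 1L, two = 2L, three = 3L, four = 4L,
                  five = 5L, six = 6L, seven = 7L, eight = 8L, nine = 9L,
                  ten = 10L, eleven = 11L, twelve = 12L)

utc <- function(y, mo = 1L, d = 1L, h = 0L, mi = 0L) {
  ISOdatetime(y, mo, d, h, mi, 0, tz = "UTC")
}

days_in_month <- function(y, mo) {
  as.integer(format(utc(y + (mo == 12L), if (mo == 12L) 1L else mo + 1L) - 1,
                    "%d"))
}

#' Construct a calendar interval
#'
#' Inclusive interval at minute resolution, UTC.
#'
#' @param earliest,latest `POSIXct` timestamps, `earliest <= latest`.
#' @return A `calendar_interval`.
#' @export
calendar_interval <- function(earliest, latest) {
  stopifnot(inherits(earliest, "POSIXct"), inherits(latest, "POSIXct"),
            earliest <= latest)
  structure(list(earliest = earliest, latest = latest),
            class = "calendar_interval")
}

new_anchor <- function(raw_text, kind, granularity = "unknown",
                       fuzzy_modifier = "none", open_start = FALSE,
                       interval = NULL) {
  structure(list(raw_text = raw_text, kind = kind, granularity = granularity,
                 fuzzy_modifier = fuzzy_modifier, open_start = open_start,
                 interval = interval),
            class = "temporal_anchor")
}

#' @export
print.temporal_anchor <- function(x, ...) {
  cat(sprintf("<TAP \"%s\"> %s/%s", x$raw_text, x$kind, x$granularity))
  if (x$fuzzy_modifier != "none") cat(" [", x$fuzzy_modifier, "]", sep = "")
  if (x$open_start) cat(" open-start")
  if (!is.null(x$interval)) {
    cat(sprintf("  %s .. %s",
                format(x$interval$earliest, "%Y-%m-%dT%H:%M", tz = "UTC"),
                format(x$interval$latest, "%Y-%m-%dT%H:%M", tz = "UTC")))
  }
  cat("\n")
  invisible(x)
}

# Two-digit year pivot: YY >= pivot -> 19YY, else 20YY. The worked example
# needs '86 -> 1986 and '02 -> 2002.
expand_year <- function(y, pivot = 30L) {
  y <- as.integer(y)
  if (y >= 100L) y else if (y >= pivot) 1900L + y else 2000L + y
}

interval_for_year <- function(y) {
  calendar_interval(utc(y), utc(y, 12L, 31L, 23L, 59L))
}

interval_for_month <- function(y, mo) {
  calendar_interval(utc(y, mo), utc(y, mo, days_in_month(y, mo), 23L, 59L))
}

interval_for_day <- function(y, mo, d) {
  calendar_interval(utc(y, mo, d), utc(y, mo, d, 23L, 59L))
}

# Fuzzy modifiers split the parent unit into calendar-aligned thirds:
# decade -> years 0-2 / 3-5 / 6-9; year -> Jan-Apr / May-Aug / Sep-Dec;
# month -> days 1-10 / 11-20 / 21-end; day -> 8-hour blocks.
apply_fuzzy_third <- function(anchor, modifier) {
  iv <- anchor$interval
  if (is.null(iv)) return(anchor)
  s <- as.POSIXlt(iv$earliest, tz = "UTC")
  y <- s$year + 1900L
  third <- match(modifier, c("early", "mid", "late"))
  iv2 <- switch(anchor$granularity,
    decade = {
      y0 <- y + c(0L, 3L, 6L)[third]
      y1 <- y + c(2L, 5L, 9L)[third]
      calendar_interval(utc(y0), utc(y1, 12L, 31L, 23L, 59L))
    },
    year = {
      m0 <- c(1L, 5L, 9L)[third]
      m1 <- c(4L, 8L, 12L)[third]
      calendar_interval(utc(y, m0), utc(y, m1, days_in_month(y, m1), 23L, 59L))
    },
    month = {
      mo <- s$mon + 1L
      d0 <- c(1L, 11L, 21L)[third]
      d1 <- c(10L, 20L, days_in_month(y, mo))[third]
      calendar_interval(utc(y, mo, d0), utc(y, mo, d1, 23L, 59L))
    },
    day = {
      mo <- s$mon + 1L; d <- s$mday
      h0 <- c(0L, 8L, 16L)[third]
      h1 <- c(7L, 15L, 23L)[third]
      calendar_interval(utc(y, mo, d, h0), utc(y, mo, d, h1, 59L))
    },
    iv
  )
  anchor$interval <- iv2
  anchor$fuzzy_modifier <- modifier
  anchor
}

parse_absolute <- function(txt, pivot) {
  t <- sub("^'", "", txt)
  if (grepl("^\\d{4}s$", t)) {
    y <- as.integer(substr(t, 1L, 4L))
    y <- y - y %% 10L
    return(new_anchor(txt, "absolute", "decade",
                      interval = calendar_interval(
                        utc(y), utc(y + 9L, 12L, 31L, 23L, 59L))))
  }
  if (grepl("^(\\d{2}|\\d{4})$", t)) {
    y <- expand_year(t, pivot)
    return(new_anchor(txt, "absolute", "year", interval = interval_for_year(y)))
  }
  m <- regmatches(t, regexec("^(\\d{2}|\\d{4})[.](\\d{1,2})$", t))[[1]]
  if (length(m)) {
    y <- expand_year(m[2], pivot); mo <- as.integer(m[3])
    if (mo >= 1L && mo <= 12L) {
      return(new_anchor(txt, "absolute", "month",
                        interval = interval_for_month(y, mo)))
    }
  }
  m <- regmatches(t, regexec("^(\\d{2}|\\d{4})[.](\\d{1,2})[.](\\d{1,2})$", t))[[1]]
  if (length(m)) {
    y <- expand_year(m[2], pivot); mo <- as.integer(m[3]); d <- as.integer(m[4])
    if (mo >= 1L && mo <= 12L && d >= 1L && d <= days_in_month(y, mo)) {
      return(new_anchor(txt, "absolute", "day",
                        interval = interval_for_day(y, mo, d)))
    }
  }
  # ISO-8601 convenience forms
  m <- regmatches(t, regexec(
    "^(\\d{4})-(\\d{2})(-(\\d{2})([T ](\\d{2}):(\\d{2}))?)?$", t))[[1]]
  if (length(m)) {
    y <- as.integer(m[2]); mo <- as.integer(m[3])
    if (mo >= 1L && mo <= 12L) {
      if (!nzchar(m[4])) {
        return(new_anchor(txt, "absolute", "month",
                          interval = interval_for_month(y, mo)))
      }
      d <- as.integer(m[5])
      if (d >= 1L && d <= days_in_month(y, mo)) {
        if (!nzchar(m[6])) {
          return(new_anchor(txt, "absolute", "day",
                            interval = interval_for_day(y, mo, d)))
        }
        h <- as.integer(m[7]); mi <- as.integer(m[8])
        if (h <= 23L && mi <= 59L) {
          p <- utc(y, mo, d, h, mi)
          return(new_anchor(txt, "absolute", "minute",
                            interval = calendar_interval(p, p)))
        }
      }
    }
  }
  NULL
}

parse_relative <- function(txt, anchor_date) {
  m <- regmatches(tolower(txt), regexec(
    "^([0-9]+|a|an|one|two|three|four|five|six|seven|eight|nine|ten|eleven|twelve)\\s+(year|month|week|day|hour|minute)s?\\s+(ago|before|earlier)$",
    tolower(txt)))[[1]]
  if (!length(m)) return(NULL)
  n <- if (grepl("^[0-9]+$", m[2])) as.integer(m[2]) else NUMBER_WORDS[[m[2]]]
  unit <- m[3]
  gran <- if (unit == "week") "day" else unit
  if (is.null(anchor_date)) {
    return(new_anchor(txt, "relative", gran))
  }
  ad <- as.POSIXlt(as.POSIXct(anchor_date, tz = "UTC"), tz = "UTC")
  y <- ad$year + 1900L; mo <- ad$mon + 1L; d <- ad$mday
  iv <- switch(unit,
    year = interval_for_year(y - n),
    month = {
      k <- (y * 12L + mo - 1L) - n
      interval_for_month(k %/% 12L, k %% 12L + 1L)
    },
    week = {
      p <- utc(y, mo, d) - n * 7 * 86400
      calendar_interval(p, p + 86340)
    },
    day = {
      p <- utc(y, mo, d) - n * 86400
      calendar_interval(p, p + 86340)
    },
    hour = {
      p <- utc(y, mo, d, ad$hour) - n * 3600
      calendar_interval(p, p + 3540)
    },
    minute = {
      p <- trunc(as.POSIXct(anchor_date, tz = "UTC"), "mins") - n * 60
      calendar_interval(p, p)
    })
  new_anchor(txt, "relative", gran, interval = iv)
}

#' Parse a temporal expression into a temporal anchor
#'
#' Total function over strings: every input yields an anchor. The dialect
#' covers the expression forms found in narrative clinical notes:
#'
#' * `"86"`, `"1986"`, `"1980s"` — year / decade (two-digit years pivot at
#'   30: `>= 30` is 19YY, `< 30` is 20YY);
#' * `"02.8"`, `"02.8.15"` — dotted year.month and year.month.day;
#' * ISO forms `"2002-08"`, `"2002-08-15"`, `"2002-08-15T10:30"`;
#' * relative offsets `"three days ago"`, `"2 hours before"` (resolved
#'   against `anchor_date`, e.g. an admission or dictation date);
#' * semi-intervals `"from X"` / `"since X"` (sets `open_start`; reasoning
#'   stays anchored at the stated start);
#' * fuzzy modifiers `"early/mid/late X"` (narrow the parent unit to its
#'   first / middle / final calendar third);
#' * entries of the optional `lexicon` (named days such as holidays).
#'
#' Anything else nonempty is kept verbatim as a proximity hint (e.g.
#' `"postop"`): a non-temporal expression implying temporal nearness, kept
#' for display and never forced onto the calendar. The empty string yields
#' a `missing` anchor.
#'
#' @param raw_text The verbatim temporal expression.
#' @param anchor_date Optional `Date`/`POSIXct` used to resolve relative
#'   forms.
#' @param lexicon Optional named character vector mapping lowercase named-day
#'   expressions to ISO dates.
#' @param pivot Two-digit-year pivot (default 30).
#' @return A `temporal_anchor` with fields `raw_text`, `kind` (absolute,
#'   relative, proximity_hint, missing), `granularity`, `fuzzy_modifier`,
#'   `open_start`, and `interval` (a [calendar_interval()], absent for
#'   hints, unresolved relatives and missing anchors).
#' @examples
#' parse_tap("86")            # the whole of 1986
#' parse_tap("from late 02.7")  # final third of July 2002, open start
#' parse_tap("postop")        # proximity hint, no interval
#' @export
parse_tap <- function(raw_text, anchor_date = NULL, lexicon = NULL,
                      pivot = 30L) {
  raw <- if (length(raw_text) == 0L || is.na(raw_text)) "" else as.character(raw_text)
  txt <- trimws(raw)
  if (!nzchar(txt)) return(new_anchor(raw, "missing"))

  m <- regmatches(txt, regexec("^(?i)(since|from)\\s+(.+)$", txt,
                               perl = TRUE))[[1]]
  if (length(m)) {
    inner <- parse_tap(m[3], anchor_date, lexicon, pivot)
    if (inner$kind %in% c("absolute", "relative")) {
      inner$raw_text <- raw
      inner$open_start <- TRUE
      return(inner)
    }
    return(new_anchor(raw, "proximity_hint"))
  }

  m <- regmatches(txt, regexec("^(?i)(early|mid|late)\\s+(.+)$", txt,
                               perl = TRUE))[[1]]
  if (length(m)) {
    inner <- parse_tap(m[3], anchor_date, lexicon, pivot)
    if (inner$kind %in% c("absolute", "relative") && !is.null(inner$interval)) {
      inner$raw_text <- raw
      return(apply_fuzzy_third(inner, tolower(m[2])))
    }
    return(new_anchor(raw, "proximity_hint"))
  }

  a <- parse_absolute(txt, pivot)
  if (!is.null(a)) { a$raw_text <- raw; return(a) }

  a <- parse_relative(txt, anchor_date)
  if (!is.null(a)) { a$raw_text <- raw; return(a) }

  if (!is.null(lexicon)) {
    hit <- lexicon[[tolower(txt)]]
    if (!is.null(hit)) {
      d <- as.POSIXlt(as.POSIXct(hit, tz = "UTC"), tz = "UTC")
      return(new_anchor(raw, "absolute", "day",
                        interval = interval_for_day(d$year + 1900L,
                                                    d$mon + 1L, d$mday)))
    }
  }
  new_anchor(raw, "proximity_hint")
}

has_interval <- function(anchor) {
  inherits(anchor, "temporal_anchor") && !is.null(anchor$interval)
}

# Integer index of a timestamp truncated to `unit`.
unit_index <- function(t, unit) {
  lt <- as.POSIXlt(t, tz = "UTC")
  switch(unit,
    years = lt$year + 1900,
    months = (lt$year + 1900) * 12 + lt$mon,
    days = floor(unclass(t) / 86400),
    hours = floor(unclass(t) / 3600),
    minutes = floor(unclass(t) / 60))
}

# Distance measurements use the finer of the two granularities, except that
# decade/year anchors are measured in months: the printed worked-example
# range (15y8m-16y7m between a bare year and a year.month) is a month count.
distance_unit <- function(ga, gb) {
  g <- if (GRANULARITY_ORDER[[ga]] >= GRANULARITY_ORDER[[gb]]) ga else gb
  switch(g, decade = "months", year = "months", month = "months",
         day = "days", hour = "hours", minute = "minutes", "months")
}

#' Possible temporal distance range between two anchors
#'
#' Both anchors' intervals are truncated to the finer of their two
#' granularities (year-level anchors measure in months); the bounds are the
#' smallest and largest whole-unit separations consistent with the two
#' possible time spans. Order of arguments does not affect the magnitude:
#' the earlier anchor is taken as the origin.
#'
#' @param a,b `temporal_anchor`s with resolved intervals.
#' @return A `duration_bounds` object: `min_units`, `max_units`, `unit`.
#' @examples
#' distance_bounds(parse_tap("86"), parse_tap("02.8"))  # 188..199 months
#' @export
distance_bounds <- function(a, b) {
  if (!has_interval(a)) stop("unresolved anchor: first argument ('",
                             a$raw_text, "') has no calendar interval")
  if (!has_interval(b)) stop("unresolved anchor: second argument ('",
                             b$raw_text, "') has no calendar interval")
  unit <- distance_unit(a$granularity, b$granularity)
  sa <- unit_index(a$interval$earliest, unit); ea <- unit_index(a$interval$latest, unit)
  sb <- unit_index(b$interval$earliest, unit); eb <- unit_index(b$interval$latest, unit)
  if (eb - sa < 0) { tmp <- sa; sa <- sb; sb <- tmp; tmp <- ea; ea <- eb; eb <- tmp }
  dmin <- max(0, sb - ea)
  dmax <- max(0, eb - sa)
  structure(list(min_units = as.numeric(dmin), max_units = as.numeric(dmax),
                 unit = unit),
            class = "duration_bounds")
}

#' @export
print.duration_bounds <- function(x, ...) {
  cat(sprintf("%g..%g %s\n", x$min_units, x$max_units, x$unit))
  invisible(x)
}

UNITS_PER_YEAR <- c(years = 1, months = 12, days = 365.25, hours = 8766,
                    minutes = 525960)

#' Rounded point estimate of the distance in years
#'
#' Midpoint of [distance_bounds()] converted to years (12 months per year)
#' and rounded half-up, matching the "about sixteen years" style of
#' estimate a reader makes from two anchors.
#'
#' @inheritParams distance_bounds
#' @return Integer number of years.
#' @examples
#' distance_estimate(parse_tap("86"), parse_tap("02.8"))  # 16
#' @export
distance_estimate <- function(a, b) {
  db <- distance_bounds(a, b)
  mid_years <- ((db$min_units + db$max_units) / 2) / UNITS_PER_YEAR[[db$unit]]
  as.integer(floor(mid_years + 0.5))
}

#' Qualitative temporal relation between two anchors
#'
#' @inheritParams distance_bounds
#' @return One of `"before"`, `"after"`, `"same_expression"`,
#'   `"undetermined"`. Identical verbatim expressions compare as
#'   `same_expression`; anchors without intervals (hints, missing) and
#'   overlapping intervals are `undetermined`.
#' @export
qualitative_relation <- function(a, b) {
  stopifnot(inherits(a, "temporal_anchor"), inherits(b, "temporal_anchor"))
  if (nzchar(a$raw_text) && identical(a$raw_text, b$raw_text)) {
    return("same_expression")
  }
  if (!has_interval(a) || !has_interval(b)) return("undetermined")
  if (a$interval$latest < b$interval$earliest) return("before")
  if (b$interval$latest < a$interval$earliest) return("after")
  "undetermined"
}

#' Problems precede their Actions within one v-structure
#'
#' The model's axiom: because a structure's Problem wing holds the causes
#' of its Action wing, a Problem starts before any Action of the same
#' structure even when both carry the same temporal expression. This holds
#' by construction; the function checks membership and returns `TRUE`.
#'
#' @param v A `v_structure`.
#' @param p,a [clinical_event()]s; `p` must be on `v`'s Problem wing and
#'   `a` on its Action wing.
#' @return `TRUE`.
#' @export
problem_precedes_action <- function(v, p, a) {
  stopifnot(inherits(v, "v_structure"))
  pids <- vapply(v$problems, `[[`, "", "event_id")
  aids <- vapply(v$actions, `[[`, "", "event_id")
  if (!(p$event_id %in% pids)) {
    stop("event '", p$event_id, "' is not on the Problem wing of structure '",
         v$structure_id, "'")
  }
  if (!(a$event_id %in% aids)) {
    stop("event '", a$event_id, "' is not on the Action wing of structure '",
         v$structure_id, "'")
  }
  TRUE
}
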