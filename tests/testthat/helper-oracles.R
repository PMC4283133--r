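# Independent brute-force oracles and fixture builders used across tests.

# --- interval-algebra oracle -------------------------------------------------
# Enumerates the unit-truncated endpoint combinations of two anchors and
# derives the distance range and qualitative relation from the enumeration,
# independently of the package's closed-form path.

oracle_unit <- function(ga, gb) {
  rank <- c(decade = 1, year = 2, month = 3, day = 4, hour = 5, minute = 6)
  finer <- if (rank[[ga]] >= rank[[gb]]) ga else gb
  c(decade = "months", year = "months", month = "months", day = "days",
    hour = "hours", minute = "minutes")[[finer]]
}

oracle_index <- function(t, unit) {
  lt <- as.POSIXlt(t, tz = "UTC")
  switch(unit,
         months = (lt$year + 1900) * 12 + lt$mon,
         days = floor(as.numeric(t) / 86400),
         hours = floor(as.numeric(t) / 3600),
         minutes = floor(as.numeric(t) / 60))
}

oracle_bounds <- function(a, b) {
  unit <- oracle_unit(a$granularity, b$granularity)
  ia <- vapply(list(a$interval$earliest, a$interval$latest), oracle_index,
               0, unit = unit)
  ib <- vapply(list(b$interval$earliest, b$interval$latest), oracle_index,
               0, unit = unit)
  combos <- as.vector(outer(ib, ia, `-`))  # every (b endpoint - a endpoint)
  if (max(combos) < 0) combos <- -combos   # orient from the earlier anchor
  list(min_units = max(0, min(combos)), max_units = max(0, max(combos)),
       unit = unit)
}

oracle_relation <- function(a, b) {
  if (nzchar(a$raw_text) && identical(a$raw_text, b$raw_text)) {
    return("same_expression")
  }
  if (is.null(a$interval) || is.null(b$interval)) return("undetermined")
  ea <- as.numeric(c(a$interval$earliest, a$interval$latest))
  eb <- as.numeric(c(b$interval$earliest, b$interval$latest))
  if (max(ea) < min(eb)) "before" else if (max(eb) < min(ea)) "after"
  else "undetermined"
}

# Random anchors drawn from the temporal dialect.
random_anchor_string <- function() {
  y <- sample(1975:2024, 1)
  yy <- sprintf("%02d", y %% 100)
  mo <- sample(1:12, 1)
  d <- sample(1:28, 1)
  base <- switch(sample(4, 1),
                 sprintf("%d", y),
                 sprintf("%s.%d", yy, mo),
                 sprintf("%s.%d.%d", yy, mo, d),
                 sprintf("%d days ago", sample(1:900, 1)))
  pre <- sample(c("", "", "", "early ", "mid ", "late ", "from ", "since "), 1)
  paste0(pre, base)
}

random_anchor_pool <- function(n, anchor_date = as.Date("2003-05-10")) {
  pool <- lapply(seq_len(n), function(i)
    parse_tap(random_anchor_string(), anchor_date))
  pool[vapply(pool, function(a) !is.null(a$interval), FALSE)]
}

# --- pattern-mining fixtures and oracle -------------------------------------

# Build a timeline whose context blocks are exactly the given shapes, each
# shape list(p = problem tag, a = action tags), one v-structure per block.
make_blocks_timeline <- function(pid, shapes) {
  events <- list()
  k <- 0L
  for (b in seq_along(shapes)) {
    sh <- shapes[[b]]
    raw <- sprintf("%02d.%d", (95 + (b - 1) %/% 12) %% 100, (b - 1) %% 12 + 1)
    aids <- sprintf("%s_a%d_%d", pid, b, seq_along(sh$a))
    k <- k + 1L
    events[[length(events) + 1L]] <- clinical_event(
      sprintf("%s_p%d", pid, b), sprintf("%s_%d", sh$p, k), sh$p,
      raw_time = raw, appearance_index = k, causal_links = aids)
    for (j in seq_along(sh$a)) {
      k <- k + 1L
      events[[length(events) + 1L]] <- clinical_event(
        aids[j], sprintf("%s_%d", sh$a[j], k), sh$a[j], raw_time = raw,
        appearance_index = k)
    }
  }
  build_timeline(events, patient_id = pid)
}

shape_key <- function(sh) sprintf("P{%s}A{%s}", sh$p,
                                  paste(sort(sh$a), collapse = ","))

# Sliding-window scan written independently of find_matches.
oracle_matches <- function(keys, pat) {
  L <- length(pat)
  if (length(keys) < L) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(length(keys) - L + 1)) {
    same <- TRUE
    for (j in seq_len(L)) if (keys[i + j - 1] != pat[j]) { same <- FALSE; break }
    if (same) hits <- c(hits, i)
  }
  hits
}

# Exhaustive rule enumeration: every contiguous n-gram of every target
# timeline, bare and with every admissible single exclusion clause, with
# supports computed by direct scanning. Returns serialized rules.
oracle_mine <- function(tkeys, bkeys, min_support, max_len) {
  ngrams_of <- function(keys) {
    out <- list()
    for (L in seq_len(min(max_len, length(keys)))) {
      for (i in seq_len(length(keys) - L + 1)) {
        out[[length(out) + 1L]] <- keys[i:(i + L - 1)]
      }
    }
    unique(out)
  }
  all_t <- unique(do.call(c, lapply(tkeys, function(k) ngrams_of(k))))
  sup <- function(pat, keysets) mean(vapply(keysets, function(k)
    length(oracle_matches(k, pat)) > 0, FALSE))
  rules <- list()
  add_rule <- function(pat, excl) {
    matches <- function(keys) {
      inc <- oracle_matches(keys, pat)
      if (!length(inc)) return(FALSE)
      ends <- integer(0)
      for (e in excl) {
        st <- oracle_matches(keys, e)
        ends <- c(ends, st + length(e) - 1L)
      }
      any(vapply(inc, function(m) !any(ends < m), FALSE))
    }
    st <- mean(vapply(tkeys, matches, FALSE))
    if (st < min_support) return()
    sb <- mean(vapply(bkeys, matches, FALSE))
    rules[[length(rules) + 1L]] <<- list(
      include = pat, exclude = excl, support_target = st,
      support_background = sb)
  }
  for (pat in all_t) {
    if (sup(pat, tkeys) < min_support) next
    add_rule(pat, list())
    bg_m <- bkeys[vapply(bkeys, function(k)
      length(oracle_matches(k, pat)) > 0, FALSE)]
    if (!length(bg_m)) next
    cand <- unique(do.call(c, lapply(bg_m, function(k) ngrams_of(k))))
    for (pre in cand) {
      if (identical(pre, pat)) next
      if (sup(pre, bg_m) < min_support) next
      occurs_before <- any(vapply(bg_m, function(k) {
        inc <- oracle_matches(k, pat)
        st <- oracle_matches(k, pre)
        length(inc) > 0 && length(st) > 0 &&
          any(outer(st + length(pre) - 1L, inc, `<`))
      }, FALSE))
      if (occurs_before) add_rule(pat, list(pre))
    }
  }
  rules
}

serialize_rule <- function(include, exclusions) {
  paste(paste(include, collapse = "\x1f"),
        paste(vapply(exclusions, paste, "", collapse = "\x1f"),
              collapse = "\x1e"), sep = "\x1d")
}
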