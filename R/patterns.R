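# Context-block pattern recognition: abstract signatures of causally
# linked runs of v-structures, matching of block n-grams across patient
# timelines, and induction of include / exclude-preceding phenotype
# candidate rules by contrasting a target cohort with a background group.

#' Abstract signature of a context block
#'
#' Projects a block onto the multisets of its wing contents, one entry per
#' structure, preserving structure order but ignoring order within a wing.
#' In `semantic_type` mode two blocks with the same tag profile compare
#' equal regardless of event text; `concept_label` mode compares the event
#' texts themselves.
#'
#' @param block A `context_block` from [extract_context_blocks()].
#' @param timeline The timeline the block came from.
#' @param mode `"semantic_type"` or `"concept_label"`.
#' @return A `block_signature`: list of per-structure
#'   `list(problems=, actions=)` sorted character vectors, with a canonical
#'   string `key` attribute used for equality and deterministic ordering.
#' @export
block_signature <- function(block, timeline, mode = c("semantic_type",
                                                      "concept_label")) {
  mode <- match.arg(mode)
  proj <- function(evs) {
    v <- vapply(evs, `[[`, "",
                if (mode == "semantic_type") "semantic_type" else "text")
    sort(v, method = "radix")
  }
  per <- lapply(timeline$structures[block$structure_index], function(s)
    list(problems = proj(s$problems), actions = proj(s$actions)))
  structure(per, class = "block_signature", mode = mode,
            key = paste(vapply(per, function(p) sprintf(
      "P{%s}A{%s}", paste(p$problems, collapse = ","),
      paste(p$actions, collapse = ",")), ""), collapse = "+"))
}

signature_key <- function(x) {
  if (!is.null(attr(x, "key"))) attr(x, "key") else as.character(x)
}

# Canonical block-signature keys of a timeline, in block order.
timeline_block_keys <- function(timeline, mode = "semantic_type") {
  blocks <- extract_context_blocks(timeline)
  vapply(blocks, function(b) signature_key(block_signature(b, timeline, mode)),
         "")
}

#' Pattern signature over consecutive context blocks
#'
#' @param block_keys Character vector of canonical block keys (one per
#'   block, consecutive, no gap).
#' @return A `pattern_signature`.
#' @export
pattern_signature <- function(block_keys) {
  stopifnot(length(block_keys) >= 1L)
  structure(list(blocks = as.character(block_keys)),
            class = "pattern_signature")
}

#' @export
print.pattern_signature <- function(x, ...) {
  cat("<pattern> ", paste(x$blocks, collapse = " >> "), "\n", sep = "")
  invisible(x)
}

#' Find matches of a pattern in a timeline
#'
#' A match is a run of consecutive context blocks (directly following,
#' no intervening block) whose signatures equal the pattern's. Overlapping
#' matches are all reported.
#'
#' @param timeline A [patient_timeline()].
#' @param signature A [pattern_signature()] or character vector of block
#'   keys.
#' @param mode Signature abstraction mode, as in [block_signature()].
#' @return Integer vector of starting block positions (1-based).
#' @export
find_matches <- function(timeline, signature, mode = "semantic_type") {
  pat <- if (inherits(signature, "pattern_signature")) signature$blocks else
    as.character(signature)
  keys <- timeline_block_keys(timeline, mode)
  L <- length(pat)
  n <- length(keys)
  if (L < 1L || n < L) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - L + 1L)) {
    if (all(keys[i:(i + L - 1L)] == pat)) starts <- c(starts, i)
  }
  starts
}

#' Phenotype candidate rule
#'
#' A cohort-selection rule induced from timeline patterns: a patient is
#' selected when the `include` pattern occurs with no `exclude_preceding`
#' pattern ending before that occurrence, optionally restricted to
#' occurrences whose first temporal anchor lies within `temporal_constraint`
#' of the patient's first structure.
#'
#' @param include A [pattern_signature()].
#' @param exclude_preceding List of [pattern_signature()]s.
#' @param temporal_constraint Optional `duration_bounds` window measured
#'   from the patient's first resolvable anchor.
#' @return A `phenotype_rule`.
#' @export
phenotype_rule <- function(include, exclude_preceding = list(),
                           temporal_constraint = NULL) {
  if (!inherits(include, "pattern_signature")) include <-
      pattern_signature(include)
  exclude_preceding <- lapply(exclude_preceding, function(e)
    if (inherits(e, "pattern_signature")) e else pattern_signature(e))
  structure(list(include = include, exclude_preceding = exclude_preceding,
                 temporal_constraint = temporal_constraint),
            class = "phenotype_rule")
}

#' @export
print.phenotype_rule <- function(x, ...) {
  cat("<rule> include:", paste(x$include$blocks, collapse = " >> "), "\n")
  for (e in x$exclude_preceding) {
    cat("  exclude preceding:", paste(e$blocks, collapse = " >> "), "\n")
  }
  if (!is.null(x$temporal_constraint)) {
    cat(sprintf("  within %g..%g %s of first anchor\n",
                x$temporal_constraint$min_units,
                x$temporal_constraint$max_units, x$temporal_constraint$unit))
  }
  invisible(x)
}

first_block_anchor <- function(timeline, block_pos) {
  blocks <- extract_context_blocks(timeline)
  if (block_pos > length(blocks)) return(NULL)
  timeline$structures[[blocks[[block_pos]]$structure_index[1]]]$tap
}

rule_matches_patient <- function(rule, timeline, mode = "semantic_type") {
  inc <- find_matches(timeline, rule$include, mode)
  if (!length(inc)) return(list(match = FALSE, indeterminate = FALSE))
  excl_ends <- integer(0)
  for (e in rule$exclude_preceding) {
    st <- find_matches(timeline, e, mode)
    if (length(st)) excl_ends <- c(excl_ends, st + length(e$blocks) - 1L)
  }
  indeterminate <- FALSE
  for (m in inc) {
    if (length(excl_ends) && any(excl_ends < m)) next
    if (!is.null(rule$temporal_constraint)) {
      ref <- NULL
      for (s in timeline$structures) {
        if (has_interval(s$tap)) { ref <- s$tap; break }
      }
      at <- first_block_anchor(timeline, m)
      if (is.null(ref) || is.null(at) || !has_interval(at)) {
        indeterminate <- TRUE
        next
      }
      db <- distance_bounds(ref, at)
      tc <- rule$temporal_constraint
      f <- UNITS_PER_YEAR[[db$unit]] / UNITS_PER_YEAR[[tc$unit]]
      lo <- db$min_units / f; hi <- db$max_units / f
      if (hi < tc$min_units || lo > tc$max_units) next
    }
    return(list(match = TRUE, indeterminate = FALSE))
  }
  list(match = FALSE, indeterminate = indeterminate)
}

#' Evaluate a phenotype rule over timelines
#'
#' @param rule A [phenotype_rule()].
#' @param timelines List of [patient_timeline()]s.
#' @param labels Optional logical vector: `TRUE` for patients that belong
#'   to the target cohort. When given, a confusion matrix over patients is
#'   reported.
#' @param mode Signature abstraction mode.
#' @return List with `match` (named logical per patient), `indeterminate`
#'   (patients whose anchors cannot support the temporal constraint,
#'   reported separately, counted as non-matching), and `confusion`
#'   (`tp`, `fp`, `fn`, `tn`) when `labels` is given.
#' @export
evaluate_rule <- function(rule, timelines, labels = NULL,
                          mode = "semantic_type") {
  res <- lapply(timelines, rule_matches_patient, rule = rule, mode = mode)
  match <- vapply(res, `[[`, FALSE, "match")
  indet <- vapply(res, `[[`, FALSE, "indeterminate")
  names(match) <- names(indet) <-
    vapply(timelines, `[[`, "", "patient_id")
  out <- list(match = match, indeterminate = names(indet)[indet])
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(timelines))
    out$confusion <- c(tp = sum(match & labels), fp = sum(match & !labels),
                       fn = sum(!match & labels), tn = sum(!match & !labels))
  }
  out
}

# All contiguous block n-grams (as key vectors) of a set of timelines, up
# to max_len, with per-patient presence.
enumerate_ngrams <- function(key_lists, max_len) {
  seen <- new.env(parent = emptyenv())
  for (p in seq_along(key_lists)) {
    keys <- key_lists[[p]]
    n <- length(keys)
    for (L in seq_len(min(max_len, n))) {
      for (i in seq_len(n - L + 1L)) {
        gram <- keys[i:(i + L - 1L)]
        id <- paste(gram, collapse = "\x1f")
        hit <- get0(id, envir = seen)
        if (is.null(hit)) {
          assign(id, list(gram = gram, patients = p), envir = seen)
        } else {
          hit$patients <- union(hit$patients, p)
          assign(id, hit, envir = seen)
        }
      }
    }
  }
  out <- as.list(seen)
  out[order(names(out), method = "radix")]
}

support_of <- function(pat, key_lists) {
  hits <- vapply(key_lists, function(keys) {
    L <- length(pat); n <- length(keys)
    if (n < L) return(FALSE)
    for (i in seq_len(n - L + 1L)) {
      if (all(keys[i:(i + L - 1L)] == pat)) return(TRUE)
    }
    FALSE
  }, FALSE)
  mean(hits)
}

# Does `pre` occur ending strictly before some occurrence of `pat`?
precedes_somewhere <- function(pre, pat, keys) {
  n <- length(keys)
  pat_starts <- integer(0)
  if (n >= length(pat)) {
    for (i in seq_len(n - length(pat) + 1L)) {
      if (all(keys[i:(i + length(pat) - 1L)] == pat)) {
        pat_starts <- c(pat_starts, i)
      }
    }
  }
  if (!length(pat_starts)) return(FALSE)
  if (n >= length(pre)) {
    for (i in seq_len(n - length(pre) + 1L)) {
      if (all(keys[i:(i + length(pre) - 1L)] == pre)) {
        if (any(i + length(pre) - 1L < pat_starts)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Mine include/exclude phenotype candidate rules
#'
#' Enumerates contiguous context-block signature n-grams in the target
#' cohort, keeps those reaching `min_support_target`, and, for kept
#' patterns that also occur in the background group, searches for patterns
#' frequently preceding them there to form exclude-preceding clauses — the
#' "includes pattern A but excludes pattern A following pattern B" shape of
#' rule. Results are ranked by target support (descending), background
#' support (ascending), include-pattern length (descending), exclusion
#' specificity (total exclusion length, descending), then lexicographically
#' on the serialized signature for determinism.
#'
#' @param target,background Nonempty lists of [patient_timeline()]s.
#' @param min_support_target Minimum fraction of target patients containing
#'   the include pattern, in (0, 1].
#' @param max_len Maximum pattern length in blocks.
#' @param mode Signature abstraction mode.
#' @return List of `mining_result`s: `rule`, `support_target`,
#'   `support_background`, `confusion` over all patients (target = positive).
#' @export
mine_rules <- function(target, background, min_support_target = 0.8,
                       max_len = 3L, mode = "semantic_type") {
  if (!length(target)) stop("target group is empty")
  if (!length(background)) stop("background group is empty")
  stopifnot(min_support_target > 0, min_support_target <= 1, max_len >= 1L)
  tkeys <- lapply(target, timeline_block_keys, mode = mode)
  bkeys <- lapply(background, timeline_block_keys, mode = mode)

  grams <- enumerate_ngrams(tkeys, max_len)
  results <- list()
  for (g in grams) {
    pat <- g$gram
    st <- length(g$patients) / length(tkeys)
    if (st < min_support_target) next
    candidates <- list(list())  # bare rule, no exclusion
    bg_matchers <- which(vapply(bkeys, function(k)
      support_of(pat, list(k)) > 0, FALSE))
    if (length(bg_matchers)) {
      # exclusion candidates: patterns frequent among background matchers
      # of the include pattern, occurring there before it
      bg_grams <- enumerate_ngrams(bkeys[bg_matchers], max_len)
      for (bg in bg_grams) {
        sup_bg <- length(bg$patients) / length(bg_matchers)
        if (sup_bg < min_support_target) next
        if (identical(bg$gram, pat)) next
        prec <- vapply(bkeys[bg_matchers], precedes_somewhere,
                       FALSE, pre = bg$gram, pat = pat)
        if (any(prec)) {
          candidates <- c(candidates, list(list(bg$gram)))
        }
      }
    }
    for (excl in candidates) {
      rule <- phenotype_rule(pattern_signature(pat),
                             lapply(excl, pattern_signature))
      ev <- evaluate_rule(rule, c(target, background),
                          labels = c(rep(TRUE, length(target)),
                                     rep(FALSE, length(background))),
                          mode = mode)
      s_t <- mean(ev$match[seq_along(target)])
      if (s_t < min_support_target) next
      s_b <- mean(ev$match[length(target) + seq_along(background)])
      results[[length(results) + 1L]] <- structure(list(
        rule = rule, support_target = s_t, support_background = s_b,
        confusion = ev$confusion), class = "mining_result")
    }
  }
  if (!length(results)) return(list())
  ser <- vapply(results, function(r) paste(
    paste(r$rule$include$blocks, collapse = "\x1f"),
    paste(vapply(r$rule$exclude_preceding, function(e)
      paste(e$blocks, collapse = "\x1f"), ""), collapse = "\x1e"),
    sep = "\x1d"), "")
  st <- vapply(results, `[[`, 0, "support_target")
  sb <- vapply(results, `[[`, 0, "support_background")
  len <- vapply(results, function(r) length(r$rule$include$blocks), 0L)
  xlen <- vapply(results, function(r)
    sum(vapply(r$rule$exclude_preceding, function(e)
      length(e$blocks), 0L)), 0L)
  results[order(-st, sb, -len, -xlen, ser, method = "radix")]
}

#' @export
print.mining_result <- function(x, ...) {
  print(x$rule)
  cat(sprintf("  support target %.2f, background %.2f; tp=%d fp=%d fn=%d tn=%d\n",
              x$support_target, x$support_background, x$confusion[["tp"]],
              x$confusion[["fp"]], x$confusion[["fn"]], x$confusion[["tn"]]))
  invisible(x)
}
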