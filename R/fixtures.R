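# Synthetic data: seeded cohort generation with planted context-block
# patterns (the target-vs-background phenotyping scenario), plus the
# packaged worked-example timeline used across the documentation and
# tests. Event texts are template strings ("Sx_17"), never realistic
# clinical content.

#' Specification of a synthetic cohort
#'
#' Describes two patient groups — a target cohort and a background group —
#' whose timelines are sequences of context blocks (each block one
#' Problem-Action v-structure). A planted pattern occurs in a controlled
#' fraction of a group's timelines; the confounded scenario additionally
#' plants a confounder pattern before the planted one in the background
#' group, the situation that forces an exclude-preceding clause.
#'
#' @param n_target,n_background Number of patients per group.
#' @param blocks_per_timeline Integer range `c(min, max)` of blocks.
#' @param planted_support Fraction of target timelines containing the
#'   planted pattern.
#' @param confounded Plant the confounder-then-pattern sequence in
#'   background timelines (otherwise the background gets noise only).
#' @param background_pattern_support Fraction of background timelines
#'   receiving the planted pattern (preceded by the confounder when
#'   `confounded`).
#' @param noise_block_rate Probability that any remaining slot holds a
#'   noise block drawn from the noise vocabulary (otherwise a common
#'   filler block).
#' @param tap_granularity_mix Named probabilities over
#'   `c(year, month, day, relative, hint_extra)` steering the temporal
#'   expressions written on block anchors (`hint_extra` adds an untimed
#'   trailing event to the block rather than a new anchor form).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_target = 5L, n_background = 5L,
                        blocks_per_timeline = c(4L, 8L),
                        planted_support = 1.0,
                        confounded = TRUE,
                        background_pattern_support = 1.0,
                        noise_block_rate = 0.6,
                        tap_granularity_mix = c(year = 0.15, month = 0.55,
                                                day = 0.2, relative = 0.05,
                                                hint_extra = 0.05),
                        seed = 1L) {
  stopifnot(n_target >= 1L, n_background >= 1L,
            length(blocks_per_timeline) == 2L,
            blocks_per_timeline[1] >= 1L,
            blocks_per_timeline[1] <= blocks_per_timeline[2],
            planted_support >= 0, planted_support <= 1,
            background_pattern_support >= 0,
            background_pattern_support <= 1,
            noise_block_rate >= 0, noise_block_rate <= 1)
  mix <- tap_granularity_mix / sum(tap_granularity_mix)
  structure(list(n_target = as.integer(n_target),
                 n_background = as.integer(n_background),
                 blocks_per_timeline = as.integer(blocks_per_timeline),
                 planted_support = planted_support,
                 confounded = isTRUE(confounded),
                 background_pattern_support = background_pattern_support,
                 noise_block_rate = noise_block_rate,
                 tap_granularity_mix = mix,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Block vocabulary: each entry is the (problem tag, action tags) content of
# one v-structure. The planted pattern is the two-block sequence A1, A2;
# the confounder is C1, C2 sharing A's first block shape, differing in the
# second — the red/green vs red/blue contrast.
PLANTED_BLOCKS <- list(
  A1 = list(problem = "Sx", actions = c("Test")),
  A2 = list(problem = "Purpose", actions = c("Tx", "Drug")))
CONFOUNDER_BLOCKS <- list(
  C1 = list(problem = "Sx", actions = c("Test")),
  C2 = list(problem = "Finding", actions = c("Op")))
NOISE_BLOCKS <- list(
  list(problem = "Sx", actions = c("Drug")),
  list(problem = "Purpose", actions = c("Test", "Test")),
  list(problem = "Sx", actions = c("Op", "Tx")),
  list(problem = "Finding", actions = c("Drug", "Drug")),
  list(problem = "Sx", actions = c("Plan")))
FILLER_BLOCK <- list(problem = "Purpose", actions = c("Other"))

# Raw temporal expression for block b of a synthetic timeline, advancing
# one month per block from 1998.1 so the anchors stay chronological and
# every expression is unique within the patient. Relative forms resolve
# (against the generator's fixed anchor date) to a day inside block b's
# month, and bare-year forms fall in the 1980s, so chronological
# reordering never splits a planted pair of adjacent blocks.
SYNTH_ANCHOR_DATE <- as.Date("1999-06-15")

synth_raw_time <- function(b, form) {
  k <- (b - 1L)
  y <- 1998L + k %/% 12L
  mo <- k %% 12L + 1L
  yy <- sprintf("%02d", y %% 100L)
  if (form == "relative") {
    days_ago <- as.integer(SYNTH_ANCHOR_DATE - as.Date(sprintf(
      "%04d-%02d-15", y, mo)))
    if (days_ago < 1L) form <- "month"
    else return(sprintf("%d days ago", days_ago))
  }
  switch(form,
         year = sprintf("%d", 1980L + b),      # distinct bare years
         month = sprintf("%s.%d", yy, mo),
         day = sprintf("%s.%d.%d", yy, mo, (b * 7L) %% 27L + 1L),
         sprintf("%s.%d", yy, mo))
}

make_block_events <- function(block, b, pid, raw_time, counter) {
  evs <- list()
  p_id <- sprintf("%s_e%d", pid, counter); counter <- counter + 1L
  a_ids <- character(0)
  for (atag in block$actions) {
    a_ids <- c(a_ids, sprintf("%s_e%d", pid, counter))
    counter <- counter + 1L
  }
  evs[[1]] <- clinical_event(p_id, sprintf("%s_%d", block$problem, counter),
                             block$problem, raw_time = raw_time,
                             appearance_index = counter * 10L,
                             causal_links = a_ids)
  for (i in seq_along(block$actions)) {
    evs[[i + 1L]] <- clinical_event(
      a_ids[i], sprintf("%s_%d", block$actions[i], counter + i),
      block$actions[i], raw_time = raw_time,
      appearance_index = counter * 10L + i)
  }
  list(events = evs, counter = counter + length(block$actions) + 1L)
}

generate_timeline <- function(pid, n_blocks, planted_at, confounder_at,
                              spec, pidx = 1L) {
  blocks <- vector("list", n_blocks)
  forms <- sample(names(spec$tap_granularity_mix), n_blocks, replace = TRUE,
                  prob = spec$tap_granularity_mix)
  fixed <- integer(0)
  if (!is.null(planted_at)) {
    blocks[[planted_at]] <- PLANTED_BLOCKS$A1
    blocks[[planted_at + 1L]] <- PLANTED_BLOCKS$A2
    fixed <- c(fixed, planted_at, planted_at + 1L)
  }
  if (!is.null(confounder_at)) {
    blocks[[confounder_at]] <- CONFOUNDER_BLOCKS$C1
    blocks[[confounder_at + 1L]] <- CONFOUNDER_BLOCKS$C2
    fixed <- c(fixed, confounder_at, confounder_at + 1L)
  }
  # planted blocks keep plain month anchors so their block signatures stay
  # exactly the planted shape
  forms[fixed] <- "month"
  # slots adjacent to a planted/confounder run take a patient-rotated noise
  # block: small cohorts then never share a longer super-pattern by accident
  adjacent <- setdiff(unique(c(fixed - 1L, fixed + 1L)),
                      c(fixed, 0L, n_blocks + 1L))
  for (b in adjacent) {
    blocks[[b]] <- NOISE_BLOCKS[[(pidx - 1L) %% length(NOISE_BLOCKS) + 1L]]
  }
  for (b in seq_len(n_blocks)) {
    if (is.null(blocks[[b]])) {
      blocks[[b]] <- if (stats::runif(1) < spec$noise_block_rate) {
        NOISE_BLOCKS[[sample.int(length(NOISE_BLOCKS), 1L)]]
      } else {
        FILLER_BLOCK
      }
    }
  }
  events <- list()
  counter <- 1L
  for (b in seq_len(n_blocks)) {
    form <- forms[b]
    raw <- synth_raw_time(b, if (form == "hint_extra") "month" else form)
    made <- make_block_events(blocks[[b]], b, pid, raw, counter)
    counter <- made$counter
    events <- c(events, made$events)
    if (form == "hint_extra") {
      # an untimed trailing event inherits the block's anchor
      events[[length(events) + 1L]] <- clinical_event(
        sprintf("%s_e%d", pid, counter), sprintf("Other_%d", counter),
        "Other", raw_time = "", appearance_index = counter * 10L + 5L)
      counter <- counter + 1L
    }
  }
  # bare-year anchors deliberately appear out of document order; the
  # assembler's chronological correction is part of what is being emulated
  suppressWarnings(
    build_timeline(events, anchor_date = SYNTH_ANCHOR_DATE,
                   patient_id = pid))
}

#' Generate a synthetic two-group cohort
#'
#' Seeded and reproducible: the same spec yields byte-identical cohorts.
#' The planted two-block pattern is inserted at a random position in
#' `ceiling(planted_support * n_target)` target timelines; in the
#' confounded scenario, background timelines receive the confounder blocks
#' directly before the planted pattern, so the planted pattern alone does
#' not separate the groups but an exclude-preceding rule does.
#'
#' @param spec A [cohort_spec()].
#' @return List with `target` and `background` lists of
#'   [patient_timeline()]s, plus `planted` and `confounder`
#'   [pattern_signature()]s describing what was planted.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$blocks_per_timeline[1] < 2L) {
    stop("infeasible spec: planted pattern spans 2 blocks but timelines may have fewer")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  n_planted <- ceiling(spec$planted_support * spec$n_target)
  planted_in <- if (n_planted > 0)
    sort(sample.int(spec$n_target, n_planted)) else integer(0)
  n_bg_pat <- ceiling(spec$background_pattern_support * spec$n_background)
  bg_pat_in <- if (n_bg_pat > 0)
    sort(sample.int(spec$n_background, n_bg_pat)) else integer(0)

  target <- lapply(seq_len(spec$n_target), function(i) {
    nb <- sample(seq(spec$blocks_per_timeline[1],
                     spec$blocks_per_timeline[2]), 1L)
    planted_at <- if (i %in% planted_in) sample.int(nb - 1L, 1L) else NULL
    generate_timeline(sprintf("t%02d", i), nb, planted_at, NULL, spec,
                      pidx = i)
  })
  background <- lapply(seq_len(spec$n_background), function(i) {
    need <- if (spec$confounded) 4L else 2L
    nb <- sample(seq(max(spec$blocks_per_timeline[1], need),
                     max(spec$blocks_per_timeline[2], need)), 1L)
    if (i %in% bg_pat_in) {
      if (spec$confounded) {
        conf_at <- sample.int(nb - 3L, 1L)
        generate_timeline(sprintf("b%02d", i), nb, conf_at + 2L, conf_at,
                          spec, pidx = i)
      } else {
        generate_timeline(sprintf("b%02d", i), nb,
                          sample.int(nb - 1L, 1L), NULL, spec, pidx = i)
      }
    } else {
      generate_timeline(sprintf("b%02d", i), nb, NULL, NULL, spec, pidx = i)
    }
  })

  mk_key <- function(block) sprintf(
    "P{%s}A{%s}", block$problem,
    paste(sort(block$actions, method = "radix"), collapse = ","))
  list(target = target, background = background,
       planted = pattern_signature(vapply(PLANTED_BLOCKS, mk_key, "")),
       confounder = pattern_signature(vapply(CONFOUNDER_BLOCKS, mk_key, "")))
}

#' The packaged worked-example timeline
#'
#' A gastric-cancer history fragment used throughout the documentation: a
#' total gastrectomy with Roux-en-Y anastomosis in '86; chief complaints
#' from late July 2002 linked to the August 2002 workup (brain MRI, a
#' rule-out diagnosis, and a near-total resection of the tumor); and FAM
#' chemotherapy placed only by the proximity expression "postop". The
#' complaint-to-MRI link spans structures, so the July and August
#' structures form one context block.
#'
#' @return A validated [patient_timeline()] of four v-structures.
#' @export
worked_example_timeline <- function() {
  events <- list(
    clinical_event("op86", "TG c Roux-en-Y anastomosis", "Op",
                   raw_time = "86", appearance_index = 1L),
    clinical_event("cc1", "headache", "Sx", raw_time = "from late 02.7",
                   appearance_index = 2L),
    clinical_event("cc2", "dizziness", "Sx", raw_time = "",
                   appearance_index = 3L),
    clinical_event("mri", "Br. MRI", "Test", raw_time = "02.8",
                   appearance_index = 4L),
    clinical_event("dx", "r/o CRP diagnosis", "Dx", raw_time = "",
                   appearance_index = 5L),
    clinical_event("ntr", "NTR of tm.", "Op", raw_time = "",
                   appearance_index = 6L),
    clinical_event("fam", "FAM", "Tx", raw_time = "postop",
                   appearance_index = 7L))
  tl <- build_timeline(events, patient_id = "example")
  link_problem_to_later_action(tl, "cc1", "mri")
}
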