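sx_test <- list(p = "Sx", a = "Test")
purpose_chemo <- list(p = "Purpose", a = c("Tx", "Drug"))
finding_op <- list(p = "Finding", a = "Op")
sx_drug <- list(p = "Sx", a = "Drug")

test_that("block signatures abstract wings as order-free multisets", {
  tl <- make_blocks_timeline("p", list(list(p = "Sx", a = c("Test", "Test"))))
  b <- extract_context_blocks(tl)[[1]]
  sig <- block_signature(b, tl)
  expect_length(sig, 1L)
  expect_equal(sig[[1]]$problems, "Sx")
  expect_equal(sig[[1]]$actions, c("Test", "Test"))
  expect_equal(attr(sig, "key"), "P{Sx}A{Test,Test}")

  # permuting events within a wing leaves the signature unchanged
  tl2 <- make_blocks_timeline("q", list(list(p = "Sx", a = c("Tx", "Drug"))))
  tl3 <- make_blocks_timeline("r", list(list(p = "Sx", a = c("Drug", "Tx"))))
  k2 <- attr(block_signature(extract_context_blocks(tl2)[[1]], tl2), "key")
  k3 <- attr(block_signature(extract_context_blocks(tl3)[[1]], tl3), "key")
  expect_equal(k2, k3)

  # concept mode distinguishes texts that tag mode merges
  tlA <- make_blocks_timeline("a", list(sx_test))
  key_tag <- attr(block_signature(extract_context_blocks(tlA)[[1]], tlA,
                                  "semantic_type"), "key")
  key_txt <- attr(block_signature(extract_context_blocks(tlA)[[1]], tlA,
                                  "concept_label"), "key")
  expect_false(identical(key_tag, key_txt))
})

test_that("a multi-structure block keeps structure order in its signature", {
  # two linked structures: cross-link binds them into one block
  ev <- list(
    clinical_event("p1", "cc", "Sx", raw_time = "02.7",
                   appearance_index = 1L),
    clinical_event("a1", "MRI", "Test", raw_time = "02.8",
                   appearance_index = 2L))
  tl <- build_timeline(ev, patient_id = "p")
  tl <- link_problem_to_later_action(tl, "p1", "a1")
  blocks <- extract_context_blocks(tl)
  expect_length(blocks, 1L)
  sig <- block_signature(blocks[[1]], tl)
  expect_length(sig, 2L)
  expect_equal(attr(sig, "key"), "P{Sx}A{}+P{}A{Test}")
})

test_that("find_matches agrees with a sliding-window oracle", {
  set.seed(31)
  vocab <- list(sx_test, purpose_chemo, finding_op, sx_drug)
  for (trial in 1:25) {
    shapes <- vocab[sample.int(4, sample(3:8, 1), replace = TRUE)]
    tl <- make_blocks_timeline(sprintf("p%d", trial), shapes)
    keys <- vapply(shapes, shape_key, "")
    for (L in 1:3) {
      start <- sample.int(max(length(shapes) - L + 1, 1), 1)
      pat <- keys[start:(start + L - 1)]
      expect_equal(find_matches(tl, pat), oracle_matches(keys, pat))
    }
    # a pattern absent from the timeline
    expect_equal(find_matches(tl, c("P{Dx}A{Plan}")), integer(0))
  }
})

test_that("overlapping and separated occurrences are reported faithfully", {
  tl <- make_blocks_timeline("p", list(sx_test, sx_test, sx_test))
  k <- shape_key(sx_test)
  expect_equal(find_matches(tl, c(k, k)), c(1L, 2L))  # overlapping
  tl2 <- make_blocks_timeline("q", list(sx_test, finding_op, sx_test))
  expect_equal(find_matches(tl2, c(k, k)), integer(0))  # separated
  expect_equal(find_matches(tl2, k), c(1L, 3L))
})

test_that("rule evaluation honors exclusion and temporal windows", {
  A <- shape_key(sx_test)
  B <- shape_key(finding_op)
  tl_a <- make_blocks_timeline("pa", list(sx_drug, sx_test))
  tl_ba <- make_blocks_timeline("pb", list(finding_op, sx_test))
  rule <- phenotype_rule(A, list(B))
  ev <- evaluate_rule(rule, list(tl_a, tl_ba), labels = c(TRUE, FALSE))
  expect_equal(unname(ev$match), c(TRUE, FALSE))
  expect_equal(ev$confusion, c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  # consistency with find_matches for bare include rules
  bare <- phenotype_rule(A)
  for (tl in list(tl_a, tl_ba)) {
    expect_equal(unname(evaluate_rule(bare, list(tl))$match),
                 length(find_matches(tl, A)) > 0)
  }

  # a window that excludes the only occurrence
  win <- structure(list(min_units = 0, max_units = 2, unit = "months"),
                   class = "duration_bounds")
  tight <- phenotype_rule(A, temporal_constraint = win)
  tl_late <- make_blocks_timeline("pc", list(sx_drug, sx_drug, sx_drug,
                                             sx_drug, sx_drug, sx_test))
  expect_false(unname(evaluate_rule(tight, list(tl_late))$match))
  tl_early <- make_blocks_timeline("pd", list(sx_test, sx_drug))
  expect_true(unname(evaluate_rule(tight, list(tl_early))$match))
})

test_that("patients with unresolvable anchors under a window are flagged", {
  ev <- list(
    clinical_event("p1", "pain", "Sx", raw_time = "postop",
                   appearance_index = 1L, causal_links = "a1"),
    clinical_event("a1", "CT", "Test", raw_time = "postop",
                   appearance_index = 2L))
  tl <- build_timeline(ev, patient_id = "hint_only")
  win <- structure(list(min_units = 0, max_units = 24, unit = "months"),
                   class = "duration_bounds")
  rule <- phenotype_rule(shape_key(sx_test), temporal_constraint = win)
  ev_out <- evaluate_rule(rule, list(tl))
  expect_false(unname(ev_out$match))
  expect_equal(ev_out$indeterminate, "hint_only")
})

test_that("the miner matches exhaustive enumeration on small instances", {
  set.seed(77)
  vocab <- list(sx_test, purpose_chemo, finding_op, sx_drug)
  for (trial in 1:6) {
    n_t <- sample(2:3, 1); n_b <- sample(2:3, 1)
    tls_t <- lapply(seq_len(n_t), function(i) make_blocks_timeline(
      sprintf("t%d_%d", trial, i),
      vocab[sample.int(4, sample(2:8, 1), replace = TRUE)]))
    tls_b <- lapply(seq_len(n_b), function(i) make_blocks_timeline(
      sprintf("b%d_%d", trial, i),
      vocab[sample.int(4, sample(2:8, 1), replace = TRUE)]))
    tkeys <- lapply(tls_t, vmodel:::timeline_block_keys)
    bkeys <- lapply(tls_b, vmodel:::timeline_block_keys)
    for (ms in c(0.5, 1.0)) {
      got <- mine_rules(tls_t, tls_b, min_support_target = ms, max_len = 2L)
      want <- oracle_mine(tkeys, bkeys, ms, 2L)
      got_ser <- sort(vapply(got, function(r) serialize_rule(
        r$rule$include$blocks,
        lapply(r$rule$exclude_preceding, `[[`, "blocks")), ""))
      want_ser <- sort(vapply(want, function(r)
        serialize_rule(r$include, r$exclude), ""))
      expect_equal(got_ser, want_ser)
      # supports agree rule by rule
      got_sup <- vapply(got, `[[`, 0, "support_target")
      names(got_sup) <- vapply(got, function(r) serialize_rule(
        r$rule$include$blocks,
        lapply(r$rule$exclude_preceding, `[[`, "blocks")), "")
      for (w in want) {
        expect_equal(unname(got_sup[serialize_rule(w$include, w$exclude)]),
                     w$support_target)
      }
    }
  }
})

test_that("raising the support threshold never adds rules", {
  co <- generate_cohort(cohort_spec(seed = 13, n_target = 4L,
                                    n_background = 4L))
  ser <- function(res) vapply(res, function(r) serialize_rule(
    r$rule$include$blocks,
    lapply(r$rule$exclude_preceding, `[[`, "blocks")), "")
  lo <- ser(mine_rules(co$target, co$background, 0.5, max_len = 2L))
  hi <- ser(mine_rules(co$target, co$background, 1.0, max_len = 2L))
  expect_true(all(hi %in% lo))
  expect_lte(length(hi), length(lo))
})

test_that("mining rejects empty groups", {
  tl <- make_blocks_timeline("p", list(sx_test))
  expect_error(mine_rules(list(), list(tl)), "target group is empty")
  expect_error(mine_rules(list(tl), list()), "background group is empty")
})

test_that("identical target and background admit no separating rule", {
  tls <- lapply(1:3, function(i) make_blocks_timeline(
    sprintf("s%d", i), list(sx_test, finding_op)))
  res <- mine_rules(tls, tls, min_support_target = 1.0, max_len = 2L)
  for (r in res) {
    expect_equal(r$support_background, r$support_target)
    expect_equal(unname(r$confusion["fp"]), unname(r$confusion["tp"]))
  }
})
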