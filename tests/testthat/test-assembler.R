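role_of <- function(tag, linked) {
  assign_role(clinical_event("e", "x", tag,
                             causal_links = if (linked) "other" else
                               character(0)),
              has_explicit_cause_link = linked)$role
}

test_that("role assignment covers every tag with and without causality", {
  expected <- c(Purpose = "Problem", Sx = "Problem",
                Dx = "Action", Finding = "Action",
                Drug = "Action", Op = "Action", Other = "Action",
                Plan = "Action", Test = "Action", Tx = "Action",
                Adm = "Visit", Death = "Visit", Disch = "Visit",
                Visit = "Visit")
  for (tag in semantic_tags()) {
    expect_equal(role_of(tag, FALSE), unname(expected[tag]), info = tag)
    linked_role <- if (tag %in% c("Dx", "Finding")) "Problem" else
      unname(expected[tag])
    expect_equal(role_of(tag, TRUE), linked_role,
                 info = paste(tag, "linked"))
  }
  # the dual diagnosis case: cause -> Problem, plain mention -> Action
  expect_equal(role_of("Dx", TRUE), "Problem")
  expect_equal(role_of("Dx", FALSE), "Action")
  expect_error(assign_role(clinical_event("e", "x", "Lab")),
               "unknown semantic tag")
})

test_that("events sharing one expression share a TAP, split per causal relation", {
  # two problems, each with its own test, same expression -> two v's
  ev <- list(
    clinical_event("p1", "hemiparesis", "Sx", raw_time = "02.8",
                   appearance_index = 1L, causal_links = "t1"),
    clinical_event("t1", "Br. MRI", "Test", raw_time = "02.8",
                   appearance_index = 2L),
    clinical_event("p2", "back pain", "Sx", raw_time = "02.8",
                   appearance_index = 3L, causal_links = "t2"),
    clinical_event("t2", "L-spine MRI", "Test", raw_time = "02.8",
                   appearance_index = 4L))
  tl <- build_timeline(ev, patient_id = "p")
  expect_length(tl$structures, 2L)
  expect_identical(tl$structures[[1]]$tap, tl$structures[[2]]$tap)
  expect_equal(vapply(tl$structures[[1]]$problems, `[[`, "", "event_id"),
               "p1")
  expect_equal(vapply(tl$structures[[2]]$actions, `[[`, "", "event_id"),
               "t2")

  # one problem, three actions -> one v with a three-event action wing
  ev2 <- list(
    clinical_event("p1", "tumor", "Dx", raw_time = "02.8",
                   appearance_index = 1L, causal_links = c("a1", "a2", "a3")),
    clinical_event("a1", "biopsy", "Test", raw_time = "02.8",
                   appearance_index = 2L),
    clinical_event("a2", "resection", "Op", raw_time = "02.8",
                   appearance_index = 3L),
    clinical_event("a3", "chemo", "Tx", raw_time = "02.8",
                   appearance_index = 4L))
  tl2 <- build_timeline(ev2, patient_id = "p")
  expect_length(tl2$structures, 1L)
  expect_length(tl2$structures[[1]]$actions, 3L)
  expect_equal(tl2$structures[[1]]$problems[[1]]$event_id, "p1")

  # unlinked events at one expression -> a single residual structure in
  # appearance order
  ev3 <- list(
    clinical_event("a1", "Br. MRI", "Test", raw_time = "02.8",
                   appearance_index = 1L),
    clinical_event("a2", "r/o CRP diagnosis", "Dx", raw_time = "02.8",
                   appearance_index = 2L),
    clinical_event("a3", "NTR of tm.", "Op", raw_time = "02.8",
                   appearance_index = 3L))
  tl3 <- build_timeline(ev3, patient_id = "p")
  expect_length(tl3$structures, 1L)
  expect_equal(vapply(tl3$structures[[1]]$actions, `[[`, "", "text"),
               c("Br. MRI", "r/o CRP diagnosis", "NTR of tm."))

  expect_length(build_timeline(list(), patient_id = "p")$structures, 0L)
})

test_that("problems sharing actions merge instead of duplicating events", {
  ev <- list(
    clinical_event("p1", "fever", "Sx", raw_time = "02.8",
                   appearance_index = 1L, causal_links = "a1"),
    clinical_event("p2", "cough", "Sx", raw_time = "02.8",
                   appearance_index = 2L, causal_links = c("a1", "a2")),
    clinical_event("a1", "chest X-ray", "Test", raw_time = "02.8",
                   appearance_index = 3L),
    clinical_event("a2", "antibiotics", "Drug", raw_time = "02.8",
                   appearance_index = 4L))
  tl <- build_timeline(ev, patient_id = "p")
  expect_length(tl$structures, 1L)
  ids <- unlist(lapply(tl$structures, function(s)
    vapply(c(s$problems, s$actions, s$visits), `[[`, "", "event_id")))
  expect_setequal(ids, c("p1", "p2", "a1", "a2"))
  expect_false(anyDuplicated(ids) > 0)
})

test_that("every input event lands in exactly one structure", {
  co <- generate_cohort(cohort_spec(seed = 3, n_target = 4L,
                                    n_background = 3L))
  for (tl in c(co$target, co$background)) {
    ids <- unlist(lapply(tl$structures, function(s)
      vapply(c(s$problems, s$actions, s$visits), `[[`, "", "event_id")))
    expect_false(anyDuplicated(ids) > 0)
  }
})

test_that("input order does not matter, only appearance_index does", {
  ev <- list(
    clinical_event("p1", "pain", "Sx", raw_time = "01.2",
                   appearance_index = 1L, causal_links = "a1"),
    clinical_event("a1", "CT", "Test", raw_time = "01.2",
                   appearance_index = 2L),
    clinical_event("a2", "op", "Op", raw_time = "01.5",
                   appearance_index = 3L),
    clinical_event("v1", "ward 3", "Adm", raw_time = "01.2",
                   appearance_index = 4L))
  tl1 <- build_timeline(ev, patient_id = "p")
  set.seed(9)
  tl2 <- build_timeline(ev[sample(4)], patient_id = "p")
  expect_equal(tl1, tl2)
})

test_that("untimed events inherit the nearest preceding expression", {
  tl <- worked_example_timeline()
  expect_length(tl$structures, 4L)
  aug <- tl$structures[[3]]
  expect_equal(aug$tap$raw_text, "02.8")
  expect_equal(vapply(aug$actions, `[[`, "", "event_id"),
               c("mri", "dx", "ntr"))
})

test_that("resolvable expressions out of document order are reordered", {
  ev <- list(
    clinical_event("a1", "op", "Op", raw_time = "02.8",
                   appearance_index = 1L),
    clinical_event("a2", "earlier test", "Test", raw_time = "86",
                   appearance_index = 2L))
  expect_warning(tl <- build_timeline(ev, patient_id = "p"),
                 "out of document order")
  expect_equal(render_tap_labels(tl), c("86", "02.8"))
})

test_that("assembly rejects malformed inputs with precise errors", {
  expect_error(build_timeline(list(
    clinical_event("e1", "x", "Sx", appearance_index = 1L),
    clinical_event("e1", "y", "Sx", appearance_index = 2L)),
    patient_id = "p"), "duplicate event_id")
  expect_error(build_timeline(list(
    clinical_event("e1", "x", "Sx", appearance_index = 1L,
                   causal_links = "zz")),
    patient_id = "p"), "outside this patient")
  expect_error(build_timeline(list(
    clinical_event("e1", "x", "Dx", appearance_index = 1L,
                   causal_links = "e2"),
    clinical_event("e2", "y", "Finding", appearance_index = 2L,
                   causal_links = "e1")),
    patient_id = "p"), "cyclic causal links")
})

test_that("cross-structure problem-action links respect ordering", {
  tl <- worked_example_timeline()
  expect_equal(nrow(tl$cross_links), 1L)
  expect_error(link_problem_to_later_action(tl, "dx", "op86"),
               "action precedes its problem")
  expect_error(link_problem_to_later_action(tl, "cc1", "cc1"), "self-link")
  expect_error(link_problem_to_later_action(tl, "nope", "mri"),
               "unknown event")
  tl2 <- link_problem_to_later_action(tl, "cc2", "ntr")
  expect_equal(nrow(tl2$cross_links), 2L)
})

test_that("visit events attach to the nearest following structure", {
  ev <- list(
    clinical_event("v1", "ER", "Adm", raw_time = "02.7",
                   appearance_index = 1L),
    clinical_event("p1", "pain", "Sx", raw_time = "02.8",
                   appearance_index = 2L))
  tl <- build_timeline(ev, patient_id = "p")
  expect_length(tl$structures, 1L)
  expect_equal(tl$structures[[1]]$visits[[1]]$event_id, "v1")
  # trailing admission with nothing after: a visit-only structure
  tl2 <- build_timeline(list(
    clinical_event("v1", "ER", "Adm", raw_time = "02.7",
                   appearance_index = 1L)), patient_id = "p")
  expect_true(tl2$structures[[1]]$visit_only)
  expect_length(validate_timeline(tl2), 0L)
})
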