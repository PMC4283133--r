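iso <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

test_that("the temporal dialect parses into the expected intervals", {
  a <- parse_tap("86")
  expect_equal(a$kind, "absolute")
  expect_equal(a$granularity, "year")
  expect_equal(iso(a$interval$earliest), "1986-01-01T00:00")
  expect_equal(iso(a$interval$latest), "1986-12-31T23:59")

  b <- parse_tap("02.8")
  expect_equal(b$granularity, "month")
  expect_equal(iso(b$interval$earliest), "2002-08-01T00:00")
  expect_equal(iso(b$interval$latest), "2002-08-31T23:59")

  f <- parse_tap("from late 02.7")
  expect_true(f$open_start)
  expect_equal(f$fuzzy_modifier, "late")
  expect_equal(f$granularity, "month")
  expect_equal(iso(f$interval$earliest), "2002-07-21T00:00")
  expect_equal(iso(f$interval$latest), "2002-07-31T23:59")

  r <- parse_tap("three days ago", as.Date("2002-08-15"))
  expect_equal(r$kind, "relative")
  expect_equal(r$granularity, "day")
  expect_equal(iso(r$interval$earliest), "2002-08-12T00:00")
  expect_equal(iso(r$interval$latest), "2002-08-12T23:59")

  h <- parse_tap("postop")
  expect_equal(h$kind, "proximity_hint")
  expect_null(h$interval)

  m <- parse_tap("")
  expect_equal(m$kind, "missing")
  expect_null(m$interval)
})

test_that("two-digit years pivot at 30 and decades span ten years", {
  expect_equal(iso(parse_tap("30")$interval$earliest), "1930-01-01T00:00")
  expect_equal(iso(parse_tap("29")$interval$earliest), "2029-01-01T00:00")
  d <- parse_tap("1980s")
  expect_equal(d$granularity, "decade")
  expect_equal(iso(d$interval$latest), "1989-12-31T23:59")
})

test_that("named-day lexicon resolves, otherwise names stay hints", {
  lex <- c("korean thanksgiving day" = "2002-09-21")
  a <- parse_tap("Korean Thanksgiving Day", lexicon = lex)
  expect_equal(a$granularity, "day")
  expect_equal(iso(a$interval$earliest), "2002-09-21T00:00")
  expect_equal(parse_tap("Korean Thanksgiving Day")$kind, "proximity_hint")
})

test_that("parse_tap is total over arbitrary strings", {
  set.seed(7)
  chars <- c(letters, LETTERS, 0:9, ".", "-", " ", "/", "'", "~", "%")
  for (i in 1:300) {
    s <- paste(sample(chars, sample(0:20, 1), replace = TRUE),
               collapse = "")
    expect_s3_class(parse_tap(s, as.Date("2000-01-01")), "temporal_anchor")
  }
  # relatives without an anchor date stay unresolved, never error
  u <- parse_tap("three days ago")
  expect_equal(u$kind, "relative")
  expect_null(u$interval)
})

test_that("distance bounds and estimate reproduce the worked example", {
  a <- parse_tap("86"); b <- parse_tap("02.8")
  db <- distance_bounds(a, b)
  expect_equal(db$unit, "months")
  expect_equal(db$min_units, 188)   # 15 years 8 months
  expect_equal(db$max_units, 199)   # 16 years 7 months
  expect_equal(distance_estimate(a, b), 16L)

  # identical year anchors at month truncation
  self <- distance_bounds(a, a)
  expect_equal(c(self$min_units, self$max_units), c(0, 11))

  d1 <- parse_tap("02.8.1"); d2 <- parse_tap("02.8.4")
  dd <- distance_bounds(d1, d2)
  expect_equal(dd$unit, "days")
  expect_equal(c(dd$min_units, dd$max_units), c(3, 3))

  expect_equal(distance_estimate(parse_tap("1990"), parse_tap("2000")), 10L)
  expect_equal(distance_estimate(d1, d1), 0L)
})

test_that("distance errors identify the unresolved argument", {
  expect_error(distance_bounds(parse_tap("postop"), parse_tap("02.8")),
               "unresolved anchor: first")
  expect_error(distance_bounds(parse_tap("02.8"), parse_tap("")),
               "unresolved anchor: second")
})

test_that("qualitative relations follow interval endpoints", {
  expect_equal(qualitative_relation(parse_tap("86"), parse_tap("02.8")),
               "before")
  expect_equal(qualitative_relation(parse_tap("02.8"), parse_tap("86")),
               "after")
  expect_equal(qualitative_relation(parse_tap("from late 02.7"),
                                    parse_tap("02.8")), "before")
  expect_equal(qualitative_relation(parse_tap("02"), parse_tap("02.8")),
               "undetermined")  # containment
  expect_equal(qualitative_relation(parse_tap("postop"), parse_tap("02.8")),
               "undetermined")
  expect_equal(qualitative_relation(parse_tap("02.8"), parse_tap("02.8")),
               "same_expression")
})

test_that("bounds and relations agree with the endpoint-enumeration oracle", {
  set.seed(101)
  pool <- random_anchor_pool(120)
  expect_gt(length(pool), 50)
  for (i in 1:800) {
    a <- pool[[sample.int(length(pool), 1)]]
    b <- pool[[sample.int(length(pool), 1)]]
    ob <- oracle_bounds(a, b)
    db <- distance_bounds(a, b)
    expect_equal(db$unit, ob$unit)
    expect_equal(db$min_units, ob$min_units)
    expect_equal(db$max_units, ob$max_units)
    expect_equal(qualitative_relation(a, b), oracle_relation(a, b))
    # anti-symmetry
    rel <- qualitative_relation(a, b)
    rev <- qualitative_relation(b, a)
    if (rel == "before") expect_equal(rev, "after")
    if (rel == "after") expect_equal(rev, "before")
    # zero self-distance
    expect_equal(distance_bounds(a, a)$min_units, 0)
  }
})

test_that("refining a year to one of its months never widens the bounds", {
  set.seed(55)
  pool <- random_anchor_pool(60)
  for (i in 1:100) {
    y <- sample(1980:2015, 1)
    coarse <- parse_tap(sprintf("%d", y))
    fine <- parse_tap(sprintf("%02d.%d", y %% 100, sample(1:12, 1)))
    other <- pool[[sample.int(length(pool), 1)]]
    # refinement tightens bounds wherever the order of the two anchors is
    # decided; inside the coarse interval the origin itself flips
    if (qualitative_relation(coarse, other) == "undetermined") next
    bc <- distance_bounds(coarse, other)
    bf <- distance_bounds(fine, other)
    expect_true(bf$min_units >= bc$min_units)
    expect_true(bf$max_units <= bc$max_units)
  }
})

test_that("a problem precedes any action of its own structure", {
  tl <- worked_example_timeline()
  s3 <- tl$structures[[3]]
  # structure holding the August actions has no problems; use a built one
  ev_p <- clinical_event("p", "pain", "Sx", raw_time = "02.8",
                         appearance_index = 1L, causal_links = "a")
  ev_a <- clinical_event("a", "CT", "Test", raw_time = "02.8",
                         appearance_index = 2L)
  v <- build_timeline(list(ev_p, ev_a), patient_id = "x")$structures[[1]]
  expect_true(problem_precedes_action(v, ev_p, ev_a))
  expect_error(problem_precedes_action(v, ev_a, ev_a),
               "not on the Problem wing")
  stray <- clinical_event("z", "other", "Sx", appearance_index = 9L)
  expect_error(problem_precedes_action(v, stray, ev_a),
               "not on the Problem wing")
  expect_length(s3$problems, 0L)
})
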