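---
title: "Problem-Action timelines: model, temporal reasoning, and pattern mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Problem-Action timelines: model, temporal reasoning, and pattern mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmodel)
```

## The problem

Narrative clinical documents — discharge summaries above all — carry the
richest account of a patient's history: what happened, when, and, crucially,
*why*. Conventional timeline views struggle with exactly the properties that
make narrative valuable: temporal expressions are implicit ("'86", "02.8"),
fuzzy and half-bounded ("from late 02.7"), of wildly mixed granularity
(years next to "two hours before"), sometimes absent, and sometimes not
calendar expressions at all ("postop"). Causality ("due to cervix cancer,
concurrent chemo RT was done") is stated in prose and lost by event-grid
layouts.

`vmodel` implements a v-shaped timeline model for such material. Each
annotated event belongs to one of 14 semantic categories and is placed on a
v-glyph: a *temporal anchor point* (TAP) on the baseline, a left **Problem**
wing (why care happened: symptoms, purposes, explicitly causal diagnoses and
findings), a right **Action** wing (what was done), and administrative
**Visit** items. Timelines are *dynamically scaled*: consecutive anchors are
equally spaced regardless of elapsed time, which is what lets a bare year
sit beside an hour-level emergency without zooming. On top of the model the
package provides interval-based temporal reasoning, deterministic SVG
rendering, and context-block pattern mining for cohort phenotyping.

The package ingests *pre-annotated* events (id, text, semantic tag, verbatim
temporal expression, appearance order, stated causal links). Extracting
those annotations from raw text is a natural-language-processing problem
outside this package's scope.

## Role assignment and assembly

Roles follow the tag, with one deliberate wrinkle. Symptoms and purposes are
always Problems. Diagnoses and findings are Problems *only when the source
text states them as the cause of another event*; the same concept mentioned
without a causality expression is an Action. This keeps modeling faithful to
what was written rather than to medical inference, and it is why
`assign_role()` takes the causality flag explicitly:

```{r}
assign_role(clinical_event("e1", "cervix cancer", "Dx",
                           causal_links = "rt1"), TRUE)$role
assign_role(clinical_event("e2", "cervix cancer", "Dx"), FALSE)$role
```

`build_timeline()` turns a flat event list into v-structures:

* events with the same verbatim temporal expression share one anchor;
* within a shared anchor, each distinct causal relationship becomes its own
  v-structure. We implement "distinct relationship" as a connected component
  of the within-group Problem-Action link graph. Two problems each linked to
  their own test yield two v's sharing the expression; problems whose action
  sets coincide merge. We chose components over one-structure-per-problem
  because overlapping (but unequal) action sets would otherwise force the
  shared action to appear in two structures, and event conservation — every
  event in exactly one structure — is the invariant we consider
  non-negotiable;
* unlinked events of the group join one residual structure, either wing may
  be empty of the other, and no internal order or gap is invented within a
  wing: events stay in appearance order, grouped by semantic tag so the
  rendering can head each run with one colored tag box;
* untimed events inherit the nearest preceding expression, preserving the
  order-of-appearance principle for missing temporal information;
* structures are ordered chronologically wherever anchors decide the order,
  by appearance otherwise. When a resolvable anchor contradicts document
  order, chronology wins and a warning is raised — the timeline is the
  product, and narration is only *mostly* chronological;
* administrative events attach to the structure of their expression group,
  or to the nearest following structure when their group has no clinical
  events; a trailing admission with nothing after it stays as a
  visit-only structure.

Cross-structure Problem-to-Action links (complaints in late July, workup in
August) are recorded on the timeline, rejected when the action's structure
precedes the problem's, and consumed by block extraction and rendering.

```{r}
tl <- worked_example_timeline()
tl
```

## Temporal anchors

`parse_tap()` is total: every string yields an anchor, never an error.
The dialect covers dotted year/month/day forms (`"86"`, `"02.8"`,
`"02.8.15"`), ISO forms, decades (`"1980s"`), relative offsets
(`"three days ago"`, resolved against an anchor date such as the admission
date), semi-intervals (`"from X"` / `"since X"`), fuzzy modifiers
(`"late 02.7"`), and an optional lexicon for named days. Anything else
nonempty becomes a *proximity hint*: kept verbatim, displayed verbatim, and
excluded from calendar arithmetic — "postop" is more informative as context
than as a forced date.

Conventions the data do not determine are fixed once, visibly:

* **Two-digit year pivot at 30.** `YY >= 30` reads 19YY, otherwise 20YY.
  In gastric-cancer histories spanning the 1980s–2000s this is the only
  assignment consistent with an "about sixteen years" separation between
  '86 and 02.8.
* **Fuzzy thirds are calendar-aligned.** `early/mid/late` split the parent
  unit into thirds at natural boundaries: a year into Jan–Apr / May–Aug /
  Sep–Dec, a month into days 1–10 / 11–20 / 21–end, a day into 8-hour
  blocks. Day-aligned boundaries keep "late 02.7" strictly before "02.8",
  matching how a reader orders the two.
* **Semi-intervals anchor at their stated start.** `open_start` is recorded,
  but ordering and distance use the parsed interval of the stated boundary;
  the open end does not extend it. The alternative (treating the ongoing
  state as unbounded) would make "from late 02.7" incomparable with
  everything after it, which contradicts how such complaints are read.

An anchor resolves to an inclusive calendar interval at minute resolution
(UTC): `"86"` spans 1986-01-01T00:00 to 1986-12-31T23:59.

## Distance and qualitative reasoning

`distance_bounds()` measures two resolved anchors in the finer of their two
granularities, with one adjustment: decade- and year-level anchors are
measured in **months**, because the useful answer for "operation in '86,
resection in 02.8" is a month range — here 188 to 199 months, i.e. 15 years
8 months to 16 years 7 months. Endpoints are truncated to the measurement
unit before subtraction; the earlier anchor is the origin, so argument order
does not change magnitudes. `distance_estimate()` is the half-up-rounded
midpoint in years (12 months per year) — the "about sixteen years" a reader
infers:

```{r}
distance_bounds(parse_tap("86"), parse_tap("02.8"))
distance_estimate(parse_tap("86"), parse_tap("02.8"))
```

`qualitative_relation()` returns `before`/`after` only when the intervals
are disjoint, `same_expression` for identical verbatim strings, and
`undetermined` otherwise — including every comparison against a hint or
missing anchor. Within one v-structure no interval arithmetic is needed:
the Problem wing holds causes of the Action wing, so
`problem_precedes_action()` holds by construction even under a shared
expression.

The test suite checks both operations against a brute-force oracle that
enumerates unit-truncated endpoint combinations on randomized anchor pairs
(10,000 pairs in the acceptance suite), plus anti-symmetry and zero
self-distance. One property needs a caveat the bare statement lacks:
refining a year to one of its months tightens distance bounds only when the
order against the second anchor is decided; when the second anchor lies
*inside* the coarse year, refinement can flip which anchor is the origin,
so the property test conditions on a decided order.

## Rendering

`layout_timeline()` is a pure function from (timeline, configuration) to
geometry; `render_svg()` is a pure function from geometry to an SVG 1.1
string, and repeated renders are byte-identical. Anchor marks sit on one
baseline at constant spacing (`unit_spacing`, default 170 px). Problem wings
extend up-left and Action wings up-right (`wing_angle`, default 45°,
validated to 15–75°); wing labels stack vertically with a fixed pitch, each
same-tag run headed by a tag box filled red (`#CC0000`) for Problems or blue
(`#0033CC`) for Actions. Label boxes are width-clamped so that columns of
neighbouring structures can never collide — the no-overlap invariant is
asserted geometrically in the tests. Visit items render in a strip below
the baseline; cross-structure links draw as a restrained dashed arc between
the two anchors, without arrowheads. Anchor labels are always the verbatim
expression, never a normalized date. Canvas height follows the deepest wing,
not the number of distinct concepts — the compactness that makes long
histories readable in one strip. Context-block rectangles are available
behind `show_blocks = TRUE` but default off: they are an explanatory
overlay, not part of the visualization.

Glyph proportions (angle, pitch, spacing) are nowhere prescribed by the
model; the defaults are aesthetic choices exposed in `render_config()` and
the YAML `render:` section.

## Context blocks and pattern mining

A *context block* is a maximal run of consecutive structures tied by shared
context: a causal link crossing between neighbours, or neighbours carrying
the identical verbatim expression (the multiple-cause case, where one
expression was split into several v's). Structures without ties form
singleton blocks, so blocks always partition the timeline. Whether a block
may span an admission→discharge boundary is unstated in the model; we allow
it, since the link evidence, not the visit structure, is what defines
context.

`block_signature()` abstracts a block to per-structure wing multisets —
order-free within a wing, order-preserving across structures — either at
semantic-tag level (two "symptom → test" blocks compare equal regardless of
wording) or at concept-label level. `find_matches()` finds all occurrences,
overlapping included, of a signature n-gram over *adjacent* blocks — we read
"directly followed" literally, with no gap allowed.

`mine_rules()` contrasts a target cohort with a background group: it
enumerates contiguous block n-grams up to `max_len`, keeps those reaching
`min_support_target`, and for kept patterns that also occur in the
background searches for patterns that frequently precede them there,
emitting include / exclude-preceding candidate rules — "select patients with
pattern A, unless pattern B came first". The exclusion search is bounded to
patterns with support at least `min_support_target` *among background
patients matching the include pattern*; an unbounded search over all
preceding patterns would be quadratic in vocabulary for little gain.
Ranking is deterministic: target support (desc), background support (asc),
include length (desc), total exclusion length (desc), then a lexicographic
tie-break on the serialized signature. Longer includes and more specific
exclusions outrank shorter ones at equal support because they are the
stricter, more falsifiable rule. `evaluate_rule()` applies a rule per
patient — an include occurrence with no exclusion occurrence ending before
it, optionally within a `duration_bounds` window of the patient's first
resolvable anchor — and reports a confusion matrix; patients whose anchors
cannot support a temporal window are flagged indeterminate and reported
separately rather than silently counted.

We mine whole-block signatures only; single-wing (partial-block) patterns
are a plausible extension we deliberately left out, since the block is the
model's unit of context.

## Synthetic cohorts

`generate_cohort()` emulates the structure that the mining operations are
designed for, with no clinical data anywhere: timelines of 4–8 single-v
blocks; a planted two-block pattern (symptom→test, then purpose→treatment
with a drug) inserted at a random position in `ceiling(support × n)` target
timelines; and, in the confounded scenario, a confounder pair (sharing the
planted pattern's first block shape, differing in the second) placed
directly before the planted pattern in background timelines — the situation
where plain pattern presence fails and an exclude-preceding clause is the
correct rule. Default group sizes are 5 and 5, the scale at which such
cohort sketches are drawn and at which the exhaustive-enumeration oracle
stays cheap.

Design choices worth knowing when interpreting test results:

* Anchor expressions advance one month per block from 1998, with bare-year
  forms falling in the 1980s and relative forms resolving inside their
  block's month against a fixed generator anchor date. Chronological
  correction therefore moves year-form blocks to the front but can never
  split a planted pair.
* Planted and confounder blocks always carry plain month anchors; slots
  adjacent to them take a patient-rotated noise block, so small cohorts
  never share an accidental longer super-pattern that would outrank the
  planted rule under the length-descending tie-break.
* Event texts are template strings ("Sx_17"); nothing resembling real
  patient content appears in generated data.
* About 5% of blocks gain an untimed trailing event, exercising the
  missing-expression inheritance path during assembly.

What the generator does *not* emulate — and what passing tests therefore do
not show — includes annotation noise (wrong tags, missed links), synonymy
between event texts, non-narrative orderings, multi-document patients, and
realistic marginal frequencies of semantic tags. Results on synthetic
cohorts demonstrate algorithmic correctness, not clinical performance.

## Numerical and degenerate-input choices

* All calendar arithmetic is in UTC at minute resolution with inclusive
  endpoints; months are indexed as `year * 12 + month`, days as epoch days.
* Rounding of the year estimate is half-up (`floor(x + 0.5)`), so 15.5
  rounds to 16.
* Empty inputs are valid everywhere: an empty event list builds an empty
  timeline, which renders to a valid empty canvas and yields zero blocks.
* Unparseable expressions never fail: they become hints, excluded from
  arithmetic with an explicit "unresolved anchor" error only when distance
  is demanded of them.
* Cyclic causal links and cross-patient links are rejected at assembly with
  errors naming the cycle or the foreign ids.
* Interchange is JSON-canonical (TSV import as convenience); unknown fields
  are rejected with located errors, a `schema_version` gate refuses
  documents from other versions, and verbatim expressions survive
  round-trips byte-for-byte.

## Problem sizes used in the checks

The packaged suites run at desk scale: 10,000 randomized anchor pairs for
the interval-algebra oracle, cohorts of 5+5 patients with 4–8 blocks per
timeline for recovery, and exhaustive-oracle comparisons on instances of up
to 8 blocks and 6 patients — sizes at which brute-force enumeration is
still an independent, fast oracle.

## Known limitations

* The temporal dialect is the one needed for narrative discharge summaries
  of this shape; it is config-extensible but not a TimeML/TIMEX3
  implementation, and time zones are deliberately ignored.
* Qualitative relations collapse all overlap to `undetermined`; finer
  interval-algebra distinctions (meets, during, overlaps) are not exposed
  because the display never uses them. For display ordering only, the
  assembler falls back to appearance order — reasoning never does.
* Negation/uncertainty of events and concept normalization (UMLS/SNOMED)
  are out of scope; event identity is caller-supplied, and the library
  never merges events by text equality (a test done twice is two events).
* Mined rules are candidates ranked by support contrast; no statistical
  significance testing is attached.
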