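# vmodel — Problem-Action timelines for narrative clinical events

Narrative clinical documents are the richest source for EHR-based
phenotyping, and the hardest to put on a timeline: their temporal
expressions are implicit ("'86", "02.8"), fuzzy and half-bounded
("from late 02.7"), of mixed granularity (years beside "two hours before"),
sometimes missing, and sometimes not dates at all ("postop"); their
causality ("due to cervix cancer, concurrent chemo RT was done") is stated
in prose and lost by event-grid views.

`vmodel` implements a v-shaped timeline model for such material, for
clinical informaticians building cohort-selection (phenotyping) pipelines
from pre-annotated narrative events. Each v-structure is a **temporal
anchor point (TAP)** on a dynamically scaled baseline — equal spacing
between anchors, never proportional to elapsed time — with a left
**Problem** wing (symptoms, purposes, explicitly causal diagnoses/findings:
the *why*), a right **Action** wing (tests, drugs, operations, …: the
*what*), and attached **Visit** items. Events keep a semantic tag from a
fixed 14-category taxonomy. On top of the model the package provides:

* **Temporal parsing and reasoning.** `parse_tap()` turns every expression
  into a granularity-aware calendar interval (or keeps it verbatim as a
  proximity hint); `distance_bounds()` gives the possible distance range
  between two anchors at the finer granularity (year-level anchors measure
  in months), `distance_estimate()` its rounded midpoint in years, and
  `qualitative_relation()` the before/after/undetermined ordering.
* **Assembly.** `build_timeline()` applies the modeling strategy: shared
  TAPs for shared expressions, one v-structure per causal relationship,
  chronological-then-appearance ordering, untimed events inheriting the
  preceding anchor.
* **Rendering.** `render_timeline()` lays the timeline out deterministically
  and writes SVG: red/blue tag boxes, wings, visit strip, link arcs —
  byte-identical output for identical input.
* **Pattern mining.** Maximal runs of causally tied structures form
  *context blocks*; `mine_rules()` contrasts a target cohort with a
  background group and induces include / exclude-preceding phenotype
  candidate rules ("pattern A, unless pattern B came first"), evaluated
  per patient by `evaluate_rule()`.
* **Synthetic cohorts.** `generate_cohort()` builds seeded cohorts with
  planted patterns and confounders, so everything is testable with no
  clinical data.

## Worked example

A gastric-cancer history fragment: an operation in '86, chief complaints
from late July 2002 linked to the August workup, and chemotherapy placed
only by the proximity expression "postop".

```r
library(vmodel)
tl <- worked_example_timeline()
tl
#> <timeline example> 4 structure(s)
#> <v example-s1> TAP "86"
#>   A: Op:TG c Roux-en-Y anastomosis
#> <v example-s2> TAP "from late 02.7"
#>   P: Sx:headache; Sx:dizziness
#> <v example-s3> TAP "02.8"
#>   A: Test:Br. MRI; Dx:r/o CRP diagnosis; Op:NTR of tm.
#> <v example-s4> TAP "postop"
#>   A: Tx:FAM
```

How far apart were the two operations? The anchors "86" and "02.8" bound
the distance to 188–199 months — 15 years 8 months to 16 years 7 months —
and the midpoint estimate is the "about sixteen years" a reader infers:

```r
distance_bounds(parse_tap("86"), parse_tap("02.8"))
#> 188..199 months
distance_estimate(parse_tap("86"), parse_tap("02.8"))
#> [1] 16
```

The complaint-to-MRI link ties the July and August structures into one
context block; the other structures stand alone:

```r
for (b in extract_context_blocks(tl)) print(b)
#> <block example-b1> structures: example-s1
#> <block example-b2> structures: example-s2 -> example-s3
#> <block example-b3> structures: example-s4
writeLines(render_timeline(tl), "example.svg")
```

Mining a seeded confounded cohort (5 target patients carrying a planted
two-block pattern, 5 background patients carrying it only after a
confounder pair) recovers the include/exclude rule with a perfect patient
confusion matrix:

```r
co <- generate_cohort(cohort_spec(seed = 42))
res <- mine_rules(co$target, co$background, min_support_target = 1, max_len = 2)
res[[1]]
#> <rule> include: P{Sx}A{Test} >> P{Purpose}A{Drug,Tx}
#>   exclude preceding: P{Sx}A{Test} >> P{Finding}A{Op}
#>   support target 1.00, background 0.00; tp=5 fp=0 fn=0 tn=5
```

Signatures read as `P{problem tags}A{action tags}` per structure, `>>`
meaning "directly followed by".

## Command line

A thin Rscript wrapper drives the same functions from a shell:

```sh
Rscript inst/cli/vmodel.R validate --events inst/extdata/example-events.json
Rscript inst/cli/vmodel.R build    --events inst/extdata/example-events.json --out out/
Rscript inst/cli/vmodel.R render   --timeline out/example.timeline.json --out out/example.svg
Rscript inst/cli/vmodel.R reason   --a "86" --b "02.8"
Rscript inst/cli/vmodel.R simulate --out cohort/ --seed 7
Rscript inst/cli/vmodel.R mine     --target cohort/target --background cohort/background \
                                   --out rules.json --min-support 1.0 --max-len 2
```

Exit codes: 0 success, 1 validation failure, 2 usage error. A YAML
`--config` file can set the temporal dialect (century pivot, named-day
lexicon), rendering geometry and colors, and mining parameters; see
`inst/extdata/example-config.yaml`. The JSON interchange schema ships at
`inst/extdata/events-schema.json`.

## Documentation

The methods vignette (`vignettes/v-model-timelines.Rmd`) describes the
model and its assumptions, the temporal-dialect conventions (century pivot,
calendar-aligned fuzzy thirds, semi-interval anchoring), the mining
procedure and its ranking, what the synthetic cohorts do and do not
emulate, and known limitations.
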