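---
title: "Cohort selection methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort selection methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortforge)
```

## The selection model

`cohortforge` automates the construction of analytic datasets from a
prospective cohort's normalized study tables (participants, cancers,
hospitalizations, surveys, plus a covariate catalog). A project is fully
described by a six-section *selection spec*: endpoint, start of
follow-up, censoring rules, covariate selectors, custom-data
declarations, and project metadata. The spec is declarative and
serializable (JSON/YAML), any single section can be revised without
touching the others, and a run is a pure function of `(tables, spec)` —
the basis for the package's determinism and revision-equivalence
guarantees.

### Time-to-event construction

Follow-up for participant $i$ runs from a start date $s_i$ (baseline
survey, a chosen follow-up wave, or a fixed calendar date) to the
earliest of the candidate exits on/after $s_i$:

* the first **qualifying endpoint event** on/before the end of study;
* the first **other cancer** (any cancer not matching the endpoint), if
  other-cancer censoring is on;
* the first relevant **surgery** — bilateral mastectomy, hysterectomy, or
  bilateral oophorectomy for breast, uterine and ovarian endpoints,
  identified from hospitalization procedure codes; forced on for those
  endpoint groups unless explicitly disabled;
* **death**;
* the **administrative** end, $\min(\text{end of study},
  \text{end of linkage})$, always present.

Same-date ties are broken by the fixed precedence `event > other_cancer >
surgery > death > admin_censor`. This ordering is a design choice (the
tie cases are genuinely ambiguous): it favors sensitivity of event
capture — a participant diagnosed on the day they die counts as an event
— and makes output deterministic. Person-time is measured in integer
days over the closed interval $[s_i, \text{exit}_i]$ as
`person_days = exit − start`; participants with zero days of follow-up
are excluded and logged. Days were chosen as the unit because every
source date is day-resolved; any coarser unit is a division the analyst
can apply.

### Eligibility and attrition

Criteria are applied sequentially and logged: (1) a valid start date
(e.g., the chosen wave was actually completed); (2) alive at start; (3)
start on/before the end of study; (4) no prevalent cancer, i.e. no
cancer diagnosed before the start date (on by default, the conventional
choice for incidence analyses); (5) any user-supplied criteria. The log
satisfies `input n − Σ excluded = output rows` identically. Prevalence
is defined relative to the *chosen* start date rather than baseline,
which keeps the rule coherent under arbitrary fixed start dates; a
participant whose endpoint event occurred between baseline and a later
start is therefore excluded as prevalent rather than carried in as an
immortal-time survivor. The alternative (censoring them at start) was
considered and rejected as silently mixing prevalent and incident cases.

### Endpoint matching

All ICD and ICD-O-3 matching is normalized prefix matching: codes are
uppercased, trimmed, and de-dotted (`"C50.9"` → `"C509"`), and a code
qualifies when any configured prefix is a leading substring. Coding
conventions differ across registry vintages mostly in punctuation and
granularity, which prefix matching on canonical forms absorbs. The SEER
site-group recode ships as a small editable subset table (breast,
uterus, ovary, colon, lung, melanoma of the skin) with
histology-override rows taking priority over site ranges; a full recode
table can be supplied in the same four-column format. Behavior-code
(in-situ vs invasive) filtering is deliberately not implemented: the
eligibility of in-situ disease is study policy, not engine mechanics,
and silently guessing it would be worse than omitting it.

Hospitalization phenotypes are operational definitions: ICD diagnosis
prefixes, an optional minimum length of stay (days), a minimum count of
qualifying admissions, and a position rule (`any_listed` by default —
claims positions are not reliably ordered across sources;
`principal_only` restricts to the first-listed code). When several
phenotypes are supplied, each contributes an indicator/date column pair
assessed within the follow-up window, and the *first-listed* phenotype
defines the analytic endpoint event.

### Cross-sectional designs

A cross-sectional spec names a reference date; rows are participants
enrolled, alive and under linkage coverage at that date, the endpoint
indicator marks a qualifying event on/before it, and no person-time
columns are emitted. These semantics are the package's own construction
(the design label itself does not pin them down); with censoring off and
no mortality the indicator count provably equals the cohort design's
event count at the same horizon, which is tested.

## The synthetic cohort generator

The generator emulates the *structure* of a large women's prospective
cohort: one baseline survey per participant inside the 1995-10-27 to
1999-08-20 enrollment window, up to five follow-up waves with
missing-by-design gaps, ~1200 tagged survey covariates, ICD-O-3 coded
cancer events with contiguous sequence numbers, hospitalizations with
ICD diagnosis/procedure codes and derived length of stay, and ICD-coded
deaths. Waiting times are exponential (constant hazards) — the simplest
mechanism with the right qualitative behavior, and closed-form
expectations make the generator testable (simulated incidence is checked
against $\frac{\lambda_c}{\lambda_c+\lambda_m}\,(1-e^{-(\lambda_c+\lambda_m)\tau})$
per participant, within Monte-Carlo error).

Key defaults (all config knobs):

| parameter | default | rationale |
|---|---|---|
| cancer hazard | 0.011 /person-year | ≈ published tally of participants with cancer over ~25 y at full scale |
| mortality hazard | 0.012 /person-year | ≈ published death tally over ~25 y |
| hospitalization rate | 0.08 admissions/person-year | P(ever admitted) ≈ published fraction over ~25 y |
| surgery code fraction | 0.05 | enough mastectomy/hysterectomy/oophorectomy codes that surgery censoring is exercised |
| wave offsets | 2, 5, 10, 16, ~20 y | spacing of repeat questionnaires; the last wave plus jitter fits the simulation horizon so surviving responders complete all five waves |
| response prob. / never-responders | 0.80 / 0.05 | typical questionnaire-wave response behavior |
| item nonresponse | 0.03 | plain missingness, distinct from missing-by-design |

Because death competes with observation, realized event tallies at full
scale sit somewhat below the naive rate × time product; the published
tallies informed the hazards but are not conformance claims. What the
generator does **not** emulate: age-specific or secular incidence
trends, correlated covariates, informative censoring, geospatial /
dietary / genomic content. Passing tests therefore demonstrate the
*engine's* correctness on structurally faithful data, not
epidemiological realism of the simulated rates.

Presets: `unit` (100 participants, 150 covariates — fast fixtures),
`desk` (10,000 × 1200 — workstation checks), `cts_scale` (133,477 ×
1200, five waves — the emulated cohort's full size). The essential
covariate set requires at least 48 baseline items, hence the 150-column
floor at unit scale.

`inject_scenario()` appends fully specified edge-case participants
(same-day diagnosis and death, prevalent cancer, surgery predating
diagnosis, never-responder, second primary) so corner cases are present
by construction rather than by luck of the draw.

## Missing-by-design

A dead participant cannot complete later surveys; those cells are
*missing by design*, which is analytically different from nonresponse.
The package encodes the distinction end to end: in CSV the reserved
token `.D` (vs an empty cell), in memory `NaN` in numeric columns and
`".D"` in character columns (vs `NA`). Serialization round-trips both
states losslessly; the wide presentation table marks a wave's columns by
design exactly when that wave's date is absent, and this closure is a
validated invariant. The generated SAS reader maps the token onto SAS's
native special missing value; the generated R reader reads both kinds as
`NA` (R has no native second missing state) and says so in a comment,
with the dictionary documenting the sentinel.

## Covariates and the essential set

Every dataset automatically includes a fixed 62-member essential set —
participant-level fields (dates of birth/death/enrollment, wave dates,
vital status, race/ethnicity, linkage end), derived BMI and smoking
status, and a core block of baseline items. The count is enforced as a
configuration contract at catalog load: a catalog flagging any other
number is rejected rather than silently accepted, because downstream
dictionary and dataset contracts quantify over exactly this set. BMI is
`weight / height²` (kg/m², from self-reported height and weight); the
synthetic surveys are metric, and imperial-unit conversion is a
catalog-level recipe left off by default.

## Deliverables, versioning, integrity

A completed run emits exactly six artifacts: the dataset CSV and its
value-label formats file into the read-only data directory; the
SAS data call, the R reader script, the data dictionary, and the
selection summary into the project directory. Versions are
monotonically increasing per project; files are written to temporary
names and moved into place atomically (any failure rolls back the whole
version), prior versions are never mutated, and the data files have
their write bits cleared. Read-only enforcement is permission-bit plus
refuse-overwrite at the application layer — filesystem ACLs are a
deployment concern. Manifests record an MD5 checksum per file (byte
integrity and tamper evidence, not a cryptographic guarantee — the
threat model is accidental modification). The summary is deterministic
markdown rather than PDF: diffable, dependency-free, and byte-stable
apart from its timestamp line. Reader scripts are validated
structurally (every dataset column declared exactly once, versioned
paths correct) rather than by executing SAS, though the R reader is
executed in the test suite. Both the spec and the dataset are
versioned: revisions create new spec objects, generation creates new
dataset versions, and the manifest ties the two together.

## Numerical and degenerate-input choices

* Dates are ISO-8601 everywhere internally and on disk; `MM/DD/YYYY` is
  accepted only at user-input boundaries and normalized on entry.
* Numeric covariates are generated at fixed decimal precision so CSV
  round-trips are bit-exact; serialization is tested as the identity.
* An empty cohort (criteria exclude everyone) is a warning, not an
  error — an over-restrictive draft spec is a legitimate interim state.
* Cancer events flatten to the first 3 primaries by sequence number
  (configurable); higher multiplicities are rare enough that fixed
  flattening beats ragged output.
* A spec whose end of study precedes a participant's start excludes that
  participant (logged), so an administrative exit candidate always
  exists; the resolver treats a missing administrative candidate as an
  internal error.

## Verification problem sizes

The shipped checks run the full-scale preset once (dimensions only),
the desk preset for throughput and accounting (50 random specs), exact
brute-force oracle comparison on 1,000-participant cohorts × 20 random
specs, and property suites (monotonicity, determinism, revision
equivalence, dictionary bijection) at the 300–1,000 participant scale.
These sizes were chosen to exercise every code path with comfortable
margins; all empirical claims above are computed by the test suite or
`scripts/acceptance.R`, not asserted.

## Known limitations

No nested case-control matching or incidence-density sampling; no
statistical modeling on the output (the dataset is built *for* Cox/rate
models, not fitted); no ICD-9↔ICD-10 cross-walking; the bundled SEER
recode and surgery code sets are deliberately minimal and meant to be
replaced by curated tables in real deployments; multi-user concurrency
is reduced to atomic version allocation.
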