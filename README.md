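# cohortforge

Self-service cohort selection for prospective cohort studies.

Epidemiologists working with a large prospective cohort — participants
enrolled at a baseline survey, followed through repeat questionnaires and
registry linkages for cancer, hospitalization and mortality — spend weeks
turning each research question into an analytic dataset: choosing an
endpoint, a start of follow-up, censoring rules and covariates, then
assembling, documenting and versioning the result. `cohortforge`
implements that entire pipeline as a library plus a thin command-line
tool: a declarative *selection specification* goes in, an analysis-ready
dataset with its data dictionary, value-label formats, reader scripts and
selection summary comes out, versioned into a read-only data directory.

Because real cohort data of this kind are controlled-access, the package
ships a seeded synthetic cohort generator that emulates the structure of a
large women's cohort study — 133,477 participants enrolled 1995–1999, up
to five follow-up surveys, ~1200 survey covariates, linked event
histories, missing-by-design survey gaps — so every part of the engine
runs and is tested without any data download.

## What it computes

For each participant *i* with start of follow-up *s_i*, the engine
collects candidate exits: the first qualifying endpoint event, the first
*other* (non-endpoint) cancer, the first organ-removing surgery relevant
to the endpoint (bilateral mastectomy, hysterectomy, or bilateral
oophorectomy for breast, uterine and ovarian endpoints), death, and the
administrative end min(end of study, end of linkage). The exit is

> exit_i = earliest candidate on/after *s_i*, with same-date ties broken by
> the fixed precedence **event > other_cancer > surgery > death >
> admin_censor**,

and person-time is `person_days = exit_i − s_i` in integer days. Endpoints
are computable phenotypes in coding-system terms:

- **cancer** — ICD-O-3 topography prefixes and/or SEER site-group recode
  values, refined by morphology (histology) include/exclude sets;
- **mortality** — ICD cause-of-death prefixes (empty set = all-cause);
- **hospitalization** — ICD diagnosis prefixes with minimum length-of-stay
  and minimum qualifying-admission count, principal-only or any-listed.

Eligibility is applied sequentially and logged as an attrition table
(valid start → alive at start → within study window → no prevalent cancer
→ extra criteria), so `input n − Σ excluded = output rows` holds for every
run.

## Worked example

```r
library(cohortforge)

tables <- generate_cohort(default_config("unit", seed = 42))

spec <- selection_spec(
  endpoint   = list(type = "cancer", site_prefixes = "C50"),   # breast
  start      = list(rule = "baseline"),
  censoring  = list(end_of_study = "2015-12-31",
                    censor_other_cancers = TRUE),
  covariates = list(selector_search("smok")),
  metadata   = list(project = "breast-demo"))

built <- build_cohort_dataset(tables, spec)
built$attrition
#>                                criterion n_excluded n_remaining
#> 1:                     source population          0         100
#> 2:           no valid start of follow-up          0         100
#> 3:        died before start of follow-up          0         100
#> 4: start of follow-up after end of study          0         100
#> 5:         prevalent cancer before start          0         100
#> 6:                zero days of follow-up          0         100

table(built$dataset$status)
#> admin_censor        death        event other_cancer      surgery
#>           67           17            3           10            3

sum(built$dataset$person_days) / 365.25
#> [1] 1502
```

100 participants contribute ~1,502 person-years; 3 exit at an incident
breast cancer, 10 are censored at a non-breast cancer, 3 at a bilateral
mastectomy (applied automatically for a breast endpoint), 17 at death and
67 administratively. Note the real-time summary counts 6 participants
with a qualifying event overall —

```r
summarize_frequencies(tables, spec)
#> <frequency summary>
#>   participants: 100  eligible: 100
#>   with qualifying endpoint event: 6
#>   endpoint by site group:
#>     Breast       6
```

— but only 3 reach it during follow-up; the rest are censored first or
fall outside the study window. Generating the full deliverable set:

```r
m <- run_pipeline(spec, tables, "project", "data")
#> data/:     v001_dataset.csv  v001_formats.sas        (read-only)
#> project/:  v001_read_dataset.sas  v001_read_dataset.R
#>            v001_dictionary.csv  v001_summary.md  v001_manifest.json
```

Re-running the same spec produces version 2 with byte-identical data
checksums; `revise_spec()` changes one of the six sections without
touching the others. The same workflow is scriptable from a shell via
`inst/cli/cohortforge` (`simulate`, `validate`, `summarize`, `select`
(wizard), `run`, `revise`, `versions`).

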