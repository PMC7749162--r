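# ctgaudit

Metadata-quality auditing for clinical-trial registration records in the
ClinicalTrials.gov public-XML dialect.

Trial registrations are the largest source of structured metadata about
clinical studies, and they are reused well beyond their regulatory purpose:
systematic reviews, metanalyses of funding and study design, and matching
of patients to trials all query these records. That reuse depends on
records being complete, well-typed and drawn from controlled vocabularies.
`ctgaudit` measures exactly that, for registry curators, meta-researchers
and informaticians:

* **Schema registry** — the data dictionary as a machine-readable table
  (149 elements; type categories, enumerated value sets, requirement
  rules, and the dictionary ↔ XML ↔ FDAAA801 ↔ WHO name mapping).
* **Type validation** — Boolean (`Yes|No`), integer, date
  (`Unknown | Month [day,] year`, day 1–31) and age
  (`N/A | [1-9][0-9]* Unit`) grammars, with age normalization to a
  minutes-equivalent so `2 Years` = `24 Months`.
* **Enumerated-value validation** — 16 fields checked against their
  permitted sets; out-of-set values become `ROGUE_VALUE` findings, and
  the record-form syntax of *interventional study model* and *masking*
  ("Parallel Group Assignment", "Double(Participant, Care Provider)") is
  recognized and canonicalized.
* **Completeness audit** — 28 audited FDAAA801 required fields over
  interventional records, with conditional requirements (why study
  stopped; site status), the Final Rule era split at 2017-01-18,
  agency-class stratification, the principal-investigator partition and
  the overall-contact-or-every-site contact rule.
* **Eligibility criteria** — classification of criteria text into
  correct / headers-only / malformed-headers / missing, parsing of
  conformant blocks into inclusion/exclusion lists, a multi-group
  heuristic, and Wilson-interval sample extrapolation.
* **Lexicon coverage** — exact-match (normalize-then-compare) coverage of
  condition and intervention values against pluggable terminology
  lexicons, per source and per intervention type.
* **Synthetic corpus generator** — seeded, deterministic corpora with
  exact planted defect counts, so every audit statistic is testable
  against ground truth without the live registry.

## Worked example

```r
library(ctgaudit)
library(dplyr)

# a 400-record corpus with known defects
gen <- generate_corpus(corpus_config(
  400, seed = 7,
  study_type_mix = c(Interventional = 0.8, Observational = 0.2),
  missing_plan = list(allocation = 40, "arm information" = 25),
  rogue_plan = data.frame(field = "allocation",
                          value = "Random Sample", count = 6),
  criteria_class_plan = c(correct = 243, headers_only = 98,
                          malformed_headers = 58, missing = 1)))

summary <- run_audit(gen$records, lexicons = ctg_fixture_lexicon())
summary
#> <ctg_audit_summary> 400 records (320 interventional)
#>   findings: 646 (6 problem-level)
#>   criteria classes: correct=243, headers_only=98, malformed_headers=58, missing=1

filter(summary$enumerated, rogue > 0)
#> # A tibble: 1 × 3
#>   dictionary_name rogue example_values
#>   <chr>           <int> <chr>
#> 1 allocation          6 Random Sample

filter(summary$missing_by_era, field %in% c("allocation", "arm information")) |>
  select(field, missing_all, pct_all)
#> # A tibble: 2 × 3
#>   field           missing_all pct_all
#>   <chr>                 <int>   <dbl>
#> 1 allocation               40    12.5
#> 2 arm information          25    7.81
```

The audit recovers the planted counts exactly: 6 rogue allocation values,
40 records missing *allocation*, 25 missing *arm information* (12.5% and
7.8% of the 320 interventional records), and the 243/98/58/1 criteria
class split. The 646 findings include 640 informational notes recording
the record-form syntax of *interventional study model* and *masking* in
conformant records (two per interventional record); only the 6 planted
rogue values are problem-level.

Sample extrapolation, as used to scale a manual review of 400 records to
a 117,906-record stratum:

```r
extrapolate(55, 400, 117906)
#> Sample 55/400 (13.8%) of population 117906
#>   point estimate 16212, 95% CI [0.1072, 0.1747]
```

## Command line

A thin CLI over the same functions ships in `inst/cli/ctgaudit.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ctgaudit.R", package="ctgaudit"))')" \
  generate --n 500 --seed 1 --out corpus/
```

with verbs `generate`, `audit`, `criteria` and `coverage`.
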