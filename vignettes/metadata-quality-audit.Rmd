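---
title: "Auditing the metadata quality of clinical-trial registrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the metadata quality of clinical-trial registrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgaudit)
library(dplyr)
```

## The problem

ClinicalTrials.gov registrations are the largest collection of descriptive
metadata about clinical trials: key-value records describing a trial's
design, eligibility criteria, interventions, sponsors, investigators and
outcome measures. These records are reused far beyond their regulatory
purpose -- in systematic reviews, funding and study-design metanalyses, and
patient-to-trial matching -- and all of those uses depend on the records
being *complete* (required fields filled), *well-typed* (values conforming
to their declared grammars and value sets), and *interoperable* (search
fields drawn from controlled vocabularies).

`ctgaudit` turns that assessment into a reusable pipeline. It audits
records in the registry's public-XML dialect along four axes:

1. **Simple types.** Boolean, integer, date and age fields are validated
   against explicit grammars.
2. **Enumerated values.** Sixteen dictionary fields carry enumerated value
   sets; out-of-set ("rogue") values are flagged, and two fields whose
   record syntax deviates from the dictionary's printed set are handled
   specially.
3. **Completeness.** Interventional records are audited for 28 required
   registration fields, with conditional-requirement logic, a regulatory
   era split, agency-class stratification, and dedicated
   principal-investigator and contact-information rules.
4. **Vocabulary coverage.** Condition and intervention values are measured
   for exact-match coverage against pluggable terminology lexicons.

Because the full registry dump is hundreds of thousands of records and not
something a test suite can depend on, the package includes a seeded
synthetic-corpus generator with controlled defect injection: every audit
statistic can be checked against a planted ground truth.

## The field registry

The data dictionary is shipped as a versioned delimited file
(`inst/extdata/field_registry.tsv`) with one row per dictionary element --
149 in all, with composite elements (study design, outcome measures,
facility information) expanded into sub-specifications. Each row records
the element's type category, permitted values, multiplicity, requirement
status, and its name in four naming systems (data dictionary, XML dialect,
FDAAA801, WHO Trial Registration Data Set).

```{r}
reg <- ctg_registry()
count(reg, value_kind)
registry_lookup(reg, "number_of_arms", "xml")[, c("dictionary_name", "value_kind")]
```

Of the 41 FDAAA801 required fields, 13 are excluded from completeness
auditing for reasons the registry records explicitly: 5 are conditionally
required on information not available in the public data, 3 are stored
internally and never published, 3 were only added to the registry in late
2017, and 2 are administrative values present in every record. That leaves
28 audited fields. The WHO mapping is carried as metadata only;
completeness is audited against the FDAAA801 set plus the separately
reported principal-investigator rule.

Two transcription decisions are worth knowing about:

* The dictionary's printed value set for *study phase* omits the plain
  "Phase 2" even though "Phase 1/Phase 2" and "Phase 2/Phase 3" are both
  present and "Phase 2" demonstrably occurs in records. The registry
  includes it and notes the discrepancy in the data file's header comment
  in `data-raw/field_registry.R`.
* *Agency class* is constrained in practice to NIH / U.S. Fed / Industry /
  Other, but it is a sponsor attribute rather than one of the dictionary's
  sixteen enumerated-value fields, so it is typed on the record object and
  not checked by the enumerated-value validator.

## Record I/O and the date problem

`read_trial_record()` maps a public-dialect XML document onto a typed
record object. Two principles govern it. First, *no coercion at parse
time*: every value, dates included, is stored as raw text. Registry dates
may be day-absent ("March, 2005"), and general-purpose date parsers behave
unpredictably on such input, so interpretation is deferred to
`parse_ctg_date()`, which implements the registry grammar exactly and
flags when it has imputed a day. Second, *nothing is dropped*: every leaf
element is preserved in a `raw_values` table in document order, and the
typed fields are views over the same content.

`write_trial_record()` emits the same dialect with a fixed element order,
so a generated corpus is byte-deterministic and write-then-read is the
identity on the retained field set (a property the test suite checks on
generated fixtures).

## Grammars and their quirks

The simple-type grammars are:

| kind    | grammar |
|---------|---------|
| Boolean | `Yes` or `No`, exactly |
| integer | unsigned decimal digits |
| date    | `Unknown`, or month name + optional day (1--31) + `, ` + four-digit year; optional `Actual`/`Anticipated`/`Estimate` attribute |
| age     | `N/A`, or a positive integer with no leading zero + one space + `Year(s)`/`Month(s)`/`Week(s)`/`Day(s)`/`Hour(s)`/`Minute(s)` |

The dictionary's printed patterns are typeset with missing spaces and a
day alternation that technically admits a day of zero; every printed
example ("January 3, 2004", "2 Years") contains the space and no example
shows day zero, so this package's grammars follow the examples: exactly
one space, day 1--31. Month-day plausibility (e.g. "February 31, 2010")
is deliberately *not* checked, as the published grammar admits any day up
to 31; the grammar's fidelity comes first and a calendar-validity check
would be a different (stricter) contract. The grammars are verified
against brute-force rule checkers over exhaustive small domains in the
test suite.

Ages with different units are made comparable by `normalize_age()`, which
applies a fixed conversion table (Year = 525,600 minutes, Month = 43,800,
Week = 10,080, Day = 1,440, Hour = 60), so "2 Years" and "24 Months"
compare equal:

```{r}
normalize_age("2 Years")$minutes_equivalent
normalize_age("24 Months")$minutes_equivalent
```

## Enumerated fields, record forms, and severity semantics

Enumerated matching is exact and case-sensitive after trimming: the value
sets are short controlled lists and the registry's entry system emits them
with fixed capitalization, so a case difference *is* a deviation worth
flagging. Two fields need special handling because the syntax in public
records differs from the dictionary's printed set:

* *Interventional study model*: records carry "Parallel Group
  Assignment", "Crossover Assignment", etc. rather than "Parallel",
  "Crossover". Record forms are accepted;
  `canonicalize_enumerated()` maps them back to dictionary form.
* *Masking*: records carry a Single/Double/Triple/Quadruple count word
  with a parenthesised role list ("Double(Participant, Care Provider)").
  The count word must agree with the number of roles;
  canonicalization returns the role set.

Findings carry one of four severity levels, mirroring the registry entry
system's own warning taxonomy (Error / Warning / Alert / Note). The
per-code assignment is this package's own: `TYPE_MISMATCH` is an error,
`ROGUE_VALUE` a warning, and `FORMAT_VARIANT` -- emitted for every valid
record-form model/masking value -- a note. Notes are informational: they
mark a documented divergence between dictionary and dialect, not a defect
in the record. Consequently "a clean corpus yields no findings" is
defined over problem-level severities (error/warning/alert); a fully
conformant record in the real dialect *necessarily* produces
`FORMAT_VARIANT` notes, because the dialect itself diverges from the
dictionary.

## Completeness logic

`audit_completeness()` evaluates interventional records only (the
required-element rules are defined for interventional trials; other
record kinds pass through every other stage). The rules with judgment in
them:

* **Multiplicity.** A field permitting multiple occurrences is missing
  iff zero occurrences are listed. Sub-fields that attach to listed
  parents (outcome time frame/description; facility name, city, country;
  site status) are tabulated only when the parent group exists --
  otherwise the parent's absence is the finding.
* **Conditional requirements.** *Why study stopped* is required only when
  the overall status is Suspended, Terminated or Withdrawn; *individual
  site status* only when facilities are listed. A conditional field is
  "missing" iff absent *and* active. Conditional fields whose condition
  cannot be evaluated from public data are excluded by the registry,
  never guessed.
* **The era split.** The Final Rule's updated definitions bind trials
  starting on or after 2017-01-18. Four fields (official title, why study
  stopped, study start date, study completion date) were only
  recommended before that date; for pre-rule records their absence is
  reported in a separate `missing_recommended` bucket rather than
  `missing_required`. Corpus tabulations (`summarize_completeness()`)
  count missingness era-agnostically -- the requirement's era-dependence
  is a property of the *requirement*, not of the observation -- which is
  also what makes pre-rule missingness columns meaningful.
* **Day-absent January 2017.** A start date of "January, 2017" is
  era-ambiguous. The package imputes day 1 (hence pre-rule), reports the
  imputation as a per-record flag, and leaves the convention documented
  rather than hidden.
* **Unknown start dates** are binned with the pre-rule column in
  era-stratified tables: a record whose start date is missing cannot be
  post-rule-required, and this is the only binning under which the
  missing-start-date row itself can be tabulated.
* **Contacts.** Contact information is satisfied by an overall contact
  *or* a contact at every listed site. A contact detail counts as
  provided iff at least one sub-field (name, phone, email) is present;
  `audit_contact_details()` then counts missing phones and emails among
  provided details only.
* **Principal investigators.** A PI can be designated through the
  responsible party (type "Principal Investigator" or
  "Sponsor-Investigator") or through an overall official; the four-way
  partition (neither / responsible party only / official only / both) is
  computed per record.

## Eligibility criteria

The expected criteria format is two headers -- "Inclusion Criteria",
"Exclusion Criteria" -- each followed by a bulleted list. The registry
does not publish the exact expressions behind its format statistics, so
this package defines one canonical grammar and treats it as *the*
classification; all class counts are relative to it:

* Header matching is case-insensitive after whitespace normalization and
  tolerates a trailing colon only. "Key Inclusion Criteria" or
  "INCLUSION:" are *malformed* (alternative headers), matching the
  observed error taxonomy.
* The bullet-marker set is `-`, `*`, `•`, and numbered items
  (`1.`/`2)`), covering the pre-populated entry format plus common
  variants; it is configurable.
* Blank lines are ignored everywhere.

```{r}
classify_criteria(
  "Inclusion Criteria:\n- age over 18\nExclusion Criteria:\n- pregnancy")
```

`detect_multi_group()` flags blocks that appear to define criteria for
more than one participant group (more than two header-like lines, or a
header carrying a qualifier such as "Inclusion Criteria - Cohort B"). It
is precision-oriented and advisory: the published multi-group rate came
from human review, and the heuristic is validated only against synthetic
plants.

`extrapolate()` scales a sample count to a population with a Wilson score
interval. Wilson is preferred to the Wald interval because it behaves at
the boundaries (zero successes give a zero lower bound, not a negative
one) and is accurate at moderate sample sizes; the choice is documented
and the function is small enough to swap. `sample_size_for_margin()`
gives the planning arithmetic: 385 subjects suffice for a +/-5% margin at
95% confidence with a worst-case proportion, which is why a 400-record
review sample is comfortably adequate.

```{r}
extrapolate(55, 400, 117906)
sample_size_for_margin(0.95, 0.05)
```

Splitting a block into separate inclusion/exclusion fields
(`split_criteria_fields()`) and reclassifying each half in headerless
mode removes header-related error codes by construction -- the per-record
version of the observation that separate structured fields would
eliminate the header-error class entirely.

## Lexicon coverage

"Exact match" is defined as equality after trimming, internal-whitespace
collapsing and case-folding. Registry values capitalize inconsistently,
so case-folding is the default; a strict-case mode exists for vocabulary
work where case is meaningful. Values are counted as a bag -- every
listed occurrence counts -- because the registry's published denominators
are listing counts, not unique strings.

The bundled lexicon (`ctg_fixture_lexicon()`) is synthetic: real-looking
condition and intervention names with fabricated source assignments and
identifiers, deliberately overlapping across its three sources so union
accounting is exercised. A live terminology-service adapter can stand
behind the same `read_lexicon()` contract, but network-backed sources are
kept out of the test suite by design.

```{r}
match_terms(c("Diabetes Mellitus", "diabetes  mellitus", "unmapped term"),
            ctg_fixture_lexicon())
```

## The synthetic generator

`generate_corpus()` is the test bed for everything above. Design points:

* **Exact counts by default.** In `exact_counts` mode a plan entry of
  *k* plants exactly *k* defects by sampling eligible records without
  replacement, turning recovery checks into equalities. `rates` mode
  exists for realism experiments and demonstration profiles.
* **Independent defect families.** Each family (era assignment, each
  missing field, each rogue entry, criteria classes, lexicon membership,
  contacts) draws from its own stream, split deterministically from the
  master seed -- editing one plan entry does not reshuffle unrelated
  placements, and the same configuration is byte-identical across runs.
* **Fixed interaction order.** Criteria classes, then lexicon
  membership, then missing fields (facility removal first, since
  site-level plants need surviving sites), then rogue values, then
  contact degradation. Start-date removal is drawn from pre-rule records
  so it cannot silently move records between era bins.
* **Deliberate irregularities.** Person names are written into the
  last-name field complete with degrees ("Sarah Smith, M.D."), as the
  registry does, so downstream consumers must cope with it.
* **What it does not emulate.** Free-text realism (criteria wording
  beyond format class, condition-name distributions, inter-field
  correlation) is out of scope. Passing recovery tests therefore shows
  the audit counts what it claims to count -- it does not show how a
  particular historical corpus scores.

`headline_profile()` is a rates-mode preset whose plan rates echo headline
registry statistics (roughly 61/24/15/0.3% criteria classes, 74% of
records without an overall contact, a 12/7.5/54/27 PI split, 10% of
interventional records without arms, 62%/46% condition/intervention
coverage), for demonstration reports and the acceptance script.

## Problem sizes and orchestration

`run_audit()` makes one pass over a corpus, applying every stage and
assembling per-field tallies, era/agency missingness tables, the PI
partition, contact summaries, the criteria-class table and coverage
tables; `render_audit()` writes them as deterministic delimited or JSON
files, with criteria-class percentages at one decimal and integer
percentages elsewhere, matching how such tables are conventionally
printed. The test suite exercises corpora of up to 1,000 records and the
acceptance script audits a 1,000-record profile corpus plus a 200-record
clean control -- sizes chosen so the full check suite completes in a few
minutes on one CPU while keeping binomial noise in rates-mode checks
well below the 4-standard-deviation acceptance bands.

## Known limitations

* The XML dialect is fixed to the element names used by the audit;
  results-section XML is out of scope.
* The criteria grammar is a declared stand-in for the registry's
  unpublished expressions; class counts on real corpora are relative to
  it.
* The multi-group heuristic trades recall for precision and is validated
  against synthetic plants only.
* Synonym expansion and hierarchy navigation over vocabularies are out
  of scope; coverage is exact-match only.
* One pre/post-Final-Rule distinction is modeled; the dictionary's full
  revision history is not.
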