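---
title: "Methods: hierarchical etiology assignment and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical etiology assignment and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepetio)
```

## The problem

Administrative healthcare data — physician billing claims, hospital
discharge abstracts, emergency-department records and centralized
laboratory feeds — contain no clinical narrative, so studies of chronic
liver disease (CLD) and cirrhosis must infer each patient's disease
*etiology* from surrogates: viral-hepatitis serology results and ICD-9 /
ICD-10 diagnosis codes. hepetio implements a hierarchical assignment
algorithm for this task, the diagnostic-accuracy machinery needed to
validate it against gold-standard chart review, and a synthetic
linked-cohort generator with a known observation model so the whole
validation design can be exercised end to end without access to protected
health data.

## The hierarchy

Each patient is anchored at an *index date* (their clinic-visit date).
Rules are evaluated in a fixed order and the first satisfied rule assigns
the label, mirroring how a hepatologist excludes more plausible causes
first:

1. **HCV** — a positive HCV RNA or HCV genotype result on or before the
   index date. A positive HCV antibody in isolation is *not* diagnostic:
   antibody persists after viral clearance, so only evidence of viremia
   counts.
2. **HBV** — a positive HBV DNA or HBV surface antigen result.
3. **Autoimmune** — at least one diagnosis code for autoimmune hepatitis,
   primary biliary cholangitis or primary sclerosing cholangitis,
   strictly before the index date.
4. **Hereditary hemochromatosis** — at least one matching code, same
   window.
5. **Alcohol-related** — at least one code from a broad alcohol list
   (alcoholic liver disease, dependence and withdrawal, alcohol
   poisoning, and alcohol-attributed damage to other organs).
6. **NAFLD/cryptogenic** — the terminal default. There is no "unknown"
   output; rare etiologies outside the label set (Wilson disease,
   alpha-1 antitrypsin deficiency) necessarily land here.

A single matching record suffices at the code steps: the code lists are
specific enough that requiring repeat claims would trade sensitivity for
little specificity in this setting. Steps 3 and 4 form one conceptual
"rare causes" evaluation; we order autoimmune first as the more prevalent
condition, record an `ambiguity_flags` note whenever both code sets
match, and expose the order as a `hierarchy` argument so the choice can
be stress-tested:

```{r}
dx <- dplyr::bind_rows(
  tibble::tibble(patient_id = "P1", system = "ICD10", code = "K743",
                 service_on = as.Date("2010-05-05"), source = "DAD"),
  tibble::tibble(patient_id = "P1", system = "ICD10", code = "E8310",
                 service_on = as.Date("2011-06-06"), source = "NACRS"))
classify_patient(NULL, dx, as.Date("2013-06-15"))[c("label", "step",
                                                    "ambiguity_flags")]
```

### Time windows

Coded diagnoses must fall **strictly before** the index date — the
algorithm is designed to be applicable at the moment a patient presents.
Lab results are accepted **on or before** the index date: same-day
serology drawn at the clinic visit is plausibly part of that visit's
work-up, and the asymmetry is isolated behind `has_positive_hcv()` /
`has_positive_hbv()` should a user want to change it. Diagnosis rows
dated after the index date are retained on ingest and filtered at
classification time, so one cohort file supports several index-date
analyses. `INDETERMINATE` lab results count as non-positive everywhere:
every rule demands an affirmative positive result.

### Code normalization and matching

Published code lists and administrative extracts mix dotted (`K74.3`,
`571.42`) and undotted (`K700`) styles, and mix three-digit category
codes (`303`, alcohol dependence) with five-character specific codes.
We therefore normalize every code (upper-case, dots and whitespace
removed; idempotent) and match by **prefix**: pattern `303` catches
`30390`, while `3050` deliberately does not catch `30510` (tobacco use
disorder). Exact-versus-prefix matching is a genuinely open design point
for administrative-data phenotyping; prefix matching is our documented
choice because real claims usually carry fuller codes than the published
category entries. Matching never crosses code systems, and no
ICD-9-to-ICD-10 cross-mapping is attempted: each list is authoritative
per system. The built-in lists (`default_code_lists()`) can be replaced
from a YAML/JSON config (`read_code_lists()`) for reuse in other
jurisdictions; the record source (DAD / NACRS / OHIP) never changes
matching semantics but is preserved in evidence so users can audit which
database contributed — relevant because outpatient billing systems often
lack specific codes for the autoimmune conditions and hemochromatosis.

## Validation statistics

`validate_etiology()` compares assignments with gold-standard labels
one-vs-rest per etiology, stratified by cirrhosis status plus an overall
stratum. Per (stratum, etiology) row it reports the confusion cells and:

* **Sensitivity** tp/(tp+fn), **specificity** tn/(tn+fp), **PPV**
  tp/(tp+fp), **NPV** tn/(tn+fn), each with a two-sided binomial
  interval. The default is the exact Clopper–Pearson interval — the
  conservative standard for validation studies, where cells are often
  small — with the Wilson score interval selectable (`ci_method`).
* **Cohen's kappa** \((p_o - p_e)/(1 - p_e)\) with a Fleiss-style
  asymptotic standard error
  \(\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}\), normal-approximation interval
  truncated to \([-1, 1]\). Conventionally, kappa above 0.60 indicates
  substantial and above 0.80 almost perfect agreement. A supplementary
  multi-class kappa over all six labels is reported by `glance()`.

Degenerate inputs are reported as missing, never coerced: a metric with a
zero denominator (no gold-positive patients in a stratum) is `NA`, and
kappa is `NA` when both raters are constant (\(p_e = 1\)). Etiologies
absent from a stratum are omitted entirely, the same convention
validation papers use when an etiology cannot be validated for lack of
cases. `alpha` outside (0, 1) and misaligned vectors raise classed
validation errors.

### Small-cell suppression

Privacy agreements covering administrative data holdings typically forbid
reporting cells of n ≤ 5. `write_report()` applies this at **reporting
time only** (computation always uses full precision): any confusion count
at or below the threshold is rendered as a marker, as is every statistic
whose defining cells include such a count (sensitivity depends on
{tp, fn}, specificity on {tn, fp}, PPV on {tp, fp}, NPV on {tn, fn},
kappa on all four). The threshold (default 5) and marker (default `"NR"`)
are configurable, and suppression is monotone in the threshold. Displayed
statistics are rounded to two decimals, the customary precision of
published validation tables.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure of a linked validation study:
a patient cohort with index dates in a summer 2013 clinic window, a
qualitative viral-serology table, and a coded-diagnosis table whose
records carry a source database and an ICD revision determined by service
year (ICD-9 before 2002, ICD-10 from 2002 onward, matching when each
revision was in use in Canadian data).

The generative model: each of `n` patients draws a cirrhosis status
(default probability 233/442) and a true etiology from a prevalence
vector. The default mix — HCV 45%, NAFLD/cryptogenic 26%, alcohol 10%,
HBV 9%, autoimmune 9%, hemochromatosis 1% — reproduces the composition of
a single-centre outpatient hepatology cohort, the setting such validation
studies draw from. With `stratified = TRUE`, per-stratum vectors are used
instead; the two cells a privacy-suppressed source table leaves
unprintable (alcohol and hemochromatosis by stratum) are filled by
allocating the overall counts proportionally across strata (36/5 with
cirrhosis, 9/1 without), which is consistent with every printed bound and
with the stratum totals — a documented convention, not observed data.

Observation error is modeled as independent events given the true label:

| Parameter | Default | Meaning |
|---|---|---|
| `lab_sensitivity` (HCV, HBV) | 0.95, 0.94 | qualifying positive lab recorded for a true case |
| `lab_fpr` | 0.002 | spurious qualifying positive for a non-case |
| `code_sensitivity` (AI, HH, alcohol) | 0.70, 0.40, 0.85 | ≥1 matching code before index for a true case |
| `code_background` | 0.01, 0.005, 0.03 | ≥1 matching code for a non-case |

The code-recording defaults were chosen once to echo the magnitude of
published per-etiology accuracy in this field — code capture is strong
for alcohol-related disease, moderate for autoimmune disease and weak for
hemochromatosis, which outpatient billing cannot code specifically — and
the lab defaults reflect that centralized serology feeds capture nearly
all viral-hepatitis testing. True HCV cases also receive a positive
antibody record (probability 0.98) that the classifier must ignore, and
negative serology plus non-matching chronic-disease filler codes are
sprinkled in so matching is exercised against realistic clutter.

Because observation events are independent given the truth, the
composition of the generator with the hierarchy has a closed form:
`expected_classification_matrix()` returns the 6×6 matrix of
\(P(\text{assigned}=a \mid \text{true}=t)\) by multiplying the
first-satisfied-rule probabilities. This is the analytic oracle for
parameter-recovery tests: simulated per-etiology sensitivity and
specificity must fall inside the 99% Monte-Carlo band the matrix implies
at the simulated size, and a perfect observation model must recover the
identity matrix — every defined metric exactly 1.

```{r}
cfg <- sim_config(n = 1000, seed = 1)
sim <- simulate_cohort(cfg)
v <- validate_etiology(sim$cohort, classify_cohort(sim$cohort))
glance(v)
round(expected_classification_matrix(cfg), 3)
```

What the generator does **not** emulate: correlated coding (a sick
patient accumulating codes across several lists), healthcare-utilization
intensity differences between strata, secular drift in testing practice,
or record-linkage error. Passing parameter recovery therefore shows the
pipeline is internally consistent under a known observation model — it
does not certify accuracy on real claims, where coding is correlated with
disease severity and contact frequency.

## Problem sizes and numerical choices

The test suite validates the classifier against an independent
first-satisfied-rule oracle on thousands of randomized small cohorts,
cross-checks kappa against an independent implementation to 1e-10, runs
parameter recovery at n = 20,000, checks the analytic matrix against
Monte-Carlo frequencies at n = 20,000 within four standard errors per
cell, and checks Clopper–Pearson coverage with 1000 replicates of
n = 100 at p ∈ {0.1, 0.5, 0.9} — sizes chosen to make sampling noise
negligible relative to the tolerances while keeping the suite quick to
run. All simulation is seeded; identical configurations yield
byte-identical output files. Dates are ISO-8601 throughout. Lab results
are qualitative only (POSITIVE / NEGATIVE / INDETERMINATE): the
hierarchy uses positivity, never viral-load magnitude.

## Known limitations

* Single-label output: mixed etiologies (e.g. viral hepatitis with
  contributing alcohol use) resolve to the highest-ranked satisfied rule,
  by design.
* The autoimmune composite cannot distinguish AIH, PBC and PSC.
* No record linkage or deduplication: identifiers are assumed pre-linked.
* Accuracy claims transfer to real administrative data only to the
  extent the observation model holds; the generator's independence
  assumption is optimistic for patients with heavy healthcare contact.
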