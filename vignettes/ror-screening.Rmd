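---
title: "Disproportionality screening of spontaneous reports with faerssignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports with faerssignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerssignal)
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports linking a patient's drug
exposures to suspected adverse events, each event coded as a MedDRA-style
preferred term (PT) nested in a system organ class (SOC). Because there is
no denominator population, the standard screening question is
*disproportionality*: is a (drug, PT) pair reported more often than the
database background would predict? `faerssignal` implements this workflow
for infection-related adverse events of targeted anti-cancer drugs — the
motivating use case is the CDK4/6-inhibitor class used in hormone
receptor-positive breast cancer, where myelosuppression makes infections a
clinically important signal — but nothing in the package is specific to
that class.

## The statistic

For a target drug and target PT the package builds the 2×2 table

|                | target PT | other PTs |
|----------------|-----------|-----------|
| target drug    | a         | b         |
| other drugs    | c         | d         |

and computes the reporting odds ratio

$$\mathrm{ROR} = \frac{a/c}{b/d}, \qquad
95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\right).$$

A pair is flagged as a **signal** when `a >= 3` and the lower CI bound is
strictly greater than 1. Both thresholds are configurable (`min_a`,
`ci_floor`); the defaults are the classical screening criteria. No other
disproportionality estimator (PRR, EBGM, BCPNN) is provided, and no
multiplicity adjustment is applied across PTs — the screen is a triage
device, not a hypothesis test family.

### Counting conventions

Published extracts are ambiguous about what the universe `a+b+c+d` counts.
Two conventions are implemented:

* `"pairs"` (default): the universe is the set of distinct (report, PT)
  incidence pairs — a report with *k* distinct PTs contributes *k* rows,
  so `a+b` is the drug's total adverse-event count. This matches
  OpenVigil-style report–reaction counting, in which a drug's "all AEs"
  column is far larger than its report count.
* `"reports"`: the universe is the set of distinct cases.

Within a report, PT multiplicity never matters: a case listing the same
PT twice contributes once to `a`. Both conventions agree on `a`.

### Zero cells

When any cell is zero the CI is undefined: the bounds are reported as
`NA`, the result is flagged `undefined_ci`, and the pair never signals.
No Haldane–Anscombe 0.5 continuity correction is applied — the `a >= 3`
gate already excludes the region where the correction would change a
verdict, and an explicit flag is more honest than a corrected estimate.

## The pipeline

`run_pipeline()` chains five steps per drug, mirroring standard
pharmacovigilance practice:

1. extract every PT reported under the drug (any role code);
2. map PTs to SOCs with a user-supplied PT→SOC table;
3. keep PTs from the infection-related SOCs — by default *infections and
   infestations* and *respiratory, thoracic and mediastinal disorders* —
   as screening candidates;
4. screen candidates with the ROR rule, counting the drug under **all**
   role codes;
5. retrieve the cases listing at least one enrolled (signalled) PT and
   keep those where the drug is the **primary suspect** (role `PS`).

The ordering in steps 4–5 is deliberate: the primary-suspect restriction
is a case-selection step, not a counting step, so the screen sees the full
reporting background while the descriptive analyses see only the cases
most plausibly attributable to the drug. Disabling the PS filter can only
enlarge each enrolled case set (a tested invariant).

The respiratory SOC contains inflammatory, non-infectious terms
(pneumonitis, organising pneumonia) whose inclusion is a judgment call
rather than a rule; the config exposes `pt_allow` / `pt_deny` override
lists instead of hard-coding that judgment.

Stage counts are emitted per drug: `all_aes` (the drug's adverse-event
count under the counting convention), `infection_aes` (distinct cases
listing an enrolled PT), and `infection_ps` (those with the drug as
primary suspect). They nest by construction, and the pipeline is a pure
function of (config, reports, map): reruns are byte-identical.

## The report model

* **Deduplication.** FAERS publishes follow-up versions of a case; all
  counting assumes one record per case. `deduplicate()` keeps, per case
  id, the record with the greatest version key under plain C-locale
  string comparison (keys have the form `"2020Q3-2"`: receipt quarter
  plus version); exact ties keep the record appearing last in input
  order, which falls out of a stable radix sort. The operation is
  idempotent.
* **Drug matching** is exact normalized-name equality (trimmed,
  case-folded, whitespace-collapsed) against a per-drug synonym list —
  never substring matching, which produces false positives on combination
  strings. Free-text spelling correction is out of scope; the synonym
  list is where brand names and common variants belong.
* **Ages** are stored in years; the FAERS dialect converts from the
  recorded unit (decades ×10, months ÷12, weeks and days via 365.25,
  hours likewise). Missing sex/age/country remain explicit `unknown`
  categories rather than dropped rows, matching how published
  characteristics tables report them.
* **Quarter window.** Receipt-quarter filtering (default 2015Q1–2022Q3,
  the post-approval window of the motivating drug class) uses the
  demographics table's receipt date, which is what a quarterly extract
  actually selects on.

## Severity and descriptives

Outcome codes follow the FAERS vocabulary: hospitalization (HO), death
(DE), life-threatening (LT), disability (DS), other (OT), or none
recorded. A case is **serious** when it carries any of HO/DE/LT/DS,
**non-serious** when its only code is OT, and **unknown** when no code is
recorded.

`outcome_table()` assigns each case to exactly **one** outcome category,
because descriptive outcome tables whose columns sum to the case totals
imply one category per case. Since a case can carry several codes, a
precedence order decides: the default DE > LT > DS > HO > OT attributes
each case to its worst outcome; the order is a configurable argument,
not a claim about reporting practice.

Age bands are `<40`, `40–64`, `≥65`, `unknown`; band membership uses the
recorded age in years with 40 and 65 as the cut points. Age summaries
report median, interquartile range and min–max range separately —
published tables in this area sometimes label a min–max range as an
interquartile range, so the package never conflates the two.

`pearson_chi_square()` is the classic Pearson statistic without
continuity correction, with explicit dropping of categories (such as the
`unknown` level, which belongs to neither severity group) and a
degenerate-table error when an expected cell is zero. The implementation
delegates to `stats::chisq.test(correct = FALSE)`; the test suite checks
it against a hand-coded $\sum (O-E)^2/E$. On the bundled severity tables
of the motivating case series the sex comparison gives
$\chi^2 = 1.533$ (df = 1, p = 0.2156) and the age comparison
$\chi^2 = 3.775$ (df = 2, p = 0.1515) — reproducing the published values
exactly confirms that those analyses excluded the unknown rows and used
no continuity correction.

### Reconstructing case sets from published count tables

`cases_from_count_tables()` expands per-drug marginal counts (sex, age
band, year, country, outcome category) into a synthetic case-level
report set whose *marginal* tallies reproduce the inputs exactly. The
joint distribution is arbitrary — each characteristic is filled
independently in level order — so cross-tabulations of the result are
meaningless, and ages within a band sit at a representative value (35 /
50 / 70). This is exactly enough to verify that the descriptive code
reproduces a published table's totals and percentages, and nothing more.
The bundled tables under `inst/extdata/` hold the published per-drug
counts of a CDK4/6-inhibitor infection case series (1281 cases:
892/337/52 across the three drugs). One internal inconsistency is worth
recording: the series' narrative quotes 225/337 = 66.77% serious
outcomes for the middle drug, while its own outcome table sums to
228/337 = 67.66%; the package reports the table-derived value, since the
table is the unit the code reproduces.

## The synthetic generator

`simulate_reports()` draws complete FAERS-like databases from an explicit
generative model, so every pipeline stage can be tested against known
ground truth without any download:

* each case draws its drug set as independent Bernoulli indicators
  (rejection-sampled until non-empty), then each PT independently with
  probability `min(1, p × rate)`, where `rate` is the largest planted
  enrichment matching any of the case's drugs (1 when none);
  rejection-sampling again guarantees at least one PT;
* demographics, role codes and a single outcome code are drawn
  independently; a configurable fraction of cases emits a follow-up
  version dated one quarter later, exercising deduplication;
* the same (config, seed) always reproduces the identical report set,
  and the caller's RNG state is restored.

Because the conditionals introduced by rejection sampling are available
in closed form, `expected_counts()` computes the exact expected 2×2
cells for any pair by enumerating drug subsets — an independent oracle
the tests compare empirical counts against, and a practical power
calculator for choosing planted rates.

The default configuration emulates the motivating setting: three target
drugs of decreasing market share (marginal probabilities 0.10 / 0.03 /
0.02) against five common background drugs, 24 PTs across four SOCs at
background rates of 0.8–9%, a predominantly female (85%) and elderly
population, US-weighted countries, uniform 2015–2022 reporting years,
FAERS-like outcome frequencies with a 40% unknown fraction, and a 5%
duplicate rate.

What the generator deliberately does **not** emulate: PT–PT correlation
(draws are independent Bernoulli, while real syndromes co-report),
drug–demographic dependence, free-text drug strings, real FAERS marginal
frequencies, or multiple outcome codes per case. Passing tests therefore
demonstrate that the counting, screening and summarisation machinery is
correct under a clean model — not that any particular real-world signal
is true.

## Numerical and design choices

* Version keys, quarters and all ordered text compare in the C locale
  (radix sort), so results do not depend on the session locale.
* Screening output orders signals first (descending ROR, alphabetical on
  ties), then non-signals alphabetically — determinism over aesthetics.
* Printed outputs round percentages and ROR/CI to 2 decimals and
  p-values to 4; internal objects keep full precision.
* Enrichments combine by maximum (not product) when several match one
  case, keeping planted relative rates interpretable one at a time.
* Problem sizes in the shipped tests: brute-force oracles run at 100–2000
  cases; operating characteristics use 100 replicates of 5000 cases
  (planted relative rate 5, analytic expected `a` ≈ 70), where the screen
  recovers the planted pair in ≈100% of replicates and flags ≈2–3% of
  unplanted candidate PTs under independence, consistent with the
  one-sided 2.5% level implied by the CI criterion.

## Limitations

Disproportionality is association, not causation: reporting odds ratios
inherit all the biases of spontaneous reporting (stimulated reporting,
confounding by indication, unknown denominators), and a screen of many
PTs at a fixed CI criterion will always carry false positives. The
package's job is to make the screening arithmetic and its operating
characteristics explicit and reproducible — causality assessment is a
separate, clinical task.
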