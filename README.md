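# faerssignal

Disproportionality signal detection for FAERS-style spontaneous
adverse-event reports.

Spontaneous-report pharmacovigilance databases (FAERS being the largest)
have no denominator population, so post-marketing safety screening asks a
relative question: is a (drug, event) pair reported *disproportionately*
often against the database background? `faerssignal` implements that
workflow end to end for anyone mining FAERS-structured data — the
motivating application is infection-related adverse events of CDK4/6
inhibitors (palbociclib, ribociclib, abemaciclib) in breast-cancer
pharmacovigilance, but the machinery is drug-agnostic:

* **ingestion** of the quarterly `"$"`-delimited FAERS ASCII tables
  (DEMO/DRUG/REAC/OUTC) or an equivalent TSV dialect, with case-version
  deduplication;
* the **reporting odds ratio** on the 2×2 table of drug × event report
  counts,

  ```
  ROR = (a/c) / (b/d),   95% CI = exp( ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d) )
  ```

  with the classical screening rule *a ≥ 3 and lower 95% CI bound > 1*;
* a five-step **pipeline**: extract a drug's PTs → group by system organ
  class → keep infection-related SOCs → ROR-screen → retrieve
  primary-suspect cases of the enrolled PTs;
* **descriptives**: clinical-characteristics tables, outcome-severity
  classification (serious = hospitalization / death / life-threatening /
  disability), yearly trend proportions, and Pearson chi-square
  comparisons of severe vs non-severe groups;
* a seedable **synthetic report generator** with planted drug–event
  enrichments and an analytic expected-count oracle, so every stage is
  testable without downloading anything.

## Worked example

Simulate a 5000-report database in which `drugx` carries a planted
5-fold reporting enrichment for pneumonia, then screen the
infection-related PTs and summarise the enrolled primary-suspect cases:

```r
library(faerssignal)

cfg <- simulation_config(n_reports = 5000,
  enrichments = data.frame(drug = "drugx", pt = "pneumonia", rate = 5))
sim <- simulate_reports(cfg, seed = 2024)
reports <- deduplicate(sim$reports)

pipe <- run_pipeline(pipeline_config(list(drugx = "drugx"),
                                     quarter_range = c("2015Q1", "2023Q4")),
                     reports, sim_pt_soc_map(cfg))
pipe
#> <faers_pipeline>
#>   drug all_aes infection_aes infection_ps n_signals
#>  drugx     856           132           73         1

summary(pipe$drugs$drugx$screen)
#> Signal screen for 'drugx' (pairs counting)
#>   12 candidate PT(s); 1 flagged as signals
#>   signals (descending ROR):
#>     pneumonia                      a=132  ROR 4.51 (3.60-5.65)

round(severity_counts(enrolled_cases(pipe))$pct, 2)
#>             drugx total
#> serious     32.88 32.88
#> non_serious 20.55 20.55
#> unknown     46.58 46.58
```

Reading the output: `drugx` contributed 856 report–PT incidence pairs
("all AEs"); of the 12 candidate PTs from the two infection-related
SOCs, only the planted one passed the screen (a = 132 supporting
reports, ROR 4.51 with CI clear of 1 — close to the planted rate of 5);
132 distinct cases listed it, 73 of them with `drugx` as primary
suspect; and about a third of those enrolled cases carried a serious
outcome code. `plot(pipe$drugs$drugx$screen)` draws the corresponding
forest plot.

The same screen runs on real quarterly extracts via
`parse_reports(..., dialect = "faers_ascii")` and a PT→SOC table
(`load_pt_soc_map()`), or from the shell:

```sh
inst/cli/faers-signal run --config cfg.yaml --demo DEMO.txt --drug DRUG.txt \
    --reac REAC.txt --outc OUTC.txt --pt-soc-map pt_soc.tsv --out-dir out/
```

which writes `signals.tsv`, `stage_counts.tsv`, `enrolled_cases.tsv`,
`characteristics.tsv`, `outcomes.tsv`, `severity_tests.tsv`,
`yearly_trend.tsv` and a checksummed `manifest.json`.

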