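# Descriptive summaries, severity classification, chi-square comparisons.

test_that("severity classification follows the serious > non-serious > unknown precedence", {
  rs <- toy_report_set(rep(list("drugx"), 5), rep(list("pt"), 5),
                       outcomes = list("HO", "OT", character(),
                                       c("HO", "OT"), c("OT", "OT")))
  sev <- classify_severity(rs)
  expect_equal(unname(sev), c("serious", "non_serious", "unknown",
                              "serious", "non_serious"))
  # partition invariant on simulated data
  sim <- simulate_reports(small_sim_config(n = 300), seed = 2)
  rs2 <- deduplicate(sim$reports)
  sev2 <- classify_severity(rs2)
  expect_equal(length(sev2), length(case_ids(rs2)))
  expect_true(all(sev2 %in% c("serious", "non_serious", "unknown")))
})

test_that("age bands use the <40 / 40-64 / >=65 edges and the median skips missing", {
  rs <- toy_report_set(rep(list("drugx"), 3), rep(list("pt"), 3),
                       age = c(30, 64, 65))
  ch <- summarize_characteristics(list(drugx = rs))
  expect_equal(unname(ch$age_band$counts[, "drugx"]), c(1, 1, 1, 0))
  expect_equal(unname(ch$age_stats["drugx", "median"]), 64)

  rs_na <- toy_report_set(rep(list("drugx"), 3), rep(list("pt"), 3),
                          age = NA)
  ch_na <- summarize_characteristics(list(drugx = rs_na))
  expect_equal(unname(ch_na$age_band$counts[, "drugx"]), c(0, 0, 0, 3))
  expect_true(is.na(ch_na$age_stats["drugx", "median"]))
})

test_that("characteristics summary matches generator ground truth", {
  sim <- simulate_reports(small_sim_config(n = 300), seed = 17)
  rs <- deduplicate(sim$reports)
  gt <- sim$ground_truth$assignments
  ch <- summarize_characteristics(list(drugx = rs))
  for (lvl in c("female", "male", "unknown")) {
    expect_equal(unname(ch$sex$counts[lvl, "drugx"]), sum(gt$sex == lvl),
                 info = lvl)
  }
  for (lvl in c("<40", "40-64", ">=65", "unknown")) {
    expect_equal(unname(ch$age_band$counts[lvl, "drugx"]),
                 sum(gt$age_band == lvl), info = lvl)
  }
  for (y in unique(gt$report_year)) {
    expect_equal(unname(ch$year$counts[as.character(y), "drugx"]),
                 sum(gt$report_year == y))
  }
  # percentages recompute exactly from counts
  expect_equal(ch$sex$pct[, "drugx"],
               round(100 * ch$sex$counts[, "drugx"] /
                       sum(ch$sex$counts[, "drugx"]), 2))
})

test_that("outcome table assigns one category per case by precedence and columns sum to totals", {
  rs <- toy_report_set(rep(list("drugx"), 4), rep(list("pt"), 4),
                       outcomes = list(c("DE", "HO"), "HO", character(),
                                       c("OT", "LT")))
  ot <- outcome_table(list(drugx = rs))
  expect_equal(unname(ot$counts[, "drugx"]),
               c(1, 1, 1, 0, 0, 1))  # HO, DE, LT, DS, OT, Unknown
  expect_equal(sum(ot$counts[, "drugx"]), 4)
  # brute-force tally on simulated data (one code per case by design)
  sim <- simulate_reports(small_sim_config(n = 400), seed = 23)
  rs2 <- deduplicate(sim$reports)
  gt <- sim$ground_truth$assignments
  ot2 <- outcome_table(list(drugx = rs2))
  want <- c(sum(gt$outcome == "HO"), sum(gt$outcome == "DE"),
            sum(gt$outcome == "LT"), sum(gt$outcome == "DS"),
            sum(gt$outcome == "OT"), sum(gt$outcome == "none"))
  expect_equal(unname(ot2$counts[, "drugx"]), want)
  expect_equal(sum(ot2$counts[, "drugx"]), length(case_ids(rs2)))
})

test_that("severity aggregate is the union of the four serious categories", {
  sim <- simulate_reports(small_sim_config(n = 500), seed = 29)
  rs <- deduplicate(sim$reports)
  sv <- severity_counts(list(drugx = rs))
  sev <- classify_severity(rs)
  expect_equal(unname(sv$counts["serious", "drugx"]),
               sum(sev == "serious"))
  expect_equal(unname(sv$counts["non_serious", "drugx"]),
               sum(sev == "non_serious"))
  expect_equal(sum(sv$counts[, "drugx"]), length(sev))
})

test_that("Pearson chi-square matches a hand-computed statistic and handles edge tables", {
  # hand oracle: sum (O-E)^2 / E over the retained cells
  hand_chisq <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  fixtures <- list(
    matrix(c(500, 6, 293, 1), 2,
           dimnames = list(c("f", "m"), c("s", "n"))),
    matrix(c(18, 171, 205, 5, 96, 138), 3,
           dimnames = list(c("a", "b", "c"), c("s", "n"))),
    matrix(c(12, 30, 45, 9, 41, 22), 3,
           dimnames = list(c("a", "b", "c"), c("s", "n"))),
    matrix(c(7, 11, 13, 17), 2, dimnames = list(c("a", "b"), c("s", "n"))))
  for (tab in fixtures) {
    res <- pearson_chi_square(tab)
    expect_equal(res$statistic, hand_chisq(tab), tolerance = 1e-3)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1))
    expect_equal(res$p_value,
                 stats::pchisq(res$statistic, res$df, lower.tail = FALSE))
  }
  # perfectly proportional table: statistic 0, p 1
  prop <- matrix(c(20, 40, 10, 20), 2,
                 dimnames = list(c("a", "b"), c("s", "n")))
  res0 <- pearson_chi_square(prop)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # category dropping and degenerate tables
  tab3 <- matrix(c(10, 5, 0, 8, 7, 0), 3,
                 dimnames = list(c("x", "y", "unknown"), c("s", "n")))
  res_drop <- pearson_chi_square(tab3, drop_categories = "unknown")
  expect_equal(nrow(res_drop$cells_used), 2)
  expect_error(pearson_chi_square(tab3), "degenerate")
})

test_that("severity crosstab excludes unknown-severity cases", {
  rs <- toy_report_set(rep(list("drugx"), 4), rep(list("pt"), 4),
                       sex = c("female", "female", "male", "female"),
                       outcomes = list("HO", "OT", "HO", character()))
  tab <- severity_crosstab(rs, "sex")
  expect_equal(tab["female", "serious"], 1)
  expect_equal(tab["female", "non_serious"], 1)
  expect_equal(tab["male", "serious"], 1)
  expect_equal(sum(tab), 3)  # the unknown-severity case is excluded
})

test_that("yearly trend guards division by zero and matches a brute-force tally", {
  all_ps <- toy_report_set(rep(list("drugx"), 4), rep(list("pt"), 4),
                           quarter = c("2015Q1", "2015Q2", "2016Q1",
                                       "2017Q3"))
  inf <- subset_cases(all_ps, c("T001", "T004"))
  tr <- yearly_trend(all_ps, inf)
  expect_equal(tr$year, c(2015, 2016, 2017))
  expect_equal(tr$proportion, c(0.5, 0, 1))
  # single-year toy arithmetic: 2 of 100 -> 0.02
  big <- toy_report_set(rep(list("d"), 100), rep(list("p"), 100))
  tr2 <- yearly_trend(big, subset_cases(big, c("T001", "T002")))
  expect_equal(tr2$proportion, 0.02)
  # a year present only in the infection set has zero total and NA proportion
  odd <- toy_report_set(list("d"), list("p"), quarter = "2019Q1")
  tr3 <- yearly_trend(subset_cases(odd, character()), odd)
  expect_true(is.na(tr3$proportion))
  # brute force per-year tally on simulated data
  sim <- simulate_reports(small_sim_config(n = 400), seed = 41)
  rs <- deduplicate(sim$reports)
  ps <- filter_primary_suspect(rs, "back1")
  infc <- subset_cases(ps, rs$reactions$case_id[rs$reactions$pt == "pneumonia"])
  tr4 <- yearly_trend(ps, infc)
  for (i in seq_len(nrow(tr4))) {
    y <- tr4$year[i]
    expect_equal(tr4$total_ps[i], sum(ps$demo$report_year == y))
    expect_equal(tr4$infection_ps[i], sum(infc$demo$report_year == y))
  }
})

test_that("count-table expansion reproduces every marginal it was built from", {
  ch_counts <- utils::read.delim(
    faerssignal_example("characteristics_counts.tsv"),
    stringsAsFactors = FALSE, check.names = FALSE)
  oc_counts <- utils::read.delim(faerssignal_example("outcome_counts.tsv"),
                                 stringsAsFactors = FALSE)
  cases <- cases_from_count_tables(ch_counts, oc_counts)
  ch <- summarize_characteristics(cases)
  for (dn in names(cases)) {
    sub <- ch_counts[ch_counts$drug == dn, ]
    for (i in seq_len(nrow(sub))) {
      blk <- switch(sub$category[i], sex = "sex", age_band = "age_band",
                    year = "year", country = "country")
      expect_equal(unname(ch[[blk]]$counts[sub$level[i], dn]),
                   sub$count[i],
                   info = paste(dn, sub$category[i], sub$level[i]))
    }
  }
  ot <- outcome_table(cases)
  totals <- vapply(cases, function(x) length(case_ids(x)), integer(1))
  expect_equal(unname(colSums(ot$counts)),
               unname(c(totals, sum(totals))))
  for (i in seq_len(nrow(oc_counts))) {
    lbl <- switch(oc_counts$category[i],
                  hospitalization = "Hospitalization initial or prolonged",
                  death = "Death", life_threatening = "Life-threatening",
                  disability = "Disability", others = "Others",
                  unknown = "Unknown")
    expect_equal(unname(ot$counts[lbl, oc_counts$drug[i]]),
                 oc_counts$count[i], info = paste(oc_counts$drug[i], lbl))
  }
})
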