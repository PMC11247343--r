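# Data model: parsing, deduplication, PT-SOC mapping, drug matching.

test_that("well-formed tables join into a report set; orphan child rows drop with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("case_id\tversion_key\tsex\tage_years\tcountry\treport_year\tquarter",
               "A\t2020Q1-1\tfemale\t60\tus\t2020\t2020Q1",
               "B\t2020Q2-1\tmale\t45\tde\t2020\t2020Q2",
               "C\t2021Q1-1\tunknown\t\t\t2021\t2021Q1"),
             file.path(dir, "demo.tsv"))
  writeLines(c("case_id\tdrug_name\trole_code",
               "A\tdrugx\tPS", "B\tdrugx\tC", "C\tdrugy\tSS"),
             file.path(dir, "drug.tsv"))
  writeLines(c("case_id\tpt", "A\tpneumonia", "B\tnausea", "C\tpneumonia",
               "ZZZ\tfatigue"),
             file.path(dir, "reac.tsv"))
  writeLines(c("case_id\toutcome", "A\tHO", "B\tOT"),
             file.path(dir, "outc.tsv"))
  expect_warning(
    rs <- parse_reports(file.path(dir, "demo.tsv"), file.path(dir, "drug.tsv"),
                        file.path(dir, "reac.tsv"), file.path(dir, "outc.tsv"),
                        "simple_tsv"),
    "no matching demographics")
  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 3)
  expect_setequal(case_ids(rs), c("A", "B", "C"))
  expect_equal(nrow(rs$reactions), 3)  # the orphan row is gone
  expect_true(is.na(rs$demo$country[rs$demo$case_id == "C"]))
})

test_that("missing mandatory columns and empty demographics are parse errors naming the culprit", {
  dir <- withr::local_tempdir()
  writeLines("case_id\tversion_key\tsex\tage_years\tcountry\treport_year\tquarter",
             file.path(dir, "demo.tsv"))
  writeLines(c("case_id\tdrug_name", "A\tdrugx"), file.path(dir, "drug.tsv"))
  writeLines(c("case_id\tpt", "A\tx"), file.path(dir, "reac.tsv"))
  writeLines(c("case_id\toutcome"), file.path(dir, "outc.tsv"))
  expect_error(
    parse_reports(file.path(dir, "demo.tsv"), file.path(dir, "drug.tsv"),
                  file.path(dir, "reac.tsv"), file.path(dir, "outc.tsv"),
                  "simple_tsv"),
    "empty")
  writeLines(c("case_id\tversion_key\tsex\tage_years\tcountry\treport_year\tquarter",
               "A\t2020Q1-1\tfemale\t60\tus\t2020\t2020Q1"),
             file.path(dir, "demo.tsv"))
  expect_error(
    parse_reports(file.path(dir, "demo.tsv"), file.path(dir, "drug.tsv"),
                  file.path(dir, "reac.tsv"), file.path(dir, "outc.tsv"),
                  "simple_tsv"),
    "role_code")
})

test_that("faers_ascii dialect converts ages, sexes and receipt quarters", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$caseversion$fda_dt$sex$age$age_cod$occr_country",
               "A.1$A$1$20200315$F$60$YR$US",
               "B.1$B$1$20211120$M$720$MON$DE",
               "C.1$C$1$20150101$$7$DEC$"),
             file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$drugname$role_cod",
               "A.1$DrugX$PS", "B.1$drugx$C", "C.1$drugy$SS"),
             file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "A.1$Pneumonia", "B.1$nausea", "C.1$sepsis"),
             file.path(dir, "REAC.txt"))
  writeLines(c("primaryid$outc_cod", "A.1$HO"), file.path(dir, "OUTC.txt"))
  rs <- parse_reports(file.path(dir, "DEMO.txt"), file.path(dir, "DRUG.txt"),
                      file.path(dir, "REAC.txt"), file.path(dir, "OUTC.txt"),
                      "faers_ascii")
  d <- rs$demo[order(rs$demo$case_id), ]
  expect_equal(d$quarter, c("2020Q1", "2021Q4", "2015Q1"))
  expect_equal(d$age_years, c(60, 60, 70))
  expect_equal(d$sex, c("female", "male", "unknown"))
  expect_equal(d$version_key, c("2020Q1-1", "2021Q4-1", "2015Q1-1"))
  # drug names are case-folded at ingestion
  expect_true(all(c("drugx", "drugy") %in% rs$drugs$drug_name))
})

test_that("deduplication keeps the highest version and is idempotent", {
  demo <- data.frame(
    case_id = c("A", "A", "B"),
    version_key = c("2020Q3-2", "2020Q1-1", "2019Q4-1"),
    sex = c("female", "male", "female"), age_years = c(61, 60, 50),
    country = "us", report_year = c(2020, 2020, 2019),
    quarter = c("2020Q3", "2020Q1", "2019Q4"), stringsAsFactors = FALSE)
  drugs <- data.frame(case_id = c("A", "B"), drug_name = "drugx",
                      role_code = "PS", stringsAsFactors = FALSE)
  reac <- data.frame(case_id = c("A", "B"), pt = "pneumonia",
                     stringsAsFactors = FALSE)
  rs <- report_set(demo, drugs, reac)
  dd <- deduplicate(rs)
  expect_equal(n_reports(dd), 2)
  expect_equal(dd$demo$version_key[dd$demo$case_id == "A"], "2020Q3-2")
  expect_equal(dd$demo$sex[dd$demo$case_id == "A"], "female")
  expect_report_set_equal(deduplicate(dd), dd)
  # a set with all-unique ids passes through unchanged
  expect_report_set_equal(deduplicate(subset_cases(rs, "B")),
                          subset_cases(rs, "B"))
})

test_that("deduplication of planted duplicates matches a brute-force group-by scan", {
  sim <- simulate_reports(small_sim_config(n = 100,
                                           duplicate_fraction = 0.25),
                          seed = 42)
  rs <- sim$reports
  n_dup <- length(sim$ground_truth$duplicated_cases)
  expect_gt(n_dup, 0)
  expect_equal(n_reports(rs), 100 + n_dup)
  dd <- deduplicate(rs)
  expect_equal(n_reports(dd), 100)
  # brute force: per case, max version_key under C-locale comparison
  by_case <- split(rs$demo$version_key, rs$demo$case_id)
  want <- vapply(by_case, function(v) sort(v, method = "radix")[length(v)],
                 character(1))
  got <- setNames(dd$demo$version_key, dd$demo$case_id)
  expect_equal(got[names(want)], want)
})

test_that("parsing is order-invariant and the simple_tsv round trip is lossless", {
  sim <- simulate_reports(small_sim_config(n = 50), seed = 3)
  rs <- sim$reports
  dir <- withr::local_tempdir()
  paths <- write_fixture(rs, "simple_tsv", dir)
  back <- parse_reports(paths[["demo"]], paths[["drug"]], paths[["reac"]],
                        paths[["outc"]], "simple_tsv")
  expect_report_set_equal(back, rs)

  # shuffle every table's rows and reparse: identical report set
  set.seed(9)
  for (p in paths) {
    lines <- readLines(p)
    writeLines(c(lines[1], sample(lines[-1])), p)
  }
  shuffled <- parse_reports(paths[["demo"]], paths[["drug"]],
                            paths[["reac"]], paths[["outc"]], "simple_tsv")
  expect_report_set_equal(shuffled, rs)
})

test_that("PT-SOC map folds case, rejects conflicts, and round-trips lookups", {
  map <- load_pt_soc_map(data.frame(
    pt = c("Pneumonia ", "nausea"),
    soc = c("Infections and Infestations", "gastrointestinal disorders")))
  expect_equal(pt_soc(map, "pneumonia"), "infections and infestations")
  expect_equal(pt_soc(map, "PNEUMONIA"), "infections and infestations")
  expect_true(is.na(pt_soc(map, "vertigo")))
  expect_error(load_pt_soc_map(data.frame(
    pt = c("pneumonitis", "Pneumonitis"),
    soc = c("infections and infestations", "respiratory disorders"))),
    "pneumonitis")
  # exhaustive lookup over a generated mapping
  socs <- paste("soc", 1:4)
  tab <- data.frame(pt = paste("term", 1:30),
                    soc = rep(socs, length.out = 30))
  m <- load_pt_soc_map(tab)
  expect_equal(pt_soc(m, toupper(tab$pt)), rep(socs, length.out = 30))
})

test_that("drug matching is exact normalized equality, never substring", {
  rs <- toy_report_set(list("PALBOCICLIB", "palbociclib tablet", "ibrance"),
                       list("pneumonia", "nausea", "sepsis"))
  m <- match_drug(rs, c("palbociclib", "ibrance"))
  expect_equal(unname(m), c(TRUE, FALSE, TRUE))
  expect_error(match_drug(rs, character()), "empty")
})

test_that("matcher agrees with generator ground truth on simulated drug assignments", {
  sim <- simulate_reports(small_sim_config(n = 200), seed = 11)
  rs <- deduplicate(sim$reports)
  gt <- sim$ground_truth$assignments
  for (dn in c("drugx", "drugy", "back1")) {
    m <- match_drug(rs, dn)
    expect_equal(unname(m[gt$case_id]), gt[[dn]], info = dn)
  }
})

test_that("quarter-range filtering is inclusive and validates its bounds", {
  rs <- toy_report_set(list("a", "b", "c"), list("x", "y", "z"),
                       quarter = c("2015Q1", "2019Q3", "2022Q4"))
  kept <- filter_quarter_range(rs, c("2015Q1", "2022Q3"))
  expect_equal(length(case_ids(kept)), 2)
  expect_error(filter_quarter_range(rs, c("2022Q5", "2022Q6")), "invalid")
  expect_error(filter_quarter_range(rs, c("2022Q3", "2015Q1")), "after")
})
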