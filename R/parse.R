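# Reading and writing the two supported table dialects.
#
# faers_ascii mirrors the quarterly FAERS extract layout: "$"-delimited
# text with a header row, one file each for DEMO/DRUG/REAC/OUTC, joined on
# primaryid (= one row per case version); demographics carry caseid,
# caseversion, fda_dt (YYYYMMDD receipt date), sex, age + age_cod unit,
# occr_country. simple_tsv is a tab-separated dialect carrying the internal
# model columns directly.

DIALECTS <- c("simple_tsv", "faers_ascii")

read_dialect_table <- function(path, sep, required, what) {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, quote = "",
                      comment.char = "", stringsAsFactors = FALSE,
                      colClasses = "character", na.strings = "",
                      check.names = FALSE),
    error = function(e) {
      stop(sprintf("failed to parse %s table '%s': %s", what, path,
                   conditionMessage(e)), call. = FALSE)
    })
  names(df) <- tolower(names(df))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s table '%s' is missing mandatory column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

# FAERS age units: years, decades, months, weeks, days, hours
convert_age_years <- function(age, cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(cod), "YR", cod)))
  cod[cod == ""] <- "YR"
  f <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
         DY = 1 / 365.25, HR = 1 / (24 * 365.25))
  mult <- unname(f[cod])
  out <- age * mult
  out[is.na(mult)] <- NA_real_
  out
}

fda_dt_quarter <- function(fda_dt) {
  ok <- !is.na(fda_dt) & grepl("^[0-9]{8}$", fda_dt)
  if (!all(ok)) {
    stop(sprintf("bad fda_dt value '%s': expected YYYYMMDD",
                 fda_dt[!ok][1]), call. = FALSE)
  }
  yr <- substr(fda_dt, 1, 4)
  mo <- as.integer(substr(fda_dt, 5, 6))
  sprintf("%sQ%d", yr, (mo - 1L) %/% 3L + 1L)
}

quarter_fda_dt <- function(quarter) {
  check_quarter(quarter)
  mid <- c("0215", "0515", "0815", "1115")
  paste0(substr(quarter, 1, 4), mid[as.integer(substr(quarter, 6, 6))])
}

#' Parse FAERS-structured report tables into a report set
#'
#' Joins the four standard spontaneous-report tables (demographics, drug
#' entries, reaction preferred terms, outcome codes) on their shared key
#' and returns the result as a [report_set()]. Two dialects are supported:
#'
#' * `"faers_ascii"` — the quarterly FAERS extract layout: `"$"`-delimited
#'   with header, joined on `primaryid`. Demographics need columns
#'   `primaryid`, `caseid`, `caseversion`, `fda_dt`, `sex`, `age`,
#'   `age_cod`, `occr_country`; drug tables `primaryid`, `drugname`,
#'   `role_cod`; reactions `primaryid`, `pt`; outcomes `primaryid`,
#'   `outc_cod`. Ages are converted to years from the `age_cod` unit
#'   (YR/DEC/MON/WK/DY/HR); the receipt quarter is derived from `fda_dt`
#'   and the orderable version key is `"<quarter>-<caseversion>"`.
#' * `"simple_tsv"` — tab-separated files carrying the model columns of
#'   [report_set()] directly (`case_id`, `version_key`, `sex`,
#'   `age_years`, `country`, `report_year`, `quarter`; `drug_name`,
#'   `role_code`; `pt`; `outcome`).
#'
#' Child rows whose join key matches no demographics row are dropped with
#' a warning giving the count. The returned set is *not* deduplicated;
#' call [deduplicate()] before any counting.
#'
#' @param demo,drug,reac,outc paths to the four tables.
#' @param dialect `"simple_tsv"` or `"faers_ascii"`.
#' @return A `report_set`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' rs <- simulate_reports(simulation_config(n_reports = 20), seed = 1)$reports
#' paths <- write_fixture(rs, "simple_tsv", dir)
#' rs2 <- parse_reports(paths[["demo"]], paths[["drug"]],
#'                      paths[["reac"]], paths[["outc"]], "simple_tsv")
#' n_reports(rs2)
#' @export
parse_reports <- function(demo, drug, reac, outc,
                          dialect = c("simple_tsv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "simple_tsv") {
    d <- read_dialect_table(demo, "\t",
                            c("case_id", "version_key", "sex", "age_years",
                              "country", "report_year", "quarter"),
                            "demographics")
    if (nrow(d) == 0) stop("demographics table is empty", call. = FALSE)
    dr <- read_dialect_table(drug, "\t",
                             c("case_id", "drug_name", "role_code"), "drug")
    re <- read_dialect_table(reac, "\t", c("case_id", "pt"), "reaction")
    ou <- read_dialect_table(outc, "\t", c("case_id", "outcome"), "outcome")
    return(report_set(d, dr, re, ou))
  }

  d <- read_dialect_table(demo, "$",
                          c("primaryid", "caseid", "caseversion", "fda_dt",
                            "sex", "age", "age_cod", "occr_country"),
                          "demographics")
  if (nrow(d) == 0) stop("demographics table is empty", call. = FALSE)
  dr <- read_dialect_table(drug, "$",
                           c("primaryid", "drugname", "role_cod"), "drug")
  re <- read_dialect_table(reac, "$", c("primaryid", "pt"), "reaction")
  ou <- read_dialect_table(outc, "$", c("primaryid", "outc_cod"), "outcome")

  quarter <- fda_dt_quarter(d$fda_dt)
  sex <- toupper(trimws(ifelse(is.na(d$sex), "", d$sex)))
  demo_df <- data.frame(
    case_id = d$caseid,
    version_key = sprintf("%s-%s", quarter, d$caseversion),
    sex = ifelse(sex == "F", "female", ifelse(sex == "M", "male", "unknown")),
    age_years = convert_age_years(d$age, d$age_cod),
    country = d$occr_country,
    report_year = quarter_year(quarter),
    quarter = quarter,
    stringsAsFactors = FALSE)

  # children join on primaryid (case version), then collapse to the case id
  id_map <- stats::setNames(d$caseid, d$primaryid)
  attach_case <- function(df, what) {
    cid <- unname(id_map[df$primaryid])
    drop <- is.na(cid)
    if (any(drop)) {
      warning(sprintf("dropping %d %s row(s) with no matching demographics case",
                      sum(drop), what), call. = FALSE)
    }
    df$case_id <- cid
    df[!drop, , drop = FALSE]
  }
  dr <- attach_case(dr, "drug")
  re <- attach_case(re, "reaction")
  ou <- attach_case(ou, "outcome")

  report_set(demo_df,
             data.frame(case_id = dr$case_id, drug_name = dr$drugname,
                        role_code = dr$role_cod, stringsAsFactors = FALSE),
             data.frame(case_id = re$case_id, pt = re$pt,
                        stringsAsFactors = FALSE),
             data.frame(case_id = ou$case_id, outcome = ou$outc_cod,
                        stringsAsFactors = FALSE))
}

#' Write a report set as a four-table fixture
#'
#' Emits DEMO/DRUG/REAC/OUTC tables in either dialect accepted by
#' [parse_reports()]; the write-then-parse round trip is lossless at the
#' case level. In the `faers_ascii` dialect each case version receives its
#' own `primaryid` and the child tables are repeated per version, as in
#' real quarterly extracts.
#'
#' @param reports a `report_set`.
#' @param dialect `"simple_tsv"` or `"faers_ascii"`.
#' @param out_dir directory to write into (created if missing).
#' @return Invisibly, a named character vector of the four file paths
#'   (`demo`, `drug`, `reac`, `outc`).
#' @export
write_fixture <- function(reports, dialect = c("simple_tsv", "faers_ascii"),
                          out_dir) {
  stopifnot(inherits(reports, "report_set"))
  dialect <- match.arg(dialect)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  if (dialect == "simple_tsv") {
    paths <- file.path(out_dir, c(demo = "demo.tsv", drug = "drug.tsv",
                                  reac = "reac.tsv", outc = "outc.tsv"))
    names(paths) <- c("demo", "drug", "reac", "outc")
    write_tsv_file(reports$demo, paths[["demo"]])
    write_tsv_file(reports$drugs, paths[["drug"]])
    write_tsv_file(reports$reactions, paths[["reac"]])
    write_tsv_file(reports$outcomes, paths[["outc"]])
    return(invisible(paths))
  }

  d <- reports$demo
  caseversion <- sub("^.*-", "", d$version_key)
  demo_out <- data.frame(
    primaryid = paste0(d$case_id, ".", caseversion),
    caseid = d$case_id,
    caseversion = caseversion,
    fda_dt = quarter_fda_dt(d$quarter),
    sex = ifelse(d$sex == "female", "F", ifelse(d$sex == "male", "M", "")),
    age = ifelse(is.na(d$age_years), "", format(d$age_years, trim = TRUE)),
    age_cod = ifelse(is.na(d$age_years), "", "YR"),
    occr_country = ifelse(is.na(d$country), "", d$country),
    stringsAsFactors = FALSE)
  pid_of <- split(demo_out$primaryid, demo_out$caseid)
  expand <- function(df) {
    reps <- lengths(pid_of[df$case_id])
    out <- df[rep(seq_len(nrow(df)), reps), , drop = FALSE]
    out$primaryid <- unlist(pid_of[df$case_id], use.names = FALSE)
    out
  }
  dr <- expand(reports$drugs)
  re <- expand(reports$reactions)
  ou <- expand(reports$outcomes)

  paths <- file.path(out_dir, c("DEMO.txt", "DRUG.txt", "REAC.txt",
                                "OUTC.txt"))
  names(paths) <- c("demo", "drug", "reac", "outc")
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "$", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wr(demo_out, paths[["demo"]])
  wr(data.frame(primaryid = dr$primaryid, drugname = dr$drug_name,
                role_cod = dr$role_code, stringsAsFactors = FALSE),
     paths[["drug"]])
  wr(data.frame(primaryid = re$primaryid, pt = re$pt,
                stringsAsFactors = FALSE), paths[["reac"]])
  wr(data.frame(primaryid = ou$primaryid, outc_cod = ou$outcome,
                stringsAsFactors = FALSE), paths[["outc"]])
  invisible(paths)
}
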