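# Expansion of marginal count tables into synthetic case-level report
# sets, used to check descriptive summaries against published per-drug
# tables of a study without access to its underlying extract.

OUTCOME_CATEGORY_CODES <- c(hospitalization = "HO", death = "DE",
                            life_threatening = "LT", disability = "DS",
                            others = "OT", unknown = "none")

#' Expand marginal count tables into a synthetic case-level report set
#'
#' Given per-drug marginal counts for sex, age band, reporting year and
#' reporting country, plus per-drug outcome-category counts, constructs
#' one synthetic case per counted unit so that every marginal tally of
#' [summarize_characteristics()], [outcome_table()] and
#' [severity_counts()] reproduces the input counts exactly. The *joint*
#' distribution across characteristics is arbitrary (each column is
#' filled independently in level order), so only marginal summaries of
#' the result are meaningful; cross-tabulations (e.g. severity by sex)
#' are not. Ages within a band are set to a representative value (35 /
#' 50 / 70), so band counts — not medians — are reproduced.
#'
#' Every drug's category blocks must sum to the same case total.
#'
#' @param characteristics data.frame with columns `drug`, `category`
#'   (`sex`, `age_band`, `year`, `country`), `level`, `count`.
#' @param outcomes data.frame with columns `drug`, `category`
#'   (`hospitalization`, `death`, `life_threatening`, `disability`,
#'   `others`, `unknown`), `count`.
#' @return Named list of `report_set`, one per drug; each synthetic case
#'   lists its drug as primary suspect with a single placeholder PT.
#' @export
cases_from_count_tables <- function(characteristics, outcomes) {
  characteristics <- as.data.frame(characteristics,
                                   stringsAsFactors = FALSE)
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "category", "level", "count") %in%
                  names(characteristics)),
            all(c("drug", "category", "count") %in% names(outcomes)))
  drugs <- unique(characteristics$drug)

  out <- lapply(drugs, function(dn) {
    ch <- characteristics[characteristics$drug == dn, , drop = FALSE]
    oc <- outcomes[outcomes$drug == dn, , drop = FALSE]
    fill <- function(category, table = ch) {
      rows <- table[table$category == category, , drop = FALSE]
      rep(rows$level, rows$count)
    }
    sex <- fill("sex")
    band <- fill("age_band")
    year <- fill("year")
    country <- fill("country")
    ocodes <- rep(unname(OUTCOME_CATEGORY_CODES[oc$category]), oc$count)
    n <- length(sex)
    sizes <- c(age_band = length(band), year = length(year),
               country = length(country), outcome = length(ocodes))
    if (any(sizes != n)) {
      stop(sprintf("count blocks for drug '%s' disagree on the case total (sex says %d)",
                   dn, n), call. = FALSE)
    }
    age <- c("<40" = 35, "40-64" = 50, ">=65" = 70,
             "unknown" = NA_real_)[band]
    case_id <- sprintf("%s-%05d", dn, seq_len(n))
    demo <- data.frame(case_id = case_id, version_key = "1",
                       sex = sex, age_years = unname(age),
                       country = ifelse(country == "unknown",
                                        NA_character_, country),
                       report_year = as.integer(year),
                       quarter = paste0(year, "Q1"),
                       stringsAsFactors = FALSE)
    keep <- ocodes != "none"
    report_set(demo,
               data.frame(case_id = case_id, drug_name = dn,
                          role_code = "PS", stringsAsFactors = FALSE),
               data.frame(case_id = case_id, pt = "infection",
                          stringsAsFactors = FALSE),
               data.frame(case_id = case_id[keep], outcome = ocodes[keep],
                          stringsAsFactors = FALSE))
  })
  names(out) <- drugs
  out
}

#' Bundled example count tables
#'
#' Returns the paths of the small tab-separated fixtures shipped with the
#' package: per-drug clinical-characteristics counts
#' (`characteristics_counts.tsv`), per-drug outcome-category counts
#' (`outcome_counts.tsv`), and the severity-by-sex / severity-by-age
#' comparison tables (`severity_by_sex.tsv`, `severity_by_age.tsv`).
#' These hold the published per-drug counts of a CDK4/6-inhibitor
#' infection case series and back the package's reproduction tests.
#'
#' @param file one of `"characteristics_counts.tsv"`,
#'   `"outcome_counts.tsv"`, `"severity_by_sex.tsv"`,
#'   `"severity_by_age.tsv"`.
#' @return The file path inside the installed package.
#' @export
faerssignal_example <- function(file) {
  path <- system.file("extdata", file, package = "faerssignal")
  if (path == "") stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  path
}

#' Read a bundled severity comparison table
#'
#' @param file `"severity_by_sex.tsv"` or `"severity_by_age.tsv"`.
#' @return Count matrix (rows = characteristic levels, columns `serious`,
#'   `non_serious`) ready for [pearson_chi_square()].
#' @export
read_severity_table <- function(file) {
  df <- utils::read.delim(faerssignal_example(file),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("serious", "non_serious")])
  rownames(m) <- df$level
  m
}
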