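# Descriptive and inferential summaries of enrolled case sets: clinical
# characteristics, outcome severity, yearly trend, chi-square comparisons.

SERIOUS_CODES <- c("HO", "DE", "LT", "DS")
AGE_BANDS <- c("<40", "40-64", ">=65", "unknown")
OUTCOME_LABELS <- c(
  HO = "Hospitalization initial or prolonged",
  DE = "Death",
  LT = "Life-threatening",
  DS = "Disability",
  OT = "Others",
  unknown = "Unknown")

age_band <- function(age) {
  ifelse(is.na(age), "unknown",
         ifelse(age < 40, "<40", ifelse(age < 65, "40-64", ">=65")))
}

#' Classify report severity from outcome codes
#'
#' A case is `serious` when it carries any of the four serious outcome
#' codes (hospitalization HO, death DE, life-threatening LT, disability
#' DS), `non_serious` when its only outcome code is `OT` ("other"), and
#' `unknown` when it carries no outcome code at all. Precedence is
#' serious > non_serious > unknown, so a case with both HO and OT is
#' serious.
#'
#' @param reports a `report_set`.
#' @return Named character vector (`case_ids(reports)` as names) with
#'   values `"serious"`, `"non_serious"`, `"unknown"`.
#' @export
classify_severity <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  ids <- case_ids(reports)
  o <- reports$outcomes
  serious_ids <- unique(o$case_id[o$outcome %in% SERIOUS_CODES])
  any_ids <- unique(o$case_id)
  out <- ifelse(ids %in% serious_ids, "serious",
                ifelse(ids %in% any_ids, "non_serious", "unknown"))
  names(out) <- ids
  out
}

# case-level characteristic vectors for one report_set (deduplicated)
case_frame <- function(reports) {
  d <- deduplicate(reports)$demo
  data.frame(case_id = d$case_id,
             sex = d$sex,
             age_years = d$age_years,
             age_band = age_band(d$age_years),
             country = ifelse(is.na(d$country), "unknown",
                              norm_term(d$country)),
             report_year = d$report_year,
             stringsAsFactors = FALSE)
}

count_block <- function(values, levels, drug_names, by_drug) {
  counts <- vapply(drug_names, function(dn) {
    v <- by_drug[[dn]]
    vapply(levels, function(l) sum(v == l), integer(1))
  }, integer(length(levels)))
  counts <- matrix(counts, nrow = length(levels),
                   dimnames = list(levels, drug_names))
  cbind(counts, total = rowSums(counts))
}

pct_of <- function(counts, totals) {
  round(100 * sweep(counts, 2, totals, "/"), 2)
}

#' Summarize clinical characteristics of enrolled cases
#'
#' Tabulates sex, age band (`<40`, `40-64`, `>=65`, `unknown`), reporting
#' year and reporting country per drug and in total, with percentages of
#' each drug's case total (2 decimals), plus the median, interquartile
#' range and min-max range of the recorded ages.
#'
#' @param cases_by_drug named list of `report_set` (e.g. from
#'   [enrolled_cases()]), one per drug.
#' @return An object of class `characteristics_summary`: a list of count
#'   and percentage tables (`sex`, `age_band`, `year`, `country`), the
#'   per-drug `age_stats`, and the case `totals`.
#' @export
summarize_characteristics <- function(cases_by_drug) {
  stopifnot(is.list(cases_by_drug), length(cases_by_drug) > 0,
            !is.null(names(cases_by_drug)))
  drug_names <- names(cases_by_drug)
  frames <- lapply(cases_by_drug, case_frame)
  totals <- vapply(frames, nrow, integer(1))
  totals <- c(totals, total = sum(totals))

  years <- sort(unique(unlist(lapply(frames, `[[`, "report_year"))))
  countries <- sort(unique(unlist(lapply(frames, `[[`, "country"))),
                    method = "radix")

  blk <- function(field, levels) {
    by_drug <- lapply(frames, `[[`, field)
    counts <- count_block(NULL, levels, drug_names, by_drug)
    list(counts = counts, pct = pct_of(counts, totals))
  }
  age_stats <- t(vapply(c(frames, list(total = do.call(rbind, frames))),
                        function(f) {
    a <- f$age_years[!is.na(f$age_years)]
    if (length(a) == 0) return(c(n = 0, median = NA_real_, q1 = NA_real_,
                                 q3 = NA_real_, min = NA_real_,
                                 max = NA_real_))
    c(n = length(a), median = stats::median(a),
      q1 = unname(stats::quantile(a, 0.25)),
      q3 = unname(stats::quantile(a, 0.75)),
      min = min(a), max = max(a))
  }, numeric(6)))

  structure(list(sex = blk("sex", SEX_LEVELS),
                 age_band = blk("age_band", AGE_BANDS),
                 year = blk("report_year", years),
                 country = blk("country", countries),
                 age_stats = age_stats,
                 totals = totals),
            class = "characteristics_summary")
}

#' @export
print.characteristics_summary <- function(x, ...) {
  cat("<characteristics_summary>\n")
  cat("  cases:", paste(sprintf("%s=%d", names(x$totals), x$totals),
                        collapse = ", "), "\n")
  for (b in c("sex", "age_band")) {
    cat(sprintf("  %s counts:\n", b))
    print(x[[b]]$counts)
  }
  invisible(x)
}

#' Outcome-event table
#'
#' Assigns every case to exactly one outcome category and tabulates per
#' drug. Because a case may carry several outcome codes but descriptive
#' tables count cases once, a precedence order decides the category; the
#' default, death > life-threatening > disability > hospitalization >
#' other, attributes each case to its worst outcome. Cases with no
#' outcome code fall under `Unknown`. Columns therefore sum to the case
#' totals.
#'
#' @param cases_by_drug named list of `report_set`, one per drug.
#' @param precedence character vector ordering the outcome codes from
#'   highest to lowest priority.
#' @return An object of class `outcome_table`: list with `counts` and
#'   `pct` matrices (rows = outcome categories incl. Unknown, columns =
#'   drugs + total).
#' @export
outcome_table <- function(cases_by_drug,
                          precedence = c("DE", "LT", "DS", "HO", "OT")) {
  stopifnot(is.list(cases_by_drug), !is.null(names(cases_by_drug)),
            setequal(precedence, OUTCOME_CODES))
  drug_names <- names(cases_by_drug)
  cat_of <- function(rs) {
    rs <- deduplicate(rs)
    ids <- case_ids(rs)
    o <- rs$outcomes
    cat <- rep("unknown", length(ids))
    names(cat) <- ids
    for (code in rev(precedence)) {  # highest priority assigned last
      cat[unique(o$case_id[o$outcome == code])] <- code
    }
    cat
  }
  by_drug <- lapply(cases_by_drug, cat_of)
  levels <- c(precedence, "unknown")
  counts <- count_block(NULL, levels, drug_names, by_drug)
  # present in the conventional row order regardless of precedence
  row_order <- c("HO", "DE", "LT", "DS", "OT", "unknown")
  counts <- counts[row_order, , drop = FALSE]
  rownames(counts) <- unname(OUTCOME_LABELS[row_order])
  totals <- colSums(counts)
  structure(list(counts = counts, pct = pct_of(counts, totals),
                 precedence = precedence),
            class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("<outcome_table> (counts)\n")
  print(x$counts)
  invisible(x)
}

#' Severity counts and proportions per drug
#'
#' The headline severity aggregate: `serious` is the union of the four
#' serious outcome categories, `non_serious` the "Others" category,
#' `unknown` the rest, computed from [outcome_table()]'s one-category-per
#' -case assignment so the three rows partition each drug's cases.
#'
#' @inheritParams outcome_table
#' @return List with `counts` and `pct` matrices (rows serious /
#'   non_serious / unknown, columns drugs + total).
#' @export
severity_counts <- function(cases_by_drug,
                            precedence = c("DE", "LT", "DS", "HO", "OT")) {
  ot <- outcome_table(cases_by_drug, precedence)
  lab <- unname(OUTCOME_LABELS[SERIOUS_CODES])
  counts <- rbind(serious = colSums(ot$counts[lab, , drop = FALSE]),
                  non_serious = ot$counts[OUTCOME_LABELS[["OT"]], ],
                  unknown = ot$counts[OUTCOME_LABELS[["unknown"]], ])
  list(counts = counts, pct = pct_of(counts, colSums(counts)))
}

#' Cross-tabulate severity against a clinical characteristic
#'
#' Builds the serious / non-serious comparison table for one pooled case
#' set: rows are the characteristic's levels (sex levels or age bands),
#' columns `serious` and `non_serious`; unknown-severity cases are
#' excluded (they belong to neither group).
#'
#' @param cases a `report_set` (pooled enrolled cases).
#' @param by `"sex"` or `"age_band"`.
#' @return Integer matrix of counts.
#' @export
severity_crosstab <- function(cases, by = c("sex", "age_band")) {
  by <- match.arg(by)
  cf <- case_frame(cases)
  sev <- classify_severity(deduplicate(cases))
  sev <- sev[cf$case_id]
  levels <- if (by == "sex") SEX_LEVELS else AGE_BANDS
  keep <- sev != "unknown"
  m <- vapply(c("serious", "non_serious"), function(s) {
    vapply(levels, function(l) sum(keep & sev == s & cf[[by]] == l),
           integer(1))
  }, integer(length(levels)))
  matrix(m, nrow = length(levels),
         dimnames = list(levels, c("serious", "non_serious")))
}

#' Pearson chi-square test on a count table
#'
#' Classic Pearson statistic without continuity correction, with optional
#' dropping of categories (rows) before testing — e.g. an "unknown" level
#' that belongs to neither comparison group. Errors when any expected
#' cell is zero.
#'
#' @param table numeric matrix of counts with row names (categories) and
#'   column names (groups).
#' @param drop_categories character vector of row names to drop before
#'   testing (case-insensitive).
#' @return An object of class `chisq_result`: list with `statistic`,
#'   `df`, `p_value`, `cells_used` (the retained table), `expected`.
#' @examples
#' tab <- matrix(c(500, 6, 293, 1), 2,
#'               dimnames = list(c("female", "male"), c("serious", "non_serious")))
#' pearson_chi_square(tab)
#' @export
pearson_chi_square <- function(table, drop_categories = character()) {
  table <- as.matrix(table)
  if (length(drop_categories)) {
    keep <- !norm_term(rownames(table)) %in% norm_term(drop_categories)
    table <- table[keep, , drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("chi-square table needs at least 2 rows and 2 columns after dropping",
         call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected == 0)) {
    stop("degenerate table: at least one expected cell is zero",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 cells_used = table,
                 expected = ht$expected),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> X-squared = %.3f, df = %d, p = %.4f\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Yearly trend of infection cases among primary-suspect reports
#'
#' For each reporting year, counts the primary-suspect reports overall
#' and those in the infection case set, and their ratio. Years with zero
#' total reports get a missing (`NA`) proportion rather than zero.
#'
#' @param all_ps_reports `report_set` of all primary-suspect reports for
#'   the target drugs in the study window.
#' @param infection_ps_cases `report_set` of the infection cases (a
#'   subset of the former).
#' @return Data frame with columns `year`, `infection_ps`, `total_ps`,
#'   `proportion` (rounded to 4 decimals).
#' @export
yearly_trend <- function(all_ps_reports, infection_ps_cases) {
  stopifnot(inherits(all_ps_reports, "report_set"),
            inherits(infection_ps_cases, "report_set"))
  yr_all <- deduplicate(all_ps_reports)$demo$report_year
  yr_inf <- deduplicate(infection_ps_cases)$demo$report_year
  years <- sort(unique(c(yr_all, yr_inf)))
  total <- vapply(years, function(y) sum(yr_all == y), integer(1))
  inf <- vapply(years, function(y) sum(yr_inf == y), integer(1))
  data.frame(year = years,
             infection_ps = inf,
             total_ps = total,
             proportion = ifelse(total == 0, NA_real_,
                                 round(inf / total, 4)))
}
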