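ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("HO", "DE", "LT", "DS", "OT")
SEX_LEVELS <- c("female", "male", "unknown")

#' Construct a report set
#'
#' A `report_set` is the package's in-memory model of a deduplicatable
#' collection of spontaneous case reports. It holds four normalized tables
#' keyed by `case_id`: demographics (one row per case *version* before
#' deduplication), drug entries with FAERS role codes, reaction preferred
#' terms (PTs), and outcome codes.
#'
#' Validation drops child rows whose `case_id` has no demographics row,
#' drops outcome codes outside the FAERS five-code vocabulary
#' (HO, DE, LT, DS, OT), and removes cases that end up with no drug entry
#' or no reaction PT, each with a warning giving the count. Drug names and
#' PTs are trimmed and case-folded; component tables are stored in a
#' canonical C-locale sort order so that a report set built from shuffled
#' input rows is identical to one built from the original order.
#'
#' @param demo data.frame with columns `case_id`, `version_key`, `sex`
#'   (`"female"`, `"male"` or `"unknown"`), `age_years` (numeric, `NA`
#'   allowed), `country` (`NA` allowed), `report_year` (integer),
#'   `quarter` (`"YYYYQn"`).
#' @param drugs data.frame with columns `case_id`, `drug_name`,
#'   `role_code` (one of PS, SS, C, I).
#' @param reactions data.frame with columns `case_id`, `pt`.
#' @param outcomes data.frame with columns `case_id`, `outcome`, or `NULL`
#'   for no outcome information (all cases then classify as unknown
#'   severity).
#' @return An object of class `report_set`.
#' @seealso [parse_reports()], [deduplicate()], [simulate_reports()]
#' @export
report_set <- function(demo, drugs, reactions, outcomes = NULL) {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(outcomes)) {
    outcomes <- data.frame(case_id = character(), outcome = character(),
                           stringsAsFactors = FALSE)
  }
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(demo, c("case_id", "version_key", "sex", "age_years", "country",
               "report_year", "quarter"), "demographics")
  need(drugs, c("case_id", "drug_name", "role_code"), "drug")
  need(reactions, c("case_id", "pt"), "reaction")
  need(outcomes, c("case_id", "outcome"), "outcome")

  demo$case_id <- as.character(demo$case_id)
  if (any(is.na(demo$case_id) | demo$case_id == "")) {
    stop("demographics table contains empty case_id", call. = FALSE)
  }
  demo$version_key <- as.character(demo$version_key)
  demo$sex <- ifelse(demo$sex %in% SEX_LEVELS, demo$sex, "unknown")
  demo$age_years <- suppressWarnings(as.numeric(demo$age_years))
  demo$age_years[!is.na(demo$age_years) & demo$age_years < 0] <- NA_real_
  demo$country <- as.character(demo$country)
  demo$country[!is.na(demo$country) & trimws(demo$country) == ""] <- NA_character_
  demo$report_year <- as.integer(demo$report_year)
  demo$quarter <- as.character(demo$quarter)
  check_quarter(demo$quarter, "demographics quarter")

  drugs$case_id <- as.character(drugs$case_id)
  drugs$drug_name <- norm_term(drugs$drug_name)
  drugs$role_code <- toupper(trimws(as.character(drugs$role_code)))
  bad_role <- !drugs$role_code %in% ROLE_CODES
  if (any(bad_role)) {
    stop(sprintf("invalid drug role code(s): %s (allowed: %s)",
                 paste(unique(drugs$role_code[bad_role]), collapse = ", "),
                 paste(ROLE_CODES, collapse = ", ")), call. = FALSE)
  }
  reactions$case_id <- as.character(reactions$case_id)
  reactions$pt <- norm_term(reactions$pt)
  outcomes$case_id <- as.character(outcomes$case_id)
  outcomes$outcome <- toupper(trimws(as.character(outcomes$outcome)))
  bad_out <- !outcomes$outcome %in% OUTCOME_CODES
  if (any(bad_out)) {
    warning(sprintf("dropping %d outcome row(s) with codes outside {%s}",
                    sum(bad_out), paste(OUTCOME_CODES, collapse = ", ")),
            call. = FALSE)
    outcomes <- outcomes[!bad_out, , drop = FALSE]
  }

  known <- unique(demo$case_id)
  orphan <- function(df, what) {
    drop <- !df$case_id %in% known
    if (any(drop)) {
      warning(sprintf("dropping %d %s row(s) with no matching demographics case",
                      sum(drop), what), call. = FALSE)
    }
    df[!drop, , drop = FALSE]
  }
  drugs <- orphan(drugs, "drug")
  reactions <- orphan(reactions, "reaction")
  outcomes <- orphan(outcomes, "outcome")

  # a case report must carry at least one drug and one reaction
  ok <- known %in% drugs$case_id & known %in% reactions$case_id
  if (any(!ok)) {
    warning(sprintf("dropping %d case(s) with no drug entry or no reaction PT",
                    sum(!ok)), call. = FALSE)
    keep <- known[ok]
    demo <- demo[demo$case_id %in% keep, , drop = FALSE]
    drugs <- drugs[drugs$case_id %in% keep, , drop = FALSE]
    reactions <- reactions[reactions$case_id %in% keep, , drop = FALSE]
    outcomes <- outcomes[outcomes$case_id %in% keep, , drop = FALSE]
  }

  # canonical order: stable radix sort, so equal version keys retain input
  # order (deduplicate() relies on this for its tie-break)
  demo <- demo[c_order(demo$case_id, demo$version_key), , drop = FALSE]
  drugs <- unique(drugs[c_order(drugs$case_id, drugs$drug_name,
                                drugs$role_code), , drop = FALSE])
  reactions <- unique(reactions[c_order(reactions$case_id, reactions$pt), ,
                                drop = FALSE])
  outcomes <- unique(outcomes[c_order(outcomes$case_id, outcomes$outcome), ,
                              drop = FALSE])
  rownames(demo) <- rownames(drugs) <- rownames(reactions) <-
    rownames(outcomes) <- NULL

  structure(list(demo = demo, drugs = drugs, reactions = reactions,
                 outcomes = outcomes),
            class = "report_set")
}

#' Number of report rows in a report set
#'
#' Before deduplication a case may contribute several versions; afterwards
#' this equals the number of distinct cases.
#' @param x a `report_set`.
#' @return Integer count of demographics rows.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$demo)
}

#' Case identifiers of a report set
#' @param x a `report_set`.
#' @return Character vector of distinct case ids, sorted.
#' @export
case_ids <- function(x) {
  stopifnot(inherits(x, "report_set"))
  unique(x$demo$case_id)
}

#' Subset a report set by case id
#' @param x a `report_set`.
#' @param ids character vector of case ids to keep.
#' @return A `report_set` restricted to `ids` (missing ids are ignored).
#' @export
subset_cases <- function(x, ids) {
  stopifnot(inherits(x, "report_set"))
  pick <- function(df) {
    df <- df[df$case_id %in% ids, , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  structure(list(demo = pick(x$demo), drugs = pick(x$drugs),
                 reactions = pick(x$reactions), outcomes = pick(x$outcomes)),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  ncase <- length(case_ids(x))
  cat(sprintf("<report_set> %d report row(s), %d distinct case(s)\n",
              n_reports(x), ncase))
  cat(sprintf("  drugs: %d entr%s (%d distinct names); reactions: %d row(s) (%d distinct PTs)\n",
              nrow(x$drugs), if (nrow(x$drugs) == 1) "y" else "ies",
              length(unique(x$drugs$drug_name)),
              nrow(x$reactions), length(unique(x$reactions$pt))))
  if (nrow(x$demo)) {
    cat(sprintf("  quarters: %s .. %s\n", min(x$demo$quarter),
                max(x$demo$quarter)))
  }
  invisible(x)
}

#' Deduplicate case versions in a report set
#'
#' FAERS publishes follow-up versions of the same case; all counting in
#' this package is defined on one record per case. For each `case_id` the
#' record with the greatest `version_key` (plain C-locale string order)
#' survives; among records sharing the greatest key, the one appearing
#' last in the original input order is kept. Idempotent.
#'
#' @param reports a `report_set`.
#' @return A `report_set` with exactly one demographics row per case.
#' @export
deduplicate <- function(reports) {
  stopifnot(inherits(reports, "report_set"))
  demo <- reports$demo
  if (nrow(demo) > 0) {
    # stable radix sort by (case_id, version_key): the last row of each
    # case block is the max-version, last-in-input record
    demo <- demo[c_order(demo$case_id, demo$version_key), , drop = FALSE]
    last <- !duplicated(demo$case_id, fromLast = TRUE)
    demo <- demo[last, , drop = FALSE]
    rownames(demo) <- NULL
  }
  out <- reports
  out$demo <- demo
  out
}

#' Restrict a report set to a receipt-quarter window
#'
#' @param reports a `report_set`.
#' @param quarter_range length-2 character vector `c(start, end)` of
#'   `"YYYYQn"` quarters, inclusive on both ends.
#' @return The filtered `report_set`.
#' @export
filter_quarter_range <- function(reports, quarter_range) {
  stopifnot(inherits(reports, "report_set"), length(quarter_range) == 2)
  check_quarter(quarter_range, "quarter_range")
  if (quarter_range[1] > quarter_range[2]) {
    stop("quarter_range start is after its end", call. = FALSE)
  }
  q <- reports$demo$quarter
  keep <- reports$demo$case_id[q >= quarter_range[1] & q <= quarter_range[2]]
  subset_cases(reports, keep)
}

#' Match reports against a drug synonym list
#'
#' A report matches when any of its drug entries' normalized names equals
#' (exactly, not as a substring) any normalized synonym, optionally
#' restricted to given role codes.
#'
#' @param reports a `report_set`.
#' @param synonyms non-empty character vector of drug names (generic and
#'   brand names are typically both listed).
#' @param roles optional character vector of role codes (`"PS"`, `"SS"`,
#'   `"C"`, `"I"`) the match must occur under; `NULL` accepts any role.
#' @return Named logical vector over the distinct case ids of `reports`.
#' @export
match_drug <- function(reports, synonyms, roles = NULL) {
  stopifnot(inherits(reports, "report_set"))
  if (length(synonyms) == 0) stop("synonym list is empty", call. = FALSE)
  syn <- norm_term(synonyms)
  d <- reports$drugs
  hit <- d$drug_name %in% syn
  if (!is.null(roles)) hit <- hit & d$role_code %in% toupper(roles)
  ids <- case_ids(reports)
  out <- ids %in% d$case_id[hit]
  names(out) <- ids
  out
}

matching_cases <- function(reports, synonyms, roles = NULL) {
  m <- match_drug(reports, synonyms, roles)
  names(m)[m]
}

#' Load a preferred-term to system-organ-class mapping
#'
#' Reads a two-column table mapping each MedDRA-style preferred term (PT)
#' to its system organ class (SOC). Both columns are normalized (trimmed,
#' case-folded) so lookups are case-insensitive. The licensed MedDRA
#' dictionary is never bundled; any user-supplied or synthetic table with
#' this shape works.
#'
#' @param x path to a tab-separated file with columns `pt` and `soc`
#'   (header required), or a data.frame with those columns.
#' @return A named character vector of class `pt_soc_map` (names = PTs,
#'   values = SOCs).
#' @export
load_pt_soc_map <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE,
                           colClasses = "character")
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  if (!all(c("pt", "soc") %in% names(x))) {
    stop("PT-SOC mapping needs columns 'pt' and 'soc'", call. = FALSE)
  }
  pt <- norm_term(x$pt)
  soc <- norm_term(x$soc)
  tab <- unique(data.frame(pt = pt, soc = soc, stringsAsFactors = FALSE))
  dup <- unique(tab$pt[duplicated(tab$pt)])
  if (length(dup)) {
    stop(sprintf("PT(s) mapped to more than one SOC: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  structure(stats::setNames(tab$soc, tab$pt), class = "pt_soc_map")
}

#' Look up the SOC of preferred terms
#' @param map a `pt_soc_map` from [load_pt_soc_map()].
#' @param pts character vector of preferred terms (any case).
#' @return Character vector of SOCs, `NA` where a PT is not in the map.
#' @export
pt_soc <- function(map, pts) {
  stopifnot(inherits(map, "pt_soc_map"))
  unname(unclass(map)[norm_term(pts)])
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat(sprintf("<pt_soc_map> %d PT(s) across %d SOC(s)\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}
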