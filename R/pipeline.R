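# The five-step screening procedure: extract PTs per drug, group by SOC,
# restrict to infection-related SOCs, ROR-screen, retrieve the cases of
# enrolled PTs, and keep primary-suspect reports.

INFECTION_SOCS <- c("infections and infestations",
                    "respiratory, thoracic and mediastinal disorders")

#' Pipeline configuration
#'
#' Bundles everything the screening pipeline needs to know: which drugs
#' to screen (with their synonym lists), which system organ classes count
#' as infection-related, the receipt-quarter window, the signal
#' thresholds, and the counting convention.
#'
#' @param target_drugs named list: one element per drug, a character
#'   vector of synonyms (generic + brand names); a bare character vector
#'   of names is accepted and promoted.
#' @param infection_socs SOC labels treated as infection-related. The
#'   default is the two classes conventionally holding infection terms:
#'   "infections and infestations" and "respiratory, thoracic and
#'   mediastinal disorders".
#' @param quarter_range inclusive `c(start, end)` receipt-quarter window
#'   as `"YYYYQn"` strings; default `c("2015Q1", "2022Q3")`.
#' @param min_a minimum supporting case count for a signal (default 3).
#' @param ci_floor lower-CI threshold a signal must exceed (default 1.0).
#' @param counting `"pairs"` (report-PT incidence pairs, default) or
#'   `"reports"` — see [contingency_table()].
#' @param screen_roles role codes counted when *screening* (default
#'   `NULL` = all roles; the primary-suspect restriction applies only to
#'   case retrieval afterwards).
#' @param pt_allow,pt_deny optional PT lists forced into / out of the
#'   infection candidate set after the SOC filter, for terms whose
#'   infection relevance the SOC alone does not settle (e.g. inflammatory
#'   respiratory terms).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_drugs,
                            infection_socs = INFECTION_SOCS,
                            quarter_range = c("2015Q1", "2022Q3"),
                            min_a = 3, ci_floor = 1,
                            counting = c("pairs", "reports"),
                            screen_roles = NULL,
                            pt_allow = character(),
                            pt_deny = character()) {
  if (is.character(target_drugs)) {
    target_drugs <- stats::setNames(as.list(target_drugs), target_drugs)
  }
  if (length(target_drugs) == 0) {
    stop("target_drugs must name at least one drug", call. = FALSE)
  }
  if (is.null(names(target_drugs)) || any(names(target_drugs) == "")) {
    stop("target_drugs must be a named list of synonym vectors",
         call. = FALSE)
  }
  target_drugs <- lapply(target_drugs, function(s) unique(norm_term(s)))
  names(target_drugs) <- norm_term(names(target_drugs))
  check_quarter(quarter_range, "quarter_range")
  if (length(quarter_range) != 2 || quarter_range[1] > quarter_range[2]) {
    stop("quarter_range must be c(start, end) with start <= end",
         call. = FALSE)
  }
  if (!is.numeric(min_a) || min_a < 1) {
    stop("min_a must be >= 1", call. = FALSE)
  }
  structure(list(target_drugs = target_drugs,
                 infection_socs = norm_term(infection_socs),
                 quarter_range = as.character(quarter_range),
                 min_a = min_a, ci_floor = ci_floor,
                 counting = match.arg(counting),
                 screen_roles = screen_roles,
                 pt_allow = norm_term(pt_allow),
                 pt_deny = norm_term(pt_deny)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  drugs: %s\n", paste(names(x$target_drugs), collapse = ", ")))
  cat(sprintf("  quarters: %s..%s; signal rule: a >= %g & CI low > %g; %s counting\n",
              x$quarter_range[1], x$quarter_range[2], x$min_a, x$ci_floor,
              x$counting))
  invisible(x)
}

#' Extract all preferred terms reported under a drug
#'
#' @param reports a deduplicated `report_set`.
#' @param drug_synonyms character vector of names identifying the drug.
#' @return Sorted character vector of the distinct PTs occurring in at
#'   least one report matching the drug (empty when the drug is absent).
#' @export
extract_drug_pts <- function(reports, drug_synonyms) {
  stopifnot(inherits(reports, "report_set"))
  ids <- matching_cases(reports, drug_synonyms)
  pts <- reports$reactions$pt[reports$reactions$case_id %in% ids]
  sort(unique(pts), method = "radix")
}

#' Restrict preferred terms to infection-related organ classes
#'
#' Keeps PTs whose mapped SOC is one of `infection_socs`
#' (case-insensitive). PTs absent from the map are excluded with one
#' warning giving their count. An allow list forces PTs in afterwards; a
#' deny list removes them last.
#'
#' @param pts character vector of PTs.
#' @param map a `pt_soc_map`.
#' @param infection_socs SOC labels counted as infection-related.
#' @param allow,deny optional PT override lists applied after the SOC
#'   filter.
#' @return Sorted character vector of retained PTs.
#' @export
select_infection_pts <- function(pts, map, infection_socs = INFECTION_SOCS,
                                 allow = character(), deny = character()) {
  pts <- unique(norm_term(pts))
  socs <- pt_soc(map, pts)
  unmapped <- is.na(socs)
  if (any(unmapped)) {
    warning(sprintf("excluding %d PT(s) absent from the PT-SOC map",
                    sum(unmapped)), call. = FALSE)
  }
  keep <- !unmapped & socs %in% norm_term(infection_socs)
  out <- union(pts[keep], intersect(pts, norm_term(allow)))
  out <- setdiff(out, norm_term(deny))
  sort(out, method = "radix")
}

#' Keep reports where a drug is the primary suspect
#'
#' Retains the reports in which the target drug appears with role code
#' `PS`, discarding those where it is only secondary suspect,
#' concomitant, or interacting. A report listing the drug under several
#' roles is retained as long as one of them is `PS`.
#'
#' @param reports a `report_set`.
#' @param drug_synonyms character vector of names identifying the drug.
#' @return The filtered `report_set`.
#' @export
filter_primary_suspect <- function(reports, drug_synonyms) {
  stopifnot(inherits(reports, "report_set"))
  subset_cases(reports, matching_cases(reports, drug_synonyms, roles = "PS"))
}

#' Run the infection-signal screening pipeline
#'
#' Executes the five-step procedure for every configured drug on a report
#' set restricted to the configured quarter window:
#' 1. extract all PTs reported under the drug;
#' 2. map them to system organ classes;
#' 3. keep PTs from the infection-related SOCs (plus allow/deny
#'    overrides) as candidates;
#' 4. screen candidates with the ROR rule (all role codes by default);
#' 5. retrieve the cases listing at least one enrolled (signalled) PT and
#'    keep those where the drug is the primary suspect.
#'
#' Stage counts are emitted per drug: `all_aes` (the drug's adverse-event
#' count under the counting convention), `infection_aes` (distinct cases
#' listing an enrolled PT), `infection_ps` (those with the drug as
#' primary suspect).
#'
#' @param config a `pipeline_config`.
#' @param reports a `report_set`; deduplication and quarter filtering are
#'   applied internally.
#' @param map a `pt_soc_map`.
#' @return An object of class `faers_pipeline`: a list with one element
#'   per drug (each holding `screen`, `enrolled_pts`, `cases`,
#'   `stage_counts`, `candidate_pts`) plus the `config`.
#' @export
run_pipeline <- function(config, reports, map) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(reports, "report_set"),
            inherits(map, "pt_soc_map"))
  known_socs <- unique(unclass(map))
  missing_soc <- setdiff(config$infection_socs, known_socs)
  if (length(missing_soc)) {
    warning(sprintf("SOC(s) not present in the PT-SOC map: %s",
                    paste(missing_soc, collapse = "; ")), call. = FALSE)
  }

  rs <- filter_quarter_range(deduplicate(reports), config$quarter_range)

  drugs <- lapply(names(config$target_drugs), function(dn) {
    syn <- config$target_drugs[[dn]]
    all_pts <- extract_drug_pts(rs, syn)
    candidates <- select_infection_pts(all_pts, map, config$infection_socs,
                                       config$pt_allow, config$pt_deny)
    if (length(candidates)) {
      screen <- screen_signals(rs, syn, candidates, drug = dn,
                               min_a = config$min_a,
                               ci_floor = config$ci_floor,
                               convention = config$counting,
                               roles = config$screen_roles)
      enrolled <- screen$pt[screen$is_signal]
    } else {
      screen <- NULL
      enrolled <- character()
    }

    drug_ids <- matching_cases(rs, syn)
    if (length(enrolled)) {
      inf_ids <- intersect(
        drug_ids,
        unique(rs$reactions$case_id[rs$reactions$pt %in% enrolled]))
    } else {
      inf_ids <- character()
    }
    ps_ids <- intersect(inf_ids, matching_cases(rs, syn, roles = "PS"))
    cases <- subset_cases(rs, ps_ids)

    all_aes <- if (config$counting == "pairs") {
      sum(rs$reactions$case_id %in% drug_ids)
    } else {
      length(drug_ids)
    }
    list(drug = dn,
         candidate_pts = candidates,
         screen = screen,
         enrolled_pts = enrolled,
         cases = cases,
         stage_counts = c(all_aes = all_aes,
                          infection_aes = length(inf_ids),
                          infection_ps = length(ps_ids)))
  })
  names(drugs) <- names(config$target_drugs)
  structure(list(drugs = drugs, config = config), class = "faers_pipeline")
}

#' Stage counts of a pipeline run
#'
#' @param x a `faers_pipeline`.
#' @return Data frame with one row per drug and columns `drug`,
#'   `all_aes`, `infection_aes`, `infection_ps`, `n_signals`.
#' @export
stage_counts <- function(x) {
  stopifnot(inherits(x, "faers_pipeline"))
  do.call(rbind, lapply(x$drugs, function(d) {
    data.frame(drug = d$drug,
               all_aes = unname(d$stage_counts["all_aes"]),
               infection_aes = unname(d$stage_counts["infection_aes"]),
               infection_ps = unname(d$stage_counts["infection_ps"]),
               n_signals = length(d$enrolled_pts),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Primary-suspect case sets of a pipeline run
#'
#' @param x a `faers_pipeline`.
#' @return Named list of `report_set`, one per drug: the cases matching
#'   the drug as primary suspect and listing at least one enrolled PT.
#' @export
enrolled_cases <- function(x) {
  stopifnot(inherits(x, "faers_pipeline"))
  lapply(x$drugs, `[[`, "cases")
}

#' @export
print.faers_pipeline <- function(x, ...) {
  cat("<faers_pipeline>\n")
  print(stage_counts(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.faers_pipeline <- function(object, ...) {
  print(object)
  for (d in object$drugs) {
    if (length(d$enrolled_pts)) {
      cat(sprintf("  %s enrolled PTs: %s\n", d$drug,
                  paste(d$enrolled_pts, collapse = ", ")))
    } else {
      cat(sprintf("  %s: no PT met the signal criteria\n", d$drug))
    }
  }
  invisible(object)
}
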