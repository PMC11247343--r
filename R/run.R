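# Configuration files, the end-to-end run, and the run manifest.

CONFIG_KEYS <- c("drugs", "infection_socs", "quarter_range", "min_a",
                 "ci_floor", "counting", "screen_roles", "pt_allow",
                 "pt_deny")

#' Load a pipeline configuration from YAML
#'
#' The file must define `drugs` (a list of `{name, synonyms}` entries;
#' `synonyms` defaults to the name); every other key is optional and
#' falls back to the defaults of [pipeline_config()]. Unknown top-level
#' keys and malformed quarter strings are rejected with an error naming
#' the offender.
#'
#' @param path path to a YAML file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(raw$drugs) || length(raw$drugs) == 0) {
    stop("config field 'drugs' must list at least one drug", call. = FALSE)
  }
  target <- list()
  for (d in raw$drugs) {
    if (is.null(d$name) || !nzchar(d$name)) {
      stop("config field 'drugs': every entry needs a 'name'", call. = FALSE)
    }
    target[[d$name]] <- unique(c(d$name, unlist(d$synonyms)))
  }
  args <- list(target_drugs = target)
  for (k in setdiff(CONFIG_KEYS, "drugs")) {
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  }
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- list(
    drugs = lapply(names(config$target_drugs), function(dn) {
      list(name = dn, synonyms = as.list(config$target_drugs[[dn]]))
    }),
    infection_socs = as.list(config$infection_socs),
    quarter_range = as.list(config$quarter_range),
    min_a = config$min_a,
    ci_floor = config$ci_floor,
    counting = config$counting,
    pt_allow = as.list(config$pt_allow),
    pt_deny = as.list(config$pt_deny))
  if (!is.null(config$screen_roles)) {
    obj$screen_roles <- as.list(config$screen_roles)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulation_config()]; `drugs`,
#' `pts` and `enrichments` are lists of records, the distributions are
#' named mappings. Absent keys fall back to the defaults.
#'
#' @param path path to a YAML file.
#' @return A `simulation_config`.
#' @export
load_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  args <- list()
  recs <- function(x) do.call(rbind, lapply(x, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(raw$n_reports)) args$n_reports <- raw$n_reports
  if (!is.null(raw$drugs)) args$drugs <- recs(raw$drugs)
  if (!is.null(raw$pts)) args$pts <- recs(raw$pts)
  if (!is.null(raw$enrichments)) args$enrichments <- recs(raw$enrichments)
  for (k in c("sex_probs", "age_band_probs", "country_probs", "year_probs",
              "outcome_probs")) {
    if (!is.null(raw[[k]])) args[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$duplicate_fraction)) {
    args$duplicate_fraction <- raw$duplicate_fraction
  }
  do.call(simulation_config, args)
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

fmt_pct_table <- function(counts, pct) {
  out <- data.frame(level = rownames(counts), stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (cn in colnames(counts)) {
    out[[paste0(cn, "_n")]] <- counts[, cn]
    out[[paste0(cn, "_pct")]] <- fmt_num(pct[, cn], 2)
  }
  out
}

#' Run the full analysis end to end
#'
#' Parses the four report tables, runs the screening pipeline, computes
#' the descriptive and severity summaries of the enrolled primary-suspect
#' cases, writes every output table as TSV into `out_dir`, and returns a
#' run manifest. Outputs: `signals.tsv`, `stage_counts.tsv`,
#' `enrolled_cases.tsv`, `characteristics.tsv`, `outcomes.tsv`,
#' `severity_tests.tsv`, `yearly_trend.tsv`, `manifest.json`. Percentages
#' are printed to 2 decimals, ROR/CI to 2, p-values to 4. Reruns with
#' identical inputs reproduce identical output checksums.
#'
#' The severity chi-square comparisons (severity by sex and by age band,
#' unknown level excluded) are computed over the pooled enrolled cases;
#' when a table is degenerate the test is skipped with a note in the
#' output file.
#'
#' @param config a `pipeline_config` or the path of a YAML config file.
#' @param demo,drug,reac,outc paths of the four report tables.
#' @param pt_soc_map path of the PT-SOC table or a `pt_soc_map`.
#' @param out_dir output directory (created if needed).
#' @param dialect table dialect, see [parse_reports()].
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_all <- function(config, demo, drug, reac, outc, pt_soc_map, out_dir,
                    dialect = c("simple_tsv", "faers_ascii")) {
  dialect <- match.arg(dialect)
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(pt_soc_map)) pt_soc_map <- load_pt_soc_map(pt_soc_map)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  inputs <- c(demo = demo, drug = drug, reac = reac, outc = outc)
  reports <- parse_reports(demo, drug, reac, outc, dialect)
  pipe <- run_pipeline(config, reports, pt_soc_map)
  cases <- enrolled_cases(pipe)

  files <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_file(df, p)
    files <<- c(files, p)
  }

  screens <- Filter(Negate(is.null), lapply(pipe$drugs, `[[`, "screen"))
  if (length(screens)) {
    sig <- do.call(rbind, lapply(screens, as.data.frame))
    sig$ror <- fmt_num(sig$ror, 2)
    sig$ci_low <- fmt_num(sig$ci_low, 2)
    sig$ci_high <- fmt_num(sig$ci_high, 2)
  } else {
    sig <- data.frame(drug = character(), pt = character())
  }
  rownames(sig) <- NULL
  put(sig, "signals.tsv")
  put(stage_counts(pipe), "stage_counts.tsv")

  enr <- do.call(rbind, lapply(names(cases), function(dn) {
    cs <- cases[[dn]]
    if (length(case_ids(cs)) == 0) return(NULL)
    d <- cs$demo
    data.frame(drug = dn, case_id = d$case_id, sex = d$sex,
               age_years = d$age_years, country = d$country,
               report_year = d$report_year, quarter = d$quarter,
               severity = unname(classify_severity(cs)[d$case_id]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(enr)) {
    enr <- data.frame(drug = character(), case_id = character())
  }
  put(enr, "enrolled_cases.tsv")

  any_cases <- any(vapply(cases, function(x) length(case_ids(x)) > 0,
                          logical(1)))
  if (any_cases) {
    ch <- summarize_characteristics(cases)
    char_df <- do.call(rbind, lapply(c("sex", "age_band", "year", "country"),
                                     function(b) {
      cbind(category = b, fmt_pct_table(ch[[b]]$counts, ch[[b]]$pct))
    }))
    put(char_df, "characteristics.tsv")
    ot <- outcome_table(cases)
    put(cbind(outcome = rownames(ot$counts),
              fmt_pct_table(ot$counts, ot$pct)[-1]), "outcomes.tsv")

    pooled_rs <- subset_cases(
      structure(list(demo = do.call(rbind, lapply(cases, `[[`, "demo")),
                     drugs = do.call(rbind, lapply(cases, `[[`, "drugs")),
                     reactions = do.call(rbind,
                                         lapply(cases, `[[`, "reactions")),
                     outcomes = do.call(rbind,
                                        lapply(cases, `[[`, "outcomes"))),
                class = "report_set"),
      unlist(lapply(cases, case_ids)))
    sev_rows <- lapply(c(sex = "sex", age_band = "age_band"), function(by) {
      tab <- severity_crosstab(pooled_rs, by)
      res <- tryCatch(pearson_chi_square(tab, drop_categories = "unknown"),
                      error = function(e) NULL)
      if (is.null(res)) {
        data.frame(comparison = by, statistic = "", df = "", p_value = "",
                   note = "degenerate table; test skipped",
                   stringsAsFactors = FALSE)
      } else {
        data.frame(comparison = by,
                   statistic = fmt_num(res$statistic, 3),
                   df = res$df, p_value = fmt_num(res$p_value, 4),
                   note = "unknown level excluded; no continuity correction",
                   stringsAsFactors = FALSE)
      }
    })
    put(do.call(rbind, sev_rows), "severity_tests.tsv")

    all_ps <- do.call(rbind, lapply(names(config$target_drugs), function(dn) {
      rs <- filter_quarter_range(deduplicate(reports), config$quarter_range)
      ids <- matching_cases(rs, config$target_drugs[[dn]], roles = "PS")
      rs$demo[rs$demo$case_id %in% ids, , drop = FALSE]
    }))
    all_ps_rs <- structure(list(demo = unique(all_ps),
                                drugs = data.frame(case_id = character(),
                                                   drug_name = character(),
                                                   role_code = character()),
                                reactions = data.frame(case_id = character(),
                                                       pt = character()),
                                outcomes = data.frame(case_id = character(),
                                                      outcome = character())),
                           class = "report_set")
    trend <- yearly_trend(all_ps_rs, pooled_rs)
    trend$proportion <- fmt_num(trend$proportion, 4)
    put(trend, "yearly_trend.tsv")
  }

  manifest <- list(
    config_hash = hash_object(unclass(config)),
    inputs = as.list(tools::md5sum(inputs)),
    dialect = dialect,
    stage_counts = stage_counts(pipe),
    outputs = as.list(stats::setNames(tools::md5sum(files),
                                      basename(files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
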