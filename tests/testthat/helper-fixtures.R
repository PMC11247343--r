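# Builders and independent oracles shared across test files.

# minimal hand-built report set; drugs/pts per case given as lists
toy_report_set <- function(case_drugs, case_pts, roles = NULL,
                           outcomes = NULL, quarter = "2020Q1",
                           sex = "female", age = 60, country = "us") {
  ids <- sprintf("T%03d", seq_along(case_drugs))
  demo <- data.frame(case_id = ids, version_key = paste0(quarter, "-1"),
                     sex = sex, age_years = age, country = country,
                     report_year = as.integer(substr(quarter, 1, 4)),
                     quarter = quarter, stringsAsFactors = FALSE)
  drugs <- do.call(rbind, lapply(seq_along(case_drugs), function(i) {
    dn <- case_drugs[[i]]
    rc <- if (is.null(roles)) rep("PS", length(dn)) else roles[[i]]
    data.frame(case_id = ids[i], drug_name = dn, role_code = rc,
               stringsAsFactors = FALSE)
  }))
  reac <- do.call(rbind, lapply(seq_along(case_pts), function(i) {
    data.frame(case_id = ids[i], pt = case_pts[[i]],
               stringsAsFactors = FALSE)
  }))
  outc <- if (is.null(outcomes)) NULL else
    do.call(rbind, lapply(seq_along(outcomes), function(i) {
      oc <- outcomes[[i]]
      if (length(oc) == 0) return(NULL)
      data.frame(case_id = ids[i], outcome = oc, stringsAsFactors = FALSE)
    }))
  report_set(demo, drugs, reac, outc)
}

# per-case PT sets / drug matches, recomputed the slow way
case_pt_sets <- function(rs) {
  ids <- case_ids(rs)
  out <- lapply(ids, function(id) {
    unique(rs$reactions$pt[rs$reactions$case_id == id])
  })
  names(out) <- ids
  out
}

case_drug_sets <- function(rs, roles = NULL) {
  ids <- case_ids(rs)
  d <- rs$drugs
  if (!is.null(roles)) d <- d[d$role_code %in% roles, , drop = FALSE]
  out <- lapply(ids, function(id) unique(d$drug_name[d$case_id == id]))
  names(out) <- ids
  out
}

# brute-force double loop over reports x PTs: pair-counting contingency
brute_contingency <- function(rs, synonyms, pt, roles = NULL) {
  pts_by_case <- case_pt_sets(rs)
  drugs_by_case <- case_drug_sets(rs, roles)
  syn <- tolower(trimws(synonyms))
  a <- b <- cc <- d <- 0L
  for (id in names(pts_by_case)) {
    in_drug <- any(drugs_by_case[[id]] %in% syn)
    for (p in pts_by_case[[id]]) {
      if (in_drug && p == pt) a <- a + 1L
      else if (in_drug) b <- b + 1L
      else if (p == pt) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  list(a = a, b = b, c = cc, d = d)
}

# independently coded odds ratio + log-variance interval
oracle_ror <- function(a, b, cc, d, z = 1.96) {
  log_or <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(ror = exp(log_or), ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se))
}

# small generator config used in several files: 2 target-ish drugs,
# 2 background drugs, 8 PTs in 2 SOCs
small_sim_config <- function(n = 600, enrichments = NULL,
                             duplicate_fraction = 0.05) {
  drugs <- data.frame(
    name = c("drugx", "drugy", "back1", "back2"),
    p = c(0.15, 0.10, 0.35, 0.35),
    ps = 0.5, ss = 0.2, c = 0.25, i = 0.05, stringsAsFactors = FALSE)
  pts <- data.frame(
    name = c("pneumonia", "sepsis", "influenza", "pneumonitis",
             "nausea", "fatigue", "anaemia", "diarrhoea"),
    soc = c(rep("infections and infestations", 3),
            "respiratory, thoracic and mediastinal disorders",
            rep("gastrointestinal disorders", 2),
            rep("blood and lymphatic system disorders", 2)),
    p = c(0.04, 0.02, 0.03, 0.02, 0.10, 0.12, 0.06, 0.08),
    stringsAsFactors = FALSE)
  if (is.null(enrichments)) {
    enrichments <- data.frame(drug = character(), pt = character(),
                              rate = numeric())
  }
  simulation_config(n_reports = n, drugs = drugs, pts = pts,
                    enrichments = enrichments,
                    duplicate_fraction = duplicate_fraction)
}

# field-wise equality of two report sets (component data frames)
expect_report_set_equal <- function(x, y) {
  for (comp in c("demo", "drugs", "reactions", "outcomes")) {
    a <- x[[comp]]; b <- y[[comp]]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, info = comp)
  }
}
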