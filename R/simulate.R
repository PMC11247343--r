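# Seedable generator of FAERS-like spontaneous report databases with
# configurable background rates and planted drug-PT enrichments.

default_sim_drugs <- function() {
  data.frame(
    name = c("drugx", "drugy", "drugz", "backdrug1", "backdrug2",
             "backdrug3", "backdrug4", "backdrug5"),
    p = c(0.10, 0.03, 0.02, 0.25, 0.25, 0.25, 0.25, 0.25),
    ps = c(rep(0.6, 3), rep(0.25, 5)),
    ss = c(rep(0.15, 3), rep(0.25, 5)),
    c = c(rep(0.2, 3), rep(0.45, 5)),
    i = c(rep(0.05, 3), rep(0.05, 5)),
    stringsAsFactors = FALSE)
}

default_sim_pts <- function() {
  inf <- c("pneumonia", "urinary tract infection", "sepsis", "cellulitis",
           "influenza", "oral candidiasis", "herpes zoster", "nasopharyngitis")
  resp <- c("pneumonitis", "dyspnoea", "cough", "pleural effusion")
  gi <- c("nausea", "diarrhoea", "vomiting", "abdominal pain")
  blood <- c("neutropenia", "anaemia", "thrombocytopenia")
  gen <- c("fatigue", "pyrexia", "asthenia", "death nos", "malaise")
  data.frame(
    name = c(inf, resp, gi, blood, gen),
    soc = c(rep("infections and infestations", length(inf)),
            rep("respiratory, thoracic and mediastinal disorders",
                length(resp)),
            rep("gastrointestinal disorders", length(gi)),
            rep("blood and lymphatic system disorders", length(blood)),
            rep("general disorders and administration site conditions",
                length(gen))),
    p = c(0.030, 0.020, 0.010, 0.010, 0.015, 0.008, 0.008, 0.012,
          0.015, 0.040, 0.035, 0.010,
          0.080, 0.070, 0.050, 0.040,
          0.060, 0.030, 0.020,
          0.090, 0.060, 0.040, 0.015, 0.030),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic report generator
#'
#' Defines a complete generative model for a FAERS-like database: drug
#' marginal probabilities with role-code distributions, PT background
#' probabilities with their SOC labels, planted drug-PT enrichments
#' (relative reporting rates), demographic and outcome distributions, and
#' a duplicate-version rate. Defaults emulate a breast-cancer
#' pharmacovigilance setting: three target drugs of decreasing market
#' share against a background of common co-reported drugs, a
#' predominantly female elderly population, US-weighted reporting
#' countries over 2015-2022, and FAERS-like outcome frequencies with a
#' large unknown fraction.
#'
#' @param n_reports number of cases to generate.
#' @param drugs data.frame with columns `name`, `p` (marginal probability
#'   a report mentions the drug), and role probabilities `ps`, `ss`, `c`,
#'   `i` summing to 1 per row.
#' @param pts data.frame with columns `name`, `soc`, `p` (background
#'   probability a report lists the PT).
#' @param enrichments data.frame with columns `drug`, `pt`, `rate`
#'   (relative reporting rate >= 1): reports mentioning `drug` draw `pt`
#'   with probability `min(1, p * rate)`. When several enrichments match
#'   one report, the largest rate applies.
#' @param sex_probs,country_probs named probability vectors (must sum to
#'   1); the `unknown` country level becomes a missing country.
#' @param age_band_probs named probabilities over `<40`, `40-64`, `>=65`,
#'   `unknown`; ages are drawn uniformly within the band (18-39.9,
#'   40-64.9, 65-90) and rounded to 1 decimal; `unknown` yields a missing
#'   age.
#' @param year_probs named probabilities over reporting years; a quarter
#'   is drawn uniformly within the year.
#' @param outcome_probs named probabilities over `HO`, `DE`, `LT`, `DS`,
#'   `OT`, `none`; each case draws exactly one code (`none` = no outcome
#'   recorded).
#' @param duplicate_fraction probability a case additionally emits a
#'   follow-up version (next quarter, version suffix `-2`).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_reports = 2000,
    drugs = default_sim_drugs(),
    pts = default_sim_pts(),
    enrichments = data.frame(drug = character(), pt = character(),
                             rate = numeric()),
    sex_probs = c(female = 0.85, male = 0.05, unknown = 0.10),
    age_band_probs = c("<40" = 0.05, "40-64" = 0.35, ">=65" = 0.40,
                       "unknown" = 0.20),
    country_probs = c(us = 0.55, de = 0.06, gb = 0.05, ar = 0.03,
                      ca = 0.03, jp = 0.03, other = 0.15, unknown = 0.10),
    year_probs = stats::setNames(rep(1 / 8, 8), 2015:2022),
    outcome_probs = c(HO = 0.22, DE = 0.07, LT = 0.02, DS = 0.01,
                      OT = 0.28, none = 0.40),
    duplicate_fraction = 0.05) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  pts <- as.data.frame(pts, stringsAsFactors = FALSE)
  enrichments <- as.data.frame(enrichments, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "p", "ps", "ss", "c", "i") %in% names(drugs)),
            all(c("name", "soc", "p") %in% names(pts)),
            all(c("drug", "pt", "rate") %in% names(enrichments)))
  drugs$name <- norm_term(drugs$name)
  pts$name <- norm_term(pts$name)
  pts$soc <- norm_term(pts$soc)
  enrichments$drug <- norm_term(enrichments$drug)
  enrichments$pt <- norm_term(enrichments$pt)

  chk_prob <- function(p, what) {
    if (any(p < 0 | p > 1)) {
      stop(sprintf("%s probabilities must lie in [0, 1]", what),
           call. = FALSE)
    }
  }
  chk_dist <- function(p, what) {
    chk_prob(p, what)
    if (abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("%s distribution must sum to 1", what), call. = FALSE)
    }
  }
  chk_prob(drugs$p, "drug marginal")
  chk_prob(pts$p, "PT background")
  for (i in seq_len(nrow(drugs))) {
    chk_dist(unlist(drugs[i, c("ps", "ss", "c", "i")]),
             sprintf("role-code (%s)", drugs$name[i]))
  }
  chk_dist(sex_probs, "sex")
  chk_dist(age_band_probs, "age band")
  chk_dist(country_probs, "country")
  chk_dist(year_probs, "year")
  chk_dist(outcome_probs, "outcome")
  if (!setequal(names(age_band_probs), AGE_BANDS)) {
    stop("age_band_probs must be named over <40, 40-64, >=65, unknown",
         call. = FALSE)
  }
  if (!setequal(names(outcome_probs), c(OUTCOME_CODES, "none"))) {
    stop("outcome_probs must be named over HO, DE, LT, DS, OT, none",
         call. = FALSE)
  }
  if (any(enrichments$rate < 1)) {
    stop("enrichment relative rates must be >= 1", call. = FALSE)
  }
  if (all(drugs$p == 0) || all(pts$p == 0)) {
    stop("infeasible config: every report needs >= 1 drug and >= 1 PT",
         call. = FALSE)
  }
  bad <- !enrichments$drug %in% drugs$name | !enrichments$pt %in% pts$name
  if (any(bad)) {
    stop("enrichment refers to an unknown drug or PT", call. = FALSE)
  }
  if (duplicate_fraction < 0 || duplicate_fraction > 1) {
    stop("duplicate_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 pts = pts, enrichments = enrichments,
                 sex_probs = sex_probs, age_band_probs = age_band_probs,
                 country_probs = country_probs, year_probs = year_probs,
                 outcome_probs = outcome_probs,
                 duplicate_fraction = duplicate_fraction),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d reports, %d drugs, %d PTs, %d planted enrichment(s)\n",
              x$n_reports, nrow(x$drugs), nrow(x$pts), nrow(x$enrichments)))
  invisible(x)
}

# Bernoulli matrix draws per row with per-row-column probabilities,
# rejection-sampled so every row has >= 1 success.
draw_nonempty <- function(n, prob_matrix) {
  k <- ncol(prob_matrix)
  m <- matrix(stats::runif(n * k), n, k) < prob_matrix
  repeat {
    empty <- which(rowSums(m) == 0)
    if (length(empty) == 0) break
    m[empty, ] <- matrix(stats::runif(length(empty) * k),
                         length(empty), k) < prob_matrix[empty, , drop = FALSE]
  }
  m
}

sample_levels <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic FAERS-like report set
#'
#' Draws `n_reports` cases from the generative model of a
#' [simulation_config()]: each case draws its drug set (independent
#' Bernoulli per drug, rejection-sampled until non-empty), then each PT
#' independently with probability `p * rate` where `rate` is the largest
#' planted enrichment matching any of the case's drugs (1 when none),
#' rejection-sampled until at least one PT; demographics, role codes and
#' the outcome code are drawn independently. A `duplicate_fraction` of
#' cases emits a follow-up version dated one quarter later with version
#' suffix `-2`, so the returned set exercises [deduplicate()].
#'
#' @param config a `simulation_config`.
#' @param seed integer seed; the same (config, seed) always reproduces
#'   the identical report set. The caller's RNG state is restored on
#'   exit.
#' @return List with elements `reports` (a `report_set`, pre-dedup) and
#'   `ground_truth` (list: `assignments` data frame with every per-case
#'   category draw and per-drug indicator columns, `enrichments`,
#'   `duplicated_cases`).
#' @export
simulate_reports <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!missing(seed) && !is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  n <- config$n_reports
  drugs <- config$drugs
  pts <- config$pts
  J <- nrow(drugs); K <- nrow(pts)

  drug_m <- draw_nonempty(n, matrix(drugs$p, n, J, byrow = TRUE))
  colnames(drug_m) <- drugs$name

  # per-case PT probability: background times the largest enrichment rate
  # among the case's drugs, capped at 1
  pt_prob <- matrix(pts$p, n, K, byrow = TRUE)
  colnames(pt_prob) <- pts$name
  enr <- config$enrichments
  if (nrow(enr)) {
    for (k in seq_len(K)) {
      rows <- enr[enr$pt == pts$name[k], , drop = FALSE]
      if (nrow(rows) == 0) next
      rate <- rep(1, n)
      for (j in seq_len(nrow(rows))) {
        hit <- drug_m[, rows$drug[j]]
        rate[hit] <- pmax(rate[hit], rows$rate[j])
      }
      pt_prob[, k] <- pmin(1, pt_prob[, k] * rate)
    }
  }
  pt_m <- draw_nonempty(n, pt_prob)
  colnames(pt_m) <- pts$name

  case_id <- sprintf("C%06d", seq_len(n))
  sex <- sample_levels(n, config$sex_probs)
  band <- sample_levels(n, config$age_band_probs)
  lo <- c("<40" = 18, "40-64" = 40, ">=65" = 65, "unknown" = 18)[band]
  hi <- c("<40" = 39.9, "40-64" = 64.9, ">=65" = 90, "unknown" = 90)[band]
  age <- round(stats::runif(n, lo, hi), 1)
  age[band == "unknown"] <- NA_real_
  country <- sample_levels(n, config$country_probs)
  country[country == "unknown"] <- NA_character_
  year <- as.integer(sample_levels(n, config$year_probs))
  q <- sample.int(4, n, replace = TRUE)
  quarter <- sprintf("%dQ%d", year, q)
  outcome <- sample_levels(n, config$outcome_probs)

  demo <- data.frame(case_id = case_id,
                     version_key = paste0(quarter, "-1"),
                     sex = sex, age_years = age, country = country,
                     report_year = year, quarter = quarter,
                     stringsAsFactors = FALSE)

  # duplicate versions: same case, next quarter, version 2
  dup <- stats::runif(n) < config$duplicate_fraction
  if (any(dup)) {
    q2 <- ifelse(q[dup] == 4, 1L, q[dup] + 1L)
    y2 <- ifelse(q[dup] == 4, year[dup] + 1L, year[dup])
    quarter2 <- sprintf("%dQ%d", y2, q2)
    demo2 <- demo[dup, , drop = FALSE]
    demo2$version_key <- paste0(quarter2, "-2")
    demo2$quarter <- quarter2
    demo2$report_year <- y2
    demo <- rbind(demo, demo2)
  }

  drug_idx <- which(drug_m, arr.ind = TRUE)
  role_draw <- function(name, count) {
    probs <- unlist(drugs[drugs$name == name, c("ps", "ss", "c", "i")])
    sample(ROLE_CODES, count, replace = TRUE, prob = probs)
  }
  drug_rows <- data.frame(case_id = case_id[drug_idx[, 1]],
                          drug_name = drugs$name[drug_idx[, 2]],
                          stringsAsFactors = FALSE)
  drug_rows <- drug_rows[order(drug_idx[, 2], drug_idx[, 1]), , drop = FALSE]
  drug_rows$role_code <- unlist(lapply(drugs$name, function(nm) {
    cnt <- sum(drug_rows$drug_name == nm)
    if (cnt) role_draw(nm, cnt) else character()
  }))

  pt_idx <- which(pt_m, arr.ind = TRUE)
  reac_rows <- data.frame(case_id = case_id[pt_idx[, 1]],
                          pt = pts$name[pt_idx[, 2]],
                          stringsAsFactors = FALSE)
  outc_rows <- data.frame(case_id = case_id[outcome != "none"],
                          outcome = outcome[outcome != "none"],
                          stringsAsFactors = FALSE)

  # ground truth records the surviving (latest-version) receipt quarter,
  # which is what deduplicated summaries see
  final_year <- year; final_quarter <- quarter
  if (any(dup)) {
    final_year[dup] <- y2
    final_quarter[dup] <- quarter2
  }
  gt_assign <- data.frame(case_id = case_id, sex = sex, age_band = band,
                          age_years = age, country = country,
                          report_year = final_year, quarter = final_quarter,
                          outcome = outcome, stringsAsFactors = FALSE)
  gt_assign <- cbind(gt_assign, as.data.frame(drug_m))

  list(reports = report_set(demo, drug_rows, reac_rows, outc_rows),
       ground_truth = list(assignments = gt_assign,
                           enrichments = enr,
                           duplicated_cases = case_id[dup]))
}

#' Analytic expected contingency cells under a simulation config
#'
#' Computes the exact expected cell counts E[a], E[b], E[c], E[d] of the
#' pair-counting contingency table for one (drug, PT) pair under the
#' generative model of [simulate_reports()], by enumerating all non-empty
#' drug subsets and applying the rejection-sampling conditionals in
#' closed form. Useful both as an independent oracle for the generator
#' and for planning planted-signal power (`ror` of the expected cells
#' approximates the large-sample ROR).
#'
#' @param config a `simulation_config`.
#' @param drug,pt the target pair.
#' @return List with `a`, `b`, `c`, `d` (expected counts) and `ror` (the
#'   odds ratio of the expected cells).
#' @export
expected_counts <- function(config, drug, pt) {
  stopifnot(inherits(config, "simulation_config"))
  drug <- norm_term(drug); pt <- norm_term(pt)
  drugs <- config$drugs; pts <- config$pts
  J <- nrow(drugs)
  if (J > 20) stop("subset enumeration supports at most 20 drugs",
                   call. = FALSE)
  if (!drug %in% drugs$name || !pt %in% pts$name) {
    stop("unknown drug or PT", call. = FALSE)
  }
  enr <- config$enrichments
  n <- config$n_reports
  cells <- c(a = 0, b = 0, c = 0, d = 0)
  p_nonempty_drugs <- 1 - prod(1 - drugs$p)
  for (mask in seq_len(2^J - 1)) {
    in_set <- bitwAnd(mask, bitwShiftL(1L, seq_len(J) - 1L)) > 0
    p_s <- prod(ifelse(in_set, drugs$p, 1 - drugs$p)) / p_nonempty_drugs
    if (p_s == 0) next
    members <- drugs$name[in_set]
    q <- pts$p
    if (nrow(enr)) {
      for (k in seq_along(q)) {
        rows <- enr[enr$pt == pts$name[k] & enr$drug %in% members, ,
                    drop = FALSE]
        if (nrow(rows)) q[k] <- min(1, q[k] * max(rows$rate))
      }
    }
    p_any_pt <- 1 - prod(1 - q)
    if (p_any_pt == 0) next
    cond <- q / p_any_pt  # E[#pairs with PT k | subset] per report
    tgt <- pts$name == pt
    if (drug %in% members) {
      cells["a"] <- cells["a"] + n * p_s * cond[tgt]
      cells["b"] <- cells["b"] + n * p_s * sum(cond[!tgt])
    } else {
      cells["c"] <- cells["c"] + n * p_s * cond[tgt]
      cells["d"] <- cells["d"] + n * p_s * sum(cond[!tgt])
    }
  }
  out <- as.list(cells)
  out$ror <- (cells[["a"]] / cells[["c"]]) / (cells[["b"]] / cells[["d"]])
  out
}

#' PT-SOC map implied by a simulation config
#' @param config a `simulation_config`.
#' @return A `pt_soc_map` covering the config's PTs.
#' @export
sim_pt_soc_map <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  load_pt_soc_map(data.frame(pt = config$pts$name, soc = config$pts$soc,
                             stringsAsFactors = FALSE))
}
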