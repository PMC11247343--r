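# Contingency counting and the ROR statistic.

test_that("minimal balanced set gives the unit table and multiplicity collapses", {
  rs <- toy_report_set(list("drugx", "drugx", "drugw", "drugw"),
                       list("pty", "ptz", "pty", "ptz"))
  tab <- contingency_table(rs, "drugx", "pty")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 1))

  # a report listing the PT twice contributes once
  rs2 <- toy_report_set(list("drugx", "drugw"),
                        list(c("pty", "pty", "ptz"), "pty"))
  tab2 <- contingency_table(rs2, "drugx", "pty")
  expect_equal(tab2$a, 1)
  expect_equal(tab2$b, 1)
  expect_error(contingency_table(subset_cases(rs, character()), "drugx", "pty"),
               "empty")
})

test_that("pair-counting table equals a brute-force double loop on simulated data", {
  sim <- simulate_reports(small_sim_config(
    n = 500,
    enrichments = data.frame(drug = "drugx", pt = "pneumonia", rate = 4)),
    seed = 21)
  rs <- deduplicate(sim$reports)
  for (pt in c("pneumonia", "nausea", "sepsis")) {
    got <- contingency_table(rs, "drugx", pt)
    want <- brute_contingency(rs, "drugx", pt)
    expect_equal(got[c("a", "b", "c", "d")], want, info = pt)
  }
  # role-restricted counting agrees too
  got_ps <- contingency_table(rs, "drugx", "pneumonia", roles = "PS")
  want_ps <- brute_contingency(rs, "drugx", "pneumonia", roles = "PS")
  expect_equal(got_ps[c("a", "b", "c", "d")], want_ps)
})

test_that("report-level convention counts distinct cases", {
  rs <- toy_report_set(list("drugx", "drugx", "drugw"),
                       list(c("pty", "ptz"), "ptz", "pty"))
  tab <- contingency_table(rs, "drugx", "pty", convention = "reports")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1, 1, 1, 0))
  expect_equal(tab$a + tab$b + tab$c + tab$d, length(case_ids(rs)))
})

test_that("ROR and CI match the symmetric and independently coded examples", {
  sym <- compute_ror(list(a = 10, b = 90, c = 10, d = 90))
  expect_equal(sym$ror, 1.0)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
  expect_false(sym$is_signal)

  r <- compute_ror(list(a = 20, b = 80, c = 30, d = 870))
  o <- oracle_ror(20, 80, 30, 870)
  expect_equal(r$ror, o$ror, tolerance = 1e-12)
  expect_equal(r$ci_low, o$ci_low, tolerance = 1e-12)
  expect_equal(r$ci_high, o$ci_high, tolerance = 1e-12)
  expect_true(r$ci_low <= r$ror && r$ror <= r$ci_high)
})

test_that("the a >= 3 gate overrides any ROR and zero cells yield undefined CIs", {
  big <- compute_ror(list(a = 2, b = 10, c = 10, d = 1000))
  expect_gt(big$ror, 1)
  expect_false(big$is_signal)

  z <- compute_ror(list(a = 5, b = 0, c = 10, d = 100))
  expect_true(z$undefined_ci)
  expect_true(is.na(z$ci_low))
  expect_false(z$is_signal)
})

test_that("ROR is scale-invariant, monotone in a, and its CI narrows with size", {
  base <- compute_ror(list(a = 6, b = 40, c = 12, d = 300))
  for (k in c(2L, 5L, 10L)) {
    scaled <- compute_ror(list(a = 6 * k, b = 40 * k, c = 12 * k, d = 300 * k))
    expect_equal(scaled$ror, base$ror, tolerance = 1e-12)
    expect_lt(scaled$ci_high - scaled$ci_low, base$ci_high - base$ci_low)
  }
  rors <- vapply(3:30, function(a)
    compute_ror(list(a = a, b = 40, c = 12, d = 300))$ror, numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("screening returns every candidate, signals first by descending ROR", {
  rs <- toy_report_set(
    case_drugs = c(rep(list("drugx"), 8), rep(list("drugw"), 12)),
    case_pts = c(rep(list(c("pty", "common")), 4),
                 rep(list(c("ptz", "common")), 4),
                 rep(list("common"), 10), list("pty"), list("ptz")))
  sc <- screen_signals(rs, "drugx", c("ptz", "pty", "common", "absent"))
  expect_s3_class(sc, "signal_screen")
  expect_equal(nrow(sc), 4)
  expect_setequal(sc$pt, c("pty", "ptz", "common", "absent"))
  sig <- sc[sc$is_signal, ]
  if (nrow(sig) > 1) expect_true(all(diff(sig$ror) <= 0))
  nonsig <- sc[!sc$is_signal, ]
  expect_equal(nonsig$pt, sort(nonsig$pt))
  # a candidate never reported has a = 0 and cannot signal
  expect_equal(sc$a[sc$pt == "absent"], 0)
  expect_false(sc$is_signal[sc$pt == "absent"])
  # screening composes per-PT compute_ror results
  for (i in seq_len(nrow(sc))) {
    single <- compute_ror(contingency_table(rs, "drugx", sc$pt[i]))
    expect_equal(sc$ror[i], single$ror)
    expect_equal(sc$is_signal[i], single$is_signal)
  }
})

test_that("planted enrichments are flagged and agree with per-PT calls on synthetic data", {
  sim <- simulate_reports(small_sim_config(
    n = 2000,
    enrichments = data.frame(drug = "drugx",
                             pt = c("pneumonia", "sepsis"),
                             rate = c(6, 6))),
    seed = 5)
  rs <- deduplicate(sim$reports)
  sc <- screen_signals(rs, "drugx",
                       c("pneumonia", "sepsis", "influenza", "pneumonitis"))
  expect_true(all(sc$is_signal[sc$pt %in% c("pneumonia", "sepsis")]))
  sig <- sc[sc$is_signal, ]
  expect_true(all(diff(sig$ror) <= 0))  # signals lead, descending ROR
  for (i in seq_len(nrow(sc))) {
    single <- compute_ror(contingency_table(rs, "drugx", sc$pt[i]))
    expect_equal(sc$is_signal[i], single$is_signal, info = sc$pt[i])
  }
})

test_that("under independence few PTs are flagged across seeds", {
  cfg <- small_sim_config(n = 1200)
  flags <- 0L; total <- 0L
  for (seed in 1:25) {
    rs <- deduplicate(simulate_reports(cfg, seed = seed)$reports)
    sc <- screen_signals(rs, "drugx", cfg$pts$name)
    flags <- flags + sum(sc$is_signal)
    total <- total + nrow(sc)
  }
  expect_lte(flags / total, 0.05)
})
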