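# Disproportionality statistics: 2x2 contingency tables per (drug, PT)
# pair and the reporting odds ratio (ROR) with its Wald confidence
# interval on the log scale.

# Counts for all candidate PTs at once. Two counting conventions:
#  - "pairs": the universe is the set of distinct (case, PT) incidence
#    pairs; a case with k distinct PTs contributes k rows, so a+b is the
#    drug's total adverse-event count, as in OpenVigil-style extracts.
#  - "reports": the universe is the set of distinct cases; a+b is the
#    number of cases mentioning the drug.
count_cells <- function(reports, drug_synonyms, pts,
                        convention = c("pairs", "reports"), roles = NULL) {
  convention <- match.arg(convention)
  pts <- norm_term(pts)
  drug_cases <- matching_cases(reports, drug_synonyms, roles)
  pairs <- reports$reactions[c("case_id", "pt")]  # already unique, normalized

  if (convention == "pairs") {
    in_drug <- pairs$case_id %in% drug_cases
    n_total <- nrow(pairs)
    n_drug <- sum(in_drug)
    a <- vapply(pts, function(p) sum(in_drug & pairs$pt == p), integer(1))
    tot <- vapply(pts, function(p) sum(pairs$pt == p), integer(1))
  } else {
    ids <- case_ids(reports)
    n_total <- length(ids)
    n_drug <- length(drug_cases)
    a <- vapply(pts, function(p) {
      length(intersect(unique(pairs$case_id[pairs$pt == p]), drug_cases))
    }, integer(1))
    tot <- vapply(pts, function(p) length(unique(pairs$case_id[pairs$pt == p])),
                  integer(1))
  }
  data.frame(pt = pts, a = unname(a), b = n_drug - unname(a),
             c = unname(tot) - unname(a),
             d = n_total - n_drug - (unname(tot) - unname(a)),
             stringsAsFactors = FALSE)
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' Counts reports at the case level: a case contributes to cell *a* when
#' it matches the drug synonym list and lists the target preferred term at
#' least once (multiplicity within a case is ignored). The remaining cells
#' follow the chosen counting convention — see *Details*.
#'
#' @details The four cells are: `a` reports with the target drug and the
#'   target PT; `b` reports with the target drug and other PTs; `c`
#'   reports with the target PT under other drugs; `d` everything else.
#'   Under `convention = "pairs"` (default) the universe `a+b+c+d` is the
#'   set of distinct (report, PT) incidence pairs, so `a+b` is the drug's
#'   total adverse-event count; under `"reports"` the universe is the set
#'   of distinct cases.
#'
#' @param reports a deduplicated `report_set`.
#' @param drug_synonyms character vector of drug names (see
#'   [match_drug()]).
#' @param pt target preferred term.
#' @param convention `"pairs"` or `"reports"`.
#' @param roles optional role-code restriction for the drug match; the
#'   default `NULL` counts the drug under any role.
#' @return An object of class `contingency_table`: a list with elements
#'   `a`, `b`, `c`, `d`, `pt`, `convention`.
#' @export
contingency_table <- function(reports, drug_synonyms, pt,
                              convention = c("pairs", "reports"),
                              roles = NULL) {
  stopifnot(inherits(reports, "report_set"), length(pt) == 1)
  if (length(case_ids(reports)) == 0) {
    stop("cannot build a contingency table from an empty report set",
         call. = FALSE)
  }
  convention <- match.arg(convention)
  cells <- count_cells(reports, drug_synonyms, pt, convention, roles)
  structure(list(a = cells$a, b = cells$b, c = cells$c, d = cells$d,
                 pt = cells$pt, convention = convention),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> PT '%s' (%s counting)\n", x$pt,
              x$convention))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("target drug", "other drugs"),
                              c("target PT", "other PTs")))
  print(m)
  invisible(x)
}

#' Signal verdict for one drug-event pair
#'
#' The classical screening rule for spontaneous-report disproportionality:
#' a pair is a signal when it is supported by at least `min_a` reports and
#' the lower bound of the two-sided 95% confidence interval of its ROR
#' exceeds `ci_floor`. Both comparisons are strict at the boundary for the
#' CI (`ci_low > ci_floor`) and inclusive for the count (`a >= min_a`);
#' an undefined CI (`NA`, from a zero cell) never signals.
#'
#' @param a report count supporting the pair.
#' @param ci_low lower 95% confidence bound of the ROR (may be `NA`).
#' @param min_a minimum supporting report count (default 3).
#' @param ci_floor threshold the lower bound must exceed (default 1).
#' @return Logical vector.
#' @export
signal_verdict <- function(a, ci_low, min_a = 3, ci_floor = 1) {
  a >= min_a & !is.na(ci_low) & ci_low > ci_floor
}

#' Reporting odds ratio with confidence interval
#'
#' Computes `ROR = (a/c) / (b/d)` and its Wald confidence interval
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, plus the
#' screening verdict of [signal_verdict()]. When any cell is zero the CI
#' is undefined: the bounds are `NA`, `undefined_ci` is `TRUE` and the
#' pair never signals (no continuity correction is applied; the `a >=
#' min_a` gate already excludes the cases where one would matter).
#'
#' @param table a `contingency_table`, or anything coercible via `$a` ...
#'   `$d` (a plain `list(a=, b=, c=, d=)` works).
#' @param z normal quantile for the interval (default 1.96, a two-sided
#'   95% interval).
#' @param min_a,ci_floor screening thresholds, see [signal_verdict()].
#' @return An object of class `ror_signal`: list with `a`, `b`, `c`, `d`,
#'   `ror`, `ci_low`, `ci_high`, `undefined_ci`, `is_signal`, `pt`.
#' @examples
#' compute_ror(list(a = 20, b = 80, c = 30, d = 870))
#' @export
compute_ror <- function(table, z = 1.96, min_a = 3, ci_floor = 1) {
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  cc <- as.numeric(table$c); d <- as.numeric(table$d)
  if (any(c(a, b, cc, d) < 0)) stop("negative cell count", call. = FALSE)
  undefined <- a == 0 | b == 0 | cc == 0 | d == 0
  ror <- (a / cc) / (b / d)
  if (undefined) {
    ci_low <- ci_high <- NA_real_
  } else {
    se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    ci_low <- exp(log(ror) - z * se)
    ci_high <- exp(log(ror) + z * se)
  }
  structure(list(pt = table$pt %||% NA_character_,
                 a = a, b = b, c = cc, d = d,
                 ror = ror, ci_low = ci_low, ci_high = ci_high,
                 undefined_ci = undefined,
                 is_signal = signal_verdict(a, ci_low, min_a, ci_floor)),
            class = "ror_signal")
}

#' @export
print.ror_signal <- function(x, ...) {
  cat(sprintf("<ror_signal>%s a=%g b=%g c=%g d=%g\n",
              if (is.na(x$pt)) "" else paste0(" PT '", x$pt, "'"),
              x$a, x$b, x$c, x$d))
  if (x$undefined_ci) {
    cat(sprintf("  ROR = %.2f, 95%% CI undefined (zero cell); no signal\n",
                x$ror))
  } else {
    cat(sprintf("  ROR = %.2f (95%% CI %.2f-%.2f); %s\n", x$ror, x$ci_low,
                x$ci_high, if (x$is_signal) "SIGNAL" else "no signal"))
  }
  invisible(x)
}

#' Screen candidate preferred terms for disproportionality signals
#'
#' Builds the 2x2 table and ROR for every candidate PT against one drug
#' and applies the screening rule. This is the statistical core of the
#' package: the returned object is a classed data frame that prints,
#' summarises and plots (forest plot) like a fitted screen.
#'
#' @param reports a deduplicated `report_set`.
#' @param drug_synonyms character vector of names identifying the drug.
#' @param candidate_pts non-empty character vector of PTs to screen.
#' @param drug optional display label for the drug (defaults to the first
#'   synonym).
#' @inheritParams compute_ror
#' @inheritParams contingency_table
#' @return A data frame of class `signal_screen` with columns `drug`,
#'   `pt`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`, `is_signal`,
#'   ordered signals first (descending ROR, ties alphabetical by PT) then
#'   non-signals alphabetically.
#' @export
screen_signals <- function(reports, drug_synonyms, candidate_pts,
                           drug = drug_synonyms[1], z = 1.96, min_a = 3,
                           ci_floor = 1,
                           convention = c("pairs", "reports"),
                           roles = NULL) {
  stopifnot(inherits(reports, "report_set"))
  if (length(candidate_pts) == 0) {
    stop("candidate PT list is empty", call. = FALSE)
  }
  convention <- match.arg(convention)
  pts <- unique(norm_term(candidate_pts))
  cells <- count_cells(reports, drug_synonyms, pts, convention, roles)

  res <- lapply(seq_len(nrow(cells)), function(i) {
    compute_ror(as.list(cells[i, ]), z = z, min_a = min_a,
                ci_floor = ci_floor)
  })
  out <- data.frame(
    drug = norm_term(drug),
    pt = cells$pt,
    a = cells$a, b = cells$b, c = cells$c, d = cells$d,
    ror = vapply(res, `[[`, numeric(1), "ror"),
    ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(res, `[[`, numeric(1), "ci_high"),
    is_signal = vapply(res, `[[`, logical(1), "is_signal"),
    stringsAsFactors = FALSE)

  # signals first by descending ROR (alphabetical on ties), then the
  # non-signals alphabetically
  o <- c_order(!out$is_signal,
               ifelse(out$is_signal, -out$ror, 0), out$pt)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signal_screen", "data.frame"),
            convention = convention, min_a = min_a, ci_floor = ci_floor,
            z = z)
}

#' @export
print.signal_screen <- function(x, digits = 2, ...) {
  cat(sprintf("<signal_screen> drug '%s': %d candidate PT(s), %d signal(s) (a >= %g & CI low > %g)\n",
              x$drug[1], nrow(x), sum(x$is_signal), attr(x, "min_a"),
              attr(x, "ci_floor")))
  df <- as.data.frame(x)
  df$ror <- round(df$ror, digits)
  df$ci_low <- round(df$ci_low, digits)
  df$ci_high <- round(df$ci_high, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.signal_screen <- function(object, ...) {
  sig <- object[object$is_signal, , drop = FALSE]
  cat(sprintf("Signal screen for '%s' (%s counting)\n", object$drug[1],
              attr(object, "convention")))
  cat(sprintf("  %d candidate PT(s); %d flagged as signals\n",
              nrow(object), nrow(sig)))
  if (nrow(sig)) {
    cat("  signals (descending ROR):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %-30s a=%-4g ROR %.2f (%.2f-%.2f)\n", sig$pt[i],
                  sig$a[i], sig$ror[i], sig$ci_low[i], sig$ci_high[i]))
    }
  }
  invisible(object)
}

#' Forest plot of a signal screen
#'
#' Draws ROR point estimates with 95% CI whiskers on a log axis, one row
#' per PT with a defined interval; the `ci_floor` reference line is drawn
#' dashed and flagged signals are filled.
#'
#' @param x a `signal_screen`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.signal_screen <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[!is.na(df$ci_low), , drop = FALSE]
  if (nrow(df) == 0) {
    stop("no PT with a defined confidence interval to plot", call. = FALSE)
  }
  df <- df[order(df$ror), , drop = FALSE]
  n <- nrow(df)
  xlim <- range(c(df$ci_low, df$ci_high, 1))
  graphics::plot(df$ror, seq_len(n), log = "x", xlim = xlim,
                 yaxt = "n", ylab = "", xlab = "ROR (log scale)",
                 pch = ifelse(df$is_signal, 19, 1),
                 main = sprintf("Signal screen: %s", df$drug[1]), ...)
  graphics::segments(df$ci_low, seq_len(n), df$ci_high, seq_len(n))
  graphics::abline(v = attr(x, "ci_floor"), lty = 2)
  graphics::axis(2, at = seq_len(n), labels = df$pt, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write a signal table to TSV
#'
#' Columns `drug, pt, a, b, c, d, ror, ci_low, ci_high, is_signal`; the
#' estimate and bounds are printed to 2 decimals. The same file doubles as
#' forest-plot data for downstream plotting.
#'
#' @param x a `signal_screen`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_signal_table <- function(x, path) {
  stopifnot(inherits(x, "signal_screen"))
  df <- as.data.frame(x)
  df$ror <- fmt_num(df$ror, 2)
  df$ci_low <- fmt_num(df$ci_low, 2)
  df$ci_high <- fmt_num(df$ci_high, 2)
  write_tsv_file(df, path)
}
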