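# Shared internal helpers.

# Canonical form for drug names, preferred terms and SOC labels: trimmed,
# case-folded, inner whitespace collapsed. All joins and lookups go through
# this so "Pneumonia " and "pneumonia" are one term.
norm_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

QUARTER_RE <- "^[0-9]{4}Q[1-4]$"

check_quarter <- function(q, what = "quarter") {
  bad <- !grepl(QUARTER_RE, q)
  if (any(bad)) {
    stop(sprintf("invalid %s '%s': expected YYYYQn with n in 1-4",
                 what, q[bad][1]), call. = FALSE)
  }
  invisible(q)
}

quarter_year <- function(q) as.integer(substr(q, 1L, 4L))

# Quarter strings order correctly under plain C-locale collation
# ("2015Q1" < "2015Q4" < "2016Q1"); comparisons use them directly.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable C-locale ordering used everywhere ordering must be locale-proof.
c_order <- function(...) order(..., method = "radix")

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
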