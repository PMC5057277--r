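# internal helpers shared across modules

# Read a text table (optionally gzipped), dropping blank and '#' comment lines
# but keeping the original line number of every surviving line so that parse
# errors can name the exact file line.
read_table_lines <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], line_no = which(keep), path = path)
}

# Split tab-delimited lines into a character matrix with exactly `ncol`
# leading fields; lines with fewer fields raise an error naming the line.
split_fields <- function(tl, ncol, what) {
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < ncol)) {
    bad <- which(nf < ncol)[1]
    abort(sprintf(
      "malformed %s row in '%s' line %d: expected >= %d tab-separated fields, found %d",
      what, tl$path, tl$line_no[bad], ncol, nf[bad]
    ))
  }
  mat <- vapply(parts, function(p) p[seq_len(ncol)], character(ncol))
  if (ncol == 1L) matrix(mat, nrow = 1L) else mat
}

# Numeric conversion with a line-naming error on failure.
numeric_field <- function(x, tl, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    abort(sprintf(
      "unparseable numeric field '%s' (column %s) in '%s' line %d",
      x[bad[1]], column, tl$path, tl$line_no[bad[1]]
    ))
  }
  out
}

# Deterministic 32-bit seed derived from a base seed and a string label, so
# each simulated sample gets its own reproducible RNG stream.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 69069 + h) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s", name, format(min)))
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
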