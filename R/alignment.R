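#' Read protein-alignment hits in tabular (outfmt 6) format
#'
#' Parses the 12-column BLAST/DIAMOND/USEARCH tabular report
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`). `#` comment lines are ignored, extra trailing columns
#' are dropped, and gzipped files are read transparently. A line with fewer
#' than 12 fields or an unparseable numeric field raises an error naming the
#' line.
#'
#' @param path Path to a tabular alignment file (optionally gzipped).
#' @return Tibble of hits in file order with columns `read_id`, `protein_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_opens`,
#'   `q_start`, `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: '%s'", path))
  tl <- read_table_lines(path)
  parse_alignment_lines(tl)
}

parse_alignment_lines <- function(tl) {
  if (length(tl$lines) == 0L) {
    return(tibble(
      read_id = character(), protein_id = character(),
      percent_identity = double(), align_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(),
      evalue = double(), bitscore = double()
    ))
  }
  f <- split_fields(tl, 12L, "alignment")
  num <- function(i, col) numeric_field(f[i, ], tl, col)
  hits <- tibble(
    read_id = f[1, ],
    protein_id = f[2, ],
    percent_identity = num(3, "pident"),
    align_length = as.integer(num(4, "length")),
    mismatches = as.integer(num(5, "mismatch")),
    gap_opens = as.integer(num(6, "gapopen")),
    q_start = as.integer(num(7, "qstart")),
    q_end = as.integer(num(8, "qend")),
    s_start = as.integer(num(9, "sstart")),
    s_end = as.integer(num(10, "send")),
    evalue = num(11, "evalue"),
    bitscore = num(12, "bitscore")
  )
  bad <- which(hits$percent_identity < 0 | hits$percent_identity > 100)
  if (length(bad)) {
    abort(sprintf("percent identity out of [0,100] in '%s' line %d",
                  tl$path %||% "<text>", tl$line_no[bad[1]]))
  }
  bad <- which(hits$evalue < 0)
  if (length(bad)) {
    abort(sprintf("negative e-value in '%s' line %d",
                  tl$path %||% "<text>", tl$line_no[bad[1]]))
  }
  hits
}

#' Filter alignment hits on e-value and percent identity
#'
#' Retains hits with `evalue < evalue_max` and
#' `percent_identity > identity_min`. Both comparisons are strict, so hits
#' sitting exactly on a threshold are excluded. `filter_hits(x, Inf, -1)` is
#' the identity.
#'
#' @param hits Tibble of hits from [read_alignments()].
#' @param evalue_max Maximum e-value (exclusive). Default `1e-3`.
#' @param identity_min Minimum percent identity (exclusive). Default `80`.
#' @return The retained hits, original order preserved.
#' @export
filter_hits <- function(hits, evalue_max = 1e-3, identity_min = 80) {
  assert_columns(hits, c("evalue", "percent_identity"), "hits")
  if (!is.numeric(evalue_max) || length(evalue_max) != 1L || is.na(evalue_max)) {
    abort("`evalue_max` must be a single number")
  }
  if (!is.numeric(identity_min) || length(identity_min) != 1L || is.na(identity_min)) {
    abort("`identity_min` must be a single number")
  }
  filter(hits, .data$evalue < evalue_max, .data$percent_identity > identity_min)
}

#' Resolve each read to its best-hit KO
#'
#' For every read with at least one surviving hit whose subject protein is in
#' the reference, the best-hit tier is the set of hits tied on maximum
#' bitscore and then minimum e-value. The read's effective protein length
#' `PL(r)` is the minimum protein length within that tier; the reported KO
#' and winning protein are those of the minimum-length tier member (ties
#' broken by lexicographic protein id), so the assignment is independent of
#' input order. Hits to proteins absent from the reference are dropped with a
#' message and do not contribute to the mapped-read total.
#'
#' @param hits Threshold-filtered hits ([filter_hits()]).
#' @param db A [ref_db()].
#' @return Tibble with one row per assigned read: `read_id`, `ko_id`,
#'   `protein_id` (winning hit), `protein_length_aa` (`PL(r)`).
#' @export
assign_best_hits <- function(hits, db) {
  stopifnot(inherits(db, "ref_db"))
  assert_columns(hits, c("read_id", "protein_id", "evalue", "bitscore"), "hits")
  known <- inner_join(
    hits, select(db$proteins, "protein_id", "ko_id", "length_aa"),
    by = "protein_id", relationship = "many-to-many"
  )
  n_unknown <- n_distinct(hits$read_id) - n_distinct(known$read_id)
  if (n_unknown > 0L) {
    inform(sprintf(
      "%d read(s) aligned only to proteins absent from the reference (dropped)",
      n_unknown
    ))
  }
  if (nrow(known) == 0L) {
    return(tibble(read_id = character(), ko_id = character(),
                  protein_id = character(), protein_length_aa = integer()))
  }
  known |>
    group_by(.data$read_id) |>
    filter(.data$bitscore == max(.data$bitscore)) |>
    filter(.data$evalue == min(.data$evalue)) |>
    arrange(.data$length_aa, .data$protein_id, .by_group = TRUE) |>
    summarise(
      ko_id = first(.data$ko_id),
      protein_id = first(.data$protein_id),
      protein_length_aa = first(.data$length_aa),
      .groups = "drop"
    )
}

#' Write / read per-read KO assignments
#'
#' Assignment tables are TSVs with columns `read_id`, `ko_id`, `protein_id`,
#' `protein_length_aa`.
#'
#' @param assignments Tibble from [assign_best_hits()].
#' @param path Output/input path.
#' @return `write_assignments()` returns `path` invisibly;
#'   `read_assignments()` returns the assignment tibble.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(assignments, path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  read_tsv(path, col_types = readr::cols(
    read_id = "c", ko_id = "c", protein_id = "c", protein_length_aa = "i"
  ))
}
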