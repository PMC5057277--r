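#' Raw KO read counts
#'
#' Tallies assigned reads per KO. KOs with zero reads are absent; zero rows
#' are materialized only when samples are merged ([merge_samples()]).
#'
#' @param assignments Tibble from [assign_best_hits()].
#' @return Tibble with columns `ko_id`, `raw_count`, sorted by `ko_id`.
#' @export
count_raw <- function(assignments) {
  assert_columns(assignments, "ko_id", "assignments")
  assignments |>
    dplyr::count(.data$ko_id, name = "raw_count") |>
    arrange(.data$ko_id)
}

#' Protein-length RPKM per KO
#'
#' Computes, for each KO g,
#' \deqn{RPKM(g) = \sum_{r \in R(g)} \frac{1}{PL(r) \cdot 3} \cdot
#'   \frac{1}{T} \cdot 10^9}
#' where `R(g)` is the set of reads assigned to g, `PL(r)` the amino-acid
#' length of read r's best-hit protein (the minimum length over tied best
#' hits), and `T` the total number of mapped reads. The factor 3 converts
#' amino acids to nucleotides; no stop-codon correction is applied.
#'
#' @param assignments Tibble from [assign_best_hits()]; each row's own
#'   `protein_length_aa` is its `PL(r)`.
#' @param total_mapped_reads `T`; must equal `nrow(assignments)` (every
#'   assigned read is a mapped read).
#' @return Tibble with columns `ko_id`, `rpkm`, sorted by `ko_id`.
#' @export
compute_rpkm <- function(assignments, total_mapped_reads = nrow(assignments)) {
  assert_columns(assignments, c("ko_id", "protein_length_aa"), "assignments")
  n <- nrow(assignments)
  if (total_mapped_reads != n) {
    abort(sprintf(
      "total_mapped_reads (%d) must equal the number of assignments (%d)",
      total_mapped_reads, n
    ))
  }
  if (n == 0L) return(tibble(ko_id = character(), rpkm = double()))
  if (total_mapped_reads == 0L) {
    abort("total_mapped_reads is 0 but assignments are non-empty")
  }
  if (any(assignments$protein_length_aa < 1L)) {
    abort("protein_length_aa must be >= 1")
  }
  assignments |>
    group_by(.data$ko_id) |>
    summarise(rpkm = sum(1 / (.data$protein_length_aa * 3)) /
                total_mapped_reads * 1e9,
              .groups = "drop") |>
    arrange(.data$ko_id)
}

#' Per-sample KO abundance
#'
#' Combines [count_raw()] and [compute_rpkm()] into one per-sample table.
#'
#' @param assignments Tibble from [assign_best_hits()].
#' @param sample_id Sample label stored as an attribute.
#' @return A `sample_abundance` tibble with columns `ko_id`, `raw_count`,
#'   `rpkm`; attributes `total_mapped_reads` and `sample_id`.
#' @export
quantify_sample <- function(assignments, sample_id = "sample") {
  total <- nrow(assignments)
  out <- if (total == 0L) {
    tibble(ko_id = character(), raw_count = integer(), rpkm = double())
  } else {
    left_join(count_raw(assignments), compute_rpkm(assignments, total),
              by = "ko_id")
  }
  structure(out, total_mapped_reads = total, sample_id = sample_id,
            class = c("sample_abundance", class(out)))
}

#' Total mapped reads of a per-sample abundance
#' @param x A `sample_abundance`.
#' @return Integer `T`.
#' @export
total_mapped_reads <- function(x) attr(x, "total_mapped_reads")

#' Write / read a per-sample abundance TSV
#'
#' The file carries a `#total_mapped_reads=<T>` comment line followed by a
#' TSV with header `ko_id, raw_count, rpkm`. RPKM is rounded to `digits`
#' decimals on output; in-memory values keep full double precision.
#'
#' @param x A `sample_abundance` from [quantify_sample()].
#' @param path Output/input path.
#' @param digits Decimal places for RPKM in the file (default 3).
#' @return `write_sample_abundance()` returns `path` invisibly;
#'   `read_sample_abundance()` returns a `sample_abundance`.
#' @export
write_sample_abundance <- function(x, path, digits = 3) {
  stopifnot(inherits(x, "sample_abundance"))
  con <- file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("#sample_id=%s", attr(x, "sample_id")),
    sprintf("#total_mapped_reads=%d", total_mapped_reads(x)),
    "ko_id\traw_count\trpkm"
  ), con)
  if (nrow(x) > 0L) {
    writeLines(sprintf("%s\t%d\t%.*f", x$ko_id, x$raw_count, digits, x$rpkm), con)
  }
  invisible(path)
}

#' @rdname write_sample_abundance
#' @export
read_sample_abundance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  total <- as.integer(sub("^#total_mapped_reads=", "",
                          grep("^#total_mapped_reads=", meta, value = TRUE)))
  sid <- sub("^#sample_id=", "", grep("^#sample_id=", meta, value = TRUE))
  tab <- read_tsv(path, comment = "#", col_types = readr::cols(
    ko_id = "c", raw_count = "i", rpkm = "d"
  ))
  structure(tab,
            total_mapped_reads = total %||% sum(tab$raw_count),
            sample_id = if (length(sid)) sid else "sample",
            class = c("sample_abundance", class(tab)))
}

#' Merge per-sample abundances into a KO x sample table
#'
#' Takes the union of KOs across samples (missing entries 0). KO order is
#' lexicographic; sample order is as given.
#'
#' @param per_sample List of `sample_abundance` objects ([quantify_sample()]).
#' @return A `ko_abundance` object: list with wide tibbles `raw` and `rpkm`
#'   (first column `ko_id`, one column per sample), character vectors `kos`
#'   and `samples`, and named integer vector `totals` (per-sample `T`).
#' @export
merge_samples <- function(per_sample) {
  if (length(per_sample) == 0L) abort("no samples to merge")
  ids <- map_chr(per_sample, function(x) attr(x, "sample_id") %||% "sample")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  long <- map2(per_sample, ids, function(x, id) {
    mutate(as_tibble(x), sample_id = id)
  }) |>
    list_rbind()
  kos <- sort(unique(long$ko_id))
  widen <- function(col, fill) {
    w <- long |>
      select("ko_id", "sample_id", value = all_of(col)) |>
      pivot_wider(names_from = "sample_id", values_from = "value",
                  values_fill = fill)
    w <- w[match(kos, w$ko_id), c("ko_id", ids)]
    w
  }
  structure(
    list(
      raw = widen("raw_count", 0L),
      rpkm = widen("rpkm", 0),
      kos = kos,
      samples = ids,
      totals = setNames(map_int(per_sample, total_mapped_reads), ids)
    ),
    class = "ko_abundance"
  )
}

#' @export
print.ko_abundance <- function(x, ...) {
  cat(sprintf("<ko_abundance> %d KOs x %d samples (total mapped reads: %s)\n",
              length(x$kos), length(x$samples),
              paste(x$totals, collapse = ", ")))
  invisible(x)
}

#' Extract an abundance matrix
#'
#' @param x A `ko_abundance`.
#' @param metric `"rpkm"` or `"raw"`.
#' @return Numeric matrix, rows = KOs, columns = samples.
#' @export
abundance_matrix <- function(x, metric = c("rpkm", "raw")) {
  metric <- match.arg(metric)
  tab <- x[[metric]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$ko_id
  m
}

#' Write / read a merged abundance table
#'
#' One TSV per metric: first column `ko_id`, one column per sample, preceded
#' by `#total_mapped_reads <sample> <T>` comment lines.
#'
#' @param x A `ko_abundance`.
#' @param raw_path,rpkm_path Output/input paths (`NULL` to skip one metric on
#'   write).
#' @param digits Decimal places for RPKM values in the file.
#' @return `write_abundance_table()` returns the paths invisibly;
#'   `read_abundance_table()` returns a `ko_abundance` (raw counts all 0 when
#'   only `rpkm_path` is given).
#' @export
write_abundance_table <- function(x, raw_path = NULL, rpkm_path = NULL,
                                  digits = 3) {
  stopifnot(inherits(x, "ko_abundance"))
  header <- sprintf("#total_mapped_reads\t%s\t%d", names(x$totals), x$totals)
  if (!is.null(raw_path)) {
    con <- file(raw_path, "wt")
    writeLines(header, con)
    close(con)
    write_tsv(x$raw, raw_path, append = TRUE, col_names = TRUE)
  }
  if (!is.null(rpkm_path)) {
    con <- file(rpkm_path, "wt")
    writeLines(header, con)
    close(con)
    rounded <- mutate(x$rpkm, across(-"ko_id", ~ round(.x, digits)))
    write_tsv(rounded, rpkm_path, append = TRUE, col_names = TRUE)
  }
  invisible(c(raw = raw_path, rpkm = rpkm_path))
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(rpkm_path, raw_path = NULL) {
  read_one <- function(path) {
    read_tsv(path, comment = "#", col_types = readr::cols(ko_id = "c"))
  }
  read_totals <- function(path) {
    lines <- grep("^#total_mapped_reads\t", readLines(path, warn = FALSE),
                  value = TRUE)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    setNames(as.integer(map_chr(parts, 3)), map_chr(parts, 2))
  }
  rpkm <- read_one(rpkm_path)
  raw <- if (is.null(raw_path)) {
    mutate(rpkm, across(-"ko_id", ~ 0L))
  } else {
    read_one(raw_path)
  }
  samples <- setdiff(names(rpkm), "ko_id")
  totals <- read_totals(rpkm_path)
  if (length(totals) == 0L) totals <- setNames(rep(NA_integer_, length(samples)), samples)
  structure(
    list(raw = raw, rpkm = rpkm, kos = rpkm$ko_id, samples = samples,
         totals = totals[samples]),
    class = "ko_abundance"
  )
}
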