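#' Reference annotation database
#'
#' A `ref_db` bundles the three annotation tables the pipeline queries:
#' protein-to-KO assignments with protein lengths (amino acids), pathway
#' membership (KO sets), and operon membership (KO sets, ODB3-style
#' flattened pairs). All components are tibbles.
#'
#' @param proteins tibble with columns `protein_id`, `ko_id`, `length_aa`,
#'   `taxon_domain`.
#' @param pathways tibble with columns `pathway_id`, `pathway_name`, `ko_id`.
#' @param operons tibble with columns `operon_id`, `ko_id`, `label`.
#' @return A `ref_db` object: list with elements `proteins`, `pathways`,
#'   `operons` and `ko_universe` (character vector of all KO ids occurring in
#'   the protein table).
#' @export
ref_db <- function(proteins,
                   pathways = empty_pathways(),
                   operons = empty_operons()) {
  assert_columns(proteins, c("protein_id", "ko_id", "length_aa", "taxon_domain"),
                 "proteins")
  assert_columns(pathways, c("pathway_id", "pathway_name", "ko_id"), "pathways")
  assert_columns(operons, c("operon_id", "ko_id", "label"), "operons")
  if (nrow(proteins) == 0L) abort("empty reference: no annotated proteins")
  if (any(proteins$length_aa < 1L)) {
    abort("protein length_aa must be >= 1 amino acid")
  }
  universe <- sort(unique(proteins$ko_id))
  dangling <- setdiff(unique(c(pathways$ko_id, operons$ko_id)), universe)
  if (length(dangling)) {
    warn(sprintf(
      "%d KO id(s) in pathway/operon tables are absent from the protein table (kept): %s%s",
      length(dangling), paste(head(dangling, 5), collapse = ", "),
      if (length(dangling) > 5) ", ..." else ""
    ))
  }
  structure(
    list(
      proteins = select(as_tibble(proteins), "protein_id", "ko_id",
                        "length_aa", "taxon_domain"),
      pathways = distinct(as_tibble(pathways),
                          .data$pathway_id, .data$ko_id, .keep_all = TRUE) |>
        select("pathway_id", "pathway_name", "ko_id"),
      operons = distinct(as_tibble(operons),
                         .data$operon_id, .data$ko_id, .keep_all = TRUE) |>
        select("operon_id", "ko_id", "label"),
      ko_universe = universe
    ),
    class = "ref_db"
  )
}

empty_pathways <- function() {
  tibble(pathway_id = character(), pathway_name = character(),
         ko_id = character())
}

empty_operons <- function() {
  tibble(operon_id = character(), ko_id = character(), label = character())
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf(
    "<ref_db> %d proteins, %d KOs, %d pathways, %d operons\n",
    nrow(x$proteins), length(x$ko_universe),
    n_distinct(x$pathways$pathway_id), n_distinct(x$operons$operon_id)
  ))
  invisible(x)
}

parse_protein_table <- function(path) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) abort(sprintf("empty protein table: '%s'", path))
  header <- strsplit(tl$lines[1], "\t", fixed = TRUE)[[1]]
  expected <- c("protein_id", "ko_id", "length_aa", "taxon_domain")
  if (!identical(header[seq_along(expected)], expected)) {
    abort(sprintf(
      "protein table '%s' must start with header: %s",
      path, paste(expected, collapse = ", ")
    ))
  }
  tl$lines <- tl$lines[-1]
  tl$line_no <- tl$line_no[-1]
  if (length(tl$lines) == 0L) {
    abort(sprintf("empty protein table (header only): '%s'", path))
  }
  f <- split_fields(tl, 4L, "protein table")
  len <- numeric_field(f[3, ], tl, "length_aa")
  bad <- which(len < 1 | len != floor(len))
  if (length(bad)) {
    abort(sprintf(
      "invalid length_aa '%s' in '%s' line %d: must be a positive integer",
      f[3, bad[1]], path, tl$line_no[bad[1]]
    ))
  }
  tibble(
    protein_id = f[1, ],
    ko_id = str_trim(f[2, ]),
    length_aa = as.integer(len),
    taxon_domain = f[4, ]
  )
}

parse_pair_table <- function(path, id_col, what, label_col) {
  tl <- read_table_lines(path)
  if (length(tl$lines) == 0L) {
    return(tibble(!!id_col := character(), !!label_col := character(),
                  ko_id = character()))
  }
  header <- strsplit(tl$lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- identical(header[1], id_col)
  if (has_header) {
    tl$lines <- tl$lines[-1]
    tl$line_no <- tl$line_no[-1]
  }
  if (length(tl$lines) == 0L) {
    return(tibble(!!id_col := character(), !!label_col := character(),
                  ko_id = character()))
  }
  parts <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1]
    abort(sprintf("malformed %s row in '%s' line %d: expected >= 2 fields",
                  what, path, tl$line_no[bad]))
  }
  # layout follows the declared header when present, else positional:
  # pathway tables are (id, name, ko), operon tables are (id, ko, label)
  if (has_header) {
    ko_pos <- match("ko_id", header)
    lab_pos <- match(label_col, header)
    if (is.na(ko_pos)) abort(sprintf("%s table '%s' header lacks ko_id", what, path))
  } else if (id_col == "pathway_id") {
    ko_pos <- 3L; lab_pos <- 2L
  } else {
    ko_pos <- 2L; lab_pos <- 3L
  }
  get_field <- function(pos) {
    if (is.na(pos)) return(rep("", length(parts)))
    vapply(parts, function(p) if (length(p) >= pos) p[pos] else "", character(1))
  }
  tibble(
    !!id_col := get_field(1L),
    !!label_col := get_field(lab_pos),
    ko_id = str_trim(get_field(ko_pos))
  ) |>
    filter(.data$ko_id != "")
}

# Expand comma-separated multi-KO annotations into one row per KO.
expand_multi_ko <- function(proteins) {
  multi <- str_detect(proteins$ko_id, ",")
  if (!any(multi)) return(proteins)
  inform(sprintf("expanded %d protein row(s) carrying multiple comma-separated KOs",
                 sum(multi)))
  proteins |>
    mutate(ko_id = str_split(.data$ko_id, ",")) |>
    tidyr::unnest("ko_id") |>
    mutate(ko_id = str_trim(.data$ko_id)) |>
    filter(.data$ko_id != "")
}

#' Load a reference database from TSV tables
#'
#' Reads the three tab-delimited annotation tables (`#` comment lines are
#' ignored). The protein table must carry the header
#' `protein_id, ko_id, length_aa, taxon_domain`; pathway tables are
#' `pathway_id, pathway_name, ko_id` and operon tables
#' `operon_id, ko_id, label` (header optional for the latter two). Protein
#' rows with an empty `ko_id` are dropped with a message; rows listing
#' several comma-separated KOs are expanded one-per-KO. KOs referenced by
#' pathways or operons but absent from the protein table are kept with a
#' warning, so enrichment universes remain configurable downstream.
#'
#' @param protein_path,pathway_path,operon_path Paths to the three TSV files;
#'   `pathway_path`/`operon_path` may be `NULL`.
#' @return A [ref_db()] object.
#' @export
read_reference <- function(protein_path, pathway_path = NULL,
                           operon_path = NULL) {
  for (p in c(protein_path, pathway_path, operon_path)) {
    if (!file.exists(p)) abort(sprintf("reference table not found: '%s'", p))
  }
  proteins <- parse_protein_table(protein_path)
  n0 <- nrow(proteins)
  proteins <- filter(proteins, .data$ko_id != "")
  if (n0 > nrow(proteins)) {
    inform(sprintf("dropped %d protein row(s) with missing KO id", n0 - nrow(proteins)))
  }
  if (nrow(proteins) == 0L) {
    abort(sprintf("empty reference: no protein in '%s' carries a KO id", protein_path))
  }
  proteins <- expand_multi_ko(proteins)
  pathways <- if (is.null(pathway_path)) empty_pathways() else
    parse_pair_table(pathway_path, "pathway_id", "pathway", "pathway_name")
  operons <- if (is.null(operon_path)) empty_operons() else
    parse_pair_table(operon_path, "operon_id", "operon", "label")
  ref_db(proteins, pathways, operons)
}

#' Build a reference database from raw annotations
#'
#' Applies the reference-construction filter: keep only proteins that carry a
#' KO annotation and whose taxonomic domain is in `allowed_domains`
#' (default bacteria, archaea and fungi). Taxonomy is taken from the
#' pre-computed `taxon_domain` column; taxonomy resolution itself is out of
#' scope.
#'
#' @param raw_annotations data frame with columns `protein_id`, `ko_id`
#'   (may be empty/NA), `length_aa`, `taxon_domain`.
#' @param allowed_domains character vector of retained domain labels.
#' @param pathways,operons optional annotation tibbles passed through to
#'   [ref_db()].
#' @return A [ref_db()] object containing only the retained proteins.
#' @export
build_reference <- function(raw_annotations,
                            allowed_domains = c("bacteria", "archaea", "fungi"),
                            pathways = empty_pathways(),
                            operons = empty_operons()) {
  assert_columns(raw_annotations,
                 c("protein_id", "ko_id", "length_aa", "taxon_domain"),
                 "raw_annotations")
  if (length(allowed_domains) == 0L) abort("`allowed_domains` must be non-empty")
  kept <- as_tibble(raw_annotations) |>
    mutate(ko_id = str_trim(tidyr::replace_na(as.character(.data$ko_id), ""))) |>
    filter(.data$ko_id != "", .data$taxon_domain %in% allowed_domains) |>
    arrange(.data$protein_id, .data$ko_id)
  if (nrow(kept) == 0L) abort("empty reference: no rows pass the domain/KO filter")
  kept <- expand_multi_ko(kept)
  ref_db(kept, pathways, operons)
}

#' Number of unique KO members of a pathway
#'
#' @param db A [ref_db()].
#' @param pathway_id Pathway identifier.
#' @return Integer count of distinct member KOs.
#' @export
pathway_size <- function(db, pathway_id) {
  stopifnot(inherits(db, "ref_db"))
  members <- db$pathways$ko_id[db$pathways$pathway_id == pathway_id]
  if (length(members) == 0L) abort(sprintf("unknown pathway id: '%s'", pathway_id))
  length(unique(members))
}

#' Write a reference database to TSV tables
#'
#' Inverse of [read_reference()]: files written here load back to an equal
#' database (up to row order).
#'
#' @param db A [ref_db()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, named paths of the three files.
#' @export
write_reference <- function(db, dir) {
  stopifnot(inherits(db, "ref_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    protein = file.path(dir, "proteins.tsv"),
    pathway = file.path(dir, "pathways.tsv"),
    operon = file.path(dir, "operons.tsv")
  )
  write_tsv(db$proteins, paths[["protein"]])
  write_tsv(select(db$pathways, "pathway_id", "pathway_name", "ko_id"),
            paths[["pathway"]])
  write_tsv(select(db$operons, "operon_id", "ko_id", "label"),
            paths[["operon"]])
  invisible(paths)
}

# member KO sets keyed by feature id
feature_members <- function(db, kind) {
  tab <- if (kind == "pathway") db$pathways else db$operons
  id <- if (kind == "pathway") "pathway_id" else "operon_id"
  split(tab$ko_id, tab[[id]])
}
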