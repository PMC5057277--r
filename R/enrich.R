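#' Operons whose members are all differentially abundant
#'
#' Implements the all-members rule: an operon is a DA candidate exactly when
#' its full (deduplicated) member KO set is contained in the DA set. The rule
#' is monotone — enlarging the DA set never removes an operon.
#'
#' @param da set of DA KO ids (character vector).
#' @param db A [ref_db()].
#' @return Tibble with one row per qualifying operon: `operon_id`, `label`,
#'   `size` (unique members) and list-column `members`.
#' @export
da_operons <- function(da, db) {
  stopifnot(inherits(db, "ref_db"))
  ops <- db$operons
  if (nrow(ops) == 0L || length(da) == 0L) {
    return(tibble(operon_id = character(), label = character(),
                  size = integer(), members = list()))
  }
  ops |>
    group_by(.data$operon_id) |>
    summarise(
      label = first(.data$label),
      members = list(unique(.data$ko_id)),
      size = length(unique(.data$ko_id)),
      .groups = "drop"
    ) |>
    filter(map_lgl(.data$members, ~ length(.x) >= 1L && all(.x %in% da)))
}

#' Fisher's exact enrichment of DA KOs in a feature
#'
#' Both the feature KO set and the DA set are first intersected with the
#' universe. The 2x2 table crosses feature membership with DA status over the
#' universe; the two-sided p-value sums the probabilities of all
#' fixed-margin tables whose point probability does not exceed the observed
#' one (to relative tolerance 1e-7, the [stats::fisher.test()] convention).
#'
#' @param da DA KO ids.
#' @param feature Feature (operon or pathway) member KO ids.
#' @param universe Background KO set.
#' @param sided `"two.sided"` (default), `"greater"` (over-representation) or
#'   `"less"`.
#' @return List with `p_value`, `ko_count` (DA KOs in the feature),
#'   `feature_size` (feature KOs within the universe) and
#'   `coverage = ko_count / feature_size`.
#' @export
fisher_enrichment <- function(da, feature, universe,
                              sided = c("two.sided", "greater", "less")) {
  sided <- match.arg(sided)
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe")
  feature <- intersect(unique(feature), universe)
  if (length(feature) == 0L) abort("feature has no KO within the universe")
  da <- intersect(unique(da), universe)
  a <- length(intersect(feature, da))
  b <- length(feature) - a
  c_ <- length(da) - a
  d <- length(universe) - a - b - c_
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                   alternative = sided)$p.value
  list(p_value = min(p, 1), ko_count = a, feature_size = length(feature),
       coverage = a / length(feature))
}

#' Operon- and pathway-level enrichment of the DA KO set
#'
#' For pathways, every pathway containing at least one DA KO (within the
#' universe) is tested. For operons, candidates must first pass the
#' all-members rule ([da_operons()]); each candidate is then annotated with
#' its Fisher p-value against the same universe. `avg_log2_fc` averages the
#' per-KO log2 fold changes over the feature's DA members. Results are
#' sorted by p-value and BH-adjusted within the tested set of the requested
#' kind. Single-member features are reported but flagged (`single_member`),
#' since enrichment evidence from one gene is weak.
#'
#' @param comparison A `ko_comparison` ([run_comparison()]).
#' @param db A [ref_db()].
#' @param kind `"pathway"` or `"operon"`.
#' @param universe_mode `"reference"` (all KOs in the reference, default) or
#'   `"detected"` (KOs with nonzero abundance in at least one design sample,
#'   i.e. the tested KOs).
#' @param sided Passed to [fisher_enrichment()].
#' @return A `ko_enrichment` tibble: `feature_id`, `kind`, `name`,
#'   `ko_count`, `feature_size`, `coverage`, `avg_log2_fc`, `p_value`,
#'   `q_value`, `da_ko_list` (comma-joined), `single_member`.
#' @export
enrich_features <- function(comparison, db,
                            kind = c("pathway", "operon"),
                            universe_mode = c("reference", "detected"),
                            sided = "two.sided") {
  kind <- match.arg(kind)
  universe_mode <- match.arg(universe_mode)
  stopifnot(inherits(db, "ref_db"))
  assert_columns(comparison, c("ko_id", "log2_fc", "is_da"), "comparison")

  universe <- switch(universe_mode,
    reference = db$ko_universe,
    detected = unique(comparison$ko_id)
  )
  if (length(universe) == 0L) abort("empty enrichment universe")
  da <- intersect(da_kos(comparison), universe)
  lfc <- setNames(comparison$log2_fc, comparison$ko_id)

  empty <- tibble(
    feature_id = character(), kind = character(), name = character(),
    ko_count = integer(), feature_size = integer(), coverage = double(),
    avg_log2_fc = double(), p_value = double(), q_value = double(),
    da_ko_list = character(), single_member = logical()
  )

  if (kind == "pathway") {
    feats <- db$pathways |>
      group_by(.data$pathway_id) |>
      summarise(name = first(.data$pathway_name),
                members = list(unique(.data$ko_id)), .groups = "drop") |>
      rename(feature_id = "pathway_id")
  } else {
    cand <- da_operons(da, db)
    feats <- tibble(feature_id = cand$operon_id, name = cand$label,
                    members = cand$members)
  }
  if (nrow(feats) == 0L) {
    out <- empty
  } else {
    rows <- pmap(feats, function(feature_id, name, members) {
      members_u <- intersect(members, universe)
      if (length(members_u) == 0L) return(NULL)
      hit <- intersect(members_u, da)
      if (length(hit) == 0L) return(NULL)
      fe <- fisher_enrichment(da, members_u, universe, sided = sided)
      tibble(
        feature_id = feature_id, kind = kind,
        name = name %||% "",
        ko_count = fe$ko_count, feature_size = fe$feature_size,
        coverage = fe$coverage,
        avg_log2_fc = mean(lfc[hit]),
        p_value = fe$p_value,
        da_ko_list = paste(sort(hit), collapse = ","),
        single_member = fe$feature_size == 1L
      )
    })
    rows <- rows[!map_lgl(rows, is.null)]
    out <- if (length(rows) == 0L) empty else {
      bind_rows(rows) |>
        mutate(q_value = bh_fdr(.data$p_value)) |>
        arrange(.data$p_value, .data$feature_id) |>
        relocate("q_value", .after = "p_value")
    }
  }
  structure(out, universe_mode = universe_mode, universe_size = length(universe),
            n_da = length(da), sided = sided,
            class = c("ko_enrichment", class(out)))
}

#' Write an enrichment table
#'
#' @param enrichment A `ko_enrichment` ([enrich_features()]).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  write_tsv(as_tibble(enrichment), path)
  invisible(path)
}
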