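#' KEGG pathway-map color column
#'
#' One line per DA KO, `red` for over-abundant (log2FC > 0) and `blue` for
#' under-abundant (log2FC < 0); KOs with exactly zero fold change are
#' omitted. The two-column output pastes directly into the KEGG
#' map_pathway2 web form.
#'
#' @param comparison A `ko_comparison` ([run_comparison()]).
#' @param restrict_to Optional KO set (e.g. one pathway's members) to
#'   intersect with.
#' @param hex If `TRUE`, emit hex colors (`#FF0000` / `#0000FF`) for the
#'   form's bgcolor syntax instead of the color names.
#' @return Tibble with columns `ko_id`, `color`, sorted by `ko_id`.
#' @export
kegg_colors <- function(comparison, restrict_to = NULL, hex = FALSE) {
  assert_columns(comparison, c("ko_id", "log2_fc", "is_da"), "comparison")
  out <- as_tibble(comparison) |>
    filter(.data$is_da, .data$log2_fc != 0) |>
    mutate(color = if_else(.data$log2_fc > 0, "red", "blue")) |>
    select("ko_id", "color") |>
    arrange(.data$ko_id)
  if (!is.null(restrict_to)) out <- filter(out, .data$ko_id %in% restrict_to)
  if (hex) {
    out$color <- unname(c(red = "#FF0000", blue = "#0000FF")[out$color])
  }
  out
}

#' @rdname kegg_colors
#' @param colors Tibble from [kegg_colors()].
#' @param path Output path (two-column TSV, no header).
#' @export
write_kegg_colors <- function(colors, path) {
  write_tsv(colors, path, col_names = FALSE)
  invisible(path)
}

#' Heatmap-ready RPKM matrix
#'
#' Restricts the RPKM table to the requested KOs and applies an optional
#' transform: `log10p1` is `log10(x + 1)`; `zscore_rows` centers and scales
#' each row by its population standard deviation (rows with zero variance
#' become all zeros).
#'
#' @param abundance A `ko_abundance` ([merge_samples()]).
#' @param kos `"all"` or a character vector of KO ids (must be present).
#' @param transform `"none"`, `"log10p1"` or `"zscore_rows"`.
#' @return Tibble: first column `ko_id`, one column per sample.
#' @export
heatmap_matrix <- function(abundance, kos = "all",
                           transform = c("none", "log10p1", "zscore_rows")) {
  transform <- match.arg(transform)
  stopifnot(inherits(abundance, "ko_abundance"))
  m <- abundance_matrix(abundance, "rpkm")
  if (!identical(kos, "all")) {
    missing <- setdiff(kos, rownames(m))
    if (length(missing)) {
      abort(sprintf("KO(s) not in the table: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[kos, , drop = FALSE]
  }
  dn <- dimnames(m)
  m <- switch(transform,
    none = m,
    log10p1 = log10(m + 1),
    zscore_rows = t(apply(m, 1, function(row) {
      s <- sqrt(mean((row - mean(row))^2))
      if (s == 0) rep(0, length(row)) else (row - mean(row)) / s
    }))
  )
  if (nrow(m) == 1L) dim(m) <- c(1L, length(dn[[2]]))
  dimnames(m) <- dn
  bind_cols(tibble(ko_id = rownames(m)), as_tibble(m))
}

#' @rdname heatmap_matrix
#' @param matrix_tbl Tibble from [heatmap_matrix()].
#' @param path Output path (TSV, header = sample ids).
#' @export
write_heatmap_matrix <- function(matrix_tbl, path) {
  write_tsv(matrix_tbl, path)
  invisible(path)
}

#' Volcano plot of a KO comparison
#'
#' @param object A `ko_comparison`.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 p, DA KOs colored by
#'   direction.
#' @method autoplot ko_comparison
#' @export
autoplot.ko_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  lfc_min <- attr(object, "min_abs_log2fc") %||% 1
  df <- as_tibble(object) |>
    mutate(status = dplyr::case_when(
      .data$is_da & .data$log2_fc > 0 ~ "over-abundant",
      .data$is_da & .data$log2_fc < 0 ~ "under-abundant",
      TRUE ~ "not DA"
    ))
  ggplot(df, aes(x = .data$log2_fc, y = -log10(.data$p_value),
                 colour = .data$status)) +
    geom_point(alpha = 0.7, size = 1.2) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed") +
    scale_colour_manual(values = c(`over-abundant` = "red",
                                   `under-abundant` = "blue",
                                   `not DA` = "grey60")) +
    labs(x = "log2 fold change (case vs reference)",
         y = expression(-log[10]~italic(p)), colour = NULL) +
    theme_minimal()
}

#' Dot plot of an enrichment result
#'
#' @param object A `ko_enrichment`.
#' @param top Show at most this many features (by p-value).
#' @param ... Unused.
#' @return A ggplot object: features vs -log10 p, point size = DA KO count,
#'   color = average log2 fold change.
#' @method autoplot ko_enrichment
#' @export
autoplot.ko_enrichment <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$label <- ifelse(df$name == "" | is.na(df$name), df$feature_id, df$name)
  ggplot(df, aes(x = -log10(.data$p_value),
                 y = stats::reorder(.data$label, -.data$p_value),
                 size = .data$ko_count, colour = .data$avg_log2_fc)) +
    geom_point() +
    scale_colour_gradient2(low = "blue", mid = "grey80", high = "red",
                           midpoint = 0) +
    labs(x = expression(-log[10]~italic(p)), y = NULL,
         size = "DA KOs", colour = "avg log2 FC") +
    theme_minimal()
}

#' Abundance heatmap
#'
#' @param abundance A `ko_abundance`.
#' @param kos,transform Passed to [heatmap_matrix()].
#' @return A ggplot tile heatmap of the (transformed) RPKM matrix.
#' @export
plot_abundance_heatmap <- function(abundance, kos = "all",
                                   transform = "zscore_rows") {
  hm <- heatmap_matrix(abundance, kos = kos, transform = transform)
  long <- pivot_longer(hm, -"ko_id", names_to = "sample_id",
                       values_to = "value")
  ggplot(long, aes(x = .data$sample_id, y = .data$ko_id,
                   fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = transform) +
    theme_minimal()
}
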