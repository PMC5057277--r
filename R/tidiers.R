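#' Tidy a merged abundance table
#'
#' @param x A `ko_abundance`.
#' @param ... Unused.
#' @return Long tibble with columns `ko_id`, `sample_id`, `raw_count`,
#'   `rpkm`.
#' @method tidy ko_abundance
#' @export
tidy.ko_abundance <- function(x, ...) {
  raw_long <- pivot_longer(x$raw, -"ko_id", names_to = "sample_id",
                           values_to = "raw_count")
  rpkm_long <- pivot_longer(x$rpkm, -"ko_id", names_to = "sample_id",
                            values_to = "rpkm")
  left_join(raw_long, rpkm_long, by = c("ko_id", "sample_id"))
}

#' @rdname tidy.ko_abundance
#' @method glance ko_abundance
#' @export
glance.ko_abundance <- function(x, ...) {
  tibble(n_kos = length(x$kos), n_samples = length(x$samples),
         total_mapped_reads = sum(x$totals))
}

#' Tidy a KO comparison
#'
#' @param x A `ko_comparison`.
#' @param ... Unused.
#' @return The comparison as a plain tibble.
#' @method tidy ko_comparison
#' @export
tidy.ko_comparison <- function(x, ...) as_tibble(x)

#' @rdname tidy.ko_comparison
#' @method glance ko_comparison
#' @export
glance.ko_comparison <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_da = sum(x$is_da),
    method = attr(x, "method") %||% NA_character_,
    filter_on = attr(x, "filter_on") %||% NA_character_,
    alpha = attr(x, "alpha") %||% NA_real_,
    min_abs_log2fc = attr(x, "min_abs_log2fc") %||% NA_real_,
    reference_group = attr(x, "reference_group") %||% NA_character_
  )
}

#' Tidy an enrichment result
#'
#' @param x A `ko_enrichment`.
#' @param ... Unused.
#' @return The enrichment table as a plain tibble.
#' @method tidy ko_enrichment
#' @export
tidy.ko_enrichment <- function(x, ...) as_tibble(x)

#' @rdname tidy.ko_enrichment
#' @method glance ko_enrichment
#' @export
glance.ko_enrichment <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$q_value < 0.05),
    universe_mode = attr(x, "universe_mode") %||% NA_character_,
    universe_size = attr(x, "universe_size") %||% NA_integer_,
    n_da = attr(x, "n_da") %||% NA_integer_
  )
}
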