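#' Pipeline configuration
#'
#' Collects all paths and thresholds for a full run: reference tables,
#' per-sample alignment files, design table, filtering and testing
#' parameters, and the output directory.
#'
#' @param protein_table,pathway_table,operon_table Reference TSV paths
#'   ([read_reference()]); the last two may be `NULL`.
#' @param alignments Named character vector: `sample_id = path` to each
#'   sample's outfmt-6 alignment file.
#' @param design Path to the design TSV (`sample_id`, `group`).
#' @param out_dir Output directory.
#' @param evalue_max,identity_min Hit filter thresholds ([filter_hits()]).
#' @param method,filter_on,alpha,min_abs_log2fc,pseudocount,reference_group
#'   Differential-abundance settings ([run_comparison()]).
#' @param universe_mode Enrichment universe ([enrich_features()]).
#' @param heatmap_transform Transform for the exported heatmap matrix.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(protein_table, pathway_table = NULL,
                            operon_table = NULL, alignments, design, out_dir,
                            evalue_max = 1e-3, identity_min = 80,
                            method = "kruskal", filter_on = "raw",
                            alpha = 0.05, min_abs_log2fc = 1,
                            pseudocount = 1e-3, reference_group = NULL,
                            universe_mode = "reference",
                            heatmap_transform = "zscore_rows") {
  cfg <- structure(
    list(protein_table = protein_table, pathway_table = pathway_table,
         operon_table = operon_table, alignments = alignments,
         design = design, out_dir = out_dir, evalue_max = evalue_max,
         identity_min = identity_min, method = method, filter_on = filter_on,
         alpha = alpha, min_abs_log2fc = min_abs_log2fc,
         pseudocount = pseudocount, reference_group = reference_group,
         universe_mode = universe_mode,
         heatmap_transform = heatmap_transform),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  fail <- function(msg) abort(msg, class = "koprofiler_validation_error")
  for (p in c(cfg$protein_table, cfg$pathway_table, cfg$operon_table,
              cfg$design, unname(cfg$alignments))) {
    if (!file.exists(p)) fail(sprintf("input file not found: '%s'", p))
  }
  if (length(cfg$alignments) == 0L) fail("no alignment files given")
  if (is.null(names(cfg$alignments)) || any(names(cfg$alignments) == "")) {
    fail("`alignments` must be named by sample id")
  }
  if (!is.numeric(cfg$evalue_max) || !is.numeric(cfg$identity_min)) {
    fail("thresholds must be numeric")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) fail("`alpha` must be in (0, 1]")
  if (cfg$min_abs_log2fc < 0) fail("`min_abs_log2fc` must be >= 0")
  if (!cfg$method %in% c("kruskal", "quasipoisson", "metagenomeseq")) {
    fail(sprintf("unknown method '%s'", cfg$method))
  }
  if (!cfg$filter_on %in% c("raw", "fdr")) fail("`filter_on` must be raw|fdr")
  if (!cfg$universe_mode %in% c("reference", "detected")) {
    fail("`universe_mode` must be reference|detected")
  }
  invisible(cfg)
}

run_stage <- function(out_dir, stage, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("failed at stage: %s", stage),
               file.path(out_dir, ".partial"))
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "koprofiler_stage_error", parent = e)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: reference loading; per-sample hit filtering and
#' best-hit KO assignment; per-sample quantification (raw count and RPKM);
#' sample merging; differential-abundance testing; operon and pathway
#' enrichment; KEGG color export; heatmap-matrix export. Writes one artifact
#' per stage under `out_dir` plus a `manifest.yaml` recording thresholds,
#' package version and per-stage row counts. Any stage failure leaves a
#' `.partial` marker next to the outputs produced so far and raises a
#' stage-named error. Outputs are pure functions of inputs and
#' configuration: a rerun on identical inputs is byte-identical apart from
#' the manifest timestamp.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the main result objects
#'   (`db`, `abundance`, `comparison`, `operons`, `pathways`) and `paths` to
#'   every written artifact.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, ".partial"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  counts <- list()

  db <- run_stage(out, "reference",
                  read_reference(cfg$protein_table, cfg$pathway_table,
                                 cfg$operon_table))
  counts$reference <- list(proteins = nrow(db$proteins),
                           kos = length(db$ko_universe),
                           pathways = n_distinct(db$pathways$pathway_id),
                           operons = n_distinct(db$operons$operon_id))
  say("reference: %d proteins, %d KOs", nrow(db$proteins),
      length(db$ko_universe))

  design <- run_stage(out, "design", read_design(cfg$design))

  assign_dir <- file.path(out, "assignments")
  abund_dir <- file.path(out, "abundance")
  dir.create(assign_dir, showWarnings = FALSE)
  dir.create(abund_dir, showWarnings = FALSE)
  per_sample <- list()
  sample_counts <- list()
  for (sid in names(cfg$alignments)) {
    run_stage(out, paste0("sample:", sid), {
      hits <- read_alignments(cfg$alignments[[sid]])
      passing <- filter_hits(hits, cfg$evalue_max, cfg$identity_min)
      assignments <- suppressMessages(assign_best_hits(passing, db))
      write_assignments(assignments,
                        file.path(assign_dir, paste0(sid, ".assign.tsv")))
      ab <- quantify_sample(assignments, sample_id = sid)
      write_sample_abundance(ab, file.path(abund_dir, paste0(sid, ".abund.tsv")))
      per_sample[[sid]] <- ab
      sample_counts[[sid]] <- list(
        hits_parsed = nrow(hits), hits_passing = nrow(passing),
        reads_assigned = nrow(assignments), kos = nrow(ab)
      )
    })
  }
  say("assigned %s reads across %d samples",
      format(sum(map_int(sample_counts, "reads_assigned"))),
      length(per_sample))

  abundance <- run_stage(out, "merge", merge_samples(per_sample))
  table_paths <- run_stage(out, "merge", write_abundance_table(
    abundance, file.path(out, "table.raw.tsv"), file.path(out, "table.rpkm.tsv")
  ))
  counts$kos_quantified <- length(abundance$kos)

  comparison <- run_stage(out, "compare", suppressMessages(run_comparison(
    abundance, design, method = cfg$method, filter_on = cfg$filter_on,
    alpha = cfg$alpha, min_abs_log2fc = cfg$min_abs_log2fc,
    pseudocount = cfg$pseudocount, reference_group = cfg$reference_group
  )))
  write_comparison(comparison, file.path(out, "comparison.tsv"))
  counts$kos_tested <- nrow(comparison)
  counts$da_kos <- sum(comparison$is_da)
  say("tested %d KOs, %d differentially abundant", nrow(comparison),
      sum(comparison$is_da))

  operons <- run_stage(out, "operon", enrich_features(
    comparison, db, kind = "operon", universe_mode = cfg$universe_mode))
  write_enrichment(operons, file.path(out, "operons.tsv"))
  counts$da_operons <- nrow(operons)

  pathways <- run_stage(out, "pathway", enrich_features(
    comparison, db, kind = "pathway", universe_mode = cfg$universe_mode))
  write_enrichment(pathways, file.path(out, "pathways.tsv"))
  counts$pathways_tested <- nrow(pathways)

  colors <- run_stage(out, "export-kegg", kegg_colors(comparison))
  write_kegg_colors(colors, file.path(out, "kegg_colors.tsv"))

  hm_kos <- if (any(comparison$is_da)) da_kos(comparison) else "all"
  hm <- run_stage(out, "export-heatmap",
                  heatmap_matrix(abundance, kos = hm_kos,
                                 transform = cfg$heatmap_transform))
  write_heatmap_matrix(hm, file.path(out, "heatmap.tsv"))

  manifest <- list(
    package = "koprofiler",
    version = as.character(packageVersion("koprofiler")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = list(
      evalue_max = cfg$evalue_max, identity_min = cfg$identity_min,
      method = cfg$method, filter_on = cfg$filter_on, alpha = cfg$alpha,
      min_abs_log2fc = cfg$min_abs_log2fc, pseudocount = cfg$pseudocount,
      universe_mode = cfg$universe_mode
    ),
    counts = counts,
    samples = sample_counts
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  paths <- list(
    assignments = file.path(assign_dir,
                            paste0(names(cfg$alignments), ".assign.tsv")),
    abundance = file.path(abund_dir,
                          paste0(names(cfg$alignments), ".abund.tsv")),
    table_raw = file.path(out, "table.raw.tsv"),
    table_rpkm = file.path(out, "table.rpkm.tsv"),
    comparison = file.path(out, "comparison.tsv"),
    operons = file.path(out, "operons.tsv"),
    pathways = file.path(out, "pathways.tsv"),
    kegg_colors = file.path(out, "kegg_colors.tsv"),
    heatmap = file.path(out, "heatmap.tsv"),
    manifest = file.path(out, "manifest.yaml")
  )
  invisible(list(db = db, abundance = abundance, comparison = comparison,
                 operons = operons, pathways = pathways, paths = paths))
}
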