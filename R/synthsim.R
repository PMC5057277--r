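#' Simulation configuration
#'
#' Defines the synthetic study: a reference of `n_kos` KO groups (each
#' backed by one or more proteins), pathway and operon structure, sample
#' groups, per-sample sequencing depth, and a spike-in design with known
#' true log2 fold changes. Defaults describe the package's standard
#' synthetic study: 500 KOs, 10 control vs 10 case samples, 20,000 reads
#' per sample, 10% of KOs spiked at true log2FC = 3, negative-binomial
#' counts with size 5 (moderate overdispersion).
#'
#' @param n_kos Number of KO groups.
#' @param proteins_per_ko Integer range `c(min, max)` of proteins per KO.
#' @param protein_length_range_aa Protein length range, amino acids.
#' @param n_pathways,pathway_size_range Pathway count and member-count range.
#' @param n_operons,operon_size_range Operon count and member-count range.
#' @param groups Named integer vector: samples per group; the first name is
#'   the reference group.
#' @param reads_per_sample Expected mapped reads per sample.
#' @param spiked_kos Number of KOs spiked in the non-reference group(s).
#' @param true_log2_fc True log2 fold change applied to spiked KOs.
#' @param dispersion Negative-binomial size parameter for realized per-KO
#'   read counts (smaller = more overdispersed).
#' @param identity_range Percent-identity range for emitted hits.
#' @param evalue_range E-value range (log-uniform) for emitted hits.
#' @param decoy_prob Probability that a read also emits a decoy secondary
#'   hit at strictly lower bitscore.
#' @param seed Base RNG seed; each sample derives its own stream from
#'   `(seed, sample_id)`, so adding a sample never perturbs existing ones.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_kos = 500,
                              proteins_per_ko = c(1, 3),
                              protein_length_range_aa = c(100, 1000),
                              n_pathways = 20,
                              pathway_size_range = c(5, 40),
                              n_operons = 30,
                              operon_size_range = c(2, 6),
                              groups = c(control = 10, case = 10),
                              reads_per_sample = 20000,
                              spiked_kos = 50,
                              true_log2_fc = 3,
                              dispersion = 5,
                              identity_range = c(85, 99),
                              evalue_range = c(1e-30, 1e-5),
                              decoy_prob = 0.2,
                              seed = 1) {
  cfg <- list(
    n_kos = as.integer(n_kos), proteins_per_ko = as.integer(proteins_per_ko),
    protein_length_range_aa = as.integer(protein_length_range_aa),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_operons = as.integer(n_operons),
    operon_size_range = as.integer(operon_size_range),
    groups = groups, reads_per_sample = as.integer(reads_per_sample),
    spiked_kos = as.integer(spiked_kos), true_log2_fc = true_log2_fc,
    dispersion = dispersion, identity_range = identity_range,
    evalue_range = evalue_range, decoy_prob = decoy_prob,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_kos < 1 || reads_per_sample < 1 || n_pathways < 0 || n_operons < 0) {
      abort("counts must be positive")
    }
    if (spiked_kos > n_kos) abort("spiked_kos must be <= n_kos")
    if (spiked_kos < 0) abort("spiked_kos must be >= 0")
    if (length(groups) < 2 || is.null(names(groups)) || any(groups < 1)) {
      abort("`groups` must be a named vector of >= 2 positive sample counts")
    }
    if (n_pathways > 0 && max(pathway_size_range) > n_kos) {
      abort("pathway_size_range exceeds n_kos")
    }
    if (n_operons > 0 && max(operon_size_range) > n_kos) {
      abort("operon_size_range exceeds n_kos")
    }
    if (dispersion <= 0) abort("dispersion must be > 0")
    if (decoy_prob < 0 || decoy_prob > 1) abort("decoy_prob must be in [0,1]")
  })
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror [simulation_config()] arguments.
#' @return A `sim_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$groups)) raw$groups <- unlist(raw$groups)
  do.call(simulation_config, raw)
}

rand_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Simulate a reference database
#'
#' Draws KO ids `K00001..`, per-KO proteins with uniform lengths, random
#' pathway memberships, and operons whose members come from a single
#' pathway's co-members where a large enough pathway exists (operons nest
#' inside pathways in real annotation).
#'
#' @param cfg A `sim_config`.
#' @return A [ref_db()].
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(derive_seed(cfg$seed, "reference"), {
    kos <- sprintf("K%05d", seq_len(cfg$n_kos))
    n_prot <- rand_int(cfg$n_kos, cfg$proteins_per_ko)
    proteins <- tibble(
      ko_id = rep(kos, n_prot),
      protein_id = sprintf("%s_p%d", rep(kos, n_prot),
                           unlist(lapply(n_prot, seq_len))),
      length_aa = rand_int(sum(n_prot), cfg$protein_length_range_aa),
      taxon_domain = sample(c("bacteria", "archaea", "fungi"), sum(n_prot),
                            replace = TRUE, prob = c(0.8, 0.1, 0.1))
    ) |>
      select("protein_id", "ko_id", "length_aa", "taxon_domain")
    pathways <- if (cfg$n_pathways > 0) {
      sizes <- rand_int(cfg$n_pathways, cfg$pathway_size_range)
      map2(seq_len(cfg$n_pathways), sizes, function(i, s) {
        tibble(pathway_id = sprintf("map%05d", i),
               pathway_name = sprintf("synthetic pathway %d", i),
               ko_id = sample(kos, s))
      }) |> list_rbind()
    } else empty_pathways()
    operons <- if (cfg$n_operons > 0) {
      sizes <- rand_int(cfg$n_operons, cfg$operon_size_range)
      map2(seq_len(cfg$n_operons), sizes, function(i, s) {
        big <- unique(pathways$pathway_id[
          pathways$pathway_id %in% names(which(table(pathways$pathway_id) >= s))])
        pool <- if (length(big)) {
          pathways$ko_id[pathways$pathway_id == sample(big, 1)]
        } else kos
        tibble(operon_id = sprintf("ODB%04d", i),
               ko_id = sample(pool, s),
               label = sprintf("synthetic operon %d", i))
      }) |> list_rbind()
    } else empty_operons()
    ref_db(proteins, pathways, operons)
  })
}

# True per-group relative abundances and spike design. Spiked units are
# two-sided — alternating units shift up (+true_log2_fc) and down
# (-true_log2_fc) in the case group(s) — so the unspiked majority stays
# approximately null after renormalization to relative abundance (one-sided
# spiking would shift every unspiked KO by the compositional load). Half of
# the spike budget preferentially covers whole operons, each spiked operon
# moving as one co-transcribed unit in one direction.
simulate_truth <- function(cfg, db) {
  withr::with_seed(derive_seed(cfg$seed, "truth"), {
    kos <- sort(db$ko_universe)
    base <- rlnorm(length(kos), meanlog = 0, sdlog = 1)
    units <- list()
    spiked <- character()
    if (cfg$spiked_kos > 0) {
      op_sets <- feature_members(db, "operon")
      op_sets <- op_sets[order(names(op_sets))]
      if (length(op_sets)) {
        for (s in sample(op_sets)) {
          s <- setdiff(intersect(unique(s), kos), spiked)
          if (length(s) == 0L ||
              length(spiked) + length(s) > ceiling(cfg$spiked_kos / 2)) next
          units <- c(units, list(s))
          spiked <- c(spiked, s)
        }
      }
      remaining <- cfg$spiked_kos - length(spiked)
      if (remaining > 0) {
        singles <- sample(setdiff(kos, spiked), remaining)
        units <- c(units, as.list(singles))
        spiked <- c(spiked, singles)
      }
    }
    sign_of <- setNames(numeric(length(kos)), kos)
    for (i in seq_along(units)) {
      sign_of[units[[i]]] <- if (i %% 2 == 1) 1 else -1
    }
    groups <- names(cfg$groups)
    rel <- matrix(0, length(kos), length(groups),
                  dimnames = list(kos, groups))
    rel[, 1] <- base / sum(base)
    mult <- 2^(sign_of[kos] * cfg$true_log2_fc)
    for (g in groups[-1]) {
      w <- base * mult
      rel[, g] <- w / sum(w)
    }
    is_spiked <- kos %in% spiked
    tibble(
      ko_id = kos,
      spiked = is_spiked,
      true_log2_fc = unname(sign_of[kos]) * cfg$true_log2_fc
    ) |>
      bind_cols(as_tibble(rel, .name_repair = ~ paste0("rel_", groups)))
  })
}

#' Simulate per-sample alignment files with known ground truth
#'
#' For each sample, per-KO read counts are drawn from a negative binomial
#' with mean `reads_per_sample x` the group's true relative abundance and
#' size `dispersion`. Each read emits one best hit to a random protein of
#' its source KO (identity uniform in `identity_range`, e-value log-uniform
#' in `evalue_range`) and, with probability `decoy_prob`, one decoy hit to a
#' random protein at strictly lower bitscore, so the true best hit is
#' unambiguous. Every sample uses its own RNG stream derived from
#' `(seed, sample_id)`.
#'
#' @param cfg A `sim_config`.
#' @param db The [ref_db()] from [simulate_reference()] with the same `cfg`.
#' @param out_dir Directory for the per-sample `.m8` files, `truth.tsv` and
#'   `design.tsv`.
#' @return List with `alignment_files` (named by sample), `design` tibble,
#'   `truth` tibble and the paths of the written TSVs.
#' @export
simulate_alignments <- function(cfg, db, out_dir) {
  stopifnot(inherits(cfg, "sim_config"), inherits(db, "ref_db"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(cfg, db)
  groups <- names(cfg$groups)
  design <- tibble(
    sample_id = unlist(map2(groups, cfg$groups,
                            function(g, n) sprintf("%s_%02d", g, seq_len(n)))),
    group = rep(groups, cfg$groups)
  )
  prot_by_ko <- split(seq_len(nrow(db$proteins)), db$proteins$ko_id)
  all_prot <- db$proteins

  files <- setNames(character(nrow(design)), design$sample_id)
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]
    grp <- design$group[i]
    files[sid] <- file.path(out_dir, paste0(sid, ".m8"))
    withr::with_seed(derive_seed(cfg$seed, sid), {
      mu <- cfg$reads_per_sample * truth[[paste0("rel_", grp)]]
      counts <- rnbinom(length(mu), mu = mu, size = cfg$dispersion)
      src_ko <- rep(truth$ko_id, counts)
      n_reads <- length(src_ko)
      if (n_reads == 0L) {
        writeLines(character(), files[sid])
      } else {
        # pick one protein of the source KO per read
        prot_idx <- integer(n_reads)
        for (ko in unique(src_ko)) {
          sel <- which(src_ko == ko)
          pool <- prot_by_ko[[ko]]
          prot_idx[sel] <- if (length(pool) == 1L) pool else
            sample(pool, length(sel), replace = TRUE)
        }
        pid <- runif(n_reads, cfg$identity_range[1], cfg$identity_range[2])
        ev <- 10^runif(n_reads, log10(cfg$evalue_range[1]),
                       log10(cfg$evalue_range[2]))
        alen <- 33L  # ~100 bp translated
        bits <- round(50 + pid / 2 + runif(n_reads, 0, 5), 1)
        plen <- all_prot$length_aa[prot_idx]
        sstart <- pmax(1L, as.integer(ceiling(runif(n_reads) *
                                                pmax(1L, plen - alen))))
        primary <- tibble(
          read_id = sprintf("%s_r%06d", sid, seq_len(n_reads)),
          protein_id = all_prot$protein_id[prot_idx],
          percent_identity = round(pid, 1),
          align_length = alen, mismatches = as.integer(
            round(alen * (100 - pid) / 100)),
          gap_opens = 0L, q_start = 1L, q_end = 100L,
          s_start = sstart, s_end = sstart + alen - 1L,
          evalue = signif(ev, 3), bitscore = bits,
          order_key = seq_len(n_reads), is_decoy = FALSE
        )
        has_decoy <- runif(n_reads) < cfg$decoy_prob
        hits <- primary
        if (any(has_decoy)) {
          dn <- sum(has_decoy)
          didx <- sample(nrow(all_prot), dn, replace = TRUE)
          decoy <- primary[has_decoy, ]
          decoy$protein_id <- all_prot$protein_id[didx]
          decoy$percent_identity <- round(
            runif(dn, cfg$identity_range[1], cfg$identity_range[2]), 1)
          decoy$evalue <- signif(decoy$evalue * 100, 3)
          decoy$bitscore <- round(pmax(1, decoy$bitscore - runif(dn, 10, 40)), 1)
          dlen <- all_prot$length_aa[didx]
          decoy$s_start <- pmax(1L, as.integer(ceiling(runif(dn) *
                                                         pmax(1L, dlen - alen))))
          decoy$s_end <- decoy$s_start + alen - 1L
          decoy$is_decoy <- TRUE
          hits <- bind_rows(primary, decoy) |>
            arrange(.data$order_key, .data$is_decoy)
        }
        lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                         hits$read_id, hits$protein_id, hits$percent_identity,
                         hits$align_length, hits$mismatches, hits$gap_opens,
                         hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                         formatC(hits$evalue, format = "e", digits = 2),
                         hits$bitscore)
        writeLines(lines, files[sid])
      }
    })
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  design_path <- file.path(out_dir, "design.tsv")
  write_tsv(truth, truth_path)
  write_tsv(design, design_path)
  list(alignment_files = files, design = design, truth = truth,
       truth_path = truth_path, design_path = design_path)
}

#' Simulate a complete dataset on disk
#'
#' Writes the reference tables (under `<out_dir>/reference/`), per-sample
#' alignment files, `truth.tsv` and `design.tsv`. Running twice with the
#' same configuration produces byte-identical files.
#'
#' @param cfg A `sim_config`.
#' @param out_dir Output directory.
#' @return List with the `ref_db`, reference table paths, and everything
#'   returned by [simulate_alignments()].
#' @export
simulate_dataset <- function(cfg, out_dir) {
  db <- simulate_reference(cfg)
  ref_paths <- write_reference(db, file.path(out_dir, "reference"))
  sim <- simulate_alignments(cfg, db, out_dir)
  c(list(db = db, reference_paths = ref_paths), sim)
}
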