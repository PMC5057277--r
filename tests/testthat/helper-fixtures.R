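# In-code fixtures shared across test files.

# tiny reference: 5 proteins over 4 KOs, one pathway, two operons
tiny_ref <- function() {
  ref_db(
    proteins = tibble::tibble(
      protein_id = c("P1", "P2", "P3", "P4", "P5"),
      ko_id = c("K00001", "K00001", "K00002", "K00003", "K00004"),
      length_aa = c(300L, 100L, 250L, 180L, 500L),
      taxon_domain = "bacteria"
    ),
    pathways = tibble::tibble(
      pathway_id = "map00001",
      pathway_name = "toy pathway",
      ko_id = c("K00001", "K00002")
    ),
    operons = tibble::tibble(
      operon_id = c("OP1", "OP1", "OP2"),
      ko_id = c("K00001", "K00002", "K00003"),
      label = c("two-member", "two-member", "singleton")
    )
  )
}

# one outfmt-6 line
m8_line <- function(read = "r1", prot = "P1", pident = 95, alen = 33,
                    mm = 1, gap = 0, qs = 1, qe = 100, ss = 10, se = 42,
                    evalue = 1e-10, bits = 100) {
  sprintf("%s\t%s\t%g\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g",
          read, prot, pident, alen, mm, gap, qs, qe, ss, se, evalue, bits)
}

write_m8 <- function(lines, path = tempfile(fileext = ".m8")) {
  writeLines(lines, path)
  path
}

# hit tibble without going through a file
hit_row <- function(read = "r1", prot = "P1", pident = 95, evalue = 1e-10,
                    bits = 100) {
  tibble::tibble(
    read_id = read, protein_id = prot, percent_identity = pident,
    align_length = 33L, mismatches = 1L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 10L, s_end = 42L,
    evalue = evalue, bitscore = bits
  )
}

# assignments tibble
assignment_rows <- function(ko, len, read = NULL) {
  n <- length(ko)
  tibble::tibble(
    read_id = read %||% sprintf("r%04d", seq_len(n)),
    ko_id = ko,
    protein_id = paste0(ko, "_p1"),
    protein_length_aa = as.integer(len)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sample_abundance built directly from named count/rpkm vectors
make_sample <- function(id, counts, rpkm = NULL) {
  kos <- names(counts)
  x <- tibble::tibble(
    ko_id = kos,
    raw_count = as.integer(counts),
    rpkm = if (is.null(rpkm)) as.numeric(counts) else as.numeric(rpkm)
  )
  structure(x, total_mapped_reads = sum(counts), sample_id = id,
            class = c("sample_abundance", class(x)))
}

# abundance object from an RPKM matrix (raw filled with rounded values)
abundance_from_matrix <- function(m) {
  samples <- lapply(colnames(m), function(s) {
    v <- m[, s]
    make_sample(s, setNames(as.integer(round(v)), rownames(m)), rpkm = v)
  })
  merge_samples(samples)
}

# comparison tibble with chosen DA flags / fold changes
make_comparison <- function(ko_id, log2_fc, is_da, p_value = NULL) {
  out <- tibble::tibble(
    ko_id = ko_id,
    p_value = p_value %||% ifelse(is_da, 0.001, 0.5),
    q_value = p_value %||% ifelse(is_da, 0.01, 0.7),
    log2_fc = log2_fc,
    is_da = is_da
  )
  class(out) <- c("ko_comparison", class(out))
  out
}

# independent two-sided Fisher oracle: enumerate all fixed-margin tables and
# sum probabilities of those no more likely than the observed table
fisher_two_sided_oracle <- function(a, b, c_, d) {
  m <- a + b          # feature size
  n <- c_ + d         # non-feature size
  k <- a + c_         # DA total
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

# closed-form two-group quasi-Poisson Wald oracle
qp_two_group_oracle <- function(a_vals, b_vals) {
  na <- length(a_vals); nb <- length(b_vals)
  ma <- mean(a_vals); mb <- mean(b_vals)
  mu <- c(rep(ma, na), rep(mb, nb))
  y <- c(a_vals, b_vals)
  phi <- sum((y - mu)^2 / mu) / (na + nb - 2)
  z <- log(mb / ma) / sqrt(phi * (1 / (na * ma) + 1 / (nb * mb)))
  2 * stats::pt(-abs(z), df = na + nb - 2)
}
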