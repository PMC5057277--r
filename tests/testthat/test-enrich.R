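test_that("the all-members operon rule is a strict subset test", {
  db <- tiny_ref()  # OP1 = {K00001, K00002}, OP2 = {K00003}
  hit <- da_operons(c("K00001", "K00002", "K00009"), db)
  expect_true("OP1" %in% hit$operon_id)

  partial <- da_operons(c("K00001"), db)
  expect_false("OP1" %in% partial$operon_id)

  expect_equal(nrow(da_operons(character(), db)), 0)
})

test_that("duplicate member rows collapse before the subset test", {
  db <- suppressWarnings(ref_db(
    proteins = tiny_ref()$proteins,
    operons = tibble::tibble(operon_id = "OPd",
                             ko_id = c("K00001", "K00001", "K00002"),
                             label = "dup")
  ))
  res <- da_operons(c("K00001", "K00002"), db)
  expect_equal(res$size, 2)
})

test_that("da_operons is monotone under DA-set growth", {
  set.seed(101)
  kos <- sprintf("K%05d", 1:30)
  for (i in 1:100) {
    n_ops <- sample(2:6, 1)
    operons <- dplyr::bind_rows(lapply(seq_len(n_ops), function(j) {
      tibble::tibble(operon_id = paste0("OP", j),
                     ko_id = sample(kos, sample(2:5, 1)), label = "")
    }))
    db <- suppressWarnings(ref_db(
      proteins = tibble::tibble(protein_id = kos, ko_id = kos,
                                length_aa = 100L, taxon_domain = "bacteria"),
      operons = operons
    ))
    small <- sample(kos, sample(0:20, 1))
    big <- union(small, sample(kos, sample(0:10, 1)))
    in_small <- da_operons(small, db)$operon_id
    in_big <- da_operons(big, db)$operon_id
    expect_true(all(in_small %in% in_big))
  }
})

test_that("Fisher enrichment reproduces exact hand-computed tables", {
  universe <- sprintf("K%02d", 1:10)
  feature <- universe[1:5]
  # all 5 feature KOs DA, none outside: p = 2/C(10,5) = 1/126
  res <- fisher_enrichment(feature, feature, universe)
  expect_equal(res$p_value, 1 / 126, tolerance = 1e-10)
  expect_equal(res$ko_count, 5)
  expect_equal(res$coverage, 1)

  # DA set = universe: a single admissible table, p = 1
  expect_equal(fisher_enrichment(universe, feature, universe)$p_value, 1)

  expect_error(fisher_enrichment("K01", "K01", character()), "empty universe")
  expect_error(fisher_enrichment("K01", "K99", universe), "no KO within")
})

test_that("Fisher p equals brute-force enumeration on random small tables", {
  set.seed(2024)
  for (i in 1:60) {
    N <- sample(6:40, 1)
    universe <- sprintf("K%03d", seq_len(N))
    feature <- sample(universe, sample(1:(N - 1), 1))
    da <- sample(universe, sample(0:N, 1))
    a <- length(intersect(feature, da))
    b <- length(setdiff(feature, da))
    c_ <- length(setdiff(da, feature))
    d <- N - a - b - c_
    res <- tryCatch(fisher_enrichment(da, feature, universe),
                    error = function(e) NULL)
    expect_false(is.null(res))
    expect_lt(abs(res$p_value - fisher_two_sided_oracle(a, b, c_, d)), 1e-10)
  }
})

test_that("two-sided Fisher is invariant to swapping the table rows", {
  universe <- sprintf("K%02d", 1:20)
  feature <- universe[1:6]
  da <- universe[c(1:4, 10:12)]
  p_feat <- fisher_enrichment(da, feature, universe)$p_value
  p_comp <- fisher_enrichment(da, setdiff(universe, feature), universe)$p_value
  expect_equal(p_feat, p_comp, tolerance = 1e-12)
})

enrich_fixture <- function() {
  kos <- sprintf("K%05d", 1:20)
  db <- ref_db(
    proteins = tibble::tibble(protein_id = kos, ko_id = kos,
                              length_aa = 100L, taxon_domain = "bacteria"),
    pathways = dplyr::bind_rows(
      tibble::tibble(pathway_id = "mapA", pathway_name = "hit pathway",
                     ko_id = kos[1:5]),
      tibble::tibble(pathway_id = "mapB", pathway_name = "cold pathway",
                     ko_id = kos[11:15])
    ),
    operons = tibble::tibble(operon_id = c("OP1", "OP1", "OP2", "OP2"),
                             ko_id = kos[c(1, 2, 11, 12)],
                             label = c("hot", "hot", "cold", "cold"))
  )
  cmp <- make_comparison(
    ko_id = kos,
    log2_fc = c(2, 3, 2.5, 2.2, 1.8, rep(0.1, 15)),
    is_da = c(rep(TRUE, 5), rep(FALSE, 15))
  )
  list(db = db, cmp = cmp)
}

test_that("pathway enrichment reports coverage, mean log2FC and small p", {
  fx <- enrich_fixture()
  res <- enrich_features(fx$cmp, fx$db, kind = "pathway")
  expect_equal(res$feature_id, "mapA")  # mapB has zero DA KOs: not reported
  expect_equal(res$ko_count, 5)
  expect_equal(res$feature_size, 5)
  expect_equal(res$coverage, 1)
  expect_equal(res$avg_log2_fc, mean(c(2, 3, 2.5, 2.2, 1.8)))
  # exact hypergeometric: all 5 DA inside a 5-KO pathway of a 20-KO universe
  expect_equal(res$p_value, fisher_two_sided_oracle(5, 0, 0, 15),
               tolerance = 1e-10)
  expect_equal(res$q_value, res$p_value)
  # count/coverage consistency at presentation precision
  expect_equal(round(res$ko_count / res$feature_size, 3), round(res$coverage, 3))
})

test_that("operon enrichment composes the all-members rule with Fisher", {
  fx <- enrich_fixture()
  res <- enrich_features(fx$cmp, fx$db, kind = "operon")
  expect_equal(res$feature_id, "OP1")  # OP2 members not DA
  expect_equal(res$ko_count, 2)
  expect_equal(res$avg_log2_fc, 2.5)  # mean of 2 and 3
  expect_equal(res$p_value,
               fisher_enrichment(da_kos(fx$cmp), c("K00001", "K00002"),
                                 fx$db$ko_universe)$p_value)
  expect_false(any(res$single_member))
})

test_that("coverage is 1 exactly when every in-universe member is DA", {
  fx <- enrich_fixture()
  res_full <- enrich_features(fx$cmp, fx$db, kind = "pathway")
  expect_equal(res_full$coverage, 1)
  cmp2 <- fx$cmp
  cmp2$is_da[5] <- FALSE  # drop one member of mapA from the DA set
  res_part <- enrich_features(cmp2, fx$db, kind = "pathway")
  expect_lt(res_part$coverage, 1)
  expect_equal(res_part$ko_count, 4)
})

test_that("the detected universe restricts to tested KOs", {
  fx <- enrich_fixture()
  cmp_small <- fx$cmp[1:10, ]  # pretend only 10 KOs were detected/tested
  class(cmp_small) <- class(fx$cmp)
  res <- enrich_features(cmp_small, fx$db, kind = "pathway",
                         universe_mode = "detected")
  expect_equal(attr(res, "universe_size"), 10)
  expect_equal(res$p_value,
               fisher_two_sided_oracle(5, 0, 0, 5), tolerance = 1e-10)
})

test_that("enrichment output is sorted by p and BH-adjusted within kind", {
  set.seed(6)
  kos <- sprintf("K%05d", 1:60)
  db <- ref_db(
    proteins = tibble::tibble(protein_id = kos, ko_id = kos,
                              length_aa = 100L, taxon_domain = "bacteria"),
    pathways = dplyr::bind_rows(lapply(1:6, function(i) {
      tibble::tibble(pathway_id = paste0("map", i), pathway_name = "",
                     ko_id = sample(kos, 10))
    }))
  )
  cmp <- make_comparison(kos, log2_fc = rep(1.5, 60),
                         is_da = seq_along(kos) <= 20)
  res <- enrich_features(cmp, db, kind = "pathway")
  expect_false(is.unsorted(res$p_value))
  expect_equal(res$q_value, bh_fdr(res$p_value)[order(res$p_value)])
  expect_true(all(res$ko_count <= res$feature_size))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})
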