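test_that("Kruskal-Wallis handles symmetry, the worked rank case and ties", {
  # identical groups: H = 0, p = 1
  sym <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(sym$p_value, 1, tolerance = 1e-12)

  # tie-free closed form: A = 1..5, B = 6..10 -> H = 6.8182
  kw <- kruskal_wallis(1:10, rep(c("A", "B"), each = 5))
  expect_equal(kw$statistic, 12 / (10 * 11) * (5 * (3 - 5.5)^2 + 5 * (8 - 5.5)^2),
               tolerance = 1e-4)
  expect_equal(kw$statistic, 6.8182, tolerance = 1e-4)
  expect_equal(kw$p_value, 0.00902, tolerance = 1e-3)

  # every value identical: defined as p = 1
  expect_equal(kruskal_wallis(rep(2.5, 10), rep(c("A", "B"), 5))$p_value, 1)

  expect_error(kruskal_wallis(1:4, rep("A", 4)), "2 groups")
})

test_that("quasi-Poisson matches the closed-form two-group Wald oracle", {
  a <- c(10, 12, 11, 9); b <- c(30, 28, 31, 33)
  fit <- quasi_poisson_test(c(a, b), rep(c("A", "B"), each = 4))
  # canonical-link factor fit reproduces the sample means, so the oracle applies
  expect_equal(fit$p_value, qp_two_group_oracle(a, b), tolerance = 1e-6)
  expect_equal(fit$df, 6)

  # identical groups -> p = 1
  same <- quasi_poisson_test(rep(c(4, 4, 4, 4), 2), rep(c("A", "B"), each = 4))
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # a group of zeros is a degenerate log-link fit
  expect_warning(
    z <- quasi_poisson_test(c(0, 0, 0, 5, 6, 7), rep(c("A", "B"), each = 3)),
    "degenerate"
  )
  expect_equal(z$p_value, 1)
})

test_that("quasi-Poisson tracks the oracle across random two-group fixtures", {
  set.seed(314)
  for (i in 1:100) {
    na <- sample(3:8, 1); nb <- sample(3:8, 1)
    a <- rnbinom(na, mu = runif(1, 2, 60), size = 5) + runif(na, 0.1, 1)
    b <- rnbinom(nb, mu = runif(1, 2, 60), size = 5) + runif(nb, 0.1, 1)
    got <- quasi_poisson_test(c(a, b), rep(c("A", "B"), c(na, nb)))$p_value
    expect_equal(got, qp_two_group_oracle(a, b), tolerance = 1e-6)
  }
})

test_that("quasi-Poisson uses an F-test for more than two groups", {
  set.seed(8)
  v <- c(rnbinom(4, mu = 10, size = 5), rnbinom(4, mu = 12, size = 5),
         rnbinom(4, mu = 50, size = 5)) + 0.5
  res <- quasi_poisson_test(v, rep(c("A", "B", "C"), each = 4))
  expect_true(res$p_value > 0 && res$p_value < 1)
  expect_true(res$statistic > 0)
})

test_that("log2 fold change follows the pseudocount formula", {
  expect_equal(log2_fold_change(5, 5, 1), 0)
  expect_equal(log2_fold_change(4, 1, 1e-9), 2, tolerance = 1e-6)
  expect_equal(log2_fold_change(0, 3, 1), log2(1 / 4))
  expect_error(log2_fold_change(1, 1, 0), "pseudocount")
})

test_that("BH adjustment matches hand step-up and is monotone-bounded", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle on random p-vectors
  set.seed(77)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    stepped <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- pmin(1, stepped)[order(o)]
    q <- bh_fdr(p)
    expect_equal(q, oracle)
    expect_true(all(q >= p) && all(q <= 1))
  }
})

null_abundance <- function(n_ko = 6, n_per_group = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(n_ko * 2 * n_per_group, mu = 40, size = 5) + 1,
              nrow = n_ko,
              dimnames = list(sprintf("K%05d", seq_len(n_ko)),
                              sprintf("s%02d", seq_len(2 * n_per_group))))
  m
}

test_design <- function(m, groups = c("ctrl", "case")) {
  tibble::tibble(sample_id = colnames(m),
                 group = rep(groups, each = ncol(m) / 2))
}

test_that("run_comparison flags a cleanly separated KO and only that KO", {
  m <- null_abundance(seed = 42)
  m["K00001", ] <- c(rep(10, 5), rep(80, 5))  # 8-fold, no overlap
  m["K00002", ] <- 30                          # constant -> never DA
  ab <- abundance_from_matrix(m)
  cmp <- run_comparison(ab, test_design(m))
  expect_s3_class(cmp, "ko_comparison")
  expect_true(cmp$is_da[cmp$ko_id == "K00001"])
  expect_false(cmp$is_da[cmp$ko_id == "K00002"])
  expect_equal(cmp$log2_fc[cmp$ko_id == "K00001"], 3, tolerance = 1e-3)
  expect_equal(cmp$mean_ctrl[cmp$ko_id == "K00001"], 10)
  expect_equal(cmp$mean_case[cmp$ko_id == "K00001"], 80)
})

test_that("identical values across samples yield an empty DA set", {
  m <- matrix(25, nrow = 4, ncol = 8,
              dimnames = list(paste0("K", 1:4), paste0("s", 1:8)))
  ab <- abundance_from_matrix(m)
  cmp <- run_comparison(ab, test_design(m))
  expect_equal(sum(cmp$is_da), 0)
  expect_true(all(cmp$p_value == 1))
})

test_that("swapping group labels negates fold changes and keeps p-values", {
  m <- null_abundance(seed = 7)
  ab <- abundance_from_matrix(m)
  d1 <- test_design(m)
  d2 <- d1; d2$group <- rep(c("case", "ctrl"), each = 5)
  c1 <- run_comparison(ab, d1)
  c2 <- run_comparison(ab, d2, reference_group = "ctrl")
  expect_equal(c1$p_value, c2$p_value)
  expect_equal(c1$log2_fc, -c2$log2_fc, tolerance = 1e-9)
})

test_that("all-zero KOs are dropped before testing with a message", {
  m <- null_abundance(seed = 3)
  m["K00006", ] <- 0
  ab <- abundance_from_matrix(m)
  expect_message(cmp <- run_comparison(ab, test_design(m)), "zero abundance")
  expect_false("K00006" %in% cmp$ko_id)
  expect_equal(nrow(cmp), 5)
})

test_that("run_comparison validates design and reserves metagenomeseq", {
  m <- null_abundance()
  ab <- abundance_from_matrix(m)
  expect_error(run_comparison(ab, test_design(m), method = "metagenomeseq"),
               "extension point")
  bad <- test_design(m); bad$sample_id[1] <- "missing_sample"
  expect_error(run_comparison(ab, bad), "absent")
  solo <- test_design(m)[1:2, ]; solo$group <- c("a", "b")
  expect_error(run_comparison(ab, solo), ">= 2 samples")
})

test_that("filter_on = fdr uses adjusted p for the DA flag", {
  m <- null_abundance(n_ko = 10, seed = 9)
  m[1, ] <- c(rep(5, 5), rep(90, 5))
  ab <- abundance_from_matrix(m)
  raw <- run_comparison(ab, test_design(m), filter_on = "raw")
  fdr <- run_comparison(ab, test_design(m), filter_on = "fdr")
  expect_true(all(fdr$is_da <= raw$is_da))  # FDR filter can only be stricter
  expect_equal(raw$q_value, bh_fdr(raw$p_value))
})

test_that("reference_group overrides the design's first label", {
  m <- null_abundance(seed = 15)
  ab <- abundance_from_matrix(m)
  flipped <- run_comparison(ab, test_design(m), reference_group = "case")
  straight <- run_comparison(ab, test_design(m))
  expect_equal(flipped$log2_fc, -straight$log2_fc, tolerance = 1e-9)
  expect_equal(attr(flipped, "reference_group"), "case")
})

test_that("glance reports the comparison settings and DA count", {
  m <- null_abundance(seed = 2)
  ab <- abundance_from_matrix(m)
  cmp <- run_comparison(ab, test_design(m), method = "quasipoisson")
  g <- glance(cmp)
  expect_equal(g$method, "quasipoisson")
  expect_equal(g$n_tested, nrow(cmp))
  expect_equal(g$n_da, sum(cmp$is_da))
})
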