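#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k-1 degrees
#' of freedom. When every observation is identical the test is undefined
#' (zero rank variance) and p = 1 is returned by contract.
#'
#' @param values Numeric vector of per-sample abundances.
#' @param groups Group labels, same length as `values`; >= 2 distinct groups.
#' @return One-row tibble with `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (length(values) != length(g)) abort("`values` and `groups` lengths differ")
  if (nlevels(g) < 2L) abort("need >= 2 groups")
  if (any(tabulate(g) < 1L)) abort("every group needs >= 1 observation")
  if (length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, g)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Quasi-Poisson group test
#'
#' Fits a quasi-Poisson GLM (log link) with the group factor as the only
#' covariate via iteratively reweighted least squares; dispersion is
#' estimated as Pearson X^2 / (n - k). For two groups the returned p is the
#' two-sided Wald t-test on the group coefficient (n - k residual df); for
#' k > 2 groups an F-test of the group factor is used. Any group with zero
#' mean makes the log-link fit degenerate: p = 1 is returned with a warning.
#'
#' @param values Nonnegative numeric vector (RPKM values are the intended
#'   input; non-integer values are fine under quasi-likelihood).
#' @param groups Group labels; the first factor level is the reference.
#' @param max_iter IRLS iteration cap.
#' @param epsilon IRLS relative deviance convergence tolerance.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `dispersion`.
#' @export
quasi_poisson_test <- function(values, groups, max_iter = 50, epsilon = 1e-8) {
  g <- factor(groups)
  if (length(values) != length(g)) abort("`values` and `groups` lengths differ")
  if (nlevels(g) < 2L) abort("need >= 2 groups")
  if (any(values < 0)) abort("`values` must be nonnegative")
  k <- nlevels(g)
  group_means <- tapply(values, g, mean)
  if (any(group_means == 0)) {
    warn("degenerate quasi-Poisson fit: a group has zero mean; returning p = 1")
    return(tibble(statistic = NA_real_, df = length(values) - k,
                  p_value = 1, dispersion = NA_real_))
  }
  if (length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = length(values) - k,
                  p_value = 1, dispersion = 0))
  }
  fit <- glm(values ~ g, family = quasipoisson(),
             control = glm.control(epsilon = epsilon, maxit = max_iter))
  if (!fit$converged) abort("quasi-Poisson IRLS did not converge")
  mu <- fitted(fit)
  n <- length(values)
  # Pearson dispersion at the converged fit (summary.glm would reuse the
  # working weights of the penultimate IRLS iterate)
  phi <- sum((values - mu)^2 / mu) / (n - k)
  if (k == 2L) {
    X <- stats::model.matrix(fit)
    cov_unscaled <- solve(crossprod(X, mu * X))
    t_stat <- unname(coef(fit)[2]) / sqrt(phi * cov_unscaled[2, 2])
    tibble(statistic = t_stat, df = n - k,
           p_value = 2 * stats::pt(-abs(t_stat), df = n - k),
           dispersion = phi)
  } else {
    fit0 <- glm(values ~ 1, family = quasipoisson(),
                control = glm.control(epsilon = epsilon, maxit = max_iter))
    f_stat <- (fit0$deviance - fit$deviance) / (k - 1) / phi
    tibble(statistic = f_stat, df = n - k,
           p_value = stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE),
           dispersion = phi)
  }
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_case + pseudocount) / (mean_ref + pseudocount))`. The
#' pseudocount guards against zero means; its default (1e-3 RPKM) is small
#' relative to any detectable abundance.
#'
#' @param mean_case,mean_ref Nonnegative group means (vectorized).
#' @param pseudocount Positive stabilizer added to both means.
#' @return Numeric log2 fold change(s), case vs reference.
#' @export
log2_fold_change <- function(mean_case, mean_ref, pseudocount = 1e-3) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  if (any(mean_case < 0) || any(mean_ref < 0)) abort("means must be >= 0")
  log2((mean_case + pseudocount) / (mean_ref + pseudocount))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Read a sample-to-group design table
#'
#' TSV with columns `sample_id`, `group`. The first group label encountered
#' is the reference level unless overridden in [run_comparison()].
#'
#' @param path Path to the design TSV.
#' @return Tibble with columns `sample_id`, `group`.
#' @export
read_design <- function(path) {
  d <- read_tsv(path, comment = "#",
                col_types = readr::cols(sample_id = "c", group = "c"))
  assert_columns(d, c("sample_id", "group"), "design")
  d
}

#' Per-KO differential-abundance testing
#'
#' Tests every KO's RPKM profile across sample groups (both implemented
#' methods consume RPKM), computes case-vs-reference log2 fold changes with a
#' pseudocount, BH-adjusts p-values, and flags differentially abundant (DA)
#' KOs by the convention `selected p < alpha` and `|log2FC| > min_abs_log2fc`
#' (both strict), where the selected p is the raw or the FDR-adjusted one per
#' `filter_on`. KOs with zero abundance in all design samples are excluded
#' before testing (a message reports the count). The reference group is the
#' first label in the design unless `reference_group` says otherwise; with
#' more than two groups the "case" mean pools all non-reference samples.
#'
#' `method = "metagenomeseq"` names an external zero-inflated-Gaussian
#' package and is reserved as an extension point: it errors.
#'
#' @param abundance A `ko_abundance` ([merge_samples()]).
#' @param design Design tibble ([read_design()]): `sample_id`, `group`.
#' @param method `"kruskal"` (default) or `"quasipoisson"`.
#' @param filter_on `"raw"` (default) or `"fdr"`: which p-value the DA filter
#'   uses.
#' @param alpha Significance cutoff (strict `<`). Default 0.05.
#' @param min_abs_log2fc Fold-change cutoff (strict `>` on the absolute
#'   value). Default 1.
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @param reference_group Optional reference group label.
#' @return A `ko_comparison` tibble: `ko_id`, `p_value`, `q_value`,
#'   `log2_fc`, one `mean_<group>` column per group, `is_da`. Attributes
#'   record the method and thresholds.
#' @export
run_comparison <- function(abundance, design,
                           method = c("kruskal", "quasipoisson", "metagenomeseq"),
                           filter_on = c("raw", "fdr"),
                           alpha = 0.05, min_abs_log2fc = 1,
                           pseudocount = 1e-3, reference_group = NULL) {
  method <- match.arg(method)
  filter_on <- match.arg(filter_on)
  if (method == "metagenomeseq") {
    abort(paste("method 'metagenomeseq' is not implemented here;",
                "it is an external extension point (zero-inflated Gaussian)"))
  }
  stopifnot(inherits(abundance, "ko_abundance"))
  assert_columns(design, c("sample_id", "group"), "design")
  assert_scalar_number(alpha, "alpha", min = 0)
  assert_scalar_number(min_abs_log2fc, "min_abs_log2fc", min = 0)
  missing_samples <- setdiff(design$sample_id, abundance$samples)
  if (length(missing_samples)) {
    abort(sprintf("design sample(s) absent from the abundance table: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  groups_order <- unique(design$group)
  if (!is.null(reference_group)) {
    if (!reference_group %in% groups_order) abort("unknown `reference_group`")
    groups_order <- c(reference_group, setdiff(groups_order, reference_group))
  }
  if (length(groups_order) < 2L) abort("design must have >= 2 groups")
  if (any(table(design$group) < 2L)) {
    abort("every group needs >= 2 samples for testing")
  }
  ref <- groups_order[1]

  m <- abundance_matrix(abundance, "rpkm")[, design$sample_id, drop = FALSE]
  nonzero <- rowSums(m) > 0
  if (any(!nonzero)) {
    inform(sprintf("excluded %d KO(s) with zero abundance in all design samples",
                   sum(!nonzero)))
  }
  m <- m[nonzero, , drop = FALSE]
  if (nrow(m) == 0L) abort("no KO has nonzero abundance in the design samples")
  grp <- factor(design$group, levels = groups_order)

  test_fun <- switch(method,
    kruskal = function(v) kruskal_wallis(v, grp)$p_value,
    quasipoisson = function(v) quasi_poisson_test(v, grp)$p_value
  )
  p <- apply(m, 1, test_fun)
  q <- bh_fdr(p)

  means <- vapply(groups_order,
                  function(gl) rowMeans(m[, grp == gl, drop = FALSE]),
                  numeric(nrow(m)))
  if (nrow(m) == 1L) means <- matrix(means, nrow = 1,
                                     dimnames = list(rownames(m), groups_order))
  case_mean <- rowMeans(m[, grp != ref, drop = FALSE])
  lfc <- log2_fold_change(case_mean, means[, ref], pseudocount)

  sel <- if (filter_on == "raw") p else q
  out <- tibble(
    ko_id = rownames(m),
    p_value = unname(p),
    q_value = unname(q),
    log2_fc = unname(lfc)
  )
  for (gl in groups_order) out[[paste0("mean_", gl)]] <- unname(means[, gl])
  out$is_da <- sel < alpha & abs(out$log2_fc) > min_abs_log2fc
  structure(out,
            method = method, filter_on = filter_on, alpha = alpha,
            min_abs_log2fc = min_abs_log2fc, pseudocount = pseudocount,
            groups = groups_order, reference_group = ref,
            n_zero_dropped = sum(!nonzero),
            class = c("ko_comparison", class(out)))
}

#' DA KO set of a comparison
#' @param comparison A `ko_comparison`.
#' @return Character vector of DA KO ids.
#' @export
da_kos <- function(comparison) {
  assert_columns(comparison, c("ko_id", "is_da"), "comparison")
  comparison$ko_id[comparison$is_da]
}

#' Write / read a comparison table
#'
#' @param comparison A `ko_comparison`.
#' @param path Output/input path.
#' @return `write_comparison()` returns `path` invisibly;
#'   `read_comparison()` returns the table as a `ko_comparison` tibble.
#' @export
write_comparison <- function(comparison, path) {
  write_tsv(as_tibble(comparison), path)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  out <- read_tsv(path, col_types = readr::cols(ko_id = "c", is_da = "l",
                                                .default = "d"))
  class(out) <- c("ko_comparison", class(out))
  out
}
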