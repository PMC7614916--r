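#' Cohen's d standardized mean difference
#'
#' `(mean_a - mean_b)` divided by the pooled standard deviation (pooled
#' with `n - 1` denominators).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Cohen's d.
#' @examples
#' cohens_d(c(10, 12, 14), c(11, 13, 15))  # -0.5
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance: Cohen's d undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Monte-Carlo permutation test on the t-statistic
#'
#' Compares two groups of ages (e.g. ages of diagnosis or death in carriers
#' versus non-carriers of a regulatory variant) by re-computing the pooled
#' two-sample t-statistic over random re-labelings that preserve the group
#' sizes. Two-sided: `p = (1 + #(|t_perm| >= |t_obs|)) / (1 + n_mc)`, so the
#' smallest attainable p is `1/(1 + n_mc)`.
#'
#' @param group_a,group_b Numeric vectors (both non-empty, total >= 4).
#' @param n_mc Number of Monte-Carlo permutations (>= 999; default 1e5).
#' @param seed Seed for the permutation stream.
#' @return List of class `onset_permutation`: observed mean difference,
#'   `t`, permutation `p`, Cohen's `d`, `n_mc`, `seed`.
#' @export
permutation_t_test <- function(group_a, group_b, n_mc = 1e5L, seed = 1L) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  stopifnot(na + nb >= 4, n_mc >= 999)
  pooled <- c(group_a, group_b)
  t_stat <- function(xa, xb) {
    sp2 <- ((length(xa) - 1) * stats::var(xa) +
              (length(xb) - 1) * stats::var(xb)) /
      (length(xa) + length(xb) - 2)
    (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / length(xa) + 1 / length(xb)))
  }
  t_obs <- t_stat(group_a, group_b)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_mc)) {
      idx <- sample.int(na + nb, na)
      if (abs(t_stat(pooled[idx], pooled[-idx])) >= abs(t_obs) - 1e-12)
        hits <- hits + 1L
    }
  })
  structure(list(mean_diff = mean(group_a) - mean(group_b), t = t_obs,
                 p = (1 + hits) / (1 + n_mc),
                 d = if (na >= 2 && nb >= 2) cohens_d(group_a, group_b)
                 else NA_real_,
                 n_a = na, n_b = nb, n_mc = as.integer(n_mc),
                 seed = as.integer(seed)),
            class = "onset_permutation")
}

#' @export
print.onset_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation t-test: mean shift %+.2f years (n = %d vs %d)\n  t = %.3f, permutation p = %.4g (%d permutations), Cohen's d = %.2f\n",
    x$mean_diff, x$n_a, x$n_b, x$t, x$p, x$n_mc, x$d))
  invisible(x)
}

#' Carrier versus non-carrier onset comparison for a cohort
#'
#' Convenience wrapper: splits an age column of the phenotype table by
#' carrier status of a region unit and runs [permutation_t_test()].
#'
#' @param rm A `region_matrix` (or dosage matrix) defining carriers.
#' @param phenotypes Phenotype table with the age column; rows aligned.
#' @param age_col `"age_diagnosis"` or `"age_death"`.
#' @param cases_only Restrict to cases (default TRUE: the comparison is
#'   among affected individuals).
#' @param ... Passed to [permutation_t_test()].
#' @return An `onset_permutation` object.
#' @export
onset_comparison <- function(rm, phenotypes, age_col = "age_diagnosis",
                             cases_only = TRUE, ...) {
  G <- if (inherits(rm, "region_matrix")) rm$G else rm
  stopifnot(nrow(G) == nrow(phenotypes), age_col %in% names(phenotypes))
  carrier <- rowSums(geno0(G) > 0) > 0
  keep <- !is.na(phenotypes[[age_col]])
  if (cases_only) keep <- keep & phenotypes$status == "case"
  ages <- phenotypes[[age_col]][keep]
  carr <- carrier[keep]
  permutation_t_test(ages[carr], ages[!carr], ...)
}
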