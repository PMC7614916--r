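#' Site-level quality-control thresholds
#'
#' Default thresholds for per-site QC of a merged case-control callset:
#' summed depth bounds across the cohort, an overall missingness cap,
#' and alpha levels for the exact Hardy-Weinberg (controls only) and
#' differential-missingness filters.
#'
#' @param depth_low,depth_high Bounds on total site depth (summed DP).
#' @param max_missing Maximum tolerated overall missing-genotype fraction.
#' @param hwe_alpha Significance level of the exact HWE filter in controls.
#' @param diff_missing_alpha Significance level of the case/control
#'   differential-missingness filter.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(depth_low = 10000, depth_high = 226000,
                          max_missing = 0.05, hwe_alpha = 1e-6,
                          diff_missing_alpha = 1e-6) {
  stopifnot(depth_low < depth_high, max_missing >= 0, max_missing <= 1,
            hwe_alpha > 0, hwe_alpha < 1,
            diff_missing_alpha > 0, diff_missing_alpha < 1)
  structure(list(depth_low = depth_low, depth_high = depth_high,
                 max_missing = max_missing, hwe_alpha = hwe_alpha,
                 diff_missing_alpha = diff_missing_alpha),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test on the heterozygote count given the
#' allele counts: all heterozygote counts with the parity of the minor-allele
#' count are enumerated, and the p-value sums the conditional probabilities
#' not exceeding that of the observed configuration. The exact test is the
#' standard choice for rare alleles, where the chi-square approximation
#' misbehaves.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return A p-value in `(0, 1]`.
#' @examples
#' hwe_exact_p(25, 50, 25)   # perfect HWE proportions
#' hwe_exact_p(50, 0, 950)   # gross heterozygote deficit
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(length(n_hom_ref) == 1L, length(n_het) == 1L,
            length(n_hom_alt) == 1L,
            n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_alt + n_het          # alt allele count
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | n, allele counts), constant terms dropped
  logp <- h_cond_logprob(hets, n, n_a)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# log conditional probability (up to a constant) of h heterozygotes given
# sample size n and alt-allele count n_a
h_cond_logprob <- function(h, n, n_a) {
  n_b <- 2 * n - n_a
  h * log(2) - lgamma(h + 1) - lgamma((n_a - h) / 2 + 1) -
    lgamma((n_b - h) / 2 + 1)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric summation
hypergeom_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m + n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  prob <- stats::dhyper(support, m, n, k)
  obs <- prob[match(a, support)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Case/control differential-missingness test
#'
#' Fisher exact test on the 2x2 table of missing versus called genotypes by
#' disease status. Sites where genotype dropout tracks case status inject
#' spurious association signal and are removed.
#'
#' @param geno Integer dosage vector in `{0, 1, 2, NA}` for one site.
#' @param status Character vector, `"case"`/`"control"`, aligned to `geno`.
#' @return A p-value in `(0, 1]`.
#' @export
diff_missingness_p <- function(geno, status) {
  stopifnot(length(geno) == length(status))
  is_case <- status == "case"
  if (!any(is_case) || !any(!is_case)) stop("both classes must be present")
  miss <- is.na(geno)
  hypergeom_fisher_p(sum(miss & is_case), sum(!miss & is_case),
                     sum(miss & !is_case), sum(!miss & !is_case))
}

#' Minor allele frequency within controls
#'
#' Rarity filtering is defined on the control arm of the current dataset:
#' the alternate-allele frequency over called control alleles, folded to the
#' minor allele.
#'
#' @inheritParams diff_missingness_p
#' @return Frequency in `[0, 0.5]`.
#' @examples
#' control_maf(c(0, 0, 1), rep("control", 3))  # 1/6
#' @export
control_maf <- function(geno, status) {
  stopifnot(length(geno) == length(status))
  g <- geno[status == "control" & !is.na(geno)]
  if (length(g) == 0) stop("all control genotypes missing")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Qualifying-variant rule for coding variants
#'
#' A coding variant qualifies if it is predicted to cause a frameshift,
#' canonical-splice disruption or stop gain/loss, or if it is a missense
#' substitution called deleterious by at least three of the seven prediction
#' programs (SIFT, PolyPhen2-HVAR, LRT, MutationTaster, MutationAssessor,
#' FATHMM, MetaLR).
#'
#' @param pred Data frame with a `consequence` column (one of `frameshift`,
#'   `splice`, `stop_gain`, `stop_loss`, `missense`, `other`) and seven
#'   logical/0-1 prediction columns (any names; all non-`consequence`,
#'   non-`variant` columns are treated as calls).
#' @param min_calls Minimum deleterious calls for missense (default 3).
#' @return Logical vector, one entry per row of `pred`.
#' @export
classify_coding_qualifying <- function(pred, min_calls = 3) {
  stopifnot(is.data.frame(pred), "consequence" %in% names(pred))
  lof <- c("frameshift", "splice", "stop_gain", "stop_loss")
  known <- c(lof, "missense", "other")
  bad <- setdiff(unique(pred$consequence), known)
  if (length(bad)) stop("unknown consequence label: ", paste(bad, collapse = ", "))
  call_cols <- setdiff(names(pred), c("variant", "consequence"))
  if (length(call_cols) != 7L)
    stop("expected exactly 7 prediction-call columns, got ", length(call_cols))
  n_del <- rowSums(as.matrix(pred[call_cols]) != 0)
  pred$consequence %in% lof |
    (pred$consequence == "missense" & n_del >= min_calls)
}

#' Apply site-level quality control
#'
#' Filters a set of biallelic sites against depth bounds, overall
#' missingness, exact Hardy-Weinberg equilibrium in controls (overall and
#' per stratum), and case/control differential missingness (overall and per
#' stratum). Non-autosomal or multiallelic records are rejected outright.
#' A rejected site is attributed to the first filter it fails, in the order
#' `structure`, `depth`, `missingness`, `hwe`, `diff_missing`, so rejection
#' counts partition the rejected sites.
#'
#' @param sites Data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `dp` (total summed depth).
#' @param geno Integer dosage matrix, samples x sites, columns named by
#'   `sites$id`; `NA` marks missing genotypes.
#' @param phenotypes Data frame with columns `sample`, `status`, `stratum`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `pass` (logical named by site id), `counts` (named
#'   integer rejection counts), and `report` (one row per site and filter,
#'   columns `site`, `filter`, `value`, `verdict`).
#' @export
apply_site_qc <- function(sites, geno, phenotypes,
                          thresholds = qc_thresholds()) {
  stopifnot(nrow(sites) == ncol(geno), nrow(phenotypes) == nrow(geno))
  if (!is.null(colnames(geno)) && !identical(colnames(geno), sites$id))
    stop("genotype columns misaligned with site table")
  status <- phenotypes$status
  stratum <- as.character(phenotypes$stratum)
  is_ctrl <- status == "control"
  autosomes <- as.character(1:22)
  m <- nrow(sites)

  chrom <- sub("^chr", "", as.character(sites$chrom))
  ok_struct <- chrom %in% autosomes & !grepl(",", sites$alt) &
    nchar(sites$ref) >= 1 & nchar(sites$alt) >= 1
  ok_depth <- sites$dp >= thresholds$depth_low & sites$dp <= thresholds$depth_high

  miss_rate <- colMeans(is.na(geno))
  ok_miss <- miss_rate <= thresholds$max_missing

  hwe_p <- vapply(seq_len(m), function(j) {
    p_all <- strata_hwe_p(geno[, j], is_ctrl, stratum)
    min(p_all)
  }, numeric(1))
  ok_hwe <- hwe_p >= thresholds$hwe_alpha

  dm_p <- vapply(seq_len(m), function(j) {
    p_overall <- diff_missingness_p(geno[, j], status)
    p_str <- vapply(unique(stratum), function(s) {
      sel <- stratum == s
      if (!any(status[sel] == "case") || !any(status[sel] == "control")) return(1)
      diff_missingness_p(geno[sel, j], status[sel])
    }, numeric(1))
    min(p_overall, p_str)
  }, numeric(1))
  ok_dm <- dm_p >= thresholds$diff_missing_alpha

  pass <- ok_struct & ok_depth & ok_miss & ok_hwe & ok_dm
  first_fail <- rep(NA_character_, m)
  first_fail[!ok_dm] <- "diff_missing"
  first_fail[!ok_hwe] <- "hwe"
  first_fail[!ok_miss] <- "missingness"
  first_fail[!ok_depth] <- "depth"
  first_fail[!ok_struct] <- "structure"
  counts <- c(structure = 0L, depth = 0L, missingness = 0L, hwe = 0L,
              diff_missing = 0L)
  tab <- table(first_fail)
  counts[names(tab)] <- as.integer(tab)

  report <- data.frame(
    site = rep(sites$id, times = 5L),
    filter = rep(c("structure", "depth", "missingness", "hwe", "diff_missing"),
                 each = m),
    value = c(as.numeric(ok_struct), sites$dp, miss_rate, hwe_p, dm_p),
    verdict = c(ok_struct, ok_depth, ok_miss, ok_hwe, ok_dm),
    stringsAsFactors = FALSE)

  names(pass) <- sites$id
  list(pass = pass, counts = counts, report = report)
}

# HWE exact p in controls, overall and per stratum; returns the vector of
# p-values (a site failing in any stratum is removed by the caller's min).
strata_hwe_p <- function(g, is_ctrl, stratum) {
  one <- function(sel) {
    gc <- g[sel & is_ctrl]
    gc <- gc[!is.na(gc)]
    if (length(gc) == 0) return(1)
    hwe_exact_p(sum(gc == 0), sum(gc == 1), sum(gc == 2))
  }
  c(one(rep(TRUE, length(g))),
    vapply(unique(stratum), function(s) one(stratum == s), numeric(1)))
}
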