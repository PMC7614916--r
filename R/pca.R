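#' Select common SNPs for the ancestry panel
#'
#' Restricts a site set to single-nucleotide variants with cohort-wide minor
#' allele frequency at or above `min_maf` (inclusive), the panel from which
#' population-structure principal components are computed.
#'
#' @param sites Site table (`id`, `ref`, `alt`).
#' @param geno Dosage matrix aligned to `sites` columns.
#' @param min_maf Minimum overall MAF (default 0.005).
#' @return Character vector of retained site ids.
#' @export
select_common_snps <- function(sites, geno, min_maf = 0.005) {
  is_snv <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L &
    !grepl(",", sites$alt)
  f <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  sites$id[is_snv & !is.na(maf) & maf >= min_maf]
}

#' Window-based LD pruning
#'
#' Slides a window of `window` variants (ordered as given, i.e. by position)
#' in steps of `step`; within a window, for every pair with squared Pearson
#' correlation above `r2_max` the later variant is dropped. Deterministic:
#' the earlier-position variant of a correlated pair is always kept.
#'
#' @param geno Dosage matrix of common SNPs (samples x variants), columns
#'   position-ordered and named.
#' @param r2_max Maximum tolerated squared correlation (default 0.2).
#' @param window Window size in variants (default 50).
#' @param step Window step in variants (default 5).
#' @return Character vector of retained column names (or indices if the
#'   matrix is unnamed).
#' @export
ld_prune <- function(geno, r2_max = 0.2, window = 50L, step = 5L) {
  m <- ncol(geno)
  if (m == 0L) return(character(0))
  ids <- colnames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(m))
  keep <- rep(TRUE, m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1L) {
      r2 <- suppressWarnings(stats::cor(geno[, idx, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      for (j in seq_along(idx)) {
        if (!keep[idx[j]]) next
        hits <- which(r2[j, ] > r2_max)
        hits <- hits[hits > j & keep[idx[hits]]]
        keep[idx[hits]] <- FALSE
      }
    }
    if (end == m) break
    start <- start + step
  }
  ids[keep]
}

#' Principal components of population structure
#'
#' Mean-imputes missing dosages per column, centers each variant at twice its
#' allele frequency and scales by `sqrt(2 p (1 - p))` (the unified genotype
#' scaling), then returns the leading principal-component scores from the
#' singular value decomposition. Each component's sign is fixed so its
#' largest-magnitude loading is positive, for reproducibility.
#'
#' @param geno Pruned common-SNP dosage matrix (samples x variants).
#' @param k Number of components (default 10); reduced with a warning when
#'   it exceeds the available rank.
#' @return List with `scores` (samples x k, columns `PC1..PCk`),
#'   `varexp` (proportion of variance per component).
#' @export
compute_pcs <- function(geno, k = 10L) {
  X <- as.matrix(geno)
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  p <- colMeans(X) / 2
  sdv <- sqrt(2 * p * (1 - p))
  use <- sdv > 0
  X <- sweep(X[, use, drop = FALSE], 2, 2 * p[use], "-")
  X <- sweep(X, 2, sdv[use], "/")
  sv <- svd(X, nu = min(nrow(X), ncol(X)), nv = 0)
  pos <- sv$d > max(sv$d) * 1e-8
  avail <- sum(pos)
  if (k > avail) {
    warning("requested ", k, " components but rank is ", avail)
    k <- avail
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention via loadings v = X^T u / d
  for (j in seq_len(k)) {
    v <- crossprod(X, sv$u[, j]) / sv$d[j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(geno)
  list(scores = scores, varexp = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Assemble the covariate matrix used by the association null model
#'
#' @param phenotypes Phenotype table with `sample` and `sex`.
#' @param pcs Result of [compute_pcs()] with rows aligned to `phenotypes`.
#' @return Data frame: `sample`, `sex` (0/1 indicator, male = 1), PC scores.
#' @export
build_covariates <- function(phenotypes, pcs) {
  stopifnot(nrow(phenotypes) == nrow(pcs$scores))
  data.frame(sample = phenotypes$sample,
             sex = as.integer(phenotypes$sex == "male"),
             pcs$scores, stringsAsFactors = FALSE)
}
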