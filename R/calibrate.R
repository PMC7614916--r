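#' Type-I error calibration study for the region tests
#'
#' Simulates null collapsing units (no genotype-phenotype association) and
#' measures each test's rejection rate at nominal alpha levels. The study
#' runs at reduced sample size for tractability; to keep the tests in the
#' same asymptotic regime as a full-size cohort, the rare-allele frequency
#' spectrum is scaled so that per-variant minor-allele *counts* match those
#' of a cohort of `full_size` samples (a frequency drawn for the full
#' cohort is multiplied by `full_size / n`, capped at 0.45). Variants
#' monomorphic in the sampled cohort are dropped, as they would be absent
#' from any real callset.
#'
#' @param n_regions Number of null regions simulated (each with its own
#'   phenotype draw).
#' @param n Samples per region replicate.
#' @param case_fraction Case share of the cohort (default 3955/5774).
#' @param m_range Range of variants per region.
#' @param maf_beta,maf_range Rare-allele spectrum (full-cohort scale).
#' @param full_size Cohort size whose allele-count spectrum is emulated.
#' @param tests Tests to calibrate.
#' @param n_perm Permutations for the VT test.
#' @param alpha Alpha levels at which rejection rates are reported.
#' @param seed Seed.
#' @return List with `rates` (tests x alpha matrix), `n_regions`, and the
#'   per-region p-value matrix `p`.
#' @export
calibrate_type1 <- function(n_regions = 2000L, n = 500L,
                            case_fraction = 3955 / 5774,
                            m_range = c(3L, 12L),
                            maf_beta = c(0.3, 30),
                            maf_range = c(1e-4, 0.05),
                            full_size = 5774L,
                            tests = c("SKATO", "SKAT", "CMC", "VT"),
                            n_perm = 200L,
                            alpha = c(0.05, 0.01),
                            seed = 1L) {
  scale <- full_size / n
  cfgt <- rv_test_config(n_perm = n_perm, perm_seed = seed)
  p_lo <- stats::pbeta(maf_range[1], maf_beta[1], maf_beta[2])
  p_hi <- stats::pbeta(maf_range[2], maf_beta[1], maf_beta[2])
  pvals <- matrix(NA_real_, n_regions, length(tests),
                  dimnames = list(NULL, tests))
  with_seed(seed, {
    for (b in seq_len(n_regions)) {
      m <- sample(m_range[1]:m_range[2], 1)
      p <- stats::qbeta(stats::runif(m, p_lo, p_hi), maf_beta[1], maf_beta[2])
      p <- pmin(p * scale, 0.45)
      G <- vapply(p, function(pp) stats::rbinom(n, 2L, pp), integer(n))
      colnames(G) <- paste0("v", seq_len(m))
      poly <- colSums(G) > 0
      if (sum(poly) < 2L) next
      G <- G[, poly, drop = FALSE]
      y <- stats::rbinom(n, 1L, case_fraction)
      if (length(unique(y)) < 2L) next
      nl <- rv_null_model(status ~ 1, data.frame(status = y))
      maf <- pmax(pmin(colMeans(G) / 2, 0.5), 1e-4)
      rmx <- structure(list(unit = "u", class = "NULLSIM", G = G, maf = maf,
                            weights = stats::dbeta(maf, 1, 25)),
                       class = "region_matrix")
      res <- suppressWarnings(rv_scan(list(rmx), nl, tests = tests,
                                      config = cfgt))$results
      pvals[b, ] <- res$p[match(tests, res$test)]
    }
  })
  rates <- sapply(alpha, function(a) colMeans(pvals < a, na.rm = TRUE))
  colnames(rates) <- paste0("alpha", alpha)
  list(rates = rates, n_regions = sum(stats::complete.cases(pvals)),
       p = pvals)
}

#' Genomic inflation with and without ancestry adjustment
#'
#' Simulates a strongly stratified null cohort (Balding-Nichols divergence
#' `fst`, stratum-biased case sampling), computes ancestry PCs from the
#' common-SNP panel, and contrasts the genomic inflation of the
#' collapsed-carrier test with and without the PC covariates.
#'
#' @param n_regions Null regions (ORF + UTR3 + preMIR split internally).
#' @param n_cases,n_controls Cohort arm sizes.
#' @param fst Between-stratum divergence (default 0.1, strong).
#' @param stratum_case_bias Stratum/status confounding strength.
#' @param n_pcs PCs used in the adjusted model.
#' @param seed Seed.
#' @return List with `lambda_adjusted`, `lambda_unadjusted`, `n_units`.
#' @export
stratified_lambda <- function(n_regions = 450L, n_cases = 350L,
                              n_controls = 250L, fst = 0.1,
                              stratum_case_bias = 1, n_pcs = 10L,
                              seed = 1L) {
  thirds <- c(ORF = ceiling(n_regions / 3), UTR3 = ceiling(n_regions / 3),
              preMIR = n_regions - 2 * ceiling(n_regions / 3))
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_strata = 4, n_regions = thirds,
                    variants_per_region = c(4, 12),
                    maf_range = c(0.002, 0.05),
                    common_snp_count = 1500, fst = fst,
                    stratum_case_bias = stratum_case_bias,
                    plant_gain = FALSE, seed = seed)
  co <- simulate_cohort(cfg)
  pcs <- compute_pcs(co$panel_geno, k = n_pcs)
  dat <- data.frame(status = co$phenotypes$status,
                    sex = as.integer(co$phenotypes$sex == "male"),
                    pcs$scores)
  null_adj <- rv_null_model(
    stats::reformulate(c("sex", paste0("PC", seq_len(n_pcs))), "status"), dat)
  null_raw <- rv_null_model(status ~ 1, dat)
  regions <- lapply(split(co$sites$id, co$sites$region), function(vs) {
    if (length(vs) < 2) return(NULL)
    G <- co$geno[, vs, drop = FALSE]
    maf <- pmax(vapply(vs, function(v)
      control_maf(co$geno[, v], co$phenotypes$status), numeric(1)), 1e-4)
    structure(list(unit = vs[1], class = "NULLSIM", G = G, maf = maf,
                   weights = stats::dbeta(maf, 1, 25)),
              class = "region_matrix")
  })
  regions <- Filter(Negate(is.null), regions)
  p_adj <- vapply(regions, function(rm)
    suppressWarnings(burden_cmc_test(rm, null_adj))$p, numeric(1))
  p_raw <- vapply(regions, function(rm)
    suppressWarnings(burden_cmc_test(rm, null_raw))$p, numeric(1))
  list(lambda_adjusted = qq_lambda(p_adj)$lambda,
       lambda_unadjusted = qq_lambda(p_raw)$lambda,
       n_units = length(regions))
}

#' Parameter-recovery study for a planted protective 3'UTR
#'
#' Repeatedly simulates a reduced-scale cohort containing one protective
#' 3'UTR among null 3'UTRs, and reports how often the planted unit ranks
#' first among all 3'UTR units by the collapsed-carrier (CMC) and SKAT-O
#' p-values.
#'
#' @param n_reps Number of replicates.
#' @param n_cases,n_controls Reduced-scale cohort arms.
#' @param n_utrs Total 3'UTR units per replicate (1 planted).
#' @param or,carrier_freq Planted carrier odds ratio and control carrier
#'   frequency.
#' @param seed Seed.
#' @return List with `rank1_cmc`, `rank1_skato` (fractions of replicates
#'   where the planted unit ranks first) and per-replicate ranks.
#' @export
planted_recovery <- function(n_reps = 50L, n_cases = 4000L,
                             n_controls = 2000L, n_utrs = 20L,
                             or = 0.23, carrier_freq = 0.02, seed = 1L) {
  ranks <- matrix(NA_integer_, n_reps, 2,
                  dimnames = list(NULL, c("CMC", "SKATO")))
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                      n_strata = 2,
                      n_regions = c(ORF = 1, UTR3 = n_utrs, preMIR = 1),
                      variants_per_region = c(3, 12),
                      maf_range = c(5e-4, 0.01),
                      common_snp_count = 10, fst = 0.005,
                      stratum_case_bias = 0,
                      effect_spec = list(list(gene = "gene001",
                                              class = "UTR3", or = or,
                                              carrier_freq = carrier_freq,
                                              n_variants = 11)),
                      plant_gain = FALSE,
                      seed = seed + 7919L * r)
    co <- simulate_cohort(cfg)
    nl <- rv_null_model(status ~ 1,
                        data.frame(status = co$phenotypes$status))
    utr_regions <- split(co$sites$id[co$sites$class == "UTR3"],
                         co$sites$region[co$sites$class == "UTR3"])
    res <- lapply(names(utr_regions), function(rn) {
      vs <- utr_regions[[rn]]
      maf <- vapply(vs, function(v)
        control_maf(co$geno[, v], co$phenotypes$status), numeric(1))
      keep <- maf <= 0.01
      if (sum(keep) < 2) return(NULL)
      maf <- pmax(maf[keep], 1e-4)
      rmx <- structure(list(unit = rn, class = "UTR3",
                            G = co$geno[, vs[keep], drop = FALSE],
                            maf = maf, weights = stats::dbeta(maf, 1, 25)),
                       class = "region_matrix")
      data.frame(unit = rn,
                 p_cmc = suppressWarnings(burden_cmc_test(rmx, nl))$p,
                 p_skato = suppressWarnings(skat_o_test(rmx, nl))$p)
    })
    res <- do.call(rbind, res)
    if (is.null(res) || !"gene001.utr3" %in% res$unit) next
    ranks[r, "CMC"] <- rank(res$p_cmc, ties.method = "min")[
      res$unit == "gene001.utr3"]
    ranks[r, "SKATO"] <- rank(res$p_skato, ties.method = "min")[
      res$unit == "gene001.utr3"]
  }
  list(rank1_cmc = mean(ranks[, "CMC"] == 1, na.rm = TRUE),
       rank1_skato = mean(ranks[, "SKATO"] == 1, na.rm = TRUE),
       ranks = ranks)
}
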