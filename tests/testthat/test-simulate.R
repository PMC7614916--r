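small_cfg <- function(...) {
  sim_config(n_cases = 150, n_controls = 100, n_strata = 2,
             n_regions = c(ORF = 4, UTR3 = 4, preMIR = 2),
             common_snp_count = 120, seed = 5, ...)
}

test_that("configuration rejects degenerate settings", {
  expect_error(sim_config(n_cases = 0), "non-empty")
  expect_error(sim_config(n_regions = c(ORF = 0, UTR3 = 1, preMIR = 1)),
               "positive")
  expect_error(sim_config(effect_spec = list(list(gene = "g", class = "UTR3",
                                                  or = -1))), "positive")
})

test_that("identical seeds give byte-identical files, new seeds differ", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  d3 <- file.path(tempdir(), "simC")
  unlink(c(d1, d2, d3), recursive = TRUE)
  co1 <- simulate_cohort(small_cfg(), dir = d1)
  co2 <- simulate_cohort(small_cfg(), dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                   unname(tools::md5sum(file.path(d2, "cohort.vcf"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "phenotypes.tsv"))),
                   unname(tools::md5sum(file.path(d2, "phenotypes.tsv"))))
  cfg3 <- small_cfg(); cfg3$seed <- 6
  simulate_cohort(cfg3, dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("the VCF round-trips through the reader", {
  d <- file.path(tempdir(), "simRT"); unlink(d, recursive = TRUE)
  co <- simulate_cohort(small_cfg(), dir = d)
  back <- read_vcf_cohort(file.path(d, "cohort.vcf"))
  expect_equal(back$sites$pos, co$sites$pos)
  expect_equal(back$sites$dp, co$sites$dp)
  expect_equal(unname(back$geno), unname(co$geno))
  phen <- read_phenotypes(file.path(d, "phenotypes.tsv"))
  expect_equal(phen$status, co$phenotypes$status)
})

test_that("annotation resources are consistent with the cohort", {
  cfg <- small_cfg()
  res <- simulate_annotation_resources(cfg)
  expect_equal(nrow(res$genes), 4)
  expect_equal(length(res$utr_seqs), 4)
  expect_equal(unname(nchar(res$utr_seqs)),
               res$genes$utr3_end - res$genes$utr3_start)
  expect_true(all(nchar(res$seed_catalog$seed) == 7))
  expect_false(any(grepl("[^ACGU]", res$seed_catalog$seed)))
  # conserved-site intervals carry genuine seed matches
  for (i in seq_len(nrow(res$conserved_sites))) {
    cs <- res$conserved_sites[i, ]
    hept <- seed_to_site(res$seed_catalog$seed[
      match(cs$mirna, res$seed_catalog$mirna)])
    window <- substr(res$utr_seqs[[cs$utr]], cs$start + 1, cs$end)
    if (cs$start >= nchar(res$utr_seqs[[cs$utr]]) - 30) next  # gain plant zone
    expect_equal(window, hept)
  }
  co <- simulate_cohort(cfg, resources = res)
  # every variant maps into its declared region's class
  expect_true(all(co$sites$class %in% c("ORF", "UTR3", "preMIR")))
  # prediction table covers exactly the coding variants
  expect_setequal(co$prediction$variant,
                  co$sites$id[co$sites$class == "ORF"])
  expect_equal(ncol(co$prediction), 9)   # variant, consequence, 7 calls
  # UTR variant reference alleles match the UTR sequences
  utr_sites <- co$sites[co$sites$class == "UTR3", ]
  gi <- match(sub("\\.utr3.*$", "", utr_sites$region), res$genes$gene)
  local <- utr_sites$pos - res$genes$utr3_start[gi]
  expect_true(all(substr(res$utr_seqs[gi], local, local) == utr_sites$ref))
})

test_that("the planted gain variant is a real gain under re-scanning", {
  cfg <- small_cfg()
  res <- simulate_annotation_resources(cfg)
  pg <- res$planted_gain
  expect_false(is.null(pg))
  ev <- call_mre_gain(res$utr_seqs[[pg$gene]], pg$utr_pos, pg$ref, pg$alt,
                      res$seed_catalog)
  expect_true(pg$mirna %in% ev$mirna)
  # and the brute-force oracle agrees
  want <- mre_gain_oracle(res$utr_seqs[[pg$gene]], pg$utr_pos, pg$ref,
                          pg$alt, res$seed_catalog)
  expect_true(paste(pg$mirna, pg$window_start) %in% want)
  # the variant reaches the emitted VCF
  co <- simulate_cohort(cfg, resources = res)
  expect_true(paste0(pg$gene, ".utr3_gain") %in% co$sites$id)
})

test_that("empirical MAFs track the truth spectrum at n >= 5000", {
  # fst = 0 isolates the spectrum pathway: with divergence the realized
  # stratum-mixed frequency is the (separately tested) target, not the drawn
  # global MAF
  cfg <- sim_config(n_cases = 3500, n_controls = 1500, n_strata = 2,
                    n_regions = c(ORF = 6, UTR3 = 6, preMIR = 3),
                    common_snp_count = 10, fst = 0, plant_gain = FALSE,
                    seed = 9)
  co <- simulate_cohort(cfg)
  emp <- colMeans(co$geno, na.rm = TRUE) / 2
  truth <- co$truth$maf$true_maf[match(colnames(co$geno),
                                       co$truth$maf$variant)]
  expect_gt(cor(emp, truth, method = "spearman"), 0.95)
})

test_that("a null region's empirical carrier OR is consistent with 1", {
  cfg <- sim_config(n_cases = 2000, n_controls = 2000, n_strata = 2,
                    n_regions = c(ORF = 1, UTR3 = 1, preMIR = 1),
                    variants_per_region = c(4, 6), common_snp_count = 10,
                    stratum_case_bias = 0, fst = 0, plant_gain = FALSE,
                    seed = 13)
  co <- simulate_cohort(cfg)
  vs <- co$sites$id[co$sites$region == "gene001.utr3"]
  tb <- carrier_table(co$geno[, vs], co$phenotypes)
  or <- odds_ratio(tb)
  expect_gte(1, or$lo)
  expect_lte(1, or$hi)
})

test_that("planted carrier odds ratios are recovered at nominal coverage", {
  # Woolf CI coverage of the configured OR across replicates, reduced n
  set.seed(51)
  ors <- c(0.2, 0.5, 1, 2, 5)
  cover <- hits <- 0
  for (or_true in ors) {
    for (rep in 1:40) {
      n1 <- 1500; n0 <- 1000; q0 <- 0.03
      odds1 <- or_true * q0 / (1 - q0)
      q1 <- odds1 / (1 + odds1)
      a <- rbinom(1, n1, q1); c_ <- rbinom(1, n0, q0)
      if (a == 0 || c_ == 0) next
      est <- odds_ratio(carrier_table_counts(a, n1, c_, n0))
      hits <- hits + 1
      cover <- cover + (est$lo <= or_true && or_true <= est$hi)
    }
  }
  expect_gt(hits, 150)
  ci <- qbinom(c(0.025, 0.975), hits, 0.95) / hits
  expect_gte(cover / hits, ci[1] - 0.01)
})

test_that("planted effect follows the configured OR through the generator", {
  cfg <- sim_config(n_cases = 8000, n_controls = 4000, n_strata = 3,
                    n_regions = c(ORF = 1, UTR3 = 1, preMIR = 1),
                    common_snp_count = 10, plant_gain = FALSE,
                    effect_spec = list(list(gene = "gene001", class = "UTR3",
                                            or = 0.23, carrier_freq = 0.02,
                                            n_variants = 11)),
                    seed = 17)
  co <- simulate_cohort(cfg)
  vs <- co$sites$id[co$sites$region == "gene001.utr3"]
  or <- odds_ratio(carrier_table(co$geno[, vs], co$phenotypes))
  expect_gte(0.23, or$lo)
  expect_lte(0.23, or$hi)
})
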