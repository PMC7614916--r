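# the published discovery counts: IL18RAP 3'UTR 6/3,955 cases vs 12/1,819
# controls; NEK1 127 vs 19; SOD1 36 vs 0
tabs <- load_discovery_tables()

test_that("carrier frequencies reproduce the printed percentages", {
  expect_equal(carrier_frequency(tabs$IL18RAP_3UTR, "case"), 0.15)
  expect_equal(carrier_frequency(tabs$IL18RAP_3UTR, "control"), 0.66)
  expect_equal(carrier_frequency(tabs$NEK1_ORF, "case"), 3.21)
  expect_equal(carrier_frequency(tabs$NEK1_ORF, "control"), 1.04)
  expect_equal(carrier_frequency(tabs$SOD1_ORF, "case"), 0.91)
  empty <- carrier_table_counts(0, 100, 0, 50)
  expect_equal(carrier_frequency(empty, "case"), 0)
})

test_that("odds ratios reproduce the printed estimates", {
  expect_equal(round(odds_ratio(tabs$IL18RAP_3UTR)$or, 2), 0.23)
  expect_equal(round(odds_ratio(tabs$NEK1_ORF)$or, 2), 3.14)
  sod1 <- odds_ratio(tabs$SOD1_ORF)
  expect_equal(sod1$correction, "haldane")
  expect_equal(round(sod1$or, 2), 33.89)
  # Haldane arithmetic from first principles
  expect_equal(sod1$or, (36.5 * 1819.5) / (3919.5 * 0.5))
  expect_equal(odds_ratio(tabs$NEK1_ORF)$correction, "none")
  or <- odds_ratio(tabs$IL18RAP_3UTR)
  expect_true(or$lo <= or$or && or$or <= or$hi)
  expect_error(odds_ratio(carrier_table_counts(0, 100, 0, 100)), "margin")
})

test_that("fold enrichment and cohort-size ratio match the printed values", {
  expect_equal(fold_enrichment(tabs$IL18RAP_3UTR), 4.35)
  expect_equal(round(3955 / 1819, 2), 2.17)
  even <- carrier_table_counts(10, 100, 10, 100)
  expect_equal(fold_enrichment(even), 1)
  expect_error(fold_enrichment(carrier_table_counts(0, 100, 5, 100)),
               "undefined")
})

test_that("Yates chi-square matches the continuity-corrected formula", {
  # independent arithmetic oracle for the corrected statistic
  yates_oracle <- function(a, b, c, d) {
    m <- matrix(c(a, c, b, d), 2, 2)
    ex <- outer(rowSums(m), colSums(m)) / sum(m)
    x2 <- sum((pmax(abs(m - ex) - 0.5, 0))^2 / ex)
    pchisq(x2, df = 1, lower.tail = FALSE)
  }
  t1 <- tabs$IL18RAP_3UTR
  expect_equal(chi2_yates(t1), yates_oracle(t1$a, t1$b, t1$c, t1$d),
               tolerance = 1e-10)
  # perfectly proportional table: p = 1
  prop <- carrier_table_counts(10, 110, 20, 220)
  expect_equal(chi2_yates(prop), 1, tolerance = 1e-9)
  # the correction is conservative relative to the uncorrected chi-square
  set.seed(33)
  for (i in 1:100) {
    cells <- rmultinom(1, 400, c(0.1, 0.4, 0.15, 0.35))[, 1] + 1
    tb <- carrier_table_counts(cells[1], cells[1] + cells[2],
                               cells[3], cells[3] + cells[4])
    p_un <- suppressWarnings(chisq.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2),
                                        correct = FALSE)$p.value)
    expect_gte(chi2_yates(tb) + 1e-12, p_un)
  }
})

test_that("Fisher exact agrees with stats::fisher.test and enumeration", {
  expect_equal(fisher_exact(carrier_table_counts(1, 2, 1, 2)), 1)
  f55 <- fisher_exact(carrier_table_counts(5, 5, 0, 5))
  expect_equal(f55, fisher.test(matrix(c(5, 0, 0, 5), 2))$p.value,
               tolerance = 1e-9)
  expect_equal(round(f55, 5), 0.00794)
  # symmetry: swapping both rows and both columns leaves p unchanged
  tb <- carrier_table_counts(7, 20, 3, 30)
  swapped <- carrier_table_counts(tb$d, tb$d + tb$c, tb$b, tb$b + tb$a)
  expect_equal(fisher_exact(tb), fisher_exact(swapped), tolerance = 1e-12)
  # sweep against stats::fisher.test over random small tables
  set.seed(34)
  for (i in 1:200) {
    cells <- as.vector(rmultinom(1, sample(8:60, 1), runif(4, 0.1, 1)))
    tb <- carrier_table_counts(cells[1], cells[1] + cells[2],
                               cells[3], cells[3] + cells[4])
    expect_equal(fisher_exact(tb),
                 fisher.test(matrix(c(tb$a, tb$c, tb$b, tb$d), 2))$p.value,
                 tolerance = 1e-7, info = paste(cells, collapse = ","))
  }
})

test_that("odds ratio inverts under table transposition", {
  set.seed(35)
  for (i in 1:50) {
    cells <- as.vector(rmultinom(1, 200, runif(4, 0.2, 1))) + 1
    tb <- carrier_table_counts(cells[1], cells[1] + cells[2],
                               cells[3], cells[3] + cells[4])
    tr <- carrier_table_counts(cells[3], cells[3] + cells[4],
                               cells[1], cells[1] + cells[2])
    expect_equal(odds_ratio(tb)$or, 1 / odds_ratio(tr)$or, tolerance = 1e-10)
  }
})

test_that("carrier tables from genotype matrices count samples once", {
  status <- rep(c("case", "control"), c(6, 4))
  phen <- data.frame(sample = 1:10, status = status)
  G <- matrix(0L, 10, 3)
  G[1, 1] <- 1L                 # one case heterozygous at one variant
  tb <- carrier_table(G, phen)
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(1, 5, 0, 4))
  G[1, 2] <- 2L                 # same sample carries a second variant
  tb2 <- carrier_table(G, phen)
  expect_equal(tb2$a, 1)
  G[8, 3] <- NA                 # missing counts as non-carrying
  expect_equal(carrier_table(G, phen)$c, 0)
})

test_that("planted discovery-sized cohort recovers its carrier table", {
  n_case <- 3955; n_ctrl <- 1819
  phen <- data.frame(sample = seq_len(n_case + n_ctrl),
                     status = rep(c("case", "control"), c(n_case, n_ctrl)))
  G <- matrix(0L, n_case + n_ctrl, 2)
  G[1:6, 1] <- 1L                                   # 6 case carriers
  G[n_case + (1:12), 2] <- 1L                       # 12 control carriers
  tb <- carrier_table(G, phen, unit = "planted")
  expect_equal(c(tb$a, tb$b, tb$c, tb$d), c(6, 3949, 12, 1807))
  expect_equal(round(odds_ratio(tb)$or, 2), 0.23)
})

test_that("pooled joint analysis sums cells and preserves symmetry", {
  tb <- carrier_table_counts(8, 100, 16, 200)
  twice <- pooled_joint(list(tb, tb))
  expect_equal(twice$or$or, odds_ratio(tb)$or)
  expect_equal(twice$table$a, 16)
  mirror <- carrier_table_counts(16, 200, 8, 100)
  both <- pooled_joint(list(tb, mirror))
  expect_equal(both$or$or, 1, tolerance = 1e-10)
  # cells are conserved
  set.seed(36)
  tabs3 <- lapply(1:3, function(i) {
    cells <- as.vector(rmultinom(1, 300, runif(4, 0.2, 1))) + 1
    carrier_table_counts(cells[1], cells[1] + cells[2],
                         cells[3], cells[3] + cells[4])
  })
  pool <- pooled_joint(tabs3)$table
  expect_equal(pool$a, sum(vapply(tabs3, `[[`, numeric(1), "a")))
  expect_equal(pool$d, sum(vapply(tabs3, `[[`, numeric(1), "d")))
})

test_that("stratified forest reproduces the pooled discovery estimate", {
  # three strata that sum to the printed discovery cells
  strata <- list(
    s1 = carrier_table_counts(2, 1500, 5, 700),
    s2 = carrier_table_counts(3, 1455, 4, 619),
    s3 = carrier_table_counts(1, 1000, 3, 500))
  forest <- stratified_forest(strata)
  expect_equal(nrow(forest), 4)
  pooled <- forest[forest$stratum == "pooled", ]
  expect_equal(c(pooled$a, pooled$c), c(6, 12))
  expect_equal(round(pooled$or, 2), 0.23)
  # a stratum with a zero cell carries the Haldane flag
  strata$s4 <- carrier_table_counts(0, 50, 1, 50)
  forest2 <- stratified_forest(strata)
  expect_true(forest2$corrected[forest2$stratum == "s4"])
  single <- stratified_forest(strata["s1"])
  expect_equal(single$or[1], odds_ratio(strata$s1)$or)
})
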