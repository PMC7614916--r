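test_that("null model: intercept-only fit returns the case fraction", {
  status <- rep(c(1, 0), c(30, 70))
  nm <- make_null(status)
  expect_equal(unname(fitted(nm)), rep(0.3, 100))
  expect_equal(sum(residuals(nm)), 0, tolerance = 1e-10)
  expect_error(make_null(rep(1, 50)), "both classes")
  expect_error(rv_null_model(status ~ 1, data.frame(status = rep(2, 10))),
               "binary")
})

test_that("null model adjusts for a stratifying covariate", {
  set.seed(20)
  pc1 <- rnorm(400)
  y <- rbinom(400, 1, plogis(-0.3 + 1.2 * pc1))
  nm <- rv_null_model(status ~ PC1, data.frame(status = y, PC1 = pc1))
  nm0 <- make_null(y)
  expect_gt(stats::logLik(nm$glm), stats::logLik(nm0$glm))
  expect_gt(cor(fitted(nm), pc1), 0.5)
})

test_that("burden/CMC score test matches the permutation oracle", {
  # moderate association: asymptotic and permutation p agree within MC error
  set.seed(21)
  n <- 200
  G <- make_geno(n, rep(0.03, 5), seed = 21)
  carrier <- rowSums(G) > 0
  y <- rbinom(n, 1, ifelse(carrier, 0.65, 0.45))
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  res <- burden_cmc_test(rm, nm)
  cvec <- as.numeric(carrier)
  perm <- permutation_p(function(r) abs(sum(cvec * r)), nm,
                        n_perm = 4000, seed = 2)
  se <- sqrt(perm * (1 - perm) / 4000)
  expect_lt(abs(res$p - perm), 3 * se + 1e-3)

  # complete case/control separation: extreme asymptotic p, floored perm p
  G2 <- matrix(0L, 40, 2, dimnames = list(NULL, c("v1", "v2")))
  G2[1:20, 1] <- 1L
  y2 <- rep(c(1, 0), each = 20)
  nm2 <- make_null(y2)
  rm2 <- make_region_matrix(G2, ifelse(y2 == 1, "case", "control"))
  res2 <- burden_cmc_test(rm2, nm2)
  expect_lt(res2$p, 1e-6)
  c2 <- as.numeric(rowSums(G2) > 0)
  expect_equal(permutation_p(function(r) abs(sum(c2 * r)), nm2,
                             n_perm = 1000, seed = 3), 1 / 1001)

  # carriers split evenly by status: no signal
  G3 <- matrix(0L, 40, 2, dimnames = list(NULL, c("v1", "v2")))
  G3[c(1:5, 21:25), 1] <- 1L
  res3 <- burden_cmc_test(make_region_matrix(G3, ifelse(y2 == 1, "case",
                                                        "control")), nm2)
  expect_gt(res3$p, 0.9)

  # zero carriers: p = 1 with a warning flag
  G4 <- matrix(0L, 40, 2, dimnames = list(NULL, c("v1", "v2")))
  expect_warning(res4 <- burden_cmc_test(
    make_region_matrix(G4, ifelse(y2 == 1, "case", "control")), nm2),
    "no carriers")
  expect_equal(res4$p, 1)
})

test_that("covariate adjustment removes a confounded carrier signal", {
  set.seed(22)
  n <- 600
  stratum <- rep(0:1, each = n / 2)
  y <- rbinom(n, 1, ifelse(stratum == 1, 0.7, 0.3))
  G <- sapply(1:4, function(j) rbinom(n, 2, ifelse(stratum == 1, 0.06, 0.002)))
  colnames(G) <- paste0("v", 1:4)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  p_unadj <- burden_cmc_test(rm, make_null(y))$p
  nm_adj <- rv_null_model(status ~ PC1, data.frame(status = y, PC1 = stratum))
  p_adj <- burden_cmc_test(rm, nm_adj)$p
  expect_lt(p_unadj, 0.01)
  expect_gt(p_adj, 0.05)
})

test_that("SKAT reduces to the single-variant score test at rank one", {
  set.seed(23)
  n <- 300
  g <- rbinom(n, 2, 0.05)
  G <- cbind(v1 = g, v2 = 0L, v3 = 0L)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * g))
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  res <- skat_test(rm, nm)
  u <- sum(rm$weights[1] * g * residuals(nm))
  v <- as.numeric(rvregion:::score_sigma(nm, rm$weights[1] * g))
  expect_equal(res$p, pchisq(u^2 / v, df = 1, lower.tail = FALSE),
               tolerance = 1e-5)
})

test_that("SKAT agrees with its permutation oracle on a 200-sample fixture", {
  set.seed(24)
  n <- 200
  G <- make_geno(n, c(0.02, 0.05, 0.01, 0.03), seed = 24)
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * (rowSums(G) > 0)))
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  res <- skat_test(rm, nm)
  Gw <- rvregion:::geno0(G) %*% diag(rm$weights)
  perm <- permutation_p(function(r) sum(crossprod(Gw, r)^2), nm,
                        n_perm = 4000, seed = 5)
  se <- sqrt(perm * (1 - perm) / 4000)
  expect_lt(abs(res$p - perm), 3 * se + 0.03)
})

test_that("SKAT-O endpoint grids reproduce SKAT and the weighted burden", {
  set.seed(25)
  n <- 250
  G <- make_geno(n, c(0.02, 0.04, 0.01, 0.02, 0.03), seed = 25)
  y <- rbinom(n, 1, plogis(-0.4 + 0.5 * (rowSums(G) > 0)))
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  expect_equal(skat_o_test(rm, nm, rv_test_config(rho_grid = 0))$p,
               skat_test(rm, nm)$p, tolerance = 1e-8)
  Gw <- rvregion:::geno0(G) %*% diag(rm$weights)
  b <- rowSums(Gw)
  u <- sum(b * residuals(nm))
  v <- as.numeric(rvregion:::score_sigma(nm, b))
  expect_equal(skat_o_test(rm, nm, rv_test_config(rho_grid = 1))$p,
               pchisq(u^2 / v, df = 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("SKAT-O respects the grid Bonferroni bound on random fixtures", {
  set.seed(26)
  for (i in 1:100) {
    n <- 150
    m <- sample(2:8, 1)
    G <- sapply(runif(m, 0.005, 0.06), function(p) rbinom(n, 2, p))
    colnames(G) <- paste0("v", seq_len(m))
    if (sum(colSums(G) > 0) < 2) next
    y <- rbinom(n, 1, 0.5)
    nm <- make_null(y)
    rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
    res <- suppressWarnings(skat_o_test(rm, nm))
    p_rho <- attr(res, "p_rho")
    if (is.null(p_rho)) next
    expect_lte(res$p, min(p_rho) * length(p_rho) + 1e-10)
    expect_gt(res$p, 0)
    expect_lte(res$p, 1)
  }
})

test_that("VT reduces to the burden statistic at a single threshold", {
  set.seed(27)
  n <- 200
  G <- make_geno(n, rep(0.02, 4), seed = 27)
  y <- rbinom(n, 1, 0.5)
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  rm$maf <- rep(0.02, 4)                     # all variants share one MAF
  res <- vt_test(rm, nm, rv_test_config(n_perm = 200))
  b <- rowSums(rvregion:::geno0(G))
  u <- sum(b * residuals(nm))
  v <- as.numeric(rvregion:::score_sigma(nm, b))
  expect_equal(res$stat, abs(u) / sqrt(v), tolerance = 1e-10)
})

test_that("VT permutation p matches complete enumeration on a tiny cohort", {
  set.seed(28)
  G <- matrix(rbinom(8 * 3, 1, 0.4), 8, 3, dimnames = list(NULL, paste0("v", 1:3)))
  G[1, 1] <- 1                                # ensure some carriers
  y <- rep(c(1, 0), each = 4)
  nm <- make_null(y)
  rm <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
  rm$maf <- c(0.05, 0.1, 0.2)                 # three thresholds
  p_exact <- vt_test(rm, nm, exact = TRUE)$p
  # oracle: recompute over all C(8,4) = 70 label assignments by hand
  B <- sapply(c(0.05, 0.1, 0.2), function(t)
    rowSums(rvregion:::geno0(G)[, rm$maf <= t, drop = FALSE]))
  sdv <- sqrt(diag(rvregion:::score_sigma(nm, B)))
  stat <- function(r) max(abs(crossprod(B, r)) / sdv)
  obs <- stat(residuals(nm))
  combos <- combn(8, 4)
  stats <- apply(combos, 2, function(idx) {
    r <- rep(-0.5, 8); r[idx] <- 0.5
    stat(r)
  })
  expect_equal(p_exact, mean(stats >= obs - 1e-12))
  # Monte-Carlo permutation approaches the enumerated value
  p_mc <- vt_test(rm, nm, rv_test_config(n_perm = 4000))$p
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 0.01)
  # same seed is bit-for-bit reproducible
  expect_identical(vt_test(rm, nm, rv_test_config(n_perm = 500))$p,
                   vt_test(rm, nm, rv_test_config(n_perm = 500))$p)
})

test_that("permutation p-values honor the (1 + hits)/(1 + n) convention", {
  nm <- make_null(rep(c(1, 0), each = 10))
  # statistic nobody can beat: p at the floor
  big <- permutation_p(function(r) -Inf, nm, n_perm = 500, seed = 1,
                       observed = 1)
  expect_equal(big, 1 / 501)
  # constant statistic: every permutation ties the observed value
  expect_equal(permutation_p(function(r) 1, nm, n_perm = 500, seed = 1), 1)
})

test_that("BH adjustment follows the step-up rule within families", {
  res <- data.frame(unit = c("a", "b", "c"), class = "UTR3", test = "SKATO",
                    p = c(0.01, 0.02, 0.03))
  out <- fdr_adjust(res)
  expect_equal(out$q, c(0.03, 0.03, 0.03))
  one <- fdr_adjust(data.frame(unit = "a", class = "X", test = "T", p = 0.2))
  expect_equal(one$q, 0.2)
  # q is order-preserving with p and families are corrected separately
  set.seed(29)
  res2 <- data.frame(unit = letters[1:20],
                     class = rep(c("UTR3", "ORF"), each = 10),
                     test = "SKAT", p = runif(20))
  out2 <- fdr_adjust(res2)
  for (cl in c("UTR3", "ORF")) {
    sub <- out2[out2$class == cl, ]
    expect_true(all(diff(sub$q[order(sub$p)]) >= -1e-12))
    expect_equal(sub$q, p.adjust(sub$p, "BH"))
    expect_true(all(sub$q >= sub$p - 1e-12))
  }
})

test_that("genomic inflation lambda matches its definition", {
  # median p of exactly 0.5 gives lambda 1
  p <- c(rep(0.5, 11))
  expect_equal(qq_lambda(p)$lambda, 1, tolerance = 1e-10)
  # halving p-values inflates lambda above 1
  set.seed(30)
  u <- runif(5000)
  expect_gt(qq_lambda(u / 2)$lambda, 1.1)
  expect_error(qq_lambda(c(rep(0.5, 10), 0)), "0, 1")
  expect_error(qq_lambda(rep(0.5, 5)), "at least 10")
  qq <- qq_lambda(u)$qq
  expect_equal(nrow(qq), 5000)
  # rows are ordered smallest-p first, so -log10 values descend
  expect_true(all(diff(qq$observed) <= 0))
})

test_that("scan object carries results, FDR and summaries", {
  set.seed(31)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  nm <- make_null(y)
  status <- ifelse(y == 1, "case", "control")
  regions <- lapply(1:12, function(i) {
    G <- make_geno(n, runif(3, 0.01, 0.05), seed = 100 + i)
    make_region_matrix(G, status, unit = paste0("u", i))
  })
  regions$short <- structure(list(unit = "short", n_variants = 1),
                             class = "region_insufficient")
  sc <- suppressWarnings(rv_scan(regions, nm, tests = c("SKAT", "CMC")))
  expect_s3_class(sc, "rv_scan")
  expect_equal(nrow(sc$results), 24)
  expect_equal(sc$insufficient, "short")
  expect_true(all(c("q", "carriers_case") %in% names(sc$results)))
  expect_output(print(sc), "top units")
  expect_output(print(summary(sc)), "lambda")
})

test_that("pooled-class scan tests each class once with Bonferroni", {
  set.seed(45)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  nm <- make_null(y)
  status <- ifelse(y == 1, "case", "control")
  regions <- c(
    lapply(1:3, function(i) make_region_matrix(
      make_geno(n, runif(3, 0.01, 0.05), seed = 200 + i), status,
      unit = paste0("u", i), class = "UTR3")),
    lapply(1:3, function(i) make_region_matrix(
      make_geno(n, runif(3, 0.01, 0.05), seed = 300 + i), status,
      unit = paste0("o", i), class = "ORF")))
  out <- pooled_class_scan(regions, nm)
  expect_equal(nrow(out), 2)
  expect_setequal(out$class, c("UTR3", "ORF"))
  expect_equal(out$n_variants, c(9, 9))
  expect_true(all(out$p > 0 & out$p <= 1))
  expect_equal(out$p_bonferroni, pmin(out$p * 2, 1))
})

test_that("power ordering: burden wins unidirectional, SKAT wins mixed", {
  power_pair <- function(direction, B = 500, n = 200, m = 6, seed = 46) {
    set.seed(seed)
    rej <- c(CMC = 0, SKAT = 0)
    for (b in 1:B) {
      p <- runif(m, 0.02, 0.06)
      G <- sapply(p, function(pp) rbinom(n, 2, pp))
      colnames(G) <- paste0("v", 1:m)
      beta <- if (direction == "uni") rep(0.9, m) else
        rep(c(1.6, -1.6), length.out = m)
      y <- rbinom(n, 1, plogis(-0.2 + as.vector(G %*% beta)))
      if (length(unique(y)) < 2) next
      nl <- make_null(y)
      rmx <- make_region_matrix(G, ifelse(y == 1, "case", "control"))
      rej["CMC"] <- rej["CMC"] +
        (suppressWarnings(burden_cmc_test(rmx, nl))$p < 0.05)
      rej["SKAT"] <- rej["SKAT"] +
        (suppressWarnings(skat_test(rmx, nl))$p < 0.05)
    }
    rej / B
  }
  uni <- power_pair("uni")
  expect_gte(uni["CMC"], uni["SKAT"])
  mixed <- power_pair("mixed")
  expect_gte(mixed["SKAT"], mixed["CMC"])
})
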