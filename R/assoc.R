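#' Configuration of the region association tests
#'
#' @param weight_beta Beta density parameters for variant weights evaluated
#'   at the control MAF (default `c(1, 25)`, the rare-variant kernel
#'   convention: weight falls off quickly with frequency).
#' @param rho_grid SKAT-O mixing grid over `[0, 1]`; `rho = 0` is SKAT,
#'   `rho = 1` the weighted burden test.
#' @param n_perm Permutation count for permutation p-values (>= 100).
#' @param perm_seed Seed for the permutation stream.
#' @param davies_tol Tolerance for the characteristic-function inversion.
#' @return List of class `rv_test_config`.
#' @export
rv_test_config <- function(weight_beta = c(1, 25),
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                           n_perm = 1000L, perm_seed = 1L,
                           davies_tol = 1e-9) {
  stopifnot(all(rho_grid >= 0), all(rho_grid <= 1), n_perm >= 100L)
  structure(list(weight_beta = weight_beta, rho_grid = rho_grid,
                 n_perm = as.integer(n_perm), perm_seed = as.integer(perm_seed),
                 davies_tol = davies_tol),
            class = "rv_test_config")
}

# missing dosages enter the score statistics as non-carrying (0)
geno0 <- function(G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  G[is.na(G)] <- 0
  G
}

assoc_row <- function(unit, class, test, stat, p, n_variants, carriers,
                      perm_p = NA_real_, n_perm = NA_integer_, flag = "") {
  data.frame(unit = unit, class = class, test = test, n_variants = n_variants,
             carriers_case = carriers[1], carriers_control = carriers[2],
             stat = stat, p = p, perm_p = perm_p, n_perm = n_perm,
             flag = flag, stringsAsFactors = FALSE)
}

carrier_counts <- function(G, y) {
  carrier <- rowSums(geno0(G) > 0) > 0
  c(case = sum(carrier & y == 1), control = sum(carrier & y == 0))
}

#' Collapsed-carrier burden (CMC) score test
#'
#' Collapses the unit to a per-sample carrier indicator (any minor allele at
#' any member variant) and score-tests it against the null-model residuals;
#' two-sided p from the normal approximation to the score. With a single
#' rare-frequency bin this is the combined multivariate and collapsing (CMC)
#' test in its covariate-adjusted score form.
#'
#' @param rm A `region_matrix` from [collect_genotypes()].
#' @param null An [rv_null_model()] fit.
#' @return One-row results data frame.
#' @export
burden_cmc_test <- function(rm, null) {
  stopifnot(inherits(rm, "region_matrix"))
  G <- geno0(rm$G)
  carrier <- as.numeric(rowSums(G > 0) > 0)
  cc <- carrier_counts(rm$G, null$y)
  if (sum(carrier) == 0) {
    warning("no carriers in unit ", rm$unit)
    return(assoc_row(rm$unit, rm$class, "CMC", 0, 1, ncol(G), cc,
                     flag = "no_carriers"))
  }
  u <- sum(carrier * null$resid)
  v <- as.numeric(score_sigma(null, carrier))
  z <- if (v > 0) u / sqrt(v) else 0
  assoc_row(rm$unit, rm$class, "CMC", z^2, 2 * stats::pnorm(-abs(z)),
            ncol(G), cc)
}

# shared pieces for the kernel tests: weighted genotypes, score vector and
# its null covariance
kernel_prep <- function(rm, null, config) {
  Gw <- geno0(rm$G) %*% diag(rm$weights, ncol(rm$G))
  S <- as.vector(crossprod(Gw, null$resid))
  Sigma <- score_sigma(null, Gw)
  ev_min <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-6 * max(abs(Sigma)))
    stop("projected kernel is not positive semi-definite")
  list(Gw = Gw, S = S, Sigma = Sigma)
}

#' SKAT variance-component test
#'
#' Computes `Q = r' G W^2 G' r` with Beta-density weights on control MAF and
#' refers it to its null distribution, a weighted sum of 1-df chi-squares
#' whose weights are the eigenvalues of the covariate-projected kernel
#' (tail by characteristic-function inversion with moment-matching
#' fallback; see [pchisqsum_p()]).
#'
#' @inheritParams burden_cmc_test
#' @param config An [rv_test_config()].
#' @return One-row results data frame.
#' @export
skat_test <- function(rm, null, config = rv_test_config()) {
  stopifnot(inherits(rm, "region_matrix"))
  kp <- kernel_prep(rm, null, config)
  Q <- sum(kp$S^2)
  lambda <- eigen(kp$Sigma, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > max(lambda, 0) * 1e-10]
  if (!length(lambda)) {
    warning("degenerate kernel in unit ", rm$unit)
    return(assoc_row(rm$unit, rm$class, "SKAT", 0, 1, ncol(rm$G),
                     carrier_counts(rm$G, null$y), flag = "degenerate"))
  }
  p <- as.numeric(pchisqsum_p(Q, lambda, tol = config$davies_tol))
  assoc_row(rm$unit, rm$class, "SKAT", Q, p, ncol(rm$G),
            carrier_counts(rm$G, null$y))
}

# weighted burden p for the rho = 1 endpoint
weighted_burden_p <- function(kp) {
  qb <- sum(kp$S)^2
  vb <- sum(kp$Sigma)
  if (vb <= 0) return(list(p = 1, stat = 0))
  list(p = stats::pchisq(qb / vb, df = 1, lower.tail = FALSE), stat = qb / vb)
}

#' SKAT-O: optimal kernel/burden combination
#'
#' Evaluates `Q_rho = (1 - rho) Q_SKAT + rho Q_burden` over the mixing grid
#' and combines the per-rho p-values through the minimum-p integration of
#' the optimal unified test: the minimum p is transformed to per-rho
#' statistic thresholds, and the combined p integrates the probability that
#' any threshold is exceeded over the common one-degree component. The
#' result is capped by the grid-size Bonferroni bound `min-p x |grid|`.
#'
#' @inheritParams skat_test
#' @return One-row results data frame; attributes `p_rho` (per-rho p-values)
#'   and `rho_min` (grid point attaining the minimum).
#' @export
skat_o_test <- function(rm, null, config = rv_test_config()) {
  stopifnot(inherits(rm, "region_matrix"))
  kp <- kernel_prep(rm, null, config)
  rho <- unique(sort(config$rho_grid))
  m <- ncol(rm$G)
  cc <- carrier_counts(rm$G, null$y)

  if (max(abs(kp$Sigma)) <= 0) {
    warning("degenerate kernel in unit ", rm$unit)
    return(assoc_row(rm$unit, rm$class, "SKATO", 0, 1, m, cc,
                     flag = "degenerate"))
  }
  q_skat <- sum(kp$S^2)
  q_burd <- sum(kp$S)^2
  rho_c <- pmin(rho, 0.999)                 # avoid the singular rho = 1 kernel
  lambdas <- vector("list", length(rho))
  p_rho <- numeric(length(rho))
  for (i in seq_along(rho)) {
    if (rho[i] == 1) {
      wb <- weighted_burden_p(kp)
      p_rho[i] <- wb$p
      lambdas[[i]] <- sum(kp$Sigma)
    } else {
      Rh <- rho_half(m, rho_c[i])
      K <- Rh %*% kp$Sigma %*% Rh
      lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      lam <- lam[lam > max(lam) * 1e-10]
      lambdas[[i]] <- lam
      q <- (1 - rho_c[i]) * q_skat + rho_c[i] * q_burd
      p_rho[i] <- as.numeric(pchisqsum_p(q, lam, tol = config$davies_tol))
    }
  }
  pmin_obs <- min(p_rho)

  if (length(rho) == 1L) {
    return(assoc_row(rm$unit, rm$class, "SKATO",
                     (1 - rho_c) * q_skat + rho_c * q_burd, pmin_obs, m, cc))
  }

  p <- skat_o_combine(kp$Sigma, rho_c, lambdas, pmin_obs, m)
  p <- min(p, pmin_obs * length(rho), 1)
  p <- max(p, .Machine$double.xmin)
  out <- assoc_row(rm$unit, rm$class, "SKATO", q_skat, p, m, cc)
  attr(out, "p_rho") <- stats::setNames(p_rho, rho)
  attr(out, "rho_min") <- rho[which.min(p_rho)]
  out
}

# matrix square root of R_rho = (1-rho) I + rho J
rho_half <- function(m, rho) {
  Jm <- matrix(1 / m, m, m)
  sqrt(1 - rho) * (diag(m) - Jm) + sqrt(1 - rho + m * rho) * Jm
}

# minimum-p combination over the rho grid, conditioning on the common
# component along the mean-genotype direction
skat_o_combine <- function(Sigma, rho_c, lambdas, pmin_obs, m) {
  eg <- eigen(Sigma, symmetric = TRUE)
  Z1 <- diag(sqrt(pmax(eg$values, 0)), m) %*% t(eg$vectors)   # Z1' Z1 = Sigma
  z_mean <- rowMeans(Z1)
  z_norm <- sum(z_mean^2)
  if (z_norm < max(abs(Sigma)) * 1e-12) return(pmin_obs * length(rho_c))
  cof1 <- as.vector(z_mean %*% Z1) / z_norm
  Z_it1 <- outer(z_mean, cof1)
  Z_it2 <- Z1 - Z_it1
  K2 <- crossprod(Z_it2)
  lam <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > max(lam, 0) * 1e-10]
  # rank-1 kernel: every Q_rho is the same test, so min-p needs no correction
  if (!length(lam)) return(pmin_obs)
  var_remain <- 4 * sum(crossprod(Z_it1) * K2)
  mu_q <- sum(lam)
  var_q <- 2 * sum(lam^2) + var_remain
  tau <- (m^2 * rho_c + (1 - rho_c) * sum(cof1^2)) * z_norm

  q_rho <- vapply(seq_along(rho_c), function(i)
    liu_q(pmin_obs, lambdas[[i]]), numeric(1))

  sd1 <- sqrt(max(var_q - var_remain, 0)) / sqrt(var_q)
  # conditional tail of the remainder mixture by moment matching (fast and
  # smooth; the per-rho p-values themselves use the exact inversion)
  pr <- liu_params(lam)
  cond_f <- function(x) {
    tmin <- vapply(x, function(xx)
      min((q_rho - tau * xx) / (1 - rho_c)), numeric(1))
    t_adj <- pmax((tmin - mu_q) * sd1 + mu_q, 0)
    qx <- (t_adj - pr$mu_q) / pr$sigma_q * pr$sigma_x + pr$mu_x
    f <- stats::pchisq(qx, df = pr$df, ncp = pr$ncp)
    f[tmin > sum(lam) * 1e4] <- 1
    f
  }
  # substitute x = t^2 to remove the chi^2_1 density singularity at 0:
  # Int f(x) dchisq(x, 1) dx = Int f(t^2) 2 dnorm(t) dt
  integrand <- function(t) cond_f(t^2) * 2 * stats::dnorm(t)
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = sqrt(40),
                     subdivisions = 2000L, rel.tol = 1e-8,
                     abs.tol = 1e-12)$value,
    error = function(e) NA_real_)
  if (!is.finite(val)) {            # fixed-grid Simpson fallback
    t <- seq(0, sqrt(40), length.out = 2001L)
    ft <- integrand(t)
    h <- t[2] - t[1]
    val <- h / 3 * (ft[1] + ft[2001] +
                      4 * sum(ft[seq(2, 2000, 2)]) +
                      2 * sum(ft[seq(3, 1999, 2)]))
  }
  min(max(1 - val, 0), 1)
}

#' Variable-threshold burden test
#'
#' For every distinct observed MAF threshold, forms the burden of variants
#' at or below the threshold, standardizes its score by the null-model score
#' variance, and takes the maximum absolute standardized score as the
#' statistic. Significance is assessed by permutation of the null-model
#' residuals (Freedman-Lane style, preserving the covariate structure), or
#' by complete enumeration of case-label assignments when `exact = TRUE`
#' and the null model is intercept-only.
#'
#' @inheritParams skat_test
#' @param exact Enumerate all case/control label assignments instead of
#'   Monte-Carlo permutation (intercept-only null models, small cohorts).
#' @return One-row results data frame (statistic, permutation p in both the
#'   `p` and `perm_p` columns).
#' @export
vt_test <- function(rm, null, config = rv_test_config(), exact = FALSE) {
  stopifnot(inherits(rm, "region_matrix"))
  G <- geno0(rm$G)
  cc <- carrier_counts(rm$G, null$y)
  thr <- sort(unique(rm$maf))
  B <- matrix(vapply(thr, function(t) rowSums(G[, rm$maf <= t, drop = FALSE]),
                     numeric(nrow(G))), nrow = nrow(G))
  sdv <- sqrt(pmax(diag(score_sigma(null, B)), 0))
  ok <- sdv > 0
  if (!any(ok)) {
    warning("degenerate burden at every threshold in unit ", rm$unit)
    return(assoc_row(rm$unit, rm$class, "VT", 0, 1, ncol(G), cc,
                     perm_p = 1, flag = "degenerate"))
  }
  Bk <- B[, ok, drop = FALSE]
  sdk <- sdv[ok]
  stat_fn <- function(r) max(abs(crossprod(Bk, r)) / sdk)
  t_obs <- stat_fn(null$resid)
  if (exact) {
    if (ncol(null$X) != 1L)
      stop("exact enumeration requires an intercept-only null model")
    pp <- enumerate_label_p(stat_fn, null, t_obs)
  } else {
    n <- nrow(Bk)
    hits <- with_seed(config$perm_seed, {
      R <- matrix(null$resid[vapply(seq_len(config$n_perm),
                                    function(i) sample.int(n),
                                    integer(n))], n, config$n_perm)
      z <- abs(crossprod(Bk, R)) / sdk
      sum(apply(z, 2, max) >= t_obs - 1e-12)
    })
    pp <- (1 + hits) / (1 + config$n_perm)
  }
  assoc_row(rm$unit, rm$class, "VT", t_obs, pp, ncol(G), cc,
            perm_p = pp, n_perm = if (exact) NA_integer_ else config$n_perm)
}

# exact enumeration over all case-position assignments (intercept-only null:
# residuals are determined by the labels)
enumerate_label_p <- function(stat_fn, null, observed, limit = 2e5) {
  n <- null$n
  n_case <- sum(null$y == 1)
  if (choose(n, n_case) > limit)
    stop("too many label assignments to enumerate (", choose(n, n_case), ")")
  combos <- utils::combn(n, n_case)
  ybar <- n_case / n
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    r <- rep(-ybar, n)
    r[combos[, j]] <- 1 - ybar
    if (stat_fn(r) >= observed - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combos)
}

#' Permutation p-value for a score statistic
#'
#' Monte-Carlo permutation of the null-model residuals: the statistic is
#' recomputed for `n_perm` random permutations and the p-value is
#' `(1 + #(permuted >= observed)) / (1 + n_perm)`. Permuting residuals
#' rather than raw labels keeps the covariate adjustment intact; with an
#' intercept-only model the two schemes coincide.
#'
#' @param stat_fn Function of a residual vector returning the scalar
#'   statistic (larger = more extreme).
#' @param null An [rv_null_model()] fit.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed for the permutation stream.
#' @param observed Optional precomputed observed statistic.
#' @return Permutation p-value in `(0, 1]`.
#' @export
permutation_p <- function(stat_fn, null, n_perm = 1000L, seed = 1L,
                          observed = NULL) {
  stopifnot(n_perm >= 100L)
  if (is.null(observed)) observed <- stat_fn(null$resid)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      r <- sample(null$resid)
      if (stat_fn(r) >= observed - 1e-12) hits <- hits + 1L
    }
  })
  (1 + hits) / (1 + n_perm)
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Benjamini-Hochberg adjustment within a unit class
#'
#' @param results Association results data frame (rows from the `*_test`
#'   functions).
#' @return The data frame with a `q` column, BH-adjusted within each
#'   `class` x `test` family.
#' @export
fdr_adjust <- function(results) {
  stopifnot(nrow(results) >= 1L)
  results$q <- NA_real_
  for (grp in split(seq_len(nrow(results)),
                    paste(results$class, results$test))) {
    results$q[grp] <- stats::p.adjust(results$p[grp], method = "BH")
  }
  results
}

#' Genomic inflation factor and QQ coordinates
#'
#' `lambda` is the median of the 1-df chi-square statistics implied by the
#' observed p-values divided by the null median 0.4549364; values near 1
#' indicate calibration, values well above 1 residual stratification.
#'
#' @param p Vector of p-values in `(0, 1]` (at least 10).
#' @return List with `lambda` and `qq`, a data frame of
#'   `(expected, observed)` -log10 p coordinates.
#' @export
qq_lambda <- function(p) {
  if (length(p) < 10L) stop("need at least 10 p-values")
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  n <- length(p)
  qq <- data.frame(expected = -log10(stats::ppoints(n)),
                   observed = -log10(sort(p)))
  list(lambda = lambda, qq = qq)
}
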