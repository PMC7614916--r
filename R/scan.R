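#' Region-based rare-variant association scan
#'
#' Runs the configured association tests over a list of collapsing-unit
#' genotype matrices under a shared null model, applies the
#' Benjamini-Hochberg correction within each unit class and test, and
#' returns a classed result object with print/summary/plot methods. Units
#' flagged `"insufficient"` (fewer than two qualifying variants) are listed
#' but excluded from testing and from the FDR denominator.
#'
#' @param regions List of [collect_genotypes()] outputs.
#' @param null An [rv_null_model()] fit.
#' @param tests Character subset of `c("SKATO", "SKAT", "CMC", "VT")`.
#' @param config An [rv_test_config()].
#' @return Object of class `rv_scan`: list with `results` (data frame),
#'   `insufficient` (unit ids), `tests`, `config`.
#' @export
rv_scan <- function(regions, null, tests = c("SKATO", "SKAT", "CMC", "VT"),
                    config = rv_test_config()) {
  tests <- match.arg(tests, several.ok = TRUE)
  insuff <- character(0)
  rows <- list()
  for (rm in regions) {
    if (inherits(rm, "region_insufficient")) {
      insuff <- c(insuff, rm$unit)
      next
    }
    for (tn in tests) {
      row <- switch(tn,
        SKATO = skat_o_test(rm, null, config),
        SKAT = skat_test(rm, null, config),
        CMC = burden_cmc_test(rm, null),
        VT = vt_test(rm, null, config))
      attributes(row)[setdiff(names(attributes(row)),
                              c("names", "class", "row.names"))] <- NULL
      rows[[length(rows) + 1L]] <- row
    }
  }
  results <- if (length(rows)) fdr_adjust(do.call(rbind, rows)) else
    data.frame()
  structure(list(results = results, insufficient = insuff, tests = tests,
                 config = config, n = null$n),
            class = "rv_scan")
}

#' Pooled-class association test
#'
#' Pools every qualifying variant of each unit class into one collapsed
#' hypothesis ("is this functional class of elements, as a whole, enriched
#' for risk or protective alleles?") and tests it with SKAT-O. With one
#' hypothesis per class, the adjustment is Bonferroni over the number of
#' classes rather than within-class FDR.
#'
#' @param regions List of [collect_genotypes()] outputs (mixed classes).
#' @param null An [rv_null_model()] fit.
#' @param config An [rv_test_config()].
#' @return Data frame: one row per class with the SKAT-O p and the
#'   Bonferroni-adjusted p.
#' @export
pooled_class_scan <- function(regions, null, config = rv_test_config()) {
  regions <- Filter(function(r) inherits(r, "region_matrix"), regions)
  by_class <- split(regions, vapply(regions, `[[`, character(1), "class"))
  rows <- lapply(names(by_class), function(cls) {
    Gs <- lapply(by_class[[cls]], `[[`, "G")
    pooled <- structure(list(
      unit = paste0("ALL_", cls), class = cls,
      G = do.call(cbind, Gs),
      maf = unlist(lapply(by_class[[cls]], `[[`, "maf")),
      weights = unlist(lapply(by_class[[cls]], `[[`, "weights"))),
      class = "region_matrix")
    res <- suppressWarnings(skat_o_test(pooled, null, config))
    data.frame(class = cls, n_units = length(Gs),
               n_variants = ncol(pooled$G), p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  rownames(out) <- NULL
  out
}

#' @export
print.rv_scan <- function(x, n_top = 5L, ...) {
  cat("Region-based rare-variant association scan\n")
  cat("  tested units:", length(unique(x$results$unit)),
      " | untestable (<2 variants):", length(x$insufficient), "\n")
  if (nrow(x$results)) {
    ord <- order(x$results$p)
    top <- utils::head(x$results[ord, c("unit", "class", "test", "n_variants",
                                        "carriers_case", "carriers_control",
                                        "p", "q")], n_top)
    cat("  top units:\n")
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.rv_scan <- function(object, ...) {
  res <- object$results
  out <- list()
  if (nrow(res)) {
    for (grp in split(res, paste(res$class, res$test, sep = "/"))) {
      key <- paste(grp$class[1], grp$test[1], sep = "/")
      lam <- if (nrow(grp) >= 10) qq_lambda(grp$p)$lambda else NA_real_
      out[[key]] <- data.frame(class = grp$class[1], test = grp$test[1],
                               n_units = nrow(grp), lambda = lam,
                               min_p = min(grp$p), min_q = min(grp$q))
    }
  }
  tab <- if (length(out))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame()
  structure(list(table = tab, insufficient = object$insufficient),
            class = "summary.rv_scan")
}

#' @export
print.summary.rv_scan <- function(x, ...) {
  cat("Per-class association summary (lambda = genomic inflation)\n")
  print(x$table, row.names = FALSE, digits = 3)
  if (length(x$insufficient))
    cat("untestable units:", length(x$insufficient), "\n")
  invisible(x)
}

#' QQ plot of a scan
#'
#' @param x An `rv_scan`.
#' @param test Which test's p-values to plot (default first available).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rv_scan <- function(x, test = x$tests[1], ...) {
  res <- x$results[x$results$test == test, ]
  if (nrow(res) < 10) stop("fewer than 10 results for test ", test)
  ql <- qq_lambda(res$p)
  graphics::plot(ql$qq$expected, ql$qq$observed,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = sprintf("%s (lambda = %.2f)", test, ql$lambda), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(ql)
}
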