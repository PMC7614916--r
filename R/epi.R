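#' Carrier 2x2 table
#'
#' Builds the case/control by carrier/non-carrier contingency table for a
#' collapsing unit. A carrier is a sample with at least one minor allele at
#' at least one member variant; missing genotypes count as non-carrying, and
#' a sample carrying several member variants counts once.
#'
#' @param rm A `region_matrix` from [collect_genotypes()], or a plain dosage
#'   matrix (samples x variants).
#' @param phenotypes Phenotype table aligned to the matrix rows, with a
#'   `status` column.
#' @param unit,cohort Optional labels.
#' @return Object of class `carrier_table`: list with cells `a` (case
#'   carriers), `b` (case non-carriers), `c` (control carriers), `d`
#'   (control non-carriers) and the labels.
#' @export
carrier_table <- function(rm, phenotypes, unit = NULL, cohort = "cohort") {
  G <- if (inherits(rm, "region_matrix")) rm$G else rm
  stopifnot(nrow(G) == nrow(phenotypes))
  if (is.null(unit)) unit <- if (inherits(rm, "region_matrix")) rm$unit else "unit"
  carrier <- rowSums(geno0(G) > 0) > 0
  is_case <- phenotypes$status == "case"
  carrier_table_counts(sum(carrier & is_case), sum(is_case),
                       sum(carrier & !is_case), sum(!is_case),
                       unit = unit, cohort = cohort)
}

#' Carrier table from published counts
#'
#' @param case_carriers,case_total,control_carriers,control_total Counts.
#' @param unit,cohort Labels.
#' @return A `carrier_table`.
#' @examples
#' carrier_table_counts(6, 3955, 12, 1819, unit = "IL18RAP_3UTR")
#' @export
carrier_table_counts <- function(case_carriers, case_total,
                                 control_carriers, control_total,
                                 unit = "unit", cohort = "cohort") {
  stopifnot(case_carriers >= 0, control_carriers >= 0,
            case_carriers <= case_total, control_carriers <= control_total)
  structure(list(a = case_carriers, b = case_total - case_carriers,
                 c = control_carriers, d = control_total - control_carriers,
                 unit = unit, cohort = cohort),
            class = "carrier_table")
}

#' @export
print.carrier_table <- function(x, ...) {
  cat(sprintf("Carrier table [%s / %s]\n", x$unit, x$cohort))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  cat(sprintf("carrier frequency: cases %.2f%%, controls %.2f%%\n",
              carrier_frequency(x, "case"), carrier_frequency(x, "control")))
  invisible(x)
}

#' Carrier frequency in one arm
#'
#' @param table A `carrier_table`.
#' @param group `"case"` or `"control"`.
#' @return Percentage, rounded to 2 decimals.
#' @export
carrier_frequency <- function(table, group = c("case", "control")) {
  group <- match.arg(group)
  tot <- if (group == "case") table$a + table$b else table$c + table$d
  if (tot == 0) stop("empty ", group, " arm")
  carr <- if (group == "case") table$a else table$c
  round(100 * carr / tot, 2)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)` of the carrier table. When any
#' cell is zero the Haldane-Anscombe correction (0.5 added to all four
#' cells) is applied and flagged. The 95% CI is Woolf's log-normal interval
#' on the (possibly corrected) cells.
#'
#' @param table A `carrier_table`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `or_estimate`: list with `or`, `lo`, `hi`,
#'   `correction` (`"none"` or `"haldane"`).
#' @export
odds_ratio <- function(table, conf_level = 0.95) {
  cells <- c(table$a, table$b, table$c, table$d)
  if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
      sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0)
    stop("a zero margin leaves the odds ratio undefined")
  correction <- "none"
  if (any(cells == 0)) {
    cells <- cells + 0.5
    correction <- "haldane"
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  structure(list(or = or, lo = exp(log(or) - z * se),
                 hi = exp(log(or) + z * se), correction = correction,
                 unit = table$unit, cohort = table$cohort),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR = %.2f (95%% CI %.2f-%.2f)%s [%s]\n", x$or, x$lo, x$hi,
              if (x$correction == "haldane") " [Haldane-Anscombe corrected]" else "",
              x$unit))
  invisible(x)
}

#' Yates-corrected chi-square test of a carrier table
#'
#' @param table A `carrier_table`.
#' @return Two-sided p-value of the 1-df chi-square with continuity
#'   correction.
#' @export
chi2_yates <- function(table) {
  m <- matrix(c(table$a, table$c, table$b, table$d), 2, 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin in carrier table")
  ex <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(ex <= 0)) stop("zero expected count")
  suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
}

#' Fisher exact test of a carrier table
#'
#' Two-sided exact p by summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the observed
#' one.
#'
#' @param table A `carrier_table`.
#' @return Exact p-value in `(0, 1]`.
#' @export
fisher_exact <- function(table) {
  hypergeom_fisher_p(table$a, table$b, table$c, table$d)
}

#' Fold enrichment of carrier frequency in controls over cases
#'
#' @param table A `carrier_table`.
#' @return Ratio of control to case carrier frequency, 2 decimals.
#' @export
fold_enrichment <- function(table) {
  if (table$a == 0) stop("no case carriers: fold enrichment undefined")
  f_case <- table$a / (table$a + table$b)
  f_ctrl <- table$c / (table$c + table$d)
  round(f_ctrl / f_case, 2)
}

#' Pooled joint analysis of carrier tables from disjoint cohorts
#'
#' Sums the tables cell-wise and reports the pooled table with its odds
#' ratio and Yates-corrected chi-square p-value (the joint-replication
#' analysis used when covariates are unavailable across cohorts).
#'
#' @param tables List of `carrier_table`s over disjoint cohorts.
#' @return List with `table`, `or` (an `or_estimate`), `p_yates`.
#' @export
pooled_joint <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "carrier_table")))
  a <- sum(vapply(tables, `[[`, numeric(1), "a"))
  b <- sum(vapply(tables, `[[`, numeric(1), "b"))
  c_ <- sum(vapply(tables, `[[`, numeric(1), "c"))
  d <- sum(vapply(tables, `[[`, numeric(1), "d"))
  pooled <- carrier_table_counts(a, a + b, c_, c_ + d,
                                 unit = tables[[1]]$unit, cohort = "pooled")
  list(table = pooled, or = odds_ratio(pooled), p_yates = chi2_yates(pooled))
}

#' Per-stratum odds ratios for a forest plot
#'
#' @param tables Named list of `carrier_table`s, one per stratum.
#' @return Data frame with one row per stratum plus a pooled row: cells,
#'   OR, CI bounds, and a flag marking Haldane-corrected (zero-cell)
#'   estimates.
#' @export
stratified_forest <- function(tables) {
  stopifnot(length(tables) >= 1L)
  one <- function(tb, label) {
    or <- odds_ratio(tb)
    data.frame(stratum = label, a = tb$a, b = tb$b, c = tb$c, d = tb$d,
               or = or$or, lo = or$lo, hi = or$hi,
               corrected = or$correction == "haldane",
               stringsAsFactors = FALSE)
  }
  labels <- names(tables)
  if (is.null(labels)) labels <- paste0("stratum", seq_along(tables))
  rows <- Map(one, tables, labels)
  pooled <- pooled_joint(tables)
  rows$pooled <- one(pooled$table, "pooled")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
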