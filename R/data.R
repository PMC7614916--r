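#' Published discovery-cohort carrier tables
#'
#' Carrier counts reported for the discovery case-control cohort (3,955
#' cases versus 1,819 controls): the protective IL18RAP 3'UTR signal
#' (6 case / 12 control carriers) and the deleterious NEK1 (127/19) and
#' SOD1 (36/0) coding signals. Packaged as a plain-text fixture so the
#' carrier-level statistics can be recomputed from the printed counts.
#'
#' @return Named list of [carrier_table_counts()] objects keyed by unit.
#' @examples
#' tabs <- load_discovery_tables()
#' odds_ratio(tabs$IL18RAP_3UTR)
#' @export
load_discovery_tables <- function() {
  path <- system.file("extdata", "discovery_carrier_tables.tsv",
                      package = "rvregion", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    carrier_table_counts(df$case_carriers[i], df$case_total[i],
                         df$control_carriers[i], df$control_total[i],
                         unit = df$unit[i], cohort = df$cohort[i]))
  stats::setNames(out, df$unit)
}
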