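# File I/O: VCF/BED/FASTA/TSV round-trips for the pipeline. VCF positions
# are 1-based; BED and all UTR-local coordinates are 0-based half-open.
# Conversions live here and nowhere else.

#' Write a cohort to a VCF v4.2 file
#'
#' Emits biallelic sites with declared contigs, per-site `DP` in INFO and
#' per-sample `GT`. The writer is plain-text and byte-deterministic, so
#' identical simulations yield identical file checksums.
#'
#' @param sites Site table: `chrom`, `pos`, `id`, `ref`, `alt`, `dp`.
#' @param geno Dosage matrix (samples x sites), `NA` = missing.
#' @param samples Sample ids (row order of `geno`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, geno, samples, path) {
  stopifnot(nrow(sites) == ncol(geno), length(samples) == nrow(geno))
  contigs <- unique(as.character(sites$chrom))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rvregion",
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total site depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(geno), ncol(geno))
  ok <- !is.na(geno)
  gt[ok] <- codes[geno[ok] + 1L]
  body <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", paste0("DP=", sites$dp), "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF
#'
#' Parses a VCF (via vcfR) into the site table and dosage matrix used by
#' the QC and association modules. Multiallelic records are kept in the
#' table (they are rejected by [apply_site_qc()]'s structural filter).
#'
#' @param path VCF path.
#' @return List with `sites` (chrom, pos, id, ref, alt, dp) and `geno`
#'   (samples x sites integer dosage matrix).
#' @export
read_vcf_cohort <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1", fix$INFO)))
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      id = fix$ID, ref = fix$REF, alt = fix$ALT, dp = dp,
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0|0")] <- 0L
    out[x %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[x %in% c("1/1", "1|1")] <- 2L
    out
  }
  geno <- matrix(conv(t(gt)), nrow = ncol(gt))   # samples x sites
  colnames(geno) <- sites$id
  rownames(geno) <- colnames(gt)
  list(sites = sites, geno = geno)
}

#' Write/read the phenotype table
#'
#' Tab-separated with a header: `sample`, `status` (case/control), `sex`
#' (male/female), `stratum`, `age_diagnosis`, `age_death` (years; NA when
#' unavailable).
#'
#' @param phenotypes Data frame as above.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write region units as BED
#'
#' 0-based half-open records; the name field is `unit id|class`.
#'
#' @param units Units from [build_units()].
#' @param path Output path.
#' @export
write_units_bed <- function(units, path) {
  rows <- lapply(units, function(u) {
    gr <- u$ranges
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               name = paste0(u$id, "|", u$class),
               score = 0L,
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  bed$strand[bed$strand == "*"] <- "."
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write UTR sequences as FASTA
#'
#' @param utr_seqs Named character vector of UTR sequences (transcript
#'   orientation).
#' @param path Output path.
#' @export
write_utr_fasta <- function(utr_seqs, path) {
  x <- Biostrings::DNAStringSet(utr_seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_utr_fasta
#' @export
read_utr_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

# small generic TSV helpers used by the pipeline stages
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
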