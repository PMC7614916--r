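#' Build collapsing units from annotation resources
#'
#' Constructs the region units that rare variants are collapsed into. Unit
#' classes: `ORF` (coding regions), `UTR3` (3'UTRs), `preMIR` (pre-miRNA
#' loci), `MIR_NETWORK` (one mature miRNA plus the 3'UTRs carrying a
#' conserved site for it), and `UTR3_MRE` (3'UTR units restricted, at
#' genotype-collection time, to variants causing an MRE gain/loss). Genomic
#' intervals of ORF/UTR3/preMIR units are padded by `pad` bases on each side
#' so that splice junctions are covered.
#'
#' @param annotations Annotation bundle as produced by
#'   [simulate_annotation_resources()]: a list with elements `genes`,
#'   `premirs`, `conserved_sites` (see those docs).
#' @param class Unit class, one of `"ORF"`, `"UTR3"`, `"UTR3_MRE"`,
#'   `"preMIR"`, `"MIR_NETWORK"`.
#' @param pad Padding in bases applied to each interval (default 300).
#' @return Named list of units; each unit is a list with `id`, `class`,
#'   `ranges` (a `GRanges` of padded intervals) and, for UTR-derived units,
#'   the unpadded `utr_start`, `utr_end`, `strand` and `gene`.
#' @export
build_units <- function(annotations, class, pad = 300L) {
  class <- match.arg(class, c("ORF", "UTR3", "UTR3_MRE", "preMIR",
                              "MIR_NETWORK", "UTR3_PROXIMAL_QUADRANT"))
  genes <- annotations$genes
  mk_gr <- function(chrom, start, end, strand) {
    GenomicRanges::GRanges(
      seqnames = as.character(chrom),
      ranges = IRanges::IRanges(start = pmax(0L, start - pad) + 1L,
                                end = end + pad),
      strand = strand)
  }
  units <- list()
  if (class == "ORF") {
    for (i in seq_len(nrow(genes)))
      units[[paste0(genes$gene[i], "_ORF")]] <- list(
        id = paste0(genes$gene[i], "_ORF"), class = class,
        gene = genes$gene[i],
        ranges = mk_gr(genes$chrom[i], genes$orf_start[i], genes$orf_end[i],
                       genes$strand[i]))
  } else if (class %in% c("UTR3", "UTR3_MRE")) {
    for (i in seq_len(nrow(genes)))
      units[[paste0(genes$gene[i], "_", class)]] <- list(
        id = paste0(genes$gene[i], "_", class), class = class,
        gene = genes$gene[i],
        utr_start = genes$utr3_start[i], utr_end = genes$utr3_end[i],
        strand = genes$strand[i],
        ranges = mk_gr(genes$chrom[i], genes$utr3_start[i], genes$utr3_end[i],
                       genes$strand[i]))
  } else if (class == "preMIR") {
    pm <- annotations$premirs
    for (i in seq_len(nrow(pm)))
      units[[paste0(pm$mirna[i], "_preMIR")]] <- list(
        id = paste0(pm$mirna[i], "_preMIR"), class = class,
        ranges = mk_gr(pm$chrom[i], pm$start[i], pm$end[i], pm$strand[i]))
  } else if (class == "MIR_NETWORK") {
    pm <- annotations$premirs
    cs <- annotations$conserved_sites
    for (i in seq_len(nrow(pm))) {
      targets <- unique(cs$utr[cs$mirna == pm$mirna[i]])
      gi <- match(targets, genes$gene)
      gi <- gi[!is.na(gi)]
      gr <- mk_gr(c(pm$chrom[i], genes$chrom[gi]),
                  c(pm$start[i], genes$utr3_start[gi]),
                  c(pm$end[i], genes$utr3_end[gi]),
                  c(pm$strand[i], genes$strand[gi]))
      units[[paste0(pm$mirna[i], "_NET")]] <- list(
        id = paste0(pm$mirna[i], "_NET"), class = class, ranges = gr)
    }
  } else stop("proximal-quadrant units are derived from UTR3 units via proximal_quadrant()")
  units
}

#' Proximal quadrant of a 3'UTR unit
#'
#' Returns a unit covering the 5'-most quarter (in nucleotides,
#' `floor(length/4)`) of the unpadded UTR, strand-aware; padding is not
#' re-applied, because it exists to cover splice junctions and is irrelevant
#' within the UTR body.
#'
#' @param unit A `UTR3` unit from [build_units()].
#' @return A unit of class `UTR3_PROXIMAL_QUADRANT`.
#' @export
proximal_quadrant <- function(unit) {
  stopifnot(!is.null(unit$utr_start))
  len <- unit$utr_end - unit$utr_start
  if (len < 4) stop("UTR too short for a quadrant (length < 4)")
  q <- len %/% 4L
  if (unit$strand == "+") {
    s <- unit$utr_start; e <- unit$utr_start + q
  } else {
    s <- unit$utr_end - q; e <- unit$utr_end
  }
  chrom <- as.character(GenomicRanges::seqnames(unit$ranges))[1]
  list(id = sub("_UTR3.*$", "_UTR3Q", unit$id), class = "UTR3_PROXIMAL_QUADRANT",
       gene = unit$gene, utr_start = s, utr_end = e, strand = unit$strand,
       ranges = GenomicRanges::GRanges(chrom,
                                       IRanges::IRanges(s + 1L, e),
                                       strand = unit$strand))
}

#' Assign variants to units by interval overlap
#'
#' A variant belongs to a unit when its position (VCF 1-based, converted to
#' the 0-based half-open frame internally) falls in any padded interval of
#' the unit; insertions are anchored at their left position.
#'
#' @param units List of units from [build_units()].
#' @param sites Site table with `id`, `chrom`, `pos` (1-based).
#' @return Data frame with columns `unit`, `variant`.
#' @export
assign_variants <- function(units, sites) {
  if (!length(units) || !nrow(sites))
    return(data.frame(unit = character(), variant = character(),
                      stringsAsFactors = FALSE))
  vr <- GenomicRanges::GRanges(as.character(sites$chrom),
                               IRanges::IRanges(sites$pos, width = 1L))
  out <- lapply(units, function(u) {
    hits <- GenomicRanges::findOverlaps(vr, u$ranges, ignore.strand = TRUE)
    idx <- unique(S4Vectors::queryHits(hits))
    if (!length(idx)) return(NULL)
    data.frame(unit = u$id, variant = sites$id[idx], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(unit = character(), variant = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the genotype matrix of a collapsing unit
#'
#' Restricts the cohort genotype matrix to the unit's qualifying member
#' variants and attaches control minor-allele frequencies and the
#' Beta(1, 25) kernel weights. Units with fewer than two member variants are
#' not testable and are returned as an `"insufficient"` marker (they are
#' excluded from association testing and from the FDR denominator rather
#' than assigned p = 1).
#'
#' @param unit A unit from [build_units()].
#' @param variant_ids Qualifying variant ids that are members of the unit.
#' @param geno Cohort dosage matrix (samples x variants, named columns).
#' @param phenotypes Phenotype table aligned to `geno` rows.
#' @param weight_beta Beta parameters for the variant weights on control MAF.
#' @return An object of class `region_matrix` (list with `unit`, `class`,
#'   `G`, `maf`, `weights`), or of class `region_insufficient`.
#' @export
collect_genotypes <- function(unit, variant_ids, geno, phenotypes,
                              weight_beta = c(1, 25)) {
  stopifnot(nrow(geno) == nrow(phenotypes))
  ids <- intersect(variant_ids, colnames(geno))
  if (length(ids) < 2L)
    return(structure(list(unit = unit$id, n_variants = length(ids)),
                     class = "region_insufficient"))
  G <- geno[, ids, drop = FALSE]
  maf <- vapply(ids, function(v) control_maf(G[, v], phenotypes$status),
                numeric(1))
  w <- stats::dbeta(maf, weight_beta[1], weight_beta[2])
  structure(list(unit = unit$id, class = unit$class, G = G, maf = maf,
                 weights = w),
            class = "region_matrix")
}

#' Partition a region matrix into singleton and recurrent variants
#'
#' Singletons are variants observed on exactly one haplotype cohort-wide
#' (folded minor-allele count of 1); the rest are recurrent. The two column
#' sets partition the input.
#'
#' @param rm A `region_matrix` from [collect_genotypes()].
#' @return List with elements `singleton` and `recurrent`, each a
#'   `region_matrix` (possibly with zero columns).
#' @export
partition_singletons <- function(rm) {
  stopifnot(inherits(rm, "region_matrix"))
  mac <- apply(rm$G, 2, function(g) {
    g <- g[!is.na(g)]
    min(sum(g), 2 * length(g) - sum(g))
  })
  take <- function(sel, tag) {
    structure(list(unit = paste0(rm$unit, tag), class = rm$class,
                   G = rm$G[, sel, drop = FALSE],
                   maf = rm$maf[sel], weights = rm$weights[sel]),
              class = "region_matrix")
  }
  list(singleton = take(mac == 1, "_singleton"),
       recurrent = take(mac != 1, "_recurrent"))
}
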