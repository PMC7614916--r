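#' Convert a miRNA seed to its target-site heptamer
#'
#' A miRNA represses targets through exact complementarity between its seed
#' (mature positions 2-8, given 5'->3' in RNA) and a 7-nt window of the
#' 3'UTR. The target site carried by the UTR (sense/DNA orientation) is the
#' reverse complement of the seed after U->T conversion.
#'
#' @param seed Character vector of 7-letter RNA seeds over `{A,C,G,U}`.
#' @return DNA heptamers (the site sequence to search for in UTRs).
#' @examples
#' seed_to_site("GAGGUAG")  # let-7 family -> "CTACCTC"
#' @export
seed_to_site <- function(seed) {
  stopifnot(all(nchar(seed) == 7L),
            !grepl("[^ACGU]", seed))
  dna <- chartr("U", "T", seed)
  vapply(dna, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# apply a single variant (UTR-local, 1-based pos, sense-strand alleles)
# to a UTR sequence
apply_variant_seq <- function(utr_seq, pos, ref, alt) {
  len <- nchar(utr_seq)
  if (pos < 1 || pos + nchar(ref) - 1 > len)
    stop("variant lies outside the UTR")
  if (substr(utr_seq, pos, pos + nchar(ref) - 1) != ref)
    stop("reference allele does not match the UTR sequence at position ", pos)
  paste0(substr(utr_seq, 1, pos - 1), alt,
         substr(utr_seq, pos + nchar(ref), len))
}

#' Call miRNA-binding-site gains created by a 3'UTR variant
#'
#' Scans every 7-nt window of the alternate-allele UTR sequence that overlaps
#' the variant and reports a gain event for each catalog miRNA whose target
#' site (reverse complement of the seed) equals the window while being absent
#' from the reference at that position. For substitutions the reference
#' comparison is the same-start window; for indels, where window starts no
#' longer correspond, a gain requires the site heptamer to be absent from the
#' reference sequence in the neighbourhood of the edit. Only 7-nt windows are
#' scanned; 8mer/7mer-A1 site subtypes are not distinguished, and site
#' conservation is not required.
#'
#' @param utr_seq UTR sequence, DNA alphabet, transcript (5'->3')
#'   orientation.
#' @param pos 1-based UTR-local position of the variant (sense strand).
#' @param ref,alt Alleles in the UTR's orientation.
#' @param catalog Data frame with columns `mirna` and `seed` (7-nt RNA).
#' @return Data frame of events: `mirna`, `direction` (`"gain"`), `start`,
#'   `end` (0-based half-open window in UTR-local coordinates). Zero rows if
#'   no site is created.
#' @export
call_mre_gain <- function(utr_seq, pos, ref, alt, catalog) {
  stopifnot(is.data.frame(catalog), all(c("mirna", "seed") %in% names(catalog)))
  alt_seq <- apply_variant_seq(utr_seq, pos, ref, alt)
  sites <- seed_to_site(catalog$seed)
  is_sub <- nchar(ref) == nchar(alt)
  span_end <- pos + nchar(alt) - 1          # edited span in alt coordinates
  starts <- seq(max(1, pos - 6), max(1, min(nchar(alt_seq) - 6, span_end)))
  starts <- starts[starts + 6 <= nchar(alt_seq)]
  out <- list()
  for (s in starts) {
    win <- substr(alt_seq, s, s + 6)
    hit <- which(sites == win)
    if (!length(hit)) next
    if (is_sub) {
      novel <- substr(utr_seq, s, s + 6) != win
    } else {
      lo <- max(1, s - 6)
      hi <- min(nchar(utr_seq), s + 6 + nchar(ref))
      novel <- !grepl(win, substr(utr_seq, lo, hi), fixed = TRUE)
    }
    if (novel)
      out[[length(out) + 1L]] <- data.frame(
        mirna = catalog$mirna[hit], direction = "gain",
        start = s - 1L, end = s + 6L, stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(), direction = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  ev[!duplicated(ev[c("mirna", "start")]), , drop = FALSE]
}

#' Call losses of conserved miRNA-binding sites caused by a 3'UTR variant
#'
#' For each conserved site whose interval overlaps the variant, the site's
#' seed-match heptamer is looked up in the catalog and re-scanned on the
#' reference and alternate sequences restricted to the site interval: a loss
#' is reported when the match present in the reference is absent from the
#' alternate. Any indel overlapping a site interval is treated as impairing
#' the site.
#'
#' @inheritParams call_mre_gain
#' @param sites Data frame of conserved sites with columns `start`, `end`
#'   (0-based half-open, UTR-local), `mirna`, and optionally `site_type`.
#' @return Data frame of events (`mirna`, `direction = "loss"`, `start`,
#'   `end`); zero rows when no site is impaired.
#' @export
call_mre_loss <- function(utr_seq, pos, ref, alt, sites, catalog) {
  stopifnot(is.data.frame(sites),
            all(c("start", "end", "mirna") %in% names(sites)))
  if (pos < 1 || pos + nchar(ref) - 1 > nchar(utr_seq))
    stop("variant lies outside the UTR")
  v_start <- pos - 1L
  v_end <- v_start + nchar(ref)             # 0-based half-open
  if (nchar(ref) == 0L) v_end <- v_start + 1L
  keep <- sites$start < v_end & sites$end > v_start
  hit_sites <- sites[keep, , drop = FALSE]
  out <- list()
  if (nrow(hit_sites)) {
    alt_seq <- apply_variant_seq(utr_seq, pos, ref, alt)
    shift <- nchar(alt) - nchar(ref)
    for (i in seq_len(nrow(hit_sites))) {
      st <- hit_sites$start[i]; en <- hit_sites$end[i]
      seed <- catalog$seed[match(hit_sites$mirna[i], catalog$mirna)]
      if (is.na(seed))
        stop("miRNA family '", hit_sites$mirna[i], "' absent from seed catalog")
      hept <- seed_to_site(seed)
      lost <- if (shift != 0L) {
        TRUE                                 # indel overlapping the site
      } else {
        ref_sub <- substr(utr_seq, st + 1, en)
        alt_sub <- substr(alt_seq, st + 1, en)
        grepl(hept, ref_sub, fixed = TRUE) && !grepl(hept, alt_sub, fixed = TRUE)
      }
      if (lost)
        out[[length(out) + 1L]] <- data.frame(
          mirna = hit_sites$mirna[i], direction = "loss",
          start = st, end = en, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(mirna = character(), direction = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
}

#' Map a genomic variant into UTR-local transcript coordinates
#'
#' Converts a 1-based genomic substitution into the UTR's transcript
#' (5'->3') frame: on the minus strand the position is reflected and the
#' alleles are complemented.
#'
#' @param pos Genomic position (1-based).
#' @param ref,alt Genomic (plus-strand) alleles; single nucleotides.
#' @param utr_start,utr_end UTR interval, 0-based half-open genomic.
#' @param strand `"+"` or `"-"`.
#' @return List with `pos` (1-based UTR-local), `ref`, `alt`.
#' @export
map_to_utr <- function(pos, ref, alt, utr_start, utr_end, strand = "+") {
  if (pos <= utr_start || pos > utr_end) stop("variant lies outside the UTR")
  if (strand == "+") {
    list(pos = pos - utr_start, ref = ref, alt = alt)
  } else {
    list(pos = utr_end - pos + 1L,
         ref = chartr("ACGT", "TGCA", ref),
         alt = chartr("ACGT", "TGCA", alt))
  }
}
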