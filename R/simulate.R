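#' Simulation configuration for a stratified case-control cohort
#'
#' The generator emulates the structure that the association pipeline
#' assumes: a stratified case-control cohort with a rare-variant frequency
#' spectrum, Hardy-Weinberg genotypes within strata, Balding-Nichols allele
#' frequency divergence between strata, sex and ancestry covariates, a
#' logistic disease model with optional protective/deleterious carrier
#' effects in chosen regions, per-site QC metrics with configurable planted
#' failures, and an age model with an optional carrier shift. Defaults
#' reproduce the study conditions the pipeline targets (3,955 cases versus
#' 1,819 matched controls spread over seven geographic strata) at the gene
#' counts of a desk-scale run.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param n_strata Number of geographic subcohorts (default 7).
#' @param n_regions Named counts of genes/regions per class,
#'   `c(ORF=, UTR3=, preMIR=)`; ORF and UTR3 refer to the same genes.
#' @param variants_per_region Inclusive range of rare-variant counts drawn
#'   per region.
#' @param maf_beta,maf_range Beta parameters and truncation range of the
#'   rare-allele frequency spectrum (default Beta(0.3, 30) truncated to
#'   `[1e-4, 0.05]`, which yields both singletons and recurrent variants).
#' @param effect_spec List of planted effects; each element a list with
#'   `gene`, `class` (`"UTR3"` or `"ORF"`), `or` (carrier odds ratio),
#'   `carrier_freq` (control carrier frequency), optional `n_variants`
#'   (default 11) and `age_shift` (years added to carrier cases' ages,
#'   default 0).
#' @param common_snp_count Size of the common-SNP ancestry panel.
#' @param fst Balding-Nichols divergence between strata (default 0.02).
#' @param stratum_case_bias Log-scale tilt of the per-stratum case fraction
#'   (0 = no confounding between stratum and status).
#' @param sex_male_prop Male proportion (both arms; the cohorts are
#'   sex-matched).
#' @param age_mean,age_sd Normal model for case age of diagnosis (years).
#' @param death_lag_mean,death_lag_sd Lag from diagnosis to death (years,
#'   half-normal).
#' @param qc_noise Named rates of planted QC failures among null sites:
#'   `missing`, `depth`, `hwe`, `diffmiss`.
#' @param n_mirnas Seed-catalog size (= number of pre-miRNA genes).
#' @param sites_per_utr Conserved miRNA sites planted per UTR (expected).
#' @param plant_gain Plant one near-miss seed site completed by a variant
#'   (a guaranteed MRE gain) in the first UTR.
#' @param seed Integer seed; fully determines all outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cases = 3955, n_controls = 1819, n_strata = 7,
                       n_regions = c(ORF = 20, UTR3 = 20, preMIR = 8),
                       variants_per_region = c(3, 12),
                       maf_beta = c(0.3, 30), maf_range = c(1e-4, 0.05),
                       effect_spec = list(),
                       common_snp_count = 2000, fst = 0.02,
                       stratum_case_bias = 0.3, sex_male_prop = 0.6,
                       age_mean = 63, age_sd = 10,
                       death_lag_mean = 3, death_lag_sd = 1.5,
                       qc_noise = c(missing = 0, depth = 0, hwe = 0,
                                    diffmiss = 0),
                       n_mirnas = 25, sites_per_utr = 2, plant_gain = TRUE,
                       seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop("cohort arms must be non-empty")
  if (any(n_regions < 1) || n_strata < 1) stop("counts must be positive")
  for (e in effect_spec)
    if (is.null(e$or) || e$or <= 0) stop("effect odds ratios must be positive")
  stopifnot(variants_per_region[1] >= 1,
            variants_per_region[2] >= variants_per_region[1],
            maf_range[1] > 0, maf_range[2] <= 0.5, fst >= 0, fst < 1)
  structure(as.list(environment()), class = "sim_config")
}

# truncated-Beta rare-allele frequencies
draw_maf <- function(n, cfg) {
  lo <- stats::pbeta(cfg$maf_range[1], cfg$maf_beta[1], cfg$maf_beta[2])
  hi <- stats::pbeta(cfg$maf_range[2], cfg$maf_beta[1], cfg$maf_beta[2])
  stats::qbeta(stats::runif(n, lo, hi), cfg$maf_beta[1], cfg$maf_beta[2])
}

# Balding-Nichols per-stratum frequencies around a global frequency
bn_freqs <- function(p, n_strata, fst) {
  if (fst <= 0) return(matrix(p, nrow = length(p), ncol = n_strata))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  matrix(stats::rbeta(length(p) * n_strata, rep(a, n_strata), rep(b, n_strata)),
         nrow = length(p))
}

#' Generate annotation resources for a simulated cohort
#'
#' Produces the gene models (ORF + 3'UTR intervals on autosomes, plus
#' strand), 3'UTR sequences, a miRNA seed catalog, pre-miRNA loci, a
#' conserved-site table whose intervals are genuine seed matches planted in
#' the sequences, and (optionally) a near-miss seed site that a specific
#' variant completes, giving a guaranteed MRE gain with known truth.
#' Simulated genes are plus-strand; minus-strand handling in the callers is
#' exercised by unit-level fixtures rather than the generator.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, BED/FASTA/TSV files
#'   are written and their paths returned in `$paths`.
#' @return Annotation bundle: list with `genes`, `utr_seqs`, `seed_catalog`,
#'   `premirs`, `conserved_sites`, `planted_gain` and optionally `paths`.
#' @export
simulate_annotation_resources <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 104729L, {
    n_genes <- max(config$n_regions["ORF"], config$n_regions["UTR3"])
    genes <- data.frame(
      gene = sprintf("gene%03d", seq_len(n_genes)),
      chrom = as.character(rep_len(1:22, n_genes)),
      strand = "+", stringsAsFactors = FALSE)
    orf_len <- sample(900:3000, n_genes, replace = TRUE)
    utr_len <- sample(300:1500, n_genes, replace = TRUE)
    offset <- 1000000L * (seq_len(n_genes) %/% 22L + 1L) +
      200000L * seq_len(n_genes)
    genes$orf_start <- offset
    genes$orf_end <- offset + orf_len
    genes$utr3_start <- genes$orf_end
    genes$utr3_end <- genes$utr3_start + utr_len

    utr_seqs <- vapply(utr_len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
    names(utr_seqs) <- genes$gene

    seeds <- character(0)
    while (length(seeds) < config$n_mirnas)
      seeds <- unique(c(seeds, paste(sample(c("A", "C", "G", "U"), 7,
                                            replace = TRUE), collapse = "")))
    catalog <- data.frame(mirna = sprintf("mir%03d", seq_len(config$n_mirnas)),
                          seed = seeds[seq_len(config$n_mirnas)],
                          stringsAsFactors = FALSE)

    n_pm <- config$n_regions["preMIR"]
    pm_off <- 90000000L + 5000L * seq_len(n_pm)
    premirs <- data.frame(
      mirna = catalog$mirna[rep_len(seq_len(config$n_mirnas), n_pm)],
      chrom = as.character(rep_len(22:1, n_pm)),
      start = pm_off, end = pm_off + 85L, strand = "+",
      stringsAsFactors = FALSE)

    # plant conserved seed-match sites into the UTR sequences
    cs <- list()
    for (i in seq_len(n_genes)) {
      k <- stats::rpois(1, config$sites_per_utr)
      if (k == 0) next
      len <- utr_len[i]
      starts <- sort(sample(seq(0L, len - 7L, by = 12L),
                            min(k, max(1, len %/% 24)), replace = FALSE))
      for (s in starts) {
        mi <- sample(nrow(catalog), 1)
        site <- seed_to_site(catalog$seed[mi])
        utr_seqs[i] <- paste0(substr(utr_seqs[i], 1, s), site,
                              substr(utr_seqs[i], s + 8, len))
        cs[[length(cs) + 1L]] <- data.frame(
          utr = genes$gene[i], start = s, end = s + 7L,
          mirna = catalog$mirna[mi], site_type = "7mer",
          stringsAsFactors = FALSE)
      }
    }
    conserved_sites <- if (length(cs)) do.call(rbind, cs) else
      data.frame(utr = character(), start = integer(), end = integer(),
                 mirna = character(), site_type = character(),
                 stringsAsFactors = FALSE)

    planted_gain <- NULL
    if (isTRUE(config$plant_gain)) {
      g <- 1L
      len <- utr_len[g]
      s <- len - 20L                          # clear of planted conserved sites
      mi <- sample(nrow(catalog), 1)
      site <- seed_to_site(catalog$seed[mi])
      broken <- site
      mismatch_pos <- 4L
      orig <- substr(site, mismatch_pos, mismatch_pos)
      repl <- setdiff(c("A", "C", "G", "T"), orig)[1]
      substr(broken, mismatch_pos, mismatch_pos) <- repl
      utr_seqs[g] <- paste0(substr(utr_seqs[g], 1, s), broken,
                            substr(utr_seqs[g], s + 8, len))
      planted_gain <- data.frame(
        gene = genes$gene[g], utr_pos = s + mismatch_pos,
        ref = repl, alt = orig, mirna = catalog$mirna[mi],
        window_start = s, stringsAsFactors = FALSE)
    }

    res <- list(genes = genes, utr_seqs = utr_seqs, seed_catalog = catalog,
                premirs = premirs, conserved_sites = conserved_sites,
                planted_gain = planted_gain)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      genes = write_tsv(res$genes, file.path(dir, "genes.tsv")),
      utr_fasta = write_utr_fasta(res$utr_seqs, file.path(dir, "utr3.fasta")),
      seed_catalog = write_tsv(res$seed_catalog,
                               file.path(dir, "seed_catalog.tsv")),
      premirs = write_tsv(res$premirs, file.path(dir, "premirs.tsv")),
      conserved_sites = write_tsv(res$conserved_sites,
                                  file.path(dir, "conserved_sites.tsv")))
    res$paths <- paths
  }
  res
}

#' Simulate a stratified case-control cohort
#'
#' Draws phenotypes, stratum labels, ancestry-panel genotypes and
#' region rare-variant genotypes under the model described in
#' [sim_config()]. Carrier status in effect regions follows the configured
#' odds ratio exactly: control carriers arise at the configured frequency
#' and case carriers at the odds-tilted frequency, carriers then being
#' assigned one heterozygous member variant drawn from the rare-frequency
#' spectrum (so effect regions contain singleton and recurrent variants).
#' A held-out truth object records true MAFs, effects and planted QC
#' failures; analysis modules never consume it.
#'
#' @param config A [sim_config()].
#' @param resources Annotation bundle from
#'   [simulate_annotation_resources()]; generated from `config` if `NULL`.
#' @param dir Optional output directory; when given, the VCF, panel VCF,
#'   phenotype and truth tables are written and their paths returned.
#' @return Object of class `sim_cohort`: list with `phenotypes`, `sites`,
#'   `geno`, `panel_sites`, `panel_geno`, `prediction`, `resources`,
#'   `truth`, and `paths` when written.
#' @export
simulate_cohort <- function(config, resources = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(resources)) resources <- simulate_annotation_resources(config)
  genes <- resources$genes
  n <- config$n_cases + config$n_controls
  with_seed(config$seed + 15485863L, {
    ## phenotypes -------------------------------------------------------
    status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    w_base <- stats::rexp(config$n_strata) + 0.5
    # deterministic tilt: the bias parameter, not a random draw, sets the
    # strength of stratum/status confounding
    tilt <- exp(config$stratum_case_bias *
                  seq(-1, 1, length.out = config$n_strata))
    p_ctrl <- w_base / sum(w_base)
    p_case <- w_base * tilt / sum(w_base * tilt)
    stratum <- integer(n)
    stratum[status == "case"] <- sample.int(config$n_strata, config$n_cases,
                                            replace = TRUE, prob = p_case)
    stratum[status == "control"] <- sample.int(config$n_strata,
                                               config$n_controls,
                                               replace = TRUE, prob = p_ctrl)
    sex <- ifelse(stats::runif(n) < config$sex_male_prop, "male", "female")
    age_diag <- ifelse(status == "case",
                       stats::rnorm(n, config$age_mean, config$age_sd), NA)
    age_death <- age_diag + abs(stats::rnorm(n, config$death_lag_mean,
                                             config$death_lag_sd))
    phenotypes <- data.frame(
      sample = sprintf("S%05d", seq_len(n)), status = status, sex = sex,
      stratum = paste0("stratum", stratum),
      age_diagnosis = round(age_diag, 1), age_death = round(age_death, 1),
      stringsAsFactors = FALSE)

    ## region variants --------------------------------------------------
    effect_genes <- vapply(config$effect_spec, function(e)
      paste(e$gene, e$class), character(1))
    site_rows <- list(); geno_cols <- list(); truth_rows <- list()
    add_variant <- function(id, chrom, pos, ref, alt, region, class, g,
                            true_maf) {
      site_rows[[length(site_rows) + 1L]] <<- data.frame(
        chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
        dp = 0L, region = region, class = class, stringsAsFactors = FALSE)
      geno_cols[[length(geno_cols) + 1L]] <<- g
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        variant = id, true_maf = true_maf, region = region, class = class,
        stringsAsFactors = FALSE)
    }
    null_region <- function(region, class, chrom, start, end,
                            seq_local = NULL) {
      m <- sample(config$variants_per_region[1]:config$variants_per_region[2], 1)
      m <- min(m, end - start)
      offs <- sort(sample.int(end - start, m))       # 1-based local offsets
      mafs <- draw_maf(m)
      ps <- bn_freqs(mafs, config$n_strata, config$fst)
      for (j in seq_len(m)) {
        pos <- start + offs[j]
        if (!is.null(seq_local)) {
          ref <- substr(seq_local, offs[j], offs[j])
        } else ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        pvec <- ps[j, stratum]
        g <- stats::rbinom(n, 2L, pvec)
        add_variant(paste0(region, "_v", j), chrom, pos, ref, alt,
                    region, class, g, mafs[j])
      }
    }
    draw_maf <- function(m) {
      lo <- stats::pbeta(config$maf_range[1], config$maf_beta[1],
                         config$maf_beta[2])
      hi <- stats::pbeta(config$maf_range[2], config$maf_beta[1],
                         config$maf_beta[2])
      stats::qbeta(stats::runif(m, lo, hi), config$maf_beta[1],
                   config$maf_beta[2])
    }
    effect_region <- function(e, region, class, chrom, start, end,
                              seq_local = NULL) {
      m <- if (is.null(e$n_variants)) 11L else e$n_variants
      m <- min(m, end - start)
      q0 <- e$carrier_freq
      odds1 <- e$or * q0 / (1 - q0)
      q1 <- odds1 / (1 + odds1)
      carrier <- stats::runif(n) < ifelse(status == "case", q1, q0)
      share <- draw_maf(m)
      share <- share / sum(share)
      which_v <- sample.int(m, sum(carrier), replace = TRUE, prob = share)
      offs <- sort(sample.int(end - start, m))
      for (j in seq_len(m)) {
        pos <- start + offs[j]
        if (!is.null(seq_local)) ref <- substr(seq_local, offs[j], offs[j])
        else ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        g <- integer(n)
        g[which(carrier)[which_v == j]] <- 1L
        add_variant(paste0(region, "_v", j), chrom, pos, ref, alt,
                    region, class, g, sum(g) / (2 * n))
      }
      if (!is.null(e$age_shift) && e$age_shift != 0) {
        shift <- carrier & status == "case"
        phenotypes$age_diagnosis[shift] <<-
          phenotypes$age_diagnosis[shift] + e$age_shift
        phenotypes$age_death[shift] <<-
          phenotypes$age_death[shift] + e$age_shift
      }
      invisible(carrier)
    }

    n_orf <- config$n_regions["ORF"]; n_utr <- config$n_regions["UTR3"]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (i <= n_orf) {
        key <- paste(g$gene, "ORF")
        hit <- match(key, effect_genes)
        if (!is.na(hit))
          effect_region(config$effect_spec[[hit]], paste0(g$gene, ".orf"),
                        "ORF", g$chrom, g$orf_start, g$orf_end)
        else null_region(paste0(g$gene, ".orf"), "ORF", g$chrom,
                         g$orf_start, g$orf_end)
      }
      if (i <= n_utr) {
        key <- paste(g$gene, "UTR3")
        hit <- match(key, effect_genes)
        seq_l <- resources$utr_seqs[[g$gene]]
        if (!is.na(hit))
          effect_region(config$effect_spec[[hit]], paste0(g$gene, ".utr3"),
                        "UTR3", g$chrom, g$utr3_start, g$utr3_end, seq_l)
        else null_region(paste0(g$gene, ".utr3"), "UTR3", g$chrom,
                         g$utr3_start, g$utr3_end, seq_l)
      }
    }
    for (i in seq_len(nrow(resources$premirs))) {
      pm <- resources$premirs[i, ]
      null_region(paste0(pm$mirna, ".premir"), "preMIR", pm$chrom,
                  pm$start, pm$end)
    }
    # the planted gain variant, if its position was not already drawn
    if (!is.null(resources$planted_gain)) {
      pg <- resources$planted_gain
      gi <- match(pg$gene, genes$gene)
      pos <- genes$utr3_start[gi] + pg$utr_pos
      if (!any(vapply(site_rows, function(s)
        s$chrom == genes$chrom[gi] && s$pos == pos, logical(1)))) {
        g <- integer(n)                    # singleton carrier: a sequence
        g[sample.int(n, 1)] <- 1L          # fixture, not a frequency player
        add_variant(paste0(pg$gene, ".utr3_gain"), genes$chrom[gi], pos,
                    pg$ref, pg$alt, paste0(pg$gene, ".utr3"), "UTR3", g,
                    0.5 / n)
      }
    }

    sites <- do.call(rbind, site_rows)
    geno <- do.call(cbind, geno_cols)
    colnames(geno) <- sites$id
    rownames(geno) <- phenotypes$sample
    truth_maf <- do.call(rbind, truth_rows)

    ## site depth + planted QC failures ---------------------------------
    m_tot <- nrow(sites)
    sites$dp <- as.integer(round(stats::runif(m_tot, 40000, 180000)))
    planted <- data.frame(variant = character(), filter = character(),
                          stringsAsFactors = FALSE)
    is_effect <- sites$region %in% vapply(
      config$effect_spec, function(e)
        paste0(e$gene, ".", tolower(e$class)), character(1))
    pool <- which(!is_effect)
    plant <- function(rate) {
      k <- stats::rbinom(1, length(pool), rate)
      if (k == 0) return(integer(0))
      picked <- sample(pool, k)
      pool <<- setdiff(pool, picked)
      picked
    }
    for (j in plant(config$qc_noise[["missing"]])) {
      idx <- sample.int(n, ceiling(n * stats::runif(1, 0.08, 0.3)))
      geno[idx, j] <- NA
      planted <- rbind(planted, data.frame(variant = sites$id[j],
                                           filter = "missingness"))
    }
    for (j in plant(config$qc_noise[["depth"]])) {
      sites$dp[j] <- if (stats::runif(1) < 0.5)
        as.integer(round(stats::runif(1, 100, 9000)))
      else as.integer(round(stats::runif(1, 227000, 400000)))
      planted <- rbind(planted, data.frame(variant = sites$id[j],
                                           filter = "depth"))
    }
    ctrl_idx <- which(status == "control")
    for (j in plant(config$qc_noise[["hwe"]])) {
      k <- min(15L, max(4L, length(ctrl_idx) %/% 20L))
      geno[, j] <- 0L
      geno[sample(ctrl_idx, k), j] <- 2L
      planted <- rbind(planted, data.frame(variant = sites$id[j],
                                           filter = "hwe"))
    }
    case_idx <- which(status == "case")
    for (j in plant(config$qc_noise[["diffmiss"]])) {
      geno[sample(case_idx, max(10L, length(case_idx) %/% 8L)), j] <- NA
      planted <- rbind(planted, data.frame(variant = sites$id[j],
                                           filter = "diff_missing"))
    }

    ## coding prediction table ------------------------------------------
    coding <- sites$id[sites$class == "ORF"]
    cons <- sample(c("missense", "frameshift", "splice", "stop_gain",
                     "stop_loss", "other"), length(coding), replace = TRUE,
                   prob = c(0.6, 0.08, 0.06, 0.05, 0.01, 0.2))
    calls <- matrix(0L, length(coding), 7,
                    dimnames = list(NULL, c("sift", "polyphen2_hvar", "lrt",
                                            "mutation_taster",
                                            "mutation_assessor", "fathmm",
                                            "metalr")))
    for (i in seq_along(coding)) {
      k <- stats::rbinom(1, 7, 0.45)
      if (k > 0) calls[i, sample.int(7, k)] <- 1L
    }
    prediction <- data.frame(variant = coding, consequence = cons, calls,
                             stringsAsFactors = FALSE)

    ## ancestry panel ----------------------------------------------------
    pf <- stats::runif(config$common_snp_count, 0.05, 0.5)
    pps <- bn_freqs(pf, config$n_strata, config$fst)
    panel_geno <- matrix(stats::rbinom(n * config$common_snp_count, 2L,
                                       t(pps[, stratum])),
                         nrow = n, byrow = FALSE)
    panel_sites <- data.frame(
      chrom = as.character(rep_len(1:22, config$common_snp_count)),
      pos = 50000000L + 500L * seq_len(config$common_snp_count),
      id = sprintf("snp%06d", seq_len(config$common_snp_count)),
      ref = "A", alt = "G", dp = 100000L, stringsAsFactors = FALSE)
    colnames(panel_geno) <- panel_sites$id
    rownames(panel_geno) <- phenotypes$sample

    cohort <- structure(list(
      config = config, resources = resources, phenotypes = phenotypes,
      sites = sites, geno = geno, prediction = prediction,
      panel_sites = panel_sites, panel_geno = panel_geno,
      truth = list(maf = truth_maf,
                   effects = config$effect_spec,
                   planted_qc = planted,
                   stratum = phenotypes$stratum)),
      class = "sim_cohort")
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      vcf = write_vcf(cohort$sites, cohort$geno, cohort$phenotypes$sample,
                      file.path(dir, "cohort.vcf")),
      panel_vcf = write_vcf(cohort$panel_sites, cohort$panel_geno,
                            cohort$phenotypes$sample,
                            file.path(dir, "panel.vcf")),
      phenotypes = write_phenotypes(cohort$phenotypes,
                                    file.path(dir, "phenotypes.tsv")),
      prediction = write_tsv(cohort$prediction,
                             file.path(dir, "predictions.tsv")),
      truth_maf = write_tsv(cohort$truth$maf, file.path(dir, "truth_maf.tsv")),
      truth_qc = write_tsv(cohort$truth$planted_qc,
                           file.path(dir, "truth_qc.tsv")))
    cohort$paths <- paths
  }
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated case-control cohort\n")
  cat(sprintf("  %d cases / %d controls in %d strata\n",
              x$config$n_cases, x$config$n_controls, x$config$n_strata))
  cat(sprintf("  %d rare-variant sites in %d regions; %d-SNP ancestry panel\n",
              nrow(x$sites), length(unique(x$sites$region)),
              nrow(x$panel_sites)))
  if (length(x$config$effect_spec))
    cat("  planted effects:",
        paste(vapply(x$config$effect_spec, function(e)
          sprintf("%s %s OR=%.2f", e$gene, e$class, e$or), character(1)),
          collapse = "; "), "\n")
  invisible(x)
}
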