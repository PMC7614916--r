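#' Annotate 3'UTR variants with miRNA-recognition-element events
#'
#' Maps each substitution falling inside an (unpadded) 3'UTR into UTR-local
#' transcript coordinates and runs the conserved-site loss caller and the
#' exhaustive mutated-window gain scan.
#'
#' @param sites Site table (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param resources Annotation bundle (see
#'   [simulate_annotation_resources()]).
#' @return Data frame: `variant`, `utr`, `mirna`, `direction`, `start`,
#'   `end` (UTR-local, 0-based half-open). Zero rows when nothing is hit.
#' @export
annotate_mre <- function(sites, resources) {
  genes <- resources$genes
  out <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    gi <- which(genes$chrom == s$chrom & s$pos > genes$utr3_start &
                  s$pos <= genes$utr3_end)
    if (!length(gi)) next
    gi <- gi[1]
    loc <- map_to_utr(s$pos, s$ref, s$alt, genes$utr3_start[gi],
                      genes$utr3_end[gi], genes$strand[gi])
    seq <- resources$utr_seqs[[genes$gene[gi]]]
    cs <- resources$conserved_sites
    cs <- cs[cs$utr == genes$gene[gi], , drop = FALSE]
    ev <- rbind(
      call_mre_loss(seq, loc$pos, loc$ref, loc$alt, cs,
                    resources$seed_catalog),
      call_mre_gain(seq, loc$pos, loc$ref, loc$alt, resources$seed_catalog))
    if (nrow(ev))
      out[[length(out) + 1L]] <- cbind(
        data.frame(variant = s$id, utr = genes$gene[gi],
                   stringsAsFactors = FALSE), ev)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(variant = character(), utr = character(), mirna = character(),
               direction = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] driving the simulate stage.
#' @param thresholds A [qc_thresholds()] object.
#' @param maf_cutoff Control-MAF rarity cutoff (default 0.01).
#' @param classes Unit classes to run.
#' @param tests Association tests to run.
#' @param test_config An [rv_test_config()].
#' @param n_pcs Number of ancestry PCs (default 10).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            thresholds = qc_thresholds(),
                            maf_cutoff = 0.01,
                            classes = c("ORF", "UTR3", "UTR3_MRE", "preMIR",
                                        "MIR_NETWORK"),
                            tests = c("SKATO", "SKAT", "CMC", "VT"),
                            test_config = rv_test_config(),
                            n_pcs = 10L) {
  structure(list(sim = sim, thresholds = thresholds, maf_cutoff = maf_cutoff,
                 classes = classes, tests = tests, test_config = test_config,
                 n_pcs = n_pcs),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "qc", "covariates", "annotate", "collapse",
                     "associate", "epi", "onset", "report")

stage_outputs <- list(
  simulate = c("cohort.vcf", "panel.vcf", "phenotypes.tsv", "predictions.tsv",
               "annotation/genes.tsv"),
  qc = "qc_pass.tsv",
  covariates = "covariates.tsv",
  annotate = "qualifying.tsv",
  collapse = "membership.tsv",
  associate = "results.tsv",
  epi = "epi.tsv",
  onset = "onset.tsv",
  report = "report.txt")

stage_upstream <- list(
  simulate = character(0), qc = "simulate", covariates = "simulate",
  annotate = c("simulate", "qc"), collapse = c("simulate", "annotate"),
  associate = c("collapse", "covariates"), epi = c("collapse"),
  onset = c("collapse"), report = c("associate", "epi"))

manifest_add <- function(dir, stage, files) {
  files <- files[file.exists(files)]
  md5 <- tools::md5sum(files)
  df <- data.frame(stage = stage, file = basename(names(md5)), md5 = md5,
                   stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(df)
}

check_upstream <- function(dir, stage) {
  for (up in stage_upstream[[stage]]) {
    need <- file.path(dir, stage_outputs[[up]])
    if (!all(file.exists(need)))
      stop("stage '", stage, "' requires outputs of stage '", up,
           "'; run stage '", up, "' first", call. = FALSE)
  }
}

# shared loaders -----------------------------------------------------------
load_annotation_dir <- function(dir) {
  ad <- file.path(dir, "annotation")
  list(genes = read_tsv(file.path(ad, "genes.tsv")),
       utr_seqs = read_utr_fasta(file.path(ad, "utr3.fasta")),
       seed_catalog = read_tsv(file.path(ad, "seed_catalog.tsv")),
       premirs = read_tsv(file.path(ad, "premirs.tsv")),
       conserved_sites = read_tsv(file.path(ad, "conserved_sites.tsv")))
}

load_cohort_dir <- function(dir) {
  cv <- read_vcf_cohort(file.path(dir, "cohort.vcf"))
  list(sites = cv$sites, geno = cv$geno,
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")))
}

#' Run a single pipeline stage
#'
#' Stages: `simulate`, `qc`, `covariates`, `annotate`, `collapse`,
#' `associate`, `epi`, `onset`, `report`, in that dependency order. Each
#' stage reads only the files previous stages wrote under `dir`, writes its
#' outputs there, and appends `(stage, file, md5)` lines to
#' `dir/manifest.tsv`, so reruns with identical inputs are byte-identical
#' and verifiable.
#'
#' @param stage Stage name.
#' @param config A [pipeline_config()].
#' @param dir Working directory of the pipeline run.
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(stage, config, dir) {
  stage <- match.arg(stage, pipeline_stages)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  check_upstream(dir, stage)
  out <- switch(stage,
    simulate = {
      res <- simulate_annotation_resources(config$sim,
                                           dir = file.path(dir, "annotation"))
      simulate_cohort(config$sim, resources = res, dir = dir)
    },
    qc = {
      ch <- load_cohort_dir(dir)
      qc <- apply_site_qc(ch$sites, ch$geno, ch$phenotypes, config$thresholds)
      write_tsv(ch$sites[qc$pass, ], file.path(dir, "qc_pass.tsv"))
      write_tsv(qc$report, file.path(dir, "qc_report.tsv"))
      write_tsv(data.frame(filter = names(qc$counts),
                           rejected = as.integer(qc$counts)),
                file.path(dir, "qc_counts.tsv"))
      qc
    },
    covariates = {
      pv <- read_vcf_cohort(file.path(dir, "panel.vcf"))
      ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
      keep <- select_common_snps(pv$sites, pv$geno)
      pruned <- ld_prune(pv$geno[, keep, drop = FALSE])
      pcs <- compute_pcs(pv$geno[, pruned, drop = FALSE], k = config$n_pcs)
      cov <- build_covariates(ph, pcs)
      write_tsv(cov, file.path(dir, "covariates.tsv"))
      write_tsv(data.frame(component = seq_along(pcs$varexp),
                           varexp = pcs$varexp),
                file.path(dir, "scree.tsv"))
      cov
    },
    annotate = {
      ch <- load_cohort_dir(dir)
      ann <- load_annotation_dir(dir)
      pass <- read_tsv(file.path(dir, "qc_pass.tsv"))$id
      sites <- ch$sites[ch$sites$id %in% pass, ]
      pred <- read_tsv(file.path(dir, "predictions.tsv"))
      maf <- vapply(sites$id, function(v)
        control_maf(ch$geno[, v], ch$phenotypes$status), numeric(1))
      coding_ok <- rep(FALSE, nrow(sites))
      pi <- match(sites$id, pred$variant)
      has_pred <- !is.na(pi)
      if (any(has_pred))
        coding_ok[has_pred] <- classify_coding_qualifying(
          pred[pi[has_pred], -1])
      mre <- annotate_mre(sites, ann)
      write_tsv(mre, file.path(dir, "mre_events.tsv"))
      qual <- data.frame(variant = sites$id, control_maf = maf,
                         rare = maf <= config$maf_cutoff,
                         coding_qualifying = coding_ok,
                         mre_event = sites$id %in% mre$variant,
                         stringsAsFactors = FALSE)
      write_tsv(qual, file.path(dir, "qualifying.tsv"))
      qual
    },
    collapse = {
      ch <- load_cohort_dir(dir)
      ann <- load_annotation_dir(dir)
      qual <- read_tsv(file.path(dir, "qualifying.tsv"))
      sites <- ch$sites[match(qual$variant, ch$sites$id), ]
      member <- list()
      for (cls in config$classes) {
        units <- build_units(ann, cls)
        asg <- assign_variants(units, sites)
        ok <- switch(cls,
          ORF = qual$rare & qual$coding_qualifying,
          UTR3_MRE = qual$rare & qual$mre_event,
          qual$rare)
        asg <- asg[asg$variant %in% qual$variant[ok], , drop = FALSE]
        if (nrow(asg)) {
          asg$class <- cls
          member[[cls]] <- asg
        }
      }
      mem <- if (length(member)) do.call(rbind, member) else
        data.frame(unit = character(), variant = character(),
                   class = character())
      rownames(mem) <- NULL
      write_tsv(mem, file.path(dir, "membership.tsv"))
      mem
    },
    associate = {
      ch <- load_cohort_dir(dir)
      ann <- load_annotation_dir(dir)
      mem <- read_tsv(file.path(dir, "membership.tsv"))
      cov <- read_tsv(file.path(dir, "covariates.tsv"))
      dat <- cbind(ch$phenotypes["status"], cov[-1])
      pcs <- grep("^PC", names(cov), value = TRUE)
      null <- rv_null_model(
        stats::reformulate(c("sex", pcs), response = "status"), dat)
      regions <- list()
      for (cls in unique(mem$class)) {
        units <- build_units(ann, cls)
        sub <- mem[mem$class == cls, ]
        for (uid in unique(sub$unit)) {
          regions[[uid]] <- collect_genotypes(
            units[[uid]], sub$variant[sub$unit == uid], ch$geno,
            ch$phenotypes,
            weight_beta = config$test_config$weight_beta)
        }
      }
      scan <- rv_scan(regions, null, tests = config$tests,
                      config = config$test_config)
      write_tsv(scan$results, file.path(dir, "results.tsv"))
      scan
    },
    epi = {
      ch <- load_cohort_dir(dir)
      mem <- read_tsv(file.path(dir, "membership.tsv"))
      rows <- list(); forest <- list()
      for (uid in unique(mem$unit)) {
        vs <- intersect(mem$variant[mem$unit == uid], colnames(ch$geno))
        if (!length(vs)) next
        tb <- carrier_table(ch$geno[, vs, drop = FALSE], ch$phenotypes,
                            unit = uid)
        or <- tryCatch(odds_ratio(tb), error = function(e) NULL)
        rows[[uid]] <- data.frame(
          unit = uid, class = mem$class[mem$unit == uid][1],
          a = tb$a, b = tb$b, c = tb$c, d = tb$d,
          freq_case = carrier_frequency(tb, "case"),
          freq_control = carrier_frequency(tb, "control"),
          or = if (is.null(or)) NA else or$or,
          lo = if (is.null(or)) NA else or$lo,
          hi = if (is.null(or)) NA else or$hi,
          corrected = !is.null(or) && or$correction == "haldane",
          p_fisher = fisher_exact(tb), stringsAsFactors = FALSE)
      }
      epi <- do.call(rbind, rows)
      rownames(epi) <- NULL
      write_tsv(epi, file.path(dir, "epi.tsv"))
      # per-stratum forest for the unit with the smallest Fisher p
      top <- epi$unit[which.min(epi$p_fisher)]
      vs <- intersect(mem$variant[mem$unit == top], colnames(ch$geno))
      tabs <- lapply(split(seq_len(nrow(ch$phenotypes)),
                           ch$phenotypes$stratum), function(idx)
        carrier_table(ch$geno[idx, vs, drop = FALSE],
                      ch$phenotypes[idx, ], unit = top))
      forest <- tryCatch(stratified_forest(tabs), error = function(e)
        data.frame())
      write_tsv(forest, file.path(dir, "forest.tsv"))
      epi
    },
    onset = {
      ch <- load_cohort_dir(dir)
      mem <- read_tsv(file.path(dir, "membership.tsv"))
      epi <- read_tsv(file.path(dir, "epi.tsv"))
      top <- epi$unit[which.min(epi$p_fisher)]
      vs <- intersect(mem$variant[mem$unit == top], colnames(ch$geno))
      rows <- list()
      for (endpoint in c("age_diagnosis", "age_death")) {
        res <- tryCatch(
          onset_comparison(ch$geno[, vs, drop = FALSE], ch$phenotypes,
                           age_col = endpoint, n_mc = 10000L,
                           seed = config$sim$seed),
          error = function(e) NULL)
        if (!is.null(res))
          rows[[endpoint]] <- data.frame(
            endpoint = sub("age_", "", endpoint), unit = top,
            n_carriers = res$n_a, n_noncarriers = res$n_b,
            mean_shift = res$mean_diff, t = res$t, perm_p = res$p,
            d = res$d, n_mc = res$n_mc, seed = res$seed,
            stringsAsFactors = FALSE)
      }
      onset <- if (length(rows)) do.call(rbind, rows) else
        data.frame(endpoint = character())
      rownames(onset) <- NULL
      write_tsv(onset, file.path(dir, "onset.tsv"))
      onset
    },
    report = make_report(dir))
  manifest_add(dir, stage, file.path(dir, stage_outputs[[stage]]))
  invisible(out)
}

#' Run the full pipeline
#'
#' Executes all stages in dependency order under a single directory and a
#' single global seed (carried by the simulation config and fanned out to
#' every stochastic stage).
#'
#' @inheritParams run_stage
#' @param stages Stages to run (default: all, in order).
#' @return The report object, invisibly.
#' @export
run_pipeline <- function(config, dir, stages = pipeline_stages) {
  out <- NULL
  for (s in stages) out <- run_stage(s, config, dir)
  invisible(out)
}

#' Summarize a completed pipeline run
#'
#' Collects per-class QQ/genomic-inflation tables, the top units per test,
#' carrier tables and forest data into a plain-text report plus
#' machine-readable TSVs. Empty results give an empty-but-valid report.
#' Regeneration is idempotent.
#'
#' @param dir Pipeline directory with `results.tsv` and `epi.tsv`.
#' @return List with `lambda` (per class/test), `top` (best unit per test),
#'   `epi`, written alongside `report.txt`.
#' @export
make_report <- function(dir) {
  res_path <- file.path(dir, "results.tsv")
  epi_path <- file.path(dir, "epi.tsv")
  if (!file.exists(res_path) || !file.exists(epi_path))
    stop("stage 'report' requires outputs of stages 'associate' and 'epi'; ",
         "run those stages first", call. = FALSE)
  res <- read_tsv(res_path)
  epi <- read_tsv(epi_path)
  lam_rows <- list(); qq_rows <- list()
  if (nrow(res)) {
    for (grp in split(res, paste(res$class, res$test))) {
      if (nrow(grp) < 10) next
      ql <- qq_lambda(grp$p)
      lam_rows[[paste(grp$class[1], grp$test[1])]] <- data.frame(
        class = grp$class[1], test = grp$test[1], n_units = nrow(grp),
        lambda = ql$lambda, stringsAsFactors = FALSE)
      qq_rows[[paste(grp$class[1], grp$test[1])]] <- cbind(
        class = grp$class[1], test = grp$test[1], ql$qq)
    }
  }
  lambda <- if (length(lam_rows)) do.call(rbind, lam_rows) else
    data.frame(class = character(), test = character(),
               n_units = integer(), lambda = numeric())
  rownames(lambda) <- NULL
  qq <- if (length(qq_rows)) do.call(rbind, qq_rows) else data.frame()
  write_tsv(lambda, file.path(dir, "lambda.tsv"))
  write_tsv(qq, file.path(dir, "qq.tsv"))
  top <- if (nrow(res)) do.call(rbind, lapply(split(res, res$test), function(g)
    g[which.min(g$p), ])) else data.frame()
  lines <- c("rvregion pipeline report", "========================", "",
             sprintf("tested unit-test pairs: %d", nrow(res)),
             "", "genomic inflation by class/test:",
             utils::capture.output(print(lambda, row.names = FALSE)),
             "", "top unit per test:",
             utils::capture.output(print(
               if (nrow(res)) top[c("unit", "class", "test", "p", "q")] else
                 data.frame(), row.names = FALSE)),
             "", "carrier tables (epi):",
             utils::capture.output(print(utils::head(
               epi[order(epi$p_fisher), ], 10), row.names = FALSE)))
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(list(lambda = lambda, top = top, epi = epi))
}
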