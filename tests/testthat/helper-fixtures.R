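# shared fixture builders for the test suite; everything is generated in
# code under fixed seeds

# region matrix around a raw dosage matrix (control MAF + Beta(1,25) weights)
make_region_matrix <- function(G, status, unit = "u1", class = "UTR3") {
  maf <- vapply(seq_len(ncol(G)), function(j) control_maf(G[, j], status),
                numeric(1))
  maf <- pmax(maf, 1e-4)
  structure(list(unit = unit, class = class, G = G, maf = maf,
                 weights = stats::dbeta(maf, 1, 25)),
            class = "region_matrix")
}

# intercept-only null model from a status vector
make_null <- function(status) {
  rv_null_model(status ~ 1, data.frame(status = status))
}

# small binomial genotype matrix
make_geno <- function(n, mafs, seed = 1) {
  set.seed(seed)
  G <- sapply(mafs, function(p) rbinom(n, 2, p))
  colnames(G) <- paste0("v", seq_along(mafs))
  G
}

# independent HWE oracle: conditional distribution of the heterozygote
# count by the ratio recurrence (a different algorithmic route than the
# package's closed-form log-gamma evaluation)
hwe_oracle_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_bb + n_ab
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  if (length(hets) > 1) {
    for (k in 2:length(hets)) {
      h <- hets[k]
      # P(h) / P(h-2) = 4 * n_hom_min(h-2) * n_hom_maj(h-2) / (h * (h-1))
      hom_min_prev <- (n_minor - hets[k - 1]) / 2
      hom_maj_prev <- (2 * n - n_minor - hets[k - 1]) / 2
      probs[k] <- probs[k - 1] * 4 * hom_min_prev * hom_maj_prev /
        (h * (h - 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# brute-force MRE gain oracle: rescan the full reference and alternate
# sequences for every catalog site heptamer and diff the (mirna, start)
# match sets
mre_gain_oracle <- function(utr_seq, pos, ref, alt, catalog) {
  alt_seq <- paste0(substr(utr_seq, 1, pos - 1), alt,
                    substr(utr_seq, pos + nchar(ref), nchar(utr_seq)))
  scan <- function(s) {
    hits <- list()
    for (i in seq_len(nrow(catalog))) {
      site <- seed_to_site(catalog$seed[i])
      starts <- gregexpr(site, s, fixed = TRUE)[[1]]
      if (starts[1] != -1)
        hits[[i]] <- paste(catalog$mirna[i], starts - 1L)
    }
    as.character(unlist(hits))
  }
  setdiff(scan(alt_seq), scan(utr_seq))
}

random_utr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_catalog <- function(k) {
  seeds <- unique(replicate(k * 2, paste(sample(c("A", "C", "G", "U"), 7,
                                                replace = TRUE),
                                         collapse = "")))[seq_len(k)]
  data.frame(mirna = paste0("m", seq_len(k)), seed = seeds,
             stringsAsFactors = FALSE)
}
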