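---
title: "Methods: region-based rare-variant association for regulatory regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-based rare-variant association for regulatory regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, the numerical choices, and
the known limitations.

## The analysis

The package tests whether rare variants (control minor-allele frequency
≤ 0.01) aggregated over a functional unit — a protein-coding ORF, a
3'UTR, a pre-miRNA locus, or a miRNA–target network joining one mature
miRNA with the 3'UTRs that carry a conserved site for it — are jointly
associated with case status. Units are built from annotation intervals
padded by ±300 bp so that splice junctions are covered; a unit enters
testing only when at least two qualifying variants fall in it (units
below that are excluded from testing and from the FDR denominator, not
assigned p = 1).

Qualifying rules. Coding variants qualify when predicted to cause a
frameshift, canonical-splice disruption or stop gain/loss, or when a
missense substitution is called deleterious by at least three of seven
prediction programs (SIFT, PolyPhen2-HVAR, LRT, MutationTaster,
MutationAssessor, FATHMM, MetaLR). Noncoding variants qualify by
location (3'UTR, pre-miRNA) or, for the MRE unit class, by causing a
miRNA-recognition-element loss or gain.

MRE calling. Seeds are 7-nt RNA strings (mature positions 2–8); a target
site is the reverse complement of the seed after U→T conversion, matched
on the sense-strand UTR sequence in transcript orientation. A *loss* is
a conserved-site interval whose seed match present in the reference is
absent from the alternate sequence; any indel overlapping a site
interval counts as impairing it. A *gain* scans every 7-nt window of the
alternate sequence overlapping the variant and reports catalog seeds
whose site equals the window but not the corresponding reference window.
Only 7-nt windows are scanned — 8mer and 7mer-A1 subtypes are not
distinguished, and the gain scan does not require conservation; both
simplifications are deliberate and documented here because the
literature supports several conventions.

## The association statistics

All tests are score tests under one logistic null model of status on sex
and the top 10 ancestry principal components; with fitted probabilities
$\hat\mu$, residuals $r = y - \hat\mu$, and $P$ the covariate-projected
variance, the score covariance of any burden vector or genotype matrix
follows in closed form, so a scan costs one glm fit plus cheap quadratic
forms.

* **Burden/CMC**: the collapsed carrier indicator (any minor allele in
  the unit, missing genotypes counting as non-carrying) is score-tested
  two-sidedly. With a single rare-frequency bin this is the
  covariate-adjusted score form of the combined multivariate and
  collapsing test; it may diverge from other CMC flavors that use
  multiple frequency bins.
* **SKAT**: $Q = r^\top G W^2 G^\top r$ with $w_j =
  \mathrm{Beta}(\hat f_j; 1, 25)$ evaluated at the control MAF. The null
  law is $\sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the eigenvalues of
  the projected kernel.
* **SKAT-O**: $Q_\rho = (1-\rho) Q_{SKAT} + \rho Q_{burden}$ over the
  grid $\{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$; the minimum
  per-$\rho$ p-value is combined by conditioning on the common
  one-degree component along the mean-genotype direction and integrating
  the crossing probability, capped by the grid-size Bonferroni bound.
  The endpoint grids reduce exactly to SKAT ($\rho = 0$) and the
  weighted burden test ($\rho = 1$).
* **VT**: the maximum absolute standardized burden score over all
  distinct observed MAF thresholds; significance by permutation.

Weighted-chi-square tails are computed by numerical inversion of the
characteristic function (Imhof's integral, adaptive quadrature with the
$\chi^2_1$ singularity removed by the substitution $x = t^2$), with the
Liu–Tang–Zhang moment-matching approximation as fallback when the
inversion fails or the tail mass is below the quadrature's reliable
range (~1e-9). Inside the SKAT-O combination integral the conditional
remainder tail uses the moment-matching form directly: it is smooth and
far cheaper per quadrature node, and the per-$\rho$ p-values themselves
keep the exact inversion. The test suite checks the resulting p-values
against permutation oracles, the endpoint reductions, and the grid
Bonferroni bound.

Permutations permute the null-model residuals (Freedman–Lane style),
which preserves the covariate structure and coincides with label
permutation under an intercept-only model; p-values use the
$(1 + \#\{T^{perm} \ge T^{obs}\})/(1 + B)$ convention, so they are never
zero and are conservative in the presence of ties. Exact enumeration
over case-label assignments is available for small intercept-only
fixtures. FDR is Benjamini–Hochberg within each unit class and test.

## Carrier-level epidemiology

Carrier 2×2 tables use sample-level carrier status (not allele counts).
The odds ratio is the cross-product ratio; when any cell is zero the
Haldane–Anscombe correction adds 0.5 to all four cells and the estimate
is flagged. Confidence intervals are Woolf (log-normal) — the CI method
is a package decision, as printed tables rarely state one. The joint
replication analysis pools tables cell-wise (no Mantel–Haenszel or
random-effects weighting: pooling is what a covariate-free replication
across heterogeneous repositories supports). Onset comparisons use a
pooled-variance t statistic under Monte-Carlo permutation (100,000
permutations by default, two-sided); the pooled rather than Welch
statistic is immaterial under the permutation null and is documented as
a choice. Cohen's d uses the pooled n−1 standard deviation.

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the structure the analysis assumes:

* case/control arms of configurable size (defaults 3,955/1,819 across
  seven geographic strata, the discovery-cohort composition);
* rare-allele frequencies from a Beta(0.3, 30) truncated to
  [1e-4, 0.05] — chosen once so that cohorts contain both singletons and
  recurrent variants, supporting the singleton/recurrent post-hoc
  partition;
* Hardy–Weinberg genotypes within strata, with Balding–Nichols
  between-stratum divergence (default F = 0.02; 0.1 in the "strongly
  stratified" diagnostics) so PCA has real structure to recover;
* a logistic disease model: planted effect regions draw control carriers
  at the configured frequency and case carriers at the odds-tilted
  frequency, each carrier receiving one heterozygous member variant with
  spectrum-weighted probabilities — the realized carrier OR therefore
  matches the configured OR without calibration;
* ages of diagnosis from N(63, 10) years with a half-normal lag to age
  of death, and a configurable additive carrier shift (default +6 years
  in examples, mirroring the onset analyses the package supports);
* per-site total depth, missingness, HWE and differential-missingness
  metrics, with plantable QC failures recorded in a held-out truth
  table. Planted case-only missingness can also trip the overall
  missingness filter at desk-scale cohort sizes; rejected is rejected,
  but filter attribution in the truth table is only meaningful at larger
  n;
* a deterministic seed: identical configurations give byte-identical
  VCF/TSV/FASTA outputs.

What it does **not** emulate: read-level sequencing error, relatedness
and pedigrees, sex chromosomes, structural variants and repeat
expansions, linkage disequilibrium *within* regions (rare variants are
drawn independently), and sample-level QC failures. Passing tests on
synthetic cohorts therefore demonstrate the statistics and the plumbing,
not robustness to artifacts the generator never produces. Simulated
genes are plus-strand; minus-strand coordinate handling is exercised by
unit-level fixtures instead.

## Calibration and recovery studies

The package ships three study drivers used by its tests and by
`scripts/acceptance.R`.

`calibrate_type1()` measures type-I error over 2,000 null regions at
n = 500 (one CPU, minutes). Because the statistics' finite-sample
behaviour depends on minor-allele *counts*, the reduced-n study scales
the frequency spectrum by `full_size / n` (capped at 0.45) so each
variant carries the allele count it would have at the full cohort size
of 5,774; variants monomorphic in the sampled cohort are dropped, as
they would be absent from any real callset. Without this scaling the
sampled allele counts are a fraction of the real study's and all four
tests turn strongly conservative at α = 0.05 — a property of score
asymptotics at near-zero counts, not of the implementations.

`stratified_lambda()` contrasts genomic inflation of the carrier-burden
test with and without PC adjustment on a strongly stratified null cohort
(F = 0.1, stratum-biased case sampling): adjusted λ sits near 1,
unadjusted λ well above 1.1.

`planted_recovery()` plants one protective 3'UTR (carrier OR 0.23) among
19 null 3'UTRs and reports how often it ranks first by burden and SKAT-O
p-value. The reduced-scale replicate uses 4,000/2,000 samples at a 2%
control carrier frequency — sized so that each planted variant stays
below the 1% control-MAF rarity cutoff (at higher carrier frequencies
the spectrum's occasional dominant variant crosses the cutoff and is
correctly filtered away, which dilutes the planted signal) while the
expected carrier counts (≈40 control, ≈19 case) support stable ranking.
The full-size check — a 40,000/20,000 cohort at 0.7% control carrier
frequency whose pooled OR CI must cover 0.23 — runs unreduced.

## Numerical choices and degenerate inputs

* HWE: exact conditional two-sided test on the heterozygote count,
  summing conditional probabilities ≤ the observed one (with a 1e-12
  relative tie tolerance); the exact test is standard where rare alleles
  break the χ² approximation. Applied in controls, overall and per
  stratum; a site failing anywhere is removed.
* Rejected sites are attributed to the first failing filter in the fixed
  order structure → depth → missingness → HWE → differential
  missingness, so rejection counts partition the rejected set; the full
  per-filter verdict table is also returned, making the filters
  order-independent in effect.
* Zero-carrier units test at p = 1 with a warning flag; degenerate
  (all-zero) kernels likewise. Missing dosages enter association
  statistics and carrier tables as non-carrying — conservative under
  case/control-balanced missingness, which the differential-missingness
  filter enforces upstream.
* The proximal quadrant of a 3'UTR is its 5'-most `floor(length/4)`
  nucleotides (strand-aware), computed on the unpadded UTR; nucleotide
  rather than variant-count quarters, and no re-padding, because padding
  exists for splice junctions.
* LD pruning uses r² > 0.2 within 50-variant windows stepping by 5 —
  conventional defaults, configurable, since consortium pruning
  parameters are typically unpublished. Genotypes are standardized by
  √(2p(1−p)) for PCA and each PC's largest-magnitude loading is made
  positive for reproducibility.
* Pipeline report λ values on a few dozen units are sanity checks only;
  the median-based λ has a standard error of ~0.1 at 60 units, so
  calibrated bounds are asserted only in the 2,000-region and
  10,000-p-value studies.

## Limitations

* The MRE caller matches textual 7-mers; it does not score site efficacy
  (no context++ scores), does not run external target predictors, and
  treats every overlapping indel as a loss — a conservative reading.
* The CMC implementation is the collapsed-carrier score test; published
  CMC variants with multiple frequency bins can differ.
* Whether weights apply inside other SKAT-O implementations and which
  CMC flavor a given consortium ran are configuration, not inferred
  facts; both are exposed as options (`rv_test_config()`).
* Real association p-values from access-controlled consortium genotypes
  are out of reach by design; the acceptance study substitutes
  property-based checks (calibration, oracle agreement, parameter
  recovery) at the sizes stated above.
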