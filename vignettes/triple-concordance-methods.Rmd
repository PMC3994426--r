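---
title: "Triple-concordance analysis of paired tumor/normal SNP arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-concordance analysis of paired tumor/normal SNP arrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triconcord)
```

## The analysis

`triconcord` implements a three-arm screen for somatic genomic aberrations in
cohorts where each patient contributes a tumor sample and a matched
adjacent-normal sample genotyped on the same SNP array. The design premise is
that the normal tissue is each tumor's own reference: copy-number estimates
are normalised against the matched normal (diploid baseline 2), and genotype
comparisons are within-patient, which removes between-subject variation and
gives a paired design its power at modest cohort sizes (tens of pairs).

The three arms are:

1. **Recurrent copy-number variation (CNV).** Per patient and chromosome,
   a SNP is a variant locus when its tumor copy-number estimate lies beyond
   2 ± 0.5; a *run* is at least 100 consecutive variant loci of one direction
   (gain above 2.5, loss below 1.5); a *recurrent region* is a maximal
   interval in which, SNP by SNP, at least a threshold number of patients'
   runs overlap. Gains and losses are called independently.
2. **Paired genotype association.** Genotypes are coded 0/1/2 as the count of
   minor alleles. For each SNP the 3×3 table of (normal, tumor) genotype
   pairs is tested for symmetry with the McNemar–Bowker statistic
   \(B = \sum_{i<j} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})\), referred to a
   chi-square distribution with one degree of freedom per discordant pair
   observed. Somatic genotype shifts are directional (e.g. heterozygote to
   homozygote), which is exactly the asymmetry this statistic detects.
3. **Loss of heterozygosity (LOH).** LOH at a SNP in a patient is a
   heterozygous normal call with a homozygous tumor call. A SNP is a
   recurrent-LOH locus when enough patients show LOH there.

A **candidate biomarker** is a SNP positive in all three arms: inside a
recurrent region, associated at the raw-p threshold, and LOH-flagged. The
conjunction is deliberately strict; each arm measures a different physical
consequence of the same lesion (dosage, allelic ratio, allelic identity), so
triple concordance is strong evidence that a locus is genuinely and
recurrently aberrant.

## Thresholds and conventions

The two recurrence arms intentionally use different counting conventions,
mirroring how such thresholds are commonly reported:

* CNV recurrence is **strict**: more than `floor(f·N)` patients. At
  `f = 0.30`, `N = 61`, a count of 18 is excluded and 19 is required.
* LOH recurrence is **non-strict**: at least `ceiling(f·N)` patients. At
  `f = 0.18`, `N = 61`, the threshold is 11.

Both conventions are exposed via `recurrence_threshold(n, fraction, strict)`,
and both arms accept any fraction. The product `fraction × n` is snapped to
the nearest integer when within 1e-9 before flooring/ceiling, so exact
products are never mis-rounded by floating-point fuzz.

Association significance is a **raw p-value below 0.01 with no multiplicity
correction**. That is a screening criterion, not a family-wise error
guarantee: the paired design already controls between-subject variation, and
the intersection with two independent arms is the real false-positive
control. `genome_scan(adjust =)` adds a Bonferroni/FDR column for users who
want one; it is off by default.

Degenerate Bowker tables are handled by **df reduction**: an off-diagonal
pair with zero discordant counts contributes neither to the statistic nor to
the degrees of freedom, and a fully concordant table returns p = 1 at df = 0.
This avoids 0/0 and matches common practice; the alternative fixed-df-3
convention would only make the test more conservative.

Other defaults, with reasons:

| parameter | default | why |
|---|---|---|
| `gain_threshold` / `loss_threshold` | 2.5 / 1.5 | copy number beyond 2 ± 0.5; half-copy margin above array noise |
| `min_run_snps` | 100 | run length floor; no gap tolerance (one sub-threshold SNP breaks a run) |
| `maf_min` | 0.01 | below 1% a 61-pair cohort has almost no heterozygotes to compare |
| `call_rate_min` | 0.90 | pooled over both tissues of all patients |
| `hwe_alpha` | 1e-4 | exact-test p below this flags genotyping artifacts |
| association `alpha` | 0.01 | raw-p screen, see above |
| `loh_fraction` | 0.18 | recurrence floor for the LOH arm |

The per-SNP copy-number **estimate** (normal-referenced, diploid = 2) is what
is thresholded. Quality control attributes each removed SNP to the *first*
failing filter in `filter_order`, so removal counts are mutually exclusive
and `n_input = n_retained + Σ removed` always holds; the retained *set* is
order-independent. Hardy–Weinberg is always tested on normal-tissue
genotypes — tumor genotypes violate equilibrium by the nature of somatic
aberration, so testing them would discard exactly the signal of interest.
Which tissue defines the allele frequency is configurable (`maf_tissue`,
default normal).

The Hardy–Weinberg test is the **exact conditional test** (full enumeration
of heterozygote counts given the allele counts, two-sided by summing
configurations no more probable than the observed one), not the chi-square
approximation: QC must be valid at low minor-allele counts, which is exactly
where the chi-square test misbehaves. The implementation enumerates in log
space; the test suite checks it exhaustively against an independent
exact-integer enumeration for every genotype table of up to 20 individuals.

Coordinates are 1-based inclusive throughout the R API and all TSV outputs
(SNP indices within a chromosome, bp positions); only BED export converts to
0-based half-open, preserving interval lengths. The ΔΔCt helper
`copy_number_from_ddct()` implements relative quantification against a
two-copy reference assay, `2·2^(−ΔΔCt)`; it is exact at the identity
(ΔΔCt = 0 → 2 copies) and strictly decreasing.

## The synthetic cohort generator

`simulate_cohort()` exists because every stage of the pipeline should be
verifiable against known ground truth without access to any real cohort. It
emulates the statistical structure the analysis assumes, at the study's
scale (defaults: 61 patients; SNP counts per chromosome are configurable up
to array scale):

* Normal genotypes are drawn per SNP from Hardy–Weinberg proportions at a
  minor allele frequency sampled uniformly from `maf_range`.
* Tumor genotypes copy the normal ones, then receive (in order) null
  discordance noise, planted association shifts (het → random homozygote
  with probability `shift_prob`), and planted LOH conversions for carriers.
* Copy number is Gaussian noise around 2, except planted segments for their
  carriers (Gaussian around `mean_cn`), truncated at 0.
* Carriers of every planted element are exactly the first
  `round(carrier_fraction · N)` patients of a seeded permutation, so
  carrier counts are integer-exact and recovery tests have sharp targets.
* Identical configurations (including the seed) give bit-identical cohorts.

**The null discordance kernel is reversible by construction.** A naive
symmetric flip ("each call flips to a uniform other genotype with rate d")
does *not* produce a symmetric paired table: the expected count of 0→1
discordances is proportional to the frequency of genotype 0, and 1→0 to that
of genotype 1, which differ whenever the SNP is not at 50% frequency. A
symmetry test would then reject its own null. The generator instead proposes
one of the two other genotypes uniformly and accepts with probability
`min(1, π_proposed/π_current)` under the SNP's Hardy–Weinberg distribution
π — a Metropolis kernel, reversible with respect to π, so
`π_i T(i→j) = π_j T(j→i)` holds exactly and the expected paired table is
symmetric at every null SNP. The test suite checks this balance aggregately
over 10⁴ SNPs.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent), intensity-level array artifacts (wave/GC effects, batch
structure), allele-specific copy number, and spatially correlated
copy-number noise. Passing recovery tests therefore demonstrate algorithmic
correctness under the assumed model, not robustness to real-array artifacts;
on real data the upstream normalisation is responsible for the latter.

### The default recovery scenario

`default_scenario()` is the fixed benchmark used by `recovery_experiment()`:
60 patients, two chromosomes of 2,500 SNPs, one planted gain of 150 SNPs
(40% carriers, mean copy number 3.4, noise sd 0.2), one planted LOH segment
of 50 SNPs (30% carriers, conversion probability 0.9), and five planted
association SNPs (shift probability 0.6). Two geometry choices matter:

* **The gain region and the LOH segment overlap at exactly one SNP**, which
  is also the in-region association SNP. LOH is itself a tumor/normal
  genotype asymmetry, so any SNP inside both a high-conversion LOH segment
  and a recurrent region tends to trip all three arms; a nested layout would
  make many segment SNPs legitimate candidates and the "unique
  triple-planted locus" ill-defined. The single-SNP overlap makes exactly
  one locus carry more than one aberration.
* **Aberrations are planted on common SNPs** (`maf_range = c(0.3, 0.5)`).
  This is a power consideration fixed at design time: with 60 pairs, a SNP
  at 10% frequency has about 11 heterozygotes, and neither a 0.6-probability
  shift (≈6–7 discordant pairs) nor a 0.9-probability LOH conversion in 30%
  of carriers clears the respective thresholds reliably. Recurrent-biomarker
  candidates are by nature common variants; rare-SNP behaviour is covered by
  the calibration arm instead.

Under this scenario the triple-planted SNP is the top-ranked (and in
practice the only) candidate, and the planted region boundary is recovered
within ±2 SNP indices, in 50 of 50 seeded runs of the acceptance script.

## Calibration: what the type-I experiment shows

`typeI_experiment()` simulates null cohorts and reports the empirical size
of the genome scan. Two regimes matter:

* **Study-like sparsity.** At 60 patients and 5% discordance a SNP has ~2–3
  discordant pairs. The Bowker statistic then has a very coarse support: a
  single pair must reach |n_ij − n_ji| ≥ 7 with all flips in one direction
  before B exceeds the df = 1 critical value at α = 0.01. The asymptotic
  test is therefore *severely conservative* here: measured rejection is
  ~1.5×10⁻³ at α = 0.05 and 0 at α = 0.01 over 10⁵ null tests. This is a
  property of applying a chi-square reference to sparse discordances, not
  an implementation artifact.
* **Dense discordance.** At 200 patients and 30–60% discordance the same
  code rejects at 0.005–0.007 for α = 0.01, approaching the nominal level
  from below, the expected residual discreteness of an exact-support
  statistic.

The practical reading: under study-like conditions the scan's raw-p screen
is conservative, so its false-positive rate is *below* the nominal α; power
for real directional shifts at common SNPs remains high (see the recovery
scenario). Users wanting exact finite-sample calibration at sparse counts
would need an exact conditional symmetry test, which is out of scope here.

## Problem sizes used in the test and acceptance runs

The bundled suites size their simulations to exercise every code path at
full statistical fidelity while remaining quick to run end-to-end: null
calibration pools 10 replicate cohorts of 10,000 SNPs × 60 patients;
recovery runs 50 seeded replicates of the 5,000-SNP default scenario;
oracle-equivalence sweeps use 100+ random tracks of up to 2,000 SNPs; the
QC accounting chain is computed on a 906,600-row per-SNP table, the size of
the emulated array. All stochastic results are reproducible from the
reported seed lists.

## Known limitations

* Runs have no gap tolerance; one noisy SNP splits a run, and two fragments
  below the length floor are both discarded. Real pipelines often smooth by
  segmentation first; change-point segmentation is deliberately out of
  scope.
* Region support counts distinct patients per SNP, not per-region overlap
  fractions; regions from different patient subsets merge when their
  coverage is contiguous.
* The LOH definition cannot see copy-neutral LOH at SNPs that are
  homozygous in the normal tissue, and a 0↔2 homozygote switch is reported
  as a diagnostic discordance, never as LOH.
* The candidate definition requires the SNP itself to be LOH-flagged (not
  merely near a flagged locus) and lies inside a region by bp position.
* Whether the allele frequency filter should use normal, tumor, or pooled
  genotypes is not identifiable from the outputs alone; it is a
  configuration choice (default: normal tissue).
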