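---
title: "Tumor-informed ctDNA detection from WGS read counts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-informed ctDNA detection from WGS read counts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection problem

Plasma cell-free DNA of a cancer patient contains a small tumor-derived
fraction (ctDNA). A tumor-informed whole-genome approach first catalogues the
patient's somatic single-nucleotide variants from tumor and matched-normal
sequencing — the *mutational compendium*, of size $N$ — and then scans plasma
WGS reads at exactly those sites. At ~20× plasma coverage each individual site
is uninformative, but aggregating evidence over thousands of sites makes tumor
fractions (TF) of $10^{-5}$ and below detectable.

cfMRD implements the count-level core of this design. Per plasma sample it
computes:

* $R$ — total reads covering compendium sites; $cov = R / n_{covered}$, the
  mean depth over covered sites;
* $M$ — the variant evidence: by default the total number of
  variant-supporting reads (`mode = "reads"`), optionally the number of sites
  with at least one variant read (`mode = "sites"`);
* $det\_rate = M / R$.

Sequencing artifacts also produce variant-supporting reads, at a rate that
depends on the compendium (its sequence contexts), so the artifact level must
be estimated per compendium. Scoring healthy-control plasma under a patient's
compendium yields the null distribution of $det\_rate$; its mean and sample
standard deviation $(\mu, \sigma)$ form the noise model, and the sample-level
statistic is
$$ Z = \frac{det\_rate - \mu}{\sigma}. $$

The plasma tumor fraction is estimated by subtracting the expected artifact
evidence and normalizing by the number of informative trials:
$$ TF_{raw} = \frac{M - \mu R}{N \cdot cov}, \qquad TF = \max(0, TF_{raw}). $$
When every compendium site is covered, $N \cdot cov = R$ and
$TF_{raw} = det\_rate - \mu$; under the binomial read model this makes
$TF_{raw}$ unbiased for the true TF. The signed raw value is kept because
cohort-level calibration checks need the negative excursions that clipping
destroys.

### Why `mode = "reads"` is the default

The field describes $M$ both as "SNVs detected" and normalizes it by reads
checked. At $TF \ll 1/cov$ a site virtually never collects two variant reads,
so the two countings coincide; counting reads makes $det\_rate$ a proper
per-read error rate, which is what the noise-rate definition
(errors per read evaluated) requires. Both modes are implemented and tested;
their equality in the no-multi-read regime is a test invariant.

## Threshold selection

The classifier must operate at a fixed specificity. Each training-cohort
compendium scores its own plasma (one positive label) and every control
(one negative label per compendium × control pair); with 93 training patients
and 40 controls this yields 93 positives and 3720 negatives. The operating
threshold is the smallest observed negative score such that the fraction of
negatives strictly above it is at most 5%, with the classification rule
"positive iff $Z >$ threshold". Restricting candidates to observed negative
scores (no interpolation) makes the operating point reproducible from the
label set alone; the achieved specificity is then $\ge 95\%$ on the selection
set by construction, and on an independent negative set of the same size it
fluctuates within the binomial interval around the constraint. All training
data are used for selection — no held-out split — because the threshold is a
design parameter, not a performance claim.

ROC analysis is dual-route by design: the AUC is computed as the
pairwise-comparison (Mann–Whitney) statistic with ties counting one half, and
is verified internally against the trapezoidal area of the threshold sweep to
$10^{-9}$; disagreement aborts rather than warns.

## FFPE artifact filtering

Compendia called from formalin-fixed (FFPE) tissue contain spurious low-VAF
"somatic" calls. A two-component univariate Gaussian mixture is fitted to the
compendium VAF distribution by EM (tolerance $10^{-6}$, at most 500
iterations, k-means initialization under a fixed seed; the lower-mean
component is the artifact component by convention, which makes the fit
label-switch-safe). The VAF threshold is the smallest value on a $10^{-4}$
grid above the artifact-component mean where the posterior probability of the
artifact component is at most 10%; sites with VAF strictly above the
threshold are retained. The 10% figure is interpreted as a posterior
probability — the chance that a retained site at the threshold VAF is an
artifact — rather than as artifact-component tail mass; both readings yield a
cutoff, the posterior one is the direct false-positive statement and is the
package default (`gmm_target_fp_rate`). Fresh-frozen compendia are never
filtered.

## SNP concordance

Inter-patient sample swaps are detected from genotype concordance over a
panel of ~1200 diverse exonic SNPs. Genotypes are banded on the B-allele
fraction: depth must exceed 10×; sites deeper than 300 reads are first
downsampled to 300 by seeded hypergeometric sampling of the allele counts
(the cap bounds the influence of any single site without biasing the
fraction); then $f \ge 0.85$ is homozygous-alternate, $f \le 0.15$
homozygous-reference (the mirrored band — both homozygous states must be
callable, and under biallelic coding the two definitions coincide),
$0.35 \le f \le 0.65$ heterozygous, anything else excluded. The SNP score is
the fraction of mutually accepted sites with identical calls; HET-vs-HOM
counts as discordant. A patient's sample set is coherent when the reference
sample scores $> 0.8$ against all of the patient's samples and $< 0.7$
against all other patients' references. Base- and mapping-quality filters
are upstream of the evidence model and are not re-implemented.

## The synthetic cohort generator

No patient data are distributable, so the generator emulates the count-level
structure the analysis consumes, with truth files for every latent quantity.

* **Compendium sites**: distinct random genomic positions; VAFs truncated
  normal, mean 0.4, SD 0.1 for genuine somatic sites. FFPE compendia draw 30%
  of sites from an artifact component (mean 0.05, SD 0.01) and flag them in
  the truth table.
* **Evidence**: per site, depth $\sim$ Poisson(20) — Poisson rather than
  fixed so that the $cov \ne$ nominal-depth code path is exercised — and
  variant reads $\sim$ Binomial(depth, $tf + a$), merging tumor-derived and
  artifactual reads into one success probability. At $TF \ll 1$ the
  distinction is second-order, and the merged rate keeps the oracle analytic:
  the expected detection rate is exactly $tf + a$.
* **Tumor fractions**: per patient, log-normal with the group's configured
  median and IQR. The defaults are the reported group medians — CRC
  $3.1\times10^{-4}$ (IQR $9.5\times10^{-5}$–$1.3\times10^{-3}$), symptomatic
  adenomas $5.9\times10^{-5}$ ($4.0$–$6.3\times10^{-5}$), asymptomatic
  adenomas $7.8\times10^{-6}$ ($7.6$–$8.4\times10^{-6}$). The log-scale SD is
  solved from the quartile ratio, $\sigma_{\log} = \log(q_{75}/q_{25}) /
  (2\,\Phi^{-1}(0.75))$, the natural two-parameter fit to a reported
  (median, IQR) pair; an IQR that does not straddle its median is rejected.
* **Artifact rates**: per compendium, log-normal with median $10^{-5}$ per
  read and sdlog 0.25 — a modest spread reflecting that compendium context
  composition varies between patients but the error chemistry does not.
* **Mutation loads**: uniform over [1000, 10000] sites by default, the
  generic WGS range; loads are config-exposed because they are the main
  sensitivity driver.
* **FFPE assignment**: each patient is FFPE with probability 0.15
  (roughly the asymptomatic-adenoma share of the target cohort).
* **Controls**: pure-noise plasma. `simulate_cohort()` materializes one
  evidence table per control over the union of all compendium sites, each
  site inheriting the artifact rate of the compendium it belongs to.
  `run_pipeline()` instead generates control evidence per
  (compendium, control) pair on the fly: compendium site sets are disjoint,
  so the per-pair tables are distributionally identical to slicing one
  genome-wide control, and the whole run stays deterministic through a single
  sequential RNG stream seeded from the run config.

### What the generator does not emulate

Read-level structure (no FASTQ/BAM, no fragment lengths, no UMIs), germline
contamination of compendia, copy-number and fragmentomic signal, site-to-site
error-rate heterogeneity within a compendium, and between-control variation
beyond binomial sampling. Consequently, passing tests demonstrate the
statistical machinery — calibration, thresholding, recovery — under the
stated count model, not performance on real plasma. Two visible consequences:
real-data AUCs and sensitivities are not reproduced (group TF distributions
here give *every* patient a positive TF, whereas real cohorts include
non-shedders), and per-compendium noise variance is purely binomial, which
makes high-mutation-load samples easier to detect than they are in practice.

## Numerical choices and edge cases

* $\sigma = 0$ across controls (all rates identical) is floored at
  $10^{-12}$ with a warning flag carried into every downstream score, rather
  than failing: degenerate synthetic edge cases must not abort a cohort run,
  and the flag keeps the affected Z scores interpretable.
* $R = 0$ (no coverage at all) gives $det\_rate = 0$ with a `zero_coverage`
  flag; TF estimation refuses to divide and errors instead.
* Evidence rows outside the compendium are ignored with a count; compendium
  sites missing from evidence count as depth 0.
* Classification is strict (`Z > threshold`), matching how the threshold is
  chosen; a score exactly at the threshold is negative.
* The EM fit floors component SDs at $10^{-6}$ and errors on non-convergence
  or degenerate (zero-spread) input.
* Duplicate compendium sites are collapsed on (chrom, pos, alt); multi-allelic
  VCF records are split per alternate allele; non-SNV records are skipped
  with a reported count.

## Problem sizes used by the packaged studies

The test suite and the acceptance script run Monte-Carlo studies at sizes
chosen to make each check sharp while staying desk-scale; they are stated
here as the package's own design choices:

* label-set construction: full 93 × 40 design at $N = 1000$;
* specificity constraint: full design at $N = 5000$, 20×;
* TF recovery: $N = 20000$, 200 replicates at TFs $10^{-3}$ and
  $5.9\times10^{-5}$;
* null calibration: leave-one-out Z over 40 controls at $N = 20000$;
* group detection-rate ordering (CRC > sAD > aAD): 100 seeds of the full
  two-cohort pipeline at fixed $N = 2000$, a mid-range mutation load at which
  the three groups' operating points are well separated without saturating
  the symptomatic-adenoma group;
* SNP concordance discrimination: 500 replicate pairs over 1200-site panels
  at 30×, population allele frequency 0.3.

One caveat on the ordering study: the CRC group's configured TF distribution
is very wide (log-scale SD 1.94 follows from its reported IQR), leaving a
tail of simulated CRC patients below the detection limit, while the
symptomatic-adenoma group is tight and small (22 patients). Strict per-seed
ordering of the empirical rates is therefore occasionally violated by a
CRC-vs-sAD reversal even though the mean rates separate cleanly; the
100-seed study observes the ordering in the low-to-mid 90s of seeds.

## Known limitations

The per-compendium noise model pools controls only through their detection
rates; a pooled-read estimator and confidence intervals on TF are out of
scope. The deep-learning read-level quality filter used by the full
sequencing pipeline this package models is replaced by an identity pre-filter
hook: evidence tables are assumed already quality-filtered. The orthogonal
deep-targeted assay is modeled only at the level of its per-sample output
(call + mean VAF), for agreement statistics; its internals are not simulated.
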