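---
title: "Methods: phase-aware allelic-expression QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-aware allelic-expression QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeqtl)
```

## The problem

Total-expression eQTL mapping regresses expression levels on genotype
across individuals. Its power is limited by *trans*-acting variation —
age, medication, cytokine levels, disease state — which moves both alleles
of a gene together and can dwarf a modest *cis* effect. The allelic
expression ratio (AER) sidesteps this: in an individual heterozygous for a
transcribed marker SNP, the two alleles' transcripts are distinguishable,
and their ratio is measured within one cellular environment, so shared
trans influences cancel exactly. Mapping candidate SNPs against the AER
(aeQTL mapping) is therefore specific for cis-acting regulation and far
more powerful per sample for small effects.

This package implements that analysis end to end for a candidate-gene SNP
panel typed in one or more cohorts, together with the LD machinery needed
to interpret it (confidence-interval haplotype blocks, tag selection) and
a two-cohort synthetic generator used to validate every stage.

## Generative model

Let individual $i$ carry haplotypes $h_1, h_2$. Each haplotype expresses

$$e_h = \exp\!\big(t_i + \textstyle\sum_s \beta_s\, a(h,s) + \eta_h\big),$$

where $t_i \sim N(0, \sigma_{trans}^2)$ is the shared trans factor,
$a(h,s) \in \{0,1\}$ is the alt-allele indicator of causal SNP $s$ on $h$,
$\beta_s$ is the natural-log allelic fold change, and
$\eta_h \sim N(0, \sigma_{allele}^2)$ is residual per-haplotype cis noise
(untyped cis variation). Total expression is
$(e_{h_1} + e_{h_2})\,e^{\text{plate}}$; the observed log AER at a marker
heterozygote is the log level of the marker-alt-carrying haplotype minus
the marker-ref-carrying one, plus $N(0, \sigma^2_{aer})$ measurement
noise. $t_i$ cancels in the AER by construction — this is the model's
expression of the biological argument above.

Transcript specificity is encoded by tagging each effect with a target:
`"A"` effects act only on the isoform-A assay; `"both"` effects act on
both isoforms, hence also on total expression. Total expression applies
only `"both"` effects — the limiting case in which isoform A is a small
share of the total transcript pool. This mirrors a locus where a variant
moves one splice isoform strongly while total expression is unmoved.

### The regression

For marker heterozygote $i$ and candidate SNP $c$, the phase design code
is

$$x_{ic} = a(h^{altM}_i, c) - a(h^{refM}_i, c) \in \{-1, 0, +1\},$$

the candidate dose on the marker-alt haplotype minus that on the
marker-ref haplotype. Under the model, $E[\log\text{AER}_i] = \beta_c
x_{ic}$ when $c$ is causal, so ordinary least squares of log AER on
$x$ estimates the log allelic fold change directly; `exp(beta)` is the
reported fold. Phase is taken as known (point estimate from upstream
phasing); phasing uncertainty is ignored. The intercept is retained to
absorb assay mapping bias at the marker.

Two design corner cases deserve note, because the strongest candidate is
typically the transcribed marker itself:

* **Marker self-test.** Testing the marker against its own AER gives
  $x \equiv +1$, collinear with an intercept. The constant design then
  *replaces* the intercept, making the fit a one-sample test of the mean
  log AER — exactly the classical allelic-imbalance test.
* **Conditioning.** Conditional scans add the lead SNP's phase code as a
  covariate. A constant covariate (conditioning on the marker or a perfect
  proxy) is absorbed by the intercept; a constant-code candidate under
  such conditioning is flagged collinear rather than tested. Candidates
  whose code never varies are reported *untestable*, never as $p = 1$.

The total-expression scan is standard: OLS of log expression on additive
dosage (0/1/2, no dominance) with PCR plate as a categorical covariate,
dropped when only one plate is present.

## LD statistics and blocks

With phased input, two-locus gamete counts are read off directly; for
unphased dosages an EM over the double-heterozygote ambiguity estimates
the four haplotype frequencies (converged at max change $<10^{-8}$ or
1000 iterations). From frequencies: $D = p_{11} - p_A p_B$, $D'$ the
usual normalization by the frequency-bound maximum, $r^2 = D^2 / (p_A
p_a p_B p_b)$. Monomorphic SNPs are flagged undefined, not dropped.

Confidence bounds on $|D'|$ follow the likelihood-mass convention: the
multinomial likelihood of the gamete counts is evaluated on a 0.001-step
grid of $|D'| \in [0,1]$ with allele frequencies fixed at their
estimates, and the one-sided 90% bounds are the points cutting 5% of
normalized mass from each tail. Blocks use the confidence-interval
classification — strong LD when `ci_low >= 0.70` and `ci_high >= 0.98`,
strong recombination when `ci_high < 0.90` — and a candidate interval is
accepted when its outermost pair is strong LD and at least 95% of its
informative pairs are; candidates are kept greedily, longest first. These
thresholds are the established defaults for the confidence-interval block
algorithm. Greedy pairwise tagging picks, at each step, the SNP covering
the most uncovered panel SNPs at $r^2$ above the threshold (default 0.8,
MAF $\ge 0.05$), ties to the lower panel index.

## Inference

Family-wise error is controlled with Holm's step-down correction, by
default over the panel actually tested (`n_tests` can pin the family at
65 when untestable SNPs must still be counted). Cohorts are combined
per-SNP with Fisher's method ($-2\sum_k \ln p_k \sim \chi^2_{2K}$)
*before* Holm is applied across the panel; effect-direction discordance
between cohorts is flagged, not dropped.

### Cis variance share

Because trans effects cancel in the AER,

$$\mathrm{Var}(\log \text{AER}) = 2\sigma_c^2 + \sigma^2_{aer},$$

with $\sigma^2_c$ the per-haplotype cis log-variance. The estimator
inverts this, and under the small-effect expansion
$\log(e^{u_1} + e^{u_2}) \approx \log 2 + (u_1+u_2)/2$ the cis
contribution to $\mathrm{Var}(\log \text{total})$ is $\sigma_c^2/2$, so

$$\widehat{\text{prop}}_{cis} =
  \frac{\hat\sigma_c^2 / 2}{\mathrm{Var}(\log \text{total} \mid
  \text{plate})}.$$

A negative numerator (measurement noise exceeding AER dispersion) is
flagged and reported alongside a clamped copy. One caveat is structural:
the AER conditions on marker heterozygosity, so a causal variant in
strong LD with the marker shifts the AER *mean* rather than its variance
(at the extreme, the marker itself contributes nothing to
$\mathrm{Var}(\log\text{AER})$). The estimator is therefore validated,
and the generator calibrated, with cis variance carried by
$\sigma_{allele}$ — variants unlinked to the marker — where it is exactly
unbiased. `calibrate_sigma_allele()` solves
$\sigma_{allele}$ in closed form for a desired true proportion;
at the default $\sigma_{trans} = 0.6$ a 3.7% cis share needs
$\sigma_{allele} \approx 0.166$.

$\sigma_{aer}$ is supplied by configuration, or estimated from the pooled
within-individual scatter when the AER table carries a `replicate`
column.

## The synthetic generator and its defaults

Cohorts are drawn from a `population_spec`: a pool of haplotypes with
sampling frequencies over the 65-SNP panel (~300 kb of chromosome
16q22.3). Two built-in pools differ only in their ancestry-segment
structure: the NE-like pool has five long segments (extended LD, long
blocks, as in a north-European cohort), the SA-like pool fourteen short
segments refining the same boundaries (rapid LD decay, as in an admixed
cohort). Within a segment, alleles follow a nested threshold pattern, so
within-segment $|D'| = 1$ with graded $r^2$ while cross-segment LD is
near zero. The pools were generated once, with a fixed seed, and ship as
plain-text fixtures so that the study conditions are frozen. The panel
names three SNPs by their field identifiers: the isoform-A transcribed
marker `rs10852515` (its NE segment spans ~93 kb, its SA segment ~7 kb —
the geometry that makes trans-ethnic narrowing visible), the
both-isoform transcribed marker `rs740178`, and the intronic
`rs8060701`, placed in the same segment as `rs740178` in both pools (in
complete LD with it, so the marker assay tags it perfectly).

Default noise magnitudes: `sigma_trans = 0.6` (dominant trans variation;
makes total expression range over roughly an order of magnitude in a
cohort of a few hundred), `sigma_allele = 0.08`, `sigma_aer_meas = 0.10`
(assay noise of the same order as the residual cis signal; no published
magnitude exists for the mass-spectrometry AER assay, so this is a
calibration choice), `n_plates = 8`, `sigma_plate = 0.15`. With these
defaults a 1.17-fold cis effect is essentially undetectable by the
total-expression scan at $n = 366$ while the aeQTL scan detects it at
~130 heterozygotes — the power asymmetry the method exists to exploit.

What the generator does *not* emulate: coalescent LD decay within blocks,
genotyping or phasing error, read-count overdispersion, shared plate
structure between assays, and any dependence of trans factors on
genotype. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those features of
real data.

## Numerical and design choices

* Natural logs internally; folds reported as `exp(beta)`, oriented to the
  cohort minor allele (defined from the data, not a reference panel) in
  `fold_minor`.
* Positions are 1-based (VCF convention) internally; exported BED is
  0-based half-open. Haplotype order (`h1`, `h2`) is the phase truth and
  survives VCF round trips; unphased heterozygote records are rejected.
* Missing candidate genotypes drop observations per test (pairwise
  deletion), with a message.
* p-values are floored at the smallest representable double so that
  step-down corrections remain defined when a test statistic underflows.
* Tag-selection and block-acceptance ties break deterministically (lower
  panel index; longer block first, then bp span, then start).
* Two runs with the same seed produce byte-identical outputs; the
  pipeline derives all randomness from one configured seed.

Validation problem sizes were chosen to match the study design the
package emulates: fold-change recovery at ~152 and ~132 informative
heterozygotes (200 replicates), cis-share recovery at $n = 366$
expression / 152 AER samples (200 replicates), null family-wise error
over 65 SNPs at 500 replicates, and trans-ethnic narrowing on cohorts of
451 and 310 (100 replicates).

## Known limitations

* The cis-variance estimator attributes marker-linked causal variance to
  the mean, as discussed; reported proportions are conservative when the
  strongest cis variant is the marker itself.
* Relatedly, when the causal variant is the transcribed marker itself,
  its effect is a constant $+\beta$ shift among marker heterozygotes, so
  imperfect proxies retain no residual slope under the intercept-retaining
  regression: the significant region then consists of the causal SNP and
  its perfect proxies only. Regions are correspondingly tight; the
  trans-ethnic comparison still narrows because perfect-proxy sets shrink
  with LD range.
* Phasing is trusted; switch errors would attenuate phase-coded effects.
* The D' confidence grid fixes allele frequencies at their estimates (the
  standard convention), which narrows intervals slightly at small n.
* Fisher's method assumes independent cohorts and ignores effect
  direction; discordant SNPs are flagged for the analyst rather than
  down-weighted.
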