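---
title: "Mapping methylation-mediated genetic effects with trioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping methylation-mediated genetic effects with trioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

## The scientific problem

Most trait-associated SNPs fall outside protein-coding sequence, and one
plausible mechanism for their effects is epigenetic: a variant alters DNA
methylation at a nearby CpG, and the methylation change in turn shifts the
expression of a local gene.  trioscan implements the statistical pipeline
for detecting such SNP → methylation → mRNA chains from sample-matched
multi-omics data: additively coded genotypes (0/1/2 ALT-allele dosage),
Illumina-style methylation beta values in $[0,1]$, and log2 microarray
expression, plus age and a binary disease status as covariates.

The pipeline has five stages:

1. **Cis-QTL scans** for three pair types — meQTL (SNP → CpG), eQTM
   (CpG → transcript) and eQTL (SNP → transcript) — each a covariate-adjusted
   linear regression over all local candidate pairs with Benjamini–Hochberg
   FDR control.
2. **Trio assembly**: the combinatorial closure of the three significant
   pair sets, restricted to genes with an official symbol.
3. **Causal inference test (CIT)** per trio, deciding whether the data are
   consistent with methylation-mediated transmission.
4. **LD analysis** of SNP groups feeding the same methylation site, via
   two-locus haplotype-frequency EM on unphased genotypes.
5. **Characterization and export**: CpG-category breakdowns, distance
   profiles, QQ data, and the signed tripartite regulatory network in
   Cytoscape-ingestible formats.

## The cis scans

For a predictor $x$ (genotype or methylation) and response $y$ (methylation
or expression) the model is ordinary least squares

$$ y = \beta_0 + \beta_1 x + \beta_2\,\mathrm{age} +
   \beta_3\,\mathrm{disease} + \varepsilon, $$

with the two-sided $t$ test on $\beta_1$ at $n - 4$ degrees of freedom.
A pair is *cis* when the predictor lies within 1 Mb of the CpG position
(point responses) or within 1 Mb of the transcript's TSS–TES interval
(interval responses); the boundary is inclusive at exactly 1,000,000 bp so
results are reproducible.  Genotype missingness is handled by pairwise
deletion per pair; a predictor left constant after deletion is flagged and
assigned $p = 1$ by convention, and pairs with fewer than 5 complete
observations are skipped.  FDR is controlled per scan over all of its cis
tests jointly, and the significance threshold defaults to $q < 0.05$.

Methylation enters the scans on the raw beta scale by default, matching the
common matrix-QTL convention; an opt-in logit transform
(`scan_config(transform = "logit")`) is provided because the choice is
genuinely open — betas are bounded and heteroskedastic, logits are
unbounded but variance-inflate near 0 and 1.  The cis pair set is identical
under both.

Internally the scan residualizes all predictor and response columns on the
covariate design once and computes every slope and $t$ statistic from
residual cross products (Frisch–Waugh), which is algebraically identical to
the per-pair regression; columns containing missing genotypes fall back to
the per-pair fit.  `fit_pair()` is the per-pair reference implementation and
the tests assert the two routes agree to $10^{-8}$ relative, with
`stats::lm` as an independent oracle.

## The causal inference test

For a trio (L = genotype, G = methylation, T = expression) the CIT requires
four conditions to hold simultaneously, each adjusted for age and disease
status:

* `p1`: L and T are associated (`T ~ L + cov`);
* `p2`: L is associated with G given T (`G ~ L + T + cov`);
* `p3`: G is associated with T given L (`T ~ G + L + cov`);
* `p4`: L is *independent* of T given G.

The omnibus CIT p-value is $\max(p_1, p_2, p_3, p_4)$, so every condition
must individually be significant.  Condition 4 is an equivalence test — the
desired outcome is a *small* test statistic — so an ordinary
non-significance check would be anti-conservative.  We use a permutation
construction: let $F_{\mathrm{obs}}$ be the F statistic for L in
`T ~ L + G + cov`; fit `G ~ L + cov` and form surrogate mediators
$G^*_b = \hat G + \mathrm{perm}_b(r)$ by permuting the residuals $r$, which
preserves G's relationship to L while destroying the residual channel
through which a true mediator absorbs the L–T association.  Then

$$ p_4 = \frac{1 + \#\{b : F^*_b \le F_{\mathrm{obs}}\}}{B + 1}. $$

Under true mediation $F_{\mathrm{obs}}$ is central while the $F^*_b$ carry
the unabsorbed marginal association, so $p_4$ is small; under a common
cause or a direct effect the two distributions coincide and $p_4$ is
roughly uniform.  $B$ defaults to 1,000; the granularity of $p_4$ is
$1/(B+1)$, so $B \ge 100$ is enforced and $B \ge 500$ is recommended when
calling significance at $\alpha = 0.05$.  A trio "fulfils" mediation when
$p_{\mathrm{CIT}} < 0.05$, the manuscript-wide convention; no FDR is
applied over CIT p-values.  Per-trio permutation seeds are derived
deterministically from the batch seed and trio index, so batches are
reproducible and order-independent.  $p_4$ is invariant to affine rescaling
of G and T (location-scale equivariance of OLS F statistics), which the
tests assert.

Only the forward direction (L → G → T) is tested; the reverse chain
L → T → G is not separately scored, but the forward test's operating
characteristics under reverse-causation data are part of the validation
(below).

## Linkage disequilibrium

Groups of nearby SNPs often feed the same CpG, and whether they are one
signal or several is an LD question.  `em_haplotypes()` estimates the four
two-locus haplotype frequencies from unphased genotypes by EM over the
double-heterozygote phase ambiguity: frequencies start at
linkage-equilibrium products and iterate until the largest change is below
$10^{-8}$ (at most 1,000 iterations); the observed-data log-likelihood is
checked to be non-decreasing.  From the converged frequencies,
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{\max}$ (defined as 0 when $D = 0$) and
$r^2 = D^2 / (p_A q_A p_B q_B)$.  A monomorphic locus is an error, not
$r^2 = 0$: LD is undefined there.  The EM estimate equals the constrained
maximum-likelihood estimate; its residual disagreement with a phased
haplotype count on the same data is irreducible phase-ambiguity noise, of
order 0.01 at $n = 500$, which is why the validation bounds the *mean*
absolute error across panels rather than each panel individually.

## The synthetic generator

Real multi-omics cohorts with known causal structure do not exist, so
validation uses a generator whose ground truth is planted.  It emulates,
post-normalization, a small observational cohort: `n_samples` defaults to
43 (a realistic single-centre methylation study size; statistical
acceptance runs use 500, since 43 gives unstable Monte-Carlo rates), age
$\sim U(30, 70)$ years, disease $\sim$ Bernoulli(0.5), and MAFs drawn from
$[0.05, 0.5]$ reflecting the usual MAF $\ge 5\%$ genotype filter.

* **Genotypes**: two haplotypes per sample; SNPs are grouped into blocks of
  `ld_block_size` consecutive (position-sorted) SNPs; within a block each
  haplotype allele is copied from the previous SNP with probability
  `1 - ld_decay`, otherwise re-drawn from Bernoulli(MAF).  This
  haplotype-copy model was chosen over coalescent simulation because it
  gives direct control of block $r^2$ for the LD oracles at desk scale.
  Columns whose realized MAF falls below half the configured lower bound
  are re-drawn, so no column is monomorphic.
* **Methylation**: $\mathrm{logit}(\beta) = \alpha_c + \beta_{LG} g +
  \text{covariates} + N(0, \sigma_m)$, mapped through the inverse logit so
  values are strictly inside $(0,1)$.
* **Expression**: $T = \mu_g + \beta_{GT}\,\mathrm{logit}(G) +
  \beta_{LT} g + \text{covariates} + N(0, \sigma_t)$, with baselines
  $\mu_g \sim U(6, 12)$ on the log2 scale.

Four trio architectures are planted, each a distinct data-generating DAG:
**mediation** ($\beta_{LG}, \beta_{GT} \ne 0$, $\beta_{LT} = 0$),
**common cause** ($\beta_{LG}, \beta_{LT} \ne 0$, $\beta_{GT} = 0$),
**reverse causation** ($\beta_{LT}, \beta_{TG} \ne 0$: L → T → G) and
**null** (all zero).  Generation is two-pass and acyclic: all non-reverse
methylation first, then expression, then the reverse-trio methylation
responses — the reverse effect is applied to the already-drawn logit
baseline, deterministically, as $\beta_{TG}(T - \bar T)$; centring T keeps
the ~8-unit log2 baseline from saturating the logit.  Default effect sizes
are $\beta_{LG} = 0.8$ (logit units per allele), $\beta_{GT} = 1$ (log2
units per logit unit), $\beta_{LT} = 0.8$ and $\beta_{TG} = 1$ — large,
cis-like effects sized for testability rather than to mimic any particular
catalogue, since typical published effect magnitudes for such chains are
not well established.  Layout guarantees cis eligibility by construction:
each trio CpG is placed within 500 kb of its gene interval and the trio SNP
within 50 kb of the CpG.  Every generator stage derives its own sub-seed
from the master seed, so datasets are bit-reproducible and each stage can
be re-run independently.

What the generator does *not* emulate: probe-level microarray signal,
batch/cell-composition structure, population stratification, trans effects,
or realistic genome-wide LD decay.  Passing tests therefore demonstrate the
statistical machinery is correct and well calibrated under the stated
model, not that real data meet that model.

## Validation results the tests compute

At $n = 500$, $B = 500$, 100 trios per architecture and the default effect
sizes, the acceptance suite verifies: mediation trios are called in
$\ge 80\%$ of cases (observed: 100%), common-cause trios in $\le 10\%$
(observed: 5%), null trios in $\le 7\%$ (observed: 0%), and the
reverse-causation call rate is strictly below the mediation rate
(observed: 8%) — the discrimination property that justifies the four-test
design.  An all-null scan of 10,000 pairs at FDR 0.05 yields on average
$\le 1$ significant pair over 20 seeds; `cis_pairs`, `fit_pair`, `bh_fdr`
and `build_trios` match exhaustive/closed-form oracles; and the EM LD
estimate tracks phased-truth $r^2$ with mean error well under 0.02 across
100 panels.  Problem sizes were chosen so the whole suite runs in about two
minutes on a laptop core.

## Numerical and design choices

* OLS via normal equations with a Cholesky solve (fast and adequate for
  4–5 column designs); rank-deficient designs are flagged as degenerate
  rather than silently dropped.
* BH q-values delegate to `stats::p.adjust(method = "BH")`; the test suite
  checks it against a hand-coded step-up oracle.
* Percent rounding in category breakdowns is half-up to 2 decimals, the
  convention of printed tables (R's `round` is round-half-even).
* Distance sign convention: predictor position minus response position;
  negative means the SNP is upstream of the CpG in genomic coordinates.
  For transcripts the distance is 0 inside the TSS–TES interval, else the
  signed distance to the nearest end.
* Coordinates are 1-based inclusive throughout, the array-annotation
  convention.
* Category breakdowns use **pair counts** as denominators (not unique
  CpGs); with published meQTL breakdown counts this convention reproduces
  the printed percentages exactly.
* Network edge signs come from the marginal regression slopes (SNP →
  methylation and methylation → expression), matching the usual
  positive/negative regulation colouring; duplicate edges with conflicting
  signs are kept once and flagged.

## Known limitations

* The CIT, like all mediation tests, cannot rule out an unmeasured
  confounder of the methylation–expression relationship; a "fulfilled"
  trio is consistent with mediation, not proof of it.
* Scans assume independent samples; no kinship, mixed models or latent
  expression factors.
* The permutation count bounds how small $p_4$ can be; with $B = 500$ the
  floor is $\approx 0.002$.
* Strong LD among SNPs feeding one CpG produces many near-duplicate trios;
  the package reports them all and provides the LD module to group them,
  but does not pick a causal SNP within a block.
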