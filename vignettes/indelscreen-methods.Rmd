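---
title: "Methods: pooled InDel screening and downstream genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled InDel screening and downstream genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelscreen)
```

This vignette is the package's account of its statistical machinery: what
each stage computes, the assumptions behind it, and the choices made where
the design was genuinely open.

## 1. The mathematical-expectation pooling design

The screening problem is Dorfman group testing specialised to one pooling
round. `N` DNA samples are combined into pools of size `n`; each pool is
one PCR reaction, and pools showing the variant band are resolved by `n`
individual reactions. If each individual independently carries the variant
(genotype ID or mutant homozygote) with probability `p`, a pool is positive
with probability `1 - (1-p)^n`, and the expected total reaction count is

$$E[RT](n) = \frac{N}{n} + N\left(1 - (1-p)^n\right).$$

`expected_reaction_times()` implements exactly this, with `n = 1` defined
as individual testing (`E = N`). Three modelling choices matter:

* **`p` is a carrier probability, not an allele frequency.** A pool of `n`
  individuals contains `2n` alleles, and the per-allele variant frequency
  `q` would give pool positivity `1-(1-q)^{2n}`. The carrier
  parameterisation is the one under which the published design points for
  a 640-sample cohort (pool sizes 8 and 11, predicted reaction counts 176
  and 126, reductions 72.50% and 80.31% at estimated frequencies 0.02 and
  0.01) are all reproduced simultaneously; the per-allele form reproduces
  none of them. Under Hardy–Weinberg the two are linked by
  `p = 1-(1-q)^2 ≈ 2q` for rare variants.
* **Continuous pool count for optimisation, ceiling for the prediction.**
  The objective uses `N/n` pools rather than `⌈N/n⌉`; the predicted count
  is `⌈E[RT](n_{opt})⌉`. The realised-screen simulator, by contrast, uses
  integer pools with a smaller final pool, and the final pool's positivity
  probability uses its actual size. The discrepancy between the two
  conventions is below two reactions across the design grid the tests
  scan, and the Monte-Carlo suite verifies the formula against the
  integer-pool simulation within sampling error.
* **Ties break toward the larger pool size.** At `p = 0.01` the integer
  minimum is genuinely `n = 11` (125.165 vs 125.196 at `n = 10`), so the
  rule is not load-bearing there, but it is stated, implemented, and
  verified numerically rather than assumed.

The objective is *not* globally unimodal in `n`: beyond the optimum it
rises and then drifts back down toward its asymptote `N` as the
exponential term dies off (`dE/dn = -N/n^2 - N\ln(1-p)(1-p)^n`). The
property tests therefore assert unimodality on the optimum's basin
(`n ≤ 4/\sqrt p`), where the design decision actually lives. The optimum
itself sits within 1 of `1/\sqrt p` throughout `p ∈ [0.001, 0.1]`.

`run_pools()` adds pool-level error: a truly negative pool flips positive
with probability `fp_rate` (gel artefacts in mixed templates motivate
this), a truly positive pool flips negative with `fn_rate`. Retests are
modelled error-free, since no retest error structure is identifiable from
a single screen. Carriers inside a false-negative pool are *miscalled*
homozygous reference — deliberate, measurable leakage rather than a silent
assumption.

## 2. The synthetic-herd generator

The generator's defaults (`sdbcgr_herd_config()`) emulate a 640-head
black-cattle conservation herd: 172 males, 466 females, 2 of unrecorded
sex; a 4-bp insertion with mutant-allele frequency 0.052 and an 8-bp
deletion with mutant-allele frequency 0.009; eleven carcass traits with
per-genotype normal distributions taken from published group moments.

**Genotypes.** Each individual receives two haplotypes drawn i.i.d. from
the four-haplotype frequency vector built from the marginal frequencies
and a target `D′`: `D = D′ · D_{max}`, with
`D_{max} = \min(p_A(1-p_B), (1-p_A)p_B)` for coupling phase (positive `D`
between the two mutant alleles) and `\min(p_A p_B, (1-p_A)(1-p_B))` for
repulsion. Because `D` is scaled by `D_{max}`, every `D′ ∈ [0,1]` is
admissible; `D′ = 1` zeroes the limiting haplotype class exactly. The
phase is a configuration knob, defaulting to coupling, because plotted
haplotype rankings alone cannot identify it. Genotypes are the unordered
allele pairs per locus; the haplotype pairs are retained as an attribute
so phase-aware quantities (the realised `D′`) stay recoverable in tests.

**Traits.** Published association tables report groups as mean ± SE with
`n`, so the generator converts `SD = SE·\sqrt n` and draws
`Normal(mean_g, SD_g)` per genotype. Negative draws are resampled —
carcass weights cannot be negative; for the default configurations the
truncation mass is negligible, so group moments are preserved. Sex
restrictions mirror the sex-stratified reporting (individuals of
unrecorded sex are generated but excluded wherever sex enters), and
per-trait missingness is set so the expected phenotyped count matches the
published group sizes, reproducing the varying `n` across traits.

**What it does not emulate.** Real carcass traits are mutually correlated,
often right-skewed, and measured on related animals; genotyping error and
trait values can be confounded through batch structure; allele frequencies
drift across cohort subsets. None of that is modelled. Passing
parameter-recovery tests on these herds demonstrates that the estimators
are correct under the stated model, not that the model captures every
feature of field data.

## 3. Population genetics

`locus_stats()` uses gene counting for allele frequencies and the standard
two-allele summaries: `Ho = p²+q²`, `He = 1-Ho`, `Ne = 1/Ho`,
`PIC = He - 2p²q²` (Botstein's measure specialised to two alleles, so
`PIC < He` strictly whenever the locus is polymorphic). The
Hardy–Weinberg test is a Pearson chi-square on 1 df without continuity
correction — the conventional default when the reporting method is
unstated — with an exact conditional test (enumeration of heterozygote
counts given the allele counts) available by flag; at a monomorphic locus
both are undefined and return `NA` rather than a fabricated p.

`em_haplotypes()` estimates two-locus haplotype frequencies by EM. Only
the double heterozygote is phase-ambiguous; the E-step splits it between
the cis and trans phasings in proportion to the current haplotype-product
masses. Initialisation is at linkage equilibrium, convergence is
`|Δ log L| < 10^{-10}` or 1000 iterations, and the log-likelihood trace is
exposed and asserted non-decreasing in tests. `D` is reported for the
`I-I` haplotype, `D′` normalises by the sign-appropriate bound, and a
monomorphic locus is flagged (`ld_defined = FALSE`, with a warning) rather
than returning silent NaNs. On this package's default herd the realised
`r²` between a 5.2% and a 0.9% variant is necessarily small even at
`D′ = 1` — with such unequal frequencies the allelic correlation is
bounded far below 1, which is why a published `D′ = 1` can coexist with a
small `r²`.

## 4. Association testing

The two-genotype case uses the pooled-variance t-test by default — the
classical "independent samples t-test" with equal variances assumed, which
is what general-purpose statistical suites run unless told otherwise —
with Welch's form behind a flag. Groups need `n ≥ 2` to be testable;
groups with `2 ≤ n < 3` are tested but flagged low-n in the output, since
published tables evidently tested groups as small as 4 and listed groups
of 2. Zero variance in both groups with equal means returns `t = 0, p = 1`
by convention.

Diplotypes (joint two-locus genotype classes such as `DD-II`) are handled
by one-way ANOVA, with pairwise pooled t-tests feeding a compact-letter
display: lowercase letters at 0.05, uppercase at 0.01, by insert-and-absorb
so the letter pattern depends only on which pairwise thresholds are
crossed, not on input order. With exactly two testable groups the ANOVA F
equals the squared t, asserted to `10^{-9}` in the tests.

The fixed-effect model `Y = µ + G + S + e` is ordinary least squares with
treatment coding and marginal (drop-one) F tests; with a single sex the
aliased term is dropped and reported, and the genotype F then equals the
one-way ANOVA F exactly. Whether a published two-genotype p came from the
raw t-test or the sex-adjusted model within one sex is not generally
recoverable, so the scan reports the t-test and `glm_fit()` is available
alongside. No multiple-testing correction is applied by default —
matching single-candidate-gene practice — but `fdr = TRUE` appends a
Benjamini–Hochberg column for honest reuse across many traits.

## 5. Expression statistics

`ddct()` implements plain `2^{-ΔΔCt}`: technical replicates are averaged
on the Ct scale (the method's convention; an arithmetic mean of Ct is a
geometric mean of quantities), `ΔCt = Ct_{target} - Ct_{reference}` per
sample, `ΔΔCt` against the calibrator, no amplification-efficiency
correction. The calibrator's relative quantity is exactly 1.

`pearson_with_p()` computes the product-moment correlation and its exact
two-tailed p from `t = r\sqrt{n-2}/\sqrt{1-r^2}` on `n-2` df.
`pearson_p_from_r()` applies the same transform to a *printed* `r` and a
known series length; with raw Ct series unpublished, reproducing all four
printed time-course (r, p) pairs (0.828→0.042 at n = 6; 0.840→0.018,
0.863→0.012, 0.913→0.004 at n = 7) is the strongest consistency check the
published record supports, and it passes to 3 decimal places. Whether the
correlations were computed on relative quantities or on ΔCt does not
matter for this check, and both columns are accepted.

## 6. Numerical and scale choices

* EM: tolerance `10^{-10}` on the log-likelihood, cap 1000 iterations;
  haplotype frequencies are floored at `10^{-12}` at initialisation only.
* Pearson `r` is clamped to `[-1, 1]` against rounding drift before the t
  transform; `|r| = 1` maps to `p = 0`.
* Pipeline stage seeds derive from the global seed by fixed offsets, so a
  config + seed pair reproduces the output bundle byte for byte.
* Test problem sizes are chosen as the smallest that make the stochastic
  oracles sharp: `10^5` Monte-Carlo replicates for the reaction-count
  check (simulated pool-by-pool from binomial carrier counts, which is
  distributionally identical to per-individual Bernoulli draws), 200
  herds of 5000 for `D′` recovery, 200 replicates of `n = 400` for
  effect-size recovery, 1000 replicates for type-I error, 100 seeded
  herds for the perfect-recovery check.

## 7. Known limitations

* Single pooling round plus retests only; no multi-stage designs.
* Biallelic loci and two-locus haplotypes only; no general phasing.
* The realised reaction count of a *particular* physical screen depends on
  ad-hoc pool assignments and repeat reactions that no formula captures;
  the package brackets such counts by simulation rather than predicting
  them.
* The association layer offers fixed effects of genotype and sex only —
  no covariates, relatedness, or mixed models.
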