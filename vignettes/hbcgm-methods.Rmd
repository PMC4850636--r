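---
title: "Haplotype-block mapping with gene-wise permutation FDR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block mapping with gene-wise permutation FDR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbcgm)
```

## The model

An inbred strain panel supplies one homozygous genotype and one trait mean
per strain; the strain is the unit of analysis throughout, and per-strain
animal counts are not used as weights. A *haplotype block* is a window of
`window_size` consecutive SNPs on one chromosome (stride 1); the distinct
allele strings over the window partition the strains into haplotype groups.
Strains with any missing call in the window sit that block out — and only
that block. No imputation is performed anywhere.

Each block is tested by one-way fixed-effects ANOVA of the strain-level trait
means across its haplotype groups,

$$F = \frac{SS_{between}/(g-1)}{SS_{within}/(n-g)},$$

with the p-value from the upper tail of the $F_{g-1,\,n-g}$ distribution.
The method itself only requires a statistic that measures how well a strain
partition separates trait values; one-way ANOVA is the standard choice for
strain-panel haplotype mapping on strain means, and it admits a brute-force
oracle (explicit sums over groups) that the test suite compares against to
1e-10.

A gene's p-value is the **minimum** block p-value over blocks whose bp span
overlaps the gene interval extended by `flank_bp` on both sides. The minimum
is deliberately *not* corrected for the number of blocks: the inflation it
produces for polymorphic genes is exactly what the permutation stage is
designed to remove, and correcting twice would make the composite scores
incomparable with the field's uncorrected ones. A gene overlapped by zero
tested blocks is reported in an explicit untested state, never as a silent
p = 1.

## The gene-wise FDR filter

For each trait, the strain-to-value assignment is permuted `B` times
(uniformly at random, seeded; the identity permutation is not excluded — its
probability at panel sizes above a dozen strains is negligible) and the
genome-wide scan is re-run on each permuted trait. All genes within a trait
share the same `B` permutations, and the permutation index matrix is stored
so any gene's result can be recomputed independently. The FDR p-value is
`k/B` with `k` the number of permutations whose gene-level p is *strictly*
smaller than the original: the removal rule is worded as "matched randomized
data more than five times in 1,000", so ties favor retention. An association
with FDR p > `alpha` (default 0.005, i.e. k > 5 at B = 1,000) is removed.

This quantity is formally a per-gene permutation p-value rather than an FDR
in the Benjamini–Hochberg sense; the package keeps the field's name for the
construction and does not offer analytic FDR procedures in its place.

Under a null trait the observed scan is exchangeable with its permutations,
so `k` is discrete-uniform on `{0, …, B}` and the FDR p-value is uniform on
`{0, 1/B, …, 1}`; the acceptance suite checks this calibration, and checks
that the fraction removed approaches `1 − alpha − 1/B`.

## Integration across traits

$$\mathrm{Score} = \sum_{i=1}^{n} -\log_{10}(p_i)$$

summed over all supplied traits. A (gene, trait) association removed by the
filter — or never tested — contributes 0 rather than deleting the gene
outright: filtering is applied per trait before integration, so a gene
removed for one trait can still score through the others. A gene contributing
0 in every trait drops out of the ranking. Ties in Score are broken
lexicographically by gene name. Contributions are clamped below at `p_floor`
so a perfect-separation block cannot produce an infinite score.

## Phenotype derivation

Six strain-level traits are computed from long-format behavioral records:

* **%MPE** `= (measured − baseline)/(cutoff − baseline) × 100`, clamped to
  [0, 100]; the cutoff (default 10 s) is the hardware ceiling.
* **Tolerance** is the fold change `ED50_post / ED50_pre` from cumulative
  morphine dose–response curves at doses 0, 1, 2, 4, 8, 16, 32 mg/kg. The
  curve model is the minimal two-parameter log-logistic (Hill) with fixed
  asymptotes 0/100 on the %MPE scale, `%MPE(d) = 100/(1 + (ED50/d)^h)`; dose
  0 anchors the lower asymptote and is excluded from the log transform. The
  fit linearises exactly through the logit (giving closed-form starting
  values) and refines by Nelder-Mead plus a BFGS polish on the residual sum
  of squares. `nls()` was rejected because it cannot converge on
  zero-residual (noiseless) curves, which the self-consistency tests require
  to 1e-6 relative error. Whether the slope should be constrained is an open
  modelling question; it is left free here, and a monotonically decreasing
  curve is an error (inverted input), as is an all-equal one (no
  information).
* **OIH** (mechanical, thermal hindpaw, thermal tail-flick) is the percent
  decrease of the withdrawal threshold/latency from baseline,
  `(1 − post/baseline) × 100`. Hypoalgesic strains (post > baseline) yield a
  negative decrease and pass through unclamped. The von Frey up–down
  threshold estimation itself is out of scope; thresholds enter as
  already-estimated values.
* **Dependence** is the naloxone-precipitated jump count in the 15-minute
  window, passed through unchanged.
* **Weight change** is `((final − initial)/initial) × 100`.

## The synthetic panel: what it states and what it does not

The generator's defaults state the reference scenario used by the validation
suite: a 24-strain panel (one more than the motivating 23-strain panels so
haplotype groups balance evenly), 100 genes — 98 with 5 blocks, one
"polymorphic" null gene with 200 blocks, one causal gene with 5 blocks — a
2-sigma planted effect on 3 of the 6 traits (tolerance, mechanical OIH,
weight change, the trio that dominates real integrated rankings),
strain-level Gaussian noise with SD 1, and two balanced haplotype groups per
block (a skew parameter is available; real panels are unbalanced). Traits
are generated independently given the genotype.

Each simulated gene sits on its own chromosome, so sliding windows never
straddle two genes; since the mapper treats chromosomes independently this is
only a relabeling. Within a gene, windows *do* straddle adjacent blocks and
produce refined partitions, monomorphic windows, and duplicate partitions —
which is why a 200-block declaration yields on the order of 350 surviving
candidate windows rather than exactly 200, and why the generator's
"indistinguishable from null" guarantees are tested against matched null
genes rather than against U(0, 1) (a minimum over correlated block tests is
stochastically smaller than uniform by construction; only the block-level
p-values are uniform under the null).

The behavioral generator draws strain-level post/baseline fractions with a
wide inter-strain spread (mechanical 0.60 ± 0.15, thermal 0.70 ± 0.12,
tail-flick 0.75 ± 0.12 of baseline), mirroring the broad strain-to-strain
range real panels display, and adds measurement noise of 3 %MPE units,
0.05 g (von Frey), 0.3 s (thermal latency) and 0.1 g (body weight). At these
settings the derivation module recovers the generating strain values with
r > 0.9, and exactly at zero measurement noise.

A green end-to-end test therefore establishes that the pipeline corrects
min-p rank inflation *under this stated world*: balanced groups, independent
blocks, Gaussian strain-level noise, a single causal block. It does not
establish robustness to population structure or kinship (no correction is
implemented, matching the method being modelled), to linkage between genes,
or to non-Gaussian trait distributions.

## Numerical choices

* Constant-trait detection: a block with total SS below `1e-12 × n × mean
  square` reports F = 0, p = 1 (no variance anywhere).
* Perfect separation (within-group SS ≤ 1e-12 of total SS with between SS
  positive) is clamped to `p_floor` (default 1e-300) and flagged degenerate.
* Adjacent windows inducing an identical strain partition are deduplicated
  before testing (left-most kept); the gene-level minimum is unchanged.
* Ties in the gene-level minimum report the left-most block as best block.
* Coordinates are 0-based half-open internally; TSV/VCF positions are
  1-based on disk and converted at the boundary only. Strain-name matching
  between genotypes and phenotypes is exact and case-sensitive; a phenotyped
  strain missing from the genotype panel is an error, not an intersection.
* Seeds are mandatory for every randomised operation; manifests carry no
  timestamps so repeated runs are bit-identical.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` | 3 SNPs | block width; stride is always 1 |
| `min_group_size` | 2 strains | at least one haplotype group must reach this size |
| `flank_bp` | 10,000 bp | gene span extension; admits proximal regulatory variation (whether the original analyses included flanks is unstated, so it is configurable) |
| `p_floor` | 1e-300 | lower clamp keeping −log10(p) finite |
| `B` | 1,000 | permutations per trait |
| `alpha` | 0.005 | FDR removal threshold (k > 5 at B = 1,000) |
| `cutoff_latency` | 10 s | tail-flick hardware ceiling for %MPE |

## Known limitations

* No kinship or population-structure correction, no LD pruning, no interval
  mapping between genes — none belong to the method being modelled.
* The block machinery is a re-specification (sliding fixed-width windows),
  not a reproduction of any particular legacy block-construction algorithm.
* Genotype input is source-agnostic: no genome build is assumed and no
  liftover is offered.
* The six traits are integrated unweighted; correlation between traits is
  not adjusted for, so the composite Score over-counts evidence shared
  between correlated phenotypes.
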