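---
title: "Methods: quantifying antioxidant attenuation of spaceflight expression signatures in spatial profiles"
author: "dspattenuate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying antioxidant attenuation of spaceflight expression signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspattenuate)
```

## The scientific problem

Digital spatial profiling (DSP) yields deduplicated digital counts of
transcripts for small, anatomically defined areas of illumination (AOIs) on a
tissue section. The study design this package serves is a 2×2 layout in the
mouse brain: condition (ground control, `GC`, vs spaceflight, `FLT`) crossed
with treatment (saline, `SAL`, vs the manganese-porphyrin superoxide-dismutase
mimic MnTnBuOE-2-PyP^5+^, `BuOE`), assayed in four regions — cortex (`CT`),
frontal cortex (`FCT`), and the hippocampal Cornu Ammonis 1 (`CA`) and dentate
gyrus (`DG`) — with about three replicate AOIs per region-by-group cell.

The question of interest is not merely which genes respond to spaceflight,
but whether an antioxidant administered during flight *attenuates* that
response: if a gene goes up in flight, does treatment push it back down, and
vice versa. The package implements that attenuation analysis end to end,
together with a synthetic data generator that plants a known answer, so every
stage can be validated without access to any particular dataset.

## Q3 normalization

AOIs differ in collected tissue area and assay efficiency, which scales all
of an AOI's counts. The DSP convention is third-quartile (Q3) normalization:
for AOI $a$ with per-gene counts $c_{ga}$, let $Q3_a$ be the 75th percentile
over genes (linear interpolation between order statistics). The scaling
factor is

$$f_a = \frac{Q3_a}{\left(\prod_b Q3_b\right)^{1/n}},$$

and normalized values are $v_{ga} = c_{ga} / f_a$. After normalization every
AOI has the same Q3, equal to the geometric mean of the raw Q3s. Downstream
statistics use $\log_2(v_{ga} + 1)$; the pseudocount keeps zeros at zero,
which matters because DSP panels contain genes at or near background.

One subtlety is worth stating precisely, because it affects what "scale
invariance" can mean. Multiplying one AOI's raw counts by $c$ multiplies its
own Q3 by $c$ and the geometric-mean anchor by $c^{1/n}$; the AOI-specific
factor is therefore absorbed exactly, but *every* normalized value in the
matrix acquires the common gauge $c^{1/n}$. That global gauge cancels from
log2 fold changes, t statistics, ANOVA F statistics and centroid distances,
so all scientific outputs are invariant; the raw normalized values are
invariant only up to the gauge. The test suite asserts exactly this.

No limit-of-quantitation or background filtering is applied before
normalization: the upstream platform pipeline is taken to have produced
usable counts for all reported genes, and a gene-level filter would be an
additional modeling choice with its own consequences for the DEG universe.
Every AOI must have a strictly positive Q3; an AOI failing that is reported
by name rather than silently dropped.

## Differential expression with permutation q-values

For each region, three unpaired contrasts are defined on the log2 normalized
values, with the sign convention *test minus reference*:

* flight response: `FLT-SAL` vs `GC-SAL`;
* antioxidant response during flight: `FLT-BuOE` vs `FLT-SAL`;
* antioxidant response on the ground: `GC-BuOE` vs `GC-SAL`.

With this convention, attenuation of a flight effect appears as opposite
log2FC signs between the first two contrasts. The per-gene statistic is a
two-sided Welch (unequal-variance) t-test; with three replicates per group,
assuming equal variances buys little and costs robustness. A variance floor
of $10^{-12}$ keeps genes with zero within-group variance finite: equal
constant groups give $t = 0$, $p = 1$; unequal constant groups give an
extreme $t$ and a vanishing $p$.

Multiplicity is handled by a permutation plug-in estimate of the false
discovery rate. Group labels are permuted within the contrast's AOIs; for
each relabeling the per-gene Welch p-values are recomputed, pooling
$S \times G$ null p-values over $S$ relabelings and $G$ genes. The q-value of
gene $g$ is

$$\hat q(g) = \frac{\tfrac{1}{S}\,\#\{p^{null} \le p_g\}}{\#\{p^{obs} \le p_g\}},$$

clipped to $[0,1]$ and made monotone nondecreasing in the p-value rank by a
running minimum from the largest p downward. Two numerical choices matter:

* **Equivalent relabelings are excluded from the null.** The identity
  relabeling (and, for equal group sizes, its complement) reproduces the
  observed p-values exactly; leaving it in the pool puts a hard floor of
  (number of equivalent relabelings)/$S$ on every q-value. With three
  replicates per group there are only $\binom{6}{3} = 20$ distinct
  relabelings, so that floor would be $0.1$ — no gene could ever reach
  $q < 0.05$ in the very design the method targets. The 18 informative
  relabelings are enumerated instead (a warning notes the enumeration);
  larger designs sample `n_perm` relabelings from a seeded stream.
* **DEG thresholds are strict**: $q < 0.05$ *and* $|\log_2 FC| > 0.585$
  (fold change above 1.5×). A gene at either boundary is not called.

Under a fully null simulation the fraction of genes at $q < 0.05$ is
essentially zero (the plug-in estimator is conservative because the pooled
null includes effect genes, whose permuted within-group variance is
inflated); with planted effects of $|\log_2 FC| = 2$ at six replicates the
call recovers most planted genes at an empirical FDR well under the nominal
level. Both experiments are in the test suite.

## The attenuation statistics

Let the flight contrast and the in-flight antioxidant contrast each define a
DEG set over the same gene universe. The overlap of the two sets is
partitioned by sign agreement of the log2 fold changes: $X_{11}$ genes change
in *opposite* directions (the attenuation signature), $X_{21}$ in the *same*
direction. With $N$ the total number of flight DEGs plus antioxidant DEGs,
the contingency table

$$\begin{pmatrix} X_{11} & N - X_{11} \\ X_{21} & N - X_{21} \end{pmatrix}$$

is formed and tested with a two-sided Fisher's exact test
(minimum-likelihood convention, computed by direct enumeration of the
hypergeometric support). This table is reproduced exactly as the source
analysis defines it, including the unusual choice of complementing both rows
against $N$ rather than against the overlap; its rows are not independent
samples, so the package also reports an exact binomial test of opposite vs
same direction among the overlapping DEGs — the orthodox test of the same
null hypothesis (that the two proportions are equal) — as `binomial_p`
alongside `fisher_p`.

### The gene-shuffling permutation null

The second significance assessment shuffles the full analyzed gene list $B$
times (default 1000, seeded); in each iteration the top $N_{up}$ genes of the
shuffled list are taken as pseudo-upregulated antioxidant DEGs and the bottom
$N_{down}$ as pseudo-downregulated ones, with $N_{up}, N_{down}$ fixed at the
actual antioxidant DEG direction counts. The number of actual flight DEGs
overlapping the pseudo-lists in the opposite direction forms the null
distribution, and

$$p_{emp} = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + B},$$

with the +1 correction avoiding $p = 0$. Under this null the expected
opposite overlap has the closed form
$n^{space}_{up} N_{down}/G + n^{space}_{down} N_{up}/G$, which the test suite
checks against the empirical null mean — an analytic guard on the shuffling
logic. List sizes are preserved exactly in every iteration by construction
(each iteration is a permutation of the gene list).

### A known limitation: shared-group correlation

The flight contrast (`FLT-SAL` vs `GC-SAL`) and the antioxidant contrast
(`FLT-BuOE` vs `FLT-SAL`) share the `FLT-SAL` group. Their log2 fold changes
are therefore negatively correlated at every gene *even when the antioxidant
does nothing*: noise that pushes a gene's `FLT-SAL` mean up inflates the
flight fold change and deflates the antioxidant one simultaneously (with
equal group variances the correlation is $-0.5$). The gene-shuffling null
treats the antioxidant DEG list as exchangeable across genes and ignores
this coupling, so for lists *derived from the observed contrast* the
empirical p-value is anti-conservative — opposite-direction overlaps exceed
the shuffling null's expectation even without any treatment effect. A
property test in the suite demonstrates the negative correlation on
no-effect simulations. Calibration of the machinery itself is verified under
the null it actually assumes: fixed-size lists whose membership is drawn
independently of the data give an approximately uniform empirical p and a
rejection rate at the nominal level. Interpreting the empirical p on real
data should bear the shared-group coupling in mind; the Fisher and binomial
tests on the overlap partition do not condition on list membership and are
not affected by this particular artifact.

## ANOVA-filtered PCA and centroid distances

For a global view, a one-way ANOVA is fit at every gene with the
experimental group (region × condition × treatment) as the factor. Treating
each AOI as its own level would leave zero residual degrees of freedom, so
the group reading is the only usable one; it is also the level at which the
downstream centroid question is posed. F statistics are computed vectorized
(between/within sums of squares) and match `stats::aov` exactly. P-values
become q-values by the Storey procedure with $\lambda$ fixed at 0.5 — a
deterministic, parameter-free choice; genes at $q < 0.05$ enter the PCA.

The PCA is computed on the gene-centered, unscaled log2 matrix (scaling to
unit variance would up-weight near-background genes). Replicates may be
averaged within each region-by-group cell first, so that each projected
point is a group expression profile; distances are then read in the PC1–PC2
plane. For each region the report contains
$d_{SAL} = \lVert \text{FLT-SAL} - \text{GC-SAL} \rVert$,
$d_{BuOE} = \lVert \text{FLT-BuOE} - \text{GC-BuOE} \rVert$, and the
attenuation ratio $d_{BuOE}/d_{SAL}$: a ratio below 1 means treatment moved
the flight transcriptome toward its matched ground control. On simulations
the ratio sits near 1 with no planted attenuation and falls well below 1
with full attenuation, and with all components retained the PCA reproduces
the pairwise sample distances of the centered filtered matrix exactly
(orthogonality check in the suite).

## Over-representation and disease association

Pathway mapping is a one-sided hypergeometric over-representation test of a
DEG list against user-supplied gene sets (GMT format), with the analyzed
gene universe as the background and Benjamini–Hochberg adjustment across
sets. A web service's composite ranking is deliberately not reproduced: the
plain hypergeometric with an explicit universe is deterministic and offline.
Disease-association screening intersects DEG lists with a two-column
gene–disease table, case-insensitively, since human disease resources list
symbols in upper case while mouse symbols are title case.

## The synthetic data generator

`simulate_dataset()` draws counts for gene $g$ in AOI $a$ (region $r$, group
$(cond, trt)$) from a negative binomial with mean

$$\mu_{ga} = 2^{\,b_g + [cond=FLT]\,\delta_{gr} - [cond=FLT,\ trt=BuOE]\,\alpha_g\,\delta_{gr} + [cond=GC,\ trt=BuOE]\,\epsilon_g} \cdot s_a$$

and a single global dispersion $\theta$ (variance $\mu + \mu^2/\theta$).
Defaults mirror the study design: four regions × four groups × three
replicate AOIs, 5000 genes (a whole-transcriptome panel down-sampled to keep
simulation studies fast), baselines uniform on $[2, 9]$ log2 units (counts
from a few to a few hundred, the dynamic range of deduplicated DSP counts),
$\theta = 10$ (strong but realistic overdispersion), log-normal AOI scale
factors with $\sigma = 0.3$ so normalization has real work to do, 200
planted flight-responsive genes per region with $|\delta| = 1$ and
deterministically alternating signs (an exact 50/50 up/down split without a
second random stream), and attenuation fraction $\alpha = 0.5$ — a partial
reversal, the qualitative regime the motivating data suggest. $\epsilon$
(an antioxidant effect in ground controls) defaults to 0 and, when enabled,
is applied with alternating sign to the genes that are flight-responsive in
at least one region. One RNG stream drives everything, so a single seed
fixes the dataset bit-for-bit.

What the generator deliberately does not emulate: per-gene dispersions,
correlated gene modules, spatial structure within regions, probe-level
noise, and nesting of AOIs within mice (replicate AOIs are exchangeable).
Passing tests therefore certify the statistical machinery under a clean
overdispersed model, not robustness to those real-data features; in
particular, AOIs from the same animal are pseudoreplicates in real data and
would narrow the effective sample size.

## Validation experiment sizes

The packaged experiments use problem sizes chosen to give stable Monte-Carlo
answers in minutes on one core: exhaustive Fisher enumeration over all 2×2
tables with total ≤ 30; 200 simulated datasets of 1000 genes for the
shuffling-null calibration; 20 seeded datasets of 5000 genes with six
replicates per group for the attenuation-recovery and FDR/recall studies
(effect size 2 — a strong planted signature, so that recovery failures
indicate implementation defects rather than power limits); and 20 matched
seed pairs for the centroid-distance contrast of $\alpha = 0$ vs
$\alpha = 1$.

## Known limitations

* The permutation-null empirical p is anti-conservative for data-derived
  lists (shared-group correlation, above); the Fisher construction it
  accompanies complements against $N$ rather than the overlap and is
  reported verbatim for fidelity, with the binomial test as the orthodox
  alternative.
* The plug-in permutation FDR is conservative when many strong effects are
  present (effect genes inflate the permuted null's tails).
* With three replicates per group the q-value resolution is limited by the
  18 informative relabelings; small designs are fundamentally
  coarse-grained here, which is a property of permutation inference, not of
  the implementation.
* Q3 normalization assumes the 75th percentile is driven by genuinely
  expressed genes; panels dominated by background would need a
  limit-of-quantitation step that this pipeline intentionally omits.
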