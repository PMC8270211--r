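---
title: "Methods: testing genetic overlap between disease subgroups with case-parent trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing genetic overlap between disease subgroups with case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioverlap)
```

## The problem

Two subgroups of a disease (for instance cleft lip with or without cleft
palate versus cleft palate alone) are each studied with case-parent
trios: an affected child and both parents. A natural scientific question
is whether a variant influences risk of *both* subgroups — genetic
overlap — rather than just one. The usual devices for combining the two
samples (pooling all trios into one test, inverse-variance
meta-analysis, Fisher's combination) all test the *global* null
hypothesis that the variant affects *neither* subgroup. A variant with a
strong effect on one subgroup only will happily reject that global null,
so those tests cannot distinguish overlap from a subgroup-specific
signal; and when sample sizes are unbalanced their rejection rate under
such "sub-null" variants can be wildly inflated relative to a nominal
overlap claim.

`trioverlap` implements the product-of-Z-scores approach: per-subgroup
gTDT summary statistics, their cross-study meta-analysis, and a test of
the *composite* null

$$H_0 : \beta_1 \beta_2 = 0 \quad\text{vs.}\quad H_a : \beta_1\beta_2 \neq 0,$$

where $\beta_k = \log \mathrm{RR}_k$ is the per-allele log relative risk
in subgroup $k$. $H_0$ is the union of the global null
($\beta_1=\beta_2=0$) and the two sub-nulls (exactly one $\beta_k \neq
0$). Rejection is evidence that the variant affects both subgroups,
whatever the directions of effect.

## Per-variant summary statistics: the additive gTDT

For a trio, the genotypic TDT conditions on the parental genotypes and
compares the affected child's genotype with the three pseudo-sibling
genotypes constructible from the same parents, in a conditional-logistic
likelihood. Under additive dosage coding the MLE has a closed form in
the sufficient statistics $T$ and $U$ — effect alleles transmitted and
untransmitted by *heterozygous* parents:

$$\hat\beta = \log(T/U), \qquad
  \widehat{\mathrm{se}} = \sqrt{1/T + 1/U}, \qquad
  Z = \hat\beta / \widehat{\mathrm{se}}.$$

`gtdt_additive()` uses this closed form; the test suite verifies it
against an independent generic conditional-logistic maximizer (and
against `survival::coxph` with exact conditional likelihood) to
$10^{-8}$ relative error on hundreds of random panels. Because the test
conditions on parental genotypes, it is immune to population
stratification, which is what licenses combining multi-ethnic trios.

Degenerate counts ($T=0$ or $U=0$) yield an infinite $\hat\beta$; the
p-value then falls back to the exact binomial test of transmission
probability $1/2$ and the variant is flagged (`"degenerate"`) and
excluded from downstream overlap testing. No continuity correction is
applied: under the MAF $\ge 5\%$ founder filter such variants are
vanishingly rare, and a flag is more transparent than a corrected
estimate. Trios whose child is Mendelian-impossible given the parents
are removed by `mendelian_filter()`, which also reports the per-variant
violation rate for the conventional $\le 5\%$ variant screen.

The 1-df SNP-by-sex interaction model (`gtdt_sex_interaction()`)
exploits the fact that sex is constant within a trio, so the
conditional likelihood factorizes by stratum and the interaction MLE is
the difference of stratum-specific estimates with variances adding.

## Combining studies, and the global-null competitors

`ivw_meta()` is standard fixed-effects inverse-variance weighting;
Cochran's Q is reported but never used to filter (no random-effects
model is offered, deliberately). Variants present in a single study are
carried through as single-study results rather than imputed. All
studies must share one effect-allele convention; the pipeline sets it
once, as the minor allele among the founders of the first-configured
study/subgroup, and applies it everywhere.

`pooled_gtdt()` (one gTDT on the union of trios), `fisher_combine()`
($\chi^2_4$) and the dual-threshold criteria
(`naive_criterion()`; presets $p_1 < 5\times10^{-8}$ with
$p_2 < 10^{-5}$ or $10^{-3}$) are implemented as comparators. They are
global-null tests (or ad-hoc criteria) and serve as the baseline in the
evaluation harness.

## The composite-null product test

With genome-wide $Z_1, Z_2$ from independent trio samples, the test
statistic is $T = Z_1 Z_2$. Under the global null, $T$ follows the
normal product distribution with density $K_0(|x|)/\pi$ ($K_0$: modified
Bessel function of the second kind); its two-sided tail is

$$F(u) = \frac{2}{\pi}\int_{|u|}^{\infty} K_0(x)\,dx.$$

Under a sub-null, the associated subgroup's effects vary across the
genome; modelling the latent mean of $Z_k$ as $N(0, \tau_k^2)$ gives
marginal variance $v_k = 1 + \tau_k^2 \ge 1$. The composite-null
p-value is the three-term composition

$$p = F(t/s_1) + F(t/s_2) - F(t),$$

which reduces exactly to $F(z_1 z_2)$ when $v_1 = v_2 = 1$ (an algebraic
identity, asserted in the tests).

**Scaling choice.** If $Z_1 \sim N(0, v_1)$ independent of
$Z_2 \sim N(0,1)$, then $Z_1 Z_2 / \sqrt{v_1}$ has *exactly* the
standard normal-product distribution. The scaling is therefore the
standard deviation, $s_k = \sqrt{v_k}$ (the default, verified against
Monte Carlo of the sub-null product in the tests). Because variance
notation is sometimes read literally, `scaling = "variance"` divides by
$v_k$ itself; it is strictly conservative for $v_k > 1$ and is provided
for compatibility only.

**Evaluating $F$.** Two regimes, both accurate to better than
$10^{-12}$ relative error against adaptive quadrature:

* $|u| < 1$: the ascending series of $K_0$ integrated term by term
  (18 terms reach machine precision; the $u \log u$ behaviour near 0 is
  handled analytically).
* $|u| \ge 1$: 64-node Gauss–Laguerre quadrature of the exponentially
  scaled integrand $K_0(u+y)e^{-y}$, carried on the log scale so tails
  far below double-precision underflow remain usable
  (`log.p = TRUE`).

The switch point $u = 1$ was chosen from measured accuracy curves of
both branches (series degrades slowly above $u \approx 5$ from
cancellation; Gauss–Laguerre degrades below $u \approx 0.5$ from the
log singularity of $K_0$ at the origin). Reported p-values are clamped
to $[10^{-300}, 1]$ so downstream $-\log_{10}$ plots never meet an
exact zero. Rejection counting on large panels inverts the monotone
p-value once per level (`placo_threshold()`, Brent's method at
tolerance $10^{-11}$) instead of evaluating per-variant tails.

**Estimating the marginal variances.** `estimate_var_z()` screens out
strongly associated variants (two-sided $p <$ `p_screen`, default
$10^{-4}$) and estimates $v$ from the remaining $z^2$. Screening
truncates the distribution at $\pm c$, $c = \Phi^{-1}(1 -
p_{\mathrm{screen}}/2)$, and the plain mean of $z^2$ is therefore
biased low precisely when $\tau^2 > 0$ — for an all-sub-null panel with
$\tau_Z \approx 1.5$ the plain estimator under-estimates $v$ by ~17%,
which would roughly double the rejection rate at $\alpha = 10^{-4}$.
The default estimator corrects this by method of moments: it solves

$$v \cdot g(c/\sqrt{v}) = \overline{z^2_{\mathrm{retained}}}, \qquad
  g(x) = 1 - \frac{2x\phi(x)}{2\Phi(x)-1},$$

for $v$ ($g(x)$ is the second moment of a standard normal truncated to
$[-x,x]$), then floors at 1. The uncorrected version remains available
as `method = "naive"`. With the corrected default, empirical rejection
on million-variant all-sub-null panels is statistically
indistinguishable from nominal at $\alpha \in \{10^{-3}, 10^{-4}\}$;
with the naive estimator it is visibly inflated. The estimator warns
below 1,000 variants, where the method-of-moments step is noisy.

## The trio simulator

`simulate_trios()` emulates ascertainment on an affected child under a
multiplicative genotype relative-risk model: parents drawn from
Hardy–Weinberg proportions at the stratum's effect-allele frequency,
child by Mendelian transmission, trio accepted with probability
proportional to $\mathrm{RR}^{g_{\mathrm{child}}}$ (the rare-disease
ascertainment weight; the baseline prevalence cancels from the
retrospective likelihood, so prevalences in `scenario_config()` are
carried as stratum labels, not used numerically). Two consequences of
the model, both tested: conditional on a heterozygous parent the effect
allele is transmitted with probability $\mathrm{RR}/(1+\mathrm{RR})$,
and at $\mathrm{RR}=1$ the gTDT Z is standard normal.

Because the ascertained likelihood factorizes per parent,
`simulate_transmission_counts()` draws the gTDT sufficient statistics
directly from three binomials per stratum — a fast path whose
distributional equivalence to the trio-level path is checked by a
Kolmogorov–Smirnov comparison of gTDT Z over 1,000 replicates. All
genome-scale work (null panels of $10^6$ variants, 3,000-replicate
power runs) uses this path; a $10^6$-variant bi-ethnic panel simulates
in roughly ten seconds.

**Scenario defaults.** A panel describes 2,400 trios split between
subgroups 1:1 (1200/1200), 3:1 (1800/600) or 7:1 (2100/300), each
subgroup half-and-half across two ethnic strata. Where a concrete value
had to be fixed once: stratum effect-allele frequencies default to 0.10
and 0.20 (a moderate between-ancestry difference typical of common
variants), prevalences to 0.001 and 0.002, and power scenarios use MAF
0.10 in both strata. Null-panel presets:

* `scenario_global_null()` — every variant null on both subgroups;
* `scenario_fixed_subnull()` — 99.8% global null, 0.1% each carrying a
  fixed RR of 1.15 on exactly one subgroup;
* `scenario_random_subnull()` — every variant with a random effect on
  subgroup 1 only, $\log \mathrm{RR} \sim N(0, 0.1^2)$.

Panels default to $10^6$ variants, a deliberate scale-down from the
tens of millions a full genome-wide replication would use; calibration
is correspondingly assessed at $\alpha \ge 10^{-4}$, where $10^6$
variants give useful binomial resolution.

**Randomness.** One master seed drives a single vectorized stream per
panel; seeded runs are bit-reproducible. Per-variant counter-based
streams (which would make panels invariant to variant order) were
considered and dropped: base R's RNG offers no cheap splitting, and
order-independence buys nothing for i.i.d. variants.

**What the simulator does not emulate.** Variants are independent (no
linkage disequilibrium), genotypes are error-free hard calls with no
missingness, no imputation uncertainty, no maternal or parent-of-origin
effects, and ascertainment uses the rare-disease approximation. Passing
calibration and power checks on these panels therefore speaks to the
statistical machinery — not to robustness against genotyping error,
imputation artefacts, or LD-induced dependence in real data.

## The evaluation harness

`power_study()` simulates single-variant replicates under the
scenario's alternative and tallies rejections per method;
`type1_study()` does the genome-scale analogue on null panels,
reporting 99% Wilson intervals per method and level. Power runs fix the
product-test variances at 1: a single-variant design has no genome-wide
panel from which to estimate them, and unit variances are the honest
match to comparing against fixed-threshold criteria. Monte-Carlo
standard errors use $\sqrt{r(1-r)/n}$; 3,000 replicates put the SE
near 0.9 percentage points at 50% power, which is why power targets are
quoted to about $\pm 3$ points.

At the reference design — 1,800 + 600 trios, MAF 0.10, RR 1.5 on both
subgroups, $\alpha = 5\times10^{-8}$ — the product test rejects in
about 62% of replicates while the liberal dual-threshold criterion
manages about 25%; with opposite-direction effects (RR 1.5 and 1/1.5)
the contrast is about 46% versus 15%. With all effects at RR = 1 every
method's rejection rate matches its nominal level (asserted in the
tests).

A caveat surfaced by the million-variant calibration grid: at the
smallest subgroup size (300 trios, roughly 150 heterozygous parents)
the gTDT Wald Z is slightly light-tailed in finite samples (measured
$P(|Z| > 3.09) \approx 8\times10^{-4}$), so the product test inherits a
mild *conservatism* at $\alpha = 10^{-3}$ under extreme 7:1 imbalance.
Error control is preserved; exact nominality at such small per-arm
counts is not claimed.

`genomic_lambda()` maps p-values to 1-df $\chi^2$ statistics and
returns the empirical/theoretical percentile ratio (median for bulk
inflation, $x = 0.001$ for the tail); `qq_coordinates()` emits QQ data
with pointwise beta order-statistic bands. Both are plain coordinate
emitters — plotting is left to the caller.

## Files, pipeline, loci

`read_trios()` assembles complete trios from VCF (hard GT calls,
biallelic records; multiallelics skipped with a warning) plus a FAM
pedigree and an optional subgroup/ethnicity sidecar; a missing genotype
in any member excludes that trio at that variant only.
`filter_founder_maf()` applies the founders-only MAF $\ge$ 5% filter
(inclusive at the boundary). `run_pipeline()` chains read → QC →
per-study gTDT → per-subgroup meta → overlap test, writing per-stage
TSVs (full double precision; round trips are lossless to 15
significant digits) and a log with version, seed and configuration. If
the two "subgroups" are declared identical it warns loudly: the method
assumes the two Z panels are independent, and sample overlap
invalidates the p-values.

`clump_loci()` groups suggestively significant variants
($p < 10^{-6}$) into loci greedily: most significant unassigned variant
as index, members within $\pm 500$ kb (1-based, inclusive) and
$r^2 > 0.2$ with the index. LD is injected by the caller (matrix or
function); a missing pair is treated as $r^2 = 0$ with a warning by
default (a multi-ethnic analysis has no single reference LD), or as an
error on request. Ties in $p$ break by input order.

## Known limitations

Only two subgroups are compared; the two panels must be independent
(no decorrelation step for correlated or overlapping samples); common
variants only — the summary statistics and the variance model are
asymptotic and degrade below MAF 5% or a few hundred informative
trios; additive coding only (the machinery would extend to other
codings via the retained generic likelihood, but none is exposed); no
set- or gene-based aggregation; X-chromosome and parent-of-origin
analyses are out of scope.
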