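# trioverlap

Tests whether a genetic variant influences risk of **two disease
subgroups at once**, using case-parent trio studies — the design in
which an affected child and both parents are genotyped and association
is measured through transmission distortion, immune to population
stratification. The intended users are statistical geneticists analysing
trio GWAS of related disease subtypes (the motivating setting is
orofacial cleft subgroups) who have, or can compute, per-subgroup
summary statistics.

## The statistics

For subgroup *k* with per-allele log relative risk βₖ = log RRₖ, the
additive genotypic TDT (gTDT) conditional-logistic MLE has the closed
form

    β̂ = log(T/U),   se = √(1/T + 1/U),   Z = β̂/se

where T and U count effect alleles transmitted and untransmitted by
heterozygous parents. Studies are combined by fixed-effects
inverse-variance meta-analysis.

Genetic overlap is then tested per variant through the **composite null**

    H₀: β₁β₂ = 0   vs.   Hₐ: β₁β₂ ≠ 0,

i.e. H₀ holds if *at most one* subgroup is associated. The statistic is
the product T = Z₁Z₂, whose p-value is

    p = F(t/s₁) + F(t/s₂) − F(t),   F(u) = (2/π) ∫₍|u|₎^∞ K₀(x) dx,

the two-sided tail of the normal product distribution, with sₖ = √Var(Zₖ)
estimated genome-wide under a screened mixture model. Rejection —
unlike rejection by pooling trios, meta-analysis or Fisher's combination,
which test the *global* null — is evidence the variant affects **both**
subgroups. A bi-ethnic ascertained trio simulator and an evaluation
harness (type-I error on million-variant null panels, power studies,
genomic inflation factors, QQ coordinates) are included, along with
VCF/FAM input, founder-MAF and Mendelian QC, distance/LD locus clumping
and an end-to-end pipeline.

## Worked example

Simulate one variant (MAF 10%) carrying RR = 1.5 on both subgroups,
with 1,800 trios for subgroup 1 and 600 for subgroup 2:

```r
library(trioverlap)
set.seed(2024)
trios1 <- simulate_trios(1800, maf = 0.10, rr = 1.5)
trios2 <- simulate_trios(600,  maf = 0.10, rr = 1.5)
(s1 <- gtdt_additive(trios1))
#> gTDT (additive): beta = 0.4411 (RR = 1.554), se = 0.07257, z = 6.079, p = 1.21e-09
#>   T/U = 485/312 over 702 informative trios [ok]
(s2 <- gtdt_additive(trios2))
#> gTDT (additive): beta = 0.2719 (RR = 1.312), se = 0.1355, z = 2.007, p = 0.0447
#>   T/U = 126/96 over 200 informative trios [ok]
placo_test(s1$z, s2$z)
#>          t            p
#> 1 12.20137 1.095194e-06
```

Each gTDT line shows the estimated log relative risk (and RR), its
standard error, Wald Z and p-value, built from the transmitted /
untransmitted counts. The smaller subgroup alone is unremarkable
(p = 0.045); the product test combines the two signals into suggestive
evidence of overlap (p ≈ 1.1e-6) *without* letting either subgroup
carry the rejection by itself — `placo_test(0, z2)` returns p = 1 no
matter how large z2 is.

Power comparison at genome-wide significance when the two effects point
in **opposite** directions (RR 1.5 vs 1/1.5) — the situation in which
global-null methods collapse because pooled transmissions cancel:

```r
cfg <- scenario_config(n1 = 1800, n2 = 600, maf = c(0.10, 0.10),
                       rr1 = 1.5, rr2 = 1/1.5)
power_study(cfg, methods = c("placo", "pooled", "naive2"),
            alpha = 5e-8, n_reps = 3000, seed = 7)
#>   method alpha n_reps n_reject      rate       mc_se
#> 1  placo 5e-08   3000     1370 0.4566667 0.009094361
#> 2 pooled 5e-08   3000      129 0.0430000 0.003703647
#> 3 naive2 5e-08   3000      415 0.1383333 0.006303365
```

The product test detects the overlap in ~46% of replicates; the liberal
dual-threshold criterion (p₁ < 5e-8 and p₂ < 1e-3) in ~14%; pooling
drops to ~4% as the opposite transmissions cancel.

Null-panel calibration and the full pipeline
(`simulate → gTDT → meta → overlap test`) are exercised by
`type1_study()` and `run_pipeline()`; see the methods vignette
(`vignettes/trioverlap-methods.Rmd`) for the model, the defaults and
their rationale.

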