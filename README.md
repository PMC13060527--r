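# alcgwis

Genome-wide gene–alcohol interaction analysis of blood pressure, as an R
package.

Habitual alcohol consumption raises blood pressure, and it also modifies how
genetic variants affect it: some variants show several-fold larger effects in
drinkers than in non-drinkers.  Detecting such gene–environment interactions
at genome-wide scale requires a specific analysis chain — per-cohort
interaction regression, strict QC, multi-population meta-analysis, and a
multiple-testing framework tuned to the low power of interaction tests.
`alcgwis` implements that chain end-to-end for researchers running
gene–alcohol GWIS of SBP, DBP and pulse pressure, together with a synthetic
cohort generator so the entire pipeline can be exercised, calibrated and
taught without access to individual-level consortium data.

## The model

Each cohort fits, per variant, the joint main + interaction model

    E(Y) = β0 + β_Alc·Alc + β_G·G + β_GxAlc·G·Alc + β_C·C

with model-based standard errors and the covariance of (β̂_G, β̂_GxAlc),
yielding the 1df interaction Wald test, the 2df joint Wald test

    χ²₂ = (β̂_G, β̂_GxAlc) Ω⁻¹ (β̂_G, β̂_GxAlc)ᵀ,

and a marginal GWAS model for the 2-step screen.  Cohorts are pooled by
fixed-effects inverse-variance (1df) and inverse-covariance (2df)
meta-analysis, within populations and then across them.  Discovery proceeds
in tiers: genome-wide interaction significance (A), the 2-step screen at
0.05/M_eff among marginally associated variants (B), Bonferroni-corrected
interactions among genome-wide 2df loci (C), and 2df loci without
interaction (D), with LD clumping (r² ≥ 0.1, 500 kb fallback), novelty
classification against a known-loci catalog, sex/population heterogeneity
screens, and decomposition of each lead into unexposed (b0 = β_G) and
exposed (b1 = β_G + β_GxAlc) effects with fold-change b1/b0.

## Worked example

Simulate four cohorts in two populations sharing one true interaction
variant (unexposed effect 0.5 mmHg/allele, exposed effect 3.0 — a six-fold
amplification in drinkers), then run the full pipeline:

```r
library(alcgwis)

one_hit <- function(id, pop, freq = 0.3)
  list(id = id, population = pop, n_individuals = 2000, n_variants = 100,
       allele_freq = freq,
       beta_G = c(0.5, rep(0, 99)), beta_GxAlc = c(2.5, rep(0, 99)))

fit <- run_pipeline(list(
  seed = 7, traits = "SBP", contrasts = "CURDRINK",
  sex_groups = "combined", apply_reporting = FALSE,
  cohorts = list(one_hit("eur1", "EUR"), one_hit("eur2", "EUR"),
                 one_hit("eas1", "EAS", 0.4), one_hit("eas2", "EAS", 0.4))))
print(fit)
#> GWIS pipeline run (seed 7 ): 1 scan(s)
#>
#> -- SBP.CURDRINK.combined --
#> Discovery report [CPMA]
#>   primary interaction loci: 1 ( Meff = 1 over 1 screened variants )
#>    lead chrom   p_lead tier    b0   b1 fold
#>  v00001     1 1.57e-05    B 0.302 2.87  9.5
#>   2df loci (M_2df): 1 ; tier C: 1 ; tier D: 0
#>   nominal-interaction enrichment: k = 1 of 1 , P = 0.05
```

The planted variant is recovered as a tier-B locus: at 8,000 pooled
individuals its interaction p (1.6e-5) misses genome-wide significance, but
it passes the 2-step screen (marginal filter + Bonferroni at 0.05/M_eff).
The decomposition estimates an unexposed effect b0 ≈ 0.30, an exposed
effect b1 ≈ 2.9 mmHg/allele, and a fold-change of 9.5 (true value 6; at
this sample size the ratio is noisy because b0's SE is ~0.2).

Single-cohort pieces are available directly:

```r
cfg  <- sim_config(2000, 100, beta_G = c(0.5, rep(0, 99)),
                   beta_GxAlc = c(2.5, rep(0, 99)), seed = 8)
co   <- harmonize_cohort(simulate_cohort(cfg))
scan <- gwis(build_slices(co, "SBP", "CURDRINK", "combined")[[1]],
             co$dosage, co$variant_meta)
summary(scan)
#> GWIS scan summary: SBP ~ CURDRINK ( combined )
#>   n = 1997 ; 100 variants analysed, 0 skipped
#>   lambda_GC (interaction): 0.7116  lambda_GC (marginal): 0.6777
#>   min P_GxAlc: 0.00627  min P_2df: 7.8e-05
```

`plot(scan)` draws the interaction QQ plot; `coef(scan)` returns the
per-variant (β_G, β_GxAlc, β_marg) matrix.  See the methods vignette
(`vignettes/gene-alcohol-interaction-methods.Rmd`) for the full model,
harmonization rules, QC/genomic-control policy and design rationale.

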