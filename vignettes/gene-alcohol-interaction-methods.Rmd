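---
title: "Methods: gene-alcohol interaction analysis of blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-alcohol interaction analysis of blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcgwis)
```

## The model

`alcgwis` analyses how habitual alcohol consumption modifies genetic effects
on blood pressure.  For each variant, each cohort fits the joint main +
interaction model

$$E(Y) = \beta_0 + \beta_{Alc}\,Alc + \beta_G\,G +
\beta_{G\times Alc}\,G\!\cdot\!Alc + \beta_C C$$

by ordinary least squares, where $Y$ is SBP, DBP or pulse pressure (mmHg),
$G$ an imputed genotype dosage in $[0,2]$, $Alc$ a binary exposure contrast,
and $C$ the covariates (age, age$^2$, sex in sex-combined analyses).  The
engine reports model-based standard errors and, crucially, the covariance
between $\hat\beta_G$ and $\hat\beta_{G\times Alc}$, which feeds both the
2df joint Wald test

$$\chi^2_2 = (\hat\beta_G, \hat\beta_{G\times Alc})\,
\Omega^{-1}(\hat\beta_G, \hat\beta_{G\times Alc})^\top$$

and the decomposition of the genetic effect into the unexposed stratum
($b_0=\beta_G$) and exposed stratum ($b_1=\beta_G+\beta_{G\times Alc}$, with
$\mathrm{Var}(b_1)=se_G^2+se_{int}^2+2\,\mathrm{cov}$).  The ratio $b_1/b_0$
is the fold-change of the genetic effect under exposure; a 12q24-type signal
has $b_1/b_0 \approx 6$ in current drinkers.  A marginal model
($E(Y)=\beta_0+\beta_G G+\beta_C C$) supplies the standard GWAS statistics
used by the 2-step screen.

Wald p-values use the $\chi^2$ (large-sample) approximation rather than the
t distribution, the convention for GWAS-scale regression.  A
heteroscedasticity-consistent covariance is available (`robust = TRUE`) but
off by default, matching the model-based-SE convention of the interaction
analysis tools this package mirrors.  Covariate-by-exposure product terms
can be added (`covariate_alc_interactions = TRUE`) but default to off; the
joint model above is the reference specification.

## Harmonization

Phenotypes are prepared in a fixed order: antihypertensive-medication
adjustment (+15 mmHg SBP, +10 mmHg DBP), pulse pressure as the
adjusted SBP$-$DBP difference, very-heavy-drinker exclusion, then per-trait
winsorization at mean $\pm$ 6 SD.  Two of these placements are genuinely
open choices:

* winsorization runs after exclusions, with sex-combined moments, so the
  capping bounds describe the analysis sample; moments are estimated once
  from the input and values are set to exactly the 6-SD bound;
* the 6-SD rule for drinks per week (DPW) is evaluated among current
  drinkers (DPW $\ge 1$) in both the sex-specific and sex-combined strata
  (`among_drinkers = FALSE` reverts to all individuals).  With the point
  mass of never-drinkers included, the mean and SD collapse toward zero and
  the rule would remove ordinary heavy drinkers in low-consumption cohorts.

Exposure contrasts use the standard-drink scale (1 StDrk = 14 g ethanol;
volume $\times$ ABV $\times$ 0.78945 g/ml):
never $<1$ DPW; light 1–7 (F) / 1–14 (M), boundary inclusive; heavy above.
`CURDRINK` treats DPW $\ge 1$ as current drinking, aligning "not current"
with the never definition; the boundary between light and heavy belongs to
light, per the inclusive 1–7/1–14 ranges.

## Quality control and genomic control

Variants are removed when imputation quality $R^2 < 0.5$ or when
$\mathrm{MAC}\times R^2 < 20$ in the exposed, unexposed or total sample
(MAC computed from unrounded dosages as $\sum\min(d, 2-d)$ per stratum).
Cohort slices with fewer than 100 individuals, or fewer than 50 in either
exposure group, are excluded from meta-analysis.

Genomic control divides a test's $\chi^2_1$ by
$\lambda = \mathrm{median}(\chi^2_1)/0.45494$ when $\lambda > 1$ (never
deflating).  $\lambda$ is computed and applied separately to the
interaction, the genetic main-effect and the marginal tests; the 2df joint
statistic is then rebuilt from the corrected components, with the
main/interaction covariance scaled by $\sqrt{\lambda_G \lambda_{int}}$, so
the corrected 2df statistic remains a valid quadratic form.  How to correct
a 2df statistic is not standardised; rebuilding from corrected components
was chosen over correcting the 2df $\chi^2$ directly because it preserves
the decomposition identity used downstream.

## Meta-analysis

Cohort results are pooled with fixed effects only: scalar inverse-variance
weighting for the interaction and marginal effects, and inverse-covariance
(multivariate) pooling for the $(\beta_G, \beta_{G\times Alc})$ pair.
Pooling proceeds within population (AFR, BRA, EAS, EUR, HIS, SAS; at least
two contributing studies per variant) and then across populations on the
population-level records, not the raw cohorts.  Population records carry
both the IVW interaction estimate and the joint-pooled pair, so the
cross-population 2df statistic of a single contributing population
reproduces that population's statistic exactly.  Results are reportable
above 5,000 individuals (AFR/BRA/HIS/SAS) or 20,000 (EUR/EAS) with two
studies, and cross-population results above 20,000 individuals with two
populations; single-cohort populations (e.g. a Brazilian cohort of a few
thousand) therefore surface only through the cross-population analysis.

## Tiered discovery

Four complementary searches are applied per scan:

* **A** — interaction $P < 5\times10^{-8}$ and BH FDR $< 5\%$;
* **B** — 2-step: filter on marginal $P < 10^{-5}$, then test interaction at
  $0.05/M_{eff}$ (and FDR among the filtered set).  $M_{eff}$ is the
  simpleM-style count: the smallest number of leading eigenvalues of the
  filtered variants' dosage correlation matrix explaining $\ge 99.5\%$ of
  variance.  The 99.5% threshold is the simpleM convention and is
  configurable; the screen is valid because marginal and interaction
  Z-scores are asymptotically independent (verified empirically in the
  acceptance suite);
* **C** — among loci with genome-wide 2df significance ($M_{2df}$ of them,
  counted per population on clumped loci, not raw variants), interaction
  $P < 0.05/M_{2df}$;
* **D** — 2df-significant loci with no interaction signal.  Two cutoff
  conventions exist for "no interaction" ($P > 0.05$ or $P > 0.05/M_{2df}$);
  the plain 0.05 is the default with `d_bonferroni = TRUE` switching to the
  Bonferroni form.

Loci are formed by greedy clumping: ascending p, each lead claiming
variants with $r^2 \ge 0.1$ (from the simulator's hard-genotype reference
panel); variants absent from the panel join a locus within 500 kb and
otherwise stand alone.  Ties are broken by smaller position, then allele.
A locus is novel when every member is $>500$ kb from all catalogued
variants or in linkage equilibrium ($r^2<0.1$) with them; a nearby
catalogued variant with unknown LD marks the locus known (the conservative
reading of the inclusive $\pm 500$ kb bound).  Sex heterogeneity uses the
independent two-sample Z-test on sex-specific interaction estimates;
population heterogeneity uses Cochran's Q across population records; both
at Bonferroni levels over the tested leads.  Enrichment of nominal
interactions among 2df loci is the exact binomial upper tail
$P(X \ge k), X\sim\mathrm{Bin}(n, 0.05)$, evaluated in log space so tails
of order $10^{-40}$ are representable.

## The synthetic cohort generator

The generator exists so every stage is testable without access to consortium
data; its defaults are fixed study conditions, not tuning knobs.  BP is
generated from the same joint model the engine fits — so parameter recovery
is a genuine end-to-end check — with defaults chosen to resemble an adult
epidemiological cohort: SBP intercept 120 mmHg (DBP 75), residual SD 15
(DBP 10), age uniform on 30–75 years with 0.4 mmHg/year, a 3 mmHg
male–female offset, and DBP sharing half the SBP linear predictor.
Exposure is zero DPW with probability 0.40 (F) / 0.30 (M) and otherwise
lognormal (meanlog 1.0 / 1.7, sdlog 0.7) left-truncated at 1 drink/week, so
the generative drinker/never split coincides with the $<1$ DPW
classification boundary; untruncated draws would put drinkers below the
boundary and make configured never-fractions unrecoverable.  Medication is
assigned by a logistic link on latent SBP ($-9 + 0.05\,\mathrm{SBP}$,
about 10–15% treated) and subtracts a true effect of 10/6 mmHg from
observed BP, so the +15/+10 adjustment is deliberately a partial
(over)correction, as in real data.

Genotypes are Hardy–Weinberg draws; imputation noise is a convex blend of
the hard genotype with an independent draw, the blend weight solved
analytically from the target dosage quality
($R^2 = a^2/(a^2+(1-a)^2)$) — the simplest mechanism whose quality is
exactly controllable and whose dosages stay in $[0,2]$.  Optional
exchangeable LD blocks (latent-Gaussian thresholding) provide correlated
variants for clumping and $M_{eff}$ exercises.  All randomness flows from
one seed in a documented order (sex, age, exposure, genotypes, BP noise,
medication), so identical configurations are bit-identical.

What the generator does not emulate — realistic MAF spectra, fine-scale LD,
relatedness and population structure, X chromosome, strand flips,
longitudinal change — bounds what passing tests show: they validate the
statistical machinery under its stated assumptions, not robustness to the
artefacts of real consortium data.  Relatedness in particular is out of
scope; all cohorts are unrelated-individual OLS.

## Numerical choices and problem sizes

The engine solves the normal equations by Cholesky factorization, skipping
variants whose design is singular (monomorphic dosage, empty exposure-arm
carriers, collinearity) with a logged reason; a relative pivot threshold of
$10^{-10}$ guards near-singularity.  The $\chi^2_1$ null median is fixed at
0.45494.  Fold-changes are undefined when $|b_0| < 10^{-12}$.

Calibration checks in the test-suite use a null cohort of 5,000 individuals
by 5,000 independent variants (type-I error within $0.05\pm0.01$; genomic
control $\lambda$ within $1\pm0.05$ after correction; marginal-interaction
Z correlation $|r|<0.05$), and fold-change recovery uses 100 replicates of
50,000 individuals at generative $b_1/b_0 = 6$ (median recovered fold in
$[5,7]$).  These sizes give stable Monte-Carlo estimates at desk scale; the
consortium-scale discoveries themselves (dozens of loci from $>10^6$
individuals) are far outside what synthetic desk-scale data can or should
reproduce.

## Known limitations

Fixed-effects pooling only (no random-effects estimator); no
sample-overlap correction; no mixed models for related individuals; no
score tests; allele harmonization handles swaps but real strand flips never
arise from the simulator; the LD reference is the first cohort's hard
genotypes rather than an external ancestry-matched panel.
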