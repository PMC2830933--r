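---
title: "Recursive threshold mixed models for calving traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive threshold mixed models for calving traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recalv)
```

## The model

`recalv` fits Bayesian multi-trait sire–maternal-grandsire (sire–MGS) models
for three calving traits recorded on first-parity dairy cows: gestation
length (GL, in days, continuous), calving difficulty (CD, ordinal) and
stillbirth (SB, binary). CD and SB are modelled on a latent liability scale
with a probit (threshold) link: the observed score is the category whose
threshold interval contains the liability. For identification, the first CD
threshold and the SB threshold are fixed at 0, the second CD threshold at 1,
and the residual variance of the SB liability at 1.

The phenotype vector of calf $i$ is $y_i = (\mathrm{GL}_i, l_{CD,i},
l_{SB,i})'$. The recursive (structural equation) variants postulate one-way
phenotypic paths GL $\to$ CD, GL $\to$ SB and CD $\to$ SB, with rates that
depend on the category $k$ of the realized GL phenotype (by default
$k \in \{\le 267, 268\text{–}273, 274\text{–}279, \ge 280\}$ days, boundary
days belonging to the lower category):

$$\Lambda_k\, y_i = X_i b + Z_{i(h)} h + Z_{i(s)} s + Z_{i(mgs)}\, mgs +
\varepsilon_i, \qquad
\Lambda_k = \begin{pmatrix} 1 & 0 & 0\\ -\lambda_{CD\gets GL(k)} & 1 & 0\\
-\lambda_{SB\gets GL(k)} & -\lambda_{SB\gets CD(k)} & 1 \end{pmatrix}.$$

Systematic effects are sex of calf (2 levels), age at first calving
(4 levels) and year–season (12 levels); $h$ are herd-year contemporary-group
effects with $h \sim N(0, H_0 \otimes I)$; each bull carries a joint
six-dimensional (sire, MGS) effect $\sim N(0, G_0)$; residuals are iid
$N(0, R_0)$. Because the system is strictly recursive (unit-lower-triangular
$\Lambda_k$, determinant 1), premultiplying by $\Lambda_k^{-1}$ yields the
reduced form, with category-dependent covariance matrices
$\Lambda_k^{-1} G_0^{(\cdot)} \Lambda_k^{-T}$,
$\Lambda_k^{-1} H_0 \Lambda_k^{-T}$ and $\Lambda_k^{-1} R_0 \Lambda_k^{-T}$.
The overall effect of one day of GL on the SB liability in category $k$ is
the direct rate plus the path through CD,
$\lambda_{SB\gets GL(k)} + \lambda_{CD\gets GL(k)}\lambda_{SB\gets CD(k)}$,
which is exactly the (SB, GL) entry of $\Lambda_k^{-1}$'s action.

Four nested variants differ in which covariances are free and which are
attributed entirely to the recursion:

| variant | $\Lambda_k$ | $R_0$ | $H_0$ | $G_0$ | free parameters |
|---------|-------------|-------|-------|-------|-----------------|
| SMM  | $I$ | unstructured | unstructured | unstructured | 32 |
| RMM1 | free | diagonal | unstructured | unstructured | 41 |
| RMM2 | free | diagonal | diagonal | unstructured | 38 |
| RMM3 | free | diagonal | diagonal | per-trait (s, mgs) 2×2 blocks | 26 |

The counts include the structural coefficients (3 per GL category for the
recursive variants) and the free covariance entries; the fixed SB residual
variance is never counted. `count_free_parameters()` reproduces the table.

In RMM3 the sire, MGS *and* sire–MGS cross blocks of $G_0$ are all diagonal
across traits, but the per-trait sire–MGS covariance $\sigma_{s,mgs}$ is
kept: this is the only reading consistent with the parameter count of 26
(9 genetic + 3 herd + 2 residual + 12 structural).

## Direct and maternal genetic parameters

Under the sire–MGS parameterization, $s = \tfrac12 a_d$ and
$mgs = \tfrac14 a_d + \tfrac12 a_m$, so $a_d = 2s$ and $a_m = 2\,mgs - s$.
`willham_transform()` applies this linear map to the (possibly reduced-form)
6×6 genetic matrix, giving $\sigma^2_d = 4\sigma^2_s$,
$\sigma_{dm} = 4\sigma_{s,mgs} - 2\sigma^2_s$,
$\sigma^2_m = 4\sigma^2_{mgs} + \sigma^2_s - 4\sigma_{s,mgs}$ and the
bilinear between-trait analogues. Heritabilities use the phenotypic variance
$\sigma^2_p = \sigma^2_s + \sigma^2_{mgs} + \sigma_{s,mgs} + \sigma^2_e$ per
trait on the reduced-form scale; the herd-year variance is excluded by
default (`include_herd` switches it on). This denominator is the common
convention in sire–MGS analyses of calving traits; it is a convention, not a
theorem, and the flag exists because reasonable analysts differ on it.

All derived quantities (reduced-form matrices, heritabilities, correlations,
overall GL$\to$SB effects) are computed from **every retained draw** and then
summarized (`genetic_summary()`), not from posterior means of the inputs, so
the posterior uncertainty propagates correctly through the non-linear
transformations. Draws whose implied per-trait (direct, maternal) block is
not positive semidefinite are counted and reported, never silently dropped:
they occur legitimately in the tails of the posterior.

## A note on the scale of the recursion

Inside the recursive terms, GL enters as a deviation from a fixed reference
length `gl_ref` (default: the rounded sample mean). The rates are unchanged
— they remain liability units per day of GL, and the reduced-form and
overall-effect algebra never sees the reference — but the intercepts absorb
$\lambda \cdot gl\_ref$. With raw GL (around 280 days) a set of
category-specific rates would imply jumps of several liability units at the
category boundaries that no shared intercept could absorb; centring makes
the generative model coherent and, incidentally, nearly orthogonalizes the
rates and the intercepts, which helps mixing. The same reference is stored
in the fit and used for prediction.

## Gibbs sampler

All full conditionals are closed-form, so inference is by plain Gibbs
sampling with liability augmentation:

1. **Liabilities.** Each CD/SB liability is drawn from a normal truncated to
   its category's threshold interval. In the recursive variants the CD
   conditional pools the CD equation with the information flowing back from
   the SB equation (where $l_{CD}$ is a predictor); records are updated
   CD-then-SB. In the SMM, each trait's residual is conditioned on the other
   two through the unstructured $R_0$.
2. **Location effects.** The working variable $w_i = \Lambda_{k(i)} y_i$
   reduces the model to a standard multi-trait mixed model. Fixed effects
   (flat prior) are drawn jointly across traits; herd-year effects per level
   from 3×3 conditionals; per-bull (sire, MGS) 6-vectors jointly, with the
   record-level residuals kept current while scanning bulls so the update is
   exact single-site Gibbs. Sampling the bull effects jointly is what makes
   $\sigma_{s,mgs}$ estimable.
3. **Structural coefficients** (recursive variants; $R_0$ diagonal). Per GL
   category, $\lambda_{CD\gets GL}$ is a normal regression draw on centred
   GL, and $(\lambda_{SB\gets GL}, \lambda_{SB\gets CD})$ a joint bivariate
   draw — GL and $l_{CD}$ are correlated predictors, and the joint update
   avoids the slow mixing a one-at-a-time scan would give. GL is an observed
   covariate; $l_{CD}$ enters at its current augmented value. An empty
   category falls back to a prior draw with a warning.
4. **Thresholds.** With the default three CD categories both CD thresholds
   are fixed (0 and 1) and this step is a no-op; with more categories each
   free threshold is uniform between the extreme liabilities of the adjacent
   categories.
5. **Dispersion.** Unstructured blocks from inverted-Wishart conditionals,
   diagonal variances from scaled inverse chi-squares, RMM3's per-trait
   (s, mgs) blocks from 2×2 inverted Wisharts. The SMM residual matrix, whose
   (SB, SB) entry is fixed at 1, is drawn from the exact conditional obtained
   by partitioning the inverted Wishart: the Schur complement of the fixed
   entry is itself inverted-Wishart with the same degrees of freedom, and the
   regression vector is conditionally normal (`riw_corner()`); the fixed
   corner therefore holds exactly at every iteration, as do all variant
   zero-masks.

### Priors and tuning constants

* Structural coefficients: $N(0, 10^4)$ — effectively flat but proper, so
  the conditional stays well-defined in sparse categories.
* Inverted Wishart: degrees of freedom = block dimension + 1, scale $0.1 I$.
* Scaled inverse chi-square: $\nu = 4$, $s^2 = 0.1$.
* Fixed effects and free thresholds: flat.

These are weakly informative defaults (`rmm_priors()` exposes all of them);
with hundreds of levels per random term the data dominate. The reference
sampling protocol is 5 chains × 10,000 iterations, 1,000 burn-in, thinning
10, i.e. 4,500 retained draws (`rmm_control()`), with convergence monitored
by split-$\hat R$ (flagged above 1.05), batch-means Monte Carlo errors and
effective sample sizes in `summary()`. Burn-in and chain length are fixed by
configuration rather than adaptive stopping.

Numerical edge cases: truncated-normal draws in saturated tails collapse to
just inside the interval rather than returning infinities; precision
matrices get a $10^{-8}$ ridge only if a Cholesky fails; an empty GL
category draws its rates from the prior and warns.

## The synthetic-data generator

No public data set with this structure exists, so `simulate_calving_data()`
generates one: records distributed over sires, MGS and herd-year groups
(defaults 60/120/40 at n = 5,000, a scaled-down version of a national
calving-ease programme's 90,000-cow structure), uniform level assignment,
and phenotypes generated under the recursive threshold model itself — GL
from its linear predictor plus residual, rounded to integer days; the
category from the realized GL; liabilities propagated through the
triangular system and thresholded. A configurable fraction (default 0.3) of
MGS identities also appear as sires, because the sire–MGS covariance is only
identifiable through bulls observed in both roles. GL is not truncated: the
outer categories absorb the tails. Latent liabilities and true effects are
returned in a separate truth table that the fitting functions never read.

Default true parameters are set to the magnitudes recursive sire–MGS
analyses of US Holstein calving data report: $\lambda_{CD\gets GL} =
(0.005, 0.021, 0.033, 0.041)$ liability units per day across the four
categories, $\lambda_{SB\gets CD} \approx 0.32$, overall GL$\to$SB effects
running from $-0.044$ to $+0.025$; a direct GL heritability near 0.39 with
maternal near 0.08; CD and SB heritabilities below 0.1; a GL residual
variance of about 16 d² (so the in-sample GL mean squared error lands near
19 d²); and intercepts putting roughly 70% of calvings in the easiest CD
category and under 10% stillbirths. Herd-year magnitudes are scale choices
— only their correlations are constrained by published analyses — and are
documented as such.

What the generator does **not** emulate: selection and culling, missing
records, multiple parities, pedigree relationships among bulls (bull effects
are iid across bulls; the numerator relationship matrix is a deliberate
non-goal), genotypes, and seasonality beyond the year–season factor. Tests
passing on these data therefore validate the algebra and the sampler, not
robustness to real-data pathologies.

## Model comparison

Goodness of fit follows the plug-in protocol: at the posterior means of all
unknowns, GL is fitted by its expectation (no residual) and CD/SB by the
expected category score $\sum_c c\,P(c)$ with
$P(c) = \Phi(\tau_c - \hat l) - \Phi(\tau_{c-1} - \hat l)$, where $\hat l$
is the plug-in structural expectation of the liability given observed GL
(for SB, chaining through the expected CD liability). $\Phi$ is used as the
standard normal CDF even though the CD residual variance is a free
parameter — that is the published prediction equation, kept as-is.
Predictive ability uses 3-fold cross-validation with random record-level
folds of near-equal size; test records are predicted from the training
posterior means, with unseen herd/sire/MGS levels contributing zero, and the
metrics (per-trait MSE and Pearson correlation between observed scores and
fitted/predicted values) are computed once on the concatenated test sets.
Herd effects are included in the expected GL — they are part of the linear
predictor — and shared between training and test because the partition is at
the record level. DIC and Bayes factors are intentionally out of scope.

`concordance()` correlates plug-in fitted values between two variants fitted
to the same records. The GL equation is identical in all four variants, so
its concordance is expected to exceed 0.999 — a useful end-to-end
consistency check that the tests exercise.

## Problem sizes used in the test suite

The packaged checks run at sizes chosen to make their statistical
tolerances meaningful: the structural-coefficient recovery study at
n = 5,000 records with one 3,000-iteration chain (12 true rates against
their 95% HPD intervals); the reduced-form Monte-Carlo identity at
n = 20,000 with a 3-standard-error band; oracle-equivalence comparisons
(joint sampler vs independent single-trait samplers, and vs REML-style
fits) at n = 700–800 with a 3-MCSE band; and the four-variant concordance
at n = 6,000 with 1,000 retained draws per fit. The concordance size matters:
fitted GL differs across variants only through finite-sample borrowing via
the unstructured covariance blocks, a discrepancy that shrinks as $O(1/n)$
(measured concordances: ~0.998 at n = 1,500–4,000, 0.9995 at n = 6,000,
0.9997 at n = 9,000), so the invariance check is run at a size where the
asymptotic identity of the GL equation — and not residual shrinkage noise —
is what is being tested. The innermost GL category sits in the tail of the
default GL distribution (about 1–2% of records), so its rates are recovered
with wide intervals — as they should be.

## Known limitations

* Bulls are unrelated in both the generator and the sampler; a numerator
  relationship matrix would drop in at the per-bull update but is not
  implemented.
* Records with missing phenotypes are rejected at load rather than
  marginalized.
* The single-site liability scan mixes slowly when recursion and residual
  correlations are both strong; the reference protocol's thinning masks
  this, and split-$\hat R$/ESS will flag it when it matters.
* The number of CD categories defaults to 3 (both thresholds then fixed by
  identification); more categories are supported and add free thresholds,
  whose uniform conditionals mix slowly on large data — a known property of
  this augmentation scheme, acceptable at the scales used here.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_calving_data(sim_design(2000), seed = 1)
fit <- rmm(sim$records, "RMM3",
           control = rmm_control(n_chains = 2, n_iter = 2000,
                                 burn_in = 500, thin = 5, seed = 1))
print(fit)
summary(fit, pars = c("lambda_sb_cd[2]", "R0[1,1]"))
gs <- genetic_summary(fit)
subset(gs$summary, parameter == "h2_direct_GL")
goodness_of_fit(fit)
```
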