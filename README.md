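# recalv — recursive threshold mixed models for calving traits

`recalv` is an R package for Bayesian joint analysis of three correlated
calving traits in dairy cattle: **gestation length** (GL, days), **calving
difficulty** (CD, ordinal score) and **stillbirth** (SB, binary). CD and SB
are modelled on a latent liability scale with probit (threshold) links. The
package is aimed at animal breeders and quantitative geneticists who want to
ask *why* these traits are correlated: because genes, herds and environments
jointly affect them, or because the phenotypes themselves cause one another
(a long gestation makes a difficult calving more likely, and a difficult
calving makes a stillbirth more likely).

## The model family

For calf *i* with GL in category *k* (cutpoints 267/273/279 days by
default), the structural system is

```
Λ_k y_i = X_i b + Z_h h + Z_s s + Z_mgs mgs + ε_i,      ε_i ~ N(0, R0)

        ⎛        1              0            0 ⎞
Λ_k  =  ⎜ −λ_CD←GL(k)           1            0 ⎟
        ⎝ −λ_SB←GL(k)    −λ_SB←CD(k)         1 ⎠
```

with `y_i = (GL_i, l_CD,i, l_SB,i)'`, herd-year effects `h ~ N(0, H0)`,
joint per-bull sire/maternal-grandsire effects `(s, mgs) ~ N(0, G0)` (6×6),
and identification constraints: CD thresholds 0 and 1, SB threshold 0, SB
residual variance 1. The rates λ change across GL categories, capturing the
non-linearity of the GL effect. Four nested variants are supported:

* **SMM** — no recursion (`Λ = I`), unstructured G0, H0, R0 (32 free
  dispersion parameters);
* **RMM1** — recursion + diagonal R0 (41 free parameters);
* **RMM2** — RMM1 + diagonal H0 (38);
* **RMM3** — RMM2 + per-trait sire/MGS genetic blocks (26), i.e. *all*
  cross-trait correlation attributed to the phenotypic recursion.

Inference is by Gibbs sampling with liability augmentation (all full
conditionals are closed-form, including the conditional inverted Wishart for
the residual matrix with its fixed corner). Reduced-form covariances
(`Λ_k⁻¹ Σ Λ_k⁻ᵀ`), Willham direct/maternal genetic parameters, heritabilities
and correlations are computed per posterior draw; model comparison uses
plug-in goodness of fit and 3-fold cross-validated predictive ability
(per-trait MSE and Pearson correlation). Because no public data set with
this structure exists, the package ships a synthetic-data generator
emulating national calving-ease programme records.

## A worked example

```r
library(recalv)

sim <- simulate_calving_data(sim_design(2000), seed = 1)
fit <- rmm(sim$records, "RMM3",
           control = rmm_control(n_chains = 2, n_iter = 2000,
                                 burn_in = 500, thin = 5, seed = 1))
print(fit)
```

```
Recursive threshold mixed model (RMM3)
  2000 records, 144 sires/MGS bulls, 40 herd-years, 4 GL categories
  2 chains x 2000 iterations (burn-in 500, thin 5): 600 retained draws
  free dispersion + structural parameters: 26
  posterior mean structural coefficients:
           k1      k2      k3     k4
cd_gl -0.0619  0.0444  0.0418 0.0449
sb_gl -0.0347 -0.0152 -0.0680 0.0074
sb_cd  0.6565  0.3127  0.2875 0.5171
```

The coefficient matrix shows the posterior-mean rates per GL category: e.g.
`cd_gl` k4 = 0.045 means each extra day of gestation beyond 279 d raises the
CD liability by 0.045 liability units (the generator's true value is 0.041;
the innermost category k1 holds ~1% of records, so its rates are poorly
determined at n = 2000). `summary(fit)` adds posterior SDs, 95%/90% HPD
intervals, Monte-Carlo errors, effective sample sizes and split-R̂ per
parameter:

```r
summary(fit, pars = c("lambda_sb_cd[3]", "R0[1,1]"))
```

```
Posterior summaries (RMM3, 2 parameters)
       parameter    mean     sd hpd95_lo hpd95_hi hpd90_lo hpd90_hi   mcse      ess   rhat
 lambda_sb_cd[3]  0.2875 0.0745   0.1366   0.4310   0.1431   0.3919 0.0047 255.0572 1.0157
         R0[1,1] 16.1264 0.5266  15.1830  17.2064  15.2118  16.8965 0.0270 379.2452 1.0053
```

(`R0[1,1]` is the GL residual variance in days²; the generator's truth is
16, and the true `lambda_sb_cd[3]` is 0.319.) Derived genetic parameters,
transformed per draw:

```r
gs <- genetic_summary(fit)
subset(gs$summary, parameter == "h2_direct_GL" & category == 2)
```

```
   category    parameter     mean         sd  hpd95_lo  hpd95_hi ...
23        2 h2_direct_GL 0.304105 0.07142714 0.1819073 0.4533121
```

a direct heritability of GL around 0.30 (truth 0.39, within the interval).
Goodness of fit on the score scale:

```r
goodness_of_fit(fit)
```

```
  trait         mse pearson_r
1    GL 14.96047989 0.5629027
2    CD  0.36692024 0.4049351
3    SB  0.07121445 0.3584891
```

`cross_validate()` produces the same table for held-out records;
`concordance(fit_a, fit_b)` correlates fitted values between variants
(the GL equation is shared, so its concordance is ≈ 1).

A thin command-line wrapper covering the simulate → fit → summarize →
compare → cross-validate workflow ships in
`inst/scripts/recalv-cli.R` (e.g.
`Rscript inst/scripts/recalv-cli.R count-params --variant RMM1` prints 41).

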