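---
title: "Modeling how sexual dimorphism in gene expression evolves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling how sexual dimorphism in gene expression evolves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphr)
```

## The model

Sexual dimorphism in gene expression — the difference between male and
female mean log2 expression of a gene or expression trait — is usually
interpreted as the footprint of sexually antagonistic selection (SAS),
selection favoring opposite changes in the two sexes. But dimorphism also
evolves under sexually concordant selection (SCS) whenever the sexes
differ in their genetic variances or covariances. `dimorphr` implements
the quantitative-genetic machinery needed to treat both routes
symmetrically.

The central object is the sex-specific genetic covariance matrix over
trait copies expressed in males and in females,

$$\mathbf G = \begin{pmatrix}\mathbf G_M & \mathbf B\\
\mathbf B^\top & \mathbf G_F\end{pmatrix},$$

where $\mathbf G_M$ and $\mathbf G_F$ are the within-sex blocks and
$\mathbf B$ holds the cross-sex covariances; its diagonal, scaled by the
sex-specific variances, gives the intersexual correlations
$r_{MF} = b/\sqrt{mf}$. We fix the orientation of $\mathbf B$ by its
placement: rows are male variables, columns female variables. Traits may
be expressed in one sex only (sex-limited traits); traits present in
both sexes are *shared*, and dimorphism is defined over them.

Responses to a sex-specific selection gradient
$\beta = (\beta_M, \beta_F)$ follow the two-sex breeder's equation

$$\begin{pmatrix}\Delta\bar z_M\\ \Delta\bar z_F\end{pmatrix}
 = \tfrac12\,\mathbf G\,\begin{pmatrix}\beta_M\\ \beta_F\end{pmatrix},$$

the 1/2 reflecting that each sex contributes half the autosomal genes of
the next generation. `predict_response()` reports, per gradient, the
per-variable responses, the dimorphism-change vector
$\Delta = \Delta\bar z_M - \Delta\bar z_F$ over shared traits and its
norm $\lVert\Delta\rVert$, the evolvability
$e = \beta^\top\mathbf G\beta/\beta^\top\beta$ and respondability
$R = \lVert\mathbf G\beta\rVert/\lVert\beta\rVert$. Following the
evolvability-statistics convention, $e$ and $R$ do *not* carry the 1/2;
every ratio the pipeline reports is invariant to that choice, and we do
not attempt absolute reproduction of published response magnitudes,
whose scale convention is not stated.

### What controls the dimorphism response

Writing $\bar{\mathbf G} = (\mathbf G_M + \mathbf G_F)/2$ and splitting
$\mathbf B$ into its symmetric and antisymmetric parts
$\mathbf B_S = (\mathbf B + \mathbf B^\top)/2$,
$\mathbf B_A = (\mathbf B - \mathbf B^\top)/2$, the closed forms
implemented in `dimorphism_change_closed_form()` are

* antagonistic ($\beta_F = -\beta_M$):
  $\Delta = (\bar{\mathbf G} - \mathbf B_S)\,\beta_M$;
* concordant ($\beta_F = \beta_M$):
  $\Delta = \big((\mathbf G_M - \mathbf G_F)/2 + \mathbf B_A\big)\beta_M$.

So the antagonistic response depends only on the *symmetric* components,
and the concordant response only on the *asymmetries*. Two structural
theorems follow, and hold exactly for any valid matrix: substituting
$\bar{\mathbf G}$ for both within-sex blocks leaves every antagonistic
dimorphism response unchanged (ratio 1), and the joint
$\bar{\mathbf G} + \mathbf B_S$ substitution eliminates the concordant
dimorphism response entirely (ratio 0). `apply_modification()` and
`modification_ratio_table()` implement these substitution experiments
(`avg_G`, `sym_B`, `zero_B` and their combinations). Substituted
matrices are artificial constructs and need not remain positive
semi-definite; validation therefore downgrades PSD violations to
warnings for every modified matrix — the predictions from them are the
point of the exercise.

In the single-trait case the same decomposition gives
$\Delta_A = \beta\bar g(1 - d\,r_{MF})$ and
$\Delta_C = \beta(m - f)/2$, with
$d = \sqrt{mf}/\bar g$ the ratio of geometric to arithmetic mean
variance (`d_statistic()`). Concordant selection changes dimorphism
faster than antagonistic selection of equal strength when
$d < 2r_{MF}/(r_{MF}^2 + 1)$ (`concordant_dominance_condition()`;
`d_to_variance_ratio()` converts a $d$ threshold into the implied
variance ratio by solving $2\sqrt\rho/(1+\rho) = d$). We implement the
stated condition as printed; the worked variance-ratio figures quoted
alongside it in the source literature do not solve it exactly, and we do
not force agreement. Two-trait special cases with unit variances
(`two_trait_indirect()`, `two_trait_both_selected()`) expose the role of
the average within-sex ($\bar r_w$) and between-sex ($\bar r_b$)
cross-trait correlations, and of their asymmetries; each closed form is
tested for exact agreement with the general engine on the implied 4x4
matrix. One wrinkle: under concordant selection on both traits the
B-asymmetry term enters the two traits with *opposite* signs — direct
evaluation of the breeder's equation fixes the signs, and the
engine-equivalence tests pin them.

`conditional_response()` treats the complementary regime in which all
trait combinations orthogonal to the gradient are held fixed by strong
stabilizing selection: the response collapses onto the gradient
direction with magnitude the conditional evolvability
$c(\beta) = (\hat\beta^\top\mathbf G^{-1}\hat\beta)^{-1} \le e(\beta)$.
Rank-deficient matrices are regularized by flooring eigenvalues at
$10^{-8}\lambda_{\max}$ before inversion, recorded in the output.

## The gene-wise pipeline

The empirical side consumes a log2 expression panel from inbred lines:
every sample annotated with line, sex and replicate (and optionally
probe), the design the synthetic generator emulates (about 40 lines, 2
sexes, 2 replicates).

**Screening.** `screen_genes()` tests each gene for genetic variance by
comparing the restricted likelihood of a mixed model (fixed sex — plus
probe and probe-by-sex for multi-probe genes — random line, line-by-sex,
and line-by-probe) against the fixed-effects-only model, referring the
statistic to $\chi^2_2$ (single probe) or $\chi^2_3$ (multi-probe), and
retains genes at $p < 0.01$. For the balanced single-probe design the
REML problem is solved in closed form: the data split into orthogonal
within-cell, line-difference and line-mean strata whose variance scales
are ordered, so the constrained REML fit is a three-point weighted
isotonic regression; this path is vectorized over thousands of genes.
Because the null pins variance components to the boundary, the plain LRT
is conservative — realized type-I retention sits below the nominal 1%,
which the calibration tests assert one-sidedly. `lme4::lmer()` is the
independent oracle for this path in the tests (variance components match
to at least four decimals) and the fallback implementation for
unbalanced or multi-probe genes.

**Per-gene summaries.** From least-squares line means (`line_means()`;
arithmetic cell means in the balanced case, equally weighted
probe-adjusted means otherwise), `gene_summaries()` assembles: the
dimorphism $D$ (mean male minus female line mean, a log2 ratio) and
bias class (MB: $D > 1$; FB: $D < -1$; UB: $|D| \le 1$, a closed
boundary); the between-line variances $m, f$, covariance $b$ and
$r_{MF}$ — entries of the exploratory matrix G\*, reported on the
inbred-line scale without an outbred correction, since the object of
interest is the sample covariance of line means; the aggregate
cross-gene statistics $\bar r_{w,i}$, $\bar r_{b,i}$,
$|\bar r_{\delta w,i}|$, $|\bar r_{\delta b,i}|$ (sums of line-mean
correlations over gene pairs with the $2(n-1)$ denominator), computed by
standardized matrix products in $O(\text{genes}^2)$ and verified against
the brute-force double loop; the mean expression $\bar E$; and the
tissue-specificity index
$\tau = \sum_t (1 - x_t/\max_t x_t)/(N_t - 1) \in [0, 1]$ from any
user-supplied tissue table (nonnegative intensities required; a negative
log-scale table is shifted by its minimum, with a message; transcripts
are averaged per gene after computing $\tau$).

**Regression.** `fit_dimorphism_regression()` regresses
$\log_{10}(|D| + 0.01)$ — the offset keeps near-zero dimorphism from
creating a left tail — on the G\*-derived predictors, with
$\bar g$ and $|m - f|$ entered as $\log_{10}$ and $|\bar r_{\delta b}|$
as $\log_{10}(\cdot + 0.01)$, all to tame right skew. Per-predictor
variance explained is the squared semipartial correlation (the increment
in model $R^2$ when the predictor enters last), in percent; this
decomposition is our choice — the convention behind published per-term
$R^2$ values is not stated, so we document rather than match it.
`bootstrap_dimorphism_regression()` resamples *inbred lines* with
replacement (the unit of independent sampling), recomputes every
line-mean-derived quantity per replicate, refits, and reports
type-7-quantile 95% intervals; an effect is "significant" when both
quantiles share a sign. The screen runs once on the original panel:
retention is treated as part of the data definition, not re-randomized.
Gene-level covariates that do not depend on lines ($\tau$, set-membership
indicators added by `add_indicator_covariates()`) stay fixed across
replicates.

## Trait construction and G estimation

With only tens of lines, a gene-level G matrix is hopeless; instead we
estimate G for a few linear combinations. `class_pca()` performs
covariance-matrix PCA (centered, never variance-standardized) of line
means within each bias class: for unbiased genes the observations are
the pooled line-sex mean vectors (2 per line) so that one shared loading
set scores both sexes — a UB trait's dimorphism is then literally
loadings$^\top$(male $-$ female gene means) — while biased classes use
the dominant sex only (a switch to sex-averaged observations exists for
the UB PCA). Components are oriented so the largest-magnitude loading is
positive, a convention fixed here because none is inherited. The default
trait set is 2 MB (male-only) + 2 FB (female-only) + 4 UB in both sexes
= 12 sexed variables; subordinate-sex scores of biased classes are not
constructed, mirroring the absence of detectable genetic variance there.

`estimate_g()` uses the balanced-design MANOVA moment identity
$\widehat{\mathbf G} = \mathrm{cov}(\text{line means}) - \mathbf E/R$
(with $\mathbf E$ the pooled within-line covariance of replicate-level
trait scores), in place of a factor-analytic REML program: same
estimand, closed form, no external binary. Each candidate rank $r$ is
then fitted by maximum likelihood in the error-whitened space — with
whitened sample eigenvalues $\ell_i$, the rank-$r$ model
$\mathbf I + \mathbf G_r$ has the closed-form fit
$d_i = \max(\ell_i, 1)$ for the top $r$ components and 1 elsewhere —
and ranks are compared by AICc with parameter count $pr - r(r-1)/2$ and
sample size the number of lines. Minimal AICc alone tends to absorb one
spurious eigenvalue: under a true rank, the largest residual whitened
eigenvalue sits near the upper bulk edge of a Fisher (Wachter) spectrum,
not at 1, because both scatter matrices are estimated. We therefore
select the *smallest* rank whose AICc lies within the spurious
log-likelihood gain implied by that edge,
$n\,(b - 1 - \log b)$ with
$b = (1 + \sqrt{y_1 + y_2 - y_1 y_2})^2/(1 - y_2)^2$,
$y_1 = (p - r)/(L - 1)$, $y_2 = p/(L(R-1))$. In the synthetic
validation (8 traits, true rank 3, 200 lines, 2 replicates) this selects
rank 3 in 40/40 runs, against roughly 2/3 for minimal AICc.

`sample_g_replicates()` propagates estimation uncertainty by parametric
resampling: central Wishart draws of the between-line scatter (at the
fitted line-mean covariance, $L - 1$ df) and the within-line scatter
($L(R-1)$ df), re-estimating G from each draw at the selected rank. This
is a stand-in for resampling the asymptotic distribution of REML
estimates (the published workflow), whose information matrix is not
available; it preserves what downstream code needs — a set of replicate
matrices summarized by medians and 2.5%/97.5% type-7 quantiles
(`summarize_over_replicates()`). The modification-ratio statistics that
are analytically 1 or 0 come out exactly 1 or 0 on every replicate, a
useful internal consistency check.

## The synthetic generator

`simulate_expression_panel()` generates
$y_{glsr} = \mu_g \pm D_g/2 + a_{gls} + e_{glsr}$: Gaussian line
genetic values combining shared line-level factors (sex-specific gene
loadings, cross-sex factor correlations) with per-gene idiosyncratic
effects carrying planted $(m, f, b)$, plus i.i.d. Gaussian replicate
noise — the same distributional assumptions the mixed models make.
Defaults emulate the study design: 40 lines, 2 replicates, and
(scaled-down) gene counts of 150 male-biased, 200 female-biased and 700
unbiased genes, chosen to keep full-pipeline runs in minutes on one CPU;
the per-class dimorphism means (about $\pm 1.6$ for biased classes, 0
for unbiased) and variance scales (between-line variances lognormal
around 0.15 log2², residual 0.05) are in the range typical of
inbred-panel expression arrays. `implied_trait_g()` returns the
*analytic* trait-level sexed G for any loading-defined trait set, the
ground truth for recovery tests.

Named scenarios (`scenario_config()`):

* `table2_like` — eight latent factors defining 2 male-only, 2
  female-only and 4 shared traits. Within each shared block the female
  gene-level structure is proportional to the male structure, so the
  implied trait-level $r_{MF}$ are exactly the four cross-sex factor
  correlations (0.90, 0.86, 0.80, 0.72 — mean 0.82, matching the
  average reported for the reanalyzed expression panel); the loading
  scale ratios make the sex variances unequal, and a small asymmetric
  cross-block factor coupling makes B asymmetric without touching the
  diagonal correlations.
* `null` — no genetic variance; calibrates the screen's type-I rate.
* `sas_architecture` — dimorphism magnitude decreasing in $r_{MF}$, the
  signature the antagonistic route leaves in G\*.
* `scs_architecture` — dimorphism magnitude increasing in $|m - f|$,
  the concordant signature.

The end-to-end tests assert directional recovery: a negative median
$r_{MF}$ slope on `sas_architecture` and a positive median
$\log_{10}|m - f|$ slope on `scs_architecture` in the bootstrapped
regression.

What the generator does *not* emulate: probe-level microarray artifacts
and normalization effects, heavy-tailed or discrete expression noise,
relatedness among lines (assumed unrelated, as in the reanalyzed panel),
and linkage-driven gene-gene dependence beyond the factor structure.
Passing tests therefore certify the estimators and the algebra under the
stated model, not robustness to those features of real data.

## Numerical choices and degenerate inputs

* Symmetry tolerance $10^{-10}$ (relative); PSD tolerance: smallest
  eigenvalue $\ge -10^{-8}\lambda_{\max}$. An optional `bend_sexed_g()`
  clips negative eigenvalues and rescales the trace; it is never applied
  implicitly.
* Gradient normalization `unit_total` scales the full sexed vector to
  unit norm, so a one-trait antagonistic gradient is $\pm 1/\sqrt 2$.
* All quantiles are type 7 (linear interpolation).
* Genes with an undefined $r_{MF}$ ($mf = 0$) are dropped from the
  regression by complete-case filtering; zero-variance genes are
  excluded from the aggregate correlation sums with $n$ adjusted;
  predictors constant within a bootstrap replicate are recorded as
  missing for that replicate.
* A panel without replication degrades `estimate_g()` to the raw
  line-mean covariance with a warning, and uncertainty sampling refuses
  to run; the Wishart sampler also requires more lines than traits.
* Scale choices in tests and the pipeline default (`gene_scale`,
  bootstrap and replicate counts) are set so the whole suite runs in a
  few minutes; the statistical assertions are sized to those runs
  (Monte-Carlo allowances stated in the tests).

## Known limitations

The screen's $\chi^2$ reference is conservative at the boundary (no
half-mixture correction is applied — deliberately, to match the stated
procedure). The AICc parameter-count convention for reduced-rank models
is ours and is validated on synthetic truth only; a different convention
could select different ranks on real data. The Wishart resampler
understates uncertainty relative to full REML sampling when the error
covariance is itself poorly estimated. Absolute evolvability scales are
reported in variance units of the input traits and are not comparable
across differently scaled trait sets.
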