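---
title: "Power analysis for bulk and single-cell eQTL study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for bulk and single-cell eQTL study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqtlpwr)
```

## The design problem

An eQTL study asks whether the expression of a gene depends on the genotype
at a nearby variant. Effect sizes are small, and a scan tests up to millions
of SNP-gene pairs, so each single test runs at a Bonferroni-adjusted level
`fwer / n_tests` — often in the 1e-7 range. Before collecting tissue or
cells, an investigator needs to know how many subjects (and, for single-cell
assays, how many cells per subject) give adequate power to detect a variant
of a given minor allele frequency (MAF) and effect size. `eqtlpwr` answers
that question with closed-form calculators for three models, a
simulation-based engine for raw single-cell counts, and solvers that invert
any calculator for sample size, effect size or minimum allowable MAF.

Throughout, the genotype at a biallelic variant with MAF $p \in (0, 0.5]$
is drawn from Hardy–Weinberg proportions $((1-p)^2,\, 2p(1-p),\, p^2)$ and
coded additively as $x \in \{0, 1, 2\}$ copies of the minor allele, so
$\operatorname{Var}(x) = 2p(1-p)$. MAFs above 0.5 are rejected rather than
silently folded; by definition the minor allele is the rarer one, and a
value like 0.7 usually signals a data-handling error upstream.

## Bulk tissue: regression and ANOVA

With one expression value per subject, the regression engine
(`power_eqtl_slr`) tests the slope $\beta_1$ of
$y_i = \beta_0 + \beta_1 x_i + \varepsilon_i$. The user supplies the
*marginal* outcome SD $\sigma_y$, so the residual SD is
$\sigma_e = \sqrt{\sigma_y^2 - \beta_1^2 \cdot 2p(1-p)}$ (an effect with
$\beta_1^2 \cdot 2p(1-p) \ge \sigma_y^2$ is rejected as infeasible). The
two-sided test at level $\alpha^\ast = \mathrm{fwer}/n_\mathrm{tests}$ has
power

$$P\left(|T'_{n-2,\,\lambda}| > t_{1-\alpha^\ast/2,\,n-2}\right),
\qquad
\lambda = \frac{\beta_1 \sqrt{2p(1-p)}\sqrt{n}}{\sigma_e}.$$

The ANOVA engine (`power_eqtl_anova`) instead treats the three genotypes as
categories — the model the GTEx consortium used — and computes the
noncentral-F power of the overall test with expected Hardy–Weinberg group
weights in the noncentrality and df $(2,\, n-3)$. Group means are anchored
at the major-allele homozygote and parameterized by the two successive
differences `delta`. When the truth is additive the regression test
dominates the ANOVA test (categorizing a continuous code discards
information); the test suite checks this across a 30-point grid.

Two approximations are worth knowing about:

* **Expected vs realized genotype counts.** The closed forms plug the
  *expected* genotype variance (or group weights) into the noncentrality.
  In a real study the realized counts are random; averaging power over that
  randomness shifts it, typically by well under 0.01 when the expected
  minor-homozygote count is above ~10, but by a few percent for small
  $n \times \mathrm{MAF}$ near the steep part of the power curve. The
  Monte-Carlo validation grid shipped with the package
  (`inst/extdata/oracle_grid.csv`) deliberately sits where this
  approximation is accurate; at very small $n\,p^2$ treat the closed form
  as an optimistic approximation and simulate instead.
* **Genotype-group occupancy.** The ANOVA oracle redraws the rare
  replicates in which a genotype group has fewer than two members; the
  closed form does not model that conditioning.

## Single-cell expression: random-intercept LMM

Single-cell assays profile $m$ cells in each of $n$ subjects. Cells from
one subject are correlated — `power_eqtl_sclmm` models (suitably
transformed, approximately Gaussian) expression as
$y_{ij} = \beta_{0i} + \beta_1 x_i + \varepsilon_{ij}$ with a Gaussian
random intercept, parameterized by the marginal SD $\sigma_y$ and the
intra-subject correlation $\rho = \operatorname{Corr}(y_{ij}, y_{ik})$. The
$m$ cells then carry the information of $m / (1 + (m-1)\rho)$ independent
ones (the design effect), giving

$$\lambda = \frac{\beta_1 \sqrt{2p(1-p)}\sqrt{nm}}
{\sigma_e \sqrt{1 + (m-1)\rho}}$$

referred to a noncentral t with $nm - 2$ df. Two sanity limits are exact on
the noncentrality and hold to $10^{-3}$ on power across the df convention:
$m = 1$ or $\rho = 0$ reduces to the bulk engine with $nm$ subjects, and
$\rho \to 1$ collapses to the bulk engine with $n$ subjects — beyond a
point, sequencing more cells cannot substitute for recruiting more
subjects. `effective_sample_size()` reports the design-effect-adjusted
count directly.

Choices behind the formula, made where more than one convention exists:

* **df convention.** We use $nm - 2$. A subject-level convention ($n - 2$)
  differs by less than $10^{-3}$ in power whenever $nm$ is in the hundreds,
  which is every practical single-cell design; the Monte-Carlo oracle
  cannot tell the two apart at realistic replicate counts.
* **Variance decomposition.** $\sigma_e^2 = \sigma_y^2 - \beta_1^2
  \cdot 2p(1-p)$ is the conditional (residual) variance, and $\rho$ is
  applied to it as the conditional intraclass correlation. The marginal
  variance of $y$ is then exactly $\sigma_y^2$ and the marginal cell-cell
  correlation differs from $\rho$ only by $O(\beta_1^2 \, 2p(1-p) /
  \sigma_y^2)$, negligible at eQTL effect sizes. Putting the marginal
  $\sigma_y$ in the noncentrality denominator instead fails the oracle
  checks whenever the slope is comparable to $\sigma_y$.
* **Equal cells per subject.** Real datasets have variable $m_i$, but the
  realized counts are unknowable at design time; the engine takes one
  planning value of $m$.

## Raw counts: the ZINB simulation engine

Transformed-Gaussian models ignore two signatures of droplet scRNA-seq
counts: overdispersion and excess zeros. `power_zinb_sim` therefore
estimates power by brute force under a generative model for the counts
themselves: cell $j$ of subject $i$ is a structural zero with probability
$\pi$ and otherwise negative binomial with mean
$\mu_{ij} = \exp(\gamma_{0i} + \beta_1 x_i)$ and dispersion $\theta$
(variance $\mu + \mu^2/\theta$), where $\gamma_{0i} \sim
N(\gamma_0, \sigma_b^2)$ carries the subject-level heterogeneity. Zero
inflation and dispersion are genotype-independent scalars; only the NB mean
carries the effect.

Each replicate is fitted by marginal maximum likelihood
(`fit_zinb_mixed`): the random intercept is integrated out by adaptive
Gauss–Hermite quadrature (default 15 nodes, centered and scaled at the
per-subject posterior mode — the standard accuracy/cost point for
random-intercept models), with $\sigma_b$, $\pi$ and $\theta$ estimated on
log, logit and log scales. The likelihood kernel is compiled code; because
all cells of a subject share one mean, the per-subject conditional
log-likelihood collapses to sufficient statistics and a fit costs tens of
milliseconds, so thousand-replicate power runs complete in well under a
minute on one core.

Decisions a user may want to revisit:

* **Test statistic.** One Wald test per replicate (a likelihood-ratio test
  would double the fitting cost). The Wald statistic is referred to a t
  distribution with $n - 2$ df, not the normal: the genotype varies only
  between subjects, so its information is subject-limited, and with tens of
  subjects the normal reference measurably inflates the null rejection
  rate (we observed 0.07 at $n = 30$ against a nominal 0.05, while the t
  reference is within Monte-Carlo error of nominal).
* **Non-convergence.** Replicates whose fit fails are excluded from the
  power denominator and reported (`n_failed`); `conservative = TRUE`
  counts them as non-rejections instead, a strict lower bound. At the
  defaults non-convergence is rare (none in 1000 replicates at
  $n = 30,\ m = 20$).
* **Boundary fits.** When $\hat\sigma_b \to 0$ the information matrix for
  the full model degenerates; such fits are flagged and their Wald
  covariance is taken from the model profiled at $\sigma_b = 0$.
* **Reproducibility.** Replicate $r$ draws its seed deterministically from
  the master seed, so reports are bit-identical across runs and across
  `workers` settings; parallelism changes scheduling, never streams.

## Inverting a design

`solve_eqtl()` solves for whichever of power, $n$, effect size or MAF is
passed as `NULL`, by bracketed root-finding on the monotone power function
(tolerance far below the $10^{-6}$ the round-trip tests assert). Sample
sizes are rounded up to the smallest integer meeting the target and
returned with the power actually achieved; the ANOVA effect is inverted as
a positive scale on a user-supplied direction `delta_direction`, since one
power value cannot determine two mean differences. Unattainable targets
(e.g. a MAF solve whose ceiling at 0.5 is below the target) produce an
error stating the attainable range rather than a boundary value. For the
simulation engine no root-finder is exposed — the objective is stochastic —
but a practical recipe is a coarse grid over $n$ with `power_zinb_sim` at
moderate `n_sim`, refined once around the crossing.

## Validation strategy

Every analytic engine is checked against an independent Monte-Carlo oracle
that shares no code with the closed forms: raw-data simulation plus
ordinary least squares for the regression engine, multinomial group sizes
plus exact sufficient statistics for the ANOVA engine, and exact
generalized least squares with known covariance for the mixed model (the
oracle must not add estimation noise of its own). The committed grid of 18
parameter sets (6 per engine, spanning MAF 0.05–0.5 and $\rho$ 0–0.8) is
rerun at $10^5$ replicates (regression/ANOVA) or $10^4$ (LMM) by
`validate_engines()` and the `validate` CLI subcommand; agreement within 3
binomial SEs is required. The ZINB engine, being itself simulation-based,
is instead validated by null calibration, parameter recovery on
self-generated data, agreement of its fitter with a plain NB regression in
the degenerate no-mixture case, and an independent mixed-model
implementation on one dataset.

The simulation-depth defaults used by the test suite (e.g. 1000 null
replicates at $n = 30,\ m = 20$; 200 recovery replicates at
$n = 100,\ m = 50$) were chosen so the full suite validates every engine in
a few minutes on one core; all depths scale up by argument when sharper
estimates are wanted.

What these checks do *not* establish: the generative models are idealized.
Real data have covariates (sex, age, batch, disease state), LD structure
between tests, dosage uncertainty, variable cells per subject, and
cell-type mixtures — none are modeled here, and Bonferroni across
correlated tests is conservative. Power estimates are planning
instruments, best fed with MAF, effect-size and variance values
extrapolated from pilot data of the actual assay.

## Defaults

`fwer = 0.05` and `n_tests = 1e6` reflect a genome-wide cis-scan scale;
the CLI's `sigma_y = sigma = 0.13` echoes the variability scale of a
GTEx-like bulk cohort. They are starting points, printed with every CLI
result, not recommendations: supply study-specific values whenever any
pilot data exist.
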