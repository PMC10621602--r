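---
title: "AUC inference with three-level hierarchical data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AUC inference with three-level hierarchical data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierAUC)
```

## The problem

The area under the ROC curve (AUC) is the probability that a randomly chosen
event observation carries a higher prediction score than a randomly chosen
nonevent observation. Standard AUC inference (Hanley–McNeil, DeLong) assumes
independent observations. In ophthalmology, dentistry, audiology and family
studies the data are often *three-level*: subunits (eyes, teeth, frequencies)
nested in persons nested in families, with exchangeable correlation at each
level. Ignoring that dependence leaves the point estimate intact but makes
confidence intervals too narrow.

`hierAUC` provides dependency-adjusted inference for the AUC in this setting:
the extended Mann–Whitney estimator, a closed-form variance built from
bivariate-normal concordance probabilities, probit-scale delta-method
confidence intervals, pooled random tie-breaking, and a Monte Carlo harness
for validating calibration.

## Estimator and working model

Let $S_{ijk}$ be the prediction score and $\delta_{ijk}$ the event indicator
of subunit $k$ of person $j$ in family $i$. With $F$ event and $G$ nonevent
subunits, every (nonevent, event) pair is a *discordant pair*, and

$$\hat\theta_3 = \frac{A + B + C}{F\,G},$$

where $A$, $B$, $C$ count concordant pairs (nonevent scored below event)
among pairs drawn within a person, between persons of one family, and
between families. `auc_decomposition()` computes the counts with per-family
rank sums; the result equals the literal double sum over all pairs, which
the test suite verifies by exhaustive enumeration on small random datasets.

Scores are first mapped to normal scores
$Z_{ijk} = \Phi^{-1}[\hat F(S_{ijk})]$ using the *pooled* empirical
distribution function over all records with the $\mathrm{rank}/(N+1)$
convention. Pooling (rather than transforming events and nonevents
separately) is required because the concordance indicator compares scores
across the two outcome groups, and the location-shift working model below is
stated on the common transformed scale; $\mathrm{rank}/(N+1)$ rather than
$\mathrm{rank}/N$ keeps the largest transformed value finite. The
transformation is strictly rank-preserving, so the point estimate is
unchanged by it.

The working model assumes transformed nonevent scores are $N(0,1)$ and event
scores $N(\mu,1)$, with exchangeable correlations $\rho_s$ (two subunits of
one person) and $\rho_f$ (subunits of two persons in one family). The
implied component AUCs are

$$\theta_s = \Phi\!\Big(\tfrac{\mu}{\sqrt{2(1-\rho_s)}}\Big),\quad
  \theta_f = \Phi\!\Big(\tfrac{\mu}{\sqrt{2(1-\rho_f)}}\Big),\quad
  \theta   = \Phi\!\Big(\tfrac{\mu}{\sqrt{2}}\Big),$$

and the expectation of $\hat\theta_3$ is the pair-count-weighted average of
the three (`expected_auc()`).

## Fitting the working model

The three model parameters are exactly identified by the three component
AUCs, so `fit_shift_model()` inverts them through the probit link
(method of moments): $\hat\mu = \sqrt2\,\Phi^{-1}(C/n_C)$ and
$\hat\rho = 1 - \hat\mu^2 / (2\,[\Phi^{-1}(\mathrm{component})]^2)$. This
choice is exact under the working model and uses only quantities the
estimator already produces. Estimated correlations are clipped to $[0, 1-10^{-6}]$, and
$\hat\rho_s \ge \hat\rho_f$ is enforced: under nested exchangeable
dependence the within-person correlation cannot be smaller than the
within-family one, and violating that ordering (a finite-sample artifact)
can push a comparison-pair correlation outside $[-1,1]$ in the variance
construction below. A component AUC on the wrong side of 0.5 relative to
$\hat\mu$ yields a clipped 0 with a warning.

## Variance construction

Each comparison $c=(a,b)$ has indicator $I_c = 1(D_c > 0)$ with
$D_c = Z_b - Z_a \sim N(\mu,\, 2(1-\rho_{ab}))$. For two comparisons,
$(D_1, D_2)$ is bivariate normal with covariance assembled from the four
pairwise score covariances $r(x,y) \in \{1, \rho_s, \rho_f, 0\}$, so

$$\mathrm{Cov}(I_1, I_2) = P(D_1 > 0, D_2 > 0) - \theta_{L_1}\theta_{L_2},$$

an orthant probability of a bivariate normal. Summing over all $(FG)^2$
ordered pairs of comparisons and dividing by $(FG)^2$ gives
$VAR(\hat\theta_3)$.

Two comparisons that share no family are independent, so only
family-sharing pairs contribute. The production evaluator
(`theta3_variance()`) groups the quadruples into 25 relationship classes —
e.g. "both comparisons within one person, sharing the event subunit" or
"two between-family comparisons whose nonevents share a family and whose
events share another" — whose counts reduce to polynomial identities in the
per-person counts $\{f_{ij}, g_{ij}\}$, evaluated in $O(\text{persons} +
\text{families})$ time with one bivariate-normal CDF call per class.
Identical comparisons contribute $\theta_L(1-\theta_L)$.

The class list was derived by enumerating set partitions of the four
subunits involved, and its correctness is not taken on faith: the package
ships `theta3_variance_brute()`, the literal $O((FG)^2)$ double sum, and the
test suite asserts equality of the two evaluators to $10^{-10}$ on hundreds
of randomized small datasets. On fully independent data under the null the
construction collapses to the classical Wilcoxon variance
$(F+G+1)/(12FG)$, which is also asserted.

The variance is evaluated at the plug-in $(\hat\mu, \hat\rho_s,
\hat\rho_f)$ from the fitted working model.

### Bivariate normal probabilities

No bivariate-normal CDF is needed at dependence zero, but the grouped
classes require $\Phi_2(h, k; \rho)$ across the full correlation range.
`pbvnorm()` implements Gauss–Legendre quadrature of the
Drezner–Wesolowsky angular representation with the Genz tail expansion for
$|\rho| > 0.925$; tests compare it against an independent one-dimensional
adaptive-quadrature representation at tolerance $10^{-10}$ (observed
agreement is near machine precision). Correlations that land outside
$[-1,1]$ by more than $10^{-10}$ raise an internal error rather than being
clipped silently.

## Confidence intervals

Because $\theta_3 \in [0,1]$, the Wald interval is built on the probit
scale: $\omega = \Phi^{-1}(\hat\theta_3)$,
$SE(\omega) = \sqrt{VAR(\hat\theta_3)}\,/\,\phi(\omega)$ by the delta
method (evaluated at the estimate, the standard plug-in), and the limits
$\Phi(\omega \mp z_{\alpha/2} SE(\omega))$ are guaranteed to stay inside
$[0,1]$. Estimates exactly on the boundary are truncated half a discordant
pair inward with a warning.

## Ties

The working model requires a strict ordering, so tied scores cannot enter
the pipeline directly. `hier_auc(ties = "pool")` (chosen automatically when
ties are present) repeats the analysis $L$ times (default $L = 10$), each
time adding independent Uniform$(-\Delta, \Delta)$ noise to the tied scores
only, and pools by Rubin's rules: the estimate and probit-scale estimate are
averaged, and the pooled variance is the mean within-iteration variance
plus $(1 + 1/L)$ times the between-iteration variance of
$\hat\theta_\ell$. With no ties present the pooled path reduces *exactly*
to the single pass. The default half-width $\Delta$ is one decimal finer
than the detected score resolution, capped at half the smallest gap between
distinct scores so originally distinct scores can never be reordered; only
the random ordering of tied values matters, so the result is insensitive to
the exact $\Delta$ below that cap.

## The simulation harness

`simulate_hier_data()` generates scores from the nested random-intercept
model

$$Y_{ijk} = B_1\,\mathrm{event}_{ijk} + u_i + v_{ij} + e_{ijk},$$

with independent zero-mean normal intercepts and Bernoulli(prevalence)
events per subunit. The default parameterization — $B_1 = 1.5$, variances
$(5, 3, 2)$ for family, person, subunit — implies $\rho_s = 0.80$,
$\rho_f = 0.50$, $\mu = 1.5/\sqrt{10} = 0.474$ and component AUCs
$(0.773, 0.682, 0.631)$. `scenario_settings()` enumerates five validation
designs: (1) balanced designs with 20–100 families, 2–3 persons, 2
subunits, prevalence 0.50 or 0.25; (2) scores binned into 5/10/20
equal-probability quantile bins to create ties (bin midpoints as the tied
value; whether one uses midpoints or bin indices is immaterial since the
pipeline is rank-based); (3) family sizes drawn from the 2012 US census
child-count distribution, probabilities $(0.48, 0.36, 0.15, 0.03)/1.02$
for 1–4 children (the reported census probabilities sum to 1.02 because
the tail beyond four children is truncated, so they are renormalized); (4) 10% of persons
losing one of two subunits, deleted rather than imputed; (5) additive
$N(0, \sigma^2)$ measurement error with $\sigma \in \{0.1, 0.25, 0.5\}$.

`run_scenario()` reports, per parameterization, the mean estimate, bias,
the ratio of mean theoretical to empirical variance, and the coverage of
the proposed and DeLong-type intervals. Coverage is judged against the
composite expectation evaluated with *expected* pair counts
(`expected_theta3()`); a realized-count expectation differs only in Monte
Carlo noise. For the binning and measurement-error scenarios the target is
deliberately the unperturbed expectation: those scenarios measure
robustness of the interval, not re-estimation of a shifted parameter.
Per-replicate seeds are derived from the master seed by a counter scheme,
so runs are reproducible and order-independent; degenerate replicates
(a single outcome class, or a boundary between-family component AUC) are
redrawn and counted.

The DeLong comparator (`delong_auc()`) uses midrank placement values and
is computed by default on the probit scale, mirroring the proposed
interval's scale so that coverage differences isolate the variance
estimator; the classical linear-scale Wald interval is available with
`scale = "linear"`. A family-level percentile bootstrap (100 resamples) is
available as a further comparator in `run_scenario(bootstrap = TRUE)`.

### What the generator does and does not emulate

The generator reproduces the dependence structure the method targets —
exchangeable normal random intercepts at two nesting levels, varying
cluster sizes, missingness, coarsened (tied) scores and score-level noise.
It does not emulate non-exchangeable correlation (e.g. serial correlation
in longitudinal data), informative cluster sizes, covariate-driven score
models, or non-normal random effects. Passing the simulation checks
therefore supports calibration under exchangeable nested dependence, not
under those departures; the method itself assumes exchangeability, and
users should assess that assumption on real data.

### Problem sizes used in the shipped checks

The packaged acceptance checks run every scenario at 1000 replicates per
parameterization, a size chosen so the whole validation completes
comfortably on a single CPU while keeping the Monte Carlo standard error
of a coverage mean across settings near 0.002.
The variance-oracle equivalence check uses 200 randomized datasets of at
most 16 records, where the literal quadruple sum is affordable.

## Numerical choices and degenerate inputs

* Empty datasets, single-class datasets, and `F·G = 0` raise errors rather
  than returning NaN.
* A between-family component AUC of exactly 0 or 1 would leave $\mu$
  infinite; it is truncated half a pair inward with a warning, mirroring
  the boundary rule of the confidence interval. With no between-family
  pairs at all ($n_C = 0$) the shift is unidentifiable and an error is
  raised; in the simulation harness such replicates are redrawn.
* When a decomposition level has no pairs (`nA` or `nB` zero), its
  correlation falls back to the next coarser level.
* All internal correlations are validated against $[-1, 1]$ with a
  $10^{-10}$ clipping tolerance; violations raise internal errors.
* A negative variance after summation (impossible up to rounding) raises an
  internal error; values in $(-10^{-12}, 0)$ are snapped to 0.

## Limitations

* The variance is evaluated at plug-in parameter estimates; with very few
  families the added estimation noise can leave intervals slightly
  liberal, consistent with the simulation results for 20-family designs.
* The method consumes prediction scores; it does not fit the
  score-generating mixed model, handle covariate missingness, or
  cross-validate. Scores produced by any upstream model (GLMM, GEE, or
  otherwise) are accepted as given.
* Correlation must be exchangeable at both nesting levels; longitudinal
  autocorrelation violates this.
* Two correlated AUCs cannot yet be compared; the package constructs
  one-sample confidence intervals only.
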