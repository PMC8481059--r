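---
title: "Stress-strength reliability under the exponentiated inverted Weibull model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-strength reliability under the exponentiated inverted Weibull model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiwss)
library(dplyr)
```

## The model

A component survives as long as its strength $X$ exceeds the stress $Y$ it
is exposed to.  When both are random, the single-number summary of the
design margin is the stress-strength reliability

$$R = P(Y < X),$$

the probability that a randomly met stress stays below a randomly drawn
strength — identical to the probabilistic index (two-sample AUC) used in
biostatistics.

`eiwss` models both samples with the exponentiated inverted Weibull (EIW)
law, a heavy-tailed lifetime distribution on $x > 0$ with CDF

$$F(x;\theta,\beta) = \exp(-\theta x^{-\beta}), \qquad \theta, \beta > 0.$$

$\beta$ is a shape parameter; $\theta$ enters as an exponentiation (power)
of the standard inverted Weibull CDF and plays the role of a scale-type
parameter.  The transform $T = X^{-\beta}$ is exponential with rate
$\theta$, which gives cheap moment checks and exact inverse-transform
sampling via the quantile $x = (-\ln q / \theta)^{-1/\beta}$ (the algebraic
inverse of $F$; `qeiw()` and `peiw()` round-trip to $10^{-12}$ by
construction and by test).

When strength and stress share the shape,
$X \sim \mathrm{EIW}(\theta_1, \beta)$ and
$Y \sim \mathrm{EIW}(\theta_2, \beta)$, the reliability has the closed form

$$R = \frac{\theta_1}{\theta_1 + \theta_2},$$

free of $\beta$.  Every estimator below therefore reduces to estimating the
triple $(\theta_1, \theta_2, \beta)$ jointly from the two samples and
mapping it through this ratio; the identity $\hat R = \hat\theta_1 /
(\hat\theta_1 + \hat\theta_2)$ is exact in every fitted object.

The common-shape assumption is what buys the closed form.  It is a real
restriction: the goodness-of-fit workflow (`fit_eiw()` plus
`eiw_ks_test()`) fits each sample separately with its own shape precisely
so that the shared-$\beta$ simplification can be judged against the data
before the joint model is trusted.

## The eight estimators

`fit_ss(data, method)` implements eight criteria.  With order statistics
$x_{(1)} \le \dots \le x_{(n)}$, fitted probabilities
$F_i = F(x_{(i)}; \theta_1, \beta)$ (and the analogous $G_j$ for stress),
and spacings $\Delta_i = F_i - F_{i-1}$ with boundary conventions $F_0 = 0$,
$F_{n+1} = 1$:

* **`mle`** maximises the joint log-likelihood.  At fixed $\beta$ the
  likelihood is maximised analytically by $\theta_1 = n / \sum x_i^{-\beta}$
  and $\theta_2 = k / \sum y_j^{-\beta}$; substituting these gives a profile
  log-likelihood whose derivative in $\beta$ is root-found on
  $[10^{-3}, 10^3]$ (bracket expanded geometrically if needed, tolerance
  $10^{-10}$).  The MLE is therefore exact up to root-finding tolerance —
  no 3-D numerical optimisation is involved.  The weighted means
  $\sum x_i^{-\beta}\log x_i / \sum x_i^{-\beta}$ inside the score are
  evaluated by log-sum-exp so large $\beta$ cannot underflow them.
* **`mpse`** maximises the mean log spacing of both samples,
  $\frac{1}{n+1}\sum \log \Delta_i + \frac{1}{k+1}\sum \log \Delta_j$
  (maximum product of spacings).
* **`msade`** / **`msalde`** minimise
  $\sum |\Delta_i - \tfrac{1}{n+1}|$ or
  $\sum |\log \Delta_i - \log\tfrac{1}{n+1}|$ summed over both samples —
  minimum spacing distance with absolute and absolute-log distance.
* **`lse`** / **`wlse`** minimise the squared distance between $F_i$ and the
  plotting positions $i/(n+1)$, unweighted or with the classical weights
  $\omega_i = (n+1)^2(n+2) / (i(n-i+1))$ (inverse variance of the $i$-th
  uniform order statistic).
* **`cme`** minimises the Cramér-von Mises statistic
  $\frac{1}{12n} + \sum_i (F_i - \frac{2i-1}{2n})^2$, summed over both
  samples.
* **`ade`** minimises the sum of the two samples' Anderson-Darling
  statistics
  $A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\ln F_i + \ln(1 - F_{n+1-i})\right]$.

### Numerical choices

These choices were genuinely open and are recorded here as the package's
own:

* **Log-parameter optimisation.**  All distance criteria are optimised over
  $(\log\theta_1, \log\theta_2, \log\beta)$, which enforces positivity
  without constraints and makes multiplicative jitter natural.
* **Starts and restarts.**  Every optimisation starts at the exact MLE
  (free, via the profile) plus `restarts` (default 4) lognormally jittered
  starts (sd 0.5 on the log scale, fixed deterministic jitter stream).  The
  surfaces of the least-squares-type criteria are flat and multimodal along
  a $\theta$–$\beta$ ridge, and single-start results are
  optimizer-path-dependent; the best criterion value over all starts wins
  and the restart count is recorded in the fit.
* **Smooth vs non-smooth.**  The smooth criteria (`mpse`, `lse`, `wlse`,
  `cme`, `ade`) get two rounds of Nelder-Mead followed by a quasi-Newton
  (BFGS) polish, accepted only if it improves the criterion.  The
  absolute-distance criteria `msade`/`msalde` are non-smooth at spacing
  ties, so they stay with polytope search throughout.
* **Spacing floor and CDF clamp.**  Inside log/ratio criteria any spacing
  below $10^{-10}$ is floored there (tied observations otherwise send
  $\log \Delta$ to $-\infty$); Anderson-Darling CDF values are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ before logs.  Ties are admitted by the floor,
  not dropped.
* **Cramér-von Mises plotting positions.**  The reversed pairing
  $(2(n-i)+1)/(2n)$, which appears in some printed accounts of the
  criterion, pairs the smallest order statistic with the largest
  probability; taken literally it drives the fit degenerate
  ($\theta \to 0$).  The standard $(2i-1)/(2n)$ is the default;
  `cme_positions = "as_printed"` keeps the reversed variant available for
  sensitivity checks only.
* **Convergence.**  Relative objective tolerance $10^{-12}$ in the
  optimiser; the MLE additionally verifies that the profile score vanishes
  below $10^{-6}$ at the root.  Tests assert *dominance*: each fitted
  optimum must beat an exhaustive log-space grid around it, and must beat
  the MLE point on its own criterion.  Dominance checks are what make
  under-converged optima detectable; on flat ridges two optimisers can
  disagree substantially in $(\theta_1, \theta_2)$ while differing only in
  the sixth decimal of the criterion, so criterion values — not parameter
  agreement with any particular earlier run — are the arbiter of
  correctness here.

Standard errors for the MLE come from the inverse observed information,
with the Hessian of the log-likelihood computed by central differences
using steps scaled to each parameter's magnitude ($10^{-4}|p_i|$).  The
distance criteria do not define an information matrix; for them a bootstrap
standard deviation from `ss_bootstrap()` is the supported (and clearly
different in kind) uncertainty measure.

## Bootstrap intervals for R

`ss_bootstrap()` implements a *parametric* bootstrap: replicate samples of
the original sizes are drawn from the fitted EIW laws and refit with the
same estimator — never resampled from the data.  Two intervals summarise
the $B$ replicates (default $B = 1000$ for data analyses):

* **Percentile (`boot_p`)**: order statistics at ranks
  $\lceil B\gamma/2 \rceil$ and $\lceil B(1-\gamma/2) \rceil$.  The plain
  ceiling rank rule is the default; an interpolating-quantile variant sits
  behind `rule = "interpolate"` for sensitivity checks.  A slack of
  $10^{-9}$ inside the ceiling keeps exact multiples from being pushed up a
  rank by floating-point representation.
* **Bias-corrected percentile (`boot_bcp`)**: ranks shifted through
  $z_0 = \Phi^{-1}(\hat p)$ where $\hat p$ is the fraction of replicates
  below the point estimate.  Replicates exactly equal to the estimate count
  with weight $\tfrac12$ (a symmetric tie treatment), and $\hat p$ is
  clamped to $[\tfrac{1}{2B}, 1-\tfrac{1}{2B}]$ so $z_0$ stays finite when
  all replicates fall on one side.  No acceleration constant is used (this
  is BC, not BCa).

Sub-seeds for the replicates are derived from the master seed by a counter
scheme, so runs are reproducible and failed refits can be redrawn (at most
10 times each, counted in the result) without disturbing other replicates.

## The Monte Carlo harness

`ss_sim_config()` + `run_ss_study()` reproduce the estimator-comparison
experiment: for each truth triple and size pair, draw both samples by
inverse transform, fit every requested method *to the same generated data*,
and accumulate the mean and MSE of each parameter and of $\hat R$, plus
mean bootstrap interval lengths when a bootstrap block is configured.

The defaults are the study conditions themselves:

* truth triples $(\theta_1, \theta_2, \beta)$:
  $(0.1, 0.1, 0.5)$, $(3, 0.1, 0.5)$, $(3, 0.4, 0.9)$, $(3, 2, 0.9)$,
  $(0.5, 0.4, 0.5)$, $(0.5, 1.5, 0.5)$;
* size grid $(n, k) = (30, 40), (35, 45), (50, 60), (70, 80)$ — the stated
  experimental design; one published table header repeats a conflicting
  pair (30, 35)/(40, 45), which disagrees with the stated design and with
  the other tables, so the stated grid is used;
* 10000 replicates, all eight methods, nested bootstrap $B = 500$
  (interval lengths are insensitive to $B$ beyond a few hundred).

Failed replicate fits are excluded (not redrawn) from the summaries and
counted, so every method is compared on identical data streams.

The package's own test and acceptance runs scale this down to keep the
suite quick while leaving Monte Carlo error well inside the asserted
bands: 2000 replicates for the point-summary reproduction (MC standard
error of the mean of $\hat R$ about $0.0013$; of the MSE about 3%), and a
500-experiment coverage study of the 95% percentile interval at
$(\theta_1, \theta_2, \beta) = (0.5, 0.4, 0.5)$, $n = 30$, $k = 40$,
$B = 500$, asserted against the loose band $[0.90, 0.99]$.

### What the generator does and does not emulate

`ss_simulate_data()` draws i.i.d. complete samples from exact EIW laws with
a genuinely shared shape.  Passing recovery and coverage tests under it
demonstrates correctness of the estimators and intervals *under the model*;
it says nothing about robustness to misspecification that real data can
exhibit: unequal shapes between the two samples, censoring or truncation,
measurement rounding (the case-study values are printed to 2–3 decimals,
producing occasional ties the spacing floor must absorb), or dependence
between stress and strength.  None of those features are simulated.

## Goodness of fit

`fit_eiw()` fits each sample alone (own $\theta$, own $\beta$) by the same
profile construction, and `eiw_ks_test()` computes the one-sample
Kolmogorov-Smirnov statistic
$D = \max_i \max\{i/n - F_{(i)},\, F_{(i)} - (i-1)/n\}$ against the fitted
law.  The p-value rule mirrors standard practice: exact finite-$n$
distribution when $n < 100$ and the sample has no ties, asymptotic
Kolmogorov distribution at $\sqrt{n}D$ otherwise (both forceable).  No
correction is applied for the parameters having been estimated from the
same sample, so these p-values are optimistic — they are reported for
descriptive comparison, not as calibrated tests.  `pp_series()` and
`eiw_cdf_series()` expose the P-P and CDF-overlay coordinates for plotting
(`autoplot()` renders them).

## A worked case study

```{r jute}
jute <- eiw_dataset("jute")
fit_ss_all(jute, methods = c("mle", "mpse", "lse", "ade"))
```

```{r jute-boot}
b <- ss_bootstrap(jute, "mle", B = 500, conf_levels = c(0.90, 0.95), seed = 1)
tidy(b)
```

```{r jute-gof}
x <- filter(jute, role == "strength")$value
fx <- fit_eiw(x)
eiw_ks_test(x, fx$theta, fx$beta)
```

## Known limitations

* Complete, independent samples only: no censoring, no covariates, no
  Bayesian machinery.
* The common-shape assumption is required for $R = \theta_1/(\theta_1 +
  \theta_2)$; the package checks it only informally through the separate
  single-sample fits.
* Reliability standard errors for the non-MLE criteria are bootstrap
  quantities, not information-based ones; the two are not interchangeable.
* On flat likelihood/criterion ridges (small samples, heavy tails) point
  estimates of $(\theta_1, \theta_2)$ are individually ill-determined even
  when $\hat R$ and $\hat\beta$ are stable; compare criterion values, not
  raw parameter values, when cross-checking against other software.
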