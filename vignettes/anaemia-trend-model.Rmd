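---
title: "Estimating haemoglobin and anaemia trends from heterogeneous surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating haemoglobin and anaemia trends from heterogeneous surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbtrends)
```

## The estimation problem

Population haemoglobin is measured by surveys that differ in almost every
design dimension: some provide individual records, others only a mean, an
sd, and prevalences; some cover the whole country, others only a few
regions; some report pregnant and non-pregnant women separately, others
pool them; some are adjusted for altitude of residence, others are not; and
all of them carry variability beyond sampling noise (season, sample design,
assay). `hbtrends` estimates, from such data, full haemoglobin
*distributions* for every country, year, and population group (children
6--59 months; women 15--49 by pregnancy status), so that mean haemoglobin
and the prevalence of total and severe anaemia at the WHO cutoffs — or any
other cutoff — are all read off one coherent object.

## Model

The population distribution of haemoglobin $h$ (g/L) in country $c$, year
$t$, group $g$ is a five-component normal mixture

$$ f_{c,t,g}(h) = \sum_{k=1}^{5} w_k \,
   \mathcal N\!\left(h;\; \theta_{c,t,g} + o_k,\; \tau_k^2\right), $$

with ordered component offsets $o_k$ constrained by
$\sum_k w_k o_k = 0$, so the analytic mean of the mixture equals the
location $\theta$ exactly and the offsets carry the (typically
left-skewed) shape. The shape $(o, w, \tau)$ is shared across countries
within a group family (children; women), while the location varies:

$$ \theta_{c,t} = (a_0 + a_{r(c)} + a_c) + (b_0 + b_{r(c)} + b_c)(t - 2000)
   + u_0(t) + u_{r(c)}(t) + u_c(t) + z_{c,t}^\top \beta, $$

a linear trend plus a smooth nonlinear trend at the global, regional, and
national level, plus covariates (maternal education, urban share, absolute
latitude, sickle-cell/thalassaemia prevalence, and mean BMI for women or
mean weight-for-age Z score for children, standardised before entering).
Pregnant women's location is the non-pregnant location minus a country
offset $\delta_c \ge 0$ shrunk towards a region mean (prior centred at
11.5 g/L: haemoglobin runs 8--15 g/L lower in pregnancy). Deviations are
shrunk to zero through estimated variances with half-Normal hyperpriors,
which is what lets data-poor countries borrow strength from their region
and the world, while data-rich countries are dominated by their own data.

The smooth nonlinear trends $u(\cdot)$ follow second-order random-walk
(RW2) priors, which penalise second differences and so favour smooth
curves. Because the RW2 null space is exactly the space of straight lines,
each $u$ is represented in a basis orthogonal to $\{1, t\}$; the linear
trend belongs to $(a, b)$ alone and the decomposition is identified.

### Likelihood by data form

* **Individual records** contribute the log mixture density at the cell's
  location. Each individual-level survey also carries a latent
  survey-level offset $\varepsilon_s \sim \mathcal N(0, \sigma_{ns}^2)$
  (variance augmented by $\sigma_{sub}^2$ for subnational sources), the
  same non-sampling variability that summary sources receive through
  their variance term.
* **Summary means** contribute a Normal likelihood with variance
  $sd^2/n + \sigma_{ns}^2 + [\text{subnational}]\,\sigma_{sub}^2 +
  [\text{age mismatch}]\,\sigma_{age}^2$: survey statistics vary more than
  sampling theory alone predicts, and subnational or age-mismatched
  sources more still.
* **Summary prevalences** are compared on the probit scale with the
  probit of the model's mixture cdf at the group cutoff; the measurement
  variance is the delta-method binomial variance plus the design-inflation
  terms mapped through the probit slope. Observed prevalences are clamped
  to $[1/(2n), 1 - 1/(2n)]$ so zero counts remain usable.
* **Combined-women sources** (no pregnancy stratification) observe the
  two-group mixture $(1-p)f_{np} + p f_p$ with recorded pregnant fraction
  $p$; their pooled mean is the linear combination
  $\theta_{np} - p\,\delta_c$, so they inform both groups.

Sources are included only if nationally representative or covering at
least three regions; haemoglobin is adjusted downward for altitude of
residence with the CDC polynomial ($-0.32A + 0.22A^2$ g/L, $A$ = altitude
in thousands of feet, applied from 1000 m; about 3.8 g/L at 1500 m and
9.2 g/L at 2200 m), individually where altitude is known and through the
population altitude distribution for summary sources from countries where
more than 5% live at or above 1500 m. No smoking post-adjustment is made
(the effect, roughly 0.3 g/L, is an order of magnitude below altitude).
Pregnancy is classified operationally as strictly after 8 completed
gestational weeks — reporting only becomes consistent around weeks 6--10 —
with the boundary resolved strictly (`> 8`) for determinism.

## Inference

The sampler is Metropolis-within-Gibbs:

* The entire latent Gaussian field (intercepts, slopes, RW2 coefficients,
  covariate effects, pregnancy offsets, survey offsets; 300--400
  dimensions at the default problem size) is updated in **one block**. The
  non-Gaussian likelihood terms (individual-record cells, probit
  prevalences) are locally replaced by their second-order Taylor
  expansion, giving a Gaussian proposal whose precision combines the prior
  and all data terms; the proposal is corrected by Metropolis-Hastings, so
  the update is exact. For purely Gaussian data the proposal is the exact
  conditional and acceptance is 1; in practice acceptance runs around
  0.8--0.9. Chains are initialised at the conditional mode (a few Newton
  iterations of the same approximation) so the expansion is accurate from
  the first iteration.
* The hierarchy and noise sds are updated by univariate log-scale random
  walks (several sweeps per iteration; they are cheap).
* The 14 transformed mixture-shape parameters (weight logits, first
  offset, log gaps, log component sds) are updated jointly by an adaptive
  Metropolis step whose proposal covariance is learned during warmup
  (Haario-style) and frozen afterwards, which handles their strong
  correlation.

Defaults are 4 chains with 1000 warmup iterations, pooled and trimmed to
exactly 2500 retained draws; every reported quantity is computed per draw
and summarised by its posterior mean with 2.5th--97.5th centile
credibility intervals (`quantile(type = 7)` interpolation everywhere).
Chains run sequentially with seeds derived from one integer, so a fit is
byte-reproducible.

## Reported quantities

Per draw, mixture cdfs give anaemia prevalences at the group cutoffs
(110/120 g/L total, 70/80 g/L severe); regional and global distributions
are population-weighted averages of country results (checked to conserve
exactly, draw by draw); counts are prevalence times population. Changes
between 1995 and 2011 are reported per decade — absolute for means,
proportional for prevalences with the geometric convention
$(p_2/p_1)^{10/16} - 1$ by default (the arithmetic convention is a flag;
"proportional change" does not by itself pin down a formula, so the
output records which convention was used). The posterior probability of a trend
is the fraction of draws in which the quantity increased, ties counted
0.5. The probability of halving prevalence by 2025 extrapolates each
draw's linear trend, freezing the RW2 component at its last fitted value
and holding covariates at their final year — extrapolating a random walk
would inflate variance with no principled gain. The iron-amenable share of
anaemia applies the supplementation shifts (10.17 / 8.64 / 8.0 g/L for
pregnant women, non-pregnant women, children) to everyone below the
cutoff and reports the fraction cleared,
$(F(c) - F(c - s))/F(c)$; shifting the whole distribution instead is a
documented alternative, but the trial evidence concerns haemoglobin gains
*in those anaemic at baseline*, so the sub-cutoff variant is the default.

## The synthetic world

Real compilations of anaemia surveys cannot be redistributed, so the
package ships a generator that plays the role of the data: a known world
(the model's own data-generating process: hierarchical lines, detrended
RW2 wiggles, covariate effects, pregnancy offsets drawn uniformly from
8--15 g/L, one shared mildly left-skewed mixture shape with overall sd
about 13 g/L) observed by surveys with the heterogeneity catalogued above
— summary-only (50%), combined women (30%), subnational (25%, of which
those covering fewer than three regions are later excluded),
age-mismatched (10%), highland countries with altitude effects embedded
and mostly unadjusted at source, per-survey non-sampling offsets of 2 g/L
(plus 3 g/L subnational), and 150--800 persons per group cell. Defaults
are two regions of five countries over 1990--2012 with two surveys per
country-decade, the scale at which the whole pipeline (simulate, adjust,
fit with 2 chains / 500 warmup / 2500 retained, summarise) runs in a few
minutes on one CPU; the vignette-scale tests use smaller worlds still.

What the generator does *not* emulate — cluster designs, seasonality,
assay differences beyond the single variance term, duplicate and
overlapping sources, and real-world model misspecification (the world is
drawn from the model family itself) — bounds what passing tests show:
they demonstrate that the machinery recovers truth under the model's
assumptions at desk scale, not that the model is correct for real surveys.

## Numerical choices and edge cases

* Observed prevalences are clamped before the probit; mixture cdf values
  are clamped to $[10^{-12}, 1 - 10^{-12}]$.
* The inverse of the standardised-shape cdf (used to map prevalence
  variances) uses monotone grid interpolation inside the sampler and root
  finding elsewhere.
* Summary sources lacking an sd receive a 14 g/L fallback for their
  mean's sampling variance.
* Prevalence summaries from high-altitude countries cannot be shifted
  exactly; they are recomputed from a Normal approximation at the shifted
  mean with the reported sd, and the approximation is recorded.
* Individual records outside 25--220 g/L are flagged and excluded with a
  count, never silently dropped.
* Draws with zero baseline prevalence are excluded (with a count) from
  proportional change; ties in trend probabilities count 0.5.
* The positivity constraint on pregnancy offsets is enforced by rejection
  in the latent-field update (the posterior keeps offsets far from 0, so
  rejections are rare).

## Limitations

Estimates for 1990--1994 and 2012 carry boundary effects — trends are
poorly identified at the edges of the fitting window, which is why
reporting concentrates on 1995--2011. The shared-shape assumption
(location-only variation across countries within a family) is the minimal
structure supporting full-distribution estimation from sparse data; a
config switch allows region-level shape deviations for robustness checks.
Prevalence likelihood terms assume the probit-delta approximation is
adequate, which degrades for cells with tiny expected counts. The sampler
is tuned for hundreds of latent dimensions; worlds with many hundreds of
countries would need sparse Cholesky machinery it does not use.
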