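# hbtrends

Bayesian hierarchical mixture models for national, regional, and global
trends in population haemoglobin and anaemia prevalence.

## The problem

Anaemia — haemoglobin below 110 g/L for children under 5 and pregnant
women, below 120 g/L for non-pregnant women (severe: below 70/70/80 g/L) —
is tracked through surveys that are wildly heterogeneous: individual
records or summary statistics only; national or subnational coverage;
women reported by pregnancy status or pooled; haemoglobin adjusted for
altitude of residence or not; and all of it noisier than sampling theory
predicts. `hbtrends` is for quantitative epidemiologists who need
internally consistent country-year estimates of the *full* haemoglobin
distribution from such data, with honest uncertainty.

## The model

The haemoglobin distribution of country $c$, year $t$, group $g$ is a
five-component normal mixture
$f(h) = \sum_k w_k\, \mathcal N(h;\, \theta_{c,t,g} + o_k,\, \tau_k^2)$
with $\sum_k w_k o_k = 0$, so the mixture mean is the location
$\theta_{c,t,g}$ and the components capture skewness. Locations follow

$$\theta_{c,t} = (a_0 + a_r + a_c) + (b_0 + b_r + b_c)(t - 2000)
  + u_0(t) + u_r(t) + u_c(t) + z_{c,t}^\top\beta,$$

a linear plus smooth nonlinear (second-order random walk) trend at the
global, regional, and national level with covariates, all deviations
shrunk hierarchically so data-poor countries borrow strength; pregnant
women sit a country-specific offset $\delta_c \ge 0$ below non-pregnant
women. Summary statistics enter with a non-sampling variance term
($\sigma^2_{ns}$, plus subnational and age-mismatch components);
prevalences enter on the probit scale; pooled-women sources enter through
the pregnant-fraction mixture. Inference is MCMC (one-block
Gaussian-Taylor Metropolis-Hastings for the latent field, adaptive
Metropolis for the mixture shape), retaining 2500 posterior draws from
which every output — means, prevalences at any cutoff, counts, change per
decade, trend probabilities, iron-amenable shares, halving probabilities —
is computed draw by draw with 2.5th–97.5th centile credibility intervals.
The methods vignette (`vignettes/anaemia-trend-model.Rmd`) has the full
specification.

Real survey compilations cannot be redistributed, so the package includes
a first-class synthetic-data generator (`generate_true_world()`,
`generate_surveys()`) reproducing the heterogeneity above with known
ground truth; the whole pipeline runs and validates at desk scale.

## Worked example

The `analysis/` scripts run the full workflow on the benchmark synthetic
world (2 regions × 5 countries, 1990–2012, ~43 surveys):

```sh
Rscript analysis/01_simulate.R 1    # world + surveys -> results/sim/
Rscript analysis/02_fit.R 1        # adjust + MCMC    -> results/fit/
Rscript analysis/03_summarize.R    # estimates        -> results/summaries/
Rscript analysis/04_recovery.R     # truth comparison -> results/recovery.csv
```

which prints, among other things:

```
children model: 2500 retained draws, latent-field acceptance 0.86/0.88
women model:    2500 retained draws, latent-field acceptance 0.78/0.75
Global total-anaemia prevalence, 2011 (posterior mean and 95% CrI):
        group     point        lo        hi
     children 0.3785532 0.3257326 0.4346810
 non_pregnant 0.2798105 0.2119490 0.3481972
     pregnant 0.3032639 0.2332301 0.3758926
Coverage of 95% credibility intervals over country-year true means: 0.933
children      max |global mean error|: 2.93 g/L (all years), 1.33 g/L (1995-2011)
non_pregnant  max |global mean error|: 3.63 g/L (all years), 3.14 g/L (1995-2011)
pregnant      max |global mean error|: 4.22 g/L (all years), 3.67 g/L (1995-2011)
```

Reading this: the model recovers 93.3% of the 690 country-year true means
inside their 95% credibility intervals; the global mean is recovered to
within 1.3 g/L for children across the reporting years, while the women
models drift up to ~3–4 g/L in the latest years, where this world's few
surveys happen to sit high — the intervals widen accordingly. The
summaries include, for example, a global children's improvement of
4.5 g/L per decade (95% CrI 2.8–6.0, posterior probability of increase
1.0), iron-amenable shares of total anaemia of 0.47/0.53/0.59
(children / non-pregnant / pregnant) under the supplementation shifts of
8.0/8.64/10.17 g/L, and probabilities of halving anaemia prevalence
between 2011 and 2025 of 0.12 (children) and 0.004 (non-pregnant women)
at the global level under continued linear trends.

Single computations are available directly:

```r
library(hbtrends)
cdc_altitude_shift(c(1500, 2200))   # 3.753222 9.151450  (g/L, downward)
w <- c(0.05, 0.15, 0.35, 0.3, 0.15)
d <- mixture_distribution(110, center_offsets(c(-20,-10,0,5,10), w), w,
                          rep(9, 5))
mixture_cdf(d, 110)                 # 0.478333: prevalence at 110 g/L
```

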