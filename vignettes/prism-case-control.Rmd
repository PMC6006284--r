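---
title: "Testing sufficient-cause interaction in case-control studies of non-rare diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing sufficient-cause interaction in case-control studies of non-rare diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prismcc)
```

## The problem

Two binary exposures $X$ and $Z$ show a *sufficient-cause interaction*
(also called mechanistic interaction or causal co-action) when some
sufficient cause of disease requires both of them. This is a stronger and
more mechanistically interpretable statement than a product term in a
regression model, and two families of tests target it directly:

* the **RERI** test, based on additivity of relative risks:
  $\mathrm{RERI} = RR_{1,1} - RR_{1,0} - RR_{0,1} + 1$, which is zero under
  risk additivity; and
* the **PRISM** test, based on additivity of *log perils*, where the peril
  of profile $(x,z)$ is $\mathrm{Peril}_{x,z} = (1-\mathrm{Risk}_{x,z})^{-1}$
  and
  $$\log \mathrm{PRISM} = \log\mathrm{Peril}_{1,1} - \log\mathrm{Peril}_{1,0}
    - \log\mathrm{Peril}_{0,1} + \log\mathrm{Peril}_{0,0},$$
  which is zero under the no-interaction null.

Both quantities are defined through absolute risks, so they are estimable
in cohort studies. In a case-control study only the exposure-profile
proportions among cases ($\hat q_{x,z}$) and controls ($\hat r_{x,z}$) are
observed; absolute risks are not identified. The classical work-around is
the rare-disease approximation ($\mathrm{Risk} \approx \mathrm{Odds}$,
$\log\mathrm{Peril} \approx \mathrm{Odds}$), which replaces risks by odds
ratios — but it breaks down for non-rare diseases such as hypertension,
and the resulting odds-scale tests can badly over-reject.

## The prevalence adjustment

Following Cornfield's classical argument, one external number rescues the
absolute scale: an estimate $\hat p = D/N$ of the *overall* disease
prevalence of the source population, typically available from vital
statistics. By Bayes' theorem the disease odds of profile $(x,z)$ are

$$\widehat{\mathrm{Odds}}_{x,z}
  = \frac{\hat p}{1-\hat p}\cdot\frac{\hat q_{x,z}}{\hat r_{x,z}},
\qquad
\log\widehat{\mathrm{Peril}}_{x,z} = \log\!\big(1 + \widehat{\mathrm{Odds}}_{x,z}\big).$$

Only the overall prevalence is needed — no sex-, age- or profile-specific
prevalences and no sampling fractions. The prevalence-adjusted PRISM test
plugs these log perils into the $\log\mathrm{PRISM}$ contrast and refers

$$Z = \frac{\log\widehat{\mathrm{PRISM}}}
           {\sqrt{\widehat{\mathrm{Var}}(\log\widehat{\mathrm{PRISM}})}}$$

to the standard normal. Note the ratio $\hat q_{x,z}/\hat r_{x,z}$ must be
formed from *sample proportions*, not raw count ratios: the two differ by
the constant $N_0/N_1$, and only the proportion form combines correctly
with $\hat p/(1-\hat p)$.

```{r example}
ex <- hypertension_example()
fit <- prism_test(ex$table, ex$prevalence)
summary(fit)
```

## The variance

The variance treats the three data sources as independent:
case profile counts $\sim$ Multinomial$(N_1, q)$, control profile counts
$\sim$ Multinomial$(N_0, r)$, and $D \sim$ Binomial$(N_{pop}, p)$ for the
prevalence estimate. Writing $a_{x,z} =
\mathrm{Odds}_{x,z}/(1+\mathrm{Odds}_{x,z})$ (the estimated risk) and
$s = (+1,-1,-1,+1)$ for the contrast signs, the first-order delta method
with the full within-multinomial covariances gives

$$\mathrm{Var}(\log\widehat{\mathrm{PRISM}})
 = \frac{1}{N_1}\Big[\sum \frac{a^2}{q} - \big(\textstyle\sum s\,a\big)^2\Big]
 + \frac{1}{N_0}\Big[\sum \frac{a^2}{r} - \big(\textstyle\sum s\,a\big)^2\Big]
 + \frac{\big(\sum s\,a\big)^2}{p(1-p)\,N_{pop}}.$$

The last term is the price of an estimated prevalence; it is monotone
decreasing in $N_{pop}$, numerically negligible for vital-statistics-sized
sources ($N_{pop} \ge 10^5$), and dropped entirely when the prevalence is
declared exact (`prevalence(p, n = Inf)`). On the hypertension example
this variance reproduces the published confidence interval and p-value to
print precision, which is the package's evidence that it matches the
variance used in the original analysis.

Two numerical conventions matter at the edges. Log perils are evaluated
with `log1p`, so rare-disease odds of order $10^{-4}$ lose no precision.
A zero *case* cell is allowed: its odds estimate is 0 and its gradient
contribution enters by its analytic limit (the term $q\,(a/q)^2 = a^2/q$
vanishes as $q \to 0$ because $a \propto q$), never as $0/0$. A zero
*control* cell leaves the estimator undefined and is an error by default;
an optional add-0.5-to-all-cells correction (`correction = TRUE`) exists
but is off, because the original analysis uses none.

### The delta variance and the parametric bootstrap

`bootstrap_variance()` (and `simulate()` on a fitted test) provides an
independent check: it redraws all three data sources from the fitted
model and returns the empirical variance of the recomputed statistic.
At large counts the two agree to about a percent, for every method. At
the modest counts of the worked example (20 cases and 18 controls in the
doubly exposed cell) the bootstrap distribution of these ratio-based
statistics is right-skewed, and the first-order variance sits below the
bootstrap variance — about 11% below for logPRISM, more for the
odds-ratio-scale statistics, while robust spread measures of the
bootstrap distribution (MAD, IQR) agree with the delta standard error to
within 2%. This is intrinsic first-order behaviour at small counts, not
an implementation artefact, and it is shared by any variance consistent
with the published confidence interval; users with very small cells who
want tail-accurate uncertainty should prefer the bootstrap draws
themselves.

## The comparator tests

Three comparators put the proposed test in context, all exposed through
`sc_test(method = ...)`:

* **Odds-scale PRISM** (`"prism-odds"`): the rare-disease approximation
  $\log\mathrm{PRISM} \approx \mathrm{Odds}_{1,1} - \mathrm{Odds}_{1,0} -
  \mathrm{Odds}_{0,1} + \mathrm{Odds}_{0,0}$, computed from pseudo-odds
  $\hat q/\hat r$. No prevalence is needed: the unknown factor
  $p/(1-p)$ multiplies the statistic and its standard error equally, so
  $Z$ is invariant to it. As $\hat p \to 0$ the prevalence-adjusted $Z$
  converges to this $Z$ — the package tests that limit explicitly.
* **Odds-scale RERI** (`"reri-odds"`): RERI with odds ratios standing in
  for relative risks, variance by the usual delta method through the log
  odds ratios (the shared reference cell makes the three log odds ratios
  correlated).
* **Risk-scale RERI** (`"reri-risk"`): RERI on relative risks recovered
  from the same prevalence adjustment,
  $\mathrm{Risk}_{x,z} = \mathrm{Odds}_{x,z}/(1+\mathrm{Odds}_{x,z})$.

**Sidedness.** The PRISM tests default to two-sided: log-peril additivity
is the exact null, and departure in either direction is evidence of
interaction (synergistic or antagonistic). The RERI comparators are run
one-sided (`alternative = "greater"`) in the simulation experiments,
because RERI-based sufficient-cause reasoning is directional: under
monotonicity, a significantly *positive* RERI is the evidence of synergy.
This matters for interpreting the comparators under the PRISM null:
log-peril additivity implies a *negative* true risk-scale RERI for a
non-rare disease (about $-0.18$ at prevalence 0.2 and $-0.40$ at 0.4 in
the default scenarios), so the one-sided risk-scale RERI test is very
conservative there — a two-sided version would instead reject often, for
the uninteresting reason that its own null is false. For rare diseases
all scales coincide, the true RERI is only slightly negative, and the
one-sided RERI rates sit near (slightly above) nominal rather than below.

## Simulation scenarios

`sc_scenario()` builds the population truth from the quantities such
studies report: overall prevalence, the marginal relative risks, and the
true PRISM. Defaults mirror the canonical design: both exposures
independent with prevalence 0.5 (so $\pi_{x,z} = 1/4$), $RR_{1,0} = 3$,
$RR_{0,1} = 2$, a vital-statistics source of $N_{pop} = 10^6$, and
$\alpha = 0.05$. The baseline risk is found by `uniroot` on a bracket
$(\varepsilon, \min(1/RR_{1,0}, 1/RR_{0,1}) - \varepsilon)$ with
$\varepsilon = 10^{-12}$; monotonicity of the mean risk over the bracket
is *checked* on a grid rather than assumed, infeasible constraint systems
produce a descriptive error, and the returned risks satisfy all four
constraints to $10^{-10}$. Parameterising the alternative by its PRISM
value (rather than by $RR_{1,1}$) matches how the scenarios are printed:
PRISM $\in \{1.0155, 1.0109, 1.0048\}$ at prevalence 0.02 and
$\{1.1710, 1.1172, 1.0500\}$ at 0.2.

`simulate_study()` draws the three data sources of one study;
`rejection_rate_experiment()` wraps the full Monte Carlo loop. A master
seed spawns one substream per replicate, so experiments are reproducible
and order-independent, and `prevalence_sensitivity_experiment()` can vary
the prevalence-source size against identical simulated studies.
Replicates on which a test is undefined (zero cells, possible at small
samples with rare exposure profiles) are excluded from the denominator
and counted; they are essentially absent (zero) in all the printed-scale
scenarios, and more than 20% of them is an error. Prevalence draws with
$\hat p \in \{0,1\}$ are redrawn and counted.

What the generator emulates is exactly the sampling model the tests
assume: multinomial exposure profiles within cases and controls, an
independent binomial prevalence source, and no confounding,
misclassification, covariates or matching. Passing tests therefore
validate internal correctness and the operating characteristics under
that model — not robustness to the complications of real observational
data, which the single-2x2x2-table method does not address.

### Problem sizes

The full-scale design (10,000 replicates per scenario) is a documented
script-level run; the package's own checks use scaled-down sizes chosen
so Monte Carlo error is still informative: 2,000 replicates for the null
grid (binomial SE about 0.005 at a rate of 0.05, checked within 3 SEs),
1,000 for power and comparator points, and 10,000 bootstrap replicates
for variance validation. With those sizes the whole test suite runs in a
few seconds. One consequence is worth stating plainly: the true power of
the proposed test in the printed 500-case scenario (prevalence 0.2,
PRISM = 1.1710) is 0.8007 by a 10,000-replicate run — genuinely "more
than 80%", but so close to the boundary that a 1,000-replicate estimate
lands on either side of 0.80 depending on the seed.

## Known limitations

* One 2x2x2 table: no covariate adjustment, stratification, matching, or
  regression embedding of the contrast.
* Wald-type inference only, matching the original Z-test; no profile or
  bootstrap intervals (though bootstrap draws are available).
* The first-order variance understates the tail spread of the ratio
  statistics when cells are small (tens of subjects); see the bootstrap
  discussion above.
* The prevalence estimate must refer to the population the cases and
  controls were drawn from and to the same risk interval; a mismatched
  prevalence biases the absolute-odds reconstruction, though the
  sensitivity experiment shows the test tolerates a noisy estimate (a
  source as small as 1,000 barely moves the power).
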