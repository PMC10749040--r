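---
title: "Latent natal-sex models for race times: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent natal-sex models for race times: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical model the package implements, the
assumptions behind it, the parameters a user may want to tune, and the
design decisions taken where the problem left genuine freedom. It states no
empirical result that the test suite and the acceptance script do not
themselves compute.

## The problem

Race series that offer male, female and non-binary registration categories
record gender identity but not natal sex for the non-binary field. Comparing
natal-male and natal-female non-binary athletes therefore requires treating
natal sex as a partially observed binary covariate. The package's pipeline
has three stages: build a one-record-per-athlete dataset from many races;
attach to each athlete a probability of being natal male; fit log-time
linear models in which natal sex is latent with that known probability.

## The model and its estimator

For athlete $i$ let $S_i \in \{M, F\}$ be natal sex, with known
$P(S_i = M) = p_i$, and let $x_i(s)$ be the design row with the natal-sex
and natal-sex-dependent non-binary covariates evaluated at $s$. The model is

$$y_i \mid S_i = s \;\sim\; N\!\left(x_i(s)^\top \beta,\; \sigma^2\right),
\qquad y_i = \log(\text{time}_i),$$

with a single $\sigma$ shared across both components (one residual SD is
reported, matching standard practice for this model class). The marginal
likelihood is
$\prod_i \left[ p_i\, \phi(y_i; x_i(M)^\top\beta, \sigma^2) +
(1-p_i)\, \phi(y_i; x_i(F)^\top\beta, \sigma^2) \right]$;
records with $p_i \in \{0,1\}$ contribute a single Gaussian factor.

**Estimator.** EM with fractional-weight duplicated rows. The E-step
computes posterior male responsibilities
$r_i = p_i \phi_M / (p_i \phi_M + (1-p_i)\phi_F)$; the M-step is weighted
least squares on the stacked male/female completion rows with weights
$r_i$ and $1-r_i$, followed by $\hat\sigma^2 = \text{weighted SS}/n$.
Certain records enter the normal equations once, through a precomputed
cross-product, which makes repeated refits (the bootstrap below) cheap.
Because the M-step with no uncertain records is exactly ordinary least
squares, the estimator reduces to OLS when every $p_i$ is degenerate — the
test suite checks this against an independent `lm()` oracle to $10^{-8}$.
A direct quasi-Newton maximization of the marginal likelihood would be an
acceptable alternative; EM was chosen for its monotone log-likelihood
(asserted as a property test) and its exact degenerate reduction.

**Numerical choices.** Convergence is declared when successive marginal
log-likelihoods differ by less than $10^{-10}$ (default), with a 500
iteration cap; hitting the cap in a user-facing fit is an error. Columns
identically zero under *both* completions (e.g. `is_nb` when no athlete
registered non-binary) are dropped with a warning rather than producing a
singular system; genuinely rank-deficient designs raise a "singular design"
error. Age is centred at 40 before squaring; events are dummy-coded with
the alphabetically first event absorbed into the intercept.

**Model specifications.** `model_spec(1:4)` encode the four fitted
formulas: the sex term is latent natal sex in models 1, 3 and 4 and
declared gender identity in model 2; the non-binary term is the signed
`nb_predictor` (models 1 and 2), the pair `is_nbm + is_nbf` (model 3), or
`is_nb` (model 4). `nb_predictor` is $+1$ for natal-male non-binary
athletes, $-1$ for natal-female non-binary athletes, $0$ otherwise; only
terms involving natal sex differ between the two completion rows.

## Monte Carlo p-values

The error distribution of a coefficient in this mixture model is not the
classical one, so Wald inference is avoided. `monte_carlo_pvalues` runs a
parametric bootstrap under a plug-in null: the null parameter vector is the
fitted $\hat\beta$ with the tested term set to zero, together with
$\hat\sigma$. Each replicate draws $S_i \sim \text{Bernoulli}(p_i)$,
simulates $y_i^\ast = x_i(S_i)^\top \beta_0 + N(0, \hat\sigma^2)$, refits
the latent model, and records the term's estimate $\beta^\ast$. P-values use
the add-one estimator $(r+1)/(n_{\text{sims}}+1)$, which cannot be zero and
has resolution $1/(n_{\text{sims}}+1)$ — consistent with reporting
`0.0001` at $10^5$ samples. The one-tailed p counts exceedances in the
alternative's direction: by default the direction of the observed estimate,
or a pre-registered `"positive"`/`"negative"`.

Two deliberate choices: (i) the null simulation conditions on the observed
$p_i$ — names are not resimulated, because the probability model for sex is
treated as known throughout; (ii) bootstrap refits use a slightly looser EM
tolerance ($10^{-8}$) and keep the final iterate if a simulated dataset
hits the iteration cap (counted and reported as `n_nonconverged`) rather
than aborting a long p-value run; coefficient accuracy at that tolerance is
far below bootstrap noise. Calibration is verified by a
Kolmogorov–Smirnov uniformity test of the two-tailed p-values over 200
true-null replications.

## Sex probabilities from names

`assign_prob_male` applies a strict precedence: **declared** category
(male → 1, female → 0), then a partial **lookup** table of known sexes
(labels map to 1/0), then the **name model**, else the record is flagged
unassigned and excluded from fitting. The name model takes the athlete's
given name — the first whitespace-separated token of the case-folded,
accent-stripped full name — and returns the male share of US births with
that name, pooled over the two candidate birth years implied by race-day
age. Pooling uses raw count sums over the two years, not the mean of two
proportions: "the proportion of babies born in those two years" is a single
ratio of pooled counts, and the sum form is invariant to rescaling all
counts, which the test suite asserts. Absence of a name from both years is
a distinguished *unassigned* value, not a zero.

Athlete identity for deduplication and lookup matching is the normalized
*full* name; name-frequency matching uses the given name only. Whether a
real lookup source should be matched on full or given names is not
decidable here; full-name matching is the conservative choice and is the
one the synthetic lookup generator emulates.

`widen_uncertainty(p, ε) = (1-ε)p + ε/2` shrinks a probability linearly
toward 0.5 to absorb causes the birth registry cannot see (name changes,
immigration). The functional form of the original supplementary analysis is
not published; linear shrinkage with a single ε is the simplest
one-parameter family with the right fixed point and is exposed as the
`epsilon` pipeline parameter (default 0).

## Cross-race construction

Each event is calibrated against the marathon on athletes who ran both: a
no-intercept slope on all pairs, then a second slope on the
$\lceil 0.98 n \rceil$ pairs with the smallest $|\text{residual}|/\text{time}$.
Open choices, resolved as follows and parameterized where reasonable:

- **Trim ratio denominator**: the marathon time (the predicted quantity);
  the event-time denominator is selectable via `denominator = "event"`.
- **Correlation**: Pearson, computed on the *retained* pairs on the raw
  seconds scale; a log-scale option (`log_scale_cor`) mirrors the log-log
  diagnostic view.
- **Ceiling convention**: $\lceil 0.98 \times 78 \rceil = 77$ pairs kept,
  so a 78-pair event trims exactly one.
- **Ties** in marathon correlation break by larger shared-athlete count,
  then lexicographic event id.
- **Events sharing fewer than two athletes with the marathon** cannot be
  calibrated; their results are ineligible for selection and are counted in
  the build summary.
- **Duplicate results within one (athlete, event)** collapse to the fastest
  time before pairing and selection.

Per athlete, the record from the most marathon-correlated event is kept
(the marathon, correlation 1, always wins when run), then records with
predicted marathon time above 11 hours (39600 s, the marathon cut-off) are
discarded. Trimmed calibration pairs are *not* removed from the dataset —
trimming only affects slope estimation.

## Power analysis

`power_two_sample_t` uses the normal-quantile formula
$n_{\text{per group}} = \lceil 2((z_{1-\alpha}+z_{\text{power}})\,
\sigma/\delta)^2 \rceil$, because that formula reproduces the published
total of 138 at $\delta = 24.6$ min, $\sigma = 58$ min, 80% power,
one-tailed $\alpha = 0.05$; the exact noncentral-$t$ computation
(`method = "t"`, via `power.t.test`) is exposed behind a flag and gives a
slightly larger total.

## The synthetic world

The generator's defaults state one world and stay there:

- **Scale**: 85173 athletes, a fraction 166/85173 registering non-binary,
  two events per athlete (so total results ≈ 2.2 × unique athletes), all
  races in one calendar year. Tests use the smaller sizes their criteria
  state (500, 300, 5000), never retuned after seeing outcomes.
- **Coefficients**: natal-female offset 0.12224, age slope 0.00375/yr and
  curvature 0.00012/yr² at 40, non-binary offset 0.03225, residual SD 0.20
  of log time. The signed within-non-binary term `beta_nbp` defaults to 0,
  so hypothesis-test calibration runs under a true null.
- **Events**: 21, spanning 4 miles to the marathon, with log-mean times
  from a pace model of $540 + 4d$ seconds per mile at distance $d$ — a
  ~37 min 4-miler and a ~4 h 42 min marathon. At σ = 0.20 this implies a
  marathon SD of ≈ 56 min, consistent with the ≈ 58 min used in the power
  analysis.
- **Ages**: uniform integers on [18, 70]. Only the approximate mean age
  (≈ 40) of the real field is known; the uniform range is a declared
  choice, and its realized mean is 44, not 40 — the models centre age at 40
  regardless, which only shifts the intercept.
- **Birth years**: race year minus age, minus one more with a fair coin, so
  the two-candidate-year logic is genuinely exercised.
- **Names**: four categories — strongly male (share 0.995–0.999), strongly
  female, ambiguous (0.2–0.8), and rare names absent from ~40% of years.
  `exclusive = TRUE` makes the strong categories fully sex-specific, the
  stated world for tests that require name-determined sex. Surnames are
  de-duplicated so every synthetic athlete has a distinct identity key;
  real data would contain same-name collisions, which the pipeline resolves
  by assumption (same name ⇒ same athlete) — a known source of discarded
  records the synthetic world does not reproduce.

**What a green test establishes — and does not.** Recovery and calibration
tests show the estimator is unbiased and its p-values uniform *in this
world*: independent Gaussian log-time residuals, correct functional form,
name frequencies that truly generate the names, no repeated-measures
correlation, no course, weather or pacing effects, and no mislabelled
declared sexes. They do not validate the substantive conclusions of any
particular real-data analysis, and the acceptance targets that depend on
the proprietary source data (coefficient values, table counts) are out of
reach by design; only the self-contained published quantities (the power
total and effect-size conversions) are reproduced.

## Known limitations

- One record per athlete: within-athlete correlation across races is
  deliberately not modelled.
- The EM standard errors are not reported at all — inference is bootstrap
  only, as intended; users wanting Wald intervals must look elsewhere.
- The plug-in parametric bootstrap ignores estimation error in the
  nuisance coefficients of the null fit; its calibration is checked
  empirically rather than proved.
- Name-based probabilities inherit the US birth registry's coverage;
  athletes with names rare in it are excluded, which in a real analysis is
  a potential selection effect.
- The piecewise-linear age alternative is out of scope; the quadratic was
  reported to make no material difference in the motivating analysis.
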