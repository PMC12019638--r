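---
title: "Methods: the coupled Markov and macrosimulation model in depcare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled Markov and macrosimulation model in depcare}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcare)
```

`depcare` projects depressive-symptom prevalence and social-care costs in
an ageing population under housing-quality intervention scenarios. This
vignette documents the model, its assumptions, the tunable parameters, the
synthetic-data generator, and the numerical and design choices that were
genuinely open.

## Depression states and measurement

Depressive symptoms are measured with the 8-item CES-D: six negative
statements scored 1 for "yes" and two positive statements reverse-coded, so
the sum lies in 0–8. Severity bands are 0 = none, 1–2 = mild,
3–5 = moderate, 6–8 = severe. Person-waves with any missing CES-D item get
an explicit missing score and are excluded from estimation rather than
imputed; the instrument gives no guidance on part-missing batteries and
imputation machinery is out of scope. Functional difficulty has four
categories (none, IADL difficulties only, 1–2 ADL difficulties, 3+ ADL
difficulties) and care receipt is summarised as one of four modes (no care,
home care only, unpaid care only, both).

## The transition model

Severity at wave *T*+1 is regressed on wave-*T* covariates by multinomial
logistic regression with "none" as base outcome: number of housing problems
(raw count 0–12), current severity indicators, age (continuous), gender,
tenure, education, and equivalised weekly income. Waves are biennial, so
the fitted probabilities are two-year probabilities. Three points deserve
note:

* **Income enters per £/week unscaled.** The published relative-risk ratio
  of 0.99 per pound is taken at face value, which makes income a strong
  predictor across a realistic income distribution. The synthetic generator
  uses the same scale, so estimation and generation are consistent; users
  replacing the coefficients should keep the per-£ convention.
* **Annualization.** Two-year probabilities are converted with the
  constant-hazard formula `p1 = 1 − (1 − p2)^(1/2)`, applied element-wise
  to each off-diagonal (move) entry of a transition row; the stay entry is
  restored as the complement, and if the annualized moves exceed 1 they are
  rescaled proportionally (the stay probability becomes 0). The exact
  multi-state "half step" would be a matrix square root, which can produce
  negative or complex entries; the element-wise rule is an approximation
  whose behaviour is pinned down by an exactness property in the
  single-destination case: applying the annual stay/leave probabilities for
  two successive years reproduces the two-year leave probability to
  machine precision. Whether to renormalize after element-wise conversion
  was an open choice; proportional rescaling with a zero diagonal is the
  least-surprising rule and is exercised directly by the tests.
* **Materialized matrices.** Matrices are built per single year of age and
  gender. Age enters prediction continuously; tenure, education and income
  are held at their estimation-sample means, because scenario predictions
  are conditioned on age, gender and housing only. Housing enters as a
  stratum-level mixture: the living block of a row is the
  housing-distribution-weighted average of the annualized rows at each
  problem count, since a cohort model cannot carry individual housing
  histories.

Mortality is an absorbing state. The stratum's marginal annual death
probability comes from an age–gender schedule; differential mortality by
severity is a configuration input (default multipliers 1.0/1.1/1.3/1.6 for
none/mild/moderate/severe) normalized against the stratum's state shares so
that the share-weighted death probability equals the marginal rate. The
ordering within a year — death resolved first, then morbidity transitions
among survivors — is a modelling choice; the alternative ordering changes
entries by O(q·p) and nothing in the design identifies it.

## The cohort projection

The projection starts from base-year (2022) population counts by single
year of age 45–100+ and gender, split across severity states by baseline
prevalence shares. Each year every (age, gender) state vector is multiplied
by its 5×5 matrix, survivors advance one year of age, the open 100+ group
pools its survivors, deaths accumulate, and entrants are injected at the
youngest modelled age. Counts are real-valued expected values — no agents,
no stochastic rounding — so the accounting identity
`living(t+1) + new deaths = living(t) + entrants` holds to machine
precision and is asserted every year in the tests. Transition matrices are
time-constant (homogeneous-chain assumption); reported year-*Y* tables are
start-of-year stocks. Entrants at age 45 carry the base year's age-45 state
mix; people who "turn 65" inside the model therefore arrive with twenty
years of modelled history, which is why the model starts at 45 even though
reporting covers 65+.

## The macrosimulation

For each projection year the 65+ population is pooled into age bands
(65–69, ..., 85–89, 90+) and decomposed into cells by gender, functional
category and severity using a conditional functional-difficulty
distribution that is estimated (or configured) once in the base year and
held fixed: the projection moves people across severity states only, and
no generative law for the evolution of the functional mix is available.
Care-mode probabilities come from a cross-sectional multinomial model
(severity, age, gender, functional category; people 65+ only); a cell's
unpaid-care users are `count × (p(unpaid only) + p(both))` and analogously
for home care. Weekly hours come from linear models fitted on recipients
only — a two-part reading of the published design, where hours are
conditional on receipt — and are floored at zero, since least squares on
skewed hours can go negative at covariate extremes. Banded cells enter the
continuous-age models at band midpoints (92.5 for 90+). Annual hours are
weekly hours × 52.14; costs attach per-year unit costs.

Cost parameters: home care £23/hour in 2022; unpaid care valued at the same
£23 under the replacement-cost approach or £14.8 under the opportunity-cost
approach (the switch rescales unpaid costs by exactly 14.8/23 ≈ 0.64, about
36% lower). Unit costs are expressed in constant 2022 prices and follow a
real growth path — default 1.3% per year with a one-off 1.035 uplift at
2024 for the planned living-wage rise. The forecast rates behind the
published projections are not printed anywhere; the defaults are chosen so
that cumulative unit-cost growth over 2022–2042 (~34%) matches the growth
differential between published cost and user counts, and both are plain
config inputs. Cost tables exclude the symptom-free population by default
(the reported tables cover people *with* symptoms); a flag includes them.
Rounding (users to thousands, costs to £0.1bn) happens only in a separate
presentation output; totals are always computed pre-rounding.

## Scenarios and sensitivity analyses

A scenario is (housing cap, progression perturbation, effectiveness scale,
costing approach). Housing caps relocate all probability mass above the cap
onto the cap (∞ = no intervention). The accelerated/delayed progression
variants multiply worsening entries of every annual matrix by 1±0.05 and
improving entries by 1∓0.05, leaving the death column untouched and
restoring the diagonal; "5% larger" is read multiplicatively, not as
percentage points. Effectiveness scaling interpolates entry-wise between
the base and scenario matrices (`base + f·(scenario − base)`), clipped and
re-diagonalized, so f = 1.05 and 0.95 bracket the estimated intervention
effect. Perturbations are applied to annual (post-conversion)
probabilities.

Monte Carlo credible intervals redraw every regression coefficient
independently from a normal on its estimation scale (log-RRR or linear)
using the stored standard errors, rerun the full pipeline, and report the
2.5th/97.5th percentiles over draws (default 1,000). Published tables print
standard errors but no covariance, so independence is an approximation
that can widen or narrow intervals relative to the unknown joint; it is
documented rather than hidden. Each draw gets a deterministic substream
derived from the master seed and draw index, making results reproducible
and order-invariant. Intervals are computed for both costs and prevalence
measures, since nothing restricts the uncertainty propagation to one of
them.

## The synthetic cohort generator

The generator emulates a biennial ageing panel: wave-1 marginals (female
share 0.552, rented 0.160, education 0.378/0.309/0.313, lognormal income
with mean £392/week, ages 50+ centred near 67), housing-problem shares
0.717/0.182/0.063/0.038 on 0/1/2/3+ (the 3+ band expands onto 3–12 with a
truncated geometric tail), and baseline severity shares
0.480/0.319/0.143/0.058. Severity then evolves by the same
multinomial-logit law the estimator assumes, with the published
relative-risk ratios as generating truth; Gompertz mortality
(male a = 1.74e-5, b = 0.099; female a = 6.6e-6, b = 0.107, giving
UK-plausible death rates) and 12% per-wave missing-at-random attrition thin
the panel; care modes and hours follow the published care coefficients for
members aged 65+.

Choices worth flagging:

* **Intercepts are calibrated, not published.** Transition intercepts are
  solved (deterministically, at config construction) so that the
  mean-profile chain's stationary distribution equals the baseline severity
  shares — the operational meaning of "reproduce wave-6-like prevalence".
  Care-mode intercepts are solved so population-weighted 65+ mode shares
  are survey-like (about 20% unpaid-care users and 3.8% home-care users);
  hours intercepts set reference weekly hours of 8 (home) and 10 (unpaid)
  at age 65 for a symptom-free man without functional difficulties.
* **Housing problems are fixed within person.** The panel models housing as
  a lagged covariate but says nothing about its within-person dynamics;
  a fixed count is the simplest structure consistent with stable marginals
  across waves, and it is flagged here as an assumption.
* **CES-D items are generated state-first**: the state is drawn, a score is
  drawn uniformly inside the state's band, and items consistent with the
  score are drawn. Items exist to exercise the scoring path, not as a
  latent measurement model.
* **Functional difficulty is drawn conditional on severity** from a 4×4
  table (worse symptoms, worse function); the association direction is
  supported by the care regressions but the exact law is a generator
  default.
* **Attrition is missing-at-random** and state-independent. Real panel
  attrition is unlikely to be MAR; passing recovery tests on this generator
  therefore demonstrates correctness of the estimators under the assumed
  law, not robustness to informative dropout, survey weighting, household
  clustering or measurement error — none of which the generator attempts.

All randomness flows from the single config seed; identical config and
seed give byte-identical output.

## Numerical choices and degenerate inputs

Probability vectors are validated to sum to 1 within 1e-9; materialized
matrices are asserted row-stochastic at machine tolerance. Softmax
computations subtract the row maximum before exponentiating. Annualization
rescaling, perturbation overflow and effectiveness clipping all renormalize
proportionally and (for perturbation) warn. Zero populations, zero
mortality, zero standard errors, empty age bands and horizon-zero
projections are all defined and tested rather than rejected. Quantiles use
the default type-7 estimator.

## Problem sizes used by the tests

Parameter-recovery checks run at 50,000 individuals over 5 seeds for the
transition model (with two waves, one transition pair per person — the
regression's unit) and 50,000/20,000-person cross-sections for the care
models; these sizes make the published-coefficient tolerances a 2–3 sigma
event rather than a coin flip. Monte Carlo coverage is checked at 1,000
draws against closed-form Gaussian propagation on a pipeline that is linear
in a single uncertain coefficient. Projection, conservation and scenario
properties run on small deterministic worlds where hand-computed replicas
are feasible.

## Known limitations

* No care-home or health-care costs; no discounting; no nominal-price
  series; no migration; no survey weights.
* Time-constant transition probabilities and first-order Markov dynamics
  are maintained assumptions.
* The element-wise annualization and the independent-normal coefficient
  draws are documented approximations.
* Absolute cost levels depend on the synthetic population scale and the
  calibrated intercepts; scenario *differences*, growth rates and the
  costing-approach ratio are the quantities with structural meaning.
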