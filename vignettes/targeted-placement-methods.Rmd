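---
title: "Targeted kidney placement: labeling rules, endogenous-treatment models and in-silico experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted kidney placement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kidneytp)
```

## The problem

When a deceased-donor kidney becomes available, candidates are ranked in a
strict priority sequence and higher-ranked candidates hold the right of first
refusal. Transplant programs nevertheless often place kidneys with
lower-ranked candidates ("list diving"). Some of these out-of-sequence
placements are deliberate: the program simultaneously declines a batch of
higher-ranked candidates — identical response codes with identical
timestamps, a *batch turn down* (BTD) — at or after the moment it accepts
for a lower-ranked candidate. `kidneytp` identifies these *targeted
placements* (TPs) from timestamped match-run records, and estimates their
causal effect on one-year patient-and-graft survival while treating the
targeting decision as endogenous: programs choose whom to target using
judgment that is invisible in registry data and plausibly correlated with
survival risk.

Because the real national registry extracts are restricted-access, the
package ships a synthetic match-run generator with full ground truth; every
statistical claim the test suite makes is a claim about recovery of known
generating parameters or agreement with an independent oracle, not about
real patients.

## Labeling rules

A transplanted kidney is labeled TP when three criteria hold at the
recipient's program within the match run:

1. at least 5 candidates at that program received an initial response
   (Y = accept, N = decline, Z = provisional yes);
2. at least `threshold` (default 4; 3 and 5 as robustness variants)
   higher-ranked candidates share one initial code, "N" or "Z", *and* one
   initial timestamp;
3. that shared timestamp is at or after the recipient's initial response
   time.

Three response patterns then assign the rule:

* **Rule 1** — the batch code is "N"; the recipient responded "Y" or "Z".
* **Rule 2** — the batch code is "Z"; the recipient responded "Y", or "Z"
  finalized at the same minute.
* **Rule 3** — batch and recipient both "Z", and the batch members'
  final responses came after the recipient's final response or on/after the
  transplant day.

Numerical conventions the source rules leave open, fixed here:

* *"Same time" means equal at minute resolution.* Registry response stamps
  carry minute precision; all equality and ordering comparisons floor to
  the minute.
* *Precedence is 1 → 2 → 3, first match wins* (configurable via
  `rule_order`). Overlaps exist — a "Z" batch with a recipient "Z"
  finalized instantly satisfies both Rule 2 and potentially Rule 3 — and
  disjoint rule counts require a precedence.
* *Rule 3's final-time condition is evaluated per batch member*, and the
  batch qualifies if at least `threshold` members pass. This makes the
  labeler exactly equivalent to a brute-force enumeration over candidate
  subsets, which the test suite verifies on thousands of random groups.
* *A batch member whose decline was never finalized* (missing final
  timestamp) counts as satisfying the final-time condition: a response
  still open at transplant time cannot have preceded the recipient's final
  response.
* When several batches qualify under the matched rule, the largest is
  recorded (earliest on ties) as the BTD event.

BTD membership is defined only through events attached to a labeled TP;
simultaneous declines that were never followed by a targeted acceptance are
not collected. Candidates skipped in such unlabeled events are therefore
missed, mirroring the construction the labeling rules imply.

## The synthetic generator

`simulate_cohort()` emulates the structure of match-run extracts: donors
with KDPI (donor quality percentile, higher = worse) positively associated
with age; candidates with EPTS (expected post-transplant survival
percentile) assigned to programs within donation service areas; and one
match run per donor kidney. For each transplant pair the generator draws a
bivariate-normal disturbance pair `(xi, eps)` with correlation `rho` and
realizes

* treatment: `TP = 1[a0 + a_age*age + a_kdpi*KDPI + a_epts*EPTS + xi > 0]`,
* survival: `Y = 1[b0 + b1*TP + b'W + eps > 0]`,

so the targeting indicator is endogenous exactly when `rho != 0`. A
targeted pair's match run embeds a batch of identical-code,
identical-timestamp declines above the recipient following one of the three
rules; a non-targeted pair is accepted near the top of its list with
strictly distinct decline timestamps, so it can never satisfy criterion
(2). With no timestamp jitter, the labeler therefore recovers the true
flags exactly; jitter (minutes of Gaussian noise on batch member stamps)
breaks timestamp ties and degrades recall monotonically.

Default parameter choices, fixed once:

* Propensity slopes (age 0.026/yr, KDPI 0.395, EPTS −0.613) are the
  magnitudes characteristic of observed targeted utilization; the intercept
  −2.70 puts the targeted share near 7% of transplants. The outcome
  intercept 2.8 puts marginal one-year survival near 94%.
* `rho` defaults to −0.05, a small negative error correlation of the size
  estimated in practice.
* Rule mixture defaults to (0.145, 0.078, 0.777), the observed composition
  of rule-1/2/3 labels.
* Batch sizes 4–8 with decaying weights; mean KDPI 0.43; cold ischemia
  ~20 h for targeted vs ~16.3 h for in-sequence transplants.
* Response-latency distributions are not documented anywhere, so offsets
  (batch 0–120 min after the acceptance, finals 30 min–10 h later) are
  arbitrary but harmless: the labeling rules depend only on orderings and
  ties, which are generated exactly.
* Bypass-resolved runs, pediatric donors/candidates, dual and multi-organ
  transplants, open offers, stale provisional-yes codes and refusal codes
  (801, free text, other numeric) are injected at configurable rates solely
  to exercise the preparation chain.

What the generator does **not** emulate: real allocation point systems (the
priority order is exogenous), organ discards, competing offers across
donors, waitlist deterioration, or any dependence of the targeting decision
on program market share. Passing tests demonstrate correctness of the
algorithms under the stated model, not fidelity to OPTN data.

## Cohort preparation

The preparation chain reconstructs registry cleaning as seven ordered,
individually toggleable steps: date window; pediatric (< 18 years — the
conventional cutoff, as "pediatric" is otherwise undefined) donors and
recipients; dual-kidney transplants; multi-organ transplants; match runs
resolved by a bypass ("B") action; open-offer placements; and atypical
records (timestamp inversions, acceptances never transplanted). Each step
logs in/out counts; the log telescopes and the chain is idempotent. A
terminal "Z" on a transplanted offer is first reinterpreted as "Y"
(`normalize_responses()`), since the code was simply never updated. The
refusal-code filter (`filter_refusal_801()`) — dropping declines coded 801
or free text — is a robustness variant applied before labeling.

## Estimation

**Endogenous-treatment probit.** The central estimator is the two-equation
threshold-crossing model above, fit by full-information maximum likelihood:
each observation contributes `log Phi2(q_t * w'alpha, q_y * x'beta, q_t *
q_y * rho)` with sign flips `q = 2*indicator − 1`. The bivariate normal CDF
is evaluated by Gauss–Legendre quadrature of the bivariate density over the
correlation (order 24, ~1e-11 absolute error), vectorized over
observations, with analytic gradients; `rho` is optimized on the `atanh`
scale and standard errors come from the numerically differentiated Hessian
of the analytic gradient. The likelihood factorizes into two independent
probits at `rho = 0`, which the tests assert. A two-step control-function
variant (treatment-equation generalized residual inserted into the outcome
probit) is provided; FIML is the default because it delivers `rho` and the
ATE in one consistent fit. The ATE is averaged on the probability scale:
`mean[pnorm(x'b + b1) − pnorm(x'b)]`.

*Identification caveat.* The model carries no exclusion restriction — the
treatment-equation covariates all appear in the outcome equation — so
`(b1, rho)` are identified only through functional form. When the
propensity index barely varies (as under the default, observation-scale
slopes), the likelihood has a long flat ridge in `(b1, rho)` and the MLE
can sit far from the truth at realistic sample sizes, with correspondingly
enormous standard errors. This is a property of the model, not the
optimizer. The package's parameter-recovery studies therefore use a
propensity with adequate index variation (intercept −6.5, age 0.10, KDPI
1.2, EPTS −1.5; ~14% treated), under which nominal 95% confidence
intervals attain their coverage.

**Instrumental variable.** The market-share instrument is each program's
share of its donation service area's transplant volume over the previous
three calendar months, constant within a program-month; the first three
data months and observations without a defined instrument are dropped.
Step 1 regresses the treatment on the instrument by probit (instrument-only
by default — the published first stage reports only the instrument row —
with an option to add controls); step 2 regresses the outcome on the
predicted treatment probability plus controls. Relevance (step-1 z, weak
below 2) and exclusion (instrument coefficient in a survival probit) are
checked, and the step-2 treatment SE comes from a nonparametric bootstrap
because the predicted treatment is a generated regressor.

**Double machine learning.** `crossfit_plm()` implements the partially
linear model via the Robinson partialling-out score with K-fold
cross-fitting (default 4 folds, seeded permutation): nuisance regressions
of outcome and treatment on controls are fit on fold complements,
`theta` solves the residual-on-residual moment, and the SE comes from the
influence-function variance. `crossfit_plm_iv()` residualizes outcome,
treatment and the single continuous instrument, then applies the IV moment
on residuals, with a weak-instrument error when the residual
instrument–treatment covariance is indistinguishable from zero (|t| < 2).
The partialling-out score (not the interactive score) matches a model
without interaction terms, and a binary outcome is handled on the
linear-probability scale, so `theta` is itself the ATE. Learners are
penalized linear (glmnet, default, deterministic), random forest (ranger)
and gradient boosting (xgboost), all with fixed hyperparameters for
reproducibility.

## In-silico experiments

**Counterfactual for targeted recipients.** A survival probit *without*
the treatment indicator is fit to recipients (all recipients by default;
the fit population is toggleable to NTP-only since the source description
is ambiguous). Each TP recipient is matched to NTP recipients at the same
program, in the same EPTS vigintile (20 equal-probability bins of the
pooled recipient EPTS distribution), with longer waiting time; predicted
survival is re-evaluated substituting the matched sets' average KDPI and
waiting time, all other covariates held at observed values. A paired
t-test compares current and counterfactual predictions; recipients without
matches are counted and excluded.

**Missed opportunities for skipped candidates.** A survival probit with a
BTD-exposure indicator is fit on all recipients — fitting on BTD
recipients alone would leave the indicator's coefficient unidentified,
since it equals one for every row of that subset; because the indicator
takes the recipient's own value in both the accepted and hypothetical
predictions, it cancels from every comparison. For each BTD recipient,
each earlier skipped offer is scored by substituting that donor's KDPI and
the waiting time implied by the offer date; a recipient counts as having a
missed opportunity when at least one earlier offer predicts survival at
least as high as the accepted transplant (ties count). Lead time uses
30.44 days per month. Excluding justified refusals (code 801/free-text)
can only remove dominating offers, so the count is monotone under
exclusion — asserted in the tests.

**Placebo.** Per replicate, as many transplants as the true TP count are
relabeled pseudo-TP uniformly at random and the exogenous (and optionally
endogenous) models are refit; under the null the pseudo-treatment
coefficient should be nonsignificant and the treatment-equation covariates
uninformative. Replicate seeds derive from one master seed, so runs replay
exactly.

## Problem sizes and numerical choices

The shipped test suite and acceptance script run everything at sizes chosen
to make Monte-Carlo conclusions stable on a single CPU: labeling oracle
agreement on 1,000 random groups; perfect-recovery and monotonicity checks
on cohorts of 500–600 donors; endogenous-treatment coverage on 20 cohorts
of 20,000 transplants; DML recovery at n = 5,000–8,000; placebo calibration
over 10 master seeds of 5 replicates at n = 3,000; descriptive type-I
calibration over 200 null replicates. Optimizer settings (BFGS, relative
tolerance 1e-10, analytic gradients, starts at the single-equation probit
estimates with `rho = 0`) are fixed; `|rho| > 0.99` is flagged as a
boundary fit.

## Known limitations

* The seven preparation steps reconstruct named exclusions; the original
  cleaning protocol is not public, so counts on real data would differ.
* BTD events not followed by a labeled TP are invisible, understating BTD
  candidate exposure.
* Without an exclusion restriction the endogenous-treatment model is
  weakly identified at realistic signal strength (above); IV and DML
  results are the more robust companions.
* The generator's priority order is exogenous; questions that hinge on the
  allocation mechanism itself are outside scope.
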