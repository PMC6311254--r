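---
title: "Selecting survival-predictive lncRNA transcripts with mlrldacp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting survival-predictive lncRNA transcripts with mlrldacp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlrldacp)
```

## The model

`mlrldacp` models the clinical survival time of tumor patients as an
ordinary linear function of the expression of a small subset of long
noncoding RNA (lncRNA) transcripts:

$$ La_i \;=\; \Theta_0 + \sum_{j \in S} \Theta_j \, g_{i \sim j} + \varepsilon_i, $$

where $La_i$ is patient $i$'s survival response in days (days to death for
deceased patients, days to last follow-up for living ones), $g_{i \sim j}$
is the expression quantity of transcript $j$ in sample $i$, $S$ is the
selected transcript subset of size $\Delta$, and $\Theta$ is the fitted
coefficient vector (days of survival per expression unit).  The fitted
$\Theta$ serves two purposes: predicting survival for new expression
profiles, and scoring each lncRNA's association with the disease.

Two modeling simplifications are deliberate and inherited from the method's
design:

* **No censoring model.** For living patients the follow-up time is used
  directly as the response.  This makes $La$ a plain regression target but
  biases it downward for heavily censored cohorts; the package's scope is
  this regression formulation, not proportional-hazards modeling.
* **Gaussian errors, linear effects.** The final fit and the AIC used
  throughout the search assume homoscedastic Gaussian noise on the raw
  day scale.

## The selection procedure

The search space is a binary inclusion vector $X$ over candidate
transcripts that pass a differential-expression screen (normal vs. tumor,
two-sided Welch $t$ test, retained when raw $P < 10^{-3}$, ordered by
ascending $P$; ties are broken by transcript ID so the ordering is total).
Position $j$ of $X$ corresponds to the $j$-th most significant candidate.

Starting from a seed $X^0$ that activates every candidate with
$P < 10^{-12}$ (the retention cap $\theta$ is set to the seed's population
count), the search runs $D = 10$ iterations of three deterministic steps:

1. **Windowed bitwise inversion** (the $\Gamma$ operation).  At iteration
   $d$, all bits inside the window centred at
   $Center(d) = C/2 + (C/D)\,(-1)^{d-1}\lfloor d/2\rfloor$ (and $C/2$ at
   $d = 1$) with half-width $\xi(d)\,C/2$ are flipped.  The decay
   coefficient $\xi(d) = \tanh\!\big(2(D-d)/(D+1)\big)$ shrinks from
   $\approx 0.93$ at $d = 1$ to a hard floor of exactly $0.1$ at the final
   iteration: wide exploratory flips early, narrow refinements late.  The
   centers alternate symmetrically around the midpoint so that every
   position falls under some window during a run.  Window endpoints are
   rounded to the nearest integer before clipping to $[1, C]$ — necessary
   because $C/2$ is fractional for odd $C$ — and a window that clips to
   empty skips the iteration rather than aborting.
2. **Stagnation kick and correction.**  If the leading $\theta$ bits are
   unchanged from the previous iteration's vector, they are flipped to
   force the search out of a stalled configuration.  A $\Gamma$ correction
   then caps the active set at $\theta$ bits, keeping the smallest-index
   (most significant) ones.
3. **Stepwise-AIC reduction.**  The active set is reduced by a
   bidirectional stepwise loop: a forward phase repeatedly adds the
   candidate whose inclusion most decreases the Gaussian AIC
   ($n\ln(2\pi\,RSS/n) + n + 2(k+2)$, the same convention as
   `stats::AIC` on an `lm` fit), a backward phase repeatedly removes the
   component whose exclusion most decreases it, and two flags — one per
   direction, each reset by the other direction's success — terminate the
   loop only when both directions stall.  Every accepted move strictly
   decreases the AIC, which guarantees termination and, together with
   smallest-index tie-breaking, determinism.

A best-so-far *bulletin board* records the reduced set with the lowest AIC
seen.  Stepwise results never overwrite the vector the $\Gamma$ operation
acts on — only the bulletin board — so the variation trajectory and the
model-quality bookkeeping are decoupled.  After $D$ iterations the winning
subset is refitted by OLS, giving $\Theta$, the residual standard error on
$n - \Delta - 1$ degrees of freedom, and the overall $F$-test $P$ value.

### Design choices where the procedure was underdetermined

* **"Significant effect" in the stepwise loop** is operationalised as
  "strictly decreases AIC", applied best-first one component per pass.
  AIC is the procedure's only stated quality measure, which makes
  AIC-greedy the internally consistent reading; on orthogonal designs it
  provably attains the exhaustive best-subset optimum, which the test
  suite verifies.
* **Retention in the $\Gamma$ correction** keeps the smallest-index
  one-bits.  Positions are $P$-ranked, so this reads "top $\theta$" as
  "most significant $\theta$" and exactly reproduces the documented
  two-round worked trace from a 107-bit seed on a 481-long vector.
* **The stagnation comparison** uses positions $1 \ldots \theta$ against
  the previous iteration's post-correction vector, and is active from the
  first iteration (where the partner is the seed $X^0$).
* **The decay schedule** is $\tanh\!\big(2(D-d)/(D+1)\big)$ by default;
  this satisfies both published anchors (close to 1 at $d = 1$, exactly
  0.1 at the end).  A gentler $\tanh\!\big(0.75 (D-d)/(D+1)\big)$ variant
  and an explicit per-iteration lookup are selectable through
  `gamma_config()` / `decay_coefficient()`, because no single closed form
  is consistent with every documented iteration window.
* **The screen statistic** is Welch's $t$ by default (a conservative
  choice for unequal group sizes and variances), with a Wilcoxon
  rank-sum alternative.  No multiple-testing correction is applied: the
  candidate list is defined by the raw $P < 10^{-3}$ filter, and the
  downstream search is itself the guard against spurious candidates.  A
  transcript with zero variance in both groups gets $P = 1$ when the
  group means agree (it carries no signal) and $P = 0$ when they differ
  (the $t$ statistic diverges).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `alpha` | $10^{-3}$ | raw $P$ | screen retention threshold |
| `init_threshold` | $10^{-12}$ | raw $P$ | seeds $X^0$; $\theta$ = seed size |
| `D` | 10 | iterations | variation budget; the $\xi$ floor binds at $d = D$ |
| `schedule` | `"tanh"` | — | decay-coefficient parameterisation |
| `horizon` | 1825 | days | fixed-horizon (5-year) survival ROC |

If no candidate reaches `init_threshold`, the seed falls back to the
$\max(10, \lceil C/10\rceil)$ smallest-$P$ candidates with a warning — an
empty seed would make $\theta = 0$ and stall the entire search.

## Evaluation harnesses

* **Survival ROC.**  Patients are labelled by their status at a fixed
  horizon (dead within the horizon = positive; observed event-free beyond
  it = negative).  Living patients whose follow-up ends inside the horizon
  are indeterminate at that horizon and are excluded — a fixed-horizon
  binary label is simply undefined for them.  The score is the negated
  predicted survival time.  AUC is computed by the trapezoid rule over all
  distinct thresholds, which makes it exactly the Mann–Whitney probability
  that a random positive outscores a random negative (ties count ½); the
  tests assert this identity to $10^{-12}$ and cross-check against an
  independent ROC implementation.
* **Association LOOCV.**  Each known lncRNA–disease pair is withheld in
  turn; the scorer ranks it against all never-known candidate pairs, and
  the pooled scores give one ROC/AUC.  How a fitted survival regression
  becomes an association score is the method's main interpretive gap, so
  the scorer is a pluggable function; the default
  (`model_association_scorer()`) uses the absolute standardised
  coefficient $|\Theta_j| \cdot \mathrm{sd}(g_j)$ — the effect of one
  standard deviation of expression on predicted survival — with 0 for
  unselected transcripts.

## The synthetic cohort generator

Real cohorts of matched expression + clinical exports are not shippable,
so `generate_cohort()` produces data with exactly the structure the
pipeline assumes: log-normal expression (meanlog 1, sdlog 0.5 — positive,
right-skewed, RPKM-like), an additive group mean shift on a planted
differential subset, and tumor survival generated as a sparse linear
combination of a causal subset (causal $\subseteq$ differential) plus
Gaussian noise, floored at 1 day.  Default shape mirrors a
prostate-cancer-sized study: 44 normal / 176 tumor samples, 600
transcripts, 481 differential.  Default effect choices — intercept 2000
days, coefficient magnitudes 50–150 days per expression unit with
alternating signs, noise SD 100 days, 40% of patients alive — give
survival times spanning a few years with a clearly recoverable but not
trivial signal.  Censoring status is assigned independently of survival
time, matching the regression's own treatment of follow-up as a plain
response.

What the generator does **not** emulate: transcript–transcript
correlation, batch or library-size effects, informative censoring, and
heavy-tailed expression noise.  Passing the parameter-recovery tests
therefore shows the machinery is correct under the model's own
assumptions, not that the method is robust on real cohorts.

## Problem sizes and numerical choices

The test suite and examples run the full pipeline on a scaled cohort of
120 tumor / 40 normal samples with 150 transcripts (30 differential, 5
causal, effect size 5, noise SD 10) — large enough that every causal
transcript is ultra-significant in the screen (the "strong signal" regime
where recovery is the correct expectation) and small enough that the
whole suite runs in seconds.  Parameter-recovery assertions use a fixed
seed; the coefficient check (within 3 standard errors of truth) is a
statistical property with a per-coefficient tail probability of ~0.3%,
so occasional honest exceedances exist at other seeds.

Other numerical conventions: OLS is fitted by QR with pivoting, and
collinear columns are dropped (with their IDs recorded) rather than
propagating `NA` coefficients; residual orthogonality of the final fit is
tested to a relative $10^{-8}$; an exact fit drives the AIC to $-\infty$,
which the comparison logic tolerates; numbers in emitted TSVs are
serialised with 17 significant digits so write/read round-trips are exact.

## Known limitations

* The survival response ignores censoring; predicted "survival" for
  heavily censored cohorts is really a mixture of death and follow-up
  times.
* The variation operator is deterministic and greedy; it explores a tiny
  fraction of the $2^C$ subsets and offers no optimality guarantee beyond
  the bulletin board's monotonicity.
* AIC-greedy stepwise can retain a spurious component when candidates are
  correlated (on orthogonal designs it is provably optimal; the general
  case is only bracketed by the exhaustive range, as the tests document).
* Association scoring from a single fitted regression cannot distinguish
  correlated co-selected transcripts; the LOOCV harness measures ranking
  quality, not causality.
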