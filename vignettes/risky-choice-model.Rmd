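---
title: "Modelling gain-loss asymmetry in risky lottery choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gain-loss asymmetry in risky lottery choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and its design space

The package analyses binary choices between two-outcome token lotteries.
A lottery pays a non-zero integer amount $x \in \{\pm 1, \pm 2, \pm 3\}$
(tokens) with probability $p \in \{0.25, 0.5, 0.75, 1\}$ and nothing
otherwise. The subject starts every trial with a 3-token stock, so
negative amounts are losses relative to that reference point rather than
absolute deprivation: the end-of-trial gauge is $3 + x_{\text{realized}}$
tokens in $[0, 6]$, rewarded at 100 water units per token ($[0, 600]$).

Pairs of lotteries fall into seven types. Types 1–5 contain a first-order
stochastically dominant member (they probe discrimination of sign,
magnitude and probability); types 6 (gains) and 7 (losses) oppose a
riskier member — larger $|x|$, smaller $p$ — to a safer one with no
dominance, and only these two types inform the risk-attitude model.
`classify_pair()` canonicalizes each pair before testing the defining
inequalities: the first member is the dominant one for types 1–5 and the
riskier one for types 6/7, because the choice model indexes the risky
option first. Full factorial enumeration over the grids gives 36, 12, 12,
18, 18, 18, 18 pairs for types 1–7. The published design lists 12 pairs
for type 4 where the factorial grid has 18; since the subset actually
used is not recoverable, `design_table()` returns the factorial 18 and
records the discrepancy in a note attribute instead of silently dropping
pairs.

## The decision model

Amounts are normalized by the maximal absolute amount, $x/3 \in [-1, 1]$
(the divisor is a package choice; the model is stated on a normalized
scale without naming one). Three ingredients per outcome domain:

* **Utility.** $u(x) = x^{1-\omega_G}$ for gains,
  $u(x) = -|x|^{1+\omega_L}$ for losses, $u(0) = 0$, with
  $\omega_G, \omega_L \in [-1, 1]$. Positive $\omega_G$ bends the gain
  branch concave (risk aversion); negative $\omega_L$ bends the loss
  branch convex (risk seeking for losses). Note the exponent asymmetry:
  both conventions make larger $\omega$ mean "more risk-averse" in its
  own domain.
* **Probability weighting.** The one-parameter Prelec form
  $w(p) = \exp(-(-\ln p)^\alpha)$, $\alpha \in (0, 1]$: the identity at
  $\alpha = 1$, increasingly inverse-S-shaped as $\alpha \to 0$, fixed
  point at $1/e$, and $w(1) = 1$ exactly — degenerate $p = 1$ lotteries
  pass through with no epsilon.
* **Stochastic choice.** A direct softmax over subjective values
  $U(L) = w(p)\,u(x/3)$ can reverse preferences non-monotonically in
  $\omega$, so the choice rule instead works through the pair's
  *indifference point* $\omega^*$: the risk attitude at which the two
  members have equal subjective value. Then
  $P(\text{risky}) = \text{logistic}(\lambda(\omega^* - \omega))$ with
  precision $\lambda > 0$. This is monotone decreasing in $\omega$ by
  construction and crosses $1/2$ exactly at $\omega = \omega^*$.

$\omega^*$ has a closed form because amounts enter as a ratio: for gains
$\omega^* = 1 - \ln(w(p_2)/w(p_1)) / \ln(x_1/x_2)$, for losses
$\omega^* = \ln(w(p_2)/w(p_1)) / \ln(|x_1|/|x_2|) - 1$. Two choices are
deliberate here. First, the indifference point is computed under the
*distorted* probabilities $w(p;\alpha)$ of the pair's own domain —
indifference should be defined under the same valuation that prices the
lotteries — with a `probabilities = "raw"` switch for the undistorted
alternative, since the original description leaves this open. Second,
$\omega^*$ is returned unclamped even when it falls outside $[-1, 1]$:
the logistic remains well-defined for any real argument, and clamping
would distort likelihoods near the box edge.

## Likelihood and fitting

Risky-pair trials are aggregated per distinct pair into counts
$(n_i, k_i)$ of trials and risky choices. The model likelihood is the
product of binomial masses with $p_i$ the model's risky-choice
probability; the binomial coefficient is included so reported
log-likelihoods are comparable across aggregation granularities. All
probability arithmetic is done in log space
(`plogis(z, log.p = TRUE)`), so extreme precisions produce harsh finite
penalties rather than `NaN`.

`fit_mle()` maximizes the log-likelihood over the box with `L-BFGS-B`
from a deterministic $2 \times 2 \times 2$ grid of starting points
($\omega \in \{-0.5, 0.5\}$, $\alpha \in \{0.3, 0.8\}$,
$\lambda \in \{0.5, 5\}$). $\lambda$ is searched on $\log \lambda$ with
box $[10^{-3}, 10^3]$ as a well-conditioned proxy for $(0, \infty)$, and
the open $\alpha$ bound is proxied by $10^{-6}$. Gain (type 6) and loss
(type 7) parameters enter disjoint likelihood terms, so the joint fit
separates exactly into two 3-parameter problems — the test suite asserts
this equivalence. A domain with no pairs yields `NA` estimates; a domain
with a single distinct pair is fitted but flagged under-identified
(one binomial frequency cannot pin three parameters).

`chunked_fit()` implements the stability check used in this paradigm:
trials are ordered chronologically, split into 20 contiguous near-equal
chunks (remainder spread over the first chunks), fitted independently,
and summarised by the per-chunk mean and standard deviation of each
parameter.

## Descriptive and inferential analyses

* **Certainty-risk contrast** (`certainty_risk_test()`): 2×2 chi-square
  on domain × (risky, safe) counts for the two certainty pairs (±1 for
  sure vs ±2 half the time), one degree of freedom, no Yates correction —
  the counts involved are large and the original analysis names no
  correction.
* **Dominance performance** (`dominance_performance()`): per-pair
  frequency of choosing the dominant member; per-type median, quartiles
  and 1.5·IQR whiskers.
* **EV-difference sigmoid** (`fit_risk_sigmoid()`):
  $f(\Delta) = 1/(1+e^{-\beta(\Delta-\gamma)})$ fitted per domain to
  per-pair risky-choice frequencies by Levenberg–Marquardt
  (`minpack.lm::nls.lm` with an analytic Jacobian). $\Delta$ is the
  expected-value difference riskier-minus-safer in *token* units — the
  analysis is model-free and lives on the task's own scale. Points are
  weighted by trial counts by default (an unweighted mode exists; the
  original is silent). Margins are Wald intervals from
  $\hat\sigma^2 (J^\top W J)^{-1}$ at the 0.01 level.
* **Gain-vs-loss contrasts** (`compare_gain_loss_params()`):
  two-sided Mann–Whitney U on the 20 gain-domain vs 20 loss-domain
  per-chunk values for each family ($\omega$, $\alpha$, $\lambda$),
  normal approximation with tie-corrected variance and no continuity
  correction, Bonferroni multiplicity $m = 3$ (the three families
  compared per subject). The reported `u` is the classical
  $\min(U_1, U_2)$. An exact enumeration mode backs the approximation
  in the test suite.
* **Temporal trend** (`parameter_trend()`): OLS of the per-chunk values
  on chunk index with the F test of the slope; a constant series reports
  an undefined F rather than an error.

## The synthetic subject

`agent_spec()` + `build_schedule()` + `simulate_agent()` generate trial
tables with the statistical structure the analysis assumes. The defaults
*are* the study conditions: 151 daily sessions with trial counts drawn
from a truncated normal (mean 195.07, sd 102.42, floored at one trial);
pairs sampled uniformly over the design (a weight table is available —
whether the real schedule balanced pair frequencies per session is not
documented); model parameters set to the published Monkey-H means
($\omega_G = 0.28$, $\omega_L = -0.71$, $\alpha_G = 0.63$,
$\alpha_L = 0.21$, $\lambda_G = 2.52$, $\lambda_L = 1.82$). Dominance
pairs are answered with a per-type Bernoulli accuracy — the
indifference-point choice rule is defined only for risky-vs-safe pairs,
so an error-rate model is the honest extension. The default accuracies
(0.97, 0.90, 0.62, 0.92, 0.85 for types 1–5) mimic the reported
qualitative pattern, in particular the markedly poorer discrimination of
loss magnitudes (type 3, around 0.6) versus loss probabilities (type 5,
above 0.8). Everything is reproducible from integer seeds; side
placement and stimulus rotation are simulated metadata only.

What the generator does *not* emulate: session-level non-stationarity
(fatigue, learning drift), error/aborted trials, lapses, and any
departure of the animals' behaviour from the fitted model family. Tests
passing on synthetic data therefore validate the estimator and the
statistical machinery, not the model's adequacy for real animals.

One consequence deserves emphasis. With model-generated choices the
per-chunk parameter estimates are *cleaner* than the animals': the
published non-significant precision ($\lambda$) contrast is a
just-above-threshold outcome that model-faithful simulation at the same
trial counts frequently *does* detect, because the generating
$\lambda_G$ and $\lambda_L$ genuinely differ. The $\omega$ and $\alpha$
contrasts, by contrast, are detected essentially always, and the package
treats only those as the reproducible signature of the gain-loss
asymmetry.

## Problem sizes and numerical choices

The test suite exercises parameter recovery at 20,000 risky trials over
five seeds (estimates within ±0.1 for $\omega$/$\alpha$, ±0.3 for
$\lambda$), the full chunked pipeline at 5,000 risky trials, Monte-Carlo
validation of the choice rule at $10^6$ draws against three-binomial-sd
bands, and closed-form-vs-bisection agreement of $\omega^*$ to $10^{-9}$
on all 36 risky design pairs at $\alpha \in \{0.2, 0.5, 1\}$ — sizes
chosen to make sampling error negligible relative to the asserted
tolerances while keeping the suite quick. Ties in the canonical ordering
cannot arise (identical lotteries are unclassifiable by construction);
degenerate inputs (empty domains, constant series, flat frequency data,
contradicting counts at extreme precision) all return flagged results
rather than exceptions.

## Known limitations

* The model has no loss-aversion coefficient (no $\kappa$ scaling losses
  against gains) and a single weighting family (Prelec); both mirror the
  modelling scope of the paradigm, not a claim of sufficiency.
* Estimates at 250-trial chunks are noticeably noisy for $\lambda$;
  per-chunk standard deviations should be read as spread, not standard
  errors.
* The type-4 count discrepancy means the simulated design is not
  guaranteed to match the deployed one pair-for-pair; analyses
  conditional on pair identity are unaffected.
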