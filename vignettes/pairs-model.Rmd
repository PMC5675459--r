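---
title: "Predicting high-order drug cocktails from single-dose pair measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting high-order drug cocktails from single-dose pair measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscreen)
```

## The problem

Testing every cocktail that can be drawn from even a modest drug panel is
impossible: a panel of $n$ drugs has $2^n - 1$ non-empty subsets, and the
count explodes further once doses vary. When material is scarce — patient-
derived tumor samples, expensive high-throughput screens — each drug and
drug pair may be measurable at only a *single* dose. `pairscreen` implements
and evaluates models that predict the viability effect of high-order
cocktails from exactly that information: single-drug and pair viabilities at
one fixed dose per drug.

Throughout, $g$ denotes **viability**: the fraction of cells surviving a
treatment relative to untreated control, so $g = 1$ is no effect and
$g = 0$ is complete killing. $g_i$ is the effect of drug $i$ alone, $g_{ij}$
of the pair $\{i,j\}$, and $g_{1..M}$ of an $M$-drug cocktail, all at the
same fixed doses.

## The model family

**Bliss independence** assumes drugs act independently:
$$g^{\mathrm{Bliss}}_{1..M} = \prod_{i=1}^{M} g_i.$$
It uses no pair information, so it cannot express synergy or antagonism.

The package embeds Bliss in a **log-linear family** that mixes pair and
single measurements:
$$g_{1..M} = \Big(\prod_{i<j} g_{ij}\Big)^{\alpha}
            \Big(\prod_i g_i\Big)^{\beta},
  \qquad \beta = 1 - (M-1)\,\alpha .$$
The constraint on $\beta$ is not cosmetic: it enforces **Bliss
conservation** — if every pair happens to be exactly Bliss
($g_{ij} = g_i g_j$), any member of the family collapses to the Bliss
product. Conservation pins down the family to a single free parameter
$\alpha$ and makes the members comparable:

* $\alpha = 0$: Bliss independence (`predict_bliss()`);
* $\alpha = 1$: the **regression** formula
  $\prod g_{ij} \cdot (\prod g_i)^{-(M-2)}$ (`predict_regression()`),
  for triplets $g_{12}g_{13}g_{23}/(g_1 g_2 g_3)$;
* $\alpha = 1/(M-1)$, hence $\beta = 0$: the **pairs model**
  (`predict_pairs()`),
  $$g^{\mathrm{pairs}}_{1..M} = \Big(\prod_{i<j} g_{ij}\Big)^{1/(M-1)},$$
  which consumes pair data only. For a triplet it is the square root of the
  product of the three pair effects.

Outside the family sits the **Isserlis** maximum-entropy formula
(`predict_isserlis()`), a pairing sum defined for $M = 3$
($g_1 g_{23} + g_2 g_{13} + g_3 g_{12} - 2 g_1 g_2 g_3$) and $M = 4$
(sum over the three perfect pairings of the four drugs minus twice the
singles product). We deliberately do not extrapolate it to $M \ge 5$:
the natural extensions (hafnian-style pairing sums) are not uniquely
determined by the printed low-order forms, and guessing one would change
benchmark results silently. Callers evaluating Isserlis on a full factorial
screen therefore see orders 5–6 in the skip list.

All these predictors work *only at the doses at which the inputs were
measured*. Dose–response interpolation is a different problem and out of
scope here.

## Interaction scoring and classification

Synergy and antagonism are scored against Bliss independence on a log
scale:
$$I = \ln\!\big(1 + g_{1..k} - g^{\mathrm{Bliss}}_{1..k}\big),$$
negative for synergy (more killing than independence predicts), positive
for antagonism. The natural logarithm is the convention used by
`interaction_score()`; recomputing the built-in screen's interaction column
from its printed means reproduces the printed values at two decimals (e.g.
$\ln(1 + 0.67 - 0.77\cdot 0.82) = 0.038 \to 0.04$), which base-10 or
base-2 logs do not.

`bootstrap_interaction()` follows the percentile-bootstrap recipe: compute
$I_r$ for each biological repeat of the cocktail (using the *mean*
single-drug viabilities in the Bliss product), resample the $I_r$ with
replacement `n_boot` times (default 10,000), and report the mean of the
resample means with their 5th/95th percentiles. Percentile intervals are
used as-is (no BCa correction) because the classification rule is stated in
terms of plain percentiles. Joint resampling of the single-drug repeats is
available via `single_repeats` but off by default: the point estimate
should not drift with the singles' sampling noise unless the caller asks
for it. A repeat whose log argument is non-positive makes $I$ undefined;
the function fails fast rather than dropping the repeat, since silent
dropping would bias the interval.

`classify_interaction()` calls a cocktail **antagonistic** when $I > 0$
*and* the 5th percentile is above 0, **synergistic** when $I < 0$ and the
95th percentile is below 0, and **additive** otherwise. Requiring the sign
of $I$ itself, not only the bound, keeps the three labels mutually
exclusive and exhaustive.

### Rounded confidence bounds in the built-in screen

The shipped screen (`table2_fixture()`) carries interaction estimates and
CI bounds printed at two decimals. Three H1299 rows have a bound that
prints as exactly 0.00, where the strict rule above cannot reproduce the
published significance calls from the rounded numbers alone — two rows with
an upper bound of 0.00 received *different* published calls, so no
deterministic function of the printed columns can match both. The fixture
therefore also transcribes the published per-row significance call in a
`label` column; `pair_consistency_summary()` prefers stored labels and
falls back to `classify_interaction()` when none are present. A regression
test asserts that stored labels and the CI rule disagree on exactly those
two boundary rows and nowhere else.

## Pair consistency

`pair_consistency_summary()` quantifies whether the *sign* of a high-order
interaction is anticipated by its pairs: for every significant cocktail of
order $\ge 3$ it checks for at least one significant same-sign pair among
its $M(M-1)/2$ constituents. Cocktails whose sign matches none of their
measured pairs are reported as exceptions — candidates for genuinely
third-order interactions, and exactly the cases a pair-based predictor
cannot capture. On the built-in screen: HeLa 16/16 antagonistic and 10/10
synergistic cocktails are pair-consistent; H1299 7/7 and 19/22, with three
triplet exceptions.

## Evaluating predictors

`evaluate_models()` scores each model by
$$R^2 = 1 - \sum_i (y_i - f_i)^2 \Big/ \sum_i (y_i - \bar y)^2$$
over measured cocktails, **pooling cell lines and orders 3 and up by
default**. The `min_order = 3` floor matters: singles and pairs are model
*inputs*, and letting a model predict its own inputs would inflate the fit
(a pairs model evaluated on pairs scores $R^2 = 1$ trivially). $R^2$ is not
clipped below zero — a negative value means the model is worse than
predicting the pooled mean, and the regression formula genuinely earns
$R^2 \approx -12$ on the built-in screen. Cocktails whose inputs are
missing in a cell line (e.g. every HeLa cocktail containing both CBPT and
NCZ, whose pair was too variable to measure) are skipped with recorded
reasons, so point sets stay comparable across models.

On the built-in screen (68 pooled cocktails of order 3–6) this yields
$R^2 \approx 0.55$ for the pairs model, $0.29$ for Bliss, and $-12.2$ for
regression, computed from two-decimal published means; the package's
acceptance tests assert these values with a tolerance of $\pm 0.05$ for
the first two (the original estimates were computed from repeat-level data
that is not published) and a correspondingly scaled band for the
regression value.

`alpha_scan()` evaluates the log-linear family on a grid of $\alpha$
(default $0$ to $1$ in steps of $0.05$) and reports the $R^2$ profile and
its argmax; ties resolve to the smallest $\alpha$, preferring the
lower-variance model. On exactly Bliss-consistent data the profile is flat
by construction — conservation makes all family members coincide — which
doubles as a correctness check. Restricted to the built-in screen's
triplets the scan peaks at $\alpha = 0.45$, adjacent to the pairs model's
$\alpha = 1/(M-1) = 0.5$.

`ranking_accuracy()` addresses prioritization rather than point accuracy:
the fraction of the top $k = \lfloor f\,n \rfloor$ most *effective*
cocktails (lowest viability) recovered by the model's top $k$. It is
invariant to monotone transforms of the predictions, ties break
deterministically on cocktail labels, and a random predictor scores $k/n$
in expectation (the hypergeometric mean) — the baseline the tests verify
at $f = 0.1$.

## Noise amplification

With independent multiplicative measurement noise of log-scale standard
deviation $\sigma$ on every single and pair input, first-order propagation
through the family gives a prediction noise of
$$\sigma \sqrt{\alpha^2\,\tfrac{M(M-1)}{2} + \beta^2 M}$$
(`noise_amplification_analytic()`): $\sqrt{M}$ for Bliss,
$\sqrt{M(M-1)/2 + M(M-2)^2}$ for regression, and only
$\sqrt{M/(2(M-1))}$ for the pairs model. For triplets these are
$\sqrt 3 \approx 1.7$, $\sqrt 6 \approx 2.4$–$2.5$, and
$\sqrt{3/4} \approx 0.9$; the pairs model stays *below* one $\sigma$ at
every order, which is why it is the model of choice for noisy single-dose
data. For the log-linear family the log prediction is exactly linear in
the input log noises, so `noise_amplification_mc()` — which perturbs a
simulated Bliss-consistent truth and measures the empirical sd of the log
prediction — agrees with the closed form at any small $\sigma$, not just
asymptotically; the tests require agreement within three Monte-Carlo
standard errors at $\sigma = 0.05$ with $10^5$ simulations.

## The synthetic generator

`generate_screen()` draws fully factorial screens with known ground truth:

* **true singles** uniform on `single_range`, default $(0.6, 0.9)$ — the
  regime of a screen dosed near 80% single-drug survival so that even
  six-drug cocktails remain above the detection floor;
* **true pairs** $g_{ij} = g_i g_j e^{\delta_{ij}}$ with
  $\delta_{ij} \sim N(0, \texttt{pair\_interaction\_sd}^2)$, default sd
  0.1, giving pair interactions of the magnitude seen in the real screen
  (|I| mostly up to $\approx 0.2$); the default is deliberately non-zero
  because in an exactly-Bliss world all family members coincide and
  $\alpha$ is unidentifiable;
* **true higher orders** from the log-linear family at `true_alpha`
  (default 0.5), so parameter recovery has a well-defined target; an
  optional `triplet_interaction_sd` injects third-order deviations to
  emulate pair-inconsistent exceptions;
* **observations**: `n_repeats` (default 6, the floor of the real screen's
  biological repeats) independent draws $g\,e^{\sigma Z}$ with
  $\sigma = \texttt{noise\_sigma}$ (default 0.05), summarized into means
  and standard errors with the repeats retained.

The generator is log-normal multiplicative throughout — the natural
instantiation of "independent multiplicative noise", though no particular
noise distribution is canonical for viability assays. What it does *not*
emulate: dose–response structure, plate and batch effects, correlated
noise between cocktails sharing wells, the detection floor near zero
viability, and cell-line heterogeneity. Passing recovery tests on
synthetic screens therefore demonstrates correctness of the estimation
machinery under the generator's assumptions, not robustness on real
screens.

`recover_alpha()` closes the loop: scan a generated screen (all high-order
cocktails of one order) on a grid of step 0.025 and return the best
$\alpha$. At $\sigma = 0.02$ with six drugs (20 triplets) the truth is
recovered within about two grid steps; the occasional third step reflects
the genuine sampling noise of 20 points, and the noise-amplification
penalty on high-$\alpha$ members biases recovery at $\alpha = 1$ slightly
downward — visibly the same effect that makes regression fragile on real
data.

## Numerical choices

* Drug identifiers are uppercased, trimmed, and radix-sorted, so canonical
  cocktail labels are locale-independent and set-equality is string
  equality.
* Viabilities must lie in $[0, 2]$: values modestly above 1 are expected
  noise around no-effect, while values above 2 almost certainly indicate
  percent-vs-fraction unit errors and are rejected outright.
* Singles at or below $\varepsilon = 10^{-9}$ raise a degenerate-input
  error wherever a formula divides by them ($\beta < 0$); clamping would
  silently fabricate predictions exactly where the formula is most
  unstable. $0^{\beta}$ for $\beta > 0$ is fine and yields 0.
* Negative Isserlis outputs are clamped to 0 (viability cannot be
  negative) with a `clamped` flag preserved on the prediction.
* Bootstrap and generator functions restore the caller's RNG state; all
  stochastic results are bit-reproducible given their seed argument.
* Empty cells and `"-"` both denote missing measurements on input; missing
  viabilities skip the record with a warning rather than erroring, since
  partially measured screens are the norm.

## Problem sizes in the test suite

The suite exercises: the full built-in screen (109 records); 1,000-draw
Bliss-conservation sweeps over orders 3–6; bootstrap checks at
`n_boot` = 10,000; Monte-Carlo noise factors at $10^5$ simulations;
ranking baselines over 1,000 replicates of 1,000-cocktail screens; and
parameter recovery on six-drug triplet screens at $\sigma = 0.02$. The
complete run takes well under a minute on one core.

## Limitations

Predictions are valid only at the measured doses; there is no
dose–response surface, no Loewe/HSA-style alternative synergy references,
and no mechanistic content. The Isserlis comparator stops at quadruplets.
The built-in screen carries published two-decimal summaries, not raw
repeats, so bootstrap workflows on it require synthetic repeats; and with
only two cell lines and six drugs, its headline $R^2$ values should be
read as a worked example, not a general performance guarantee.
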