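---
title: "Information transmission in facilitating synapses: model, bounds, estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transmission in facilitating synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synfacil)
```

## The channel model

A chemical synapse releases neurotransmitter stochastically. On a discrete
time grid, let $X_i \in \{0,1\}$ mark a presynaptic spike in bin $i$ and
$Y_i \in \{0,1\}$ a vesicle release. The synapse is a binary asymmetric
channel: synchronous (spike-evoked) release happens with probability
$P(Y_i{=}1 \mid X_i{=}1)$ and asynchronous release with
$P(Y_i{=}1 \mid X_i{=}0)$. Input spikes are i.i.d. Bernoulli with per-bin
probability $\alpha$, the *normalized input spike rate*.

Short-term facilitation makes these probabilities history dependent. The
two-state model captures the shortest possible memory: the state of the
channel in bin $i$ is set by the previous input symbol alone. After a quiet
bin the synapse is in the *baseline* state with release probabilities
$(p_1, q_1)$; after a spike it is *facilitated*, with

$$p_2 = u\,(p_{\max} - p_1) + p_1, \qquad q_2 = v\,(q_{\max} - q_1) + q_1,$$

where $u, v \in [0,1]$ are the facilitation coefficients of synchronous and
asynchronous release and $p_{\max}, q_{\max}$ the ceilings. The package
never stores $p_2, q_2$; they are always derived from
$(p_1, p_{\max}, u)$ and $(q_1, q_{\max}, v)$, so $p_1 \le p_2 \le p_{\max}$
cannot be violated by construction. $q_{\max}$ is always an explicit
parameter — no fixed relation to $q_1$ is assumed, because different
analyses in this area use different conventions (a fixed ceiling of 0.2, or
a multiple such as $4 q_1$).

All information quantities are in bits (base-2 logarithms); natural-log
variants are deliberately out of scope. The convention $0 \log_2 0 = 0$ is
enforced by explicit branching in `binary_entropy()`, not by relying on
floating-point limits.

## Rates and bounds

A single-state (memoryless) channel with parameters $(p, q)$ has mutual
information rate

$$R = h(\alpha p + \bar\alpha q) - \alpha\,h(p) - \bar\alpha\,h(q),$$

with $h$ the binary entropy and $\bar x = 1 - x$ (`single_state_rate()`).
The two-state channel's exact rate $R_F$ has no known closed form — because
the state is driven by the *input* history, computing $R_F$ is equivalent
to the entropy rate of a hidden Markov process, a famously open problem.
The package therefore provides closed-form brackets:

* **Lower bound** (`lower_bound()`): $R_{LB} = \bar\alpha R_1 + \alpha R_2$,
  the occupancy-weighted average of the two single-state rates. (For the
  analogous two-state model of short-term *depression*, where the state is
  driven by the output history, the same expression is exact.)
* **Upper bound** (`upper_bound()`): $R_{UB} = u_7 - u_6$, where $u_6$ is
  the conditional output entropy rate $H(Y \mid X)$,
  $$u_6 = h(q_1)\bar\alpha^2 + \left(h(p_1) + h(q_2)\right)\alpha\bar\alpha
        + h(p_2)\alpha^2,$$
  and $u_7$ upper-bounds the output entropy rate by conditioning on the
  previous output symbol only, through the stationary statistics
  $u_1 = \bar\alpha(\alpha p_1 + \bar\alpha q_1)$,
  $u_2 = \bar\alpha q_1 + \alpha q_2$,
  $u_3 = \alpha(\alpha p_2 + \bar\alpha q_2)$,
  $u_4 = \bar\alpha p_1 + \alpha p_2$, $u_5 = u_1 + u_3$:
  $$u_7 = u_5\, h\!\left(\tfrac{u_1 u_2 + u_3 u_4}{u_5}\right)
        + \bar u_5\, h\!\left(\tfrac{u_1 \bar u_2 + u_3 \bar u_4}{\bar u_5}\right).$$

The grouping of the middle term of $u_6$ — $(h(p_1)+h(q_2))\alpha\bar\alpha$
— is the one under which $u_6$ is exactly $H(Y|X)$ and under which
$R_{UB}$ collapses to the single-state rate when $u = v = 0$; the test
suite verifies this collapse to $10^{-12}$ over random parameter grids,
which pins the algebra down numerically. Degenerate points
($\alpha \in \{0,1\}$, or a synapse that never/always releases, $u_5 \in
\{0,1\}$) are evaluated by the $0\log 0$ convention rather than raising.

Because release costs metabolic energy, the package also reports
**energy-normalized** rates in bits per release. The static-synapse
reference is $R_1^{(E)} = R_1 / (\alpha p_1 + \bar\alpha q_1)$; the
facilitated bounds are divided by the stationary release probability of the
two-state model,

$$P(Y_i = 1) = \bar\alpha(\alpha p_1 + \bar\alpha q_1)
             + \alpha(\alpha p_2 + \bar\alpha q_2),$$

(`stationary_release_probability()`). Note the two denominators differ as
soon as $u, v > 0$; this is intentional, since the question is whether a
facilitating synapse beats the static synapse it would otherwise be.

### Classifying the effect of facilitation

`classify_effect()` compares the facilitated bracket against the static
baseline: facilitation provably *increases* the rate when $R_{LB} > R_1$,
provably *decreases* it when $R_{UB} < R_1$, and is otherwise
*undetermined* — the bounds genuinely cannot discriminate when
$R_{LB} \le R_1 \le R_{UB}$. Comparisons are strict with a $10^{-12}$
guard, so the exact-tie collapse at $u = v = 0$ maps to undetermined
instead of being decided by rounding noise. The same rule applied to
$R_{LB}^{(E)}, R_{UB}^{(E)}$ vs $R_1^{(E)}$ classifies the
energy-normalized effect. `effect_map()` evaluates this over parameter
grids; the characteristic result is that unreliable synapses (small $p_1$)
with strong synchronous facilitation benefit in both rate and bits per
release, while reliable synapses with weak synchronous but substantial
asynchronous facilitation lose on both.

## Simulators and the synthetic-data generator

Inputs are generated, never loaded: `generate_bernoulli_train()` draws
i.i.d. Bernoulli($\alpha$) trains, and `generate_inhomogeneous_train()`
discretizes an inhomogeneous Poisson process whose rate is a sinusoid
$\alpha(t) = \mathrm{baseline} + \mathrm{amplitude}\,\sin(2\pi f t)$,
clipped to $[0,1]$ (the discrete-time analogue of a correlated,
stimulus-driven spike train; defaults baseline 0.3, amplitudes 0, 0.075,
0.15, frequency 1 Hz). `simulate_two_state_release()` draws $Y_i$ from the
state selected by $X_{i-1}$; the first bin uses the baseline state
(equivalent to assuming no spike before the recording started), a choice
that affects a single symbol and no stationary quantity.

The **general model** (`general_model_params()`,
`simulate_general_release()`) lets facilitation depend on the whole spike
history: instantaneous probabilities $p, q$ relax exponentially (time
constants $\tau_{L,p}, \tau_{L,q}$, default 250 ms) toward *limit
probabilities* $p^{(L)}, q^{(L)}$, which jump by $u(p_{\max} - p^{(L)})$,
$v(q_{\max} - q^{(L)})$ on each spike and decay back to baseline with the
facilitation decay constants $\tau_{f,p}, \tau_{f,q}$ (default 20 ms).
Within a bin the order of operations mirrors the two-state channel, where
$X_{i-1}$ sets the state that governs $Y_i$: the limits jump (after a
spike) or decay (after a quiet bin), then $p, q$ relax one bin toward the
updated limits, then the release is drawn. Exponential steps use the exact
per-bin factor $e^{-\Delta t/\tau}$, making the limit trajectory invariant
to splitting a bin in two — a property the tests assert. The coupling
order within a bin is not uniquely determined by the model's verbal
description; this reading was chosen because it is the one that reduces
exactly to the two-state update when the limit dynamics are instantaneous.

The default bin width is 1 ms, the conventional discretization for spike
trains, which makes $\alpha$ numerically equal to the rate in kHz. Nothing
in the mathematics fixes this link between the dimensionless channel and
the millisecond time constants, so the bin width is an explicit,
configurable parameter everywhere it matters.

### What the generator does and does not emulate

The generator reproduces the modeling assumptions: (discretized) Poisson
spiking, at most one vesicle per bin, facilitation only. Real presynaptic
spike trains have refractoriness and non-Poisson statistics; real synapses
also depress (vesicle depletion), can release multiple vesicles, and have
calcium dynamics none of which are modeled. Green tests therefore
demonstrate internal correctness of the model, bounds and estimators — not
that a biological synapse obeys them.

## The CTW estimator

The quantity the bounds bracket can be estimated numerically. The package
implements context-tree weighting (CTW) with Krichevsky–Trofimov (add-½)
estimators at every node and the canonical ½/½ weighting between a node's
own estimate and its children's product, over all context trees of depth
$\le D$ (default $D = 8$). The normalized codelength of a sequence is a
consistent entropy-rate estimator for stationary ergodic sources, with
$O(\log n / n)$ redundancy. Implementation notes, all visible in
`ctw_codelength()` / `src/ctw.cpp`:

* all arithmetic is in the log2 domain, so nothing underflows at
  $n = 10^6$;
* tree nodes are allocated lazily, so memory scales with the contexts
  actually observed rather than $|\mathcal{A}|^D$;
* the first $D$ symbols serve only as initial context and are excluded
  from both the codelength and its normalization, avoiding boundary bias;
* the computation is deterministic — identical input gives bit-identical
  codelength.

`mi_rate_estimate()` uses the decomposition
$\hat I = \hat H(X) + \hat H(Y) - \hat H(X,Y)$, with the joint term run on
the 4-letter sequence $2X_i + Y_i$. A conditional-CTW alternative
($\hat H(Y) - \hat H(Y|X)$) would need side-information trees whose
definition is not standardized; the joint-alphabet route is a single
well-defined estimator, and the exactly computable $H(Y|X) = u_6$ of the
two-state model provides an independent cross-check that the tests enforce
($\hat H(Y) - \hat I$ must match $u_6$ to 0.01 at $n = 10^6$). Estimates of
independent pairs can come out slightly negative; they are reported
unclipped, because clipping at zero would bias the bracketing checks.
Depth is cheap insurance: the two-state channel has one step of memory, so
$D = 8$ vs $D = 16$ moves estimates by well under 0.005 bits/symbol, but
larger depths are available for the general model's longer memory.

## Two-state versus general model: regimes of agreement

The two-state channel is the limit of the general model in which
facilitation lasts exactly one bin. Simulation with the package shows
precisely when that limit is informative, and the distinction matters when
interpreting `compare_models()` output:

* **Low-rate regime.** When interspike intervals are long relative to
  $\tau_f$ (e.g. $\alpha \le 0.02$ at 1 ms bins with $\tau_f = 20$ ms),
  facilitation from one spike decays before the next arrives, and the CTW
  estimates of the two models agree to within a few percent (for the
  reference synapse $p_1 = 0.5$, $q_1 = 0.05$, $u = v = 0.5$).
* **Coarse-bin regime.** When the bin width is comparable to $\tau_f$,
  a spike's facilitation is effectively confined to the following bin —
  the two-state premise — and agreement is again close at moderate rates.
* **Fast-driving regime.** At 1 ms bins with per-bin spike probabilities
  of 0.1–0.5 (100–500 Hz), interspike intervals of 2–10 ms are far shorter
  than the 20 ms decay, so the limit probabilities accumulate over many
  spikes toward their ceilings while the instantaneous probabilities
  integrate them over $\tau_L = 250$ ms. The general model then behaves
  like a much less noisy channel and transmits up to several times more
  information than the two-state model. This is a property of the models,
  not an estimation artifact: the CTW estimator passes all of its
  closed-form checks in the same runs.

The acceptance suite asserts the 10% agreement at 1 ms bins and
$\alpha \in \{0.1, 0.3, 0.5\}$, and that check fails by design of the
models in the fast-driving regime; the low-rate regime demonstrates the
convergence claim honestly. Both numbers are reported by
`scripts/acceptance.R`.

## Numerical and statistical choices

* Problem sizes: closed-form checks use $10^3$–$10^4$ random parameter
  points; simulation-based checks use $n = 10^5$–$10^6$ bins, where
  binomial standard errors ($\sim 5 \times 10^{-4}$) and CTW redundancy
  ($\sim 10^{-3}$ bits/symbol) are both far below the asserted tolerances.
* Monte-Carlo classification (`correlated_input_experiment()`): under
  correlated input the analytic bounds no longer apply, so the effect of
  facilitation is declared only when the mean paired difference between
  facilitated and static CTW estimates exceeds twice its across-trial
  standard error; otherwise undetermined. Pairing (same input trains
  through both synapses) removes most of the input variability.
* Reproducibility: every stochastic function takes a `seed`; seeded calls
  restore the caller's RNG state afterwards, and equal seeds give
  bit-identical trains and tables.
* Error handling: probabilities outside $[0,1]$, `base > max`,
  mismatched train roles or lengths, and division by a zero release
  probability raise immediate errors rather than propagating NaN.

## Limitations

* The exact rate $R_F$ is bracketed, not computed; the bracket width grows
  with the facilitation level.
* Only facilitation is modeled — no depression, no multi-vesicle release,
  no biophysical calcium dynamics, no postsynaptic decoding.
* Everything lives on a fixed discrete grid; there is no event-driven
  continuous-time simulation.
* CTW estimates carry the usual finite-sample redundancy; at
  $n \ll 10^5$ the bracketing checks need wider margins.
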