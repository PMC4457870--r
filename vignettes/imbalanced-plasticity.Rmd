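---
title: "Sparse connectivity from imbalanced synaptic plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse connectivity from imbalanced synaptic plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseperceptron)
```

## The model

A single neuron receives `N` excitatory inputs through non-negative synaptic
weights `w_i >= 0` and fires whenever its net current

$$ h = \sum_{i=1}^{N} w_i x_i - \theta\sqrt{N} $$

is non-negative. The `sqrt(N)` in the threshold keeps the working point
invariant as the system is scaled. The task is *one-class recognition*: the
neuron must learn to fire for each of `K` stored patterns while staying
silent for random lures it has never seen. Negative examples never trigger
plasticity — only the failure to recognise a stored pattern does. The memory
load is `alpha = K/N`; with the sign constraint the maximal load for dense
random bipolar patterns is `alpha_max = 1`, half the capacity of an
unconstrained perceptron.

Learning starts from *tabula rasa* (`w = 0`) and cycles through the patterns
in a random order, redrawn each epoch. When a stored pattern fails to fire,
high inputs are potentiated by `a` and low inputs depressed by `b` (followed
by rectification at zero); when it already fires, nothing happens
(stop-learning). Writing `epsilon = (a+b)/2` and `lambda = (b-a)/(a+b)`, the
update below threshold is `delta w_i = epsilon (x_i - lambda)`. The
imbalance `lambda > 0` biases every update towards the zero bound; it is
exactly a stochastic subgradient step on the energy

$$ E(w) = \sum_k\big[\theta\sqrt{N} - w\cdot x^k\big]_+ \;+\;
   \lambda \sum_i w_i , $$

an L1-regularised margin objective, which is why depression-dominated
plasticity *silences* synapses rather than merely shrinking them. The
`rule = "decay"` variant also applies the uniform `-epsilon*lambda`
depression when the pattern fires; it descends the same energy and converges
somewhat faster, at the cost of never being strictly at rest. Convergence is
therefore always decided by a separate no-plasticity probe over all `K`
patterns at the end of each epoch, and the probe never applies the decay.

## Offline references

Two offline solutions bracket the online rules on any fixed pattern set:

* the **minimum-L2** solution (smallest `||w||_2` subject to all patterns
  firing) maximises the stability `Delta = theta*sqrt(N)/||w||_2` and hence
  the recognition information — lure currents are asymptotically Gaussian
  with variance `||w||_2^2`, so the false-positive rate is
  `p01 = Phi(-theta*sqrt(N)/||w||_2)`;
* the **minimum-L1** solution (smallest `sum w_i`) is the endpoint of
  imbalanced learning as `lambda` approaches its critical value, and is the
  sparse reference: for generic random patterns it is an LP vertex whose
  support size is at most `K`, so at low load almost all synapses are
  exactly silent.

Both live on the same feasible cone and are computed with the compiled
Goldfarb–Idnani quadratic-programming solver. The L1 problem is linear, and
is solved through *exact Tikhonov regularisation*: minimising
`ridge/2 * ||w||_2^2 + sum(w)` over the same constraints returns exactly the
minimum-norm point of the LP's optimal face once `ridge` is below a
problem-dependent threshold — for a generic random instance that face is a
single vertex, so the solution is the LP solution. We verified on
N = 1000 / K = 100 instances that the objective is invariant (to seven
digits) across two decades of `ridge`; the default `1e-4` is conservative
and every solution carries the duality-gap bound `ridge * ||w||_2^2` in its
diagnostics. Interior-point output satisfies active constraints only to
numerical tolerance, so solutions are rescaled multiplicatively to put the
weakest pattern response exactly on the margin (the feasible set is a cone;
the rescale is a no-op up to ~1e-9 and restores exact feasibility).

Infeasibility (reported by the solver as inconsistent constraints) is
returned as a status, not an error, so capacity sweeps can count failures.

The **min-over** batch rule reinforces, at every step, the pattern with the
smallest postsynaptic sum, with rectification after each step. Its
normalised stabilities converge to the minimum-L2 ones; the implementation
tracks responses incrementally through the pattern Gram matrix and stops
when the minimal stability has stalled (`stall_window` steps without
improvement beyond `stall_tol`) after feasibility is reached, or at the
iteration budget. With `stall_window = 1e4` it reproduces QP stabilities to
about `1e-3` relative at N = 100, alpha = 0.3 within a second.

## Codings and the adaptive threshold

Three input codings are supported. Bipolar inputs (`x_i` in {-1, +1}) are
the analytically convenient reference. Biologically, low inputs are silent:
0/1 coding with coding level `f` (probability of the high state). Its
zero-mean form `z_i = x_i - f` in `{-f, 1-f}` carries the same information.
The plasticity rule generalises by using the zero-mean signal in the update,
`delta w_i = epsilon (z_i - lambda)` — potentiation `epsilon(1-f-lambda)`
for high inputs, depression `-epsilon(f+lambda)` for low ones — which keeps
potentiation and depression balanced relative to the activity level.

For 0/1 inputs the current can be written
`h = sum w_i x_i - gamma` with the *adaptive threshold*
`gamma = f * sum(w) + theta_f * sqrt(N)`. Because `gamma` tracks the total
synaptic weight, the neuron self-regulates as learning strengthens its
synapses — a homeostatic mechanism that needs no inhibitory partner neuron —
and the 0/1 model makes, decision for decision, the same choices as the
zero-mean model (the identity is algebraic; the test suite asserts
trajectory equality on fixed seeds).

The threshold parameter is scaled by the input standard deviation:
`theta_f = theta * sqrt(f(1-f))`, which equals `theta/2` at `f = 1/2`. This
choice makes the `f = 1/2` zero-mean model *bitwise* equivalent to the
bipolar model (binary scaling is exact in floating point) and renders the
information and efficiency independent of `f` under the adaptive threshold,
which is the property the coding generalisation is meant to have. The
non-adaptive comparison model uses a fixed threshold `theta * f * sqrt(N)`;
its information degrades towards dense coding, illustrating what the
adaptive `gamma` buys.

## Pattern statistics, correlations, noise

Pattern entries are i.i.d. with the high state drawn at probability `f`
(`f = 1/2` fixed for bipolar coding); there is no fixed active count per
pattern. Each generator call takes an explicit seed and runs on a private
RNG stream, so sweeps are reproducible without touching the caller's RNG.

Correlated patterns follow a template model: a random bipolar template
`xhat` is drawn once, and each pattern copies each template entry with
probability `(1+g)/2`. In the *homogeneous* mode both `xhat` and `-xhat`
serve as templates, chosen by a fair coin per pattern (the mixing ratio is
forced to 1/2 by symmetry), which keeps every input's mean activity at 1/2.
In the *heterogeneous* mode a single template is used, so inputs that are
high in the template fire more often — the pairwise pattern correlation is
`g^2` and the per-input activity becomes bimodal. Lures are always drawn
from the same generative law (same templates, same `g`).

Presynaptic noise flips active inputs off with probability `delta10` and
silent inputs on with probability `delta01`, independently per entry;
bipolar and zero-mean codings are corrupted through their high/low states.
Lures probing a noisy recognition task are drawn with the matched mean
activity `(1-f)*delta01 + f*(1-delta10)`, so activity level alone cannot
separate lures from distorted patterns. Postsynaptic noise adds a fresh
zero-mean Gaussian of s.d. `sigma` to the current at every presentation.

## Information, efficiency, silent synapses

Recognition performance is measured by presenting stored patterns and lures
with equal probability: `2K` trials. With false-positive rate `p01` and
false-negative rate `p10`, the information per synapse is
`C = (2K/N) * I(p01, p10)` bits; below capacity learning drives `p10` to
zero and the closed form
`C = (2K/N) (1 - [(1+p01)log2(1+p01) - p01 log2 p01]/2)` applies (the
general binary mutual information is used whenever `p10 > 0`, with the
`0*log 0 = 0` convention). Paired testing with equiprobable lures is itself
suboptimal: testing against *all* `2^N - K` lures would extract about 60.6%
more information at `p01 = 1/2`; the package reproduces that ratio in
closed form rather than by enumerating lures.

The *memory efficiency* `S = C/F` charges each functional synapse a fixed
energetic cost, where `F` is the fraction of non-zero synapses. Deciding
which solver weights are "zero" is done by the information-drop procedure:
weights are removed in ascending order while the neuron is probed with a
large lure set, until the empirical information drops — beyond the binomial
standard error of the probe, or any stored pattern stops firing. A removal
that only moves currents by accumulated rounding (~1e-13) must not count as
a decision change, so decisions carry an absolute current guard of
`1e-7 * theta * sqrt(N)`; a genuine support removal moves currents by the
weight itself, orders of magnitude above the guard. The fallback count
(`w_i < 1e-8 * max w`) agrees with the drop procedure across at least three
orders of magnitude of the tolerance on LP/QP solutions, because their
supports are well separated from the numerical floor. Default information
estimates use `M = K` fresh lures per trial; noise-robustness protocols use
much larger lure sets.

Weight histograms pool solutions across trials after rescaling each vector
to unit minimal pattern response (`w / min_k w.x^k`), which fixes a common
scale without touching support or shape; the zero mass is kept separate
from the positive density. The positive part of the maximal-imbalance
distribution is summarised by a compressed exponential
`P(w) ~ exp(-c w^beta)`, fitted by maximum likelihood: the normalising
constant is `c^(-1/beta) Gamma(1+1/beta)`, the scale solves in closed form
(`c_hat = n/(beta sum w^beta)`), and a one-dimensional profile search over
`beta` does the rest. A binned least-squares fit on the log-histogram is
available as a cross-check because histogram fitting is the common
alternative; MLE is the default as it needs no binning choice. On synthetic
samples of `1e5` draws the test suite recovers `beta` in {1, 1.4, 2} to
within a few hundredths.

For 0/1 coding the analytic false-positive rate uses the lure-current
moments in their weight-distribution form (variance
`f ||w||_2^2 - f^2 |w|^2 / N`); the bipolar expression is exact for fixed
weights and is the one validated against Monte Carlo in the tests.

## Convergence theory and the critical imbalance

Assuming some feasible `w*` stores all patterns with margin `kappa` at
threshold `(theta+kappa)sqrt(N)`, the cosine between `w(m)` and `w*` after
`m` updates is bounded below by `sqrt(epsilon m N) * U / (||w*||_2 sqrt(V))`
with

```
U = kappa/sqrt(N) - lambda |w*|/N - epsilon(1 + 2 lambda q + lambda^2 q)/2
    - q epsilon (1+lambda)^2
V = 2 theta/sqrt(N) + epsilon(1 + 2 lambda q + lambda^2 q)
    + 2 q epsilon (1+lambda)^2
```

where `q` is the maximal fraction of low inputs across patterns. The bound
grows like `sqrt(m)`, so learning is guaranteed to converge exactly when
`U > 0`, in at most `m* = ||w*||_2^2 V / (epsilon N U^2)` updates. At
`lambda = 0` this reduces to the balanced small-rate condition
`epsilon < 2 kappa / (sqrt(N)(1+2q))`. The imbalance enters through
`lambda |w*|/N`: a larger allowed imbalance requires a feasible solution
with a smaller linear norm, which ties `lambda_max` to the task difficulty —
as `alpha` grows the attainable margin shrinks and `lambda_max` falls to
zero at capacity. Only the closed-form bound is implemented; the proof's
per-step bookkeeping sets are not represented. For evaluating the bound we
take `w*` from the minimum-L2 solution at the raised threshold, since the
argument only needs existence of a feasible configuration with that margin.

Empirically, `lambda_max` is estimated by training with the stop-learning
rule at increasing `lambda` (ascending grid, or bisection to resolution
0.01) and recording the largest convergent value. A finite epoch budget is
part of the definition of "no longer converges"; it is stored in the result
so that estimates are comparable. Near `lambda_max` the dynamics slows down
markedly — the linear norm of the online solution approaches the LP optimum
from above (within ten percent, and typically a few percent, in the packaged
checks), which is the practical meaning of the equivalence between maximal
imbalance and L1 minimisation.

## Numerical and protocol choices

* Firing at `h >= 0` exactly; plasticity triggers at `h < 0`. Updates add
  the increment first and clamp at zero second.
* `epsilon = 1/N` and `theta = 1` are the simulation defaults: the large
  threshold acts as an (unnormalised) stability target, and information no
  longer improves when it is raised further.
* The online trainer and min-over run in compiled code; presentation order
  uses R's RNG, so a fixed seed reproduces runs bitwise.
* Online epoch budget defaults to `1e4`; non-convergence is data, not an
  error. Min-over budget defaults to `1e5` iterations with a `1e3`-step
  stall window.
* Zero detection on solver output uses the relative `1e-8` floor;
  the information-drop count is authoritative where it matters.
* Pattern sets and configurations serialise to CSV + JSON sidecars
  (plain-text formats only).

Desk-scale protocol sizes (used by the test suite and the acceptance
script): feasibility crossing at `N = 300` with 20 instances per load;
silent-synapse fractions from minimum-L2 at `N = 500`, 20 trials per load,
20 000-lure probes; the weight-distribution exponent from 100 pooled
minimum-L1 solutions at `N = 1000`, `K = 100`; ordering properties at
`N = 200`–`500` with 3–20 trials. These sizes keep every ordering and
published quantity reproducible on a single workstation run.

## What the generator does and does not emulate

The synthetic patterns are exchangeable, spatially unstructured and
temporally independent; the correlation model induces either homogeneous
pairwise correlation or static rate heterogeneity, nothing richer. There
are no spike trains, no temporal codes, no metabolic model beyond the fixed
cost per functional synapse. Passing tests therefore demonstrate the
claimed properties of the model under its own stated statistics — they do
not certify behaviour on natural stimuli, structured correlations, or
biological plasticity with stochastic update sizes.

## Known limitations

* The true sparsest solution is an L0 problem; the L1/imbalance route is a
  convex surrogate and is not guaranteed to reach the theoretical minimum
  of functional synapses.
* `lambda_max` estimates inherit finite-size variability and depend on the
  declared epoch budget; they are meaningful as orderings and approximate
  values, not sharp constants.
* The Gaussian false-positive approximation needs enough non-zero weights;
  at extreme sparseness or vanishing load it degrades.
* The exact-regularisation LP route assumes a generic (non-degenerate)
  optimal vertex; on crafted degenerate instances the returned vertex is
  the minimum-norm point of the optimal face, and only the objective value
  is asserted unique.
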