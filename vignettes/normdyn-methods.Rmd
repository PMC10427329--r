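---
title: "Methods: the coupled action–norm–belief model in normdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled action-norm-belief model in normdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdyn)
```

## The model

`normdyn` models a group of $n$ agents repeatedly facing a social dilemma.
Agent $i$ carries an action $x_i$, a personal norm (attitude) $y_i$, an
empirical expectation $\tilde{x}_i$ (belief about the peers' mean action)
and a normative expectation $\tilde{y}_i$ (belief about the peers' mean
attitude). All four are non-negative reals.

**Decision rule.** Agents are boundedly rational myopic best responders:
each revising agent maximises the subjective utility

$$u_i(x) = \pi_i(x, \tilde{x}_i) - A_{1i}(x - y_i)^2 - A_{2i}(x -
\tilde{y}_i)^2 - A_{3i}(x - \tilde{x}_i)^2 - A_{4i}(x - G)^2,$$

where $\pi_i$ is the material payoff and $G$ the standard promoted by an
external authority. The material payoff enters only through its marginal,
assumed linear: $\partial\pi/\partial x = D_0 + D_1\tilde{x} - D_2 x$.
This covers every linear, quasi-linear or quadratic game. The sign
convention is fixed so that the self-consistent material optimum
$\theta = D_0/(D_2 - D_1)$ (the root of the marginal when peers are assumed
to mirror one's own action) reproduces the known game-specific values: the
preferred action in the coordination game, the benefit-to-cost ratio
$v b / c$ in the public goods game with quadratic costs, and the
identical-agent Nash effort $2(b-c)/(d(n+1))$ in the common pool resource
game. These three anchors are what pin the convention; they are enforced
by unit tests (`theta()` against the closed-form game formulas, and the
marginal against numerical derivatives of the literal payoffs).

Because $u_i$ is a concave quadratic, the best response is closed form: a
weighted average of $\theta$-like material terms, $y$, $\tilde{y}$,
$\tilde{x}$ and $G$, clipped at zero. The normative penalties carry weight
$A_k$ on the squared deviation with no factor $\frac12$; any consistent
factor convention gives identical dynamics after rescaling the $A_k$, so
nothing observable depends on this choice.

**Belief dynamics.** After acting and observing the leave-self-out mean
action $X_i$ of groupmates, revising agents update

$$y' = y + C_{11}(x-y) + C_{12}(X-y) + C_{13}(G-y),$$
$$\tilde{y}' = \tilde{y} + C_{21}(y-\tilde{y}) + C_{22}(X-\tilde{y}) +
C_{23}(G-\tilde{y}),$$
$$\tilde{x}' = \tilde{x} + C_{31}(\tilde{y}-\tilde{x}) +
C_{32}(X-\tilde{x}) + C_{33}(G-\tilde{x}).$$

The first column holds the cognitive forces (dissonance reduction — the
attitude justifies the action taken; social projection — others are assumed
similar to oneself; the logic constraint — beliefs about others' actions
align with beliefs about their attitudes), the second learning from peers,
the third compliance with the authority. `normalized_weights()` reports the
relative strength of the three channels per row
($\alpha + \beta + \gamma = 1$); rows with zero total weight are legal
(a frozen channel) and flagged rather than rejected, since freezing a
belief channel is a meaningful modelling choice.

## Scheduling and noise

One time step (`step_dynamics()`):

1. each agent independently revises with probability `revision_prob`
   (default 0.5);
2. revising agents post their best response as the new action, with
   additive Gaussian noise (`noise_sd`, default 0.01), clipped at zero;
   non-revisers keep their stale action;
3. all agents observe $X_i$ computed from the same simultaneously posted
   action vector (self excluded — each agent sees a slightly different
   mean);
4. revising agents update attitude and beliefs, again with additive noise
   per component, clipped at zero.

The act → observe → update order matches the narrative logic of the model:
beliefs are revised in the light of the action just taken and just
observed. Action and belief revision are coupled in a single Bernoulli
draw. Whether decision errors should perturb only actions or also beliefs
is not determined by the model statement; both channels are implemented
and individually switchable (`noise_on`), with "both" as the default.
Non-negativity is enforced by clipping at zero throughout — the model
requires non-negative variables but prescribes no mechanism, and clipping
is the minimal projection.

## Equilibrium analysis

With noise off and everyone revising, the coupled system is affine:
substituting the closed-form best response into the recurrences gives
$s' = Ls + k$ in the $3n$ stacked coordinates $(y, \tilde{y}, \tilde{x})$.
`predict()` solves $(I - L)s = k$ directly, recovers actions through the
best response, and certifies the result by applying one deterministic step
(residual below $10^{-10}$ by default). Uniqueness and stability are
checked through the spectral radius of $L$, computed on the exact
leave-self-out coupling matrix, not a mean-field approximation;
non-contractive instances raise an error rather than returning an
unreliable point. This exact finite-$n$ solve is the package's single
source of analytic truth: the known closed-form regimes (all variables
equal to the common $\theta$ in a homogeneous group without authority; all
equal to $G$ when material payoffs vanish under an authority) fall out of
it exactly, and the large-$n$ approximation "mean action = mean $\theta$"
(`predicted_mean_action()`) can be compared against it to quantify the
finite-$n$ gap (about 2% or less at $n \ge 20$ in the shipped recipes).
Interior fixed points are assumed; if clipping were active at the fixed
point the certification step reports it.

The evolutionary game theory baselines solve the material-only best-reply
systems. The coordination system is diagonally dominant and solved
linearly. The common pool resource first-order-condition system can have a
corner solution when heterogeneity is strong (the interior solve goes
negative); `nash_baseline()` then switches to damped projected best-reply
iteration (damping $1/(1 + \max|D_1|/D_2)$, which makes the projected map
a contraction) and certifies complementarity: active efforts have zero
marginal payoff, zero efforts non-positive marginal payoff, both at
$10^{-10}$. The per-capita social optimum of the common pool resource game
is the equal split of the total-payoff-maximising group effort
$(b-c)/d$, i.e. $x_{\text{opt}} = (b-c)/(dn)$ — read as a total group
effort because only then does the identical-agent Nash effort exceed it by
the factor $2n/(n+1)$, the anchor the implementation is tested against.

## The population generator

`sample_group()` draws the heterogeneous study populations:

* game primitives from log-normal distributions parameterised by their
  *distribution* mean and standard deviation (mean 1, sd 0.1 by default;
  the moment inversion is $\sigma^2 = \log(1 + sd^2/m^2)$,
  $\mu = \log m - \sigma^2/2$), matching how the study conditions are
  stated; coordination draws $\theta$, $c$, $d$; the public goods game
  draws $c$ and broken-stick shares $v$ (uniform break points of the unit
  interval, mean share $1/n$) with $b$ fixed at 40 for $n = 40$ so that
  the mean benefit-to-cost ratio is about 1; the common pool resource
  game draws $c$, $d$ with $b = 10$, $n = 20$;
* base normative weights $a_1,\dots,a_4$ log-normal(1, 0.1), scaled as
  $A_k = \varepsilon a_k$. At $\varepsilon = 0$ agents are pure material
  maximisers (the evolutionary game theory limit); at $\varepsilon = 1$
  each normative term carries the same expected weight as the quadratic
  material cost terms of the shipped games, which are also centred on 1.
  The scale is a design choice of the generator: the study conditions
  state the equal-weight property, not a recipe, and the log-normal with
  matching moments is the simplest distribution satisfying it;
* belief coefficients $C_{ij}$ log-normal(1, 0.1) per cell, with each
  agent's row rescaled to a total of `row_sum` (default 0.5, over the
  columns active given the authority setting). The rescaling guarantees
  every update is a damped convex move (boundedness) and fixes the
  per-row learning rate; 0.5 places the dynamics midway between frozen
  and one-shot assimilation. The cell-level distribution is a documented
  package choice — the study conditions do not specify it — and all of it
  is configurable;
* initial states uniform on $[0, 0.1]$: a group starting near inaction
  with weak, diffuse beliefs.

What the generator does *not* emulate: real groups have correlated
parameters (e.g. costs correlated with conformity), non-stationary
membership, network structure, and discrete or categorical actions. A
passing test suite shows the implementation reproduces the model's
predictions under the stated stochastic conditions, not that the model
describes any particular empirical population.

## Summary statistics

`equilibrium_stats()` follows the standard protocol: time-average each
agent over the last 100 recorded steps, compute across-agent mean,
standard deviation and Kendall rank correlation with $\theta$ per run,
then average over runs with equal weight (runs hold independently sampled
populations, so pooling across runs would mix different $\theta$
distributions; per-run-then-average is the defensible reading and is the
documented choice). The Kendall variant is $\tau_b$ (tie-corrected — ties
arise after clipping at zero); significance of the ensemble correlation is
a two-sided one-sample t-test of the per-run correlations against zero,
with the single-run case falling back to the per-run test. Convergence
half-time is measured on the group-mean trajectory against the exact
fixed point of that run's population, with linear interpolation between
recorded steps; trajectories that never halve their initial distance are
reported as censored at the trajectory length. Norm tightness is
operationalised as the coefficient of variation per variable (scale-free,
so groups with different equilibrium levels are comparable).

## Problem sizes and determinism

The shipped experiment recipes use the full study protocols: 40
independent runs of 1000 steps with $n = 100$ (coordination), 40 (public
goods) or 20 (common pool resource), statistics over the last 100 steps.
These complete in seconds to a couple of minutes on a single CPU. All
randomness flows from a single master seed: `run_ensemble()` derives
per-run sub-seeds, and identical configuration plus seed reproduces
byte-identical outputs (the provenance log written by `run_recipe()`
records the configuration hash and every sub-seed).

One comparison deserves a note: the direction-of-effect claim that an
authority promoting the *reduced*, socially optimal effort in the common
pool resource game increases equilibrium extraction. Under the default
generator the effect is real but small (about $10^{-3}$ action units, both
in the exact fixed points and in simulation), so the test uses enlarged
paired ensembles with common run seeds (common random numbers) to measure
the difference with adequate precision rather than enlarging the effect by
changing conditions. Mechanism: the authority column drags $\tilde{x}$
towards $G$ below the Nash level, and because $D_1 < 0$ is large in
magnitude (proportional to $n$), lowered expectations about others raise
each agent's best response by more than the direct $A_4$ pull towards $G$
lowers it.

## Known limitations

* The affine fixed-point solver ignores the non-negativity constraint;
  instances whose deterministic equilibrium sits on the boundary are
  flagged through the certification residual instead of being solved as a
  complementarity problem.
* Supplementary game variants (tragedy-of-the-commons forms, linear
  public goods, dictator-style games, and similar) are reachable only
  through `generic_game()` coefficients, not as named presets.
* No interaction networks, no asynchronous sequential updating, no
  foresight or reinforcement learning, no multidimensional actions, no
  Bayesian belief updating.
* With $\varepsilon = 0$ the common pool resource best-reply dynamics are
  near-unstable (the coupling gain $|D_1|/D_2$ exceeds 1 by an order of
  magnitude); simulated means can then sit above the Nash prediction.
  This is a property of the model, reproduced rather than suppressed.
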