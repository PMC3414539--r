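---
title: "Co-evolving opinion dynamics under a media field: model, reduction, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-evolving opinion dynamics under a media field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionfield)
```

## The model

`opinionfield` simulates how a population forms opinions about a statement
with a scientifically correct answer, under the joint influence of personal
discussions, the ambient public mood, individual attitude, and a homogeneous
mass-media drive. Each of the `N` agents carries a continuous opinion
`x_i in [-1, 1]` (`+1` = full agreement with the scientific position, `-1` =
full opposition), a quenched attitude `alpha_i ~ U(-1, 1)`, and sits on an
undirected social network that starts as an Erdos-Renyi graph with mean
degree `<k>`.

Opinions move on a fast *transaction* time scale by explicit Euler steps of
size `dt`:

```
dx_i/dt = alpha_i (m_i + x_i |m_i|)            (long-range / attitude)
        + sum_{j ~ i} sgn(x_i) (|x_i + x_j| - |x_i - x_j|) / 2   (pairs)
        + (h / 2) (1 - x_i)                    (media field)
```

* **Pairs.** The discussion term reinforces same-sign opinions (both agents
  gain conviction `min(|x_i|, |x_j|)` towards their shared sign) and weakens
  opposite-sign pairs. `sgn(0) = +1` throughout the package.
* **Field.** `h > 0` drives towards the scientific position and `h < 0`
  towards the fallacy. The `(1 - x_i)` factor is the model's built-in
  asymmetry: agents already holding the scientific position are unmoved by
  further propaganda, while opponents and undecided agents feel the field at
  full strength. This single term is the only breaker of the `x -> -x`
  symmetry.
* **Long-range.** `m_i` is the *public opinion* seen by agent `i`: the
  shell-weighted mean opinion of all agents at geodesic distance `n >= 2`
  (weights `w_n = 2^-(n-1)`, positive and strictly decreasing; direct
  neighbours are excluded because they already enter through the pair term),
  scaled by a coupling `C = long_range_coupling`. The attitude modulates the
  reaction: positive-attitude agents move with the public mood, negative
  ones against it. The receptivity factor `(1 + x_i sgn(m_i))` makes agents
  at the extreme *opposing* the prevailing mood deaf to it -- a fully formed
  conviction is defended stubbornly -- while leaving the term odd under the
  mirror `x -> -x`, so the zero-field model stays symmetric.

Any `|x_i| >= 1` is clamped to the attained extreme and the agent *freezes*
(total conviction): its opinion never changes again, though it keeps
influencing neighbours. Frozen agents at `+1` are *experts*, at `-1`
*fundamentalists*; undecided agents are *ignorants* with a positive or
negative lean.

Every `g` transactions the network rewires on the slow *generation* time
scale. Each undecided agent cuts its links in decreasing order of
disagreement `|x_i - x_j|` (all of them by default) and creates the same
number of new ones, choosing with probability `q` the *focal* mechanism
(strangers at distance >= 3 or in other components, most similar opinions
first) and otherwise the *triadic* mechanism (friends of friends at distance
2, ranked by the conviction-helping score `|x_i + x_j|`). All plans are
built from the pre-phase snapshot and applied simultaneously -- cuts as a
set union, then creations -- so the result is independent of agent order,
and the edge count may drift (a doubly-cut edge can be replaced twice).
Frozen agents initiate nothing but can be cut from or linked to.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_agents` | 200 | population size |
| `mean_degree` | 6 | initial ER mean degree |
| `field` (h) | 0 | media drive, on the opinion scale per unit time |
| `closure_mix` (q) | 0 | probability of focal (vs triadic) closure |
| `transactions_per_rewiring` (g) | 100 | fast steps per rewiring |
| `step_size` (dt) | 0.01 | Euler step |
| `max_steps` | 50000 | horizon in transactions |
| `long_range_coupling` (C) | 8 | strength of the public-opinion signal |
| `shell_decay` | 2 | base of the shell weights `w_n = b^-(n-1)` |

The published form of the long-range term is not recoverable from the source
text, so two readings are provided. The default is the *normalised* weighted
mean times `C` (an opinion-scale signal, independent of `N`);
`normalize_long_range = FALSE` gives the literal extensive weighted sum,
whose magnitude grows with the population and makes the attitude term
dominate everything else. `C` matters because the attitude term competes
with roughly `<k>` decided neighbours: with `C` well below `<k>` the
attitude is irrelevant and every agent freezes quickly; with `C` far above
`<k> + |h|` attitude-opposed agents are trapped undecided under *either*
field sign. `C = 8` (of order `<k>`) was fixed once, as the value at which
the model reproduces the qualitative asymmetries described for this system:
under a strong negative field every agent ends decided, while under the
mirrored positive field a persistent population of undecided
negative-attitude "ignorants" survives, fewer experts arise at `+|h|` than
fundamentalists at `-|h|`, and the fundamentalist remnant under positive
field is more tightly interconnected than the expert remnant under negative
field. These choices were made from the published qualitative claims, not
from test outcomes, and are not revisited.

With these defaults a typical run at `|h| <= 2` freezes most of the
population within a few hundred transactions (a handful of rewiring
phases); `max_steps` only binds in the undecided-persistence regime.

## Mean-field reduction

In the stationary regime the pair and long-range terms are replaced by slow
ensemble averages `Phi` and `M`, giving the linear equation
`dx/dt = abar |M| x + Phi + (h/2)(1 - x)` with solution
`x(t) = x* + (x0 - x*) e^{lambda t}`,

* `abar = E|alpha| = 1/2`. The raw mean attitude is zero by symmetry and
  would erase the long-range term entirely (forcing `lambda = -h/2` and a
  critical field of exactly zero); the mean *magnitude* is the effective
  modulation felt along the dominant flow, and is the closure adopted here.
  The reduction couples to the magnitude `|M|` (a restoring/repulsive
  spring) rather than transcribing the simulator kernel exactly; this is an
  approximation layer, judged by whether its predictions organise the
  simulation phenomenology.
* Scaled fixed point `z = x*/x_b` with `x_b = sqrt(2)`, chosen so the
  truncated-normal density of initial opinions reads `p0 e^{-z^2}` and the
  decided imbalance `u = n_E - n_F = 1 - 2F(x_b z)` has the exact
  third-order Taylor form `u(z) = -a (z - z^3/3)`, `a = 2 p0 x_b`.
* Closures: `Phi = kbar u(z)` (each decided neighbour pushes with full
  conviction; `|Phi| <= kbar`) and `M = -a z` (linear response of the
  distant-opinion mean; the acyclic layer factor `mu` cancels in the
  normalised average but is computed and reported).

Substituting gives a genuine cubic,

```
(kbar a / 3) z^3 + (abar a x_b) z^2 - (kbar a + h x_b / 2) z + h / 2 = 0,
```

whose branch continuous from the `h -> -infinity` asymptote (`x* -> 1`,
strongly repulsive) is the physical one; it coincides with the largest real
root at every `h`, which is how `solve_fixed_point()` selects it (and a
property test verifies no branch jumps on a fine grid). The eigenvalue
`lambda = abar a z - h/2` is then positive for every `h <= 0` -- the
repulsive fixed point drives negative consensus -- and crosses zero once at
`h_c` (about 2.74 at the defaults), beyond which the attractive fixed point
hinders freezing. In the simulator the onset of undecided persistence is
already visible below `h_c` (the trapped-ignorant mechanism is local, not
mean-field), and well above `h_c` the undecided population is large, rising
from ~6% at `h = 2` to ~28% at `h = 4` at the defaults.

Two horizons appear in the conversion fractions: `rho(s, s')` uses the
asymptotic rule (every agent below a repulsive `x*` converts to `-1`),
while the undecided fraction `s` uses the finite-horizon thresholds
`x_pm = x* + (pm 1 - x*) e^{-lambda g dt}` -- the initial opinions that
reach the extremes within one generation. At the default `g dt = 1` the
band is empty for all `h <= 0` (everyone decides within a generation, so
the degree correction vanishes and the predicted degree equals the initial
one -- the "network stays as random as it started" regime); with shorter
generations the band is non-empty and the predicted degree
`kbar(h) = k0 (1 + s^2 (1 - 1/(k0 - 1)))` decays exponentially in `|h|`.
The gain/loss coefficients in `kbar` are a transcription choice (doubly-cut
edges are replaced twice; a doubly-proposed edge collapses), isolated as
named constants and covered by a dual-path test.

## Survey calibration

The packaged tables transcribe the 15 paired science-perception statements
of the two source questionnaires (European and Mexican), with their
agreement/disagreement percentages; the residual "do not know"/"neither"
mass is carried but never used, because it depends too strongly on protocol.
A statement's agreement fraction is `n_A = yes / (yes + no)`.

`build_response_curve()` maps field strengths to the model's mean agreement
fraction `<n+>(h)` by Monte-Carlo over seeds; by default `n+` counts decided
agents only, mirroring the survey normalisation that excludes "do not know".
Raw ensemble means need not be monotone, so isotonic regression is applied
before linear interpolation -- the inversion assumes a monotone response,
hence monotonicity is enforced rather than hoped for. `assign_fields()`
inverts each statement's `n_A` through the fit; fractions outside the
calibrated range clamp to the grid ends and are flagged. Calibration is run
at a single `q` (default 0.5) because the response depends only weakly on
the closure mix. The default grid `h in [-3, 6] by 0.75` spans the full
dynamic range of the curve at the default parameters (about 0.24 to 0.83)
without saturating at either end; the module's core validity check is the
round trip -- surveys generated by the model at a known `h*` must invert
back to `h*` within one grid spacing.

## What the tests do and do not establish

The synthetic world *is* the model: the generator draws the stated
distributions (uniform attitudes, truncated-normal opinions, ER edges), so
green tests establish internal consistency -- contracts, invariants,
dual-path agreement, mean-field/simulation coherence, round-trip
calibration -- not agreement with any empirical social system. Real survey
populations have response biases, network structure, and question-wording
effects the model does not represent; the packaged survey table is an input
for the calibration procedure, not validation data.

## Numerical choices and edge cases

* Synchronous Euler updates; derivatives always evaluated at the pre-step
  state. The compiled block integrator and the pure-R reference step are
  cross-checked to 1e-12.
* `sgn(0) = +1` everywhere (pair term, classification, `n+`); `alpha = 0`
  counts as positive attitude. Measure-zero conventions, fixed for
  determinism.
* Ranking ties in cutting/closure are broken by the run's single RNG
  stream; all randomness flows from `seed`, and the per-agent draw order is
  fixed (mechanism draw, then tie-breaks), so runs are bit-reproducible.
* Isolated agents have `m_i = 0` and no pair term; under `h > 0` the
  vanishing field at `+1` lets them approach but never attain conviction.
  They are excluded from group nearest-neighbour averages (reported `NA`
  when a whole group is isolated, never silently 0).
* The cubic solver polishes `polyroot` output with Newton steps to meet the
  1e-10 residual contract; `critical_field()` requires an explicit sign
  change on its scan grid and refuses to extrapolate.
* When closure candidates are scarcer than cuts, the plan creates as many
  links as exist and records the shortfall.

## Known limitations

* The exact published algebra of the interaction terms and of the
  mean-field coefficients is not recoverable from the source text; the
  kernel record is pluggable and every transcribed grouping is isolated and
  tested, but the defaults remain this package's own reading. In
  particular, the default long-range kernel `alpha (m + x |m|)` deviates
  from the sketched `alpha x |m|`, whose attitude spring (anchored at
  `x = 0`) traps attitude-opposed agents under *both* field signs and
  cannot reproduce the one-sided undecided phase.
* The mean-field layer ignores correlations, network heterogeneity and the
  co-evolution feedback beyond a single degree correction; its value is the
  sign structure of `lambda(h)` and the existence of `h_c`, not
  quantitative agreement.
* At weak fields (|h| below about 1) the population-count asymmetry between
  truth and fallacy does not resolve: slightly *more* agents end up
  resisting a negative field (freezing at `+1`) than resisting the mirrored
  positive field, by about 1% of the population, because an agent near `+1`
  is shielded from both the field and the conformity force (both vanish
  there) while an agent near `-1` feels the positive field at full
  strength. The expected ordering -- fewer experts under `+|h|` than
  fundamentalists under `-|h|` -- emerges only at moderate-to-strong
  fields (|h| of about 2), where the undecided trap depletes the expert
  count; the cohesion asymmetry (tighter fundamentalist than expert
  communities) holds at every tested magnitude.
* At zero field the network usually, but not always, splits into
  like-minded components within the default horizon; the splitting
  probability grows with the horizon.
* Group-level nearest-neighbour averages depend on an aggregation weighting
  the source text does not define; degree-weighted is the default,
  uniform weighting is available (`nn_weighting`).
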