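---
title: "Belief-system dynamics: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief-system dynamics: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefsim)
```

## The model

`beliefsim` simulates how opinion polarization can emerge in a population
from two human traits alone: beliefs are interrelated, and people strive to
keep their belief system consistent. Agents do not talk to each other; they
are only exposed, one at a time, to a persistent piece of news that links
two concepts with a fixed sign.

Each of the `N` agents holds scalar attitudes in $[-1, 1]$ towards concept
1 ($a_1$) and concept 2 ($a_2$): $-1$ is total condemnation, $+1$ total
support, values near 0 indifference. The news asserts a relation of sign
$K_0 \in \{+1, -1\}$ between the concepts (supportive or contradictory).
When an agent is exposed, the link changes the consistency of their belief
system by the *coherence*

$$C = a_1 \, a_2 \, K_0,$$

which is always in $[-1, 1]$. Positive $C$ is *reassurance* — the news fits
what the agent already believes; negative $C$ is *cognitive dissonance*.
Both drive a re-evaluation of each linked attitude $a$:

$$a' = \mathrm{sign}(a)\,\bigl(|a| + \rho\, C\bigr) + Z_A,$$

with values leaving $[-1, 1]$ set to the nearest endpoint. Reassurance pushes
the attitude further from zero, dissonance pulls it towards zero. The
re-evaluation is *gated* by the hierarchical property of belief systems —
extreme attitudes are hard to change — via the change probability

$$p(\text{change}) = 1 - |a|,$$

applied independently to each of the two attitudes at every exposure. Both
attitudes of an event use the same pre-update coherence $C$: the event
defines one coherence value, and updating sequentially with an
already-updated attitude would be an extra modelling choice we deliberately
avoid.

Iterating this elementary step from uniformly distributed initial attitudes
polarizes the population: attitudes accumulate at the two corner states
consistent with the link sign — $(+1,-1)$ and $(-1,+1)$ for a contradictory
link, $(+1,+1)$ and $(-1,-1)$ for a supportive one — with roughly half the
population at each.

### Adopting a new belief

A second dissonance-relief strategy is "explaining things away": adopting a
third belief that re-contextualises the upsetting news. With
`new_belief = TRUE`, every agent carries a latent predisposition $a_3$
towards a potential new belief linked to concept 1 by a sign
$K_{NB} \in \{+1,-1\}$. When an exposure produces dissonance ($C < 0$), a
non-adopter adopts with probability

$$p(\text{adopt}) = \max\bigl(0,\; a_1\, a_3\, K_{NB}\bigr),$$

i.e. proportionally to the reassurance the new belief would provide, and
never when it would itself create dissonance. Once adopted, the new-belief
edge becomes part of the agent's belief system: at each of the agent's
subsequent exposures (and immediately upon adoption), $a_1$ and $a_3$
receive the same gated, clamped update along that edge, using
$C_{NB} = a_1 a_3 K_{NB}$. Adoption is permanent — no un-adoption mechanism
exists — and a non-adopter's $a_3$ never changes: it is a predisposition,
not yet a belief.

## Parameters

| name | meaning | default | unit/range |
|---|---|---|---|
| `n_agents` | population size N | 100 | ≥ 1 |
| `n_steps` | exposure events T (one agent per event) | 50,000 | ≥ 1 |
| `k0` | sign of the concept-1/concept-2 link | −1 | ±1 |
| `k_nb` | sign of the new-belief link | −1 | ±1 |
| `za` | attitude noise magnitude $Z_A$ | 0.01 | ≥ 0 |
| `rho_mode`, `rho` | change scale: fixed value or U(0,1) per update | fixed, 1 | [0, 1] |
| `new_belief` | enable the three-node mechanism | FALSE | |
| `seed` | RNG seed; determines the run bit-exactly | 1 | integer |
| `epsilons` | extremity thresholds for the metrics | 0.01, 0.05, 0.1 | (0, 1) |

The defaults are the conditions of the headline two-concept experiment; the
three-node experiment uses `n_agents = 1000`, `n_steps = 150000`,
`new_belief = TRUE`, `k_nb = -1`. The noise $Z_A$ takes the values $+0.01$
or $-0.01$ with equal probability, as a fixed magnitude with a random sign
rather than a draw from a continuous distribution: only the magnitude and
the symmetry are specified for the model, and the two-point form keeps
one-step outcome distributions exactly enumerable, which the tests exploit.
$\rho$ may be read either as a fixed scalar (the headline results use
$\rho = 1$) or as a per-update uniform random variable; both modes are
implemented, `fixed` being the default.

## What the simulator emulates — and what it does not

The generator *is* the study design: no external data enters. Initial
attitudes are independent uniforms on $[-1, 1]$ — every stance equally
likely, averaging zero — one uniformly chosen
agent is exposed per event (with replacement), and the news never varies —
its link sign is constant for a whole run. Passing tests therefore show
that the implementation reproduces the model's emergent behaviour
(polarization, corner symmetry, extremity growth, adoption patterns), not
that real populations behave this way: real news streams mix link signs,
real agents influence each other, and real belief systems have many more
than three nodes. Agent-to-agent network dynamics, multi-node belief
graphs, continuous-valued link strengths and heterogeneous noise are out of
scope.

## Numerical and design choices

* **`sign(0) := +1`.** Whenever an endpoint attitude is exactly 0 the
  coherence is 0, so the choice only matters for determinism of the noise
  direction; fixing it makes runs reproducible.
* **No floor on dissonance overshoot.** If $|a| + \rho C < 0$ the update
  formula is applied literally, so strong dissonance can flip an attitude's
  sign in one step before clamping. Flooring $|a| + \rho C$ at zero would
  be an undocumented modification of the update rule.
* **Noise only through an open gate.** The gate decides whether the
  attitude changes at all; a closed gate means no change, including no
  noise. Consequently corner states, where $1 - |a| = 0$, are exact fixed
  points even with $Z_A > 0$.
* **Boundary-inclusive metrics.** An attitude with $|a| \ge 1-\epsilon$
  counts as extreme; corner membership uses the same $\epsilon$ as an
  $\ell_\infty$ box around each corner. Inclusivity matters only on a
  measure-zero set but must be fixed for integer counts.
* **Fixed draw order.** Per event: agent index; then one uniform block
  (gate $a_1$, [$\rho$], noise sign $a_1$, gate $a_2$, [$\rho$], noise sign
  $a_2$, [adoption coin]); then, for adopters only, the new-belief edge
  block. Gate, $\rho$ and sign uniforms are drawn whether or not the gate
  opens, which keeps two runs' streams aligned and makes the mirror
  symmetry $a_2 \mapsto -a_2$, $K_0 \mapsto -K_0$ testable by injecting
  draws (`exposure_step(..., draws = )`). The adoption coin is drawn every
  event in new-belief mode for the same reason.
* **Adoption ordering.** The adoption *trigger* uses the event coherence
  computed from pre-update attitudes; the adoption *probability* and the
  subsequent edge update use the agent's current (post-update) $a_1$, since
  the sub-step runs after the main re-evaluation. The new-belief edge is
  updated only within the selected agent's own exposure events.
* **Serialization.** Tables are written with `%.17g` formatting (CSV) or
  17 significant digits (JSON) so attitude values round-trip bit-exactly;
  the manifest carries every parameter and the seed, which suffices to
  reproduce a run bit-identically.
* **Replicates.** Replicate $i$ uses seed $\texttt{base} + i - 1$, so a
  one-replicate sweep equals a plain run.

## Validation strategy and problem sizes

The unit tests pin the update rules to hand-computed arithmetic, and the
stochastic engine to independent oracles: an exact enumeration of the
one-step outcome distribution (compared against $10^5$ Monte-Carlo draws at
four standard errors), a Kolmogorov–Smirnov check of the initializer,
exact fixed-point and mirror-symmetry identities, and bit-reproducibility
from the seed. The end-to-end suite re-runs the published experiment
scales: the two-concept run ($N = 100$, $T = 50{,}000$; 20 replicate seeds
for the corner split), the large-population extremity-growth runs
($N = 1000$, $T = 150{,}000$, both link signs, 20 seeds) and the full
three-node run ($N = 1000$, $T = 150{,}000$). A complete suite finishes in
a few minutes on one CPU; single runs take a few seconds.

```{r}
p <- model_params(n_agents = 100, n_steps = 20000, seed = 1)
tr <- run_simulation(p)
tr
tail(subset(tr$metrics, eps == 0.1), 3)
```

## Known limitations

* Only the two- and three-node belief graphs are implemented; the general
  modular/hierarchical network case is out of scope.
* The $\rho$ sensitivity sweep and limited-exposure regimes beyond the
  neutral-peak observation are not analysed by the package (the parameters
  to run them are available).
* Metrics are descriptive fractions; no bimodality or variance-based
  polarization indices, and no inter-replicate hypothesis testing.
* The event loop is pure R; it is fast enough for the published scales
  (~10^5–10^6 elementary operations per run) but not tuned for populations
  orders of magnitude larger.
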