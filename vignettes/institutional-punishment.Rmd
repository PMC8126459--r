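---
title: "Methods: endogenous punishment institutions in a public goods game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endogenous punishment institutions in a public goods game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instevo)
```

## The model

`instevo` simulates a population of `N` agents with *fixed* economic
strategies — cooperator or free-rider — whose only adaptive channel is an
institution: the fine level `v` attached to free-riding. Each generation
couples three processes.

**Economic game.** Cooperators contribute `a = contribution_fraction * b`
of their budget `b`; the pot `C = a n_c` is multiplied by `m` and shared
equally among all `N` agents, contributors included. If `v > 0` and
free-riders are present, every free-rider is fined `fine_ratio * v` by an
obligate punisher drawn uniformly at random from the other `N - 1` agents;
the punisher pays `v` per act. Punishment is obligatory by construction,
which deliberately sidesteps the second-order free-rider problem — whether
agents would *choose* to punish is outside this model's scope. Round
accounting is exact: total payoff equals
`N b + (m - 1) C - (1 + fine_ratio) v n_f`, a property the test-suite
checks to 1e-9 over randomized rounds.

**Political game.** Once per generation a candidate fine is drawn from
`Normal(v, proposal_sd)`, clamped at zero. Proposals are exogenous draws —
no agent authors them — and are voted on *before* the round is played, so
an adopted amendment binds immediately (`vote_order` flips this for
robustness checks). Every agent compares deterministic forecasts of its
own type's long-run per-generation payoff under incumbent and candidate,
votes for the candidate only on a strict improvement, and a strict
majority (> N/2) adopts it; ties and indifference retain the status quo.

**Reproduction.** Payoffs floored at `fitness_floor` become Wright–Fisher
sampling weights for a fixed-size next generation; strategies are
inherited, never mutated. A Moran variant (N birth–death events per
generation) is available behind `reproduction = "moran"`.

## Expected dynamics and the critical fine

The forecasting machinery, and the validation oracle for the simulator, is
a mean-field "focal agent" calculation: the focal agent's type is held
fixed while the other `N - 1` agents are cooperators with probability `p`:

```
pi_c(p, v) = b - a + m a ((N-1) p + 1) / N - v (1 - p)
pi_f(p, v) = b     + m a (N-1) p / N - fine_ratio v - v (1 - p)
```

The expected obligate-punisher burden is `v (1 - p)` for *both* types: a
focal free-rider is excluded from its own punishment slot but is also
missing from its own eligible pool, and the two finite-`N` corrections
cancel exactly. The payoff gap is therefore affine in the fine,

```
pi_f - pi_c = a (1 - m/N) - fine_ratio * v,
```

with root `v* = a (1 - m/N) / fine_ratio` — the **critical fine**
(`critical_fine()`), 0.49 for the baseline economy at `N = 100`. Two
different "free-rider advantages" must not be confused here:

* *within a round*, a free-rider out-earns a cooperator by exactly `a`
  (both receive the same pot share);
* *counterfactually*, switching one agent from cooperation to free-riding
  gains only `a (1 - m/N)`, because the defector's own pot share shrinks.

Selection between types inside one population is governed by the
within-round comparison; the focal-agent expectation governs the
mean-field projection, and the realized mean-payoff crossover in
simulation sits at `a / (fine_ratio - 1/(N-1))`, within `O(1/N)` of `v*`.
The tests assert each form where it actually holds.

`project_dynamics()` iterates the selection map
`p' = p f_c / (p f_c + (1 - p) f_f)` with `f = max(pi, fitness_floor)`,
absorbing at `p = 0, 1`. With voting disabled the stochastic simulator's
mean trajectory tracks this projection within Monte-Carlo error (checked
at `N = 1000`, 50 replicates, five fine levels spanning `v*`).

## The forecast rule: steady-state by default

What does an agent compare when voting? Agents are granted *accurate
long-term prediction*: `forecast_payoff()` projects the population forward
under each fine and summarises the agent's own type's expected payoff,
treating the type as persisting even where its projected frequency
vanishes (so a forecast is defined for both types at any state).

Two summaries are implemented:

* `forecast_mode = "steady"` (default): the payoff at the projected
  steady state (convergence tolerance 1e-6, capped at `10 * H`
  iterations). The cap doubles as a foresight bound: a transition too slow
  to complete within `10 H` generations is evaluated at wherever it got.
* `forecast_mode = "horizon"`: the mean payoff over the next `H`
  projected generations.

The steady-state rule is the default because it is the reading under which
the institution can *start*. Consider the first supercritical candidate at
`p = 0.05` against incumbent 0. On the way to cooperator fixation the
majority free-riders pass through many generations of fines and punisher
duty before the growing pot repays them; averaged over a short window the
transition costs dominate, so under a horizon-mean rule with small `H`
(tens of generations) *no* candidate ever beats the incumbent and the fine
stays at zero forever. The emergence narrative requires voters who weigh
where the economy ends up, not the transition pain — which is also the
natural formalisation of agents who accept short-term losses for long-term
gains. Horizon-mean forecasting with `H` of several hundred behaves
similarly to steady-state and is kept for sensitivity work.

A consequence worth knowing: free-rider majorities prefer the *weakest*
fine whose projected outcome still favours cooperators, so between the
first adoption and cooperator majority the electorate ratchets the fine
down toward the edge of its acceptance set, where selection for
cooperators is weak. Once cooperators hold the majority the ratchet
reverses. This weak-selection interlude is why population size matters
(next section).

## Default study conditions

The baseline economy is `b = 10`, `contribution_fraction = 0.10`,
`m = 2`, `fine_ratio = 2`, initial cooperator share 5%, fine starting at
0, `G = 1000` generations and `R = 100` replicates. The remaining defaults
are this package's own choices:

* **`group_size = 5000`.** The run starts with `round(0.05 N)`
  cooperators declining at roughly 10% per generation until the first
  adoption, and then growing under selection that the ratchet can push
  close to neutrality. The rescue therefore passes through a bottleneck
  where its fate is decided by `n_c * s`; with `N = 100` the five initial
  cooperators are inside drift's reach (a branching-process survival
  chance well below one half even for a strong fine), and cooperators
  usually die out regardless of the institution. `N = 5000` puts the
  bottleneck firmly in the selection-dominated regime, so the model's
  central behaviour — emergence of punishment carrying cooperators to
  majority — is the typical outcome rather than a lucky one. The
  acceptance suite runs the full pipeline at this default.
* **`proposal_sd = 0.5`.** Unstated in the source material; chosen of the
  order of the critical fine, so supercritical candidates appear within a
  few generations (essential: the bottleneck is already shrinking), while
  the sensitivity grid `{0, 0.05, 0.1, 0.2, 0.5, 1}` still spans "cannot
  reach `v*`" to "exceeds it easily".
* **`forecast_horizon = 50`** sets the steady-mode iteration cap at 500
  projected generations — long enough to resolve transitions an order of
  magnitude slower than the baseline takeover, short enough that
  effectively-stalled transitions are scored by their (unattractive)
  intermediate state.
* **`fitness_floor = 0.01`** (currency units): payoff of an agent fined
  into the negative range still maps to a positive reproduction weight;
  0.1% of the budget preserves payoff ranking above it and makes
  floored types' expected offspring share negligible rather than zero.

## Numerical and accounting conventions

* The generation-0 cooperator count is `round(fraction * N)` exactly —
  deterministic count, random placement — so the stated initial condition
  is testable, not binomially noisy.
* Candidate fines are clamped at 0; the raw draw is kept on the proposal
  record.
* Vote ties and indifference retain the incumbent (status quo bias of a
  strict-majority rule).
* Type mean payoffs for an extinct type are emitted as missing values,
  never 0, and serialize as empty CSV fields / JSON `null`s, so medians
  across replicates are not dragged toward zero after extinctions.
* Each replicate runs on an RNG substream seeded by a counter-based hash
  of `(master_seed, replicate_id)`: replicates are order-independent,
  individually reproducible, and earlier replicates are unchanged when
  `n_replicates` grows. Within a generation the stream is consumed in a
  fixed order (proposal, punisher selection, reproduction). Identical
  configuration and seed give byte-identical trajectory files.
* Forecasts are memoised per replicate keyed by (cooperator count, fine),
  which is exact because the forecast is a deterministic function of that
  pair.

## What the simulator does and does not emulate

The generator reproduces the stated study conditions: a single isolated
group, fixed size, fixed strategies, one exogenous amendment per
generation, universal equal-weight suffrage, obligate peer punishment and
perfect-foresight voting. Passing tests therefore demonstrate the internal
logic of the two-stage mechanism — they do not speak to human groups with
strategy switching, imperfect or heterogeneous foresight, agent-authored
proposals, unequal political influence, pool punishment, optional
punishment, partial contributions, mutation, spatial or group structure,
or migration. All of those are explicit non-goals here.

Within the model, known sensitivities worth flagging: the emergence
probability depends materially on `group_size` (drift bottleneck) and
`proposal_sd` (how soon a supercritical candidate appears), and the
post-takeover fine level is a ratchet artefact of unanimous-cooperator
indifference plus occasional upward acceptances near fixation; its exact
value should not be over-interpreted.

## Problem sizes used by the checks

The test-suite exercises the full baseline (`N = 5000`, `G = 1000`) with
20 replicates for the emergence, shape, audit and sensitivity checks;
oracle-equivalence runs at `N = 1000` with 50 replicates over 100
generations; accounting and distributional properties use randomized small
rounds (thousands of draws). `scripts/acceptance.R` re-runs the same
pipeline sizes (25 replicates for the baseline batch) from a caller-
supplied seed.
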