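---
title: "Methods: a predator-prey lattice ecosystem with deep Q-learning co-evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a predator-prey lattice ecosystem with deep Q-learning co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The ecological model

`predpreyRL` simulates an individual-based predator-prey system on an
`L x L` square lattice with periodic boundaries. Each site is empty,
holds one prey, or holds one predator. Time advances in Monte Carlo
steps (MCS); one MCS is `L*L` trials, and updating is asynchronous:
every interaction mutates the lattice immediately, so later trials in
the same MCS see the change.

Each trial draws one site uniformly at random and pairs it with one of
its eight Moore neighbours (orthogonal + diagonal, wrapped). The
pairing resolves by the first matching rule:

* **predator + empty** - the predator moves;
* **predator + prey** - the prey is eaten; with probability `bX` a
  newborn predator appears on the captured site (the parent stays),
  otherwise the predator moves onto it;
* **prey + empty** - with probability `bY` a newborn prey (age 0)
  appears on the empty site (the parent stays), otherwise the prey
  moves;
* anything else (an empty first site, or two agents that cannot
  interact) changes nothing. These "failed actions" still consume a
  trial, so the MCS clock advances uniformly.

Each predator carries a food reserve, started (and restored by every
meal) at `fX_init = 1` and reduced by the metabolic rate
`metabolic_decay = 0.1` once per MCS, after the `L*L` trials. A
predator whose reserve reaches zero starves. Prey do not eat but age by
one MCS in the same sweep and die beyond `prey_max_age = 100`.
Predators have no maximum age; they die only of starvation (the model
gives them no other intrinsic mortality).

Default parameters - `L = 100`, 500 predators and 2000 prey placed
uniformly at random on distinct sites, `bX = 0.8`, `bY = 0.1` - produce
the classic quasi-stationary oscillatory coexistence: predator booms
deplete prey, starvation thins the predators, prey recover. Under these
defaults the long-run means (20,000 MCS, 1,000-MCS burn-in) are roughly
880 predators and 1650 prey.

## Numerical choices in the lattice core

* **Starvation threshold.** Food is compared against zero with a
  `1e-9` tolerance, so a unit reserve decayed by 0.1 runs out after
  exactly 10 MCS despite 0.1 having no exact binary representation.
* **Newborns.** A newborn predator starts with a full reserve, a
  newborn prey at age 0; both were open choices (fresh agents start
  fresh). Offspring born during an MCS still pass through that MCS's
  metabolism/ageing sweep.
* **Food on predation.** A meal *resets* the reserve to `fX_init`
  rather than incrementing it; the reserve is bounded and a single
  counter suffices.
* **Trial site choice.** Uniform over all `L^2` sites, occupied or not;
  an empty first site is a no-op trial.
* **RNG.** A single seeded generator drives everything - site and
  neighbour choices, reproduction draws, epsilon-greedy exploration,
  minibatch sampling, weight initialisation - in a fixed documented
  order, so every run is bit-reproducible from its seed.

# The learning layer

Selected species are promoted from random walkers to learners. A
learning agent standing at a site observes the `vr x vr` window centred
on itself (`vr = 9`, wrapped at the boundaries), coded 0 = empty,
1 = prey, 2 = predator, and chooses one of nine actions: the eight
Moore moves or stand-still. A move is then resolved by exactly the same
pairwise rules as above - a predator stepping onto prey eats it, a prey
stepping onto an empty site may instead leave a newborn, and a blocked
move changes nothing.

## Rewards

Rewards are shaped by Chebyshev distance
(`max(|dr|, |dc|)`) shells around the agent. With `n_k(Y)` prey and
`n_k(X)` predators in shell `k`:

* predator: `20 n_1(Y) + 10 n_2(Y) + sum_{k>=3} n_k(Y)` when any prey
  is visible, and -10 otherwise;
* prey: `-10 n_1(X) - n_2(X)` when any predator is visible, and +10
  otherwise.

A 9 x 9 window has shells `k = 1..4` of sizes 8, 16, 24, 32. The prey
rule's visibility condition is evaluated on predator counts - the
reward penalises nearby predators, so its branches must switch on
predators, not on prey.

The reward of a transition is evaluated on the *post-action*
observation: a state-shaped reward scored before moving would be
identical for all nine actions and carry no action gradient. One
consequence is discussed under *Limitations*.

## Q-network

Each species shares one Q-network (population learning: experience
gathered by all individuals trains the single species policy, which is
how experience reaches offspring). The architecture maps the window,
expanded into two binary channels (prey mask, predator mask), through

* 1x1 convolution, 32 filters, stride 1;
* 1x1 convolution, 64 filters, stride 1;
* a fully-connected layer of 32 units;
* batch normalization and ReLU after each hidden layer;
* a fully-connected tanh output with one Q-value per action.

The code for the centre cell (the agent itself) is included in the
input; it is constant per species and carries no information. Because
the 1x1 convolutions act per pixel on a three-valued code, the whole
network below the first fully-connected layer collapses, at inference
time, into a per-pixel per-code lookup table; `fold_policy()` exploits
this so the Monte Carlo engine evaluates one observation in a few
thousand floating-point operations.

## Training

Transitions `(s, a, r, s', terminal)` go to a bounded per-species FIFO
replay memory (default 10,000 tuples; a config choice, as is
everything below unless noted). Training minimizes the pseudo-Huber
loss `mean(sqrt(1 + (y - Q(s,a))^2) - 1)` - quadratic near zero,
asymptotically linear, so rare large shell rewards do not destabilize
the fit; plain squared error is selectable. Targets are
`y = r/100 + gamma * max_a' Q(s', a')` with `gamma = 0.95`, computed on
a lagged target copy of the parameters; terminal transitions (the agent
died later in the same MCS - eaten, starved or aged out) do not
bootstrap. Optimization is Adam, learning rate 0.01, minibatches of 32.

Rewards are divided by `reward_scale = 100` before entering targets
because the tanh head bounds Q-values to (-1, 1) while raw shell
rewards reach tens; without scaling the regression targets would be
unreachable. This is a repair the architecture forces, not a tunable of
the ecology.

**Cadence.** The behaviour policy is epsilon-greedy with epsilon
annealed linearly from 1 to 0.05 over 10,000 MCS (then held), counted
from the species' `start_mcs`. One gradient step runs every MCS once
the buffer holds a minibatch; the target network and the folded
behaviour policy refresh every `train_period` MCS (default 50). Both
cadences are config-exposed, so "train every MCS" and "train every
`t` MCS" are both expressible; the default wiring uses the per-MCS
gradient step with periodic target/behaviour refresh.

**Batch normalization** uses minibatch statistics during training and
exponential running averages (momentum 0.99, epsilon 1e-5) for
inference/action selection. Two caveats follow. First, the fixed point
`Q(s,a) = y` on a degenerate (single-transition) replay holds in the
training regime; inference-mode values need input diversity for the
running statistics to be meaningful. Second, on artificially tiny state
spaces the network can lean on batch composition; wide minibatches
remove this, which the toy-chain test does explicitly.

**Initialization.** He-scaled normal weights for the rectifier layers,
Xavier-scaled for the tanh head, BN scales at 1, drawn from the run's
seeded RNG stream.

# Experiments

`table_cases()` builds the eight standard wirings (no learning;
predator-only; prey-only; co-evolution; staggered starts 0/500 in both
orders; unequal training periods 50/100 in both orders).
`run_case()` runs one wiring and returns the per-MCS population series
(including the initial state at MCS 0), extinction times, optional grid
snapshots, training losses and the trained networks. In
`apply_frozen` mode the ecosystem runs by the base random rules for
1,500 MCS, after which previously trained, frozen networks drive
behaviour at a fixed exploration of 0.05 with no parameter updates.

Summaries (`summarize_run()`) report means over a declared window; the
default drops the first 1,000 MCS as burn-in, a choice reported
alongside every summary rather than hidden. Slow trends are read with
`lowess_trend()`, a LOWESS smoother (default span 0.1) over the count
series.

## Scaled study protocol

The full case studies run 20,000 MCS. The bundled test-suite exercises
the learning cases at a 10,000-MCS horizon with every learning
hyperparameter at its default - in particular the 10,000-MCS epsilon
anneal, so the horizon covers exactly the annealing phase. This is the
package's standard desk-scale protocol, chosen for a substantive
reason beyond runtime: shortening the anneal instead (e.g. to half the
horizon) pushes the policies into the near-greedy regime much earlier
in the ecosystem's life than the full protocol ever does, and that is
not a faithful miniature of the full experiment (see *Limitations* -
near-greedy predators over-express prey-farming and can crash their own
population).

At this horizon the qualitative case orderings match the full-scale
results: predator-only learning raises both species' means above the
baseline; prey-only learning depresses predators and lifts prey;
co-evolution yields the lowest predator mean of the first four cases;
and the inconsistent wirings in which prey learn first, or prey train on
a slower period than predators, drive predators extinct within the run.
Numeric means at the reduced horizon are *not* comparable to full-run
means (they average a different, annealing-dominated phase).

# What the synthetic worlds do and do not emulate

All inputs are generated: random initial placements via `init_world()`
(the study conditions) and prescribed placements via
`build_scenario()` for deterministic fixtures. The generator reproduces
the model's own study conditions exactly - it *is* the model - but the
model itself idealises heavily: two species, homogeneous habitat, one
agent per site, discrete synchronously-decayed metabolism, no
individual variation, no sensory noise. Passing tests therefore
establish internal correctness and reproduction of the model's
reference behaviour, not claims about any real ecosystem.

# Limitations

* **Prey farming.** Because rewards are functions of the observed
  state only, a predator maximizes its discounted return by *keeping*
  prey in its first shell, not by eating them: eating removes the
  reward source. The food reserve is not part of the observation, so
  starvation cannot be credited to the farming behaviour - the process
  is partially observable in a way the learner cannot resolve. Softly
  explorative policies (the annealing phase) express this tendency
  mildly, which in fact stabilizes the ecosystem (fewer kills, larger
  prey base - the coexistence pattern the case studies show); fully
  greedy policies express it strongly enough to starve the predator
  population. This is a property of the model's reward design, which
  the package reproduces, not an artefact of the implementation.
* **eps = 1 is not the base model.** A fully exploring learner picks
  uniformly from nine actions including stand-still, while a
  non-learning agent picks one of eight neighbours; learner kinetics
  are therefore slower by about one trial in nine, which shifts
  quasi-stationary means by a few percent (measured ~ -4% predators,
  ~ +10% prey at the defaults). Tests compare the two modes with an
  envelope, not an equality.
* **Small lattices.** Well below `L = 100` the oscillations are large
  relative to the populations and stochastic extinctions become
  common; small-lattice fixtures are for mechanics, not ecology.
* **BN idiosyncrasies** on degenerate data, as described above.

# Reproducing the headline numbers

`scripts/acceptance.R` regenerates, from a fresh seed, the baseline
ecology means (3 seeds x 20,000 MCS, burn-in 1,000) and the reward
branch values, and writes them as JSON. See the README for the exact
invocation.
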