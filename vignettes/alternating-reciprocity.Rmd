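---
title: "Memory-one strategies in alternating donation games: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-one strategies in alternating donation games: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altgame)
```

## The model

Two players repeatedly decide whether to cooperate (C) or defect (D) in a
donation game: cooperation costs the donor `c` and delivers a benefit
`b > c` to the recipient, so the per-round payoffs are `R = b - c`,
`S = -c`, `T = b`, `P = 0`. The package supports two move structures:

* **simultaneous** — both players decide at once, as in the classical
  repeated prisoner's dilemma;
* **alternating** — players move in turns; each decision is observed by
  the co-player before the co-player's next decision.

Players use *memory-one strategies*, 4-tuples
`q = (qCC, qCD, qDC, qDD)` giving the cooperation probability as a
function of (own last action, co-player's last action). *Reactive*
strategies are the sub-class that ignores the own last action
(`qCC = qDC`, `qCD = qDD`). Implementation errors flip each intended
action with probability `eps`, which turns a strategy `q` into the
effective strategy `(1 - eps) q + eps (1 - q)`; all payoff computations
apply this transform internally.

## Exact payoffs

A strategy pair induces a Markov chain on the four joint outcomes
(CC, CD, DC, DD), ordered with player 1's action first. In the
alternating game one chain transition is one full *round*: player 1 acts
on the current state, then player 2 responds to player 1's fresh action
together with its own last action. Long-run payoffs read the stationary
distribution `v` through
`pi1 = (vCC + vDC) b - (vCC + vCD) c` (and symmetrically for player 2),
which gives the exact payoff identity
`pi1 + pi2 = (b - c)(rho1 + rho2)` used as a standing regression check.

**Degenerate chains.** For deterministic strategies without errors the
chain can have several closed communicating classes (TFT self-play has
two in the alternating game, three in the simultaneous game). The engine
then decomposes the chain, computes each closed class's time-average
(Cesàro) distribution, and mixes them with absorption probabilities
started from the first round.

**First-round convention.** The game's opening is specified as a phantom
history `(a1, a2)`, default `(C, C)`: both players act *on* that virtual
previous state — player 1 moves with probability `p[a1, a2]`, player 2
responds to `(a2, i')`. We chose this over the alternative of playing
`a1` literally because it lets each strategy's own rule govern the first
move: TFT and GRIM open cooperatively from `(C, C)` (the only constraint
the theory imposes, so that their self-play payoffs are well defined)
while unconditional defectors open with defection, which keeps the
discounted payoff of ALLD against ALLD at exactly zero. The convention
only matters for degenerate chains and for discounted games; with
`eps > 0` every chain is ergodic.

**Discounting.** With continuation probability `delta < 1` per round, the
per-round outcome distribution is the normalized discounted visit vector
`(1 - delta) v0 (I - delta M)^-1`; the expected game length is
`1/(1 - delta)` (25 rounds at `delta = 0.96`), which
`expected_rounds()` recomputes from the resolvent rather than assuming.

**Irregular alternation.** With switching probability `s < 1` the game is
tracked per *move* on an 8-state chain (both last actions x whose turn it
is); the mover acts on (own last, other's last) and the turn passes with
probability `s`. Payoffs are normalized per round (two moves), which
reproduces the strict-alternation payoffs at `s = 1` to 1e-10.

**Numerics.** Stationary distributions come from a direct linear solve of
the balance equations with a normalization row (LAPACK, via a small
compiled kernel for ergodic chains); the solve is accepted only if the
result is nonnegative and satisfies `v M = v` to 1e-8, otherwise the
communicating-class path takes over (support-graph classes at an edge
threshold of 1e-12). Payoff comparisons use 1e-10, stochasticity checks
1e-12, Nash comparisons 1e-9 (weak inequalities, so boundary cases such
as WSLS at `b = 2c` count as equilibria).

## Nash machinery

Against a fixed memory-one co-player in the alternating game, any
memory-one strategy can be replaced by a *reactive* strategy — the
stationary-weighted average of its entries conditioned on the co-player's
last action — without changing either player's payoff
(`reactive_reduction()`; the package verifies this numerically and also
exhibits counterexamples for the simultaneous game, where the reduction
fails). Consequently a strategy `q` is a Nash equilibrium among
memory-one (indeed finite-memory) strategies if and only if none of the
four extreme reactive deviations ALLD, ALLC, TFT, ATFT beats `q`'s
self-payoff; `nash_check()` implements exactly this four-deviation
recipe. If the conditioning event of a reduction entry has zero
stationary mass the entry is unconstrained; we report the plain average
of the two contributing probabilities and flag it.

Nash equilibria fall into three classes, with closed-form conditions:

* **partners** (`is_partner()`): fully self-cooperative equilibria —
  `qCC = 1`, `qCD <= 1 - (c/(b-c)) qDD`, `qCD <= 1 - (c/b) qDC`;
* **defectors** (`is_defector()`): mutually defecting equilibria —
  `qDD = 0`, `qDC <= (c/b)(1 - qCD)`, `qDC <= (c/(b-c))(1 - qCC)`;
* **equalizers** (`is_equalizer()`): strategies that pin the co-player's
  payoff to a constant regardless of the co-player's behavior.

With errors (`0 < eps < 1/2`) the partner polyhedron collapses to the
line segment between Generous Tit-for-Tat and Stochastic Firm-but-Fair
(`gtft()`, `sfbf()`, `partner_with_errors()`), and partners exist only
for `eps < (1/2)(1 - c/b)`. Every such partner can be invaded neutrally
by any strategy with `pCC = pDC = 1` (e.g. ALLC or TFT): the invader
earns exactly the resident's self-payoff against the resident
(`neutral_invaders()` verifies this to 1e-9). Note that this neutrality
holds at the invasion margin only; in a mixed population the payoffs
`pi(p, p)` and `pi(q, p)` generally differ, so the fixation probability
of such an invader is close to, but not exactly, `1/N`.

`classify_strategy()` uses the closed forms when `eps = 0`. With errors,
the partner verdict remains closed-form while defector-like and
equalizer-like labels are assigned numerically and flagged as such:
defector-like means a self-cooperation rate below `eps + 0.01` — errors
alone force a self-cooperation rate of about `eps`, so a fixed 1%
threshold would be unattainable at `eps = 0.02`; the criterion we use
asks for no cooperation beyond that error floor. Equalizer-like means a
co-player payoff variance below 1e-12 across random probe opponents.

## Evolutionary dynamics

A well-mixed population of `N` players evolves by the pairwise-comparison
process: a random focal player either explores (probability `mu`,
drawing a uniformly random memory-one strategy) or imitates a random
role model with the Fermi probability
`1 / (1 + exp(-beta (pi_R - pi_F)))`. In the rare-mutation limit
(`run_rare_mutation()`) the population is monomorphic between mutations
and each mutant fixes with the standard birth-death fixation probability
computed from the four pairwise payoffs (checked against an explicit
absorption solve to 1e-12); time is counted in introduced mutants,
residents start from ALLD, and the recorders weight residents by dwell
time. Self-cooperators (self-play cooperation at least 80%) and
self-defectors (below 20%) are recorded with dwell-weighted marginals on
a fixed 50-bin grid; both thresholds are configurable. Robustness counts
how many mutants a resident survived; the final resident is
right-censored and excluded from means by default. The explicit finite-
`mu` process (`run_explicit()`) tracks the full census with pairwise
payoffs cached per strategy pair and each player's payoff averaged over
the other `N - 1` members (self-interaction excluded).

The lattice model (`run_lattice()`) places players on a periodic `L x L`
grid (default 50 x 50). Each generation every player collects the sum of
its long-run pairwise payoffs against its eight neighbors, then all
players update synchronously from that pre-update payoff field: with
probability `mu = 0.002` a player adopts a uniformly random strategy,
otherwise it imitates its best-paid neighbor, but only on strict payoff
improvement (ties broken uniformly). Mutation and imitation are mutually
exclusive branches of one update. Pairwise payoffs use the infinite-game
stationary values, cached per strategy pair.

## What the simulations do and do not show

The rare-mutation and lattice generators reproduce the *study
conditions*: baseline `b = 3`, `c = 1`, `N = 100`, `beta = 1` (or
`beta = 5` for the strategy-distribution recordings), `eps` either 0 or
0.02, mutations uniform on the strategy cube, ALLD founders. They are
exact implementations of the stylized process, not of any empirical
system: real interactions have heterogeneous stakes, structured encounter
rates, and non-uniform strategy exploration, so passing tests certify the
mathematics of the model, not behavioral predictions.

Problem sizes in the test suite are chosen to keep each check sharp at
desk scale: closed-form anchors run in milliseconds; oracle comparisons
(power iteration, birth-death absorption, Monte-Carlo move simulation)
use tens of random cases at fixed seeds; evolutionary comparisons use
10^5 introduced mutants across 10-20 seeds per condition. One property
deserves a caveat: the embedded resident chain of the simultaneous game
with errors mixes slowly, because its WSLS-like cooperative states are
simultaneously hard to reach from ALLD founders (fixation probabilities
around 1e-5 per mutant) and extremely durable once reached. Time
averages at 10^4 mutants are therefore burn-in dominated and can even
invert the long-run ordering of the two game modes; at 10^5 mutants the
ordering (simultaneous above alternating with errors) is restored in the
across-seed mean, which is what the acceptance-level test asserts.

## Design choices on open points

* GRIM is the tuple `(1, 0, 0, 0)` — defect forever after any defection.
* Strategy equality uses exact comparison for catalog constants and
  1e-12 elsewhere.
* The mutation hook accepts an arbitrary strategy pool (used by the
  two-strategy oracle tests); local Gaussian mutation kernels are out of
  scope.
* Tie-breaks among equally-paid best neighbors on the lattice are
  uniform random; a mutating player skips imitation entirely.
* The CLI (`inst/scripts/altgame`) is a thin veneer: every subcommand
  calls the exported functions documented here, and every stochastic
  entry point takes an explicit `--seed`.

## Known limitations

* Only the donation-game payoff structure is supported (no general
  prisoner's dilemmas), and only two players per game.
* Closed-form defector/equalizer characterizations *with* errors are not
  implemented; the numeric Nash check is authoritative there.
* Memory beyond one round appears only through the pure-strategy count
  `count_pure_strategies()`; no memory-2 dynamics.
* Evolutionary quantities are Monte-Carlo estimates; at the run lengths
  used in tests their across-seed spread is a few percentage points of
  cooperation rate.
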