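# altgame

Direct reciprocity with alternating moves. Most models of repeated
cooperation assume both players decide simultaneously; many natural
exchanges (food sharing, favors, taking turns leading) are asynchronous.
`altgame` provides the machinery to analyze the repeated **donation game**
(cooperation costs the donor `c`, benefits the recipient `b > c`; per
round `R = b - c`, `S = -c`, `T = b`, `P = 0`) when players move **in
turns** instead of at once, and to compare the two move structures.

For researchers and students in evolutionary game theory, the package
offers three layers:

1. **Exact payoffs.** A pair of memory-one strategies
   `q = (qCC, qCD, qDC, qDD)` (cooperation probability given both
   players' last actions) induces a 4-state Markov chain over the joint
   outcomes. `stationary()`, `payoffs_discounted()` and
   `payoffs_switching()` return the long-run outcome distribution,
   payoffs `pi1 = (vCC + vDC) b - (vCC + vCD) c` and cooperation rates —
   with implementation errors (`eps`), discounting (`delta`), and
   irregular alternation (switching probability `s`), handling degenerate
   chains by communicating-class decomposition.
2. **Equilibrium analysis.** In the alternating game, checking whether a
   memory-one strategy is a Nash equilibrium reduces to comparing its
   self-payoff against four extreme deviations (ALLD, ALLC, TFT, ATFT):
   `nash_check()`. Closed-form characterizations classify equilibria as
   **partners** (`qCC = 1`, `qCD <= 1 - (c/(b-c)) qDD`,
   `qCD <= 1 - (c/b) qDC`), **defectors**, or **equalizers**; with errors
   the partner set collapses to the segment between Generous Tit-for-Tat
   and Stochastic Firm-but-Fair (`gtft()`, `sfbf()`).
3. **Evolution.** Pairwise-comparison (Fermi) dynamics in well-mixed
   populations — including the rare-mutation limit with analytic fixation
   probabilities (`run_rare_mutation()`, `fixation_probability()`) — and
   imitate-the-best dynamics on a periodic lattice (`run_lattice()`).

## Worked example

Is Win-Stay Lose-Shift — the gold-standard cooperative strategy of the
*simultaneous* game — still an equilibrium when moves alternate and
players err 2% of the time?

```r
library(altgame)

spec <- game_spec("alternating", b = 3, c = 1, eps = 0.02)
wsls <- named_strategy("WSLS")

stationary(wsls, wsls, spec)
#> long-run outcome distribution (CC, CD, DC, DD):
#>   CC   CD   DC   DD
#> 0.25 0.25 0.25 0.25
#> payoffs: pi1 = 1.000000, pi2 = 1.000000; cooperation: rho1 = 0.500000, rho2 = 0.500000

nash_check(wsls, spec)
#> Nash: no (self payoff 1.000000)
#> best deviation: TFT with payoff 1.940032
```

WSLS self-play collapses to 50% cooperation under alternation with
errors, and deviating to Tit-for-Tat beats it — it is not an
equilibrium. The strategies that do sustain cooperation here must
randomize after mutual defection:

```r
sfbf(spec)
#> memory-one strategy (pCC, pCD, pDC, pDD):
#>        CC        CD        DC        DD
#> 1.0000000 0.0000000 1.0000000 0.6484547

classify_strategy(sfbf(spec), spec)
#> Nash: yes (self payoff 1.903846)
#> best deviation: ALLC with payoff 1.903846
#> class: partner
```

Stochastic Firm-but-Fair reciprocates cooperation always, never tolerates
exploitation, and cooperates with probability 0.648 after mutual
defection; it earns the near-full cooperation payoff 1.904 (out of
`b - c = 2`) against itself and no deviation can beat it. Its weakness is
evolutionary: any strategy with `pCC = pDC = 1` (e.g. ALLC) earns exactly
the same 1.903846 against it and can drift in neutrally —
`neutral_invaders(sfbf(spec), spec)` tabulates this.

A command-line wrapper ships in `inst/scripts/altgame`:

```sh
Rscript inst/scripts/altgame classify --q 1,0,1,0.648454746137 --b 3 --c 1 --eps 0.02 --json
Rscript inst/scripts/altgame evolve --mode alternating --eps 0.02 --N 100 --beta 1 \
    --regime rare --steps 10000 --seed 7 --out trace.csv
```

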