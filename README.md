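# sensgame

Evolutionary game models of migraine persistence.

Migraine is common, painful and disabling, yet natural selection has not
removed it. `sensgame` implements an evolutionary-game account of why: the
migraineur is a *hypersensitivity phenotype* that detects predators early,
at a personal cost, and trades that early warning for rescue during attacks
under a reciprocal-altruism agreement with less-sensitive non-migraineurs.
When the two phenotypes compete for cooperation, the payoff pattern is that
of the Hawk–Dove game, and the population can settle at a mixed
evolutionarily stable state (ESS) with a stable intermediate migraineur
frequency.

The package is for modellers who want this argument as tested, runnable
code rather than prose: every payoff matrix, equilibrium, trajectory and
knockout experiment is a function returning a tidy tibble.

## What it implements

* **Games.** Hawk–Dove built from scoring primitives (win $w$, loss $l$,
  injury $i$, time cost $t$): cells $(w+i)/2$, $w$, $l$, $(w+l)/2+t$.
  The migraineur/non-migraineur game in two forms: the printed
  frequency-dependent cells
  $(m,m) = 1 + c_n - (1-p)p(c_m - c_n)$, $(m,n) = 1$, $(n,m) = 1 + c_n$,
  $(n,n) = 1 - (c_m - c_n)$, and a constant-fitness generalisation with
  the crossing ordering $f_n > f_m > d_m > d_n$, plus the cost/benefit
  decomposition ($c_n = f_n - d_m$, $b_n = f_n - d_n$, $b_m = d_m - d_m'$)
  with the sustainability flags $b_m - c_m > 0$, $b_n - c_n > 0$.
* **Equilibria.** Expected payoffs, mixed-ESS solving (closed form for
  constant games; grid scan + Brent refinement to $10^{-10}$ otherwise),
  stability classification, invasion payoffs, population mean payoff, and
  an audit of the claimed common-payoff identity
  $1 - c_m(1-p) + c_n$ (exact for the non-migraineur; the migraineur side
  leaves the residual $(1-p)^2(1+p)(c_m-c_n)$, which the package surfaces).
* **Dynamics.** Replicator ODE
  $\dot p = p(1-p)(EV_f - EV_o)$ via fixed-step RK4, and a seeded,
  compiled Moran birth–death process with exponential payoff-to-fitness
  mapping.
* **Reciprocal-altruism ABM.** Warn/rescue exchange with debts, betrayal,
  and the three preconditions (repeat interaction, recognition, memory) as
  knockout toggles, with a conservation-checked event ledger.
* **Comparative statics.** Equilibrium sweeps over any game parameter with
  monotonicity tests (e.g. lowering $d_n$ raises the equilibrium
  migraineur share).

## Worked example

```r
library(sensgame)

g  <- hawk_dove_game(contest_rules(50, 0, -100, -10))
as_payoff_matrix(g)
#>       partner
#> actor  dove hawk
#>   dove   15    0
#>   hawk   50  -25

glance(mixed_equilibrium(g))
#>   p_star payoff_at_eq stable status   n_roots residual
#> 1  0.417         6.25 TRUE   interior       1 1.78e-15
```

The stable mix is 5/12 doves earning +6.25 each — against +15 if everyone
agreed to be a dove and −25 in an all-hawk world
(`population_mean_payoff(g, 1)` and `population_mean_payoff(g, 0)`); the
replicator flow finds the same point from any interior start
(`attr(simulate_replicator(g, 0.9), "final_p")` → `0.4166667`).

The cooperation game works the same way. With fitness values
$(f_n, f_m, d_m, d_n, d_m') = (1.2, 1.1, 1.0, 0.9, 0.5)$:

```r
gg <- generalized_game(1.2, 1.1, 1.0, 0.9, d_m_prime = 0.5)
derive_costs_benefits(gg)
#>   c_n   b_n   c_m   b_m bm_net bn_net bm_positive bn_positive
#> 1 0.2   0.3   0.3   0.5    0.2    0.1 TRUE        TRUE

glance(mixed_equilibrium(migraine_game_generalized(gg)))
#>   p_star payoff_at_eq stable status   n_roots
#> 1  0.500         1.05 TRUE   interior       1
```

— a stable population of half migraineurs, each phenotype earning 1.05.
The printed frequency-dependent form is reproduced too, and its
common-payoff claim is audited rather than assumed:

```r
verify_paper_identity(migraine_params(0.3, 0.2), p = 0.5)
#>     p c_m c_n   ev_m ev_n claimed residual_m residual_n
#> 1 0.5 0.3 0.2 1.0875 1.05    1.05     0.0375          0
```

The non-migraineur identity is exact (`residual_n = 0`); the migraineur
side exceeds the claimed line by $(1-p)^2(1+p)(c_m-c_n)$, so the printed
form's only rest point is the all-migraineur boundary — which
`mixed_equilibrium()` reports honestly as `status = "boundary"`.

Finally, the exchange itself, simulated agent by agent:

```r
sim <- simulate_encounters(encounter_config(seed = 101))
glance(sim)
#>   phenotype      n_agents mean_fitness mean_per_round
#> 1 migraineur           20         3.72        0.00186
#> 2 non_migraineur       20         7.75        0.00388
```

Both phenotypes end above their no-agreement floors (zero), and
`condition_knockout()` shows the migraineur's surplus vanishing whenever
repeat interaction, recognition or memory is disabled.

A thin command-line interface over the same functions ships in
`inst/cli/sensgame.R` (subcommands `ess`, `audit-identity`, `replicator`,
`moran`, `altruism`, `sweep`, `fixtures`).

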