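---
title: "Methods: evolutionary game models of migraine persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary game models of migraine persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensgame)
```

## The question and the modelling idea

Migraine is highly prevalent and disabling, yet it has not been removed by
natural selection. One evolutionary account treats the migraineur as a
*hypersensitivity phenotype*: a nervous system tuned to detect predators
early, at the cost of maintaining that sensitivity and of occasional
incapacitating attacks. Under a reciprocal-altruism agreement, a migraineur
warns a less sensitive partner (a non-migraineur) when danger appears, and
the partner later rescues the migraineur if a predator arrives mid-attack.
Competition for such cooperation between the two phenotypes can be cast as a
two-strategy evolutionary game of the Hawk–Dove type, whose mixed
evolutionarily stable state (ESS) is a candidate explanation for a stable,
intermediate migraineur frequency.

`sensgame` implements this model family end to end: game construction,
ESS solving, deterministic and stochastic frequency dynamics, an
agent-based model (ABM) of the exchange itself, and comparative statics.

## Games

**Hawk–Dove.** Built from four scoring primitives (win, loss, injury, time
wasted; defaults +50/0/−100/−10). Symmetric contests are decided by a fair
coin flip and each cell is the expectation over both outcomes:
hawk–hawk $(w+i)/2$, hawk–dove $w$, dove–hawk $l$, dove–dove
$(w+l)/2 + t$, giving the classic matrix $(-25, +50, 0, +15)$. The focal
strategy is the dove, so $p$ is the dove frequency; the expected payoff
lines are $EV_{hawk} = -25(1-p) + 50p$ and $EV_{dove} = 15p$.
We allow degenerate scorings (all ties permitted, e.g. all-zero rules);
only the orderings injury ≤ loss ≤ win are enforced.

**Printed migraineur game.** Parameterised by the migraineur cost $c_m$,
the non-migraineur cost $c_n$ ($c_m > c_n > 0$) and the betrayal fitness
$d_m'$. The rescued-migraineur fitness $d_m$ is normalised to 1 (fitness is
a relative rate, so any rescaling is multiplicative; values below 1 would
remove the migraineur's reason to cooperate). Cells (actor, partner), with
$p$ the migraineur frequency:

$$(m,m) = 1 + c_n - (1-p)\,p\,(c_m - c_n),\quad (m,n) = 1,$$
$$(n,m) = 1 + c_n,\quad (n,n) = 1 - (c_m - c_n).$$

**Constant-fitness generalisation.** Four constants with the
crossing-lines ordering $f_n > f_m > d_m > d_n$, the pattern shared with
Hawk–Dove. Its interior equilibrium has the closed form
$p^* = (d_m - d_n) / ((d_m - d_n) + (f_n - f_m))$ and is always unique and
stable under the ordering.

**The cost/benefit decomposition.** `derive_costs_benefits()` reports the
printed definitions verbatim: $c_n = f_n - d_m$, $b_n = f_n - d_n$,
$c_m = f_n - d_n$, $b_m = d_m - d_m'$. Note that $c_m$ and $b_n$ are
*printed as the same difference*; the package reproduces this rather than
silently reconciling it, and treats $c_m$ as a free parameter in the
printed game. The exchange requires $b_m - c_m > 0$ and $b_n - c_n > 0$;
these are reported as flags here and enforced only where the ABM's
agreement logically requires them.

## The identity audit

The printed derivation claims both phenotypes' expected payoffs simplify to
the same line $1 - c_m(1-p) + c_n$. Expanding the cells shows the
non-migraineur identity is exact,

$$EV_n = (1+c_n)p + (1-(c_m-c_n))(1-p) \equiv 1 - c_m(1-p) + c_n,$$

while the migraineur side leaves a residual we verified symbolically:

$$EV_m - \bigl(1 - c_m(1-p) + c_n\bigr) = (1-p)^2(1+p)(c_m - c_n) \ge 0,$$

zero only at $p = 1$ or $c_m = c_n$. Consequently the printed
frequency-dependent form has **no interior mixed equilibrium**: the
migraineur payoff strictly dominates for $p < 1$ and the only rest point is
the all-migraineur boundary. `verify_paper_identity()` reports both signed
residuals for any $(c_m, c_n, p)$; `mixed_equilibrium()` reports the
boundary (or, at $c_m = c_n$, degenerate) status honestly. A gap term of
the form $(1-p)(c_m-c_n)/p$ would have made the claimed simplification
exact, but deciding the intended form is not this package's job; the
constant-fitness generalisation is provided as the internally consistent
alternative, and is the default elsewhere.

```{r identity}
verify_paper_identity(migraine_params(c_m = 0.3, c_n = 0.2), p = 0.5)
```

## Equilibrium solving

For constant games the payoff gap $EV_f(p) - EV_o(p)$ is linear and solved
in closed form ($p^* = \Delta_0 / (\Delta_0 + \Delta_1)$, $\Delta_0$ the
gap at $p=0$, $\Delta_1$ minus the gap at $p=1$). Frequency-dependent games
are scanned on a $10^{-3}$ grid and every bracketed sign change is refined
with Brent's method to $10^{-10}$; all interior roots are returned.
Stability follows the sign pattern of the gap across the root
(probe offset $10^{-6}$, configurable); boundaries are classified by an
exact one-sided invasion evaluation (a rare invader's payoff is evaluated
*at* the resident composition, not at a small ε). Degenerate games (gap
identically zero) are flagged rather than given an arbitrary root.

```{r ess}
glance(mixed_equilibrium(hawk_dove_game()))
```

## Dynamics

**Replicator.** $\dot p = p(1-p)\,(EV_f(p) - EV_o(p))$, integrated with
fixed-step RK4 (defaults $dt = 0.01$, $t_{max} = 10^4$), stopping when
$|\dot p| < 10^{-8}$. For the payoff scales used here these defaults keep
trajectories monotone between fixed points and land within $10^{-6}$ of the
stable interior equilibrium from any interior start; the step bound is
generous because the gap slopes are at most a few tens of payoff points.
Frequency-dependent cells are re-evaluated at the current $p$ at every RK4
stage (the natural reading when no explicit update rule is given).

**Moran process.** Finite-population birth–death chain: per elementary
step, one birth is drawn with probability proportional to
$\exp(\text{intensity}\times \text{payoff})$ — the exponential mapping
handles negative payoffs such as the hawk's −25 without shifting — and one
uniform death; a generation is $N$ steps. Payoffs depend only on the count
$i$, so both payoff tables are precomputed over $i = 0..N$ and the chain
itself runs in compiled code using R's RNG, making runs bit-reproducible
from `set.seed()`. Boundaries are absorbing unless a symmetric mutation
rate is supplied. Default intensity 0.1; at that strength, $N = 1000$
Hawk–Dove runs fluctuate tightly around the deterministic ESS.

## The agent-based exchange model

The ABM makes the reciprocal-altruism story mechanical rather than assumed.
Fitness is booked *per event relative to the no-agreement floors* (the
betrayed-migraineur level $d_m'$ and the unwarned non-migraineur level
$d_n$ are zeros), so "no agreement" runs show identically zero change, and
the per-completed-cycle gains under the agreement are exactly
$b_m - c_m$ and $b_n - c_n$.

Per round, agents pair uniformly at random; a predator threatens each pair
with probability 0.2. In a mixed pair, the migraineur is mid-attack with
probability 0.3 — then rescue requires an open debt in the partner's memory
and transfers $b_m$ at cost $c_n$ (betrayal with probability
`defect_prob` leaves the migraineur at the floor) — otherwise the
migraineur warns, paying $c_m$ and granting $b_n$, and records the debt.
Two design rules keep the credit economy honest: a migraineur extends at
most one open debt per partner (no unbounded unpaid credit), and a partner
remembered as betraying twice is no longer warned. The three
preconditions of reciprocal altruism are explicit toggles: no repeated
interaction collapses the run to a single round (debts can never be
repaid); no recognition delivers repayment to a uniformly random agent (a
migraineur benefits only with probability ≈ its frequency); no memory
records no debts at all. `condition_knockout()` quantifies the
migraineur's fitness drop under each.

Default conditions: 40 agents, half migraineurs, 2000 rounds, payoffs from
the generalized game $(f_n, f_m, d_m, d_n, d_m') = (1.2, 1.1, 1.0, 0.9,
0.5)$, i.e. $b_m - c_m = 0.2 > 0$ and $b_n - c_n = 0.1 > 0$. The group is
small so that repeat encounters are frequent (the regime reciprocal
altruism needs), and the horizon is long enough that completed
warn–rescue cycles dominate the transient stock of open debts.

What the ABM does *not* emulate: phenotypes do not evolve within a run
(that is the dynamics module's job), there is no spatial or kin structure,
predator events are independent across pairs and rounds, and the
cost/benefit increments are constants rather than state-dependent. Passing
tests therefore show the bookkeeping and the precondition logic are right,
not that real forager societies had these rates.

## Comparative statics

`sweep_equilibrium()` re-solves the equilibrium along a parameter grid,
flagging (not dropping) grid points that break the fitness ordering;
`monotonicity_test()` checks strict directional movement across valid
rows. On the generalized game the closed form gives the predicted signs:
$\partial p^*/\partial d_n < 0$ (if non-migraineurs fare worse alone —
more vulnerable children, women of childbearing age, harder-to-scan
environments — the migraineur share rises) and
$\partial p^*/\partial (f_n - f_m) < 0$. Scenario narratives are encoded
purely as parameter presets; no demographic model is attempted because the
source material supplies directions, not magnitudes, and the printed form's
degenerate equilibria are reported as such in sweep output.

```{r sweep}
sweep_equilibrium("d_n", seq(0.95, 0.7, by = -0.05),
                  fixed = generalized_game(1.2, 1.1, 1.0, 0.9))
```

## Numerical and design choices

* Matrix orientation is always payoff(actor, partner) with $p$ the focal
  strategy's frequency (dove; migraineur). This matches each game's own
  expected-payoff lines and avoids silent transposition bugs.
* $d_m' < d_n$ is the *default* configuration but is not enforced: only
  $d_m' < d_m$ is an invariant, since the betrayal level is never ordered
  against $d_n$ in the model's assumptions.
* Infinite well-mixed populations are assumed for expected payoffs;
  self-pairing is ignored.
* Root scan step $10^{-3}$, refinement tolerance $10^{-10}$, stability
  probe $10^{-6}$ — all configurable arguments, chosen so that closed-form
  and scanned roots agree to $10^{-9}$ on thousands of random games.
* The fixture generator draws parameters uniformly inside documented
  ranges that satisfy every invariant by construction (gaps of 0.05–0.25
  around a $d_n$ of 0.6–0.95 for the generalized game), roughly the scale
  of the worked examples; property tests use it under fixed seeds.
* Problem sizes used by the shipped tests — $10^3$ random games for the
  solver cross-check, $10^4$ random triples for the identity audit, 50
  Moran replicates at $N = 1000$ for 500 generations, ABM runs of 2000
  rounds — are the package's chosen defaults for demonstrating the
  properties at comfortable statistical resolution.

## Known limitations

* The equilibrium concept is the standard two-strategy mixed ESS; no
  n-strategy games, asymmetric roles, or spatial structure.
* The printed frequency-dependent game is reproduced faithfully, which
  means faithfully degenerate: its boundary equilibrium is a property of
  the printed cells, not a package artefact.
* The Moran process is the only finite-population model (no Wright–Fisher
  or diffusion approximations), and the ABM's agreement is exogenous — the
  model asks whether the exchange pays, not how it could be enforced.
* Calibration of the equilibrium to real-world migraine prevalence is out
  of scope; only the directions of comparative statics are testable.
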