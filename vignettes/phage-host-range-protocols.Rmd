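---
title: "Serial-transfer protocols and the selection of generalist phages"
author: "phagetrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-transfer protocols and the selection of generalist phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(phagetrain)
```

## The problem

Directed evolution of phage host range exposes a pool of phages to several
bacterial strains over repeated growth-and-transfer cycles, hoping to evolve
phages that infect new hosts. Protocols differ in how the hosts are
*presented*: in separate concurrent cultures whose supernatants are pooled
(Parallel, as in the Appelmans protocol), one host at a time in alternation
(Sequential), or all hosts in one culture (Mixed). They further differ in
how the pool is *diluted* between cycles. These choices decide whether the
protocol enriches broad host-range generalists or single-host specialists,
and whether phages can be lost for purely demographic reasons. `phagetrain`
simulates the minimal system that exposes these effects: two hosts (A, B),
one specialist per host, and one generalist.

## The within-culture model

During a growth phase each culture follows a lytic-infection compartment
model. For phage $i$ and host $j$, with free phage $P_i$, infected cells
$I_{ij}$ and uninfected cells $C_j$:

$$
\frac{dP_i}{dt} = \sum_j \left( b_{ij}\,\lambda_{ij}\,I_{ij}
  - k_{ij}\,P_i\,C_j \right), \qquad
\frac{dI_{ij}}{dt} = k_{ij}\,P_i\,C_j - \lambda_{ij}\,I_{ij}, \qquad
\frac{dC_j}{dt} = r_j\,C_j - \sum_i k_{ij}\,P_i\,C_j .
$$

The assumptions this encodes, and their consequences:

* **Exponential bacterial growth** (rate $r_j$, no carrying capacity):
  cultures are assumed harvested before resource limitation matters. Cell
  densities can therefore only be capped by phage predation, which is the
  mechanism behind the demographic effects below.
* **Exponentially distributed latent periods** (lysis rate $\lambda_{ij}$;
  mean latent period $1/\lambda$): a deliberate simplification — real lysis
  times are closer to fixed delays, and early lysis is over-weighted while
  phage are expanding.
* **Mass-action adsorption** ($k_{ij} P_i C_j$): free phage are lost to
  adsorption exactly as infected cells are gained, term by term.
* **Non-permissive pairs have $k_{ij} = 0$** and there is no free-phage
  decay term anywhere, so a specialist in a culture of its non-permissive
  host is inert: it survives without growth (a per-cycle growth factor of
  exactly 1, which is also the convention of the heuristic layer).
* No bacterial resistance, no wall growth, no coinfection or recombination:
  the model isolates selection and demography.

### Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| $b_{ij}$ | burst size | 5–25 (swept) | progeny per lysed cell |
| $\lambda_{ij}$ | lysis rate | 1.0 | per time unit |
| $k_{ij}$ | adsorption rate constant | $10^{-9}$ | volume per phage per time |
| $r_j$ | bacterial growth rate | 0.1 or 0.3 | per time unit |

Time is dimensionless; with the defaults one unit is roughly an hour, so a
20-unit cycle is just under a day. Only burst size varies between strains:
differences in any growth parameter act through overall growth rate, and
burst size is the cleanest single dial for that. Cells are renewed at
$10^7$ per host at each transfer, and runs default to 50 cycles (1000 time
units).

## Integration

The default integrator is fixed-step explicit Euler at step 0.001,
implemented in C++; `integrate_culture(solver = "adaptive")` runs the same
right-hand side through `deSolve`'s lsoda at tight tolerances
(`rtol = 1e-10`) and is used throughout the test suite as an independent
reference — endpoint densities from the two agree within 1% across the
canonical scenarios, and phage-free cultures reproduce $C_0 e^{rt}$ to
better than $10^{-3}$ (Euler) and $10^{-6}$ (adaptive).

Numerical edge cases are handled explicitly rather than silently. Euler can
undershoot zero marginally when a compartment crashes to exhaustion;
undershoots smaller than $10^{-12}$ of the current total density are clamped
to zero and anything larger aborts with the time and variable (the remedy
is a smaller step). After each dilution, densities below an absolute floor
($10^{-30}$ by default) are zeroed: deterministic ODE densities never reach
exactly zero on their own, and the floor prevents denormal drift while
standing in for the biological fact that fractional phage do not exist.
Extinction of the whole pool is reported as a flag, not an error.

In the excess-cell limit (cells effectively constant at $C$) the free and
infected compartments follow a linear system whose dominant eigenvalue —
the positive root of $s^2 + (kC+\lambda)s - kC\lambda(b-1) = 0$, positive
exactly when $b > 1$ — is exposed as `invasion_rate()`. It is the growth
exponent phages sustain when dilution keeps them from ever exhausting their
hosts, and simulated early log-slopes match it to within 2%.

## The protocol layer

`run_protocol()` executes seed → grow → pool → dilute for each cycle:

* **Parallel**: two cultures, one host each; every culture receives the
  full incoming phage density map; equal-volume pooling sums densities.
* **Sequential**: one culture; the host alternates each cycle (first host
  configurable, default A — the choice only relabels the hosts).
* **Mixed**: one culture with both hosts renewed at $10^7$.

Dilution modes: **fixed count** rescales the pool to a total of 1000,
preserving proportions exactly; **fixed volume** transfers 5% of every
density; **fixed count by host** (Parallel only) rescales each host
culture's pool to 1000 separately before combining, so the combined
incoming total is 2000 — the per-host variant that protects phages growing
on a poor host. Infected cells are discarded at transfer by default
(phages are recovered free of cells); `carry_infected = TRUE` carries them
through at the same dilution, which changes no retention classification in
the canonical scenarios.

Choices the protocol description leaves open, decided once here: runs start
from 1000 total phage split equally (the fixed-count target, so cycle 1
behaves like every later cycle; configurable); final frequencies are taken
from the pooled free phage at the end of the last growth phase, before the
final dilution (fixed-mode dilutions preserve ratios, so classification is
unaffected).

## The heuristic layer

Reducing growth in one culture to a single number $N_{i|j}$ (descendants
per phage, measured just before dilution) gives closed-form per-cycle
selection ratios. Under Parallel presentation the specialists' pooled
descendants are $N_{A|A}+1$ and $N_{B|B}+1$ against the generalist's
$N_{AB|A}+N_{AB|B}$ — an *arithmetic* generalist advantage. Under
Sequential presentation a full host alternation multiplies growth factors:
$N_{A|A}\cdot 1$ against $N_{AB|A}\cdot N_{AB|B}$ — a *multiplicative*
advantage, which is why Sequential presentation all but guarantees
generalist fixation. The comparison between the two is only clean once the
generalist grows at least twofold on each host: $xy \ge x + y$ requires
$1/x + 1/y \le 1$, so for $N_{AB|\cdot} < 2$ the sequential ratio can
exceed the parallel one. The package's property tests assert the ordering
on exactly that domain.

The prediction is asymmetric by construction (`heuristic_outcome()`): a
specialist whose ratio falls below 1 is predicted lost, but a specialist
ratio above 1 does not doom the generalist, which can persist on the other
host. `generalist_tyranny()` flags the characteristic failure mode of
pooled protocols — a specialist that wins its own host yet is predicted
lost because the generalist's output on a more productive host dominates
the pool.

`bottleneck_survival()` is the companion demographic arithmetic for newly
arisen single mutants: the probability of surviving the pool-to-next-round
transfer times the probability of landing on a host that permits growth,
$(\text{volumes used}/\text{volumes pooled}) \times
(n_\text{useful}/n_\text{cultures})$.

## What the scenario fixtures emulate — and what they do not

`scenario_fixture()` encodes the canonical study conditions (symmetric
specialists 15/15 and asymmetric 20/10; $r = 0.3$ vs $0.1$; the three
presentations; the three dilution modes; the 17/17 generalist for the
single-run dynamics scenarios). These are idealized liquid-culture
conditions: deterministic dynamics with all phages common enough to escape
random loss, identical and constant rate parameters, instantaneous pooling
and renewal. Passing tests therefore demonstrate the *selective and
demographic logic of the protocols*, not quantitative predictions for any
particular empirical phage-host system, where resistance evolution,
wall growth, discrete lysis times and stochastic loss of rare mutants all
intrude.

```{r dynamics, fig.height = 4}
fx <- scenario_fixture("fig5A")
run <- run_protocol(fx$config, fx$params)
plot(run, main = "r = 0.1, fixed count: slow phages diluted to extinction")
```

The two dynamics regimes are worth internalizing. With $r = 0.1$ and
fixed-count dilution, no phage exhausts its host within a 20-unit cycle;
every phage grows exponentially at its own `invasion_rate()`, the fastest
grower sets the dilution factor, and every other phage is diluted faster
than it grows — demographic extinction that mimics selection but is not.
The end-of-cycle pool plateaus just above $10^6$. With $r = 0.3$ the
fastest phage exhausts its host mid-cycle while slower phages catch up
against theirs, and coexistence by host partitioning reappears. Lengthening
the cycle to 40 units at $r = 0.1$, or switching to fixed-volume or
per-host dilution, restores the same rescue by other means.

One quantitative note: under the $r = 0.3$ fixed-count conditions the
simulated end-of-cycle pool reaches a few $\times 10^{10}$ (a per-cycle
fold growth of about $10^{7.5}$). This is forced by mass balance — end
free phage is roughly $(b-1)$ times the cells produced, and cells grow to
several $\times 10^8$ before the crash — and is reported as computed.

## Problem sizes used in the tests

The retained-fraction analysis runs on an 11×11 burst grid (5–25 in steps
of 2, 121 runs of 50 cycles each); the qualitative regime comparisons use
4- or 5-point-per-axis grids, which already separate the protocols cleanly.
The full 21×21 single-step grid reproduces the same retained fractions
(generalist ≈ 0.77) and is a one-minute computation with the default Euler
solver if finer maps are wanted.

## Known limitations

* Two hosts, three phages: the combinatorics of more hosts is out of scope.
* No latent-period distributions other than exponential; no phage decay;
  no resistant-cell classes; no logistic bacterial growth.
* Mixed presentation renews hosts only at cycle boundaries, not
  continuously within a cycle.
* Plaque-based sequential transfer (picking plaques rather than passaging
  supernatant) is not modelled; it cannot retain phages that do not form
  visible plaques.
* Recombination and the stochastic fate of single mutants are outside the
  deterministic model; `bottleneck_survival()` covers only the transfer
  arithmetic.
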