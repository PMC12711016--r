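---
title: "Modelling infodemic diffusion: equation-based and agent-based simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling infodemic diffusion: equation-based and agent-based simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemsim)
```

# The problem

Misinformation spreads through a population much like a pathogen: people are
*susceptible* to a false narrative, may be *exposed* to it repeatedly before
believing it, become *infected* (spreading it themselves), and may *recover*
and later lose that immunity. `infodemsim` implements this analogy at two
levels of description and provides the machinery to ask how far the two
levels agree:

* **Equation-based models (EBMs)** — the six classical SEIRS-class
  compartmental models (`SI`, `SIS`, `SIR`, `SIRS`, `SEIR`, `SEIRS`) in
  discrete time, where the population is reduced to per-compartment counts
  under homogeneous mixing.
* **Agent-based models (ABMs)** — individuals moving on a toroidal grid of
  "communication channel" cells, with point-to-point transmission on
  contact; an **enhanced** variant adds an explicit information environment
  (agents post and consume true/false content, and false content in the
  environment can itself infect) plus homophily-gated belief.
* **Equivalence metrics** — per-compartment Pearson correlation and
  normalized root-mean-square error between homonymous outcome series,
  aggregated over full parameter-grid sweeps.
* **Calibration** — a multi-objective fit of the SIS-type models to a
  longitudinal two-mirrored-percentage acceptance series.

# The equation-based family

All six models are reductions of one flux template,
$$
\begin{aligned}
S' &= -\beta S I / N + \xi R, &\quad E' &= \beta S I / N - \sigma E,\\
I' &= \sigma E - \gamma I, &\quad R' &= \gamma I - \xi R,
\end{aligned}
$$
iterated with forward Euler at a step of one *tick* (the shared simulation
time unit), so the rates $\beta,\sigma,\gamma,\xi \in [0,1]$ are per-tick
fractions of the source compartment. Reduced models are obtained by zeroing
fluxes rather than by separate code paths, which makes nesting exact: a
SEIRS run with $\xi = 0$ is index-wise identical to the SEIR run.

Numerical choices:

* Compartments are real-valued; the agent-based side carries the integer
  semantics.
* Each compartment has a single outflux which, at rates $\le 1$, can never
  exceed its source; the step nevertheless clamps outfluxes defensively so
  conservation $S+E+I+R=N$ holds for any input.
* For the two-compartment models (SI, SIS) the step closes conservation
  exactly ($I := N - S$), so the susceptible and infected series are
  bit-exact mirrors — this makes the mirror identity
  $\mathrm{NRMSE}(S) = \mathrm{NRMSE}(I)$ hold to the last bit rather than
  to rounding error.

```{r ebm}
spec <- make_model_spec("SEIRS")
tr <- simulate_ebm(ebm_params(beta = 0.2, sigma = 0.1, gamma = 0.05,
                              xi = 0.01, N = 1000),
                   ebm_state(S = 990, I = 10), spec, T = 100)
tail(tr, 3)
```

# The agent-based world

Agents live on an $M \times M$ toroidal grid (distances use the minimal
image, so nothing is farther than $M\sqrt2/2$ cells). Each agent carries
coordinates, a heading, an information status in $\{S,E,I,R\}$, and an
energy reserve; each cell carries an information quantity $q \in [0,
q_{\max}]$ (split into true and false content in the enhanced model). The
reference experiments use a small world ($M=33$, $N=150$ agents) and a
large one ($M=99$, $N=1350$) at the same density.

Each tick runs fixed phases: **movement** (steer toward the most
informative visible cell), *(enhanced:* **consumption**, **posting**)*,*
**contact spreading**, *(enhanced:* **environmental infection**)*,* **state
updates** (incubation, recovery, immunity loss — at most one transition per
agent per tick, mirroring the simultaneous-flux semantics of the Euler
step), and **cell replenishment**. Within every phase agents are visited in
a fresh seeded random permutation, which approximates asynchronous parallel
execution while keeping runs bit-reproducible: identical `(config, seed)`
always gives an identical trajectory.

## Initialization

Initialization is deterministic: agents sit on an evenly spaced
sub-lattice; headings follow the golden angle ($137.5^\circ i$); the cell
landscape is a fixed sinusoid that saturates to $q_{\max}$ under
replenishment. The `I0` infected (and, under the *Case II* convention,
`E0` exposed) seeds default to $\lceil 0.05N \rceil$ and are placed at
*strided* indices $\lfloor jN/I_0 \rfloor$, dispersing them across the
lattice. We deliberately avoided seeding a contiguous block of low-index
agents: on the sub-lattice that concentrates every seed in one spatial band
and turns each outbreak into a single traveling wave whose duration is
pinned by the world size regardless of $\beta$ — a geometry artifact, not a
property of the diffusion process being modelled.

## Movement and its degenerate regime

An agent targets the visible cell (within decision radius $d_e$, view cone
$\theta$) with maximal $q$; ties break to the nearest cell, then the
smallest row-major index (`select_move_target()` documents this contract
and is tested against an exhaustive scan). When the visible field is *flat*
— no gradient at all, the steady state of the simple model once cells
saturate — there is no "most informative" cell and the agent takes a seeded
random heading instead. Without this rule the tie-break would freeze every
agent onto a deterministic straight-line loop and the population would stop
mixing, contradicting the random-walk movement the model is meant to have.
Steps are one cell along the 8-neighbour direction of the target; each
move costs `e_c` energy (status-specific in the enhanced model). Energy has
no behavioural consequence because leaving/joining dynamics are disabled;
it is tracked for bookkeeping and audit.

## Contact transmission

Each infected agent attempts to convert its nearest susceptible within the
contact radius $d_c$ (default 1.5 cells, i.e. the 8-neighbourhood), at most
one target per tick, with per-tick probability
$$p = \beta \cdot \min\!\bigl(1,\ \pi d_c^2 N / M^2\bigr),$$
i.e. $\beta$ scaled by the expected contact-neighbourhood occupancy so
that, at the reference densities (identical for both world sizes,
$\approx 0.97$), expected new infections per tick approximate the
mean-field flux $\beta S I/N$. The scaling is exposed as the
`contact_scale` configuration hook. Models with an exposed compartment
transition $S \to E$, the others $S \to I$.

## The enhanced information environment

* **Posting.** An agent whose posting delay has elapsed (and which has
  consumed since its last post) deposits one quantum of content of its own
  type — false if infected, true otherwise — onto its cell, capped at
  $q_{\max}$, paying the status-specific cost $L_P^{S,I}$ and restarting
  the delay $D_P^{S,I}$.
* **Consumption.** Agents take up to one unit per tick from their cell
  (proportionally from true and false content) and gain that amount of
  energy — a 1:1 conserving exchange. The first consumption after a post
  arms the next post and starts the countdown; further consumptions while
  the countdown runs do not restart it (otherwise continuous foraging would
  postpone posting forever).
* **Environmental (stigmergic) infection.** A susceptible standing on a
  cell with false content transitions with probability
  $(\beta/2)\,\min(q_{\mathrm{false}}/q_{\max}, 1)$. The infection rate is
  split equally between the two channels — contact transmission uses
  $\beta/2$ — so that $\beta$ retains its meaning as the total infection
  propensity. With the environment channel inert (nothing posted, no false
  content) the enhanced model reduces *exactly*, seed for seed, to the
  simple model at the halved contact rate; the test suite asserts this
  count-identity.
* **Homophily.** Agents belong to one of two social groups (default split
  80/20, drawn from a seed stream separate from the tick dynamics) and only
  *believe* false information arriving from agents of their own group:
  agent-to-agent infection is gated on equal groups. The rule names agents,
  so environmental infection is deliberately not gated; whether it should
  be is an open modelling question we left as stated.
* **Replenishment** regrows true content only (external sources); false
  content enters the environment exclusively through infected posts.

# Intermodel equivalence

For homonymous outcome pairs $y_a$ (agent-based, averaged over repeated
seeded runs) and $y_e$ (equation-based) over $q$ samples we compute the
Pearson correlation $\rho = \mathrm{cov}(y_a,y_e)/\sigma_{y_a}\sigma_{y_e}$
(shape agreement, in $[-1,1]$) and the normalized RMSE
$$\mathrm{NRMSE} = \frac{\sqrt{\tfrac1q\sum_k (y_{a,k}-y_{e,k})^2}}
  {y_{\max}-y_{\min}},$$
with the range pooled over both series, which guarantees values in
$[0,1]$. When a compartment is constant in either model $\rho$ is
undefined; such pairs are scored 1 (match) or 0 (no match) according to
whether their NRMSE is below a threshold $\tau$ (default 0.05,
configurable), and flagged as adjusted. Metrics are computed over the full
$T+1$ samples of a run.

`run_sweep()` executes the full factorial grid over the model's active
rates, anchored at $0.1$ with a configurable step (step $0.1$ gives 10
combinations for SI up to $10^4$ for SEIRS), averaging `runs_per_cell`
agent-based runs per grid point before comparison, and summarizes
per-variable grid means and SDs; `sweep_heatmap()` reshapes a two-axis
sweep into matrices for heatmap display.

```{r sweep}
sw <- run_sweep("SI", grid_step = 0.3, runs_per_cell = 2, T = 300, seed = 1)
sw$summary
```

Problem sizes used by the shipped analyses: the acceptance script runs
2000-tick runs with 10 repeats per grid point on the small SI grid and 5 on
the large, enhanced, and two-axis grids; the test suite uses 10/5/3. These
are the package's single-CPU reference sizes; repeats mainly smooth the
agent-based mean, and the grid means are stable to within a few units in
the second decimal across these choices.

What the comparison shows — and what it cannot show: with the mean-field
calibrated contact probability above, the simple agent-based model tracks
the equation-based trajectories closely on the SI family (grid-mean
correlations near 1), while recovery-type models (SIS, SIRS, SEIRS) show
the same qualitative pattern of partial equivalence reported for this
class of experiments: small errors for some compartments, large
shape disagreements at high infection/recovery rates. A NetLogo-native
implementation whose contact probability is scaled differently will sit at
a different point on this spectrum; the `contact_scale` hook is the single
knob that moves along it, and we fixed its default on mean-field grounds
rather than to reproduce any particular published table.

# Calibration to an acceptance series

The fitting module targets a longitudinal two-mirrored-percentage series
$S_{RW}(k) + I_{RW}(k) = 100$ over 36 weeks at biweekly sampling (19
points): the share of a population accepting/not accepting a vaccine,
mapped onto a SIS process (accepting = susceptible). Because the original
survey data are external, `generate_acceptance_series()` emulates their
qualitative shape — a smooth sigmoidal decline crossing 50% once near a
configurable inversion week, plus seeded noise. Passing fits on these
fixtures demonstrate pipeline correctness, not real-world performance.

A candidate $(\beta, \gamma, T_F, \dots)$ is evaluated by simulating
$T_F$ ticks per real-world week over the horizon, normalizing to percent,
binning the tick-resolution output to 19 points by contiguous window
averaging, and scoring $(\rho, \mathrm{NRMSE})$ against $S_{RW}$.
Initialization "approximates the first datapoint" with a one-step
fixed-point correction on $S(0)$: a decaying series' first window mean is
always below its starting value, so we simulate once from
$S(0) = S_{RW}(0)$, measure the first bin, and re-run with the corrected
start. Equation-based candidates use $N = 100$ (percent); agent-based
candidates scale $N = 100\,P_M$ enhanced-model agents and average a
configurable number of seeded runs.

The search maximizes $\rho$ and minimizes NRMSE over the documented bounds
($\beta,\gamma \in [0,1]$; $P_M \in [1,15]$; $T_F \in [1,336]$;
energy losses $\in [1,100]$; posting delays $\in [1,25]$; the regrowth rate
$I_R \in [0,1]$ by analogy with the other rates). Sampler design:

* Rates ($\beta, \gamma, I_R$) are drawn log-uniformly (floor $10^{-5}$) —
  plausible per-tick rates span several decades because $T_F$ trades off
  against them.
* A Latin-hypercube warmup is followed by Tree-structured-Parzen-Estimator
  style sampling: trials are split at the lower score quartile, candidates
  are proposed as joint perturbations of good-trial anchors (preserving
  rate-ratio correlation) and ranked by the good/bad kernel-density ratio.
* The last third of the budget runs a deterministic Nelder-Mead polish of
  the continuous dimensions in search scale, with short simplex runs
  restarted at their endpoint (escaping premature simplex collapse) and
  multi-anchor starts across distinct integer settings.
* The scalar score used inside the sampler is
  $\mathrm{NRMSE} + (1-\rho)/4$; the *reported* best is chosen
  lexicographically (NRMSE ascending, then $\rho$ descending) among the
  Pareto-front trials, and the front itself is returned.

The whole search is reproducible under the problem seed; agent-based
evaluations use seeds derived from it and never perturb the sampler
stream.

```{r fit}
target <- generate_acceptance_series(noise_sd = 0)
fit <- fit_model(fit_problem(target, "ebm", budget = 60, seed = 1))
fit
```

# Design notes and limitations

* **One transition per agent per tick.** Sequential phase execution would
  let an agent pass $S \to E \to I$ in a single tick at high rates; the
  guard keeps the agent-based transition semantics aligned with the
  simultaneous fluxes of the Euler step.
* **Disabled channels are skipped.** A zero consumption bite or posting
  quantum disables the phase outright (rather than running it as a no-op),
  which is what makes the channel-off reduction to the simple model exact
  under a shared seed.
* **Degenerate inputs.** Zero-variance metric pairs go through the
  adjustment rule; identical constant pairs have NRMSE 0 by convention;
  consumption clamps cell content at 0 against rounding residue; energy
  may go negative with no behavioural effect (leaving the network is
  disabled).
* **Vital dynamics** (agents leaving on energy exhaustion, joining) exist
  in the conceptual model but are deactivated and not implemented beyond
  the energy bookkeeping; network-topology interaction graphs and multiple
  concurrent falsehoods are out of scope.
* **What the fixtures do not show.** The synthetic acceptance series and
  toy worlds validate mechanics and recovery behaviour; conclusions about
  real infodemics require the real survey series (importable as
  `week,S_RW,I_RW` CSV via `read_acceptance_series()`).
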