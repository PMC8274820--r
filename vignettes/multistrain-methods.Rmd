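---
title: "Methods: multi-strain SI models with within-host mutation, treatment and prophylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-strain SI models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistrain)
```

## The modelling problem

Chronic viral infections persist for decades, long enough for the viral
population inside a single host to diversify into many strains. When some of
those strains differ in contagiousness, in their response to therapy, or in
their susceptibility to chemo-prophylaxis, the *within-host* evolutionary
process feeds back on *population-level* control: treating the infected or
protecting the susceptible can select for exactly the variants that escape
those measures. The package implements a deliberately coarse-grained model of
this feedback that stays analytically tractable: instead of tracking
time-dependent within-host dynamics, each chronically infected host founded by
strain $j$ carries a *fixed average* strain mixture, column $j$ of a mutation
matrix $A$.

## Model structure and assumptions

Both models are SI-type compartmental systems for *fractions* of a constant
population (inflow $\mu$ equals outflow), with an acute stage of mean duration
$1/\gamma$ followed by a chronic stage. The acute stage transmits only the
founder strain at rate $\beta_A = \xi\beta_C$; the chronic stage transmits the
mixture $A e_j$ at rate $\beta_C$ (per-strain $\beta_{Ci}$ in the extended
model). The force of infection for strain $i$ is
$\phi_i = \beta_{Ci}(\xi I_{Ai} + \sum_j \alpha_{ij} I_{Cj})$.

Structural assumptions worth keeping in mind:

* homogeneous contacts — no network or risk-group structure;
* single-founder infections, no coinfection or superinfection;
* treatment starts only in the chronic stage (rate $u_T$), is fully effective
  in the baseline model, and fails (reverts) at strain-specific rates
  $\zeta_i$ in the extended model;
* prophylaxis (extended model) enrolls susceptibles at rate $u_P$ for an
  average duration $1/\delta$ and multiplies the force of infection by
  $1-\psi_i$;
* every column of $A$ sums to one and $\alpha_{ii} > 0$: the founder strain
  never disappears entirely from its own host.

The state ordering is fixed everywhere (I/O, Jacobians, trajectories):
$[I_{A1..n}, I_{C1..n}, T\ (\text{or } T_{1..n}), S, (P)]$. The baseline
treated class is a scalar while the extended one is per-strain; the two
layouts are kept distinct rather than padded into one, so linearizations stay
aligned with the model notation. Both right-hand sides conserve mass exactly
and are essentially non-negative, so the unit simplex is forward invariant —
the test suite checks both properties on random states rather than trusting
the algebra.

## Reproduction numbers and the oracle

Closed forms: $R_0^{baseline}(u_T) = \beta_C\,
\frac{\xi(u_T+\mu)+\gamma}{(\gamma+\mu)(u_T+\mu)}$, independent of $A$
(neutral mutation does not alter transmission phenotype), and
$R_0^{ext}(u_T,u_P) = \bar\beta_C\frac{\gamma+\xi\mu}{(\gamma+\mu)\mu}\,
\rho(Q(u_P)N(u_T))$ with the matrices defined in `?r0`. Both are verified in
the tests against an independently constructed next-generation matrix
$\rho(FV^{-1})$: $F$ holds the Jacobian of new-infection inflows
($\phi_i S$, $(1-\psi_i)\phi_i P$) over the infected compartments
$(I_A, I_C, T_i)$ at the disease-free equilibrium, $V$ the linearized
transitions, including the $\zeta_i T_i$ reversion paths. The two routes are
algebraically independent, so their agreement (50 seeded random draws across
$n \in \{1,2,4,8\}$, tolerance $10^{-8}$) is a genuine cross-check rather
than a tautology.

### Sensitivity expansion

At zero control, with $\bar A = (\xi\mu E + \gamma A)/(\gamma+\xi\mu)$ (a
convex combination of $E$ and $A$, hence column stochastic with the same
dominant eigenvectors as $A$) and $w_0, v_0$ the dominant left/right
eigenvectors of $\bar B_C \bar A$ normalized to $w_0^\top v_0 = 1$:

$$R_{1,T} = -\,w_0^\top\Big[R_0 E - \tfrac{\xi}{\gamma+\mu}B_C\Big]
(Z+\mu E)^{-1} v_0, \qquad
R_{1,P} = -\,\frac{R_0}{\delta+\mu}\, w_0^\top \Psi v_0 .$$

The $R_{1,T}$ bracket deserves a note: we re-derived it from
$\frac{d}{du_T}\rho(Q N(u_T))$ using $w_0^\top \bar B_C \bar A = \rho
w_0^\top$; the form above is the one consistent both with the uniform-$\beta$
reduction $-R_0\frac{\gamma}{\gamma+\xi\mu} w_0^\top (Z+\mu E)^{-1} v_0$ and
with the efficiency-comparison factor $1-\beta_{Ai}\theta_A/R_0$
($\theta_A = 1/(\gamma+\mu)$, $\beta_{Ai} = \xi\beta_{Ci}$). Every release of
the formula is validated against central finite differences of the full
closed form (relative tolerance $10^{-4}$).

Interpretation: each control's coefficient is a sum over strains of
*mean intervention duration* ($\tau_i = 1/(\zeta_i+\mu)$ on treatment,
$1/(\delta+\mu)$ on prophylaxis) times *protection conferred*, weighted by
$w_{0i}v_{0i}$ — for uniform transmissibility simply the stationary strain
distribution $v_{0i}$. `classify_efficiency()` reports the resulting
preference and the global-efficiency criterion
$\xi \max_i \beta_{Ci}(1-\psi_i) < \gamma+\mu$, which says elimination by
brute-force control is possible iff acute-stage transmission of the
least-controllable strain is subcritical on its own.

## Equilibria

For irreducible $A$ and $R_0 > 1$ the baseline endemic equilibrium is unique
and proportional to the Perron eigenvector $v$ of $A$; the prefactors used
here, e.g. $I_{Ai}^* = \frac{\mu}{\gamma+\mu}(1-1/R_0)v_i$, are the unique
reading under which the components sum to one — we verified this symbolically
and the tests verify $\|rhs\| < 10^{-10}$ and the chronic mixing identity
$I_C^* = A I_C^*$ at every computed equilibrium. For reducible $A$
(`normal_form()` exposes the block structure via strongly connected
components of the mutation digraph) the unit eigenvalue can have multiplicity
$q \le k$ and `endemic_family()` returns the eigenvector basis plus a
combination helper; combinations with negative components are rejected as
non-physical rather than silently projected. Stability of individual family
members is *not* characterized — the package reports them without stability
claims.

The extended model has no usable closed form, so `endemic_extended()` runs a
damped Newton iteration on the right-hand side with $S$ eliminated through
the simplex constraint (the unreduced Jacobian is singular along the simplex
normal). Newton tolerance is $10^{-12}$ with at most 100 iterations, seeded
from the collapsed baseline closed form when the parameters permit, otherwise
from long-time integration. A subtlety found during development: the
algebraic system has spurious roots with negative strain components, and a
warm start far from the new equilibrium can converge to one. The solver
therefore rejects any root with a component below $-10^{-8}$ and restarts
from the flow, which cannot leave the physical basin.

## Numerical choices

* **Integration** (`integrate_model()`): `deSolve::lsoda`, stiff-capable,
  default `rtol = 1e-10`, `atol = 1e-12`; stored states are clipped to zero
  only for excursions above $-10^{-12}$, anything worse raises a warning.
* **Eigencomputations**: dense `eigen()` rather than power iteration — the
  unit eigenvalue of a stochastic matrix can have near-degenerate companions
  that stall power iteration, and the matrices here are small ($n \lesssim
  200$). The right Perron vector is scaled positive with unit sum; the left
  one so that $w^\top v = 1$. Non-simple dominant eigenvalues trigger a
  warning pointing to `normal_form()`.
* **Irreducibility**: strong connectivity of the sparsity digraph
  (entries $>10^{-14}$), via `igraph`.
* **Inversion feasibility**: the frequency-to-retention inversion can demand
  $\pi_j \notin [0,1]$ (e.g. a flat target distribution with small $\pi_n$);
  this is checked eagerly and reported with the offending strain index.
* **Critical control levels**: bisection on the monotone map $u \mapsto R_0$
  over $[0, 10^4]$ (geometrically expanded if needed) to $|R_0 - 1| <
  10^{-8}$, alongside a 0.01-step grid scan mirroring the reference sweep
  granularity. "No finite level" is a valid verdict, returned whenever the
  large-control limit exceeds 1.
* **Steady states**: integration in doubling time chunks up to $t_{max} =
  5\times 10^4$ (chosen so $e^{-\mu t}$ transients at $\mu = 0.025$ fall
  below $10^{-9}$), with the max-norm of the right-hand side as the stopping
  criterion.

## Study scenarios and the transmissibility readings

`case1()` and `case2()` build the four-strain nearest-neighbor scenarios with
target endemic ratios $v_j/v_{j+1} = 3$ and $7$. Two documented
inconsistencies in the source material are handled explicitly rather than
silently:

* **Case-2 retention values.** The quoted $\pi = (0.9985, 0.9796, 0.8571)$
  cannot be produced by the inversion formulas with the stated $\pi_4 = 0.25$;
  they are reproduced exactly with $\pi_4 = 0.5$. `case2()` exposes both
  (`"eq22_consistent"` and `"as_printed"`); only the self-consistent Case 1
  is pinned by reference tests.
* **The value of $\beta_C$.** The quoted $\beta_C = 0.25$ gives
  $R_0(u_T{=}0.4) \approx 0.997 < 1$, contradicting the stated calibration
  $R_0 \approx 1.2$. Three readings are selectable via `case1(beta = ...)`:
  `"figure"` ($\beta_C = 0.3$, the uniform rate of the published $R_0$
  surface, $R_0 = 1.196$), `"calibrated"` ($\beta_C \approx 0.30102$, solving
  $R_0 = 1.2$ exactly) and `"printed"` (0.25). The default is `"figure"`
  because it is the only reading that reproduces *both* published
  prophylaxis-elimination thresholds — 0.88 for Case 1 and $\approx 0.8$ for
  Case 2 (the latter additionally requires the eq22-consistent Case-2
  matrix) — which is strong evidence it is what the published sweeps used.

Sweep drivers default to grids of step 0.01 in $u_P$ and 0.05 in the
transmissibility multiplier $a$ and in $\zeta_4$ (the published figures'
resolution is unstated), with warm-started continuation along the grid.
Scenario trajectories start from 1% of the population acutely infected with
strain 1 — the reference initial conditions are unstated, and none of the
reported quantities (equilibria, thresholds) depend on this choice, only
transient plots do.

## What the random-input generators emulate — and what they do not

Property tests draw random strictly positive column-stochastic matrices
(diagonal-boosted, hence irreducible), random retention profiles, and random
rate sets spanning $\gamma \in [1,6]$, $\mu \in [0.01,0.1]$, $\xi \in [1,8]$,
transmissibilities up to 0.6 and controls up to 1 — brackets that keep the
per-event time scales in the regime the models were built for (acute stage
months, host turnover decades). Passing these tests shows internal
consistency of the formulas, oracles and integrators across that regime; it
does not validate the biological assumptions (fixed within-host mixtures,
homogeneous mixing, single founders) against real surveillance or sequence
data, and no real data enters the package.

## Problem sizes used by the shipped checks

Reference computations run at the study's own size $n = 4$; the
oracle-equivalence properties additionally cover $n \in \{1, 2, 4, 8\}$ with
50+ random draws; sweep tests use coarsened grids (3–4 points) of the same
drivers that produce full-resolution surfaces. The whole suite completes in
well under a minute.

## Known limitations

* Constant (not time-varying) controls; no optimal-control machinery.
* No demographic, contact-network, coinfection or superinfection structure.
* Reducible-matrix equilibrium family members are reported without stability
  analysis.
* The extended-model endemic solver is numeric; its convergence flag and
  residual are part of the returned object and should be checked by callers
  embedding it in larger scans.
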