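---
title: "Stochastic thermodynamics of composite processes with compthermo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic thermodynamics of composite processes with compthermo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compthermo)
```

## The model

Many driven systems — chemical reaction networks near the small-count
limit, electronic circuits, interacting molecular machines — decompose
naturally into several co-evolving subsystems.  The classical multipartite
formalism assumes that at most one subsystem changes state per jump.  That
assumption fails whenever subsystems share a physical coupling: a chemical
reaction changes several species counts at once, and a charge transfer
moves two conductor voltages simultaneously.

`compthermo` implements the more general *composite process*: a
continuous-time Markov chain over the product of finite per-subsystem state
spaces whose rate matrix is a sum of *mechanism*-specific rate matrices,

$$K_{x x'}(t) \;=\; \sum_v K_{x x'}(v; t),$$

where each mechanism $v$ (an external reservoir or coupling) can reassign
only the coordinates in its **puppet set** $P(v)$ and its rates may depend
on the source state only through its **leader set**
$\mathcal{L}(v) = \bigcup_{i \in P(v)} (\{i\} \cup \mathrm{pa}(i))$, the
puppets together with their parents in a directed **dependency network**.
We use the column convention throughout: `K[x, x']` is the rate from `x'`
to `x`, the diagonal holds negative exit rates, and every column sums to
zero.  Multipartite processes are the special case of singleton puppet
sets.

A **unit** is a subsystem subset $\omega$ whose marginal evolves under its
own rate matrix.  We operationalize this structurally: $\omega$ is a unit
iff every mechanism either has $\mathcal{L}(v) \subseteq \omega$ or
$P(v) \cap \omega = \emptyset$.  (A unit's boundary may have outgoing
dependency edges but no incoming ones; this structural reading can be
assumed without loss of generality, and the dynamical characterization —
marginal propagation commutes with projection — is kept as a test oracle
rather than as the definition.)  Verified units are closed under union and
nonempty intersection, and the full system is always a unit.  A **unit
structure** is an intersection-closed family of units covering all
subsystems.

## Thermodynamic decompositions

With rates as primitives ($k_B = 1$, entropies in nats, no Hamiltonian
assumed), every unit carries the standard apparatus of stochastic
thermodynamics, resolved by mechanism:

* one-way flows $A_{x x'}(v) = K_{x x'}(v)\,p_{x'}$ and net currents
  $J = A - A^\top$;
* dynamical activity $A(v; t) = \sum_{x \ne x'} A_{x x'}(v; t)$, shared by
  all units containing $\mathcal{L}(v)$;
* the EP rate
  $\dot\sigma^\omega = \sum_v \dot\zeta^\omega_v$ with
  $\dot\zeta^\omega_v = \sum_{x\ne x'} A_{x x'}(v) \ln
  [A_{x x'}(v) / A_{x' x}(v)]$.

Nested units satisfy $\dot\sigma^\alpha \le \dot\sigma^\omega$ for
$\alpha \subseteq \omega$: discarding degrees of freedom can only hide
dissipation.  For a unit structure $N^*$, the **in–ex information**
$I_{N^*} = \widehat\sum_\omega S^\omega - S^N$ (an inclusion–exclusion sum
of marginal entropies; the mutual information for two disjoint units, the
total correlation for many) links the unit EPs to the global EP through
the exact identity

$$\sigma^N \;=\; \widehat\sum_{\omega \in N^*} \sigma^\omega \;-\;
\Delta I_{N^*}.$$

`ep_inex_decomposition()` computes both sides independently and reports
the residual; because the identity is exact, a residual above
$10^{-6}\max(1, \sigma^N)$ is treated as an error, and the quadrature grid
is refined (doubling, from 64 up to 1024 Simpson intervals) until the
identity is resolved.  The inclusion–exclusion sum is evaluated over index
tuples, as the combinatorial formula prescribes, so its value is invariant
under re-indexing the units even when tuple intersections coincide as
sets; empty intersections contribute zero.

## Lower bounds on entropy production

**Mismatch cost.**  Running a discrete-time kernel $P$ on a distribution
$p$ rather than its optimal prior $q$ costs at least
$D(p\|q) - D(Pp\|Pq) \ge 0$ in EP.  For a family of initial distributions,
the minimum over priors of the expected mismatch cost equals the drop in
Jensen–Shannon divergence under $P$, attained at the mixture of the
family.

**Periodicity.**  If the dynamics repeats the same kernel $P$ over $N$
periods, summing mismatch costs gives
$\sigma \ge \inf_q \sum_{t=0}^{N-1} [D(P^t p_0 \| q) - D(P^{t+1} p_0 \|
Pq)] = N\,\Delta JS$ over the uniform family of iterates
$\{P^t p_0\}$.  `periodicity_ep_bound()` computes the infimum twice — by
simplex optimization and by the closed form — and reports their agreement
rather than assuming it.

**The nested composite bound.**  Over a single common period the whole
system's periodicity bound is vacuous ($q = p_0$ gives zero).  But when a
frozen subsystem $A$ conditions two periodic blocks $B$ and $C$ with
commensurate periods ($\lambda_B = m\lambda_C/n$, coprime $m, n$), the
units $\{A\}, \{A,B\}, \{A,C\}$ each complete several of their own periods
within $\tau = n\lambda_B = m\lambda_C$, and the in–ex decomposition knits
their individual bounds into a strictly positive bound on the global EP:

$$\sigma^N \;\ge\; -\Delta I_{N^*} \;+\; n\,\Delta JS_{AB} \;+\;
m\,\Delta JS_{AC}, \qquad -\Delta I_{N^*} \ge 0 .$$

(The decrease of the in–ex information reduces, for this structure, to the
decrease of the conditional mutual information $I(X_B; X_C \mid X_A)$,
which is nonnegative by the data-processing inequality.)  We state the
bound with the explicit period counts $n$ and $m$ multiplying the two
Jensen–Shannon drops: that is the value of the infimum-of-sums from which
the bound is derived, computed and cross-checked numerically by
`nested_periodic_bound()`.

**Uncertainty relations.**  At a nonequilibrium steady state, any linear
current functional of a unit's jumps — including its restriction to a
single mechanism, and including information flows with their log-ratio
weights frozen at the stationary conditionals — obeys the finite-time TUR
$\sigma^\omega \ge 2\langle \mathcal{C} \rangle^2 /
\mathrm{Var}(\mathcal{C})$.  A vector of linearly independent currents
obeys $\langle \mathcal{C}\rangle^\top \Xi^{-1}
\langle \mathcal{C}\rangle \le \sigma^\omega/2$ with $\Xi$ the covariance
of the time-integrated currents; we implement this integrated-current
form, which is the dimensionally consistent reading of the vector TUR for
a fixed horizon, and say so in the report.  Current statistics come from
Gillespie trajectories, so every TUR report carries standard errors and a
verdict phrased as "not violated beyond three standard errors"; a mean
current indistinguishable from zero yields an inconclusive flag, not a
verdict.  For information flows, the nested-unit monotonicity of EP
suggests (but does not prove) that the smallest containing unit bounds the
flow's precision best; `info_flow_tur_check()` reports the empirical
ordering across containing units without asserting it as an invariant.

**Speed limits.**  The total variation distance a unit's marginal covers
in $[0, \tau]$ is bounded by
$\sum_v A^{\mathrm{tot}}_v\, g(\zeta^\omega_v / A^{\mathrm{tot}}_v)$ for
any concave nondecreasing $g$ with $g(0)=0$ dominating the total variation
distance as a function of KL divergence; Pinsker's $g(x) = \sqrt{x/2}$ is
the built-in choice (the reading of "$g = x/2$ under a square root"
consistent with Pinsker's inequality).  By Jensen's inequality this
mechanism-resolved bound is always at least as tight as the same bound
applied to the unit totals $A^{\mathrm{tot}} g(\sigma^\omega /
A^{\mathrm{tot}})$; both are computed and compared in every report.
Inverting the Pinsker form in the duration variable (holding the
time-averaged activities and the accumulated per-mechanism EP fixed) gives
a per-unit lower bound on how long the observed transformation must have
taken; `tau_lower_bound()` performs the inversion numerically — we do not
transcribe a closed-form duration bound, because the derivation, not a
formula, is what fixes it — and returns the largest bound over the
supplied units, the slowest-unit principle.

## Simulation and estimation choices

* **Propagation is exact**: matrix exponentials per protocol segment
  (dense, intended for joint spaces up to a few thousand states; the toy
  scale of interest).  Time dependence is restricted to piecewise-constant
  periodic protocols, which keeps both propagation and trajectory sampling
  exact — at a protocol breakpoint the Gillespie waiting time is simply
  redrawn, which memorylessness makes exact.
* **Seeding**: each trajectory derives its own seed deterministically from
  the root seed and its path index, so results do not depend on how many
  paths are requested.
* **Quadrature**: integrated EP and activity use composite Simpson on an
  equally spaced grid (64 intervals by default); halving the step changes
  the ensemble results by well under $10^{-6}$ relative, and the
  decomposition refines automatically as described above.
* **Zero handling**: $0 \ln(0/0) = 0$ and $0 \ln(0/a) = 0$; a positive
  flow with vanishing reverse flow is a hard error naming the transition.
  Per-mechanism reversibility (a transition has positive rate iff its
  reverse does) is enforced at validation because every EP formula divides
  by reverse rates.  EP integration from a distribution with zeros can
  still diverge transiently, so the generators draw strictly positive
  initial distributions for ensemble work.
* **Degenerate inputs**: reducible generators make `steady_state()` fail
  loudly with the communicating classes rather than silently returning one
  class's stationary vector; zero-activity mechanisms yield flagged
  undefined jump distributions and contribute zero to speed-limit sums.
* **Ordering conventions**: joint states are ordered lexicographically
  (first declared subsystem most significant), each unordered state pair
  is counted once in current functionals, and the total variation between
  forward and reverse jump distributions treats the pair-indexed tables as
  distributions.

## What the generators emulate — and what they do not

The random-instance generators define the study conditions for the
property suites.  `random_overlapping_unit_process()` draws binary
three-subsystem processes whose mechanism layout (one mechanism each for
$A$, $B \mid A$, $C \mid A$) guarantees the overlapping unit structure
$\{A, AB, AC\}$; rates are log-uniform on $[0.3, 3]$, a scale at which
instances are generically far from detailed balance while EP stays
numerically benign over the unit horizon $\tau = 1$.
`random_composite_process()` adds random multi-site puppet sets and random
leader enlargements with guaranteed irreducibility.  The nested periodic
builder uses $m = 3$, $n = 4$, two-segment protocols and the same rate
scale, with a random interior initial distribution.  Ensemble sizes (100
instances for identities and speed limits, 20 for the heavier bound
cross-checks, $10^4$ trajectories for TUR and simulation agreement) were
chosen as the smallest sizes at which the stochastic margins are resolved
beyond three standard errors.

These are toy-scale, fully reversible, truncated-state-space conditions.
Passing suites demonstrate the exactness of the identities and the
validity of the bounds under those conditions; they do not probe large
state spaces, stiff rate separations, continuous driving, or
irreversibility structures excluded by validation.  The mass-action
compiler truncates count spaces reflectingly (boundary-crossing transition
pairs are deleted together, preserving per-mechanism reversibility; cap 5
by default), so compiled processes are faithful to mass action only away
from the cap.  Conservation laws make compiled generators reducible across
total-count classes, which is physical, and `steady_state()` reports it.

## Open choices made by this package

* A dependency edge is required to be realized by *at least one* mechanism
  (the weakest consistent reading); the validator reconstructs the realized
  network from the rate tables, errors on missing declared edges, and
  warns on over-declared ones.
* Out of a stationary state, the information-flow formula is still
  computable; since its interpretation is only established at
  stationarity, non-stationary calls warn rather than fail.
* Whole-package energetics are deliberately out of scope: rates are
  primitive, local detailed balance is the user's responsibility, and all
  results that need it (the TURs' thermodynamic reading) are flagged in
  the documentation rather than enforced.

## Known limitations

Dense linear algebra bounds the practical joint-space size (a few thousand
states).  Trajectory sampling is plain Gillespie — no tau-leaping.
Discrete-time TURs, kinetic uncertainty relations, fluctuation theorems
and first-passage bounds are not implemented.  Time-dependent driving
beyond piecewise-constant periodic protocols is rejected at construction.
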