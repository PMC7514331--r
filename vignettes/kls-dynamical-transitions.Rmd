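---
title: "Relaxation and dynamical transitions in the 1D KLS exclusion process"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxation and dynamical transitions in the 1D KLS exclusion process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klsdyn)
```

## The model

The one-dimensional Katz–Lebowitz–Spohn (KLS) process describes hard-core
particles hopping rightward on a chain of $N$ nodes, a minimal model of
ribosome or molecular-motor traffic with short-range interactions.  The hop
from node $i$ to an empty node $i+1$ occurs with a rate
$\Gamma(n_{i-1}, n_{i+2})$ that depends on the occupations of the two
flanking nodes.  The package parameterizes the rates by a repulsion energy
$V$ (in units of $k_BT$) through the Glauber form
$$\Gamma(k, n) = \frac{1}{1 + e^{(n-k)V}},$$
which satisfies the two conditions
$\Gamma(0,1) = e^{-V}\Gamma(1,0)$ and
$\Gamma(0,1)+\Gamma(1,0) = \Gamma(0,0)+\Gamma(1,1)$ defining the KLS class.
Within this class the bulk stationary measure is the Boltzmann measure of a
nearest-neighbour lattice gas, and the stationary distribution factorizes
into 1- and 2-node marginals.  `glauber_rates(V)` builds the table;
`kls_rates()` accepts any user table in the class, `as_rates(V)` builds the
Antal–Schütz-type variant (no dependence on the left neighbour), and
`tasep_rates()` is the unit-rate TASEP for literature comparison.  Note the
time unit: the Glauber table at $V=0$ has all four rates equal to $1/2$, so
it is a TASEP slowed by a factor two.  All formulas are used exactly as
stated above; this keeps every quantity in the package consistent with one
single rate convention.

## Bulk stationary state and fundamental diagram

A bulk state at density $\rho$ is fully characterized by the correlator
$\eta = P[10]/(P[1]P[0])$, the positive root of
$\eta^{-2} - \eta^{-1} + \rho(1-\rho)\,[1 - \Gamma(0,1)/\Gamma(1,0)] = 0$.
Repulsion gives $\eta > 1$ (excess of particle–hole bonds).  The stationary
current is
$$J(\rho) = \Gamma(1,0)\left\{\eta\rho(1-\rho) + (1-\eta)(a + b\rho)\right\},
\qquad
a = \frac{\Gamma(1,0)-\Gamma(0,0)}{\Gamma(1,0)-\Gamma(0,1)},\;
b = \frac{\Gamma(0,0)-\Gamma(1,1)}{\Gamma(1,0)-\Gamma(0,1)}.$$
Glauber rates give $(a,b) = (1/2, 0)$; the Antal–Schütz table gives
$(0,1)$; for pure TASEP $\eta = 1$ and the $(1-\eta)$ term drops out.

The fundamental diagram $J(\rho)$ has a single maximum at $\rho = 1/2$ for
$V < V^\ast$ and two maxima flanking an interior minimum for $V > V^\ast$.
`find_vstar()` locates the threshold by bisection on the curvature of $J$
at $\rho = 1/2$ (central second differences with two Richardson levels,
$h = 0.02$, which brings the bisection bias to $\sim 5\times 10^{-9}$); it
reproduces the closed form $V^\ast = 2\ln 3$.  All dynamical analyses in
the package default to $V = 2V^\ast$, the value at which the stationary
phase diagram shows its full seven-phase structure.

```{r}
rates <- glauber_rates(2 * kls_vstar_exact())
fundamental_diagram_features(rates)$maxima
```

## Open boundaries and phase classification

The chain is coupled to reservoirs of densities $\rho_L$, $\rho_R$ through
*bulk-adapted* boundary conditions: the reservoirs behave like semi-infinite
systems in their own bulk state, which makes the extremal-current principles
exact.  `classify_phase()` implements them directly: for $\rho_L < \rho_R$
the selected current is $\min J$ over $[\rho_L, \rho_R]$, otherwise
$\max J$ over $[\rho_R, \rho_L]$, with interior extrema of the diagram
competing against the endpoints (grid scan of $2\times 10^4$ points plus
golden-section refinement; ties within $10^{-9}$ in current are reported as
coexistence rather than resolved arbitrarily — with the symmetric Glauber
diagram the two maxima always carry exactly equal currents, so the
corner of the phase diagram where both lie inside the scan interval is a
genuine tie).  Roman identifiers I–VII follow the geometry of the
seven-phase diagram at $V > V^\ast$: I/VI are the reservoir-controlled
low-density phases, III/V the high-density ones, II/VII the maximal-current
phases at the lower/upper maximum and IV the minimal-current phase.

## Pair approximation

The pair approximation (PA) closes the kinetic hierarchy at the level of
nearest-neighbour pairs: 4-node marginals are replaced by
$$P_i[k10n] \simeq
\frac{\tilde P_i[k1]\,\tilde P_{i+1}[10]\,\tilde P_{i+2}[0n]}
     {\tilde P_{i+1}[1]\,\tilde P_{i+2}[0]},$$
with the tilde tables taken from the left reservoir for indices at or below
the left edge, from the profile in the interior, and from the right
reservoir beyond the right edge.  The single-site table at node 1
deliberately uses the left reservoir: the closure is implemented exactly as
defined, including this asymmetry.  The state vector
$x = (\rho_1, \phi_1, \ldots, \rho_{N-1}, \phi_{N-1}, \rho_N)$ evolves as
$\dot x = f(x)$ with $\dot\rho_i = J_{i-1} - J_i$ and the corresponding
gain/loss equation for the pair occupations $\phi_i$.  The PA is exact for
the bulk stationary state (equal reservoir densities reproduce the flat
bulk solution to machine precision), but approximate for relaxation.

Numerical choices:

* **Stationary solve.**  Damped Newton on $f(x) = 0$ with the analytic
  Jacobian, assembled factor-by-factor from the closure (verified against
  central finite differences to $10^{-5}$ relative).  The initial guess
  blends the extremal-current bulk density into the reservoir densities
  over a three-site boundary scale.  Near phase boundaries the stationary
  profile sits on a slow manifold with a very small Newton basin
  ($\|f\|_\infty \lesssim 10^{-5}$); the solver then relaxes by stiff time
  integration (`deSolve::lsoda` with the analytic Jacobian) over
  geometrically growing horizons, polishing with Newton as soon as its
  basin is reached.  Convergence criterion: $\|f\|_\infty < 10^{-12}$.
  Degenerate reservoir densities (exactly 0 or 1) are handled by evaluating
  the reservoir tables in the analytic limit; profile-sourced denominators
  in the closure are floored at $10^{-14}$.
* **Relaxation rate.**  $M = -\partial f/\partial x$ at the stationary
  profile has positive-real-part spectrum; $\lambda_1$ is the smallest real
  part, computed by dense eigendecomposition (the largest size used
  anywhere in the package, $N = 400$, gives a $799\times799$ matrix, well
  inside dense range).  A complex slowest mode is flagged, never silently
  truncated.
* **Independent check.**  `pa_decay_rate_fit()` perturbs the stationary
  profile, integrates the kinetics and fits the exponential tail of
  $\|x(t) - x^\ast\|$; it agrees with the eigenvalue within 1%.

## Dynamical transitions

In the reservoir-controlled phases the relaxation rate $\lambda_1$ either
depends on both reservoir densities (*slow* phase, near LD/HD coexistence,
where $\lambda_1 \to 0$) or only on the bulk density (*fast* phase).  The
singularity separating them — with no accompanying change in the stationary
state — is the dynamical transition.  `pa_transition_locator()` finds it by
(i) extrapolating the fast-phase plateau over a size sequence with the
Bulirsch–Stoer algorithm ($\omega = 2$; the approach to the asymptote is
$\sim N^{-2}$ in the fast phase, which the tests verify with a log–log
slope of $-2 \pm 0.3$), and (ii) bisecting in $\rho_L$ for the point where
the finite-size rate first reaches the plateau.  For the upper HD phase the
plateau anchor is $\rho_L = 1$ (deep in the fast phase).  For the lower HD
phase of the double-humped diagram, $\rho_L = 1$ lies in a maximal-current
phase where exponential relaxation breaks down, so the locator anchors the
plateau at the arg-max of the finite-size rate inside the HD range instead
(the fast phase is where the rate is maximal); that phase yields two
crossings, one per flanking slow phase.

## Domain-wall theory

Domain-wall theory (DWT) models the LD/HD interface as a biased random
walker with hop rates $D_{L,R} = J(\rho_{L,R})/|\rho_R - \rho_L|$ and gap
$$\lambda_1^{\rm DWT} = \left(\sqrt{D_L} - \sqrt{D_R}\right)^2,$$
exact in the slow phase of pure TASEP (the package verifies this against
Bulirsch–Stoer-extrapolated exact finite-size gaps to within 2%).  The
modified DWT (mDWT) keeps the DWT in the slow phase and replaces the
unphysical part beyond it by a constant plateau.  Two constructions are
provided: the `max-plateau` rule (hold the first maximum — the TASEP-like
case), and the `min-plateau` rule for reservoir densities near the
minimal-current phase, where the DWT curve develops a second maximum and an
interior minimum.  The exact shape of the replaced region is not uniquely
specified by the qualitative description it implements, so the package
makes one concrete, continuity-preserving choice: follow the DWT up to its
first crossing of the oscillation-minimum value, hold that minimum up to
the minimum's location (this segment's bounds are the additional
dynamical-transition estimates), follow the DWT again up to the last
maximum and hold it thereafter.  An experimental `lowest-max` rule
(plateau at the lower of the two maxima) is shipped but not used for
transition lines: the two maxima exchange height at $\rho_R \approx 0.436$
(computed by bisection on the equal-height condition), where this rule
would produce a kink.

## Exact finite-size gaps

`build_generator()` assembles the sparse $2^N \times 2^N$ master-equation
generator with the bulk-adapted boundary rates derived as conditional
reservoir averages (injection $\alpha(n_2)$, extraction $\beta(n_{N-1})$
and reservoir-averaged edge hops).  Configurations are packed with node 1
in the most significant bit.  With these rates the finite-chain stationary
state at equal reservoir densities is flat to machine precision — the
construction's defining property, used as a validation invariant.  The
spectral gap (smallest nonzero decay rate) is computed by dense
eigendecomposition up to $N = 9$ and, above that, by a deterministic block
subspace iteration with Rayleigh–Ritz extraction on the uniformized chain
$P = I + Q/\Lambda$, whose dominant eigenvalues are exactly the zero mode
and the slowest decay modes.  (An ARPACK route was evaluated and rejected:
for these nonsymmetric operators its results depended on the random start
vector.)  The subspace iteration was validated against the dense solver at
$N = 8$ and $10$.

The $N \to \infty$ limit is obtained with the Bulirsch–Stoer (BST)
rational extrapolation with exponent $\omega = 2$,
applied to trailing subsequences of the gap sequence; the spread of the
extrapolants (plus the last tableau columns) serves as an error estimate,
and results whose spread exceeds 5% of the limit are flagged unreliable —
which reproducibly happens near the minimal-current phase, where the
extrapolation is dominated by noise.  The recursion reproduces sequences of
the form $a + bN^{-\omega}$ to machine precision ($\omega \in \{1,2,3\}$
tested), and `bst_omega_scan()` confirms $\omega = 2$ as near-optimal for
the gap sequences.  Default problem sizes are $N = 4$–$12$ (up to 14 in the
cross-validation against the DWT), chosen so that a full extrapolation
pipeline runs in seconds to tens of seconds on one core; $N$ up to 24 is
supported when memory allows.

## Kinetic Monte Carlo

`simulate_ring()` and `simulate_open()` are rejection-free continuous-time
simulations with per-bond rate catalogues, local updates after each event,
mandatory seeds, a discarded burn-in (20% of the simulated span by
default) and batch-means standard errors (50 batches).  They serve as a
stochastic cross-check of the analytic machinery: the open chain at equal
reservoir densities matches the exact $2^N$-state stationary vector within
error bars, and the ring current matches the exact fixed-density sector
solve at small $N$.

One caveat the tests make explicit: the fixed-density ring at half filling
with strong repulsion converges to the infinite-volume current only as
$\sim 1/N$ with a large coefficient (the exact sector solves show the
deviation still at $-2\%$ of $J$ around $N = 200$), so quantitative
comparisons against the infinite-volume fundamental diagram are made at
$\rho = 0.3$, where the correction is below the statistical error at
$N = 200$, while half filling is validated against the exact finite-ring
value instead.

## What the synthetic scans do and do not show

All experiments in the package are parameter scans of a model; there is no
external data.  The generator defaults — $V = 2V^\ast$, the three reference
cuts $\rho_R \in \{0.45, 0.75, 0.98\}$, PA sizes up to 400, exact
diagonalization up to $N \approx 14$ with $\omega = 2$ extrapolation —
reproduce the regime in which the dynamical-transition phenomenology is
established.  Passing tests demonstrate internal consistency of the five
independent routes (exact bulk algebra, PA kinetics, DWT, exact finite-size
spectra, KMC) and agreement with the closed-form reference values; they do
not, by themselves, validate the pair approximation's quantitative accuracy
for relaxation (the PA overestimates and the mDWT underestimates the true
rate, with the extrapolated exact gaps in between), nor the behaviour of
real traffic systems for which the KLS chain is a minimal caricature.

## Worked example

```{r, eval = FALSE}
rates <- glauber_rates(2 * kls_vstar_exact())

# relaxation-rate scan behind the dynamical-transition analysis
scan <- run_lambda_scan(list(V = "2vstar", rhoR = 0.75,
                             rhoL = seq(0.66, 0.98, by = 0.04),
                             N = c(50, 100), methods = c("pa", "dwt")))

# locate the dynamical transition
tr <- pa_transition_locator(0.75, rates, N_big = 100,
                            N_seq = c(25, 50, 100))
tr$rhoL_star

# exact finite-size gap, extrapolated
pipe <- gap_extrapolation_pipeline(
  boundary_conditions(0.3, 0.85, glauber_rates(0)), N_range = 4:12)
pipe$limit
```

## Known limitations

* The PA relaxation rate is an approximation; only its stationary
  predictions are exact.  Fully exact rates are limited to sizes where
  $2^N$ diagonalization is feasible.
* The extremal-current classifier reports coexistence whenever two
  arg-extrema tie in current; it does not resolve which phase a physical
  realization would select on the tie set itself.
* BST extrapolation near the minimal-current phase is noise-dominated
  (flagged, not suppressed).
* The `min-plateau` mDWT construction right of the oscillation is one
  defensible choice among several; only the bounds of the replaced segment
  should be given physical weight.
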