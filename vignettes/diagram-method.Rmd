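---
title: "Exact steady-state observables of kinetic diagrams"
author: "diagramflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact steady-state observables of kinetic diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagramflux)
```

## The model

A kinetic diagram represents a biochemical system as a connected graph of
discrete states joined by reversible transitions, each carrying forward and
reverse rate constants $k_{ij}$, $k_{ji}$. Mass-action kinetics gives the
master equations

$$\frac{dp_i}{dt} = \sum_{j \ne i} \left(k_{ji} p_j - k_{ij} p_i\right),
\qquad \sum_i p_i = 1 .$$

The discrete-state picture assumes a separation of time scales (fast
equilibration within a state, slow transitions between states), and all
transitions must be reversible. Binding steps are treated as
pseudo-first-order: a second-order on-rate $k^\circ$ (units
$\mathrm{M^{-1}s^{-1}}$) times a held-fixed ligand concentration, so the
system stays linear and always relaxes to a unique steady state.

The diagram method (King–Altman; Hill) turns the steady-state solution into
exact algebra. Three auxiliary diagram families are enumerated:

* **Partial diagrams** — the spanning trees of the diagram; their number is
  given independently by the Kirchhoff matrix-tree determinant, which this
  package uses as a mandatory cross-check on the enumeration.
* **Directional diagrams** — each spanning tree oriented toward each target
  state; the product of edge rates of one directional diagram is one
  additive term of the unnormalized probability
  $\Omega_i$, and $p_i = \Omega_i/\Sigma$ with $\Sigma = \sum_i \Omega_i$.
* **Flux diagrams** — a target cycle kept bidirectional plus one directed
  feeder edge per outside state, all feeding the cycle without closing a
  second loop. Summing feeder rate-products gives the factor $\Sigma_K$ in
  the net cycle flux
  $$J_K = \left(\Pi_+ - \Pi_-\right) \Sigma_K / \Sigma ,$$
  where $\Pi_\pm$ are the rate products along/against the cycle's positive
  direction. A Hamiltonian cycle has no flux diagrams and $\Sigma_K = 1$.

Net transition fluxes are $J_{ij} = k_{ij} p_i - k_{ji} p_j$; operational
fluxes (the observable transport rates) are signed sums of net cycle fluxes
over contributing cycles, or equivalently sums of net transition fluxes
over the ligand's unbinding transitions on the delivery side. The package
proves the two routes equal symbolically.

## Why a polynomial engine instead of a CAS

Every expression the diagram method produces is a ratio of *multilinear*
polynomials in the rate symbols: sums of products of distinct rates with
integer coefficients. No general computer-algebra system is needed (and
none is assumed): `diagramflux` represents expressions as sparse
term-coefficient maps with canonical, sorted monomial keys. Addition,
multiplication, substitution and equality are exact integer/float
arithmetic on those maps, so

* emitted expressions are byte-identical across runs (terms are kept in
  canonical order),
* `symbolically_equal()` is a genuine proof — two rational expressions with
  the common denominator $\Sigma$ are equal iff their numerator term maps
  cancel exactly — not a simplification heuristic,
* `compile_numeric()` turns any expression into a vectorized closure whose
  values agree with direct substitution to better than $10^{-12}$ relative.

If two expressions have *different* denominators, equality is decided by
cross-multiplication. When a finite time budget is given and the estimated
cross-product size exceeds it, the check falls back to evaluation at 50
random positive rate points with relative tolerance $10^{-9}$, and the
result is explicitly labelled `"numeric"` rather than silently reported as
proved. The $10^{-9}$ tolerance is a judgment call: mixed
compiled/symbolic evaluation of large expressions can disagree near machine
precision, and $10^{-9}$ sits far above that floor while far below any
physically meaningful difference.

## Orientation conventions

Figure-based conventions like "counter-clockwise is positive" do not
survive non-planar diagrams, so a cycle's positive direction is declared by
an ordered pair of adjacent cycle nodes (`orient_cycle()`). Enumeration
returns each cycle once in a canonical form (lowest-index state first, then
its lower-index neighbor), and all per-cycle quantities are reported in
that orientation. Reversing the orientation negates the transport
signature and the net cycle flux; signed sums such as operational fluxes
are invariant, and the tests assert exactly those invariants rather than
any figure-dependent per-cycle sign.

Transport bookkeeping walks a cycle once in its positive direction and
counts $+1$ for an external binding and $-1$ for an external unbinding of
a ligand; because every molecule bound during a completion is also
released, this external-side count *is* the net number moved from outside
to inside per completion.

## Thermodynamic consistency

Intrinsic (concentration-stripped) rates must satisfy cycle closure
(the Wegscheider condition) $\Pi_+^\circ = \Pi_-^\circ$ on every cycle;
`closure_residual()` reports $\ln(\Pi_+^\circ/\Pi_-^\circ)$ and the fixture
parameterizations keep it at zero identically. The chemical driving force
of a cycle is $\chi = \ln(X_+/X_-)$ over the pseudo-first-order
concentration products, in units of $kT$ ($kT \equiv 1$ throughout;
$[\mathrm{H^+}] = 10^{-\mathrm{pH}}$ M is applied at substitution time).

For validation, `generate_equilibrium_diagram()` builds random connected
diagrams with detailed-balanced rates from node potentials and symmetric
edge barriers, $k_{ij} = e^{u_i - b_{ij}}$ with
$u_i \sim U(-3, 3)$ and $b_{ij} \sim U(0, 3)$. The ranges span roughly six
decades of rates without overflow; the stationary distribution is the
Boltzmann distribution $p_i \propto e^{-u_i}$ by construction, every net
flux vanishes, and closure holds to machine precision. This generator is a
self-contained stand-in for an external consistent-rate generator whose
sampling scheme is not prescribed.

### What the synthetic validation world does and does not establish

The validation harness (`validate_random_diagrams()`, acceptance
criterion 5) samples 3–8 state diagrams at Erdős–Rényi edge densities
drawn from $U(0.2, 0.35)$. That choice keeps spanning-tree counts in the
tens to hundreds, so full symbolic expression generation for 50 diagrams
takes seconds; it deliberately does not exercise dense graphs (a complete
8-state graph has 262,144 spanning trees), nor diagrams beyond 8 states.
A green run establishes that enumeration counts match the matrix-tree
oracle, that equilibrium rate sets produce zero net fluxes
($< 10^{-12}$), and that symbolic probabilities match the matrix solver to
RMSD $< 10^{-11}$ — on *sparse-to-moderate* random topologies. It says
nothing about wall-clock scaling on large dense diagrams, which is out of
scope.

## Numerical solvers

`steady_state_matrix()` builds the rate matrix $A$ ($dp/dt = Ap$), uses the
singular value decomposition to confirm a rank deficiency of exactly one
(singular values below $10^{-12}$ times the largest) and to locate the
dependent equation, replaces that row with the normalization constraint and
solves directly.

`steady_state_ode()` integrates the master equations. Because they are
linear, the exact propagator over a step is the matrix exponential;
the solver computes one short-time propagator
($\Delta t = 0.1/\max_i |A_{ii}|$) and then squares it repeatedly
(doubling the step), renormalizing columns after each squaring since the
exact propagator is column-stochastic. This is unconditionally stable —
stiffness, the usual difficulty with chemical kinetics, costs nothing — and
probability is conserved to roundoff. Convergence is declared when
$\max_i |dp_i/dt| < 10^{-12}$ or when the iteration reaches a fixed point
to machine precision; the second criterion matters for stiff fixtures
(rates spanning nine decades) where the attainable residual floor is the
matrix norm times machine epsilon. Tested accuracy against the matrix
solver is RMSD $< 10^{-8}$ from any simplex starting point.

## The transporter fixtures

**4-state antiporter.** Driving ion R enters outside and leaves inside;
substrate L is pumped inside-out; a leak transition 2–4 uncouples them.
The symmetric parameter map (equal on/off rates on both sides, symmetric
leak) reproduces the textbook factored forms of $p_1$ and the Hamiltonian
cycle flux after substitution.

**6-state Na⁺/H⁺ antiporter.** A single productive ring — proton in
(outside → inside), sodium out — with Table-style parameters: on-rates from
the flux-through-a-disk estimate $k_\mathrm{on} = 4 R D N_A$
($R = 5\,$Å; $D = 9.3\times10^{11}$ and $2.5\times10^{11}\,$Å$^2$/s),
off-rates from $\mathrm{p}K_a = 6.8$ and $K_D = 30\,$mM, alternating-access
rates 69 and 350 s⁻¹, pH 5.5/8.5 and Na⁺ 150/10 mM. The leak variant adds
a symmetric transition 1–4, creating proton (A) and sodium (B) leakage
cycles next to the coupled ring (C), with
$J_{\mathrm{H^+}} = J_A + J_C$ and $J_{\mathrm{Na^+}} = J_B + J_C$.
Sweeping the leak rate over $10^{-2}$–$10^{2}$ s⁻¹ shows the control model
locked at 1:1 stoichiometry while the leak model decays monotonically and
crosses into net sodium backflow once the leak cycle overcomes the coupled
cycle.

**8-state EmrE free-exchange model.** The cube-topology diagram (side ×
protonation × drug occupancy) with pH 7.5/6.5 and 25 nM drug on both
sides. Both ligands' positive flux direction is inside → outside. Two
rate-biasing experiments switch the phenotype:

* `sweep_raa()` varies the antiport-type alternating-access rates as
  $10\sqrt{R_{AA}}$ and symport-type as $10/\sqrt{R_{AA}}$;
* `sweep_roff()` varies drug off-rates as $10\sqrt{R_\mathrm{off}}$,
  $10/\sqrt{R_\mathrm{off}}$ and proton off-rates as
  $10^3\sqrt{R_\mathrm{off}}$, $10^3/\sqrt{R_\mathrm{off}}$ at uniform
  alternating-access rate $k_{AA} \in \{1, 10, 100, 1000\}$ s⁻¹.

The reciprocal-pair parametrization about fixed geometric means is the one
choice that reproduces the published admissible per-rate ranges exactly at
the published extreme bias ratios, and it preserves cycle closure at every
grid point; the anchors themselves (10 s⁻¹ for alternating access and drug
off-rates, $10^3$ s⁻¹ for proton off-rates) are inferred from those
ranges, not printed directly. Consequently fluxes at *interior* sweep
points inherit the anchor inference and are held only to 20% in the
acceptance tests, while extreme-bias plateau values are insensitive to it.
One known tension is recorded rather than resolved: the baseline drug
off-rate column (1 s⁻¹) differs from the range-derived geometric mean
(10 s⁻¹); the sweeps use the range-derived anchor.

A further caveat: the drug-flux mirror symmetry
$J_D(R_{AA}) \approx -J_D(1/R_{AA})$ is only approximate here (relative
deviations of a few $10^{-4}$), because the pseudo-first-order drug
binding rate (0.25 s⁻¹) differs from the baseline drug off-rate (1 s⁻¹),
breaking the exact graph symmetry; tests assert it at $10^{-3}$ relative.

## Degenerate inputs and numerical choices

* Irreversible transitions (a declared rate with no reverse) are rejected
  at load time, as are self-loops, duplicate declarations and disconnected
  graphs. Parallel transitions between one state pair are outside the
  supported class (the enumeration algorithms assume simple graphs) and
  are rejected with a clear error.
* Enumeration order is fixed: transitions sort lexicographically by state
  index, edge combinations are generated in that order, cycles sort by
  length then node sequence. Two runs give identical ordered output.
* `kp_compile()` errors on symbols missing from the symbol order at
  compile time, not at call time.
* Expressions default to the unreduced $(\text{numerator}, \Sigma)$ pair;
  $\Sigma$ cancellation is available on request via `kp_factor_common()`.
  Downstream ratios (stoichiometries) cancel $\Sigma$ exactly, avoiding
  expression blow-up.

## Known limitations

* Multigraphs (2-state cycles via parallel transitions), irreversible
  edges, and voltage- or force-dependent rate laws are out of scope.
* The "test and select" spanning-tree enumeration scales combinatorially;
  it is intended for the modest diagram sizes treated here (the 8-state
  cube takes about a second), not for dense graphs with many states.
* Cycle identifiers are canonical node sequences; published figure-based
  cycle numberings can only be matched by node set, not by label.
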