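---
title: "Bilevel force-field parameter estimation for molecular crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilevel force-field parameter estimation for molecular crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`crystalfit` fits the empirical repulsion/dispersion component of a
rigid-molecule lattice-energy model. The intermolecular energy of a
periodic crystal is

$$U_{inter}(\Omega; p) = U_{elec}(\Omega) + U_{rd}(\Omega; p),$$

with $\Omega$ the rigid-body variables — the free cell parameters
(n_x of them, set by the crystal system), the fractional centers of
mass, and the orientations of the molecules of the asymmetric unit —
and $p$ the Buckingham parameters of the atom-type pair potentials
$\varphi(r) = A e^{-Br} - C r^{-6}$. Molecules are frozen at their
reference conformation: conformational flexibility is out of scope and
each molecule moves as a rigid body under the space-group operators.

The electrostatic term uses fixed atom-centered point charges and is
evaluated by Ewald summation (real space, reciprocal space, self term,
and a constant rigid-intramolecular correction) under tinfoil boundary
conditions; higher multipoles and polarization are not modeled and
whatever they would contribute is absorbed by the empirical term
during fitting. The repulsion/dispersion term is a direct-space sum
over atom pairs and periodic images, excluding intramolecular pairs.
All energies are normalized per mole of molecules (lattice sums divided
by Z).

Given reference geometries and intermolecular energies for a set of
training structures, the per-structure merit function is a weighted sum
of squares of

* relative deviations of the free cell parameters, normalized by
  $\sqrt{n_x}$ (angles are treated identically to lengths; the
  deviations are unit-free either way);
* deviations of relative fractional coordinates — each atom measured
  against the first atom of the asymmetric unit, which removes the
  arbitrary global translation left free in space groups with a free
  origin — normalized by $\sqrt{3 N_{at} - 3}$, with every component
  first mapped to the periodic image nearest its reference value;
* the relative deviation of the optimized intermolecular energy,
  $(U^* - U_{ref})/|U_{ref}|$. The magnitude denominator keeps
  overbinding and underbinding on opposite signs regardless of the
  sign convention of $U_{ref}$; a "signed" denominator is available as
  an option. Since the merit function squares the residual, the choice
  does not affect the fit.

The Total Merit Function is the sum over structures,
$TMF(p) = \sum_s MF_s(p)$, and each $MF_s$ depends on $p$ through the
*optimized* geometry $\Omega^*_s(p)$ — a bilevel problem.

# Derivatives through the inner minimization

Differentiating the stationarity condition
$\nabla_\Omega U_{inter}(\Omega^*; p) = 0$ yields everything the outer
optimizer needs at no extra minimization cost:

* **Envelope identity.** The total derivative of the optimal energy is
  the partial derivative of the repulsion/dispersion term at the
  optimum, $dU^*/dp = \partial U_{rd}/\partial p|_{\Omega^*}$.
* **Implicit geometry sensitivities.** Each parameter's geometry
  response solves
  $H \, d\Omega^*/dp_j = -\partial^2 U_{rd}/\partial\Omega\,\partial p_j$,
  with $H$ the Hessian at the minimum. $H$ is factored once and reused
  across parameters.
* Residual Jacobians chain these through the residual definitions; the
  coordinate rows use analytic derivatives of the asymmetric-unit
  fractional positions with respect to $\Omega$ (symmetry and rigid
  rotation chain rule), not finite differences.

The gradient $\partial U_{inter}/\partial\Omega$, the parameter
derivatives $\partial U_{rd}/\partial p$ and the cross matrix
$\partial^2 U_{rd}/\partial\Omega\,\partial p$ are fully analytic
(the Buckingham energy is linear in $A$ and $C$, so the cross terms
only require the pair-distance derivatives already assembled for the
gradient). The Hessian $H$ is obtained by central differences *of the
analytic gradient* at fixed geometry — a deliberate design choice: it
involves energy-gradient evaluations only, never lattice
minimizations, so the central cost guarantee — a full TMF gradient
costs zero additional minimizations — is preserved exactly, while avoiding a
long error-prone derivation of second-order rotation/cell chain rules.
Where the Hessian feeds the implicit solve, a two-step Richardson
extrapolation removes the leading truncation term; the sensitivities
agree with re-minimization finite differences to ~1e-6 relative on the
toy problems, comfortably inside the 1e-4 target the test suite
enforces.

## Smooth cutoffs matter

With a sharp repulsion/dispersion cutoff, atom pairs entering or
leaving the cutoff sphere make the energy discontinuous at the
1e-5 kJ/mol scale and the gradient at ~1e-4 — harmless for energies,
fatal for finite-difference Hessians and for line searches near a
minimum. The pair sum therefore applies a C2-smooth quintic switching
function over a window ending at the cutoff (`taper` in
`energy_options()`, default 2 Å on a 15 Å cutoff; `taper = 0` restores
sharp truncation). No dispersion tail correction is applied. Ewald
accuracy is controlled by a target (default 1e-6 kJ/mol per molecule);
the splitting parameter is chosen from the cell volume and the real-
and reciprocal-space cutoffs adapt to it, so the result is invariant
to the splitting parameter within the target.

# The lattice minimizer

`minimize_lattice()` is two-staged: an L-BFGS descent on scaled
variables (lengths in Å, angles in radians, fractions and rotation
increments unitless) to a loose tolerance, then a modified-Newton
refinement using the eigenvalue-shifted Hessian to an infinity-norm
gradient below 1e-9 (scaled). The tight stage-2 tolerance is what makes
it safe to iterate the outer estimation around the minimizer. In the
small-gradient regime the Newton iteration trusts the analytic gradient
alone (quadratic local convergence); an energy-decrease test there
would be defeated by the residual cutoff noise described above.

Orientations are stored as unit quaternions; the optimizer sees a
3-vector axis-angle increment about the stored orientation
(exponential map), re-baselined after each accepted step, which avoids
Euler-angle gimbal singularities while keeping the degree-of-freedom
count of an Euler parametrization. ZYZ Euler export is provided for
interoperability. Derivatives at non-zero increments use the SO(3)
left Jacobian, so finite differences in the increment chart are
consistent with the analytic gradient.

Two failure channels are detected rather than regularized:

* **Saddles.** At termination the Hessian, projected off the
  structural null modes, must be positive semidefinite (eigenvalues
  above -1e-8, scaled); otherwise the result is a saddle and the
  estimator treats the structure as failed.
* **Collapse.** The Buckingham form turns unphysically attractive at
  very short range. Trial geometries with an intermolecular contact
  below `min_contact` (default 1 Å) are rejected by the line searches;
  a minimization terminating against this floor — or stalling while
  repeatedly hitting it — is reported as `overlap_failure`. This is
  the designed failure that drives the estimator's structure-removal
  logic when parameters wander into unphysical regions.

**Structural null modes.** In space groups whose operators all fix a
translation direction (all of them in P1, the screw axis direction in
P2₁), rigidly translating the whole motif leaves the energy invariant,
so the Hessian is exactly singular there; single-atom "molecules" and
linear molecules add rotational null directions. These modes are
removed by projection (an orthonormal basis of the orthogonal
complement) in the Newton step, the saddle test and the implicit
solve; the merit function is invariant to them by the reference-atom
construction, so the projected sensitivities are exactly the ones the
residuals need.

# The outer estimator

`run_local()` minimizes the TMF with a bound-constrained
Levenberg–Marquardt iteration (minpack.lm) on the weighted residual
vector, with the analytic Jacobian and parameters scaled by their
starting magnitudes. Around it sits the control flow that makes the
bilevel problem tractable:

* **Dynamic starting points.** The first TMF evaluation starts every
  lattice minimization from the reference geometry; subsequent
  evaluations warm-start from the previous evaluation's optima, which
  suppresses discontinuities from basin switching.
* **Re-evaluation and termination.** When the inner solver terminates,
  the TMF is re-evaluated from the original reference geometries. If
  unchanged, the estimates are accepted (B3). Otherwise the loop
  compares with the previous attempt: insufficient decrease (relative
  decrease below 1e-3 — the surface is flat near the optimum) accepts
  the current estimates (B4); an increase accepts the previous ones
  (B5); exhausting the re-initialization limit accepts the best seen
  (B6); otherwise the solver restarts from the current estimates with
  the starting points reset (B1).
* **Structure removal and reintroduction.** A lattice-minimization
  failure aborts the inner solve, removes the offending structure and
  restarts from the last successful iterate; after termination all
  removed structures are reintroduced for one final optimization and
  re-evaluation, reported without further iteration.
* **Multistart.** `run_multistart()` draws starting vectors from an
  unscrambled Sobol' sequence mapped (log-uniformly by default) into
  finite per-parameter bounds — by default two decades around the
  template magnitudes, always user-visible. Results are clustered into
  distinct minima by agreement of the re-evaluated TMF (relative
  1e-3) and of the scaled parameters (infinity norm 1e-2). Because the
  sequence is deterministic, adding starting points later extends the
  sampling without reshuffling it.
* **Scheduling contract.** Per-structure work is dispatched in order
  of decreasing estimated cost (from the previous iteration's
  energy-evaluation counts), the order a worker pool would want;
  execution is organized so results are identical to serial
  processing regardless of the worker count.

# The synthetic data generator

Reference data are generated by the package itself: small rigid
molecules (bent triatomic, planar quadrupolar 4-atom unit, 6-atom
ring, charged diatomic) packed at random — rejecting initial contacts
below 2.2 Å — into random low-symmetry cells (P1, P-1, P2₁), then
relaxed to lattice-energy minima under known "true" parameters. The
relaxed geometry and its energy become the reference entry, so the
TMF vanishes identically at the true parameters and parameter recovery
has an exact, known answer. The true parameters have the magnitudes of
transferable exp-6 force fields for C and H (A ~ 1e4–1e5 kJ/mol,
B ~ 3.6–3.74 1/Å, C ~ 1e2–1e3 kJ mol⁻¹ Å⁶), and the toy charges are
chosen so electrostatics carries an appreciable share of the binding,
exercising the Ewald path during fitting.

Two caveats are intentional. First, the reference energies come from
the same force-field family being fitted (an inverse crime): this is
the right construction for validating the estimation *machinery* — the
optimum is known exactly — but it says nothing about the accuracy of
any force field against quantum-chemical or experimental data. Second,
the toys are small and rigid by design; conformational flexibility,
disorder, special positions and fractional occupancies are all outside
the model.

# Numerical choices and problem sizes

* Repulsion/dispersion cutoff 15 Å (12 Å in the fast test
  configurations), 2 Å quintic taper, no tail correction.
* Ewald target 1e-6 kJ/mol per molecule; truncation levels set four
  decades below the target.
* Stage-1 handoff at scaled gradient 1e-5; stage-2 tolerance 1e-9;
  iteration caps 500/100; saddle threshold -1e-8 (scaled).
* Hessians: central differences of the analytic gradient with scaled
  steps of 1e-3 (Richardson-extrapolated from 2e-3 where they feed
  sensitivities).
* Inner solver: ftol/ptol 1e-15 so that zero-residual synthetic optima
  are driven to machine precision; parameter lower bounds 0.
* Test problems: training sets of 2–12 structures with Z' = 1 and 3–6
  atoms per molecule; the headline recovery experiment fits 6 free
  parameters (A and C for the three pairs of two atom types, B fixed)
  to 12 structures from a 20% log-uniform perturbed start. These sizes
  keep the whole validation suite comfortably reproducible on a single
  CPU while still exercising every code path; nothing in the
  implementation is specific to them.

# Known limitations

A practical note on validating the analytic gradients by finite
differences: a cold-start FD pipeline (re-minimizing from the
reference geometries at `p ± delta`) can hop between energy basins,
which makes the FD quotient meaningless — the same discontinuity
mechanism the dynamic starting points suppress during fitting. The
package's validation experiments therefore warm-start the FD
re-minimizations from the base optima (the same-basin derivative,
which is the quantity the analytic gradient computes) and screen out
structures whose relaxation at the test parameters has already left
the reference basin. Relatedly, when a relaxation lands in a
near-collapse basin (one very tight contact, Hessian condition
~1e5), the finite-difference-based Hessian limits the implicit
sensitivities to ~1e-3 relative accuracy there — a fully analytic
Hessian would not degrade; on physically reasonable minima the
achieved sensitivity accuracy is ~1e-6.


* Point charges only; no distributed multipoles, induction or
  polarization.
* Rigid molecules only; no intramolecular degrees of freedom, no
  fractional Z', no special positions (they are detected and
  rejected).
* The short-range Buckingham turnover is guarded against, not
  regularized; fits that drive parameters into collapse territory fail
  structures rather than silently continuing.
* Second-order parameter derivatives are not computed (no Newton outer
  loop), and no covariance/uncertainty estimates of the fitted
  parameters are provided.
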