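---
title: "Testing conformal invariance of 2D flow fields: methods and design"
author: "sleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing conformal invariance of 2D flow fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleflow)
```

## The problem

Collectively moving cells — bacterial monolayers, epithelial sheets —
generate disordered vortical flows.  The line separating clockwise from
counter-clockwise rotation, the zero-vorticity isoline, is a random
planar curve, and its statistics can be compared with the predictions
for conformally invariant curve ensembles.  Three quantitative probes
are in common use:

* **Fractal dimensions.** The perimeter `l` of a vorticity cluster
  scales with its gyration radius as `l ~ R_g^D`; the *complete*
  perimeter of critical-percolation-class clusters has `D = 7/4`, the
  *accessible* external perimeter (deep fjords sealed) has `D* = 4/3`,
  and conformal invariance ties the two through the duality relation
  `4 (D - 1)(D* - 1) = 1`.
* **Winding angles.** For conformally invariant curves the winding
  angle measured along the curve is Gaussian with variance
  `Var(theta) = a + alpha log s`, `alpha = 2 kappa / (8 + kappa)`.
* **Schramm-Loewner evolution (SLE).** Chordal curves in the upper
  half-plane are encoded by the Loewner driving function `U_t`; for
  SLE(kappa) it is a Brownian motion with `Var(U_t) = kappa t`.  The
  same `kappa` controls the left-passage probability through Schramm's
  formula.  `kappa = 6` is the percolation universality class.

The package implements the full measurement chain — vorticity,
oriented isolines, cluster geometry, winding statistics, left-passage
fits and driving-function extraction — together with synthetic
generators whose ground truth is known exactly, so that every stage is
verifiable without experimental recordings.

## Vorticity and oriented contours

`compute_vorticity()` evaluates `omega = dx u_y - dy u_x` with the
fourth-order five-point stencil `(f[-2] - 8 f[-1] + 8 f[+1] -
f[+2])/(12 h)` (exact through degree-4 polynomials).  Experimental
fields use `boundary = "crop"` (the two outer rows/columns, where the
stencil is undefined, are discarded); simulation snapshots wrap
periodically.  Binarisation is the strict sign rule `1 if omega > 0
else 0`; exact zeros join the non-positive phase.

Orientation convention: the row index is physical `y` (increasing
upwards), so `omega` follows the right-handed convention, and every
traced contour edge keeps positive-vorticity sites **on its right**.
With these conventions the outer boundary of a positive cluster is
traversed clockwise (negative shoelace area) and holes
counter-clockwise; the net signed area of all traces of a field equals
minus the occupied area, which the tests exploit as an oracle.

Saddle cells of the marching squares (diagonal pairs of equal sites)
are resolved by the declared site connectivity — 4 (positive phase
4-connected, the default for vorticity fields), 8, or 6 for the
triangular-lattice embedding described below — so tracing and
labelling always agree and the number of outer traces equals the
number of clusters.

## The percolation oracle and lattice geometry

Site percolation on the triangular lattice at `p = 1/2` is exactly
critical, and its cluster boundaries are the reference SLE(6)
ensemble.  The triangular lattice is stored on a square grid with two
extra diagonal neighbours per site (`connectivity = 6`).  That grid is
a *sheared* picture of the lattice: site `(r, c)` truly sits at
`x = c - r/2`, `y = r sqrt(3)/2`.  Scaling exponents are affine
invariant, so cluster-geometry fits may be done in index coordinates,
but all angular statistics (winding, left passage, driving functions)
are computed after un-shearing into the true geometry
(`unshear_triangular()`, applied automatically to chordal traces).
Ignoring the shear tilts left-passage profiles and biases `kappa`
estimates by about one unit.

Chordal exploration traces are produced by conditioning the field
below a horizontal axis with the chordal boundary colouring (occupied
to the right of the origin, empty to the left): the plain oriented
marching walk on the conditioned field then reproduces the explorer
construction exactly, including the rule that on touching the axis the
walk slides along it until it can re-enter the upper half-plane.  In
the sheared domain the walls form a parallelogram, so the default
origin column `width/2 - height/4` centres the exploration between
the side walls at half height.

## Fractal-dimension fits

`cluster_geometry()` tabulates per-cluster size, gyration radius
(root-mean-square distance from the centroid, equal to the normalised
pair sum), complete outer-perimeter length, and the accessible
external perimeter obtained by morphologically *closing* the cluster
(plus-shaped dilation followed by erosion, which seals fjord gates of
one lattice unit) and re-tracing its outer contour.
`fit_fractal_dimension()` reduces the cluster cloud to log-binned
medians (12 bins per decade) and fits `log l` against `log R_g`.

The closing, rather than the more common plain dilation, matters: a
dilation thickens every boundary feature by the probe size, and at
accessible gyration radii (a few hundred lattice units at most, since
accessible perimeters are only resolved on large clusters) the fitted
exponent is visibly depressed -- single-, double- and triple-dilation
variants return `D* = 1.28 / 1.25 / 1.23` on `2048 x 1024`
percolation ensembles, drifting the wrong way as the probe grows.
The shipped plus-element closing, with the closed set re-traced under
the cluster's own adjacency rule, returns `D* = 1.310 +/- 0.016` on
the same clusters, consistent with the exact 4/3 within two standard
errors.  (Tracing the closed set with orthogonal-only adjacency
instead, which cuts the saddle links the triangular rule keeps, reads
slightly higher at 1.34; the package uses the adjacency-consistent
variant so that closing and labelling agree on what a cluster is.)

The default windows matter too and are deliberate:

* complete perimeters: `[10 h, R_max/4]`.  Hull scaling carries strong
  lattice corrections below ~10 lattice units, and clusters whose
  radius approaches the system scale are cut by it.  On `2048 x 1024`
  critical ensembles this window returns `D = 1.752 +/- 0.014`.
* accessible perimeters: `[32 h, R_max/2]`.  The sealing closing adds
  a morphological scale, and effective external-perimeter exponents
  are known to converge slowly from below; the accessible window
  therefore starts higher (and accessible perimeters are only measured
  for clusters with at least 32 boundary edges in the first place).
  Because `R_max` is capped by the lattice height and the window
  starts at 32 lattice units, the accessible fit needs tall lattices:
  on `1024 x 512` fields the window spans less than a decade and the
  binned fit degenerates, which is why the shipped checks use
  `2048 x 1024` fields for the exponent pair.

Both windows can be overridden with `fit_range`.  Together the two
exponents give the duality product `4(D - 1)(D* - 1) = 0.93 +/- 0.05`
on the `2048 x 1024` ensembles, compatible with the exact value 1.

## Winding-angle statistics

`winding_angles()` accumulates the signed turning angles between
consecutive segments, each wrapped to `(-pi, pi]`; for closed traces
the closing turn is included, so simple loops wind by exactly
`+/- 2 pi`.  `winding_variance_fit()` measures the winding **within
segments of `s` steps, relative to each segment's average angle**, and
fits the pooled variance against `log s`.  This convention is
essential: the variance of plain end-to-end increments over interior
windows picks up the fluctuation of *both* window ends and grows with
exactly twice the conformal coefficient.  Measuring about the segment
mean halves it back, and the slope is `alpha = 2 kappa/(8 + kappa)`;
we verified both statements empirically on percolation hulls
(`2 alpha = 1.77` vs `alpha = 0.885`) and on forward SLE at
`kappa = 2`.  Gaussianity is assessed at `s = 64` and `s = 512` by
standardised moments (Gaussian when `|skewness| < 0.2` and `|excess
kurtosis| < 0.3`).

Traces with heterogeneous segment lengths (forward SLE samples) are
first resampled to uniform arclength (`resample_trace()`).  The
variance fit uses `s` between 16 and a quarter of the shortest trace.

## Left-passage probability

`schramm_probability()` evaluates Schramm's formula through the
equivalent integral `P(phi) = 1/2 + c(kappa) * int_0^{cot phi}
(1+u^2)^{-4/kappa} du` by adaptive quadrature; the unit tests verify
it against the independent closed form (a Student-t CDF with
`8/kappa - 1` degrees of freedom) to 1e-10, together with the exact
symmetries `P(pi/2) = 1/2` and `P(phi) + P(pi - phi) = 1`.

The empirical side classifies, for each sample point, whether the
directed curve passed it on the left, using the total swept angle of
the trace around the point with the trace completed to infinity by a
vertical ray from its endpoint (the canonical chordal continuation;
without an upper-half-plane closure, traces that exit sideways are
misclassified).  The default sample set is 5 radii x 9 angles with
radii between 0.015 and 0.06 of the median trace extent.  The small
fractions matter: a truncated curve has only provisionally decided the
passage status of points at radii comparable to its exploration depth.
Per-radius diagnostics on percolation interfaces recover
`kappa = 5.97` at a twentieth of the extent but drift to `~4.9` by
half of it, and the drift is a *selection* effect, not a closure
artifact: the fraction of (point, trace) pairs whose classification
flips between completing the curve to infinity on its left and on its
right ("undecided" pairs) grows from 9% to 25% over fractions
0.05-0.25, and excluding those pairs reproduces the same biased
profile, so conditioning on early decision is itself what skews the
statistics.  The only cure is radii much smaller than the exploration
depth, which is why the default interface lattice is deep (2048 x 768)
-- it keeps the smallest default radius at ~13 lattice units while the
largest stays below a tenth of the exploration depth, where per-radius
estimates agree (5.95-5.77 across the grid at `n = 600`).
`estimate_kappa_lpp()` then minimises the
weighted mean-square deviation `Q(kappa)` over a bounded bracket
(0.5-7.9, clear of the Gamma pole at 8) and reports a curvature-based
standard error.

## Driving-function extraction

`compute_driving_function()` unzips a chordal trace with the vertical
slit map `g(z) = delta + sqrt((z - delta)^2 + 4 Delta)`: the first
unmapped point fixes `U = delta` and the capacity increment
`Delta = y^2/4`, and the remaining points are pushed forward.  Points
that touch the real axis advance the driving value without adding
capacity, keeping Loewner times strictly increasing.  The loop is
organised point by point, so with a capacity cap (`t_stop`) the cost is
quadratic in the processed points only — the driving is causal in the
point index — which is what makes wide-lattice ensembles affordable.

`fit_kappa_driving()` interpolates the ensemble onto a common time
grid (piecewise constant, matching the zipper) and fits `Var(U_t) =
kappa t` through the origin by least squares, with a bootstrap
standard error over traces.  An increments-based variant (averaging
`Var(dU)/dt`) is noisier-looking in theory but was found to
*underestimate* `kappa` by ~10% on finite lattices, because the
lattice driving carries small positive long-range increment
correlations; the cumulative-curve fit is the method's definition and
is what ships.  Distributional diagnostics rescale each trace to its
own final capacity and compare `U_t / sqrt(kappa t)` at normalised
times 0.25 and 0.75 against a unit normal (Kolmogorov-Smirnov
distance), and `driving_autocorrelation()` checks that increments are
uncorrelated (Markov/Brownian behaviour).

Geometry matters twice.  First, the variance of `U_t` is suppressed
when lateral excursions approach the side walls, so the default
interface lattice is wide (2048 columns) and the fit window (`t` up to
2800 in lattice units) keeps the explored depth well inside the
domain.  Second, the lattice must be deep enough that *every* trace
reaches the capacity cap before leaving it: at height 256 about 6% of
traces exited early, and conditioning on reaching the fit grid selects
laterally-wandering, high-variance traces (the driving estimate
drifted up to ~6.3 on some seeds).  At the default height of 768 all
traces reach the cap and the fitted slope is stable in the time range
(5.86-6.16 for `t_max` between 700 and 2800 at `n = 600`).

## Forward SLE generator

`sample_sle_trace()` runs the discrete Loewner evolution with
`U_t = sqrt(kappa) B_t` held constant on steps of size `dt`, composing
inverse slit maps.  It is the exact inverse of the zipper on the same
partition, which gives a machine-precision round-trip test.  Its
traces have capacity-parametrised (heterogeneous) steps and limited
small-scale fidelity; statistics converge as `dt` shrinks at fixed
total capacity.  The winding slope of a `kappa = 2` ensemble, for
instance, reaches `0.37` (theory 0.4) at `dt = 2.5e-5` with 12000
steps; coarse discretisations underestimate it.  At `kappa = 6` the
discrete trace under-resolves its axis touches, so the percolation
exploration — exact in the scaling limit — is the preferred SLE(6)
reference throughout.

## Active nematic simulator

The continuum model couples an incompressible Stokes flow to
Beris-Edwards transport of the traceless symmetric order parameter
`Q`, with the purely elastic free energy `F = K (d_k Q_ij)^2` (no bulk
ordering term: nematic order is induced by activity).  The stress is
the sum of viscous, elastic (Ericksen, antisymmetric and
flow-alignment parts) and active (`-zeta Q`) contributions.  The
implementation is the standard hybrid: a D2Q9 lattice-kinetic (BGK)
solver with Guo forcing for the flow, explicit finite differences for
`Q`.  Numerical choices that proved necessary:

* first-order upwinding of the `Q` advection (central differences are
  unstable once structures sharpen to cell Peclet > 1);
* one binomial smoothing pass over the body force, which removes the
  grid-Nyquist component of the stress divergence that otherwise
  destabilises the explicit backflow coupling;
* exact mean-subtraction of the force after magnitude capping, so no
  net momentum is pumped into the periodic box;
* sub-stepping of the `Q` update when the diffusion number
  `2 Gamma K` approaches the explicit stability limit.

Only the two independent components `Q_xx, Q_xy` are stored, so
tracelessness and symmetry hold exactly.  Mass is conserved to
rounding; a mirrored initial state evolves to the mirrored solution.

**Scaled-down operating point.**  The production-scale study runs this
model on a `4096^2` lattice with `Gamma = 0.05, K = 0.05, mu = 1,
lambda = 1, zeta = 0.1`, where the active length `sqrt(K/zeta) = 0.7`
lattice units.  At the package's default `256^2` domain the choice of
the elasticity/activity pair is a genuine trade-off: vorticity
isolines are smooth below a few active lengths and box-limited above
`R_g ~ N/4`, so the universal scaling window only exists between
`~5 sqrt(K/zeta)` and 64 lattice units.  Raising `K` (to 2.5, one
suggested adjustment) makes the explicit backflow loop violently
unstable, drives the kinetic solver past its low-Mach window *and*
closes the scaling window entirely; a conservative low-activity point
(`zeta = 0.002` at paper `K`, active length 5) is stable but still has
no window — its measured complete-perimeter exponent saturates near
1.5.  An activity/elasticity scan shows the window opening once the
active length drops below ~2 lattice units, and the default is
`K = 0.0125, zeta = 0.005` (active length ~1.6, flow speeds 0.01-0.05,
order parameter bounded).  Lowering `K` leans on the study's own
robustness claim (<1% exponent change when the elasticity is varied
500-fold).  Raising the activity instead does not help: at
`zeta >= 0.0075` the injected small-scale roughness overwhelms the
percolation geometry and the measured exponent climbs to 1.87-2.0
with no plateau.

**Stationarity and snapshot independence.**  Two further protocol
parameters come from explicit diagnostics at this operating point.
First, the coarsening transient of the vortex pattern outlasts 15,000
steps: isoline statistics taken at 8,000-13,000 steps are
systematically rougher (`D` reads up to 0.05 high) than the developed
state, so the default warm-up is 30,000 steps.  Second, the developed
structures span ~25 lattice units (velocity autocorrelation falls to
0.5 at r = 26) and turn over in ~1,000 steps; snapshots 1,000 steps
apart are dominated by the same few structures, which shows up as
half-ensemble exponent estimates differing by up to 0.4 and as a
spurious left-right asymmetry of the pooled left-passage profile
(`p(pi/2)` as far as 0.63 where symmetry demands 0.5).  At the default
spacing of 4,000 steps — several turnover times — half-ensemble
estimates agree to 0.01.  One caveat survives the spacing diagnostic:
*independent* 20-snapshot realisations of the protocol still scatter
by ~0.1 in the fitted exponent (two such realisations read
`1.715 +/- 0.042` and `1.839 +/- 0.049`), roughly twice the per-fit
standard error, because only ~17 in-window clusters per snapshot enter
the fit and clusters within a snapshot are correlated.  The production
protocol therefore uses 40 snapshots (seed 42), which brings the
realisation-to-realisation sampling noise under the study tolerance;
it reads `1.785 +/- 0.043` over `[8, 64]`, between the two
20-snapshot realisations as doubling the ensemble should.

**A known finite-box bias of the left-passage diffusivity.**  On the
production 40-snapshot ensemble the left-passage estimate reads
`kappa = 5.51 +/- 0.21` (20-snapshot realisations read 5.4-5.5),
below the production-scale value ~6.  This is a finite-box squeeze,
not an estimator defect: the sample radii must sit *above* the
smoothing crossover (per-radius estimates rise from 3.6 at `rho = 2.6`
to a plateau ~5.5 beyond `rho ~ 8`, i.e. ~5 active lengths) and
*below* the truncation-bias onset (~0.15 of the ~130-unit trace
extent; beyond it the percolation control shows the same downward
drift, reading 5.83 rather than 6.0 at matching radius fractions).  At
`256^2` those two scales nearly meet, so every defensible radius
window returns ~5.4 +/- 0.3.  Checks that excluded protocol artefacts:
negating the vorticity field and switching the saddle rule between
connectivity 4 and 8 leave the profile unchanged; the
vertical-ray closure of truncated traces is unbiased (trace endpoints
are left-right symmetric); moving the exploration axis off-centre
deepens the traces only marginally.  Recovering `kappa ~ 6` by left
passage needs the trace extent, not the ensemble size, to grow — i.e.
a larger box.  The warm-up is a fixed configurable count rather
than an online autocorrelation estimate, which is ill-defined before
stationarity.

## What the synthetic data do and do not show

The generators emulate (a) statistically stationary active-turbulence
velocity fields with resolvable vortices, (b) exact critical
percolation interfaces, (c) SLE(kappa) traces for arbitrary
`kappa in [0, 8)`.  They share with real microscopy-derived PIV fields
the gridded format, the boundary cropping path and (for the simulator)
the continuum physics, but not measurement noise, drift, optical
artefacts or irregular masks.  Passing tests therefore demonstrate the
*correctness of the measurement chain* and its calibration on known
universality classes — not that any particular experimental system is
conformally invariant.

## Problem sizes used by the shipped checks

The percolation-class checks use 24-60 cluster fields of
`2048 x 1024` (exponents and duality), 600-2400 chordal interfaces on
`2048 x 768` lattices (left passage, driving function, winding;
short-capacity driving fits are tempting because the variance-slope
estimator's sampling sd `~kappa sqrt(2/n)` does not depend on
capacity, but `Var(U_t)` carries a positive lattice-scale excess that
biases through-origin slopes fitted below `t ~ 2000`, so the fit
window must stay deep and the traces long), a
`kappa = 2` forward-SLE ensemble (`dt = 2.5e-5`, 10000-12000 steps)
for the cross-check at a second diffusivity, and a `256^2`, 40-snapshot
simulation run for the end-to-end continuum-model surrogate.  For the
percolation and forward-SLE oracles these sizes are the smallest at
which the finite-size systematics documented above sit comfortably
inside the stated tolerances; for the `256^2` simulator surrogate the
perimeter exponent does, while the left-passage diffusivity retains
the finite-box deficit documented above.
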