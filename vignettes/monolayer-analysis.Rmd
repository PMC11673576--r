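---
title: "Monolayer mechanics, curve projection, and interfacial observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monolayer mechanics, curve projection, and interfacial observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models and
conventions behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Isotherm mechanics

A Langmuir monolayer is a one-molecule-thick film of amphiphiles at the
air-water interface, compressed by movable barriers while a Wilhelmy
plate records the surface pressure $\pi = \gamma_0 - \gamma$, the
reduction of the bare-interface tension $\gamma_0$ (72.8 mN/m for water
at room temperature) caused by the film.  The raw observable is the
compression isotherm $\pi(A)$, with $A$ the mean molecular area in
Å$^2$.

The in-plane stiffness of the film is the compressional modulus

$$C_S^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right),$$

whose magnitude conventionally classifies the two-dimensional phase:
below 25 mN/m a low-density liquid, 25–50 mN/m liquid-expanded (LE),
100–250 mN/m liquid-condensed (LC), above 500 mN/m a solid film.  The
unassigned gaps (50–100, 250–500 mN/m) are reported as `"intermediate"`
rather than silently attached to a neighbouring band; `classify_phase()`
is total on $[0, \infty)$.

`compressional_modulus()` smooths the pressure trace by adjacent
averaging (default 10 points), resamples it onto a uniform area grid
(default 0.1 Å$^2$; central differences on a uniform grid avoid any
spline-choice ambiguity), differentiates, and smooths the resulting
modulus curve with the same window — the standard noise-reduction step
for compressibility curves, which would otherwise amplify pressure noise
by the factor $A/\Delta A$.  For a window of $w$ points the value at
position $i$ averages positions $i-\lceil w/2\rceil+1$ through
$i+\lfloor w/2\rfloor$; at the edges the window shrinks to the largest
symmetric window that fits, so constant series pass through unchanged
and odd windows leave linear series fixed.

Scalar parameters reported per curve (`parameters_at()`):

* $A_{30}$, $C_{S,30}^{-1}$ — area and modulus at the biologically
  relevant reference pressure of 30 mN/m, by linear interpolation on the
  compression branch up to the pressure maximum;
* $C_{S,max}^{-1}$ — the maximum modulus;
* $A_{ex}$ — the limiting area, the zero-pressure intercept of the
  tangent to the most condensed region.  "Most condensed" is defined
  operationally as the point of maximum $C_S^{-1}$.  The tangent is a
  least-squares line over a $\pm 1$ Å$^2$ window centred there: a
  single-point finite difference would pass measurement noise straight
  into the intercept, and nothing in the definition forces a one-point
  fit.  A maximum on the grid boundary yields a one-sided window and a
  `boundary` flag.
* $\pi_{col}$ — the collapse pressure.  Experimental collapse pressures
  are read off plateaus by eye, so a detection rule had to be defined
  here: walking in compression order, once the modulus has exceeded 25
  mN/m, collapse is the first sample where it falls below 10% of its
  running maximum; if that never happens the maximum pressure is
  returned with a `no_collapse` flag.  The scan ignores points below 5
  mN/m of surface pressure: in the dilute regime the modulus of a noisy
  isotherm is dominated by amplified noise (the $-A$ factor is largest
  there) and "collapse" below a few mN/m is not meaningful.

## Projecting whole curve families

To compare conditions by whole curves rather than by hand-picked scalar
parameters, each curve is resampled onto a common pressure grid —
area-at-pressure for isotherms, modulus-at-pressure for modulus curves —
over the conventional 0–35 mN/m window, 351 points (0.1 mN/m spacing).
The curve family then lives in $\mathbb{R}^{351}$ with plain Euclidean
distances $\delta$.

The 2D map minimises

$$\sum_{i<j}\left[\frac{\delta(x_i,x_j)-\delta_{min}}
 {\delta_{max}-\delta_{min}} - d(y_i,y_j)\right]^2 ,$$

i.e. only the input-space distances are min–max normalised; projected
distances enter as they are.  When $\delta_{max}=\delta_{min}$ (all
items equidistant, which includes the two-item case) the normalised
distances are defined as 0.  Coordinates are initialised with classic
Fastmap on the normalised distances — per axis, a far-apart pivot pair
is found by two deterministic farthest-point sweeps starting from the
first item (ties to the lowest index), items get the cosine-law
coordinate, and the procedure recurses on residual distances — and then
refined by gradient descent with a backtracking (Armijo) line search,
which guarantees a non-increasing stress trace.  The run consumes no
randomness; the `seed` argument is recorded purely for provenance.
Defaults: `max_iter = 500`, relative stress tolerance `1e-10`.

One property of this objective is worth stating because it is easy to
get wrong: subtracting $\delta_{min}$ is an affine shift, not a
rescaling, so the normalised distances of a generic planar point set are
*not* themselves realisable in the plane and the achievable stress floor
is strictly positive (typically $10^{-3}$–$10^{-2}$ normalised for
$n=8$).  The optimizer-exactness tests therefore use planar sets
containing a coincident pair ($\delta_{min}=0$), for which the
normalisation is a pure rescaling and an exact embedding exists; the
projector reaches it to round-off.

Map quality is scored by the mean silhouette on the projected 2D
coordinates (the score rates the map, not the raw features):
$s_i = (b_i-a_i)/\max(a_i,b_i)$ with $a_i$ the mean within-group and
$b_i$ the smallest mean other-group distance; singleton groups
contribute 0.  Group separations are reported as centroid-to-centroid
distances relative to a declared reference pair, because a
stress-minimised plane has no absolute scale — only ratios are
meaningful.

## Interfacial observables for slab systems

For particle configurations in an orthorhombic periodic box (positions
in nm, wrapped into $[0, L)$):

* `density_profile()` histograms $z$ in fixed-width bins and normalises
  by the bin volume $L_x L_y \Delta z$; bin sums reproduce particle
  counts exactly, by construction.
* `gibbs_dividing_surface()` returns the $z$ where the density first
  decays through half its bulk value, linearly interpolated between bin
  centers.  The bulk reference is the mean over the densest contiguous
  20% of bins — a definition that needs no prior knowledge of where the
  bulk is, but which underestimates the bulk when the dense phase
  occupies less than 20% of the box; profiles should be binned so the
  plateau is at least that long.
* `interface_region()` reports the 10%–90% bulk-density crossing
  positions and their separation $\Delta z^*$ (for a linear ramp of
  width $w$ this is $0.8w$; for a normal-CDF decay of scale $s$ it is
  $2\,\Phi^{-1}(0.9)\,s \approx 2.563\,s$).  The 10–90 rule is an
  explicit convention of this package, chosen because "the region within
  the dividing-surface limits" admits no unique operational reading.
  Crossings are located from the dilute side (last downward crossing):
  counting noise in the plateau can graze the 90% level, but the tail
  cannot reach it, so the last crossing is the robust one.
* `surface_tension()` integrates the pressure-tensor anisotropy
  $\gamma=\int_{-L_b}^{L_a}\left[p_N(z)-p_T(z)\right]dz$ by the
  trapezoidal rule.  Units are nm and MPa throughout, chosen so that
  1 MPa·nm = 1 mN/m and the integral needs no conversion factor.
  Tension is computed from *tabulated* profiles: running the molecular
  dynamics that produces them is out of scope.
* `radial_distribution()` builds $g(r)$ from a minimum-image pair
  histogram (each unordered pair once, self-pairs excluded; the hot
  $O(N^2)$ loop is compiled code), normalised per frame by the
  ideal-gas expectation with exact shell volumes, valid for
  $r_{max} \le \min(L)/2$.  The 3D isotropic normalisation is used even
  for slab-like systems; in-plane variants are out of scope.
  `pmf_from_g()` inverts $g$ to the potential of mean force
  $U(r) = -k_BT\ln g(r)$ (reported in $k_BT$; bins with $g=0$ get
  $+\infty$ and are excluded from extremum searches), and
  `first_peak()` returns the first local maximum at least 10% above the
  uncorrelated baseline.

## The synthetic-data generator

No raw isotherms or trajectories are distributed with the studies this
kind of analysis serves, so the package carries seeded generators that
reproduce the *statistical structure* the analysis assumes.

Isotherms follow a two-dimensional Volmer equation of state

$$\pi(A) = \frac{kT}{A-A_{exc}} - \Pi_{coh},$$

clipped below at zero (the balance reads ~0 before film lift-off) and
above at a collapse plateau, with i.i.d. Gaussian pressure noise
(default 0.2 mN/m, floored at −0.45 mN/m as a sensor floor; real
replicate scatter in parameter tables is of this order).  $kT$ defaults
to 407.3 mN/m·Å$^2$, the thermal energy at 295 K in these units.  A
subphase additive at concentration $c$ (µM) acts through two knobs:
$A_{exc}(c) = a_{exc0}(1+\alpha c)$ (expansion) and
$\Pi_{coh}(c) = \Pi_{coh}\max(1-\beta c, 0.05)$ (softening).  The
defaults $\alpha = 0.01/\mu M$, $\beta = 0.005/\mu M$ give a ~30%
expansion at 30 µM, the magnitude seen in published parameter tables;
effect-size sweeps use a multiplier, with 0.05/µM as the "large effect"
level (clear separation already at 1 µM) and 0.002/µM near-null.  The
four model presets (CM1/HM1/CM2/HM2) differ in excluded area, cohesion
and collapse pressure; the CM1-like baseline is back-solved so that
$A_{30}\approx 44$ Å$^2$ and $C_{S,30}^{-1}\approx 150$ mN/m, and the
unsaturated-lipid models collapse near 42 mN/m instead of 53 mN/m.
These are toy equations of state with realistic magnitudes — the Volmer
form is the simplest one showing expansion, modulus reduction and a
collapse plateau — *not* fits to any measured system: passing tests
demonstrate that the estimators recover known structure under realistic
noise, not that any particular real membrane behaves this way.  In
particular the concentration response is linear by construction, whereas
measured responses are strongly sublinear, and the noise is white,
whereas instrument drift is not.

Particle generators place points uniformly, as a sharp slab, or with a
normal-CDF (sigmoid) decay via inverse-CDF sampling; pressure-profile
generators produce rectangular anomalies whose trapezoidal integral is
*exact* (edges snapped to grid nodes and given half height) or Gaussian
anomalies exact to quadrature accuracy.  All generators are pure
functions of (specification, seed).

## Numerical choices and degenerate inputs

* Even smoothing windows are aligned per the contract above; the window
  never grows back at the edges, it shrinks symmetrically.
* Curves supplied in expansion order are flipped; non-monotone area
  grids are rejected.  Pressures below −0.5 mN/m are rejected as
  unphysical; small negative pressures are stored as-is and clipped
  only where a nonnegative modulus is required.
* Interpolations "at a pressure" use the compression branch up to the
  first pressure maximum, with mean-collapsing of ties, so noisy
  plateaus do not corrupt the inverse map.
* All-zero distance matrices embed to the origin (not an error);
  two-item distance matrices are degenerate under min–max normalisation
  and carry zero normalised distance.
* A non-finite stress during optimisation aborts with the iteration
  number; a failed line search terminates cleanly with the trace intact.
* Problem sizes in the shipped tests and acceptance checks (5000
  particles × 20 frames for the $g(r)$ null, 48-curve projection sets,
  20-replicate recovery sweeps) were chosen so the full suite documents
  the statistics it claims while completing in well under a minute per
  check.

## Known limitations

* The collapse rule and the 10–90 width are package conventions; both
  are parameterised, but numbers derived from them are comparable across
  runs of this package, not necessarily across the literature.
* The silhouette of a 2D map depends on the projection; crowded
  many-cluster maps can score lower than the high-dimensional
  separation would suggest.
* $g(r)$ normalisation assumes an isotropic, homogeneous reference;
  for strongly inhomogeneous slabs the long-range plateau of $g$ is not
  exactly 1.
* The pipeline treats pressure-tensor profiles as inputs; it cannot
  validate how they were produced.
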