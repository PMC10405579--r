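---
title: "Methods: point-model scattering, structure factors and 2D patterns in oriscat"
author: "oriscat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-model scattering, structure factors and 2D patterns in oriscat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriscat)
```

# Scope and model

oriscat simulates elastic X-ray scattering from hierarchical structural
models built out of repeating subunits. A model is a *docking list*
(`PointSet`): an ordered set of subunit positions $\mathbf r_i$ in nm,
optionally with per-subunit Tait–Bryan orientations and a periodic box.
Scattering is described by the amplitude

$$F(\mathbf q) = \int \Delta\rho(\mathbf r)\, e^{i\mathbf q\cdot\mathbf r}\,
d^3r,$$

where $\Delta\rho$ is the electron-density contrast. All lengths are nm,
reciprocal lengths nm$^{-1}$, and amplitudes are in electron units: the
Thomson scattering length $r_0 = 2.82\times 10^{-5}\,\text{Å}$
(`thomsonLength`, converted to nm) is a constant multiplicative scale and
is deliberately **not** folded into any curve, because every comparison the
package targets is on a relative scale.

A hierarchical assembly (`AssemblyNode`) combines children (closed-form
subunits, point-scatterer docking lists, precomputed grids, or further
nodes) through placements — a rotation $A$ plus translation $\mathbf R$ per
copy:

$$F(\mathbf q) = \sum_{j}\sum_{m}\sum_{k}
F_j(A_{j,m}^{-1}\mathbf q)\, e^{i\mathbf q\cdot\mathbf R_{j,m,k}}.$$

**Rotation convention.** Tait–Bryan angles $(\alpha,\beta,\gamma)$ in
degrees are applied as intrinsic rotations about x, then y, then z
($A = R_z(\gamma) R_y(\beta) R_x(\alpha)$). This is stated prominently
because the literature often says only "Tait–Bryan" — any consumer of dol
files with orientation columns must use this order to reproduce our
amplitudes.

# Subunit form factors

Closed forms are used for the three subunit kinds:

* sphere — $F(q) = 4\pi\Delta\rho\,[\sin(qR) - qR\cos(qR)]/q^3$, isotropic,
  with the $q\to 0$ limit $\Delta\rho V$ taken by a series expansion below
  $qR = 10^{-5}$ (the closed form is numerically stable above this);
* cylinder (axis along local z) —
  $F(\mathbf q) = \Delta\rho V\,\frac{2J_1(q_\perp R)}{q_\perp R}\,
  \mathrm{sinc}(q_z H/2)$;
* point — the constant scattering length $b$ in electrons.

The isotropic ("solution") form factor $\langle|f|^2\rangle$ of the
cylinder is a single polar-angle quadrature by symmetry; we use fixed-order
Gauss–Legendre (order 96 by default). For the dimensions used in the
examples ($H \le 3.2$ nm, $q \le 10$ nm$^{-1}$) the integrand has at most
a few oscillations and order 96 is converged far below the $10^{-4}$
relative target; the unit tests check it against a $10^6$-sample Monte
Carlo orientation average.

# Structure factors

The oriented structure factor of $N$ subunits is
$S(\mathbf q) = \frac1N\left|\sum_i e^{i\mathbf q\cdot\mathbf r_i}\right|^2$
and its isotropic average is the Debye sum

$$S(q) = \frac1N \sum_{i,j} \mathrm{sinc}(q\,r_{ij}),$$

with the $i=j$ self terms included, so $S(0)=N$ and $S(q)\to 1$ at large
$q$. This normalization is the one consistent with the intensity
factorization $I(q) = N\,|f(q)|^2\,S(q)$ for identical spherically
symmetric subunits, which `sqFromIntensity` inverts. The inversion is
exact *only* for spherically symmetric subunits; for cylinders the
deviation grows with $q$ and the test suite asserts it is material by
$q \approx 3$ nm$^{-1}$ at the example dimensions.

**Evaluation cost.** Pair distances are merged when equal to within
$10^{-9}$ nm (floating-point noise on lattices), which reduces a crystal's
$\binom{N}{2}$ distances to its few thousand distinct shells. Above 2000
points the distances are histogrammed on $10^{-3}$ nm bins before the sinc
sum; the induced relative error is below $10^{-4}$ for $q \le 100$
nm$^{-1}$.

**Thermal averaging.** `sqFromModel(nThermal = k, fluct = ...)` averages
the Debye curves of $k$ configurations produced by `thermalize`;
configuration $j$ uses seed $\text{seed} + j - 1$, making the average
bit-reproducible.

# Radial distribution functions

`grFromModel` bins minimum-image pair distances into half-open shells
$[r, r+\Delta r)$ and normalizes by $4\pi r^2 \Delta r\,\rho_b$ with
$\rho_b = N/V$ from the periodic box; the box is therefore required. Bin
centers are reported. The default $\Delta r$ for the crystal examples is
0.05 nm, chosen so the first-shell integration window spans several bins.
By default every subunit serves as a reference (deterministic); a smaller
`nRefs` switches to seeded random selection. No finite-size tail
correction is applied. When a subunit radius $a > 0$ is given, each
neighbor contributes to every bin the exact fraction of its spherical
volume inside that radial shell (sphere–shell overlap volumes), which
spreads the shells smoothly while conserving their integrated mass.

The coordination number over $[r_1, r_2]$ is
$4\pi\rho_b\int_{r_1}^{r_2} r^2 g(r)\,dr$, evaluated by composite Simpson
on a refined grid with $g$ linearly interpolated from the stored bins. On
the ideal simple-cubic lattice any window isolating the first shell gives
6 to quadrature accuracy.

# Fourier transforms between S(q) and g(r)

The pair of truncated sine transforms

$$S(q) = 1 + \frac{4\pi\rho_b}{q}\int_0^{r_{max}} r\,[g(r)-1]\sin(qr)\,dr,
\qquad
g(r) = 1 + \frac{1}{2\pi^2\rho_b r}\int_0^{q_{max}} q\,[S(q)-1]\sin(qr)\,dq$$

is implemented with two quadratures: composite Simpson weights on the
stored grid (`method = "simpson"`), or midpoint weights evaluated at the
natural frequencies $\pi k / L$ of the truncation interval
(`method = "dst"` — the type-II discrete sine transform when the input
sits on a midpoint grid). $q = 0$ uses the analytic limit
$1 + 4\pi\rho_b\int r^2[g-1]\,dr$. Both methods agree to better than 1% on
smooth inputs (tested against a closed-form Gaussian-shell pair), and a
forward–inverse round trip on a smooth $g(r)$ recovers it to quadrature
accuracy when the transforms have fully decayed before the cutoffs.

**Truncation sensitivity (a caution for crystal models).** For a *rigid*
finite crystal the Debye $S(q)$ does not decay — Bragg-like oscillations
persist to arbitrary $q$ — so a hard cutoff at $q_{max}$ convolves $g(r)$
with a $\mathrm{sinc}$ kernel of width $\pi/q_{max}$ that rings around
every shell, and the curve can dip below zero. Window integrals over such
ringing curves are *not* robust observables: the test suite shows that the
first-shell coordination integral of the transform-derived $g(r)$ of the
10×10×10 crystal moves by units (roughly between 3 and 8) under sub-bin
shifts of the window or mild damping of the high-$q$ tail, while the same
integral on the directly binned $g(r)$ is stable at 6. Similarly,
truncating the direct-space integral at an $r_{max}$ *smaller than the
cluster diameter* discards real correlations: a double round trip
$S \to g \to S$ with $q_{max} = 8$ nm$^{-1}$ and $r_{max} = 32.5$ nm on
the 10×10×10 crystal (diameter ≈ 55 nm) leaves a relative L2 residual of
about 12% on $q\in[1,8]$ that vanishes (to 0.3%) once $r_{max}$ covers
the full support. These behaviors are properties of the truncated
transforms themselves, fully converged in our grids (results stable
between $\Delta q = 0.05$ and $0.0025$ nm$^{-1}$); published
coordination-number values obtained through such round trips therefore
depend on the discretization used and should be quoted with the window
and cutoffs that produced them.

# Monte Carlo thermalization

`thermalize` adds either uniform displacements $\Delta r = 2uv - u$,
$v \sim U[0,1)$ per coordinate (so $\Delta r \in [-u, u)$), or Gaussian
displacements of standard deviation $\sigma_u$. `mcSimulate` runs
Metropolis iterations against a harmonic
($V = \tfrac12 k (r - r_0)^2$) or Lennard-Jones
($V = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$) pair potential acting
between *static* nearest neighbors, selected once from the initial
configuration by a distance cutoff — a lattice-topology choice that keeps
runs deterministic and cheap; re-neighboring (as a liquid would need) is
out of scope. The energy cost of a trial move is half the summed pair
energy change over the moved point's neighbors (each interaction is shared
between the pair members; no further normalization by the neighbor count
is applied), and acceptance is $\min(1, e^{-\Delta E/k_BT})$. The RNG
protocol per iteration is documented in the function help (point index,
three displacement deviates, acceptance deviate) so that an independent
implementation can replay a run exactly; the test suite's brute-force
oracle does precisely this. Periodic boxes use minimum-image distances and
coordinate wrapping.

# Reciprocal-space grids and interpolation

Amplitudes are cached on polar grids $F(q,\theta_q,\phi_q)$: radial shells
uniform in $q$ up to $q_{max}$; shell $i$ carries $2i+1$ polar rows
uniform in $[0,\pi]$; each non-pole row carries $2(2i+1)$ azimuths uniform
in $[0,2\pi)$; pole rows collapse to one sample and shell 0 is the single
origin node. This keeps the angular sample density roughly constant per
shell and the origin exact.

Interpolation is Catmull–Rom cubic across shells in $q$ combined with
bilinear interpolation in $(\theta,\phi)$ within each shell ($\phi$
periodic). We chose this over a full tensor tricubic because the angular
layout is ragged — each shell has its own row structure — so a tensor
cubic would require angular resampling that breaks node-exactness; the
chosen scheme is exact at every node, falls back to linear on the first
and last radial intervals, and its radial error contracts at fourth order
(at least fourfold per shell-count doubling is asserted in the tests).
Grid algebra (`sumGrids`, `multiplyGrids`) is node-wise and layout-checked.

Orientation averages are Monte Carlo means of $|F|^2$ over uniform
directions (area-preserving map $\phi = 2\pi u$, $\cos\theta = 2v-1$),
with the sample budget doubling until the relative L2 change of the whole
curve between consecutive estimates is below `relTol` (default $10^{-3}$)
or `maxSamples` is reached; non-convergence sets a metadata flag and a
warning rather than an error, so long pipelines can inspect and retry.

# 2D patterns

`singleOrientationPattern` identifies the flat detector with the
$(q_\perp, q_z)$ plane (small-angle approximation; no Ewald-sphere
curvature correction): each pixel maps to
$q = (q_\perp^2+q_z^2)^{1/2}$, $\theta_q = \arccos(q_z/q)$, and the grid
is interpolated at azimuth $\phi'$ for $q_\perp \ge 0$ and $\phi' + \pi$
for $q_\perp < 0$. Pixel centers sit at
$(i+\tfrac12)\,2q_{lim}/n - q_{lim}$ with even $n$, so no pixel hits the
$\theta_q$ singularity at $q = 0$; detector corners beyond the grid's
$q_{max}$ are zero-filled and flagged in a mask instead of erroring.
`fiberPattern` replaces the fixed azimuth with a Monte Carlo average over
a (possibly restricted) azimuth domain, with the same doubling convergence
control; shrinking the domain to a point recovers the single-orientation
image, and the full domain enforces the $q_\perp$ mirror symmetry.

# Smearing and polydispersity

`applyResolution` convolves a 1D curve with a Gaussian kernel of width
$\sigma_r$, truncated at $\pm 4\sigma_r$ and re-normalized per output
point (constant curves are preserved exactly; $\sigma_r = 0$ is the
identity; widths below a tenth of the grid spacing warn as
under-resolved). Smearing acts on 1D azimuthally averaged curves only.

`polydisperseIntensity` evaluates a parametric model at 15 parameter
values equally spaced on $[c - 3\sigma_p,\, c + 3\sigma_p]$ and averages
with normalized Gaussian weights; the $\pm 3\sigma$ span captures 99.7% of
the weight, and equal spacing (rather than, say, Gauss–Hermite abscissae)
was chosen as the simplest documented rule consistent with a fixed
15-model budget. Abscissae at or below zero are clipped to
$10^{-6}\,c$ with their weight retained, so normalization survives large
$\sigma_p$. The 15-point rule agrees with a 61-point reference quadrature
to better than 1% for $\sigma_p/c \le 0.2$ (tested). The hook is a plain
evaluator function, so other weighting distributions can be implemented by
the user; none are shipped.

# Synthetic fixtures: what they emulate and what they do not

All test inputs are generated programmatically: the 10×10×10 simple cubic
crystal with $a = 3.5$ nm (the running example; with its periodic box it
represents one period of an infinite crystal, so every site has exactly 6
nearest neighbors), uniform/Gaussian thermal fluctuations at the example
amplitudes (0.3 nm domains; $\sigma_u = 0.1$ nm for the broadened-shell
checks), a graphene sheet in the xz plane ($a = 0.246$ nm, two-atom
basis) whose reciprocal net validates the 2D patterns analytically, point
helices standing in for atomistic double-helix models (three-unit stacks
at ±3.5 nm reproduce the characteristic 'X' layer-line pattern), and an
ideal gas for the $g \equiv 1$ normalization. These fixtures exercise the
geometry and the transforms, not chemistry: there are no atomic form
factors, no solvent layer, no absolute-intensity calibration, so passing
tests demonstrate correctness of the interference computations, not
agreement with measured data from real macromolecules.

Problem sizes in the test suite are chosen to keep every check at desk
scale: the sphere-vs-cylinder inversion comparison runs on a 6×6×6
lattice with a Monte Carlo orientation average at `relTol` $2\times
10^{-3}$; the grid-interpolated graphene pattern uses an 8×8-cell sheet
(the Bragg positions do not depend on the sheet size, only the spot
widths do) while the grid-node oracle uses the full 25×25 sheet; the
Metropolis oracle equivalence replays 5000 iterations exactly, which is a
stronger check than a long statistical comparison.

# Known limitations

* No GPU path, no fitting machinery, no state-file compatibility with
  other packages; persistence is plain text (dol, two-column curves, the
  grid container) plus optional TIFF export for display.
* The grid-free "direct method" is available only through
  `assemblyNode`/`amplitudeAt` leaves; very large trees that would need a
  hybrid grid/direct scheme are out of scope.
* Polydispersity applies to geometric models through the evaluator hook;
  atomic-model polydispersity (conformational averaging) is not provided.
* `grFromModel` requires a periodic box; free clusters have no defined
  bulk density.
* Transform-derived $g(r)$ and window integrals over it inherit the
  truncation sensitivity discussed above; prefer the direct binned
  $g(r)$ whenever a model is available.
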