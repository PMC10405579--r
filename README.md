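# oriscat

Simulation of small- and wide-angle X-ray scattering from hierarchical
point-based structural models — for structural biophysicists and soft-matter
scientists who model solution scattering, fiber diffraction, or
single-orientation (crystallography-style) 2D patterns from assemblies of
repeating subunits.

## What it computes

A structural model is a *docking list* of subunit positions **r**_i (nm),
optionally with Tait–Bryan orientations and a periodic box. On top of it,
oriscat provides:

- **Model building and thermalization** — crystals from lattice vectors or
  constants (`buildCrystal`), uniform/Gaussian random fluctuations
  (`thermalize`, Δr = 2uv − u with v ∈ [0, 1)), and Metropolis Monte Carlo
  against harmonic or Lennard-Jones nearest-neighbor potentials
  (`mcSimulate`, acceptance min(1, exp(−ΔE/k_BT))).
- **Structure factors** — oriented
  S(**q**) = (1/N)|Σ_i exp(i**q**·**r**_i)|² (`structureFactorOriented`),
  the isotropic Debye sum S(q) = (1/N) Σ_ij sinc(q r_ij) with optional
  thermal-configuration averaging (`sqFromModel`), the inversion
  S(q) = I(q)/(N|f(q)|²) from a solution intensity (`sqFromIntensity`),
  and S(q) from g(r) by a truncated sine transform (`sqFromGr`, Simpson or
  DST).
- **Radial distribution functions** — g(r) = N(r)/(4πr²Δr ρ_b) by
  minimum-image shell binning with optional finite subunit radius and
  thermal averaging (`grFromModel`), g(r) from S(q) (`grFromSq`), and the
  coordination-number integral 4πρ_b ∫ r² g(r) dr (`coordinationNumber`).
- **Reciprocal-space amplitude grids** — closed-form subunit amplitudes
  (sphere, cylinder, point scatterer), hierarchical assembly
  F(**q**) = Σ F_j(A⁻¹**q**) exp(i**q**·**R**) (`assemblyNode`,
  `amplitudeAt`), polar grids with node-exact interpolation (`fillGrid`,
  `interpolateAmplitude`), grid algebra (`sumGrids`, `multiplyGrids`), and
  Monte Carlo orientation averaging with doubling convergence control
  (`orientationAverage`).
- **2D patterns** — Ewald-plane slices at a fixed azimuth
  (`singleOrientationPattern`) and fiber diffraction as an azimuthal Monte
  Carlo average (`fiberPattern`).
- **Instrument effects** — Gaussian resolution smearing (`applyResolution`)
  and 15-model Gaussian size polydispersity (`polydisperseIntensity`).

Units are nm and nm⁻¹ throughout; amplitudes are in electron units (the
Thomson-length scale `thomsonLength` is a documented constant factor).

## Worked example

The running example is a simple cubic crystal, lattice parameter
a = 3.5 nm, 10 × 10 × 10 subunits:

```r
library(oriscat)
crystal <- buildCrystal(latticeFromConstants(3.5, 3.5, 3.5, repeats = c(10, 10, 10)))
crystal
#> PointSet with 1000 point(s), periodic box 35 x 35 x 35 nm
#>   [1]   -15.7500   -15.7500   -15.7500
#>   [2]   -12.2500   -15.7500   -15.7500
#>   [3]    -8.7500   -15.7500   -15.7500
#>   ...

g <- grFromModel(crystal, dr = 0.05, rMax = 8)
g
#> RDFCurve: 160 bins, dr = 0.05 nm, r_max = 8 nm, rho_b = 0.0233236 nm^-3
```

The first coordination shell sits at r = a = 3.5 nm (bin centered at
3.525 nm), and integrating 4πρ_b r² g(r) across it counts the six nearest
neighbors of the simple cubic lattice:

```r
coordinationNumber(g, 3.4, 3.6)
#> [1] 6.000201
```

The Debye structure factor starts at S(0) = N and shows the first Bragg
peak near q = 2π/a ≈ 1.8 nm⁻¹:

```r
sq <- sqFromModel(crystal, seq(0, 8, 0.01))
round(sValues(sq)[c(1, which.min(abs(qValues(sq) - 2*pi/3.5)))], 2)
#> [1] 1000.00    4.52
```

Decorating the lattice with spheres of radius 1.5 nm gives the solution
intensity I(q) = N |f(q)|² S(q), which can then be smeared by an
instrument-resolution width σ_r:

```r
ff <- solutionFormFactor(sphereModel(1.5), seq(0, 8, 0.01))
I  <- scatteringCurve(qValues(ff), nPoints(crystal) * intensities(ff) * sValues(sq))
Ismear <- applyResolution(I, 0.02)
```

Beware of window integrals over *transform-derived* g(r): for a rigid
crystal the truncated sine transforms ring around every shell, and the
vignette (`vignettes/oriscat-methods.Rmd`) documents why coordination
numbers read off such curves depend strongly on the integration window
and cutoffs.

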