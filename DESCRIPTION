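Package: oriscat
Title: Hierarchical X-Ray Scattering Simulation for Oriented Structures, Fibers and Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates small- and wide-angle X-ray scattering from hierarchical
    point-based structural models. Builds and thermally equilibrates docking
    lists of subunit positions (lattices, sheets, helices), computes oriented
    and orientation-averaged structure factors (Debye sums), converts between
    structure factors and radial distribution functions by sine transforms,
    fills polar reciprocal-space amplitude grids with hierarchical assembly of
    geometric subunits (spheres, cylinders, point scatterers), renders 2D
    single-orientation and fiber diffraction patterns by Ewald-plane slicing
    and azimuthal Monte Carlo averaging, and applies instrument-resolution
    smearing and Gaussian size polydispersity to 1D curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, pracma
Suggests: testthat (>= 3.0.0), jsonlite, tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
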