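Package: redordyn
Title: Site-Resolved Protein Dynamics from REDOR Dephasing Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts pseudo-3D REDOR magic-angle-spinning ssNMR crosspeak
    intensities into effective 13C-15N dipolar coupling constants, order
    parameters and cone-model motional amplitudes for protein assemblies.
    Provides the analytical universal REDOR dephasing curve with a
    first-principles powder-average oracle, an ideal-pulse multi-spin REDOR
    simulator, chi-square buildup-curve fitting with profile uncertainties,
    diffusion-on-a-cone and diffusion-in-a-cone amplitude models, an
    axial-rotation order-parameter predictor from atomic coordinates, a
    double-quantum (1J-CC) assignment-table generator from NMR-STAR chemical
    shifts, and a synthetic-data generator that emulates the statistical
    structure of the experimental intensity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
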