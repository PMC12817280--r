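Package: silknmr
Title: Chemical-Shift-Based Structural and Dynamic Analysis of Spider Silk
    Assemblies by Solid-State NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising recombinant spider-silk protein
    assemblies (engineered ADF4 repeat constructs such as eADF4(C16)) from
    solid-state NMR observables. Provides construction and motif accounting
    of repeat-protein sequences, literature-derived reference chemical-shift
    tables, synthetic generation of CP/INEPT-edited 1D and 2D (DARR, TOBSY,
    NCaCX) spectra with pseudo-Voigt lineshapes, peak picking and linewidth
    measurement, secondary-structure / glutamate-protonation / proline
    cis-trans classification from carbon chemical shifts, secondary
    chemical-shift profiling, homogeneous-inhomogeneous linewidth
    decomposition, mono-exponential relaxation fitting, CP-over-INEPT
    editing ratios, and an end-to-end reproducible pipeline producing a
    per-component structural report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
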