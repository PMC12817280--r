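# silknmr

Chemical-shift-based structural and dynamic profiling of recombinant
spider-silk assemblies (eADF4(Cn) nanofibrils and microparticles) from
solid-state NMR observables — for structural biologists and NMR
spectroscopists who want the full inference chain from spectra to
residue-level calls as reproducible, tested code.

## What it computes

Engineered ADF4 constructs — a tag, *n* copies of a 35-residue repeat, and a
trailing glycine — assemble into beta-sheet-rich fibrils whose structure and
dynamics are read out by solid-state NMR:

* **Dynamic spectral editing**: CP experiments select rigid segments
  (correlation times τc > 10⁻⁵ s), INEPT selects mobile ones
  (τc < 10⁻⁷ s); components are partitioned rigid / mobile / both by
  presence in the matched peak lists.
* **Secondary structure from shifts**: each class c ∈ {helix, sheet, coil}
  is scored by the squared standardised distance
  score(c) = Σₐ ((δₐ − μₐ,c)/σₐ,c)², with literature means μ and SDs σ per
  residue and atom; the lowest score wins, with tie and cutoff guards.
* **Side-chain chemistry**: Glu protonation from the Cγ/Cδ pair (nearest
  reference of 36.1/183.8 deprotonated vs 32.7/179.7 protonated); proline
  cis/trans from Δβγ = δ(Cβ) − δ(Cγ) (trans ≈ 4.5 ppm, cis ≈ 9.6 ppm,
  threshold 7.0), with populations from 2D slice integration.
* **Linewidth decomposition**: Δ_inhomo = Δ_total − Δ_homo with
  Δ_homo = 1/(π·T₂′) fitted from a spin-echo decay.
* **Relaxation and rigidity ratios**: mono-exponential fits
  I(t) = I₀·exp(−t/T) of spin-lock/echo decays; CP-over-INEPT integral
  ratio over the 10–70 ppm aliphatic window.
* **Synthetic data**: every stage is exercised by a generator producing
  pseudo-Voigt 1D/2D spectra (DARR, TOBSY, NCaCX topologies) and decays
  with exactly the statistical structure the analysis assumes, including a
  reference fixture encoding the published eADF4(C16) assignments.

## Worked example

```r
library(silknmr)

c16 <- build_construct(16, "T7")
c16
#> eADF4(C16) construct [T7 tag], 575 residues
composition(c16)[["E"]]
#> [1] 16
nrow(find_motifs(c16, "PG"))          # 4 PG motifs per repeat
#> [1] 64

ref <- load_reference_tables()
classify_secondary_structure("A", c(CA = 51.5, CB = 22.8), ref)
#> A: sheet (assigned; margin 11.1)
classify_secondary_structure("A", c(CA = 53.2, CB = 19.5), ref)
#> A: coil (assigned; margin 4.51)
classify_glu_protonation(36.1, 183.6, ref)
#> Glu: deprotonated (assigned; margin 4.97)

report <- run_pipeline(pipeline_config())
report$pro_ratio$trans_cis_ratio      # slice-integrated Pro populations
#> [1] 2.92
unlist(report$linewidth[1:3])         # Hz
#>         total_hz  homogeneous_hz inhomogeneous_hz
#>              925             320              605
report$relaxation$T1rho_H$T_s * 1e3   # ms
#> [1] 3.6
```

Reading: the 16-repeat construct carries one Glu and four Pro-Gly motifs
per repeat; the intense Ala cross peak at 51.5/22.8 ppm is a beta-sheet
resonance while 53.2/19.5 ppm is random coil; the observed Glu side chain
is deprotonated; slice integration of the proline Cγ rows recovers the
3:1 trans:cis generator populations; the 925 Hz total Gly Cα linewidth
decomposes into a 320 Hz homogeneous part (from the fitted T₂′ of
0.995 ms) and a 605 Hz inhomogeneous remainder; and the spin-lock decay
fit returns its 3.6 ms generator truth.

## Layout

* `R/` — sequence model, reference tables, synthetic generator, spectral
  analysis, shift classification, dynamics analysis, pipeline.
* `inst/extdata/` — transcribed reference shift tables (TSV) with a
  provenance sidecar.
* `vignettes/silknmr-methods.Rmd` — the model, conventions, parameter
  defaults and their rationale, and known limitations.
* `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
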