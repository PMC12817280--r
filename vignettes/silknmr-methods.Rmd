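---
title: "Chemical-shift-based structural and dynamic profiling of spider-silk assemblies"
author: "silknmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-shift-based structural and dynamic profiling of spider-silk assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silknmr)
```

## The scientific problem

Engineered ADF4 variants — eADF4(Cn), built from n copies of a 35-residue
consensus repeat of the *Araneus diadematus* fibroin 4 sequence — self-assemble
into amyloid-like nanofibrils or, under kosmotropic salt jumps, into
microparticles. Solid-state NMR under magic-angle spinning is the main route
to residue-level structure and dynamics in such non-crystalline assemblies:

* **Dynamic spectral editing.** Cross-polarisation (CP) transfer is efficient
  only for rigid segments (isotropic correlation times above ~1e-5 s), while
  INEPT transfer survives only fast isotropic motion (below ~1e-7 s).
  Recording both filters the same sample by mobility.
* **Carbon chemical shifts as structure meters.** Calpha/Cbeta shifts depend
  on the backbone dihedrals, so comparing observed shifts against
  literature class statistics (helix / sheet / random coil) yields
  secondary-structure calls per resolved component. Side-chain carbons
  report protonation state (Glu Cdelta) and peptide-bond isomerisation
  (Pro Cbeta-Cgamma separation).
* **Linewidths and relaxation.** The total linewidth decomposes into a
  homogeneous part, measured independently through the spin-echo lifetime
  T2' (FWHM_homo = 1/(pi T2')), and an inhomogeneous remainder reflecting
  conformational disorder. Rotating-frame relaxation (T1rho) probes
  microsecond-to-millisecond motions, and the CP-over-INEPT integral ratio
  acts as a bulk rigidity meter.

`silknmr` implements this entire inference chain as testable, deterministic
code, together with a synthetic-data generator that produces spectra with
exactly the statistical structure the analysis assumes. Every downstream
stage can therefore be validated end to end without any experimental
download.

## The synthetic generator and its assumptions

A sample is a list of *components*: one resonance state of one residue pool,
carrying atom shifts (ppm, DSS scale), a population fraction, a rigidity
class, and a structure annotation used only for validation. The reference
fixture `build_paper_fixture()` encodes the assigned resonance components of
the eADF4(C16) nanofibril: two rigid Ala beta-sheet packings (rectangular,
51.5/22.8 ppm; staggered, 51.0/25.9 ppm), minor rigid and mobile Ala coil
states, the analogous Ser triad, three mobile Gly Calpha resonances
(44.4 ppm assigned to the PG-motif glycines, 45.1, 46.0), the rigidified
aromatic Tyr ring, deprotonated Glu (36.1/183.6 ppm), and rigid trans/cis
proline components at populations 0.75/0.25. The staggered Ala Cbeta is
taken as 25.9 ppm; the alternative reading of 25.1 ppm that appears once in
the source assignments is recorded in the fixture notes rather than silently
chosen.

Population fractions not fixed by the assignments were chosen once at
realistic values (e.g. rectangular > staggered > minor coil for Ala,
roughly reflecting the reported cross-peak intensities; the PG glycine at
0.34 of the Gly pool, close to the 4-of-12 glycines per repeat that sit in
PG motifs) and are not revisited.

**Lineshape convention.** Each visible component contributes a unit-area
pseudo-Voigt line: a mixture of a Lorentzian and a Gaussian that *share one
FWHM*, the sum of the homogeneous and inhomogeneous widths, with Lorentzian
mixing fraction eta = homogeneous/total. This additive convention is chosen
deliberately over a true Voigt convolution so that "total minus homogeneous
equals inhomogeneous" holds *exactly* in the generator — the same arithmetic
the decomposition stage performs — rather than only approximately as in the
Voigt case. The default fixture widths are 20 Hz homogeneous +
50 Hz inhomogeneous, narrow enough that every assigned resonance is
resolved on the default grids; the linewidth-decomposition studies use
`single_line_sample()` with the width pair under study (e.g. 320 + 605 Hz).

**Editing weights.** CP visibility is 1 for rigid, 0 for mobile; INEPT the
reverse. Intermediate components enter both at a reduced weight (default
0.2) — an invented, configurable knob, since only the correlation-time
regimes of the two transfers are physically bounded. Cross-peak amplitude is
the product of population and editing weight; no transfer-efficiency physics
is modelled, because CP transfer is not quantitative anyway and any
efficiency model would be spurious precision.

**2D topologies.** Short-mixing DARR produces symmetric cross peaks for
one-bond carbon pairs of rigid/intermediate components (one-bond pairs are
derived from the side-chain chain order CA-CB-CG-CD-CE-CZ); long-mixing DARR
adds sequential (i, i±1) Calpha-Calpha and Calpha-CO contacts enumerated
from the construct sequence; TOBSY gives one-bond pairs of mobile components
only; NCaCX places the filtered components' nitrogen on the indirect axis
against their carbons. Spinning sidebands, t1-noise, apodisation and
chemical-exchange lineshapes are deliberately not simulated.

**What passing tests do and do not show.** The generator emulates
multi-component resonances, editing selection, separable line broadening,
exponential decays and 2D topologies — the statistical structure the
analysis assumes. It does not emulate baseline roll, probe background,
imperfect referencing, rotor-synchronous artefacts, or exchange broadening;
green tests therefore validate the inference chain, not its robustness to
every instrumental pathology of real spectra.

## Analysis conventions and numerical choices

* **Peak picking** finds strict local maxima above
  max(snr x noise, 1% of the spectrum maximum), with the noise floor
  estimated as 1.4826 x the median absolute deviation (over a signal-free
  region when one is declared). The apex is refined by a three-point
  parabola; half-height crossings are linearly interpolated. Both choices
  are stated so results are bit-reproducible at a fixed grid. The 1%
  relative floor suppresses far-tail ripples in effectively noiseless
  synthetic spectra. At a 3-sigma threshold a pure-noise spectrum of several
  thousand points is *expected* to yield a couple of false local maxima;
  that is a property of the threshold, not a defect of the picker.
* **Resolution scope.** Picked positions coincide with generator positions
  within one grid step for resonances separated from their neighbours by
  at least ~2.5 linewidths. Heavier overlap (e.g. two lines 0.4 ppm apart
  at 0.4 ppm width) merges into a single maximum; lineshape deconvolution
  is an explicit non-goal.
* **FWHM** is converted from ppm to Hz with the Larmor frequency computed
  from the field via the IUPAC frequency-ratio convention (16.4 T gives a
  ~700 MHz class instrument; 175.6 MHz for carbon).
* **Integration** is trapezoidal after subtracting the straight line through
  the window edges. Windows of equal width cancel truncation bias in
  ratios; the proline trans:cis ratio uses ±1.2 ppm windows around the
  Cbeta positions of slices taken ±0.3 ppm around each Cgamma row.
* **Secondary-structure classification** scores each class by the squared
  standardised distance summed over atoms (diagonal covariance — the
  literature tables publish per-atom means and SDs, not covariances). Ties
  within 0.5 score units are `ambiguous`; a best *per-atom mean* score above
  9 (three SDs per atom) is `unassigned`. The per-atom reading of the cutoff
  matters: the staggered Ala sheet component sits ~3.2 SD from the sheet
  Cbeta mean and would be rejected by a summed cutoff of 9 despite being an
  unambiguous sheet resonance.
* **Glycine** is not classified through the Calpha/Cbeta route in the
  pipeline: with a single atom the class means are fractions of an SD apart
  and neighbour effects dominate (a preceding proline shields Gly Calpha by
  0.77 ppm — precisely how the 44.4 ppm resonance is attributed to the PG
  motifs). Glycine structure is instead handled by the secondary-shift
  profile, which applies context corrections and the three-consecutive-
  same-sign rule before calling any element. The combined statistic is
  Delta-delta(Calpha) − Delta-delta(Cbeta), since the two atoms shift in
  opposite senses with structure.
* **Proline isomers** are discriminated by Delta(beta-gamma) =
  delta(Cbeta) − delta(Cgamma) with a default threshold of 7.0 ppm, midway
  between the canonical trans (~4.5 ppm) and cis (~9.6 ppm) separations;
  the threshold ships with the reference tables and is configurable.
* **Rigidity partitioning** uses presence/absence matching of predicted
  component positions in CP vs INEPT peak lists (greedy nearest-neighbour,
  ties to the higher peak, 0.3 ppm default tolerance — about half an
  observed inhomogeneous width in ppm at 16.4 T), mirroring the qualitative
  reading of dynamic spectral editing rather than intensity modelling.
* **Relaxation fits** use Levenberg-Marquardt least squares of
  I0 exp(−t/T) with log-linear starting values; plain Gauss-Newton `nls()`
  fails on exactly-fitting noiseless data, which the validation suite
  relies on. Asymptotic standard errors are reported. Bulk (integral)
  fitting is the default, matching how the published relaxation times were
  obtained; the decomposition uses the Lorentzian relation
  FWHM_homo = 1/(pi T2'). A homogeneous width exceeding the measured total
  clamps the inhomogeneous part to zero with an explicit warning flag.
* **Sequence model.** Construct assembly is exact bookkeeping: tag +
  n repeats x 35-mer + trailing Gly, with the cleaved initiator Met
  excluded by default. Within-repeat numbering is 1-based with Gly1 the
  repeat's first residue; the junction-wrapping PG search is on by default
  because the glycine following the previous repeat's terminal proline is a
  PG-motif glycine. Omega angles are computed as the
  CA(i−1)-C(i−1)-N(i)-CA(i) dihedral in the standard sign convention, with
  cis defined as |omega| < 90 degrees and exact 90 labelled trans.

## Reference data

The secondary-structure class statistics (means and SDs per residue, atom
and class) are transcriptions from Wang & Jardetzky (2002), shipped as a
versioned TSV with a provenance sidecar, restricted to the residue types of
the eADF4 repeat (G, S, A, P, Y, E, N, Q). The Glu protonation references
(deprotonated 36.1/183.8 ppm, protonated 32.7/179.7 ppm) and the proline
isomer shifts are packaged the same way. All tables are on the DSS scale and
the loader rejects files declaring any other reference compound, as well as
non-positive SDs, missing class entries, or a mis-ordered protonation or
isomer reference. Users can point `load_reference_tables()` at an override
directory; validation is identical.

## Problem sizes and determinism

Default grids are 4096 points over 0-200 ppm (1D) and 1024 x 1024 (2D) —
sizes at which every validation quantity is stable to well under its test
tolerance while the whole suite runs in well under a minute. All noise is
white Gaussian, seeded; identical configuration plus seed reproduces every
spectrum, fit and report byte-for-byte (timestamps aside). The pipeline
echoes every effective threshold and the configuration hash into the report,
so a report is auditable against its configuration.

## Interface note

The package is library-first: `run_pipeline()` / `compare_reports()` and the
stage functions are the interface, with `scripts/acceptance.R` as a thin
Rscript entry point that recomputes the headline quantities. A multi-command
shell tool was considered and rejected: every envisaged invocation is a
one-liner on the R functions, and a second argument-parsing surface would
only dilute the tested API.

## Known limitations

* No lineshape deconvolution: overlapping resonances closer than about two
  linewidths are reported as merged, and `measure_fwhm()` refuses peaks
  whose half-height crossing is blocked by a rising neighbour rather than
  returning a contaminated width.
* The editing model is binary-plus-knob; real CP/INEPT efficiencies vary
  continuously with dynamics and experimental setup, so editing *ratios*
  are comparable between simulations, not absolutely calibrated.
* The classifier assumes the literature class statistics transfer to
  solid-state shifts of an assembled silk; systematic offsets (referencing,
  temperature) would shift all scores but, by scale equivariance, not the
  ranking under a common offset.
* `omega_census` through PDB text is limited by the format's three-decimal
  coordinates (~0.05 degree); the dihedral itself is rotation-invariant to
  1e-6 degree on exact coordinates.
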