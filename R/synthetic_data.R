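# Synthetic spectrum, peak-list, and relaxation-series generation with the
# statistical structure the downstream analysis assumes: multi-component
# resonances per residue pool, CP/INEPT dynamic spectral editing by
# rigidity class, pseudo-Voigt lines with separable homogeneous and
# inhomogeneous widths, mono-exponential decays, and 2D one-bond vs
# sequential cross-peak topologies.

# nucleus of an atom from its name prefix
.atom_nucleus <- function(atom) {
  first <- substr(atom, 1, 1)
  c(C = "13C", N = "15N", H = "1H")[first]
}

# chain order used to derive one-bond carbon pairs (consecutive present
# atoms are bonded: CA-CB, CB-CG, CG-CD, CD-CE, CE-CZ)
.CARBON_CHAIN <- c("CA", "CB", "CG", "CD", "CE", "CZ")

#' One resonance component of a residue pool
#'
#' @param residue One-letter residue code.
#' @param label Component label, e.g. `"Ala_sheet_rect"`.
#' @param shifts Named numeric vector of atom shifts in ppm (DSS), names
#'   like `"CA"`, `"CB"`, `"N"`.
#' @param population Fraction of the residue pool in \[0, 1\].
#' @param rigidity `"rigid"`, `"mobile"`, or `"intermediate"`.
#' @param structure Structure annotation (`"sheet"`, `"coil"`, `"helix"`,
#'   or `NA`); bookkeeping only, never consulted by the analysis.
#' @param isomer Optional isomer annotation for proline components.
#' @return A `shift_component` list.
#' @export
shift_component <- function(residue, label, shifts, population = 1,
                            rigidity = c("rigid", "mobile", "intermediate"),
                            structure = NA_character_, isomer = NA_character_) {
  rigidity <- match.arg(rigidity)
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("'shifts' must be a named numeric vector")
  if (any(shifts < 0 | shifts > 250))
    stop("shift outside 0-250 ppm in component ", label)
  if (population < 0 || population > 1)
    stop("population must be in [0, 1]")
  structure(list(residue = residue, label = label, shifts = shifts,
                 population = population, rigidity = rigidity,
                 structure = structure, isomer = isomer),
            class = "shift_component")
}

#' Sample specification for the synthetic generator
#'
#' @param components List of [shift_component()] objects.
#' @param homogeneous_hz Homogeneous (Lorentzian) FWHM contribution, Hz.
#' @param inhomogeneous_hz Inhomogeneous FWHM contribution, Hz.
#' @param field_tesla Static field, Tesla (default 16.4).
#' @param nucleus Observed nucleus for 1D spectra (default `"13C"`).
#' @param noise_sigma White Gaussian noise sd per grid point.
#' @param seed Integer RNG seed for the noise.
#' @param notes Free-text metadata.
#' @return A `sample_spec` object.
#' @export
sample_spec <- function(components, homogeneous_hz, inhomogeneous_hz,
                        field_tesla = 16.4, nucleus = "13C",
                        noise_sigma = 0, seed = 1L, notes = NULL) {
  stopifnot(homogeneous_hz >= 0, inhomogeneous_hz >= 0, field_tesla > 0,
            noise_sigma >= 0)
  if (!length(components) || !all(vapply(components, inherits, TRUE,
                                         "shift_component")))
    stop("'components' must be a non-empty list of shift_component objects")
  # populations within each residue pool must sum to 1
  res <- vapply(components, `[[`, "", "residue")
  pop <- vapply(components, `[[`, 0, "population")
  for (r in unique(res)) {
    s <- sum(pop[res == r])
    if (abs(s - 1) > 1e-9)
      stop(sprintf("populations of residue pool '%s' sum to %.6f, not 1", r, s))
  }
  structure(list(components = components,
                 homogeneous_hz = homogeneous_hz,
                 inhomogeneous_hz = inhomogeneous_hz,
                 field_tesla = field_tesla, nucleus = nucleus,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 notes = notes),
            class = "sample_spec")
}

#' @export
print.sample_spec <- function(x, ...) {
  cat(sprintf("sample_spec: %d components, widths %g + %g Hz, %g T, noise %g\n",
              length(x$components), x$homogeneous_hz, x$inhomogeneous_hz,
              x$field_tesla, x$noise_sigma))
  invisible(x)
}

# editing (visibility) weight of a rigidity class in an experiment family
.editing_weight <- function(rigidity, transfer = c("CP", "INEPT"),
                            intermediate_weight = 0.2) {
  transfer <- match.arg(transfer)
  w <- if (transfer == "CP")
    c(rigid = 1, intermediate = intermediate_weight, mobile = 0)
  else
    c(rigid = 0, intermediate = intermediate_weight, mobile = 1)
  unname(w[rigidity])
}

.new_spectrum1d <- function(ppm, intensity, nucleus, larmor_mhz, experiment,
                            field_tesla = NA_real_) {
  structure(list(ppm = ppm, intensity = intensity, nucleus = nucleus,
                 larmor_mhz = larmor_mhz, experiment = experiment,
                 field_tesla = field_tesla, scale = "DSS"),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("spectrum1d [%s %s]: %d points, %.1f-%.1f ppm @ %.2f MHz\n",
              x$experiment, x$nucleus, length(x$ppm),
              min(x$ppm), max(x$ppm), x$larmor_mhz))
  invisible(x)
}

# descending ppm grid, conventional plotting order
.ppm_grid <- function(ppm_range, n_points) {
  seq(max(ppm_range), min(ppm_range), length.out = n_points)
}

#' Simulate a 1D CP- or INEPT-edited spectrum
#'
#' Each component visible under the requested polarisation transfer
#' contributes a unit-area pseudo-Voigt line at its shift, scaled by
#' population x editing weight.  CP selects rigid components (slow
#' isotropic motion), INEPT mobile ones (fast isotropic motion);
#' intermediate components enter both at a reduced, configurable weight.
#' Total FWHM = homogeneous + inhomogeneous (additive convention).
#'
#' @param sample A [sample_spec()].
#' @param experiment `"CP"` or `"INEPT"`.
#' @param ppm_range Length-2 numeric, grid limits in ppm.
#' @param n_points Grid points (default 4096).
#' @param intermediate_weight Editing weight of intermediate components.
#' @return A `spectrum1d` (descending ppm axis).
#' @export
simulate_1d <- function(sample, experiment = c("CP", "INEPT"),
                        ppm_range = c(0, 200), n_points = 4096,
                        intermediate_weight = 0.2) {
  stopifnot(inherits(sample, "sample_spec"))
  experiment <- match.arg(experiment)
  larmor <- larmor_frequency(sample$field_tesla, sample$nucleus)
  grid <- .ppm_grid(ppm_range, n_points)
  pv <- .pv_params(sample$homogeneous_hz, sample$inhomogeneous_hz, larmor)

  # all on-nucleus shifts must sit inside the grid
  offenders <- character(0)
  for (comp in sample$components) {
    sh <- comp$shifts[.atom_nucleus(names(comp$shifts)) == sample$nucleus]
    out <- sh[sh < min(ppm_range) | sh > max(ppm_range)]
    if (length(out))
      offenders <- c(offenders, sprintf("%s/%s (%.1f ppm)", comp$label,
                                        names(out), out))
  }
  if (length(offenders))
    stop("component shifts outside the grid: ", paste(offenders, collapse = ", "))

  intensity <- numeric(n_points)
  for (comp in sample$components) {
    w <- comp$population *
      .editing_weight(comp$rigidity, experiment, intermediate_weight)
    if (w <= 0) next
    sh <- comp$shifts[.atom_nucleus(names(comp$shifts)) == sample$nucleus]
    for (s in sh)
      intensity <- intensity + w * pseudo_voigt(grid, s, pv$fwhm_ppm, pv$eta)
  }
  if (sample$noise_sigma > 0) {
    set.seed(sample$seed)
    intensity <- intensity + stats::rnorm(n_points, sd = sample$noise_sigma)
  }
  .new_spectrum1d(grid, intensity, sample$nucleus, larmor, experiment,
                  sample$field_tesla)
}

#' Simulate a 2D correlation spectrum
#'
#' Cross-peak topology by experiment kind: `DARR_short` gives symmetric
#' cross peaks for one-bond carbon pairs of rigid/intermediate components;
#' `DARR_long` additionally adds sequential (i, i+-1) Calpha-Calpha (and
#' Calpha-CO where a CO shift exists) contacts enumerated from the
#' construct sequence; `TOBSY` gives one-bond pairs of mobile components
#' only; `NCACX` gives N(i)-CX peaks of the (rigid) filtered components
#' with nitrogen on the indirect axis.  Cross-peak amplitude is the product
#' of component population and editing weight — no transfer-efficiency
#' physics is modelled (the transfer is explicitly not quantitative).
#'
#' @param sample A [sample_spec()].
#' @param experiment One of `"DARR_short"`, `"DARR_long"`, `"TOBSY"`,
#'   `"NCACX"`.
#' @param mixing_ms Mixing time, ms (metadata; defaults by experiment:
#'   20 ms short DARR, 200 ms long DARR, 7.8 ms TOBSY).
#' @param construct A [build_construct()] result; required for `DARR_long`
#'   sequential contacts.
#' @param ppm_range,n_points Direct-dimension grid (defaults 0-200 ppm,
#'   1024 points).
#' @param indirect_range,indirect_points Indirect-dimension grid; defaults
#'   to the direct grid for homonuclear experiments and 100-140 ppm for
#'   the nitrogen dimension of `NCACX`.
#' @param residue_filter Optional one-letter residue code restricting
#'   `NCACX` to one residue type.
#' @param intermediate_weight Editing weight of intermediate components.
#' @return A `spectrum2d`: direct axis `ppm_direct`, indirect axis
#'   `ppm_indirect`, intensity matrix (rows = indirect, cols = direct).
#' @export
simulate_2d <- function(sample,
                        experiment = c("DARR_short", "DARR_long", "TOBSY", "NCACX"),
                        mixing_ms = NULL, construct = NULL,
                        ppm_range = c(0, 200), n_points = 1024,
                        indirect_range = NULL, indirect_points = NULL,
                        residue_filter = NULL, intermediate_weight = 0.2) {
  stopifnot(inherits(sample, "sample_spec"))
  experiment <- match.arg(experiment)
  if (is.null(mixing_ms))
    mixing_ms <- c(DARR_short = 20, DARR_long = 200, TOBSY = 7.8, NCACX = 20)[[experiment]]
  if (experiment == "DARR_long" && is.null(construct))
    stop("'construct' is required for DARR_long sequential contacts")

  larmor_c <- larmor_frequency(sample$field_tesla, "13C")
  transfer <- if (experiment == "TOBSY") "INEPT" else "CP"
  if (is.null(indirect_range))
    indirect_range <- if (experiment == "NCACX") c(100, 140) else ppm_range
  if (is.null(indirect_points))
    indirect_points <- if (experiment == "NCACX") 256 else n_points

  direct <- .ppm_grid(ppm_range, n_points)
  indirect <- .ppm_grid(indirect_range, indirect_points)
  pv_d <- .pv_params(sample$homogeneous_hz, sample$inhomogeneous_hz, larmor_c)
  pv_i <- if (experiment == "NCACX")
    .pv_params(sample$homogeneous_hz, sample$inhomogeneous_hz,
               larmor_frequency(sample$field_tesla, "15N"))
  else pv_d

  # assemble peak table: direct ppm, indirect ppm, amplitude
  pk_dir <- numeric(0); pk_ind <- numeric(0); pk_amp <- numeric(0)
  add_peak <- function(d, i, a) {
    pk_dir <<- c(pk_dir, d); pk_ind <<- c(pk_ind, i); pk_amp <<- c(pk_amp, a)
  }

  comps <- sample$components
  if (experiment == "NCACX" && !is.null(residue_filter))
    comps <- Filter(function(co) co$residue == residue_filter, comps)

  for (comp in comps) {
    w <- comp$population *
      .editing_weight(comp$rigidity, transfer, intermediate_weight)
    if (w <= 0) next
    if (experiment == "NCACX") {
      n_shift <- comp$shifts[.atom_nucleus(names(comp$shifts)) == "15N"]
      if (!length(n_shift)) next
      cx <- comp$shifts[.atom_nucleus(names(comp$shifts)) == "13C"]
      for (s in cx) add_peak(s, n_shift[[1]], w)
    } else {
      present <- intersect(.CARBON_CHAIN, names(comp$shifts))
      if (length(present) >= 2L) {
        for (k in seq_len(length(present) - 1L)) {
          a <- comp$shifts[[present[k]]]; b <- comp$shifts[[present[k + 1L]]]
          add_peak(a, b, w); add_peak(b, a, w)  # homonuclear symmetry
        }
      }
    }
  }

  if (experiment == "DARR_long") {
    seq_chars <- strsplit(construct$full_sequence, "")[[1]]
    # rigid/intermediate components by residue type
    vis <- Filter(function(co)
      .editing_weight(co$rigidity, "CP", intermediate_weight) > 0, comps)
    by_res <- split(vis, vapply(vis, `[[`, "", "residue"))
    for (i in seq_len(length(seq_chars) - 1L)) {
      r1 <- seq_chars[i]; r2 <- seq_chars[i + 1L]
      for (c1 in by_res[[r1]] %||% list()) for (c2 in by_res[[r2]] %||% list()) {
        w12 <- c1$population *
          .editing_weight(c1$rigidity, "CP", intermediate_weight) *
          c2$population *
          .editing_weight(c2$rigidity, "CP", intermediate_weight)
        if (w12 <= 0) next
        pairs <- list(c("CA", "CA"), c("CA", "CO"), c("CO", "CA"))
        for (p in pairs) {
          if (p[1] %in% names(c1$shifts) && p[2] %in% names(c2$shifts)) {
            add_peak(c1$shifts[[p[1]]], c2$shifts[[p[2]]], w12)
            add_peak(c2$shifts[[p[2]]], c1$shifts[[p[1]]], w12)
          }
        }
      }
    }
  }

  mat <- matrix(0, nrow = indirect_points, ncol = n_points)
  if (length(pk_amp)) {
    in_d <- pk_dir >= min(ppm_range) & pk_dir <= max(ppm_range)
    in_i <- pk_ind >= min(indirect_range) & pk_ind <= max(indirect_range)
    keep <- in_d & in_i
    for (j in which(keep)) {
      prof_d <- pseudo_voigt(direct, pk_dir[j], pv_d$fwhm_ppm, pv_d$eta)
      prof_i <- pseudo_voigt(indirect, pk_ind[j], pv_i$fwhm_ppm, pv_i$eta)
      mat <- mat + pk_amp[j] * outer(prof_i, prof_d)
    }
  }
  if (sample$noise_sigma > 0) {
    set.seed(sample$seed + 1L)
    mat <- mat + matrix(stats::rnorm(length(mat), sd = sample$noise_sigma),
                        nrow = nrow(mat))
  }
  structure(list(ppm_direct = direct, ppm_indirect = indirect,
                 intensity = mat, experiment = experiment,
                 mixing_ms = mixing_ms, nucleus_direct = "13C",
                 nucleus_indirect = if (experiment == "NCACX") "15N" else "13C",
                 larmor_direct_mhz = larmor_c,
                 field_tesla = sample$field_tesla, scale = "DSS"),
            class = "spectrum2d")
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("spectrum2d [%s, %g ms]: %d x %d points\n", x$experiment,
              x$mixing_ms, length(x$ppm_indirect), length(x$ppm_direct)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a mono-exponential relaxation decay series
#'
#' @param experiment `"T1rho_H"`, `"T1rho_C"`, or `"T2prime_C"`.
#' @param true_T_s Decay time constant in seconds (> 0).
#' @param delays_s Strictly increasing non-negative delays in seconds.
#' @param noise_sigma Gaussian noise sd on the intensities.
#' @param seed RNG seed.
#' @param i0 Amplitude at zero delay (default 1).
#' @return A `relaxation_series` with `delay_s`, `intensity`, metadata.
#' @export
simulate_decay <- function(experiment = c("T1rho_H", "T1rho_C", "T2prime_C"),
                           true_T_s, delays_s, noise_sigma = 0, seed = 1L,
                           i0 = 1) {
  experiment <- match.arg(experiment)
  if (!is.numeric(true_T_s) || true_T_s <= 0) stop("'true_T_s' must be > 0")
  if (any(delays_s < 0) || is.unsorted(delays_s, strictly = TRUE))
    stop("'delays_s' must be strictly increasing and non-negative")
  intensity <- i0 * exp(-delays_s / true_T_s)
  if (noise_sigma > 0) {
    set.seed(seed)
    intensity <- intensity + stats::rnorm(length(delays_s), sd = noise_sigma)
  }
  structure(list(experiment = experiment, delay_s = delays_s,
                 intensity = intensity, true_T_s = true_T_s,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "relaxation_series")
}

#' Log-spaced relaxation delays
#'
#' Convenience for the canonical spin-lock (200 us - 40 ms) and echo
#' (1 us - 40 ms) delay ranges.
#'
#' @param from,to Range in seconds.
#' @param n Number of delays.
#' @return Numeric vector of delays in seconds.
#' @export
log_delays <- function(from = 200e-6, to = 40e-3, n = 16) {
  exp(seq(log(from), log(to), length.out = n))
}

#' The eADF4(C16) reference sample fixture
#'
#' A `sample_spec` encoding the assigned resonance components of the
#' nanofibril sample: four Ala components (two rigid beta-sheet packings,
#' rectangular 51.5/22.8 and staggered 51.0/25.9; a minor rigid coil
#' 53.2/19.5; a mobile coil 53.1/18.8), three Ser components (rigid sheet
#' 57.5/66.2, minor rigid coil 58.1/64.1, mobile coil 58.3/63.9), three
#' mobile Gly Calpha resonances (44.4 = PG-motif glycines, 45.1, 46.0),
#' the rigid aromatic Tyr ring (Ceps 118.1, Cgam 131.0, Cdel 133.4,
#' Czet 157.7), rigid deprotonated Glu (Cgam/Cdel 36.1/183.6), and rigid
#' trans/cis proline components at populations 0.75/0.25.
#'
#' The staggered Ala Cbeta is taken as 25.9 ppm; the alternative reading
#' 25.1 ppm that appears once in the source assignments is recorded in the
#' fixture notes.
#'
#' @param noise_sigma Noise level (default 0, the reference condition).
#' @param seed RNG seed for the noise.
#' @param homogeneous_hz,inhomogeneous_hz Linewidth components (Hz);
#'   defaults 20 + 50 Hz, narrow enough that every assigned resonance is
#'   resolved on the default grids.
#' @return A `sample_spec`.
#' @export
build_paper_fixture <- function(noise_sigma = 0, seed = 1L,
                                homogeneous_hz = 20, inhomogeneous_hz = 50) {
  comps <- list(
    shift_component("A", "Ala_sheet_rect", c(CA = 51.5, CB = 22.8),
                    0.40, "rigid", "sheet"),
    shift_component("A", "Ala_sheet_stag", c(CA = 51.0, CB = 25.9),
                    0.35, "rigid", "sheet"),
    shift_component("A", "Ala_coil_rigid", c(CA = 53.2, CB = 19.5),
                    0.10, "rigid", "coil"),
    shift_component("A", "Ala_coil_mobile", c(CA = 53.1, CB = 18.8),
                    0.15, "mobile", "coil"),
    shift_component("S", "Ser_sheet", c(CA = 57.5, CB = 66.2),
                    0.60, "rigid", "sheet"),
    shift_component("S", "Ser_coil_rigid", c(CA = 58.1, CB = 64.1),
                    0.15, "rigid", "coil"),
    shift_component("S", "Ser_coil_mobile", c(CA = 58.3, CB = 63.9),
                    0.25, "mobile", "coil"),
    shift_component("G", "Gly_PG", c(CA = 44.4), 0.34, "mobile", "coil"),
    shift_component("G", "Gly_b", c(CA = 45.1), 0.33, "mobile", "coil"),
    shift_component("G", "Gly_c", c(CA = 46.0), 0.33, "mobile", "coil"),
    shift_component("Y", "Tyr_aromatic",
                    c(CG = 131.0, CD = 133.4, CE = 118.1, CZ = 157.7),
                    1.0, "rigid", NA),
    shift_component("E", "Glu_sidechain", c(CG = 36.1, CD = 183.6),
                    1.0, "rigid", NA),
    shift_component("P", "Pro_trans",
                    c(CA = 62.9, CB = 32.0, CG = 27.5, CD = 50.2, N = 137.0),
                    0.75, "rigid", NA, isomer = "trans"),
    shift_component("P", "Pro_cis",
                    c(CA = 62.5, CB = 34.2, CG = 24.6, CD = 49.3, N = 135.5),
                    0.25, "rigid", NA, isomer = "cis")
  )
  sample_spec(comps, homogeneous_hz = homogeneous_hz,
              inhomogeneous_hz = inhomogeneous_hz, field_tesla = 16.4,
              nucleus = "13C", noise_sigma = noise_sigma, seed = seed,
              notes = paste("eADF4(C16) nanofibril assignment fixture;",
                            "staggered Ala Cbeta recorded as 25.9 ppm",
                            "(alternative reading 25.1 ppm)"))
}

#' Single-resonance sample for linewidth studies
#'
#' One rigid line of a given residue/atom with an explicit
#' homogeneous/inhomogeneous width split — the configuration used to study
#' total-linewidth recovery and decomposition on the Gly Calpha resonance.
#'
#' @param shift_ppm Line position (default 45.1, a Gly Calpha).
#' @param homogeneous_hz,inhomogeneous_hz Width components in Hz.
#' @param residue,atom Identity of the resonance.
#' @param ... Passed to [sample_spec()].
#' @return A `sample_spec` with a single rigid component.
#' @export
single_line_sample <- function(shift_ppm = 45.1, homogeneous_hz,
                               inhomogeneous_hz, residue = "G", atom = "CA",
                               ...) {
  shifts <- stats::setNames(shift_ppm, atom)
  sample_spec(list(shift_component(residue, paste0(residue, "_", atom, "_line"),
                                   shifts, 1, "rigid")),
              homogeneous_hz = homogeneous_hz,
              inhomogeneous_hz = inhomogeneous_hz, ...)
}
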