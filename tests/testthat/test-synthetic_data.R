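# Synthetic spectra, editing rules, decays, and the reference fixture.

test_that("a single rigid line has FWHM equal to the additive total width", {
  s <- single_line_sample(shift_ppm = 45.1, homogeneous_hz = 300,
                          inhomogeneous_hz = 500)
  sp <- simulate_1d(s, "CP")
  pk <- pick_peaks_1d(sp)
  expect_equal(nrow(pk), 1)
  step_hz <- abs(diff(sp$ppm[1:2])) * sp$larmor_mhz
  expect_equal(measure_fwhm(sp, pk$ppm[1]), 800, tolerance = step_hz / 800)
  # and the same sample is invisible in INEPT
  expect_true(all(simulate_1d(s, "INEPT")$intensity == 0))
})

test_that("the fixture INEPT spectrum shows the three glycine resonances and a silent aromatic region", {
  fx <- build_paper_fixture()
  inept <- simulate_1d(fx, "INEPT")
  pk <- pick_peaks_1d(inept)
  gly <- pk$ppm[pk$ppm > 43 & pk$ppm < 47]
  expect_equal(sort(gly), c(44.4, 45.1, 46.0), tolerance = 0.05)
  # the rigid Tyr ring does not reach the INEPT spectrum: the aromatic
  # region carries nothing beyond far-tail residue of the aliphatic lines
  arom <- inept$ppm >= 110 & inept$ppm <= 160
  expect_lt(max(abs(inept$intensity[arom])), 1e-3 * max(inept$intensity))
  expect_equal(nrow(pick_peaks_1d(inept)[pick_peaks_1d(inept)$ppm > 110 &
                                           pick_peaks_1d(inept)$ppm < 160, ]),
               0)
  # but it does reach the CP spectrum
  cp <- simulate_1d(fx, "CP")
  expect_gt(max(cp$intensity[cp$ppm >= 110 & cp$ppm <= 160]), 0.01)
})

test_that("components outside the grid are reported by name", {
  s <- single_line_sample(shift_ppm = 45.1, homogeneous_hz = 100,
                          inhomogeneous_hz = 100)
  expect_error(simulate_1d(s, "CP", ppm_range = c(100, 200)),
               "G_CA_line.*45.1")
})

test_that("editing weights never make a component fully visible in both transfers", {
  for (rig in c("rigid", "mobile", "intermediate")) {
    w_cp <- silknmr:::.editing_weight(rig, "CP")
    w_in <- silknmr:::.editing_weight(rig, "INEPT")
    expect_true(w_cp >= 0 && w_cp <= 1)
    expect_true(w_in >= 0 && w_in <= 1)
    expect_false(w_cp == 1 && w_in == 1)
  }
})

test_that("simulate -> pick round trip recovers generator positions within one grid step", {
  fx <- build_paper_fixture()
  for (exp_kind in c("CP", "INEPT")) {
    sp <- simulate_1d(fx, exp_kind)
    pk <- pick_peaks_1d(sp)
    step <- abs(diff(sp$ppm[1:2]))
    visible <- unlist(lapply(fx$components, function(co) {
      w <- silknmr:::.editing_weight(co$rigidity, exp_kind)
      if (w <= 0) return(NULL)
      co$shifts[startsWith(names(co$shifts), "C")]
    }))
    # every resolved generator position has a picked peak within a step;
    # resonances closer than ~2.5 linewidths to a neighbour are outside
    # the picker's resolution scope
    for (v in visible) {
      sep <- min(abs(setdiff(visible, v) - v))
      if (sep < 1.0) next
      if (min(abs(pk$ppm - v)) > max(step, 0.05))
        fail(sprintf("%s: no peak within one grid step of %.2f ppm",
                     exp_kind, v))
    }
    expect_true(TRUE)
  }
})

test_that("noise is reproducible under a fixed seed and differs across seeds", {
  s1 <- single_line_sample(45.1, 100, 100, noise_sigma = 0.05, seed = 3L)
  s2 <- single_line_sample(45.1, 100, 100, noise_sigma = 0.05, seed = 4L)
  expect_identical(simulate_1d(s1, "CP")$intensity,
                   simulate_1d(s1, "CP")$intensity)
  expect_false(identical(simulate_1d(s1, "CP")$intensity,
                         simulate_1d(s2, "CP")$intensity))
})

test_that("DARR short mixing gives exactly the one-bond Ala cross peaks", {
  s <- sample_spec(list(shift_component("A", "Ala", c(CA = 52.0, CB = 19.0),
                                        1, "rigid")),
                   homogeneous_hz = 20, inhomogeneous_hz = 50)
  sp <- simulate_2d(s, "DARR_short", ppm_range = c(0, 80), n_points = 800)
  pk <- pick_peaks_2d(sp)
  expect_equal(nrow(pk), 2)
  got <- pk[order(pk$ppm_direct), c("ppm_direct", "ppm_indirect")]
  expect_equal(got$ppm_direct, c(19.0, 52.0), tolerance = 0.02)
  expect_equal(got$ppm_indirect, c(52.0, 19.0), tolerance = 0.02)
})

test_that("TOBSY shows only the mobile Ala coil component", {
  fx <- build_paper_fixture()
  tob <- simulate_2d(fx, "TOBSY")
  pk <- pick_peaks_2d(tob)
  mobile_coil <- pk[abs(pk$ppm_direct - 53.1) < 0.3 &
                      abs(pk$ppm_indirect - 18.8) < 0.3, ]
  expect_equal(nrow(mobile_coil), 1)
  sheet <- pk[abs(pk$ppm_direct - 51.5) < 0.3 &
                abs(pk$ppm_indirect - 22.8) < 0.3, ]
  expect_equal(nrow(sheet), 0)
})

test_that("homonuclear 2D spectra are symmetric about the diagonal", {
  fx <- build_paper_fixture()
  for (kind in c("DARR_short", "TOBSY")) {
    sp <- simulate_2d(fx, kind, n_points = 256)
    expect_lt(max(abs(sp$intensity - t(sp$intensity))),
              1e-9 * max(sp$intensity))
  }
})

test_that("long-mixing DARR adds Pro-Gly sequential contacts at every PG junction", {
  con <- build_construct(2, "none")
  s <- sample_spec(list(
    shift_component("P", "Pro", c(CA = 62.9), 1, "rigid"),
    shift_component("G", "Gly", c(CA = 45.1), 1, "rigid")),
    homogeneous_hz = 20, inhomogeneous_hz = 50)
  short <- simulate_2d(s, "DARR_short", ppm_range = c(30, 80), n_points = 600)
  long <- simulate_2d(s, "DARR_long", construct = con,
                      ppm_range = c(30, 80), n_points = 600)
  pk_s <- pick_peaks_2d(short)
  pk_l <- pick_peaks_2d(long)
  # single-atom components give no one-bond peaks at short mixing
  expect_equal(nrow(pk_s), 0)
  # sequential Pro(CA)-Gly(CA) contacts appear with long mixing
  pg <- pk_l[abs(pk_l$ppm_direct - 62.9) < 0.3 &
               abs(pk_l$ppm_indirect - 45.1) < 0.3, ]
  expect_equal(nrow(pg), 1)
  expect_error(simulate_2d(s, "DARR_long"), "construct")
})

test_that("NCACX restricts to the filtered residue and uses the nitrogen axis", {
  fx <- build_paper_fixture()
  sp <- simulate_2d(fx, "NCACX", residue_filter = "P")
  expect_equal(sp$nucleus_indirect, "15N")
  pk <- pick_peaks_2d(sp)
  # peaks only at the two Pro nitrogen rows
  expect_true(all(abs(pk$ppm_indirect - 137.0) < 0.5 |
                    abs(pk$ppm_indirect - 135.5) < 0.5))
  expect_gt(nrow(pk), 0)
})

test_that("decay simulation matches the closed form and is deterministic", {
  d <- simulate_decay("T1rho_H", 1, delays_s = 0)
  # a single zero delay is an edge the generator must still honour
  expect_equal(d$intensity, 1.0)
  T <- 3.6e-3
  delays <- log_delays(200e-6, 40e-3, 16)
  d <- simulate_decay("T1rho_H", T, delays)
  expect_equal(d$intensity[16], exp(-40e-3 / T), tolerance = 1e-12)
  n1 <- simulate_decay("T1rho_C", T, delays, noise_sigma = 0.02, seed = 9L)
  n2 <- simulate_decay("T1rho_C", T, delays, noise_sigma = 0.02, seed = 9L)
  expect_identical(n1$intensity, n2$intensity)
  expect_error(simulate_decay("T1rho_H", -1, delays), "> 0")
  expect_error(simulate_decay("T1rho_H", 1, c(0.2, 0.1)), "increasing")
})

test_that("the reference fixture carries the assigned shifts and populations", {
  fx <- build_paper_fixture()
  by_label <- setNames(fx$components,
                       vapply(fx$components, `[[`, "", "label"))
  expect_equal(by_label$Ala_sheet_rect$shifts[["CB"]], 22.8)
  expect_equal(by_label$Ala_sheet_stag$shifts[["CB"]], 25.9)
  expect_equal(by_label$Glu_sidechain$shifts[["CD"]], 183.6)
  expect_equal(by_label$Pro_trans$population /
                 by_label$Pro_cis$population, 3)
  # populations of every pool sum to one
  res <- vapply(fx$components, `[[`, "", "residue")
  pop <- vapply(fx$components, `[[`, 0, "population")
  for (r in unique(res))
    expect_equal(sum(pop[res == r]), 1, tolerance = 1e-9)
  # a malformed pool is rejected
  expect_error(sample_spec(list(
    shift_component("A", "a1", c(CA = 50), 0.5, "rigid")),
    homogeneous_hz = 10, inhomogeneous_hz = 10),
    "sum to 0.5")
})
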