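# Secondary-structure, protonation, isomer, secondary-shift-profile, and
# rigidity-partition calls.

ref <- load_reference_tables()

test_that("the assigned Ala and Ser cross peaks classify as published", {
  cases <- list(
    list("A", c(CA = 51.5, CB = 22.8), "sheet"),
    list("A", c(CA = 51.0, CB = 25.9), "sheet"),  # staggered packing
    list("A", c(CA = 53.2, CB = 19.5), "coil"),
    list("A", c(CA = 53.1, CB = 18.8), "coil"),
    list("S", c(CA = 57.5, CB = 66.2), "sheet"),
    list("S", c(CA = 58.1, CB = 64.1), "coil"),
    list("S", c(CA = 58.3, CB = 63.9), "coil")
  )
  for (cs in cases) {
    out <- classify_secondary_structure(cs[[1]], cs[[2]], ref)
    expect_equal(out$class, cs[[3]],
                 info = paste(cs[[1]], paste(cs[[2]], collapse = "/")))
    expect_equal(out$status, "assigned")
  }
})

test_that("reference means score zero and boundary cases degrade gracefully", {
  helix <- ref$shifts[ref$shifts$residue == "A" & ref$shifts$class == "helix", ]
  shifts <- setNames(helix$mean_ppm, helix$atom)
  out <- classify_secondary_structure("A", shifts, ref)
  expect_equal(out$class, "helix")
  expect_equal(unname(out$scores["helix"]), 0)

  # an exactly equidistant point (standardised) between two classes is ambiguous
  sheet <- ref$shifts[ref$shifts$residue == "G" & ref$shifts$atom == "CA", ]
  mu <- setNames(sheet$mean_ppm, sheet$class)
  sd_ <- setNames(sheet$sd_ppm, sheet$class)
  # solve for the shift with equal standardised distance to sheet and coil
  x <- (mu["sheet"] / sd_["sheet"] + mu["coil"] / sd_["coil"]) /
    (1 / sd_["sheet"] + 1 / sd_["coil"])
  out <- classify_secondary_structure("G", c(CA = unname(x)), ref)
  expect_equal(out$status, "ambiguous")

  # a shift far from every class is unassigned
  out <- classify_secondary_structure("A", c(CA = 70, CB = 60), ref,
                                      tie_tol = 0)
  expect_equal(out$status, "unassigned")

  expect_error(classify_secondary_structure("W", c(CA = 55), ref), "absent")
  expect_error(classify_secondary_structure("A", c(HB = 1.2), ref),
               "no observed atom")
})

test_that("classifier ranking matches an independent direct evaluation", {
  score_oracle <- function(residue, shifts) {
    tab <- ref$shifts[ref$shifts$residue == residue, ]
    out <- c(helix = 0, sheet = 0, coil = 0)
    for (cl in names(out)) for (a in names(shifts)) {
      row <- tab[tab$atom == a & tab$class == cl, ]
      out[cl] <- out[cl] + ((shifts[[a]] - row$mean_ppm) / row$sd_ppm)^2
    }
    out
  }
  set.seed(31)
  for (i in 1:200) {
    res <- sample(c("A", "S", "E", "Q", "N", "Y", "P"), 1)
    shifts <- c(CA = runif(1, 40, 70), CB = runif(1, 15, 70))
    got <- classify_secondary_structure(res, shifts, ref, tie_tol = 0,
                                        cutoff = Inf)
    want <- score_oracle(res, shifts)
    expect_equal(got$scores[order(names(got$scores))],
                 want[order(names(want))], tolerance = 1e-12)
    expect_equal(got$class, names(which.min(want)))
  }
})

test_that("calls are equivariant under a common shift of scale origin", {
  shifted_ref <- ref
  const <- 2.5
  shifted_ref$shifts$mean_ppm <- shifted_ref$shifts$mean_ppm + const
  for (shifts in list(c(CA = 51.5, CB = 22.8), c(CA = 53.2, CB = 19.5))) {
    a <- classify_secondary_structure("A", shifts, ref)
    b <- classify_secondary_structure("A", shifts + const, shifted_ref)
    expect_equal(a$class, b$class)
    expect_equal(a$scores, b$scores, tolerance = 1e-9)
  }
})

test_that("glutamate protonation is called by nearest reference pair", {
  out <- classify_glu_protonation(36.1, 183.8, ref)
  expect_equal(out$class, "deprotonated")
  expect_equal(unname(out$scores["deprotonated"]), 0)

  # the observed side-chain pair is deprotonated
  out <- classify_glu_protonation(36.1, 183.6, ref)
  expect_equal(out$class, "deprotonated")

  # exact midpoint is ambiguous
  out <- classify_glu_protonation((36.1 + 32.7) / 2, (183.8 + 179.7) / 2, ref)
  expect_equal(out$status, "ambiguous")

  out <- classify_glu_protonation(NA, 183.6, ref, cd_only = TRUE)
  expect_equal(out$class, "deprotonated")
  expect_error(classify_glu_protonation(NA, 183.6, ref), "cd_only")
})

test_that("proline isomer calls follow the Cbeta-Cgamma separation", {
  # canonical separations, cross-checked against the packaged table
  expect_equal(unname(ref$proline$delta_bg["trans"]), 4.5)
  expect_equal(unname(ref$proline$delta_bg["cis"]), 9.6)
  out <- classify_pro_isomer(32.0, 27.5, ref)  # separation 4.5
  expect_equal(out$class, "trans")
  out <- classify_pro_isomer(34.2, 24.6, ref)  # separation 9.6
  expect_equal(out$class, "cis")
  out <- classify_pro_isomer(30.0, 23.0, ref)  # exactly at the threshold
  expect_equal(out$status, "ambiguous")
})

test_that("trans:cis ratios propagate uncertainty and flag a zero divisor", {
  expect_equal(cis_trans_ratio(3, 1)$ratio, 3)
  expect_equal(cis_trans_ratio(1, 1)$ratio, 1)
  r <- cis_trans_ratio(3, 1, trans_sigma = 0.3, cis_sigma = 0.1)
  expect_equal(r$sigma, 3 * sqrt(0.01 + 0.01), tolerance = 1e-9)
  z <- cis_trans_ratio(1, 0)
  expect_true(z$infinite)
  expect_equal(z$ratio, Inf)
  expect_error(cis_trans_ratio(-1, 1), "non-negative")
})

test_that("fixture slice integration recovers the 3:1 trans:cis populations", {
  fx <- build_paper_fixture()
  darr <- simulate_2d(fx, "DARR_short")
  integ <- function(cg, cb) {
    sl <- slice_2d(darr, at = cg, bandwidth = 0.6)
    integrate_region(sl, cb + c(-1.2, 1.2))
  }
  r <- cis_trans_ratio(integ(27.5, 32.0), integ(24.6, 34.2))
  expect_equal(r$ratio, 3, tolerance = 0.05)
})

test_that("secondary shift profiles require three consecutive same-sign residues", {
  con <- build_construct(1, "none")
  # residues 2..5 of the repeat (SSAA...) start at global position 3
  mk_obs <- function(positions, residues, deltas) {
    do.call(rbind, lapply(seq_along(positions), function(i) {
      rc <- random_coil_shift(ref, residues[i], "CA",
                              context = "none")
      data.frame(position = positions[i], residue = residues[i],
                 atom = "CA", shift_ppm = rc + deltas[i])
    }))
  }
  # all deltas zero: no element
  obs <- mk_obs(6:9, c("A", "A", "A", "A"), rep(0, 4))
  prof <- secondary_shift_profile(obs, con, ref)
  expect_true(all(prof$element == "none"))

  # four consecutive negative combined values: one strand segment of length 4
  obs <- mk_obs(6:9, c("A", "A", "A", "A"), rep(-1, 4))
  prof <- secondary_shift_profile(obs, con, ref)
  expect_true(all(prof$element == "strand"))

  # alternating signs never call an element
  obs <- mk_obs(6:8, c("A", "A", "A"), c(1, -1, 1))
  prof <- secondary_shift_profile(obs, con, ref)
  expect_true(all(prof$element == "none"))

  # positive runs call helix; runs shorter than three do not
  obs <- mk_obs(6:7, c("A", "A"), c(1, 1))
  expect_true(all(secondary_shift_profile(obs, con, ref)$element == "none"))
  obs <- mk_obs(6:8, c("A", "A", "A"), c(1, 1, 1))
  expect_true(all(secondary_shift_profile(obs, con, ref)$element == "helix"))
})

test_that("the Gly Calpha preceding-Pro correction shifts the coil baseline", {
  con <- build_construct(1, "none")
  # within-repeat Gly15 follows Pro14; global position = 2 (tag) + 15
  pos <- 17
  expect_equal(substr(con$full_sequence, pos - 1, pos), "PG")
  obs <- data.frame(position = pos, residue = "G", atom = "CA",
                    shift_ppm = 44.4)
  prof <- secondary_shift_profile(obs, con, ref)
  expect_equal(prof$delta_ca, 44.4 - (45.36 - 0.77), tolerance = 1e-9)
})

test_that("rigidity is partitioned by CP/INEPT presence", {
  pred <- data.frame(label = c("Tyr_CZ", "Ala_mobile", "ghost"),
                     ppm = c(157.7, 53.1, 99.0))
  cp_peaks <- data.frame(ppm = c(157.7, 118.1), height = c(1, 1))
  inept_peaks <- data.frame(ppm = c(53.1, 44.4), height = c(1, 1))
  part <- rigidity_partition(cp_peaks, inept_peaks, pred, tolerance = 0.3)
  expect_equal(part$call, c("rigid", "mobile", "unobserved"))
  # both lists empty: everything unobserved
  empty <- data.frame(ppm = numeric(0), height = numeric(0))
  part0 <- rigidity_partition(empty, empty, pred)
  expect_true(all(part0$call == "unobserved"))
})
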