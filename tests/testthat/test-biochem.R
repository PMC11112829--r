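test_that("volumetric activity converts slopes with the unit definition", {
  cfg <- assay_config("dcip520")
  expect_equal(volumetric_activity(cfg = cfg, slope = 0)$activity, 0)
  # slope 0.069 AU/min over 6.9 mM-1 cm-1 is 0.01 mM/min = 0.01 U/mL
  expect_equal(volumetric_activity(cfg = cfg, slope = 0.069)$activity, 0.01)
  # linear in slope and dilution
  a1 <- volumetric_activity(cfg = cfg, slope = 0.1)$activity
  expect_equal(volumetric_activity(cfg = cfg, slope = 0.2)$activity, 2 * a1)
  expect_equal(volumetric_activity(cfg = cfg, slope = 0.1,
                                   dilution = 5)$activity, 5 * a1)
  # negative slope clips to zero with a warning
  expect_warning(z <- volumetric_activity(cfg = cfg, slope = -0.01), "clipped")
  expect_equal(z$activity, 0)

  # noisy simulated trace recovers the truth within 2%
  sim <- simulate_assay(0.05, cfg, noise_sd = 0.002, n_points = 19,
                        seed = 5)
  got <- volumetric_activity(sim$trace, cfg)
  expect_equal(got$activity, 0.05, tolerance = 0.02)
  # noiseless inversion is exact
  sim0 <- simulate_assay(0.05, cfg, noise_sd = 0, seed = 5)
  expect_equal(volumetric_activity(sim0$trace, cfg)$activity, 0.05,
               tolerance = 1e-12)
  expect_error(simulate_assay(-1, cfg), "non-negative")
})

test_that("limit of quantification is ten blank standard deviations", {
  expect_equal(limit_of_quantification(c(2, 2, 2)), 0)
  expect_equal(limit_of_quantification(c(1, 2, 3)), 10)
  expect_error(limit_of_quantification(c(1, 2)), "at least 3")
  set.seed(17)
  blanks <- rnorm(50, 0, 0.004)
  expect_equal(limit_of_quantification(blanks), 10 * 0.004, tolerance = 0.3)
})

test_that("purification table derives the standard columns", {
  steps <- tibble::tibble(
    step = c("Supernatant", "Capture", "Polish"),
    volume = c(1000, 100, 10),
    conc = c(0.5, 1.0, 2.0),
    total_activity_dcip = c(500, 300, 150),
    a420 = c(NA, 0.2, 0.5), a280 = c(NA, 1.0, 1.0))
  tab <- purification_table(steps)
  expect_equal(tab$total_protein, c(500, 100, 20))
  expect_equal(tab$specific_activity, c(1, 3, 7.5))
  expect_equal(tab$yield_pct, c(100, 60, 30))
  expect_equal(tab$purification_factor, c(1, 3, 7.5))
  expect_equal(tab$rz[2:3], c(0.2, 0.5))

  # scale invariance of yields and factors
  steps2 <- dplyr::mutate(steps, total_activity_dcip = total_activity_dcip * 7)
  tab2 <- purification_table(steps2)
  expect_equal(tab2$yield_pct, tab$yield_pct)
  expect_equal(tab2$purification_factor, tab$purification_factor)

  # b.d.l. propagates as a distinct state, never as zero
  steps$total_activity_cytc <- c("40", "b.d.l.", "b.d.l.")
  tab3 <- purification_table(steps)
  cytc <- tab3[tab3$assay == "cytc", ]
  expect_equal(cytc$bdl, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(cytc$specific_activity[2:3])))
  expect_true(all(is.na(cytc$yield_pct[2:3])))

  bad <- dplyr::mutate(steps, total_activity_dcip = c(0, 1, 1))
  expect_error(purification_table(bad), "reference")
})

test_that("purification invariants hold across 100 simulated scenarios", {
  for (k in 1:100) {
    set.seed(k)
    n <- sample(1:3, 1)
    rec <- runif(n, 0.3, 0.95)
    pur <- sort(runif(n, 1, 8))
    sim <- simulate_purification(rec, pur,
                                 reference_totals = c(dcip = runif(1, 100, 1000)),
                                 total_protein_ref = runif(1, 500, 2000),
                                 seed = k)
    tab <- purification_table(sim$steps)
    expect_equal(tab$yield_pct[1], 100)
    expect_equal(tab$purification_factor[1], 1)
    expect_equal(tab$yield_pct, sim$truth$yield_pct, tolerance = 1e-9)
    expect_equal(tab$purification_factor, sim$truth$purification_factor,
                 tolerance = 1e-9)
    expect_equal(tab$specific_activity, sim$truth$specific_activity,
                 tolerance = 1e-9)
  }
})

test_that("bdl assays in a two-step scenario mirror the DH purification shape", {
  sim <- simulate_purification(c(0.9, 0.45), c(1.1, 3.0),
                               reference_totals = c(dcip = 946, cytc = 47),
                               total_protein_ref = 1310,
                               bdl_assays = "cytc", seed = 1)
  tab <- purification_table(sim$steps)
  cytc <- tab[tab$assay == "cytc", ]
  expect_equal(cytc$bdl, c(FALSE, TRUE, TRUE))
  dcip <- tab[tab$assay == "dcip", ]
  expect_false(any(dcip$bdl))
  expect_equal(dcip$purification_factor, c(1, 1.1, 3.0), tolerance = 1e-9)
})

test_that("epsilon280 matches residue counting", {
  expect_equal(epsilon280_from_sequence("AAAA"), 0)
  expect_equal(epsilon280_from_sequence("WY"), 6990)
  expect_equal(epsilon280_from_sequence("CCC"), 125)       # one cystine
  expect_equal(epsilon280_from_sequence("CCC", "reduced"), 0)
  expect_error(epsilon280_from_sequence(""), "empty")
  for (k in 1:5) {
    s <- random_aa(300, seed = 40 + k)
    ch <- strsplit(s, "")[[1]]
    want <- 5500 * sum(ch == "W") + 1490 * sum(ch == "Y") +
      125 * (sum(ch == "C") %/% 2)
    expect_equal(epsilon280_from_sequence(s), want)
  }
})

test_that("protein concentration follows Beer-Lambert", {
  expect_equal(protein_conc(100185e-6, 100185)$molar, 1e-6)
  expect_equal(protein_conc(1.0, 100185)$molar, 9.98e-6, tolerance = 1e-3)
  expect_equal(protein_conc(0.5, 50000, molar_mass = 100000)$mass_g_per_l, 1)
})

test_that("FAD occupancy inverts its forward model", {
  eps_p <- 100185
  # full loading: FAD molar equals protein molar
  p <- 1.5 / eps_p
  out <- fad_occupancy(a450 = p * 11300, a280 = 1.5, eps_prot280 = eps_p)
  expect_equal(out$occupancy, 1.0, tolerance = 1e-9)
  # apo-protein
  expect_equal(fad_occupancy(0, 1.5, eps_p)$occupancy, 0)
  # forward model with flavin 280-nm contribution, occupancy 9%
  occ <- 0.09; eps_f280 <- 21000
  fad <- occ * p
  a280 <- p * eps_p + fad * eps_f280
  inv <- fad_occupancy(fad * 11300, a280, eps_prot280 = eps_p,
                       eps_fad280 = eps_f280)
  expect_equal(inv$occupancy, occ, tolerance = 1e-6)
  expect_warning(fad_occupancy(p * 11300 * 1.04, 1.5, eps_p), "clipped")
  expect_error(fad_occupancy(1, 0.01, eps_prot280 = 1e5,
                             eps_fad280 = 1e6), "exceeds")
})

test_that("normalization to full FAD loading matches the published table", {
  # identity at full occupancy, monotone decreasing in occupancy
  expect_equal(normalize_to_full_fad(5, 1)$specific_activity_full_fad, 5)
  v <- vapply(c(0.2, 0.5, 0.9), function(o) {
    normalize_to_full_fad(5, o)$specific_activity_full_fad
  }, numeric(1))
  expect_true(all(diff(v) < 0))
  expect_error(normalize_to_full_fad(5, 0), "positive")
  # uncertainty propagation in quadrature
  u <- normalize_to_full_fad(10, 0.5, activity_sd = 1, occupancy_sd = 0.05)
  expect_equal(u$sd, 20 * sqrt(0.1^2 + 0.1^2))
})

test_that("spectral features detect the Soret band, its shift and RZ", {
  ox <- simulate_spectrum(state = "oxidized", heme = 1, occupancy = 0.09,
                          seed = 2)$spectrum
  red <- simulate_spectrum(state = "reduced", heme = 1, occupancy = 0.09,
                           seed = 2)$spectrum
  sf <- spectral_features(ox, red)
  expect_false(any(sf$soret$no_soret))
  expect_equal(sf$shift_nm, 9, tolerance = 1)  # centers 420 -> 429
  # RZ is the ratio definition
  a420 <- ox$absorbance[ox$wavelength == 420]
  a280 <- ox$absorbance[ox$wavelength == 280]
  expect_equal(sf$rz, a420 / a280, tolerance = 1e-9)
  # difference spectrum positive at the alpha band in the reduced state
  alpha <- sf$difference$absorbance[sf$difference$wavelength == 562]
  expect_gt(alpha, 0)

  # heme-free DH domain: no Soret band
  dh <- simulate_spectrum(heme = 0, occupancy = 0.13, seed = 3)$spectrum
  expect_true(spectral_features(dh)$soret$no_soret)
  # flat spectrum: no Soret band
  flat <- tibble::tibble(wavelength = 250:700, absorbance = 0.2)
  expect_true(spectral_features(flat)$soret$no_soret)

  # RZ increases monotonically with heme content
  rz <- vapply(c(0.2, 0.5, 1), function(h) {
    spectral_features(simulate_spectrum(heme = h, seed = 4)$spectrum)$rz
  }, numeric(1))
  expect_true(all(diff(rz) > 0))
})
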