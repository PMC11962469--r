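test_that("opening angles reproduce the reported values for all species", {
  tab <- morphometry_table()
  ok <- !is.na(tab$theta_a_derived)
  expect_equal(sum(ok), 13)
  expect_equal(round(tab$theta_a_derived[ok], 1),
               round(tab$theta_a_reported[ok], 1),
               tolerance = 0.1)
  # direct worked examples: diameter-based and area-based
  expect_equal(opening_angle(30, 14), 27.8, tolerance = 0.05)
  expect_equal(opening_angle(21.1, 0.90), 2.44, tolerance = 0.005)
  expect_equal(opening_angle(17.46, area = 124.11), 46.1, tolerance = 0.05)
  expect_equal(opening_angle(19.35, area = 168.54), 49.2, tolerance = 0.05)
  expect_error(opening_angle(10, 12), "exceeds")
})

test_that("opening angle inverts exactly", {
  th <- c(2.44, 17.6, 32.2, 49.2, 89)
  D <- 30
  expect_equal(opening_angle(D, D * sin(th * pi / 180)), th,
               tolerance = 1e-10)
})

test_that("coverage fraction and flagellar density reproduce worked values", {
  expect_equal(round(coverage_fraction(112, 1.58, 17.35, 32.2), 2), 0.25)
  expect_equal(round(coverage_fraction(143, 0.14, 1.5, 30), 2), 0.33)
  expect_equal(flagellar_density(112, 17.35, 32.2), 0.032, tolerance = 0.01)
  expect_equal(flagellar_density(50, 10, 90), 50 / (2 * pi * 100))
  # density x available area recovers N exactly
  dens <- flagellar_density(137, 12, 41)
  expect_equal(dens * 2 * pi * 12^2 * (1 + cos(41 * pi / 180)), 137)
  expect_equal(hex_packing_fraction, 0.907, tolerance = 5e-4)
})

test_that("wavenumber from waveform matches the measured values", {
  w <- wavenumber_from_waveform(9.83, 5.98, 0.74, 0.48)
  expect_equal(w$kl_over_pi, 3.29, tolerance = 0.005)
  expect_lt(abs(w$kl_over_pi - 3.30), 0.27)
  expect_equal(wavenumber_from_waveform(10.4, 5)$kl_over_pi, 4.16)
  expect_equal(wavenumber_from_waveform(7, 14)$kl_over_pi, 1)
  # propagated SD shrinks with the input SDs and vanishes in the noiseless limit
  s1 <- wavenumber_from_waveform(9.83, 5.98, 0.74, 0.48)$sd_over_pi
  s2 <- wavenumber_from_waveform(9.83, 5.98, 0.37, 0.24)$sd_over_pi
  s0 <- wavenumber_from_waveform(9.83, 5.98, 0, 0)$sd_over_pi
  expect_gt(s1, s2)
  expect_equal(s0, 0)
})

test_that("minimum chamber diameter behaves geometrically", {
  # non-contacting flagella at the measured parameters
  D <- min_chamber_diameter(112, 1.58, 9.83, 32.2)
  expect_equal(D, 36.4, tolerance = 0.10)
  # layout-based criterion packs less tightly, so needs a larger chamber
  Dl <- min_chamber_diameter(112, 1.58, 9.83, 32.2, method = "layout")
  expect_gt(Dl, D)
  # vanishing amplitude lets tips meet at the center
  expect_equal(min_chamber_diameter(112, 1e-9, 9.83, 32.2), 2 * 9.83,
               tolerance = 1e-6)
  # non-decreasing in N for both criteria
  for (meth in c("hex", "layout")) {
    Ds <- vapply(seq(50, 150, by = 10), function(n)
      min_chamber_diameter(n, 1.58, 9.83, 32.2, method = meth), numeric(1))
    expect_true(all(diff(Ds) > -1e-9))
  }
})

test_that("dimensional conversion reproduces the printed physical values", {
  d <- dimensionalize(Q = 0.071, P = 1, L_um = 13, nu_Hz = 26.1)
  expect_equal(d$Q_um3_per_s, 4.07e3, tolerance = 0.01)
  expect_equal(d$P_Pa, 0.026, tolerance = 0.01)
  id <- dimensionalize(Q = 0.3, P = 0.7, L_um = 1, nu_Hz = 1, mu_Pa_s = 1)
  expect_equal(id$Q_um3_per_s, 0.3)
  expect_equal(id$P_Pa, 0.7)
})

test_that("efficiency bands flag species near the simulated optimum", {
  th <- seq(10, 90, by = 10)
  sim <- do.call(rbind, lapply(c(0.02, 0.04), function(dd)
    data.frame(density = dd, theta_a = th,
               eta = exp(-((th - 35) / 25)^2))))
  species <- data.frame(species = c("at_peak", "far_off"),
                        theta_a = c(35, 88), density = c(0.03, 0.03))
  out <- efficiency_band(species, sim)
  expect_true(out$near_optimal[1])
  expect_false(out$near_optimal[2])
  expect_lt(out$band_lo[1], 35)
  expect_gt(out$band_hi[1], 35)
  expect_error(efficiency_band(species, sim[sim$density == 0.02, ]),
               ">= 2 densities")
})

test_that("morphometry CSV round-trips through the schema", {
  tab <- morphometry_table()
  f <- tempfile(fileext = ".csv")
  write_morphometry(tab, f)
  back <- read.csv(f)
  expect_equal(back$chamber_diameter_um, tab$chamber_diameter_um)
  expect_equal(nrow(back), 13)
})
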