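test_that("temperature-pressure correction matches the ideal-gas ratio", {
  expect_equal(ptp_correction(20.0, 101.325), 1.0)
  expect_equal(ptp_correction(25.0, 101.325), 298.15 / 293.15)
  expect_equal(ptp_correction(20.0, 100.0), 1.01325)
  # configurable reference conditions
  expect_equal(ptp_correction(22.0, 101.325, ref_temperature_c = 22.0), 1.0)

  # increasing in T, decreasing in P
  expect_true(all(diff(sapply(18:26, ptp_correction, pressure_kpa = 101)) > 0))
  expect_true(all(diff(sapply(seq(98, 104, 1), function(p)
    ptp_correction(20, p))) < 0))

  expect_error(ptp_correction(-300, 101), "absolute zero")
  expect_error(ptp_correction(20, -1), "positive")
})

test_that("polarity correction averages the two polarities", {
  expect_equal(polarity_correction(1, 1, 1), 1.0)
  expect_equal(polarity_correction(1.01, 0.99, 1.01), 2.00 / (2 * 1.01))
  expect_equal(polarity_correction(0.99, 1.01, 0.99), 2.00 / (2 * 0.99))
  expect_error(polarity_correction(1.01, 0.99, 1.0), "one of the two")
  expect_error(polarity_correction(0, 1, 0), "nonzero")

  # whichever reading is 'used', the corrected magnitude is the same average
  set.seed(11)
  for (i in 1:25) {
    mp <- runif(1, 0.9, 1.1)
    mm <- runif(1, 0.9, 1.1)
    expect_equal(polarity_correction(mp, mm, mp) * mp,
                 polarity_correction(mp, mm, mm) * mm)
  }
})

test_that("two-voltage recombination follows the pulsed-beam formula", {
  expect_equal(recombination_correction(1, 1, 2), 1.0)
  expect_equal(recombination_correction(1.004, 1.000, 2), (1 - 2) / (1.004 - 2))
  expect_error(recombination_correction(2, 1, 2), "singular")
  expect_warning(recombination_correction(0.99, 1.0, 2), "sub-unity")

  # P_ion > 1 whenever 1 < M_h/M_l < voltage ratio
  set.seed(12)
  for (i in 1:25) {
    v <- runif(1, 1.5, 3)
    x <- runif(1, 1 + 1e-4, v - 1e-4)
    expect_gt(recombination_correction(x, 1, v), 1)
  }

  # quadratic hook replaces the linear formula
  expect_equal(recombination_correction(1.01, 1, 2,
                                        quadratic_coefficients = c(0.5, 0.3, 0.2)),
               0.5 + 0.3 * 1.01 + 0.2 * 1.01^2)
})

test_that("corrected reading multiplies the full factor stack", {
  # identity case: every factor exactly 1
  rs <- reading_set(10, 20.0, 101.325, m_opposite_polarity_nc = 10,
                    m_reduced_voltage_nc = 10, voltage_ratio = 2)
  cf <- corrected_reading(rs)
  expect_identical(cf$p_leak, 1)
  expect_identical(cf$p_rp, 1)
  expect_equal(cf$m_corrected_nc, 10)

  # linearity in the raw reading
  rs2 <- reading_set(20, 20.0, 101.325, m_opposite_polarity_nc = 20,
                     m_reduced_voltage_nc = 20, voltage_ratio = 2)
  expect_equal(corrected_reading(rs2)$m_corrected_nc, 2 * cf$m_corrected_nc)

  # full set reproduces the product of individually computed factors
  rs3 <- reading_set(9.85, 23.1, 99.8, m_opposite_polarity_nc = 9.92,
                     m_reduced_voltage_nc = 9.80, voltage_ratio = 2.5,
                     p_elec = 1.002)
  cf3 <- corrected_reading(rs3)
  manual <- 9.85 *
    ptp_correction(23.1, 99.8) *
    recombination_correction(9.85, 9.80, 2.5) *
    polarity_correction(9.85, 9.92, 9.85) *
    1.002
  expect_equal(cf3$m_corrected_nc, manual, tolerance = 1e-12)
  expect_equal(cf3$m_corrected_nc,
               cf3$m_raw_nc * cf3$p_tp * cf3$p_ion * cf3$p_pol * cf3$p_elec *
                 cf3$p_leak * cf3$p_rp,
               tolerance = 1e-12)

  # absent optional data contribute a factor 1, with a notice
  rs4 <- reading_set(10, 22, 100.5)
  expect_message(cf4 <- corrected_reading(rs4), "P_pol = 1")
  expect_identical(cf4$p_pol, 1)
  expect_identical(cf4$p_ion, 1)

  # leakage / radial-profile overrides are honoured
  pol <- correction_policy(p_leak = 0.999, p_rp = 1.001)
  cf5 <- suppressMessages(corrected_reading(rs4, pol))
  expect_equal(cf5$m_corrected_nc / cf4$m_corrected_nc, 0.999 * 1.001)
})

test_that("reading_set validates its invariants", {
  expect_error(reading_set(0, 20, 101), "nonzero")
  expect_error(reading_set(1, 20, -5), "positive")
  expect_error(reading_set(1, -280, 101), "absolute zero")
  expect_error(reading_set(1, 20, 101, m_reduced_voltage_nc = 0.99),
               "given together")
  expect_error(reading_set(1, 20, 101, m_reduced_voltage_nc = 0.99,
                           voltage_ratio = 1), "> 1")
  expect_error(reading_set(1, 20, 101, monitor_units = 0), "positive")
})
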