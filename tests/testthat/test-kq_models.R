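test_that("fitted kQ' forms evaluate their closed-form expressions", {
  # power law: spot values that round to the published 3-decimal factors
  expect_equal(round(kq_prime_power(0.978, 0.112, 0.816, 2.37), 3), 1.033)
  expect_equal(round(kq_prime_power(0.926, 0.129, 0.279, 5.76), 3), 1.005)
  expect_equal(kq_prime_power(0.9, 0, 0.5, 3.3), 0.9)
  expect_error(kq_prime_power(1, 1, 1, 0), "positive")

  # exponential: closed form at r50 = c gives a + b/e
  expect_equal(round(kq_prime_exponential(0.992, 0.114, 2.864, 2.37), 3), 1.042)
  expect_equal(kq_prime_exponential(0.992, 0.114, 2.864, 2.864),
               0.992 + 0.114 / exp(1))
  expect_equal(kq_prime_exponential(0.9, 0, 2, 3.3), 0.9)
  expect_error(kq_prime_exponential(1, 1, -1, 2), "positive")
})

test_that("kq_prime dispatches on the chamber fit model and carries RMSD", {
  reg <- builtin_registry()
  a1sl <- kq_prime(reg[["Exradin A1Sl"]], 3.84)
  expect_equal(round(a1sl$value, 3), 1.019)
  expect_equal(a1sl$method, "fit_power")
  expect_equal(a1sl$rmsd_pct, 0.13)

  a11 <- kq_prime(reg[["Exradin A11"]], 5.955)
  expect_equal(round(a11$value, 3), 1.006)
  expect_equal(a11$method, "fit_exponential")

  # dispatch equals the direct call of the matching fit form
  ptw <- reg[["PTW 30013"]]
  expect_equal(kq_prime(ptw, 4.1)$value,
               kq_prime_power(ptw$fit_a, ptw$fit_b, ptw$fit_c, 4.1))
  expect_equal(kq_prime(reg[["Exradin A11"]], 4.1)$value,
               kq_prime_exponential(0.992, 0.114, 2.864, 4.1))
})

test_that("kQ' is strictly decreasing in R50 and decays toward 'a'", {
  reg <- builtin_registry()
  r <- seq(1.5, 9, by = 0.25)
  for (nm in names(reg)) {
    ch <- reg[[nm]]
    v <- vapply(r, function(x) kq_prime(ch, x)$value, numeric(1))
    expect_true(all(diff(v) < 0), label = paste("monotone decrease for", nm))
    # b > 0 in both forms: the factor stays above 'a' and the gap shrinks
    # (the exponential form underflows to exactly 'a' at large R50)
    gaps <- vapply(c(10, 1e3, 1e6), function(x) kq_prime(ch, x)$value,
                   numeric(1)) - ch$fit_a
    expect_gt(gaps[1], 0)
    expect_true(all(gaps >= 0), label = paste("kQ' >= a for", nm))
    expect_true(all(diff(gaps) <= 0), label = paste("gap shrinks for", nm))
  }
  # the exponential form reaches its asymptote at any large R50
  a11 <- reg[["Exradin A11"]]
  expect_equal(kq_prime(a11, 1e6)$value, a11$fit_a, tolerance = 1e-12)
})

test_that("table interpolation is linear in R50, exact at grid points, and bounded", {
  tab <- toy_kq_table()
  expect_equal(kq_trs398(tab, "toy", 4.5)$value, 0.9095)
  expect_equal(kq_trs398(tab, "toy", 4.0)$value, 0.911)
  expect_equal(kq_trs398(tab, "toy", 5.0)$value, 0.908)
  expect_equal(kq_trs398(tab, "TOY", 4.5)$value, 0.9095) # case-insensitive
  expect_equal(kq_trs398(tab, "toy", 4.5)$method, "table_interpolation")

  # outside the tabulated range the factor is not determinable
  expect_error(kq_trs398(tab, "toy", 2.37), "not determinable")
  expect_error(kq_trs398(tab, "toy", 5.5), "not determinable")
  expect_error(kq_trs398(tab, "unknown", 4.5), "not present")

  # surrogate aliasing maps an untabulated chamber onto its table key
  expect_equal(kq_trs398(tab, "Exradin A1Sl", 4.2,
                         aliases = c("Exradin A1Sl" = "toy"))$value,
               kq_trs398(tab, "toy", 4.2)$value)

  # dense-grid cross-check against an independent piecewise-linear oracle
  ex <- example_kq_table()
  for (ch in unique(ex$entries$chamber)) {
    rows <- ex$entries[ex$entries$chamber == ch, ]
    grid <- seq(min(rows$r50_cm), max(rows$r50_cm), length.out = 101)
    oracle <- stats::approx(rows$r50_cm, rows$kq_qo, xout = grid)$y
    mine <- vapply(grid, function(r) kq_trs398(ex, ch, r)$value, numeric(1))
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("kq tables validate their grid and round-trip through CSV", {
  expect_error(kq_table(data.frame(chamber = "c", r50_cm = c(4, 4),
                                   kq_qo = c(0.91, 0.9))),
               "non-monotone or duplicate")
  expect_error(kq_table(data.frame(chamber = "c", r50_cm = c(4, 5),
                                   kq_qo = c(0.5, 0.9))),
               "0.8")

  path <- withr::local_tempfile(fileext = ".csv")
  tab <- toy_kq_table()
  save_kq_table(tab, path)
  back <- load_kq_table(path, provenance = tab$provenance)
  expect_equal(back, tab)

  # two-row file -> one chamber, two points
  expect_equal(nrow(back$entries), 2L)
  expect_length(unique(back$entries$chamber), 1L)
})
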