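test_that("setup depth follows each protocol's positioning rule", {
  cyl <- demo_cylindrical() # rcyl = 0.6 cm
  pp <- demo_parallel_plate() # EPOM shift 0.177 cm

  expect_equal(setup_depth("trs398", cyl, 2.0), 2.3) # zref + 0.5*rcyl
  expect_equal(setup_depth("modified", cyl, 2.0), 2.0) # axis at zref
  expect_equal(setup_depth("trs398", pp, 2.0), 2.0) # front plane at zref
  expect_equal(setup_depth("modified", pp, 2.0), 1.823) # EPOM at zref

  expect_error(setup_depth("trs398", cyl, 0), "positive")
})

test_that("standard-protocol dose is M * N_D,w * kQ,Qo with a table factor", {
  one <- chamber_spec("unit", "none", "cylindrical", nd_w_gy_per_nc = 1,
                      fit_model = "power", fit_a = 1, fit_b = 0, fit_c = 1,
                      cavity_radius_cm = 0.3)
  tab <- toy_kq_table()
  kq1 <- kq_trs398(kq_table(data.frame(chamber = "u", r50_cm = c(1, 9),
                                       kq_qo = c(1.05, 1.05))), "u", 5)
  expect_equal(dose_trs398(1, one, kq1), 1.05)

  ptw <- builtin_registry()[["PTW 30013"]]
  kq <- kq_trs398(tab, "toy", 4.0) # 0.911
  expect_equal(dose_trs398(20.0, ptw, kq), 20.0 * 0.05389 * 0.911)
  expect_equal(dose_trs398(40.0, ptw, kq), 2 * dose_trs398(20.0, ptw, kq))

  # fitted kQ' is the wrong protocol here
  expect_error(dose_trs398(20, ptw, kq_prime(ptw, 4.0)), "protocol mismatch")
})

test_that("modified-calibration dose is M * kQ' * kQ,ecal * N_D,w and refuses unset kQ,ecal", {
  reg <- demo_registry(kq_ecal = 0.9)
  ptw <- reg[["PTW 30013"]]
  kqp <- kq_prime(ptw, 2.37)
  expect_equal(dose_modified(10, ptw, kqp),
               10 * kqp$value * 0.9 * 0.05389)

  # kq_ecal must be supplied explicitly, never assumed 1.0
  bare <- builtin_registry()[["PTW 30013"]]
  expect_error(dose_modified(10, bare, kqp), "kq_ecal")

  # table kQ,Qo is the wrong protocol here
  expect_error(dose_modified(10, ptw, kq_trs398(toy_kq_table(), "toy", 4.5)),
               "protocol mismatch")

  # algebraic identity of the two dose equations at equal corrected reading
  tab <- example_kq_table()
  kq_qo <- kq_trs398(tab, "PTW 30013", 4.68)
  m <- 19.7
  expect_equal(dose_modified(m, ptw, kq_prime(ptw, 4.68)) /
                 dose_trs398(m, ptw, kq_qo),
               kq_prime(ptw, 4.68)$value * 0.9 / kq_qo$value)
})

test_that("dose per MU converts zref dose to zmax and normalizes by MU", {
  expect_equal(dose_per_mu(1, 100, 100), 1.0)
  expect_equal(dose_per_mu(0.98684, 98.684, 100), 1.0)
  expect_equal(dose_per_mu(1, 50, 100), 2.0)
  expect_equal(dose_per_mu(2, 80, 100), 2 * dose_per_mu(1, 80, 100))
  expect_error(dose_per_mu(1, 0, 100), "0, 100")
  expect_error(dose_per_mu(1, 100, 0), "positive")

  # dose at zmax >= dose at zref whenever PDD(zref) <= 100
  set.seed(3)
  for (i in 1:20) {
    dz <- runif(1, 0.5, 2)
    pdd <- runif(1, 60, 100)
    expect_gte(dose_per_mu(dz, pdd, 100), 100 * dz / 100)
  }
})

test_that("protocol comparison reports the Dw ratio, discrepancy and tolerance verdict", {
  reg <- demo_registry()
  tab <- example_kq_table()
  beam <- make_beam(4.68, 99.672)
  rs <- reading_set(19.5, 22, 100.2, m_opposite_polarity_nc = 19.55,
                    m_reduced_voltage_nc = 19.42, voltage_ratio = 2)
  mod <- calibrate_record(rs, reg[["PTW 30013"]], beam, "modified")
  ref <- calibrate_record(rs, reg[["PTW 30013"]], beam, "trs398",
                          kq_table = tab)

  cmp <- compare_protocols(mod, ref)
  # identical corrected readings: ratio is exactly kQ' * kQ,ecal / kQ,Qo
  kq_qo <- kq_trs398(tab, "PTW 30013", 4.68)$value
  kqp <- kq_prime(reg[["PTW 30013"]], 4.68)$value
  expect_equal(cmp$dose_ratio, kqp * 0.9 / kq_qo)
  expect_equal(cmp$discrepancy_pct, (cmp$dose_ratio - 1) * 100)

  # identical doses compare to exactly 1 / 0 / within
  same <- compare_protocols(mod, ref)
  same$dose_ratio
  id <- compare_protocols(
    modified = mod,
    reference = local({ r <- ref; r$dose_per_mu_cgy <- mod$dose_per_mu_cgy; r }))
  expect_equal(id$dose_ratio, 1.0)
  expect_equal(id$discrepancy_pct, 0.0)
  expect_true(id$within_tolerance)

  # a ratio of 1.013 is a 1.3% discrepancy, within the +/-2% tolerance
  r13 <- local({ r <- ref; r$dose_per_mu_cgy <- mod$dose_per_mu_cgy / 1.013; r })
  cmp13 <- compare_protocols(mod, r13)
  expect_equal(cmp13$discrepancy_pct, 1.3)
  expect_true(cmp13$within_tolerance)

  # 2.5% is outside
  r25 <- local({ r <- ref; r$dose_per_mu_cgy <- mod$dose_per_mu_cgy / 1.025; r })
  cmp25 <- compare_protocols(mod, r25)
  expect_false(cmp25$within_tolerance)

  # mismatched protocols or beams are refused
  expect_error(compare_protocols(ref, mod), "modified result")
  other <- calibrate_record(rs, reg[["PTW 30013"]], make_beam(5.76, 98.684),
                            "modified")
  expect_error(compare_protocols(other, ref), "different beams")
})

test_that("run_session processes records independently and pairs protocols", {
  reg <- demo_registry()
  tab <- example_kq_table()

  # empty session -> empty report
  empty <- data.frame(record_id = character(0), chamber = character(0),
                      protocol = character(0), r50_cm = numeric(0),
                      pdd_at_zref_pct = numeric(0), monitor_units = numeric(0),
                      m_raw_nc = numeric(0), temperature_c = numeric(0),
                      pressure_kpa = numeric(0))
  rep0 <- run_session(empty, reg, tab)
  expect_length(rep0$results, 0L)
  expect_length(rep0$comparisons, 0L)
  expect_equal(nrow(as.data.frame(rep0)), 0L)

  # a noiseless generated session recovers the true dose per MU
  out <- withr::local_tempdir()
  paths <- generate_session_file(out, reg, r50_values = c(4.002, 5.955),
                                 dose_per_mu_cgy = 1.0, noise_rel = 0,
                                 seed = 123, kq_table = tab)
  rep <- run_session(read_session(paths$session), load_registry(paths$registry),
                     load_kq_table(paths$kq_table))
  expect_equal(nrow(rep$errors), 0L)
  df <- as.data.frame(rep)
  expect_equal(df$dose_per_mu_cgy, rep(1.0, nrow(df)), tolerance = 1e-12)
  expect_length(rep$comparisons, 8L) # 4 chambers x 2 beams
  for (cmp in rep$comparisons) expect_true(cmp$within_tolerance)

  # an R50 below the cylindrical-chamber table range yields a per-record
  # "not determinable" entry, and the other records still process
  low <- data.frame(
    record_id = c("low_cyl", "ok_pp"),
    chamber = c("PTW 30013", "Exradin A11"),
    protocol = "trs398", r50_cm = 2.37, pdd_at_zref_pct = 99.172,
    monitor_units = 100, m_raw_nc = c(19.0, 20.5),
    temperature_c = 21, pressure_kpa = 101)
  replow <- run_session(low, reg, tab)
  expect_equal(replow$errors$record_id, "low_cyl")
  expect_match(replow$errors$message, "not determinable")
  expect_length(replow$results, 1L)
  expect_equal(replow$results[[1]]$record_id, "ok_pp")
})
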