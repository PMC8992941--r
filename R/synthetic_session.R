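#' Ground truth for a simulated measurement
#'
#' Describes the "real" conditions behind a simulated reading set: the true
#' linac output, the beam quality, the reading noise and the environmental
#' conditions present during the simulated irradiation. Everything a
#' simulation produces is reproducible from the `seed`.
#'
#' @param true_dose_per_mu_cgy True dose per monitor unit at zmax, cGy/MU
#'   (default 1.0, the usual clinical calibration point).
#' @param r50_cm Target beam-quality index, cm.
#' @param noise_rel Relative standard deviation of the multiplicative
#'   Gaussian reading noise (default 0 = noiseless).
#' @param seed Integer random seed.
#' @param temperature_c,pressure_kpa Environmental conditions "present"
#'   during the simulated readings (defaults 22 deg C, 100.5 kPa — a typical
#'   clinic, deliberately off the reference conditions so P_TP != 1).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(true_dose_per_mu_cgy = 1.0, r50_cm,
                            noise_rel = 0, seed = 1L,
                            temperature_c = 22, pressure_kpa = 100.5) {
  if (!is.finite(true_dose_per_mu_cgy) || true_dose_per_mu_cgy <= 0) {
    stop("'true_dose_per_mu_cgy' must be positive")
  }
  if (!is.finite(noise_rel) || noise_rel < 0) stop("'noise_rel' must be >= 0")
  structure(
    list(true_dose_per_mu_cgy = true_dose_per_mu_cgy,
         r50_cm = as.numeric(r50_cm), noise_rel = as.numeric(noise_rel),
         seed = as.integer(seed), temperature_c = as.numeric(temperature_c),
         pressure_kpa = as.numeric(pressure_kpa)),
    class = "synthetic_truth")
}

#' Synthetic electron depth-dose curve with prescribed R50
#'
#' Generates a realistic-looking electron PDD curve from the analytic shape
#' \deqn{n(z) = (1 - e^{-z/s})\,\sigma\!\big((R_{50}' - z)/w\big) + t,}
#' where \eqn{\sigma} is the logistic function, \eqn{s} the build-up scale,
#' \eqn{w} the falloff width and \eqn{t} a bremsstrahlung-like tail. The
#' internal parameter \eqn{R_{50}'} is calibrated by bisection so that the
#' sampled, normalized curve's interpolated 50% falloff crossing equals
#' `r50_cm` within 0.01 cm. Only this contract (max = 100, calibrated R50)
#' matters to consumers; the shape itself is an engineering choice, not a
#' transport model.
#'
#' @param r50_cm Target R50 in cm (> 0.5).
#' @param buildup_scale_cm Build-up saturation scale, cm (default R50/6).
#' @param falloff_width_cm Logistic falloff width, cm (default R50/12).
#' @param tail_fraction Flat tail level as a fraction of the unnormalized
#'   plateau, in [0, 0.1).
#' @param grid_step_cm Depth sampling step, cm (default 0.02).
#' @return A [depth_dose_curve()] normalized to max = 100.
#' @export
#' @examples
#' curve <- synth_pdd(4.0)
#' r50_from_curve(curve) # 4.0 within 0.01
synth_pdd <- function(r50_cm, buildup_scale_cm = r50_cm / 6,
                      falloff_width_cm = r50_cm / 12,
                      tail_fraction = 0.02, grid_step_cm = 0.02) {
  if (!is.finite(r50_cm) || r50_cm <= 0.5) stop("'r50_cm' must exceed 0.5 cm")
  if (buildup_scale_cm <= 0 || falloff_width_cm <= 0 || grid_step_cm <= 0) {
    stop("shape parameters must be positive")
  }
  if (tail_fraction < 0 || tail_fraction >= 0.1) {
    stop("'tail_fraction' must lie in [0, 0.1)")
  }
  z <- seq(0, 2 * r50_cm + 1, by = grid_step_cm)
  curve_for <- function(r50p) {
    n <- (1 - exp(-z / buildup_scale_cm)) *
      stats::plogis((r50p - z) / falloff_width_cm) + tail_fraction
    depth_dose_curve(z, n, normalize = TRUE)
  }
  err <- function(r50p) r50_from_curve(curve_for(r50p)) - r50_cm
  lo <- r50_cm - 0.8
  hi <- r50_cm + 0.8
  flo <- err(lo)
  fhi <- err(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    stop("R50 calibration failed to bracket; adjust shape parameters")
  }
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    fm <- err(mid)
    if (fm == 0 || (hi - lo) / 2 < 1e-5) break
    if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  out <- curve_for(mid)
  if (abs(r50_from_curve(out) - r50_cm) > 0.01) {
    stop("R50 calibration did not converge to 0.01 cm")
  }
  out
}

#' Simulate a reading set consistent with a known truth
#'
#' Inverts the calibration chain: from the true dose per MU it computes the
#' corrected reading M the chamber would have to deliver under the chosen
#' protocol (inverting the dose-per-MU conversion and then the protocol dose
#' equation), then "de-corrects" it into a raw reading by dividing out
#' P_TP for the truth's environment and the configured P_pol, P_ion and
#' P_elec. The opposite-polarity and reduced-voltage companion readings are
#' synthesized from the (noisy) raw reading so that the correction factors
#' computed by the pipeline equal the configured targets exactly.
#'
#' Noise is one multiplicative Gaussian factor applied to the reading set
#' (shot-to-shot output variation common to the companion readings). With
#' `noise_rel = 0` the pipeline recovers the truth to machine precision;
#' with noise the recovered dose is truth times the noise factor.
#'
#' @param truth A [synthetic_truth()].
#' @param chamber A [chamber_spec()] (needs `kq_ecal` for the modified
#'   protocol).
#' @param beam A [make_beam()] result for the same beam quality.
#' @param protocol `"trs398"` or `"modified"`.
#' @param voltage_ratio Two-voltage ratio used in the simulated session.
#' @param target_p_pol,target_p_ion Correction-factor values the synthesized
#'   companions encode.
#' @param p_elec Electrometer factor recorded in the session.
#' @param monitor_units MU delivered.
#' @param kq_table,aliases Needed when `protocol = "trs398"`.
#' @return A [reading_set()].
#' @export
simulate_readings <- function(truth, chamber, beam, protocol,
                              voltage_ratio = 2,
                              target_p_pol = 1.002, target_p_ion = 1.004,
                              p_elec = 1, monitor_units = 100,
                              kq_table = NULL, aliases = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(chamber, "chamber_spec"),
            inherits(beam, "beam_quality"))
  protocol <- match.arg(protocol, c("trs398", "modified"))
  kq_product <- if (protocol == "trs398") {
    if (is.null(kq_table)) stop("simulating a trs398 record needs a kq_table")
    kq_trs398(kq_table, chamber$name, beam$r50_cm, aliases = aliases)$value
  } else {
    if (is.null(chamber$kq_ecal)) {
      stop(sprintf("chamber '%s' needs kq_ecal set to simulate the modified protocol",
                   chamber$name))
    }
    kq_prime(chamber, beam$r50_cm)$value * chamber$kq_ecal
  }
  dose_zmax_gy <- truth$true_dose_per_mu_cgy * monitor_units / 100
  dose_zref_gy <- dose_zmax_gy * beam$pdd_at_zref_pct / 100
  if (dose_zref_gy <= 0) stop("infeasible truth: non-positive dose")
  m_corrected <- dose_zref_gy / (chamber$nd_w_gy_per_nc * kq_product)
  p_tp <- ptp_correction(truth$temperature_c, truth$pressure_kpa)
  m_ideal <- m_corrected / (p_tp * target_p_pol * target_p_ion * p_elec)
  set.seed(truth$seed)
  eps <- 1 + truth$noise_rel * stats::rnorm(1)
  if (eps <= 0) stop("noise draw produced a non-positive reading; lower 'noise_rel'")
  m_raw <- m_ideal * eps
  reading_set(
    m_raw_nc = m_raw,
    temperature_c = truth$temperature_c, pressure_kpa = truth$pressure_kpa,
    m_opposite_polarity_nc = m_raw * (2 * target_p_pol - 1),
    m_reduced_voltage_nc = m_raw /
      (voltage_ratio + (1 - voltage_ratio) / target_p_ion),
    voltage_ratio = voltage_ratio,
    p_elec = p_elec, monitor_units = monitor_units)
}

#' Synthetic kQ,Qo table spanning a beam-quality range
#'
#' Builds a smooth, clearly synthetic kQ,Qo grid (linearly decreasing with
#' R50) for the given chambers, so that standard-protocol records can be
#' simulated for any beam quality without code-of-practice data. Values are
#' placeholders for simulation only.
#'
#' @param chamber_names Chamber names to include.
#' @param r50_range Range of R50 covered, cm.
#' @param n_points Grid points per chamber.
#' @return A [kq_table()] with provenance `"synthetic"`.
#' @export
synthetic_kq_table <- function(chamber_names, r50_range = c(1, 9),
                               n_points = 9) {
  r <- seq(r50_range[1], r50_range[2], length.out = n_points)
  k <- 0.94 - 0.005 * (r - r50_range[1])  # smooth decrease, stays in (0.8, 1.1)
  entries <- do.call(rbind, lapply(chamber_names, function(ch) {
    data.frame(chamber = ch, r50_cm = r, kq_qo = k)
  }))
  kq_table(entries, provenance = "synthetic (simulation placeholder values)")
}

#' Generate a synthetic session on disk
#'
#' Writes a complete simulated measurement session — one record per chamber
#' x beam x protocol — together with a ground-truth sidecar, the chamber
#' registry and the kQ,Qo table used, so that the whole pipeline can be
#' exercised end to end from files alone. PDD(zref) for each beam comes from
#' a [synth_pdd()] curve. Record seeds are derived deterministically from
#' `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param registry A [chamber_registry()]; chambers used under the modified
#'   protocol must have `kq_ecal` set.
#' @param r50_values Beam qualities to simulate, cm.
#' @param chambers Chamber names (default: all in `registry`).
#' @param protocols Protocols to simulate (default both).
#' @param dose_per_mu_cgy True output, cGy/MU.
#' @param noise_rel Relative reading noise.
#' @param seed Base integer seed.
#' @param monitor_units,voltage_ratio,target_p_pol,target_p_ion,temperature_c,pressure_kpa
#'   Session conditions, see [simulate_readings()] and [synthetic_truth()].
#' @param kq_table A [kq_table()] covering all simulated beams; default a
#'   [synthetic_kq_table()].
#' @return Invisibly, a list with paths `session`, `truth`, `registry`,
#'   `kq_table`.
#' @export
generate_session_file <- function(out_dir, registry, r50_values,
                                  chambers = names(registry),
                                  protocols = c("trs398", "modified"),
                                  dose_per_mu_cgy = 1.0, noise_rel = 0,
                                  seed = 1L, monitor_units = 100,
                                  voltage_ratio = 2, target_p_pol = 1.002,
                                  target_p_ion = 1.004,
                                  temperature_c = 22, pressure_kpa = 100.5,
                                  kq_table = NULL) {
  stopifnot(inherits(registry, "chamber_registry"))
  protocols <- match.arg(protocols, c("trs398", "modified"),
                         several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(kq_table)) {
    kq_table <- synthetic_kq_table(
      chambers, r50_range = range(r50_values) + c(-0.5, 0.5))
  }
  grid <- expand.grid(chamber = chambers, r50_cm = r50_values,
                      protocol = protocols, stringsAsFactors = FALSE)
  beams <- lapply(unique(grid$r50_cm), function(r) {
    make_beam(r, synth_pdd(r))
  })
  names(beams) <- vapply(unique(grid$r50_cm), function(r) sprintf("%.9g", r),
                         character(1))
  records <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    beam <- beams[[sprintf("%.9g", g$r50_cm)]]
    truth <- synthetic_truth(
      true_dose_per_mu_cgy = dose_per_mu_cgy, r50_cm = g$r50_cm,
      noise_rel = noise_rel, seed = as.integer(seed) + i,
      temperature_c = temperature_c, pressure_kpa = pressure_kpa)
    rs <- simulate_readings(
      truth, registry[[g$chamber]], beam, g$protocol,
      voltage_ratio = voltage_ratio, target_p_pol = target_p_pol,
      target_p_ion = target_p_ion, monitor_units = monitor_units,
      kq_table = kq_table)
    records[[i]] <- data.frame(
      record_id = sprintf("rec%03d_%s_%s", i, gsub("\\s+", "", g$chamber),
                          g$protocol),
      chamber = g$chamber, protocol = g$protocol, r50_cm = g$r50_cm,
      pdd_at_zref_pct = beam$pdd_at_zref_pct,
      monitor_units = monitor_units, m_raw_nc = rs$m_raw_nc,
      temperature_c = temperature_c, pressure_kpa = pressure_kpa,
      m_opposite_polarity_nc = rs$m_opposite_polarity_nc,
      m_reduced_voltage_nc = rs$m_reduced_voltage_nc,
      voltage_ratio = voltage_ratio, p_elec = 1)
  }
  session <- do.call(rbind, records)
  paths <- list(session = file.path(out_dir, "session.csv"),
                truth = file.path(out_dir, "truth.json"),
                registry = file.path(out_dir, "registry.json"),
                kq_table = file.path(out_dir, "kq_table.csv"))
  utils::write.csv(session, paths$session, row.names = FALSE)
  jsonlite::write_json(
    list(true_dose_per_mu_cgy = dose_per_mu_cgy, noise_rel = noise_rel,
         seed = seed, temperature_c = temperature_c,
         pressure_kpa = pressure_kpa,
         records = data.frame(record_id = session$record_id,
                              true_dose_per_mu_cgy = dose_per_mu_cgy)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_registry(registry, paths$registry)
  save_kq_table(kq_table, paths$kq_table)
  invisible(paths)
}
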