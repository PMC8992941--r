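#' Chamber setup depth for a protocol
#'
#' Physical placement depth in water for the chamber under each protocol:
#' \describe{
#'   \item{standard (`"trs398"`), cylindrical}{central axis at
#'     \eqn{z_{ref} + 0.5\, r_{cyl}} (the shift places the effective point of
#'     measurement at the reference depth).}
#'   \item{standard, parallel-plate}{front reference plane at \eqn{z_{ref}}.}
#'   \item{modified, cylindrical}{central axis at \eqn{z_{ref}} — the fitted
#'     kQ' absorbs gradient effects, so no shift is applied.}
#'   \item{modified, parallel-plate}{effective point of measurement at
#'     \eqn{z_{ref}}: the front reference plane sits at
#'     \eqn{z_{ref} - }`epom_shift_cm`.}
#' }
#' The shift is a placement instruction only; no transformation is applied
#' to readings.
#'
#' @param protocol `"trs398"` or `"modified"`.
#' @param chamber A [chamber_spec()].
#' @param zref_cm Reference depth in cm (> 0).
#' @return Setup depth in cm.
#' @export
#' @examples
#' ch <- builtin_registry()[["IBA CC13"]]
#' setup_depth("trs398", ch, 2.0)   # 2.0 + 0.5 * 0.30
#' setup_depth("modified", ch, 2.0) # 2.0
setup_depth <- function(protocol, chamber, zref_cm) {
  protocol <- match.arg(protocol, c("trs398", "modified"))
  stopifnot(inherits(chamber, "chamber_spec"))
  if (!is.finite(zref_cm) || zref_cm <= 0) stop("'zref_cm' must be positive")
  if (chamber$geometry == "cylindrical") {
    if (is.null(chamber$cavity_radius_cm)) {
      stop(sprintf("chamber '%s' has no cavity radius configured", chamber$name))
    }
    if (protocol == "trs398") {
      zref_cm + 0.5 * chamber$cavity_radius_cm
    } else {
      zref_cm
    }
  } else {
    if (protocol == "trs398") zref_cm else zref_cm - chamber$epom_shift_cm
  }
}

#' Absorbed dose to water at zref, standard protocol
#'
#' \eqn{D_{w,Q_o} = M \, N_{D,w}^{Co-60} \, k_{Q,Q_o}} with the table-derived
#' beam-quality factor. Passing a fitted kQ' here is a protocol mismatch and
#' is refused.
#'
#' @param m_corrected_nc Fully corrected reading M in nC, or a
#'   `correction_factors` object from [corrected_reading()].
#' @param chamber A [chamber_spec()].
#' @param kq_qo A `kq_result` produced by [kq_trs398()].
#' @return Absorbed dose to water at the reference depth, Gy.
#' @export
dose_trs398 <- function(m_corrected_nc, chamber, kq_qo) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(kq_qo, "kq_result"))
  if (inherits(m_corrected_nc, "correction_factors")) {
    m_corrected_nc <- m_corrected_nc$m_corrected_nc
  }
  if (kq_qo$method != "table_interpolation") {
    stop("protocol mismatch: dose_trs398() requires a table-interpolated kQ,Qo")
  }
  if (m_corrected_nc <= 0) stop("'m_corrected_nc' must be positive")
  m_corrected_nc * chamber$nd_w_gy_per_nc * kq_qo$value
}

#' Absorbed dose to water at zref, modified calibration
#'
#' \eqn{D_{w,Q}(z_{ref}) = M \, k_Q' \, k_{Q,ecal} \, N_{D,w}^{Co-60}} with
#' the fitted beam-quality factor. Requires the chamber's `kq_ecal` to be
#' set; an unset value is a configuration error, never an implicit 1.0.
#'
#' @param m_corrected_nc Fully corrected reading M in nC, or a
#'   `correction_factors` object.
#' @param chamber A [chamber_spec()] with `kq_ecal` set.
#' @param kq_prime A `kq_result` produced by [kq_prime()] (fit methods only).
#' @return Absorbed dose to water at the reference depth, Gy.
#' @export
dose_modified <- function(m_corrected_nc, chamber, kq_prime) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(kq_prime, "kq_result"))
  if (inherits(m_corrected_nc, "correction_factors")) {
    m_corrected_nc <- m_corrected_nc$m_corrected_nc
  }
  if (!kq_prime$method %in% c("fit_power", "fit_exponential")) {
    stop("protocol mismatch: dose_modified() requires a fitted kQ'")
  }
  if (is.null(chamber$kq_ecal)) {
    stop(sprintf(
      "chamber '%s' has no kq_ecal configured; supply one (it is never assumed to be 1)",
      chamber$name))
  }
  if (m_corrected_nc <= 0) stop("'m_corrected_nc' must be positive")
  m_corrected_nc * kq_prime$value * chamber$kq_ecal * chamber$nd_w_gy_per_nc
}

#' Dose per monitor unit at zmax
#'
#' Converts the dose at the reference depth to dose at the depth of maximum,
#' \eqn{D_w(z_{max}) = 100 \, D_w(z_{ref}) / PDD(z_{ref})}, then expresses it
#' per monitor unit in cGy/MU.
#'
#' @param dose_zref_gy Absorbed dose at zref, Gy.
#' @param pdd_at_zref_pct PDD at zref in percent, in (0, 100].
#' @param monitor_units Monitor units delivered.
#' @return Dose per monitor unit at zmax, cGy/MU.
#' @export
#' @examples
#' dose_per_mu(1, 100, 100) # 1 cGy/MU
dose_per_mu <- function(dose_zref_gy, pdd_at_zref_pct, monitor_units) {
  if (pdd_at_zref_pct <= 0 || pdd_at_zref_pct > 100) {
    stop("'pdd_at_zref_pct' must lie in (0, 100]")
  }
  if (monitor_units <= 0) stop("'monitor_units' must be positive")
  dose_zmax_gy <- 100 * dose_zref_gy / pdd_at_zref_pct
  100 * dose_zmax_gy / monitor_units
}

calibration_result <- function(protocol, chamber, beam, m_corrected_nc,
                               kq_used, dose_zref_gy, dose_per_mu_cgy,
                               setup_depth_cm, record_id = NA_character_) {
  structure(
    list(record_id = record_id, protocol = protocol, chamber = chamber,
         beam = beam, m_corrected_nc = m_corrected_nc, kq_used = kq_used,
         dose_zref_gy = dose_zref_gy, dose_per_mu_cgy = dose_per_mu_cgy,
         setup_depth_cm = setup_depth_cm),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> [%s] %s, R50 = %.3f cm\n  M = %.5f nC, k = %.4f (%s), D(zref) = %.5f Gy, D/MU = %.4f cGy/MU, setup %.3f cm\n",
    x$protocol, x$chamber$name, x$beam$r50_cm, x$m_corrected_nc,
    x$kq_used$value, x$kq_used$method, x$dose_zref_gy, x$dose_per_mu_cgy,
    x$setup_depth_cm))
  invisible(x)
}

#' Single-record calibration
#'
#' Runs the full chain for one measurement: corrected reading, beam-quality
#' factor (fitted or table-interpolated according to `protocol`), dose at
#' zref, dose per MU at zmax, and the setup depth.
#'
#' @param readings A [reading_set()].
#' @param chamber A [chamber_spec()].
#' @param beam A [make_beam()] result.
#' @param protocol `"trs398"` or `"modified"`.
#' @param kq_table Required for `"trs398"`: a [kq_table()].
#' @param aliases Optional surrogate-chamber alias map for the table lookup.
#' @param policy A [correction_policy()].
#' @param record_id Optional identifier carried into the result.
#' @return A `calibration_result`.
#' @export
calibrate_record <- function(readings, chamber, beam, protocol,
                             kq_table = NULL, aliases = NULL,
                             policy = correction_policy(),
                             record_id = NA_character_) {
  protocol <- match.arg(protocol, c("trs398", "modified"))
  stopifnot(inherits(beam, "beam_quality"))
  cf <- corrected_reading(readings, policy)
  if (protocol == "trs398") {
    if (is.null(kq_table)) {
      stop("the standard protocol requires a kQ,Qo table")
    }
    kq <- kq_trs398(kq_table, chamber$name, beam$r50_cm, aliases = aliases)
    dz <- dose_trs398(cf$m_corrected_nc, chamber, kq)
  } else {
    kq <- kq_prime(chamber, beam$r50_cm)
    dz <- dose_modified(cf$m_corrected_nc, chamber, kq)
  }
  calibration_result(
    protocol = protocol, chamber = chamber, beam = beam,
    m_corrected_nc = cf$m_corrected_nc, kq_used = kq, dose_zref_gy = dz,
    dose_per_mu_cgy = dose_per_mu(dz, beam$pdd_at_zref_pct,
                                  readings$monitor_units),
    setup_depth_cm = setup_depth(protocol, chamber, beam$zref_cm),
    record_id = record_id)
}

#' Compare the modified calibration against the standard protocol
#'
#' Both results must describe the same beam, and the reference must be a
#' standard-protocol result. The comparison is made on dose per MU at zmax:
#' the ratio \eqn{D_w} = modified / standard, the percent discrepancy
#' \eqn{(D_w - 1) \times 100}, and a verdict against the +/-2% clinical
#' tolerance.
#'
#' @param modified A `calibration_result` with protocol `"modified"`.
#' @param reference A `calibration_result` with protocol `"trs398"`.
#' @param tolerance_pct Tolerance half-width in percent (default 2).
#' @return An object of class `comparison_result` with `dose_ratio`,
#'   `discrepancy_pct` and `within_tolerance`.
#' @export
compare_protocols <- function(modified, reference, tolerance_pct = 2) {
  stopifnot(inherits(modified, "calibration_result"),
            inherits(reference, "calibration_result"))
  if (modified$protocol != "modified" || reference$protocol != "trs398") {
    stop("compare_protocols() expects a modified result and a trs398 reference")
  }
  if (abs(modified$beam$r50_cm - reference$beam$r50_cm) > 1e-9) {
    stop("comparison error: results describe different beams (R50 mismatch)")
  }
  ratio <- modified$dose_per_mu_cgy / reference$dose_per_mu_cgy
  disc <- (ratio - 1) * 100
  structure(
    list(chamber = modified$chamber$name, r50_cm = modified$beam$r50_cm,
         dose_ratio = ratio, discrepancy_pct = disc,
         tolerance_pct = tolerance_pct,
         within_tolerance = abs(disc) <= tolerance_pct),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s @ R50 %.3f cm: Dw ratio = %.4f, discrepancy = %+.2f%% (%s +/-%g%%)\n",
    x$chamber, x$r50_cm, x$dose_ratio, x$discrepancy_pct,
    if (x$within_tolerance) "within" else "OUTSIDE", x$tolerance_pct))
  invisible(x)
}

# columns a session table may carry; chamber/protocol/r50/m_raw etc.
.session_required <- c("record_id", "chamber", "protocol", "r50_cm",
                       "pdd_at_zref_pct", "monitor_units", "m_raw_nc",
                       "temperature_c", "pressure_kpa")
.session_optional <- c("m_opposite_polarity_nc", "m_reduced_voltage_nc",
                       "voltage_ratio", "p_elec")

#' Read a measurement session file
#'
#' A session file holds one record per beam x chamber x protocol. CSV (by
#' extension `.csv`) or JSON (array of records) are accepted; required
#' columns are `record_id`, `chamber`, `protocol`, `r50_cm`,
#' `pdd_at_zref_pct`, `monitor_units`, `m_raw_nc`, `temperature_c`,
#' `pressure_kpa`, with optional `m_opposite_polarity_nc`,
#' `m_reduced_voltage_nc`, `voltage_ratio`, `p_elec`.
#'
#' @param path Session file path.
#' @return A data frame of session records.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("session file not found: %s", path))
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
  missing <- setdiff(.session_required, names(df))
  if (length(missing)) {
    stop(sprintf("session file missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  df
}

#' Run a full calibration session
#'
#' Processes every record of a session table through the full chain
#' (corrected reading, beam-quality factor, dose at zref, dose per MU), then
#' pairs modified/standard records measured with the same chamber on the
#' same beam and compares them. A failing record is reported with its
#' identifier and does not abort the remaining records.
#'
#' @param session A session data frame ([read_session()]) or a file path.
#' @param registry A [chamber_registry()].
#' @param kq_table A [kq_table()] (required if any record uses the standard
#'   protocol).
#' @param aliases Optional surrogate alias map for table lookups.
#' @param policy A [correction_policy()].
#' @return An object of class `session_report` with elements `results` (list
#'   of `calibration_result`), `comparisons` (list of `comparison_result`)
#'   and `errors` (data frame of record_id, message).
#' @export
run_session <- function(session, registry, kq_table = NULL, aliases = NULL,
                        policy = correction_policy()) {
  if (is.character(session)) session <- read_session(session)
  stopifnot(is.data.frame(session), inherits(registry, "chamber_registry"))
  results <- list()
  errors <- data.frame(record_id = character(0), message = character(0))
  opt <- function(rec, f) {
    v <- if (f %in% names(rec)) rec[[f]] else NA
    if (length(v) == 0L || is.na(v)) NULL else as.numeric(v)
  }
  for (i in seq_len(nrow(session))) {
    rec <- session[i, , drop = FALSE]
    rid <- as.character(rec$record_id)
    res <- tryCatch({
      chamber <- registry[[as.character(rec$chamber)]]
      beam <- make_beam(rec$r50_cm, rec$pdd_at_zref_pct)
      rs <- reading_set(
        m_raw_nc = rec$m_raw_nc,
        temperature_c = rec$temperature_c, pressure_kpa = rec$pressure_kpa,
        m_opposite_polarity_nc = opt(rec, "m_opposite_polarity_nc"),
        m_reduced_voltage_nc = opt(rec, "m_reduced_voltage_nc"),
        voltage_ratio = opt(rec, "voltage_ratio"),
        p_elec = if (is.null(opt(rec, "p_elec"))) 1 else opt(rec, "p_elec"),
        monitor_units = rec$monitor_units)
      calibrate_record(rs, chamber, beam,
                       protocol = as.character(rec$protocol),
                       kq_table = kq_table, aliases = aliases,
                       policy = policy, record_id = rid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors,
                      data.frame(record_id = rid,
                                 message = conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  comparisons <- list()
  if (length(results)) {
    keys <- vapply(results, function(r)
      paste(tolower(r$chamber$name), format(r$beam$r50_cm, digits = 12)),
      character(1))
    protos <- vapply(results, function(r) r$protocol, character(1))
    for (k in unique(keys)) {
      im <- which(keys == k & protos == "modified")
      ir <- which(keys == k & protos == "trs398")
      if (length(im) == 1L && length(ir) == 1L) {
        comparisons[[length(comparisons) + 1L]] <-
          compare_protocols(results[[im]], results[[ir]])
      }
    }
  }
  structure(list(results = results, comparisons = comparisons,
                 errors = errors),
            class = "session_report")
}

#' Tabulate a session report
#'
#' @param x A `session_report`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (unused).
#' @return A data frame, one row per successful calibration.
#' @export
as.data.frame.session_report <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  if (!length(x$results)) {
    return(data.frame(record_id = character(0), chamber = character(0),
                      protocol = character(0), r50_cm = numeric(0),
                      zref_cm = numeric(0), m_corrected_nc = numeric(0),
                      kq = numeric(0), dose_zref_gy = numeric(0),
                      dose_per_mu_cgy = numeric(0),
                      setup_depth_cm = numeric(0)))
  }
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(record_id = r$record_id, chamber = r$chamber$name,
               protocol = r$protocol, r50_cm = r$beam$r50_cm,
               zref_cm = r$beam$zref_cm, m_corrected_nc = r$m_corrected_nc,
               kq = r$kq_used$value, dose_zref_gy = r$dose_zref_gy,
               dose_per_mu_cgy = r$dose_per_mu_cgy,
               setup_depth_cm = r$setup_depth_cm)
  }))
}

#' @export
print.session_report <- function(x, round = 4, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<session_report> %d result(s), %d comparison(s), %d error(s)\n",
              length(x$results), length(x$comparisons), nrow(x$errors)))
  if (nrow(df)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = round)
    print(df, row.names = FALSE)
  }
  for (cmp in x$comparisons) print(cmp)
  if (nrow(x$errors)) {
    cat("errors:\n")
    print(x$errors, row.names = FALSE)
  }
  invisible(x)
}
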