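#' Measurement reading set
#'
#' Raw electrometer data for one irradiation: the charge at the operating
#' voltage and polarity, environmental conditions, and the optional companion
#' readings needed for the polarity and two-voltage recombination
#' corrections. Charges are handled as magnitudes after the raw polarity is
#' recorded, which avoids electrometer sign ambiguity.
#'
#' @param m_raw_nc Charge reading at the operating voltage/polarity, nC
#'   (nonzero).
#' @param temperature_c Water/air temperature in deg C.
#' @param pressure_kpa Ambient pressure in kPa.
#' @param m_opposite_polarity_nc Optional charge at reversed polarity, nC.
#' @param m_reduced_voltage_nc Optional charge at the lower voltage of the
#'   two-voltage pair, nC. Must be given together with `voltage_ratio`.
#' @param voltage_ratio Ratio V_high/V_low (> 1) of the two-voltage pair.
#' @param p_elec Electrometer calibration factor (dimensionless, default 1).
#' @param monitor_units Monitor units delivered (default 100, the usual
#'   output-calibration irradiation).
#' @return An object of class `reading_set`.
#' @export
reading_set <- function(m_raw_nc, temperature_c, pressure_kpa,
                        m_opposite_polarity_nc = NULL,
                        m_reduced_voltage_nc = NULL,
                        voltage_ratio = NULL,
                        p_elec = 1, monitor_units = 100) {
  if (!is.finite(m_raw_nc) || m_raw_nc == 0) stop("'m_raw_nc' must be nonzero")
  if (!is.finite(pressure_kpa) || pressure_kpa <= 0) {
    stop("'pressure_kpa' must be positive")
  }
  if (!is.finite(temperature_c) || temperature_c <= -273.15) {
    stop("'temperature_c' must exceed absolute zero")
  }
  if (is.null(voltage_ratio) != is.null(m_reduced_voltage_nc)) {
    stop("'voltage_ratio' and 'm_reduced_voltage_nc' must be given together")
  }
  if (!is.null(voltage_ratio) && (!is.finite(voltage_ratio) || voltage_ratio <= 1)) {
    stop("'voltage_ratio' must be > 1")
  }
  if (!is.finite(monitor_units) || monitor_units <= 0) {
    stop("'monitor_units' must be positive")
  }
  structure(
    list(m_raw_nc = as.numeric(m_raw_nc),
         temperature_c = as.numeric(temperature_c),
         pressure_kpa = as.numeric(pressure_kpa),
         m_opposite_polarity_nc = if (!is.null(m_opposite_polarity_nc))
           as.numeric(m_opposite_polarity_nc),
         m_reduced_voltage_nc = if (!is.null(m_reduced_voltage_nc))
           as.numeric(m_reduced_voltage_nc),
         voltage_ratio = if (!is.null(voltage_ratio)) as.numeric(voltage_ratio),
         p_elec = as.numeric(p_elec),
         monitor_units = as.numeric(monitor_units)),
    class = "reading_set")
}

#' Temperature-pressure correction P_TP
#'
#' Corrects an open-to-atmosphere chamber reading to standard environmental
#' conditions: \eqn{P_{TP} = \frac{273.15 + T}{273.15 + T_{ref}} \cdot
#' \frac{P_{ref}}{P}}. Reference conditions default to the 20.0 deg C /
#' 101.325 kPa convention of absorbed-dose codes of practice; laboratories
#' following a 22 deg C standard can override them.
#'
#' @param temperature_c Measured temperature, deg C.
#' @param pressure_kpa Measured pressure, kPa.
#' @param ref_temperature_c Reference temperature, deg C (default 20.0).
#' @param ref_pressure_kpa Reference pressure, kPa (default 101.325).
#' @return Dimensionless correction factor.
#' @export
#' @examples
#' ptp_correction(25, 101.325) # 298.15 / 293.15
ptp_correction <- function(temperature_c, pressure_kpa,
                           ref_temperature_c = 20.0,
                           ref_pressure_kpa = 101.325) {
  if (temperature_c <= -273.15 || ref_temperature_c <= -273.15) {
    stop("temperatures must exceed absolute zero")
  }
  if (pressure_kpa <= 0 || ref_pressure_kpa <= 0) {
    stop("pressures must be positive")
  }
  (273.15 + temperature_c) / (273.15 + ref_temperature_c) *
    ref_pressure_kpa / pressure_kpa
}

#' Polarity correction P_pol
#'
#' \eqn{P_{pol} = (|M_+| + |M_-|) / (2 |M_{used}|)}, where `m_used_nc` is the
#' reading taken at the routinely used polarity (it must be one of the two
#' polarity readings).
#'
#' @param m_plus_nc,m_minus_nc Charge readings at the two polarities, nC.
#' @param m_used_nc The one of the two used for the measurement.
#' @return Dimensionless correction factor.
#' @export
#' @examples
#' polarity_correction(1.01, 0.99, 1.01) # 0.990099...
polarity_correction <- function(m_plus_nc, m_minus_nc, m_used_nc) {
  if (m_plus_nc == 0 || m_minus_nc == 0) {
    stop("polarity readings must be nonzero")
  }
  if (!isTRUE(all.equal(m_used_nc, m_plus_nc)) &&
      !isTRUE(all.equal(m_used_nc, m_minus_nc))) {
    stop("'m_used_nc' must be one of the two polarity readings")
  }
  (abs(m_plus_nc) + abs(m_minus_nc)) / (2 * abs(m_used_nc))
}

#' Ion recombination correction P_ion
#'
#' Two-voltage method for pulsed beams (clinical linacs are pulsed):
#' \eqn{P_{ion} = (1 - V_H/V_L) / (M_H/M_L - V_H/V_L)}. An optional hook
#' accepts user-supplied quadratic coefficients \eqn{(a_0, a_1, a_2)} for the
#' tabulated variant, in which case
#' \eqn{P_{ion} = a_0 + a_1 (M_H/M_L) + a_2 (M_H/M_L)^2}.
#'
#' @param m_high_nc Reading at the operating (higher) voltage, nC.
#' @param m_low_nc Reading at the reduced voltage, nC (same sign as
#'   `m_high_nc`).
#' @param voltage_ratio V_high/V_low, > 1.
#' @param quadratic_coefficients Optional numeric length-3 vector
#'   `c(a0, a1, a2)` replacing the linear pulsed-beam formula.
#' @return Dimensionless correction factor.
#' @export
#' @examples
#' recombination_correction(1.004, 1.000, 2) # 1.0040160...
recombination_correction <- function(m_high_nc, m_low_nc, voltage_ratio,
                                     quadratic_coefficients = NULL) {
  if (voltage_ratio <= 1) stop("'voltage_ratio' must be > 1")
  if (m_high_nc == 0 || m_low_nc == 0 || sign(m_high_nc) != sign(m_low_nc)) {
    stop("readings must be nonzero and of the same sign")
  }
  x <- abs(m_high_nc) / abs(m_low_nc)
  if (x < 1) {
    warning("M_high/M_low < 1: sub-unity collection anomaly")
  }
  if (!is.null(quadratic_coefficients)) {
    stopifnot(is.numeric(quadratic_coefficients),
              length(quadratic_coefficients) == 3L)
    a <- quadratic_coefficients
    return(a[1] + a[2] * x + a[3] * x^2)
  }
  if (isTRUE(all.equal(x, voltage_ratio))) {
    stop("M_high/M_low equals the voltage ratio: singular input")
  }
  (1 - voltage_ratio) / (x - voltage_ratio)
}

#' Correction policy
#'
#' Controls which optional corrections [corrected_reading()] applies and the
#' constants they use. Leakage and radial-profile factors default to exactly
#' 1 — their contributions (<= 0.05% and <= 0.15%) are conventionally
#' neglected in electron output calibration — but explicit overrides are
#' accepted.
#'
#' @param apply_polarity,apply_recombination Apply the correction when the
#'   companion readings are present (default `TRUE`).
#' @param p_leak Leakage correction factor (default exactly 1).
#' @param p_rp Radial beam-profile correction factor (default exactly 1).
#' @param ref_temperature_c,ref_pressure_kpa Reference conditions for
#'   [ptp_correction()].
#' @param quadratic_coefficients Optional quadratic recombination
#'   coefficients, see [recombination_correction()].
#' @return An object of class `correction_policy`.
#' @export
correction_policy <- function(apply_polarity = TRUE,
                              apply_recombination = TRUE,
                              p_leak = 1, p_rp = 1,
                              ref_temperature_c = 20.0,
                              ref_pressure_kpa = 101.325,
                              quadratic_coefficients = NULL) {
  structure(
    list(apply_polarity = isTRUE(apply_polarity),
         apply_recombination = isTRUE(apply_recombination),
         p_leak = as.numeric(p_leak), p_rp = as.numeric(p_rp),
         ref_temperature_c = as.numeric(ref_temperature_c),
         ref_pressure_kpa = as.numeric(ref_pressure_kpa),
         quadratic_coefficients = quadratic_coefficients),
    class = "correction_policy")
}

#' Fully corrected chamber reading
#'
#' Applies the full multiplicative correction stack to a raw reading:
#' \deqn{M = M_{raw} \, P_{TP} \, P_{ion} \, P_{pol} \, P_{elec} \,
#'       P_{leak} \, P_{rp}.}
#' Optional corrections whose companion data are absent contribute a factor
#' of exactly 1 (a notice is emitted). All charges enter as magnitudes.
#'
#' @param readings A [reading_set()].
#' @param policy A [correction_policy()].
#' @return An object of class `correction_factors` with each factor, the raw
#'   reading magnitude and the corrected reading `m_corrected_nc`.
#' @export
#' @examples
#' rs <- reading_set(10, 22, 100.5,
#'   m_opposite_polarity_nc = 10.04,
#'   m_reduced_voltage_nc = 9.96, voltage_ratio = 2)
#' corrected_reading(rs)
corrected_reading <- function(readings, policy = correction_policy()) {
  stopifnot(inherits(readings, "reading_set"),
            inherits(policy, "correction_policy"))
  m_raw <- abs(readings$m_raw_nc)
  p_tp <- ptp_correction(readings$temperature_c, readings$pressure_kpa,
                         policy$ref_temperature_c, policy$ref_pressure_kpa)
  if (policy$apply_polarity && !is.null(readings$m_opposite_polarity_nc)) {
    p_pol <- polarity_correction(m_raw, abs(readings$m_opposite_polarity_nc),
                                 m_raw)
  } else {
    if (policy$apply_polarity) {
      message("no opposite-polarity reading: P_pol = 1")
    }
    p_pol <- 1
  }
  if (policy$apply_recombination && !is.null(readings$m_reduced_voltage_nc)) {
    p_ion <- recombination_correction(
      m_raw, abs(readings$m_reduced_voltage_nc), readings$voltage_ratio,
      policy$quadratic_coefficients)
  } else {
    if (policy$apply_recombination) {
      message("no reduced-voltage reading: P_ion = 1")
    }
    p_ion <- 1
  }
  p_elec <- readings$p_elec
  p_leak <- policy$p_leak
  p_rp <- policy$p_rp
  structure(
    list(m_raw_nc = m_raw,
         p_tp = p_tp, p_ion = p_ion, p_pol = p_pol, p_elec = p_elec,
         p_leak = p_leak, p_rp = p_rp,
         m_corrected_nc = m_raw * p_tp * p_ion * p_pol * p_elec *
           p_leak * p_rp,
         monitor_units = readings$monitor_units),
    class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf(
    "<correction_factors> M_raw = %.5f nC -> M = %.5f nC\n  P_TP=%.5f P_ion=%.5f P_pol=%.5f P_elec=%.5f P_leak=%.5f P_rp=%.5f\n",
    x$m_raw_nc, x$m_corrected_nc, x$p_tp, x$p_ion, x$p_pol, x$p_elec,
    x$p_leak, x$p_rp))
  invisible(x)
}
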