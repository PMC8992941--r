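#' Depth-dose curve
#'
#' A sampled percentage depth-dose (PDD) curve for an electron beam,
#' normalized so that its maximum is 100.
#'
#' @param depths_cm Strictly increasing depths in cm.
#' @param pdd_pct PDD values (percent) aligned with `depths_cm`; all >= 0,
#'   maximum equal to 100 (within 1e-9).
#' @param normalize If `TRUE`, rescale `pdd_pct` so its maximum is 100
#'   before validation.
#' @return An object of class `depth_dose_curve`.
#' @export
#' @examples
#' z <- seq(0, 8, by = 0.1)
#' depth_dose_curve(z, 100 * exp(-(z - 2)^2 / 4), normalize = TRUE)
depth_dose_curve <- function(depths_cm, pdd_pct, normalize = FALSE) {
  depths_cm <- as.numeric(depths_cm)
  pdd_pct <- as.numeric(pdd_pct)
  if (length(depths_cm) < 2L || length(depths_cm) != length(pdd_pct)) {
    stop("'depths_cm' and 'pdd_pct' must be equal-length vectors (>= 2 points)")
  }
  if (any(!is.finite(depths_cm)) || any(!is.finite(pdd_pct))) {
    stop("depth-dose curve contains non-finite values")
  }
  if (any(diff(depths_cm) <= 0)) stop("'depths_cm' must be strictly increasing")
  if (any(pdd_pct < 0)) stop("PDD values must be >= 0")
  if (normalize) pdd_pct <- 100 * pdd_pct / max(pdd_pct)
  if (abs(max(pdd_pct) - 100) > 1e-9) {
    stop("curve must be normalized to max = 100 (use normalize = TRUE)")
  }
  structure(list(depths_cm = depths_cm, pdd_pct = pdd_pct),
            class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  cat(sprintf("<depth_dose_curve> %d points, depth %.2f-%.2f cm, z_max = %.2f cm\n",
              length(x$depths_cm), min(x$depths_cm), max(x$depths_cm),
              x$depths_cm[which.max(x$pdd_pct)]))
  invisible(x)
}

#' Read a depth-dose curve from CSV
#'
#' Expects a two-column CSV with header `depth_cm,pdd_pct`.
#'
#' @param path CSV file path.
#' @param normalize Passed to [depth_dose_curve()].
#' @return A [depth_dose_curve()].
#' @export
read_pdd_curve <- function(path, normalize = FALSE) {
  df <- utils::read.csv(path)
  need <- c("depth_cm", "pdd_pct")
  if (!all(need %in% names(df))) {
    stop("PDD curve CSV must have header columns 'depth_cm' and 'pdd_pct'")
  }
  depth_dose_curve(df$depth_cm, df$pdd_pct, normalize = normalize)
}

#' Write a depth-dose curve to CSV
#' @param curve A [depth_dose_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdd_curve <- function(curve, path) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  utils::write.csv(
    data.frame(depth_cm = curve$depths_cm, pdd_pct = curve$pdd_pct),
    path, row.names = FALSE)
  invisible(path)
}

#' Electron reference depth from R50
#'
#' The reference measurement depth for electron beams,
#' \eqn{z_{ref} = 0.6 R_{50} - 0.1} cm. Returned at full precision; round at
#' the reporting layer (tables conventionally print 3 decimals).
#'
#' @param r50_cm Beam-quality index R50 in cm; must exceed 1/6 cm so the
#'   reference depth is positive.
#' @return Reference depth in cm.
#' @export
#' @examples
#' reference_depth(2.484) # 1.3904
reference_depth <- function(r50_cm) {
  if (!all(is.finite(r50_cm)) || any(r50_cm <= 1 / 6)) {
    stop("'r50_cm' must exceed 1/6 cm (reference depth would be non-positive)")
  }
  0.6 * r50_cm - 0.1
}

#' R50 from a depth-dose curve
#'
#' Finds the depth on the distal falloff — beyond the depth of maximum —
#' where the curve first crosses 50% of maximum, by linear interpolation
#' between the bracketing samples. The build-up region is excluded because
#' it can also cross 50%.
#'
#' @param curve A [depth_dose_curve()].
#' @return R50 in cm.
#' @export
r50_from_curve <- function(curve) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  z <- curve$depths_cm
  p <- curve$pdd_pct
  imax <- which.max(p)
  n <- length(z)
  for (i in seq(imax, length.out = max(0L, n - imax))) {
    if (p[i] >= 50 && p[i + 1] < 50) {
      return(z[i] + (50 - p[i]) * (z[i + 1] - z[i]) / (p[i + 1] - p[i]))
    }
  }
  stop("falloff not captured: curve never falls below 50% beyond its maximum")
}

#' Interpolate a depth-dose curve
#'
#' Piecewise-linear interpolation of PDD at a given depth; exact at sample
#' points. Extrapolation outside the sampled range is an error.
#'
#' @param curve A [depth_dose_curve()].
#' @param depth_cm Query depth in cm.
#' @return PDD in percent.
#' @export
pdd_at <- function(curve, depth_cm) {
  stopifnot(inherits(curve, "depth_dose_curve"))
  if (depth_cm < min(curve$depths_cm) || depth_cm > max(curve$depths_cm)) {
    stop(sprintf(
      "depth %.3f cm outside sampled range [%.3f, %.3f]: refusing to extrapolate",
      depth_cm, min(curve$depths_cm), max(curve$depths_cm)))
  }
  stats::approx(curve$depths_cm, curve$pdd_pct, xout = depth_cm)$y
}

#' Beam quality descriptor
#'
#' Packages the beam-quality index R50, the derived reference depth and the
#' PDD at the reference depth for one electron beam. `pdd_source` may be a
#' scalar percent (e.g. a value from a commissioning table) or a
#' [depth_dose_curve()], in which case PDD(zref) is interpolated with
#' [pdd_at()].
#'
#' @param r50_cm R50 in cm.
#' @param pdd_source Scalar PDD(zref) in percent, or a `depth_dose_curve`
#'   covering the reference depth.
#' @param nominal_energy_mev Optional nominal energy label in MeV.
#' @return An object of class `beam_quality` with fields `r50_cm`, `zref_cm`,
#'   `pdd_at_zref_pct`, `nominal_energy_mev`.
#' @export
#' @examples
#' make_beam(5.955, 98.752) # zref = 3.473 cm
make_beam <- function(r50_cm, pdd_source, nominal_energy_mev = NULL) {
  zref <- reference_depth(r50_cm)
  pdd <- if (inherits(pdd_source, "depth_dose_curve")) {
    pdd_at(pdd_source, zref)
  } else {
    as.numeric(pdd_source)
  }
  if (!is.finite(pdd) || pdd <= 0 || pdd > 100) {
    stop("PDD(zref) must lie in (0, 100] percent")
  }
  structure(
    list(nominal_energy_mev = nominal_energy_mev,
         r50_cm = as.numeric(r50_cm), zref_cm = zref,
         pdd_at_zref_pct = pdd),
    class = "beam_quality")
}

#' @export
print.beam_quality <- function(x, ...) {
  lab <- if (is.null(x$nominal_energy_mev)) "" else
    sprintf(" (%g MeV)", x$nominal_energy_mev)
  cat(sprintf("<beam_quality>%s R50 = %.3f cm, zref = %.3f cm, PDD(zref) = %.3f%%\n",
              lab, x$r50_cm, x$zref_cm, x$pdd_at_zref_pct))
  invisible(x)
}
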