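#' Ionization chamber specification
#'
#' Bundles everything the calibration pipeline needs to know about one
#' ionization chamber: its absorbed-dose-to-water calibration factor
#' \eqn{N_{D,w}^{Co-60}}, the fitted beam-quality model for the modified
#' protocol, and the geometry used by the positioning rules.
#'
#' @param name Chamber identifier (e.g. `"PTW 30013"`). Registry lookup is
#'   case-insensitive on this key.
#' @param manufacturer Manufacturer name.
#' @param geometry `"cylindrical"` or `"parallel_plate"`.
#' @param nd_w_gy_per_nc Calibration factor \eqn{N_{D,w}^{Co-60}} in Gy/nC;
#'   must be positive.
#' @param fit_model Functional form of the fitted beam-quality factor
#'   \eqn{k_Q'}: `"power"` (\eqn{a + b R_{50}^{-c}}, cylindrical chambers) or
#'   `"exponential"` (\eqn{a + b e^{-R_{50}/c}}, parallel-plate chambers).
#' @param fit_a,fit_b,fit_c Dimensionless fit coefficients.
#' @param fit_rmsd_pct Root-mean-square deviation of the fit, in percent.
#' @param cavity_radius_cm Cavity radius \eqn{r_{cyl}} in cm. Required for
#'   cylindrical chambers (TRS-398 positions the axis \eqn{0.5 r_{cyl}}
#'   beyond the reference depth); must be unset for parallel-plate chambers.
#' @param epom_shift_cm Downstream shift of the effective point of
#'   measurement from the chamber's front reference plane, in cm.
#'   Parallel-plate chambers only; must be >= 0.
#' @param kq_ecal Chamber-specific conversion factor to the reference
#'   electron quality (R50 = 7.5 cm). Ships unset (`NULL`); the modified
#'   protocol refuses to run until the user supplies it — it is never
#'   silently assumed to be 1.
#' @param operating_voltage_v Operating voltage magnitude in volts.
#'
#' @return An object of class `chamber_spec`.
#' @seealso [builtin_registry()], [kq_prime()], [setup_depth()]
#' @export
#' @examples
#' ch <- chamber_spec("PTW 30013", "PTW", "cylindrical",
#'   nd_w_gy_per_nc = 0.05389, fit_model = "power",
#'   fit_a = 0.978, fit_b = 0.112, fit_c = 0.816, fit_rmsd_pct = 0.15,
#'   cavity_radius_cm = 0.305, operating_voltage_v = 400)
#' ch
chamber_spec <- function(name, manufacturer, geometry,
                         nd_w_gy_per_nc, fit_model,
                         fit_a, fit_b, fit_c, fit_rmsd_pct = 0,
                         cavity_radius_cm = NULL, epom_shift_cm = NULL,
                         kq_ecal = NULL, operating_voltage_v = NA_real_) {
  geometry <- match.arg(geometry, c("cylindrical", "parallel_plate"))
  fit_model <- match.arg(fit_model, c("power", "exponential"))
  x <- structure(
    list(
      name = as.character(name),
      manufacturer = as.character(manufacturer),
      geometry = geometry,
      cavity_radius_cm = if (!is.null(cavity_radius_cm)) as.numeric(cavity_radius_cm),
      epom_shift_cm = if (!is.null(epom_shift_cm)) as.numeric(epom_shift_cm),
      nd_w_gy_per_nc = as.numeric(nd_w_gy_per_nc),
      fit_model = fit_model,
      fit_a = as.numeric(fit_a),
      fit_b = as.numeric(fit_b),
      fit_c = as.numeric(fit_c),
      fit_rmsd_pct = as.numeric(fit_rmsd_pct),
      kq_ecal = if (!is.null(kq_ecal)) as.numeric(kq_ecal),
      operating_voltage_v = as.numeric(operating_voltage_v)
    ),
    class = "chamber_spec"
  )
  validate_chamber_spec(x)
}

#' Validate a chamber specification
#'
#' Checks the structural invariants of a [chamber_spec()]: positive
#' calibration factor, non-negative fit RMSD, and geometry-dependent
#' requirements (cylindrical chambers need a positive cavity radius and no
#' EPOM shift; parallel-plate chambers need a non-negative EPOM shift and no
#' cavity radius).
#'
#' @param x A `chamber_spec` object.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_chamber_spec <- function(x) {
  stopifnot(inherits(x, "chamber_spec"))
  if (!nzchar(x$name)) stop("chamber 'name' must be a non-empty string")
  if (!is.finite(x$nd_w_gy_per_nc) || x$nd_w_gy_per_nc <= 0) {
    stop("'nd_w_gy_per_nc' must be a positive calibration factor (Gy/nC)")
  }
  if (!is.finite(x$fit_rmsd_pct) || x$fit_rmsd_pct < 0) {
    stop("'fit_rmsd_pct' must be >= 0")
  }
  for (f in c("fit_a", "fit_b", "fit_c")) {
    if (is.null(x[[f]]) || !is.finite(x[[f]])) {
      stop(sprintf("missing or non-finite fit coefficient '%s'", f))
    }
  }
  if (x$geometry == "cylindrical") {
    if (is.null(x$cavity_radius_cm) || !is.finite(x$cavity_radius_cm) ||
        x$cavity_radius_cm <= 0) {
      stop("cylindrical chamber requires 'cavity_radius_cm' > 0")
    }
    if (!is.null(x$epom_shift_cm)) {
      stop("'epom_shift_cm' must be unset for a cylindrical chamber")
    }
  } else {
    if (is.null(x$epom_shift_cm) || !is.finite(x$epom_shift_cm) ||
        x$epom_shift_cm < 0) {
      stop("parallel-plate chamber requires 'epom_shift_cm' >= 0")
    }
    if (!is.null(x$cavity_radius_cm)) {
      stop("'cavity_radius_cm' must be unset for a parallel-plate chamber")
    }
  }
  if (!is.null(x$kq_ecal) && (!is.finite(x$kq_ecal) || x$kq_ecal <= 0)) {
    stop("'kq_ecal', when set, must be a positive factor")
  }
  x
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber_spec> %s (%s, %s)\n", x$name, x$manufacturer,
              x$geometry))
  cat(sprintf("  N_D,w = %.5f Gy/nC; %s fit (a=%.3f, b=%.3f, c=%.3f, RMSD %.2f%%)\n",
              x$nd_w_gy_per_nc, x$fit_model, x$fit_a, x$fit_b, x$fit_c,
              x$fit_rmsd_pct))
  if (x$geometry == "cylindrical") {
    cat(sprintf("  r_cyl = %.3f cm", x$cavity_radius_cm))
  } else {
    cat(sprintf("  EPOM shift = %.3f cm", x$epom_shift_cm))
  }
  cat(sprintf("; kQ,ecal = %s; V = %s V\n",
              if (is.null(x$kq_ecal)) "<unset>" else format(x$kq_ecal),
              format(x$operating_voltage_v)))
  invisible(x)
}

#' Build a chamber registry
#'
#' A registry is a named collection of [chamber_spec()] objects keyed
#' case-insensitively by chamber name. Duplicate names (up to case) are an
#' error.
#'
#' @param chambers A list of `chamber_spec` objects.
#' @return An object of class `chamber_registry`.
#' @export
chamber_registry <- function(chambers) {
  stopifnot(is.list(chambers))
  for (ch in chambers) validate_chamber_spec(ch)
  keys <- tolower(vapply(chambers, function(ch) ch$name, character(1)))
  if (anyDuplicated(keys)) {
    stop("duplicate chamber name(s) in registry: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  names(chambers) <- vapply(chambers, function(ch) ch$name, character(1))
  structure(list(chambers = chambers), class = "chamber_registry")
}

#' @export
print.chamber_registry <- function(x, ...) {
  cat(sprintf("<chamber_registry> %d chamber(s): %s\n",
              length(x$chambers), paste(names(x$chambers), collapse = ", ")))
  invisible(x)
}

#' @export
length.chamber_registry <- function(x) length(x$chambers)

#' @export
names.chamber_registry <- function(x) names(x$chambers)

#' @export
`[[.chamber_registry` <- function(x, name) {
  hit <- match(tolower(name), tolower(names(x$chambers)))
  if (is.na(hit)) {
    stop(sprintf("chamber '%s' not found in registry (have: %s)",
                 name, paste(names(x$chambers), collapse = ", ")))
  }
  x$chambers[[hit]]
}

#' @export
`[.chamber_registry` <- function(x, name) `[[.chamber_registry`(x, name)

#' Set kQ,ecal values on registry chambers
#'
#' The built-in registry ships with `kq_ecal` unset because chamber-specific
#' values must come from the user's own reference (the modified protocol
#' never assumes 1.0). This helper returns a copy of the registry with the
#' given values filled in.
#'
#' @param registry A [chamber_registry()].
#' @param values Named numeric vector, names matching chamber names
#'   (case-insensitive).
#' @return The updated registry.
#' @export
set_kq_ecal <- function(registry, values) {
  stopifnot(inherits(registry, "chamber_registry"), is.numeric(values),
            !is.null(names(values)))
  keys <- tolower(names(registry$chambers))
  for (nm in names(values)) {
    hit <- match(tolower(nm), keys)
    if (is.na(hit)) stop(sprintf("chamber '%s' not found in registry", nm))
    registry$chambers[[hit]]$kq_ecal <- as.numeric(values[[nm]])
    validate_chamber_spec(registry$chambers[[hit]])
  }
  registry
}

# Fields accepted in registry JSON files; anything else is rejected.
.chamber_fields <- c(
  "name", "manufacturer", "geometry", "cavity_radius_cm", "epom_shift_cm",
  "nd_w_gy_per_nc", "fit_model", "fit_a", "fit_b", "fit_c", "fit_rmsd_pct",
  "kq_ecal", "operating_voltage_v"
)
.chamber_required <- c("name", "manufacturer", "geometry", "nd_w_gy_per_nc",
                       "fit_model", "fit_a", "fit_b", "fit_c")

#' Built-in registry of the four reference chambers
#'
#' Returns the four chambers used throughout the package examples and tests:
#' PTW 30013, IBA CC13 and Exradin A1Sl (cylindrical, power-law kQ' fit) and
#' Exradin A11 (parallel-plate, exponential kQ' fit), with their published
#' calibration factors, fit coefficients, fit RMSDs and operating voltages.
#'
#' Cavity radii are not part of the published calibration data; they are
#' loaded from a geometry defaults file (vendor data-sheet values, clearly
#' flagged as such) that the user may override. `kq_ecal` is left unset and
#' must be supplied (see [set_kq_ecal()]) before the modified protocol can
#' compute a dose.
#'
#' @param geometry_defaults Path to a JSON file supplying cavity radii by
#'   chamber name. Defaults to the file shipped with the package.
#' @return A [chamber_registry()] with four chambers.
#' @export
#' @examples
#' reg <- builtin_registry()
#' reg[["ptw 30013"]]$nd_w_gy_per_nc
builtin_registry <- function(geometry_defaults = system.file(
                               "extdata", "chamber_geometry_defaults.json",
                               package = "ebcal")) {
  geo <- jsonlite::fromJSON(geometry_defaults)
  radii <- geo$cavity_radius_cm
  chamber_registry(list(
    chamber_spec("PTW 30013", "PTW", "cylindrical",
                 nd_w_gy_per_nc = 0.05389, fit_model = "power",
                 fit_a = 0.978, fit_b = 0.112, fit_c = 0.816,
                 fit_rmsd_pct = 0.15,
                 cavity_radius_cm = radii[["PTW 30013"]],
                 operating_voltage_v = 400),
    chamber_spec("IBA CC13", "IBA", "cylindrical",
                 nd_w_gy_per_nc = 0.271, fit_model = "power",
                 fit_a = 0.926, fit_b = 0.129, fit_c = 0.279,
                 fit_rmsd_pct = 0.10,
                 cavity_radius_cm = radii[["IBA CC13"]],
                 operating_voltage_v = 300),
    chamber_spec("Exradin A1Sl", "Exradin", "cylindrical",
                 nd_w_gy_per_nc = 0.6033, fit_model = "power",
                 fit_a = 0.205, fit_b = 0.854, fit_c = 0.036,
                 fit_rmsd_pct = 0.13,
                 cavity_radius_cm = radii[["Exradin A1Sl"]],
                 operating_voltage_v = 300),
    chamber_spec("Exradin A11", "Exradin", "parallel_plate",
                 nd_w_gy_per_nc = 0.05026, fit_model = "exponential",
                 fit_a = 0.992, fit_b = 0.114, fit_c = 2.864,
                 fit_rmsd_pct = 0.13,
                 epom_shift_cm = 0.177,
                 operating_voltage_v = 300)
  ))
}

#' Load a chamber registry from a JSON file
#'
#' The file holds a top-level `chambers` array with one object per chamber,
#' fields mirroring [chamber_spec()] (lengths in cm, `nd_w_gy_per_nc` in
#' Gy/nC). Unknown fields are rejected, missing required fields are reported
#' by name, and every record is validated.
#'
#' @param path Path to the registry JSON file.
#' @return A [chamber_registry()].
#' @seealso [save_registry()] for the inverse; `save(load(x))` round-trips.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop(sprintf("registry file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$chambers)) stop("registry file must have a 'chambers' array")
  chambers <- lapply(raw$chambers, function(rec) {
    unknown <- setdiff(names(rec), .chamber_fields)
    if (length(unknown)) {
      stop(sprintf("unknown chamber field(s): %s",
                   paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(.chamber_required, names(rec))
    if (length(missing)) {
      stop(sprintf("chamber record missing required field(s): %s",
                   paste(missing, collapse = ", ")))
    }
    chamber_spec(
      name = rec$name, manufacturer = rec$manufacturer,
      geometry = rec$geometry,
      nd_w_gy_per_nc = rec$nd_w_gy_per_nc, fit_model = rec$fit_model,
      fit_a = rec$fit_a, fit_b = rec$fit_b, fit_c = rec$fit_c,
      fit_rmsd_pct = if (is.null(rec$fit_rmsd_pct)) 0 else rec$fit_rmsd_pct,
      cavity_radius_cm = rec$cavity_radius_cm,
      epom_shift_cm = rec$epom_shift_cm,
      kq_ecal = rec$kq_ecal,
      operating_voltage_v = if (is.null(rec$operating_voltage_v)) {
        NA_real_
      } else {
        rec$operating_voltage_v
      }
    )
  })
  chamber_registry(chambers)
}

#' Save a chamber registry to a JSON file
#'
#' Writes the registry in the format read by [load_registry()];
#' `load_registry(save_registry(x, path))` reproduces `x` exactly.
#'
#' @param registry A [chamber_registry()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  stopifnot(inherits(registry, "chamber_registry"))
  recs <- lapply(registry$chambers, function(ch) {
    ch <- unclass(ch)
    ch[!vapply(ch, is.null, logical(1))]
  })
  names(recs) <- NULL
  jsonlite::write_json(list(chambers = recs), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
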