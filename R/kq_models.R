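#' Fitted beam-quality factor, power-law form
#'
#' \eqn{k_Q' = a + b \, R_{50}^{-c}} — the fitted form used for cylindrical
#' chambers in the modified calibration. The fit implicitly includes gradient
#' effects, so no explicit gradient correction is applied when the chamber
#' sits at the reference depth.
#'
#' @param a,b,c Dimensionless fit coefficients.
#' @param r50_cm Beam-quality index R50 in cm (> 0).
#' @return kQ' at full precision.
#' @export
#' @examples
#' kq_prime_power(0.978, 0.112, 0.816, 2.37) # ~1.033
kq_prime_power <- function(a, b, c, r50_cm) {
  if (any(r50_cm <= 0)) stop("'r50_cm' must be positive")
  a + b * r50_cm^(-c)
}

#' Fitted beam-quality factor, exponential form
#'
#' \eqn{k_Q' = a + b \, e^{-R_{50}/c}} — the fitted form used for
#' parallel-plate chambers in the modified calibration.
#'
#' @param a,b,c Dimensionless fit coefficients; `c` must be positive.
#' @param r50_cm Beam-quality index R50 in cm (> 0).
#' @return kQ' at full precision.
#' @export
#' @examples
#' kq_prime_exponential(0.992, 0.114, 2.864, 2.37) # ~1.042
kq_prime_exponential <- function(a, b, c, r50_cm) {
  if (c <= 0) stop("'c' must be positive for the exponential form")
  if (any(r50_cm <= 0)) stop("'r50_cm' must be positive")
  a + b * exp(-r50_cm / c)
}

kq_result <- function(value, method, rmsd_pct = NA_real_) {
  method <- match.arg(method,
                      c("fit_power", "fit_exponential", "table_interpolation"))
  if (!is.finite(value) || value <= 0) {
    stop("beam-quality factor must be positive")
  }
  structure(list(value = value, method = method, rmsd_pct = rmsd_pct),
            class = "kq_result")
}

#' @export
print.kq_result <- function(x, ...) {
  cat(sprintf("<kq_result> %.5f (%s%s)\n", x$value, x$method,
              if (is.finite(x$rmsd_pct))
                sprintf(", fit RMSD %.2f%%", x$rmsd_pct) else ""))
  invisible(x)
}

#' Fitted kQ' for a chamber
#'
#' Dispatches on the chamber's `fit_model`: power-law
#' ([kq_prime_power()]) for cylindrical chambers, exponential
#' ([kq_prime_exponential()]) for parallel-plate chambers. The chamber's fit
#' RMSD is carried along as metadata.
#'
#' @param chamber A [chamber_spec()] with fit coefficients.
#' @param r50_cm Beam-quality index R50 in cm.
#' @return A `kq_result` with `method` `"fit_power"` or `"fit_exponential"`.
#' @export
#' @examples
#' kq_prime(builtin_registry()[["Exradin A11"]], 5.955)
kq_prime <- function(chamber, r50_cm) {
  stopifnot(inherits(chamber, "chamber_spec"))
  value <- switch(chamber$fit_model,
    power = kq_prime_power(chamber$fit_a, chamber$fit_b, chamber$fit_c,
                           r50_cm),
    exponential = kq_prime_exponential(chamber$fit_a, chamber$fit_b,
                                       chamber$fit_c, r50_cm))
  kq_result(value,
            method = if (chamber$fit_model == "power") "fit_power"
                     else "fit_exponential",
            rmsd_pct = chamber$fit_rmsd_pct)
}

#' Beam-quality factor lookup table
#'
#' Holds kQ,Qo grid values per chamber as a function of R50, for the
#' standard-protocol interpolation. Within each chamber the R50 grid must be
#' strictly increasing and values must lie in (0.8, 1.1).
#'
#' @param entries Data frame with columns `chamber`, `r50_cm`, `kq_qo`.
#' @param provenance Free-text description of where the grid values come
#'   from (e.g. the user's own transcription of the code-of-practice table).
#' @return An object of class `kq_table`.
#' @export
kq_table <- function(entries, provenance = "user supplied") {
  entries <- as.data.frame(entries)
  need <- c("chamber", "r50_cm", "kq_qo")
  if (!all(need %in% names(entries))) {
    stop("kq table needs columns: chamber, r50_cm, kq_qo")
  }
  entries <- entries[order(entries$chamber, entries$r50_cm), need]
  rownames(entries) <- NULL
  for (ch in unique(entries$chamber)) {
    r <- entries$r50_cm[entries$chamber == ch]
    if (any(diff(r) <= 0)) {
      stop(sprintf("non-monotone or duplicate r50_cm grid for chamber '%s'", ch))
    }
  }
  if (any(entries$kq_qo <= 0.8 | entries$kq_qo >= 1.1)) {
    stop("kq_qo values must lie in (0.8, 1.1)")
  }
  structure(list(entries = entries, provenance = as.character(provenance)),
            class = "kq_table")
}

#' @export
print.kq_table <- function(x, ...) {
  cat(sprintf("<kq_table> %d chamber(s), %d grid points [%s]\n",
              length(unique(x$entries$chamber)), nrow(x$entries),
              x$provenance))
  invisible(x)
}

#' Load a kQ,Qo table from CSV
#'
#' CSV columns: `chamber`, `r50_cm`, `kq_qo`. The grid is grouped by
#' chamber, sorted and validated (strictly increasing R50 per chamber).
#'
#' @param path CSV file path.
#' @param provenance Provenance string to attach; defaults to the file path.
#' @return A [kq_table()].
#' @export
load_kq_table <- function(path, provenance = path) {
  if (!file.exists(path)) stop(sprintf("kq table file not found: %s", path))
  kq_table(utils::read.csv(path), provenance = provenance)
}

#' Save a kQ,Qo table to CSV
#' @param table A [kq_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_kq_table <- function(table, path) {
  stopifnot(inherits(table, "kq_table"))
  utils::write.csv(table$entries, path, row.names = FALSE)
  invisible(path)
}

#' Table-interpolated beam-quality factor kQ,Qo
#'
#' Standard-protocol beam-quality factor by linear interpolation in R50
#' between the bracketing grid points of the chamber's table entry; exact at
#' grid points. An R50 outside the chamber's tabulated range is not
#' determinable under the standard protocol (cylindrical-chamber tables do
#' not extend to low-energy beams) and raises an error rather than
#' extrapolating.
#'
#' Chambers absent from the table can be mapped to a tabulated surrogate via
#' `aliases` (e.g. `c("Exradin A1Sl" = "Exradin A1")`); matching is
#' case-insensitive.
#'
#' @param table A [kq_table()].
#' @param chamber_key Chamber name to look up.
#' @param r50_cm Beam-quality index R50 in cm.
#' @param aliases Optional named character vector mapping chamber names to
#'   the table keys of their surrogates.
#' @return A `kq_result` with `method = "table_interpolation"`.
#' @export
kq_trs398 <- function(table, chamber_key, r50_cm, aliases = NULL) {
  stopifnot(inherits(table, "kq_table"))
  key <- chamber_key
  if (!is.null(aliases)) {
    hit <- match(tolower(key), tolower(names(aliases)))
    if (!is.na(hit)) key <- aliases[[hit]]
  }
  rows <- table$entries[tolower(table$entries$chamber) == tolower(key), ]
  if (nrow(rows) == 0L) {
    stop(sprintf("chamber '%s' not present in kQ,Qo table", chamber_key))
  }
  r <- rows$r50_cm
  k <- rows$kq_qo
  if (r50_cm < min(r) || r50_cm > max(r)) {
    stop(sprintf(
      "kQ,Qo for '%s' not determinable under TRS-398: R50 = %.3f cm outside tabulated range [%.3f, %.3f]",
      chamber_key, r50_cm, min(r), max(r)))
  }
  # bracketing-interval linear interpolation, exact at grid points
  i <- findInterval(r50_cm, r, rightmost.closed = TRUE)
  value <- if (r50_cm == r[i]) {
    k[i]
  } else {
    k[i] + (k[i + 1] - k[i]) * (r50_cm - r[i]) / (r[i + 1] - r[i])
  }
  kq_result(value, method = "table_interpolation")
}
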