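#' @section Units:
#' All delta values are handled in per mil (permil) at the user-facing
#' surface and converted to dimensionless ratio space in exactly one place
#' ([delta_to_ratio_factor()]); downstream code never divides by 1000 again.
#' @name units
#' @keywords internal
NULL

# compounds the assay design covers; TCE appears as an intermediate but
# carries no position-parameter registry entries
CSIA_COMPOUNDS <- c("PCE", "TCE", "cDCE", "VC", "1,2-DCA")

CSIA_ELEMENTS <- c("C", "Cl")

.default_reference <- function(element) {
  switch(element, C = "VPDB", Cl = "SMOC")
}

#' Create a delta value with element and reference standard
#'
#' Represents one isotope-ratio measurement in delta notation: the per-mil
#' deviation of the sample ratio (13C/12C or 37Cl/35Cl) from an
#' international reference standard, V-PDB for carbon and the SMOC-anchored
#' laboratory scale for chlorine. The reference is determined by the
#' element; supplying a conflicting reference is an error.
#'
#' @param value delta in permil; must exceed -1000 (the isotope ratio must
#'   stay positive).
#' @param element `"C"` or `"Cl"`.
#' @param reference optional standard name; defaults to `"VPDB"` for carbon
#'   and `"SMOC"` for chlorine.
#' @return An object of class `delta_value`.
#' @examples
#' delta_value(-27.5, "C")
#' @export
delta_value <- function(value, element = c("C", "Cl"), reference = NULL) {
  element <- match.arg(element)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value) || value <= -1000) {
    stop("invalid isotopic composition: delta must be > -1000 permil",
         call. = FALSE)
  }
  expected <- .default_reference(element)
  if (is.null(reference)) {
    reference <- expected
  } else if (!identical(reference, expected)) {
    stop(sprintf("reference '%s' does not match element %s (expected '%s')",
                 reference, element, expected), call. = FALSE)
  }
  structure(list(value = value, element = element, reference = reference),
            class = "delta_value")
}

#' @export
print.delta_value <- function(x, ...) {
  cat(sprintf("delta %s = %+.2f permil (vs %s)\n",
              x$element, x$value, x$reference))
  invisible(x)
}

#' Convert delta notation to an isotope-ratio multiplier
#'
#' R = 1 + delta, with delta expressed as a fraction: a sample at
#' delta = -27.5 permil has an isotope ratio 0.9725 times the reference.
#' This is the single permil-to-fraction boundary in the package.
#'
#' @param delta numeric vector of delta values in permil, or a
#'   [delta_value].
#' @return Dimensionless strictly positive ratio multiplier(s).
#' @seealso [ratio_factor_to_delta()] for the inverse.
#' @export
delta_to_ratio_factor <- function(delta) {
  if (inherits(delta, "delta_value")) delta <- delta$value
  stopifnot(is.numeric(delta))
  if (any(is.finite(delta) & delta <= -1000)) {
    stop("invalid isotopic composition: delta must be > -1000 permil",
         call. = FALSE)
  }
  1 + delta / 1000
}

#' Inverse of [delta_to_ratio_factor()]
#'
#' @param ratio dimensionless positive ratio multiplier(s).
#' @return Delta in permil.
#' @export
ratio_factor_to_delta <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(is.finite(ratio) & ratio <= 0)) {
    stop("ratio multiplier must be strictly positive", call. = FALSE)
  }
  (ratio - 1) * 1000
}

#' Fraction of substrate remaining
#'
#' f = C_t / C_0, the residual electron-acceptor concentration relative to
#' the initial concentration. Values above 1 can arise from measurement
#' noise near the start of an assay; they are returned with a warning
#' rather than rejected.
#'
#' @param c_t residual concentration(s) at sampling time t; same units as
#'   `c_0`.
#' @param c_0 initial concentration; must be positive.
#' @return Dimensionless fraction remaining.
#' @examples
#' fraction_remaining(250, 500)  # 0.5
#' @export
fraction_remaining <- function(c_t, c_0) {
  stopifnot(is.numeric(c_t), is.numeric(c_0))
  if (any(!is.finite(c_0)) || any(c_0 <= 0)) {
    stop("initial concentration c_0 must be positive", call. = FALSE)
  }
  if (any(is.finite(c_t) & c_t < 0)) {
    stop("residual concentration c_t must be non-negative", call. = FALSE)
  }
  f <- c_t / c_0
  if (any(is.finite(f) & f > 1)) {
    warning("fraction remaining > 1 (measurement noise?); value returned",
            call. = FALSE)
  }
  f
}

#' Assemble an experiment series (one assay "set")
#'
#' One series corresponds to one sacrificial-vial fractionation assay: a
#' given substrate degraded by resting cells of a given cultivation
#' history, with vials sacrificed across a range of fractions remaining and
#' isotope ratios measured in replicate.
#'
#' The initial isotopic composition (delta0) can be given explicitly or is
#' taken as the mean of measurements at `f == 1` (reference vials).
#'
#' @param compound substrate identity, one of PCE, TCE, cDCE, VC, 1,2-DCA.
#' @param cultivation_acceptor electron acceptor the inoculum was grown on.
#' @param f fraction remaining per measurement, in (0, 1] (values slightly
#'   above 1 are tolerated with a warning).
#' @param delta_c,delta_cl delta 13C / delta 37Cl in permil per measurement;
#'   `delta_cl` may be `NULL`/`NA` for carbon-only series.
#' @param sd_c,sd_cl replicate standard deviations in permil (>= 0).
#' @param vial_id,replicate optional identifiers; generated if missing.
#' @param delta0_c,delta0_cl initial composition in permil; required unless
#'   derivable from `f == 1` rows.
#' @param series_id label used in reports and file output.
#' @return An object of class `experiment_series` with a `measurements`
#'   data frame and the initial compositions.
#' @export
experiment_series <- function(compound, cultivation_acceptor = compound,
                              f, delta_c, delta_cl = NULL,
                              sd_c = NA_real_, sd_cl = NA_real_,
                              vial_id = NULL, replicate = NULL,
                              delta0_c = NULL, delta0_cl = NULL,
                              series_id = NULL) {
  compound <- match.arg(compound, CSIA_COMPOUNDS)
  n <- length(f)
  stopifnot(is.numeric(f), n >= 1L)
  if (is.null(delta_cl)) delta_cl <- rep(NA_real_, n)
  stopifnot(length(delta_c) == n, length(delta_cl) == n)
  if (length(sd_c) == 1L) sd_c <- rep(sd_c, n)
  if (length(sd_cl) == 1L) sd_cl <- rep(sd_cl, n)
  if (any(!is.na(sd_c) & sd_c < 0) || any(!is.na(sd_cl) & sd_cl < 0)) {
    stop("replicate standard deviations must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("fraction remaining must be finite and > 0", call. = FALSE)
  }
  if (any(f > 1)) {
    warning("series contains f > 1 (tolerated, flagged by validate_series)",
            call. = FALSE)
  }
  if (all(is.na(delta_c)) && all(is.na(delta_cl))) {
    stop("at least one element must carry delta values", call. = FALSE)
  }
  if (is.null(vial_id)) vial_id <- sprintf("vial%02d", seq_len(n))
  if (is.null(replicate)) replicate <- rep(1L, n)
  meas <- data.frame(
    vial_id = as.character(vial_id),
    replicate = as.integer(replicate),
    f = as.numeric(f),
    delta_c = as.numeric(delta_c),
    delta_cl = as.numeric(delta_cl),
    sd_c = as.numeric(sd_c),
    sd_cl = as.numeric(sd_cl),
    stringsAsFactors = FALSE
  )
  ref <- meas$f == 1
  if (is.null(delta0_c) && any(ref & !is.na(meas$delta_c))) {
    delta0_c <- mean(meas$delta_c[ref], na.rm = TRUE)
  }
  if (is.null(delta0_cl) && any(ref & !is.na(meas$delta_cl))) {
    delta0_cl <- mean(meas$delta_cl[ref], na.rm = TRUE)
  }
  if (is.null(series_id)) {
    series_id <- sprintf("%s_on_%s", compound, cultivation_acceptor)
  }
  structure(list(
    series_id = series_id,
    compound = compound,
    cultivation_acceptor = cultivation_acceptor,
    measurements = meas,
    delta0_c = if (is.null(delta0_c)) NA_real_ else as.numeric(delta0_c),
    delta0_cl = if (is.null(delta0_cl)) NA_real_ else as.numeric(delta0_cl)
  ), class = "experiment_series")
}

#' @export
print.experiment_series <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("experiment_series '%s': %s degraded by %s-grown cells\n",
              x$series_id, x$compound, x$cultivation_acceptor))
  cat(sprintf("  %d measurements, f in [%.3g, %.3g]; delta0_C = %s, delta0_Cl = %s permil\n",
              nrow(m), min(m$f), max(m$f),
              formatC(x$delta0_c, format = "fg"),
              formatC(x$delta0_cl, format = "fg")))
  invisible(x)
}

#' Validate an experiment series
#'
#' Report-only quality screen applied before regression: flags series with
#' too few points, fractions remaining outside (0, 1], measurements
#' carrying neither element, missing initial composition, and duplicated
#' vial/replicate identifiers. The series is never modified.
#'
#' @param series an [experiment_series].
#' @return A data frame with columns `severity` (`"error"`/`"warning"`),
#'   `code`, and `message`; zero rows when the series is clean.
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "experiment_series"))
  m <- series$measurements
  out <- list()
  add <- function(severity, code, message) {
    out[[length(out) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      stringsAsFactors = FALSE)
  }
  if (nrow(m) < 3L) {
    add("error", "too_few_points",
        sprintf("insufficient points for regression (%d < 3)", nrow(m)))
  }
  bad_f <- which(!is.finite(m$f) | m$f <= 0)
  for (i in bad_f) {
    add("error", "f_out_of_range",
        sprintf("vial %s: f = %s outside (0, 1]", m$vial_id[i], m$f[i]))
  }
  over_f <- which(is.finite(m$f) & m$f > 1)
  for (i in over_f) {
    add("warning", "f_above_one",
        sprintf("vial %s: f = %s > 1 (measurement noise?)",
                m$vial_id[i], m$f[i]))
  }
  no_element <- which(is.na(m$delta_c) & is.na(m$delta_cl))
  for (i in no_element) {
    add("error", "no_element",
        sprintf("vial %s: neither delta 13C nor delta 37Cl present",
                m$vial_id[i]))
  }
  if (is.na(series$delta0_c) && any(!is.na(m$delta_c))) {
    add("warning", "missing_delta0",
        "no initial delta 13C (delta0_c); Rayleigh fit will fail")
  }
  if (is.na(series$delta0_cl) && any(!is.na(m$delta_cl))) {
    add("warning", "missing_delta0",
        "no initial delta 37Cl (delta0_cl); Rayleigh fit will fail")
  }
  key <- paste(m$vial_id, m$replicate)
  dup <- unique(key[duplicated(key)])
  for (k in dup) {
    add("warning", "duplicate_measurement",
        sprintf("duplicated vial/replicate identifier '%s'", k))
  }
  if (length(out) == 0L) {
    return(data.frame(severity = character(), code = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
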