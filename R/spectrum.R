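#' Construct an infrared spectrum
#'
#' A spectrum is a wavenumber-indexed absorbance trace. The wavenumber axis
#' must be strictly monotonic; it is stored ascending regardless of the input
#' direction (the original direction is kept in the object's metadata so file
#' round trips are faithful).
#'
#' @param wavenumbers numeric vector of wavenumbers (cm^-1), strictly
#'   monotonic in either direction, length >= 2.
#' @param absorbance numeric vector of absorbances (AU), same length, finite.
#' @param timestamp acquisition time in seconds from an arbitrary origin.
#' @param resolution nominal instrument resolution (cm^-1), optional.
#' @param label free-text label.
#' @return an object of class `ir_spectrum` with fields `wavenumbers`,
#'   `absorbance`, `timestamp`, `resolution`, `label`, `meta`.
#' @examples
#' s <- ir_spectrum(c(1000, 1001, 1002), c(0.1, 0.2, 0.15))
#' @export
ir_spectrum <- function(wavenumbers, absorbance, timestamp = NA_real_,
                        resolution = NULL, label = "") {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    abort("wavenumbers and absorbance must have equal length", "atmcorr_shape_error")
  if (length(wavenumbers) < 2)
    abort("a spectrum needs at least 2 points", "atmcorr_too_short_error")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance)))
    abort("spectrum values must be finite", "atmcorr_value_error")
  d <- diff(wavenumbers)
  direction <- "ascending"
  if (all(d > 0)) {
    # already ascending
  } else if (all(d < 0)) {
    direction <- "descending"
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else {
    abort("wavenumber axis must be strictly monotonic", "atmcorr_axis_error")
  }
  structure(
    list(
      wavenumbers = wavenumbers,
      absorbance = absorbance,
      timestamp = as.numeric(timestamp),
      resolution = resolution,
      label = as.character(label),
      meta = list(original_direction = direction)
    ),
    class = "ir_spectrum"
  )
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ir_spectrum> %d points, %.6g to %.6g cm-1%s%s\n",
    length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
    if (!is.na(x$timestamp)) sprintf(", t = %gs", x$timestamp) else "",
    if (nzchar(x$label)) paste0(", '", x$label, "'") else ""
  ))
  invisible(x)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

#' Construct a wavenumber region
#'
#' Regions are closed intervals on the wavenumber axis, given as
#' `lo` to `hi` in cm^-1 and mapped to index ranges by the nearest axis
#' point (inclusive at both ends).
#'
#' @param lo,hi region bounds in cm^-1, `lo < hi`.
#' @return an object of class `wn_region`.
#' @examples
#' wn_region(1205, 2072)
#' @export
wn_region <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    abort("region requires finite lo < hi", "atmcorr_region_error")
  structure(list(lo = lo, hi = hi), class = "wn_region")
}

#' @export
print.wn_region <- function(x, ...) {
  cat(sprintf("<wn_region> %g to %g cm-1\n", x$lo, x$hi)); invisible(x)
}

#' Describe an atmospheric interferent and its correction regions
#'
#' An interferent (e.g. the water-vapor bending band) is corrected over
#' `correct_region`. When an intense analyte band contaminates that region,
#' the scaling factor can instead be estimated over `gamma_region`, an
#' alternative region where the same gas absorbs but the analyte does not;
#' the factor found there is transferred to `correct_region`.
#'
#' @param name free-text interferent name, e.g. `"H2O-bend"`.
#' @param correct_region a [wn_region] in which the correction is applied.
#' @param gamma_region optional [wn_region] used only to estimate the scaling
#'   factor; defaults to `correct_region`. Must belong to the same physical
#'   interferent (caller's responsibility).
#' @return an object of class `interferent_spec`.
#' @examples
#' interferent_spec("H2O-bend", wn_region(1205, 2072),
#'                  gamma_region = wn_region(3231, 4000))
#' @export
interferent_spec <- function(name, correct_region, gamma_region = NULL) {
  stopifnot(inherits(correct_region, "wn_region"))
  if (!is.null(gamma_region)) stopifnot(inherits(gamma_region, "wn_region"))
  structure(
    list(name = as.character(name), correct_region = correct_region,
         gamma_region = gamma_region),
    class = "interferent_spec"
  )
}

#' Default atmospheric interferent set
#'
#' The mid-infrared regions in which water vapor and CO2 absorb, in the
#' order they are processed (each correction acts on the output of the
#' previous one; the CO2 combination bands lying inside the broad water
#' stretching region are handled after it).
#'
#' @return list of [interferent_spec] objects.
#' @export
default_interferents <- function() {
  path <- system.file("extdata", "interferents.json", package = "atmcorr")
  read_interferent_config(path)
}

#' Map a region to axis indices and extract the segment
#'
#' The region bounds are mapped to the nearest axis points; the returned
#' index range is inclusive. Bounds outside the axis span clamp to the ends
#' via the nearest-point rule, but a region wholly outside the span is an
#' error, as is a segment of fewer than 3 points.
#'
#' @param s an [ir_spectrum].
#' @param r a [wn_region].
#' @return list with `idx` (integer `c(i_lo, i_hi)`, 1-based inclusive) and
#'   `spectrum` (the segment as an `ir_spectrum`).
#' @export
slice_region <- function(s, r) {
  stopifnot(inherits(s, "ir_spectrum"), inherits(r, "wn_region"))
  w <- s$wavenumbers
  if (r$hi < w[1] || r$lo > w[length(w)])
    abort(sprintf("region [%g, %g] lies outside the axis span [%g, %g]",
                  r$lo, r$hi, w[1], w[length(w)]),
          "atmcorr_range_error")
  i_lo <- which.min(abs(w - r$lo))
  i_hi <- which.min(abs(w - r$hi))
  if (i_hi - i_lo + 1 < 3)
    abort(sprintf("region [%g, %g] maps to fewer than 3 axis points", r$lo, r$hi),
          "atmcorr_too_short_error")
  seg <- ir_spectrum(w[i_lo:i_hi], s$absorbance[i_lo:i_hi],
                     timestamp = s$timestamp, resolution = s$resolution,
                     label = s$label)
  list(idx = c(i_lo, i_hi), spectrum = seg)
}

#' Construct an ordered series of replicate spectra
#'
#' All spectra must share a bitwise-identical wavenumber axis (after the
#' ascending normalization) and have strictly increasing timestamps. The
#' correction subtracts spectra point by point, so no resampling is ever
#' performed; mismatched axes are an error.
#'
#' @param spectra list of [ir_spectrum] objects in acquisition order.
#' @param sample_id free-text sample identifier.
#' @return an object of class `ir_series`.
#' @export
ir_series <- function(spectra, sample_id = "") {
  if (length(spectra) == 0)
    abort("empty series", "atmcorr_empty_series_error")
  for (s in spectra) stopifnot(inherits(s, "ir_spectrum"))
  out <- structure(list(spectra = spectra, sample_id = as.character(sample_id)),
                   class = "ir_series")
  assert_common_axis(out)
  ts <- vapply(spectra, function(s) s$timestamp, numeric(1))
  if (length(ts) > 1 && !all(is.na(ts))) {
    if (any(is.na(ts)) || any(diff(ts) <= 0))
      abort("series timestamps must be strictly increasing",
            "atmcorr_timestamp_error")
  }
  out
}

#' @export
print.ir_series <- function(x, ...) {
  cat(sprintf("<ir_series> %d spectra x %d points%s\n",
              length(x$spectra), length(x$spectra[[1]]$wavenumbers),
              if (nzchar(x$sample_id)) paste0(", sample '", x$sample_id, "'") else ""))
  invisible(x)
}

#' @export
length.ir_series <- function(x) length(x$spectra)

#' Assert that all spectra of a series share one axis
#'
#' @param series an [ir_series] (or plain list of spectra).
#' @return invisibly `TRUE`; raises on the first mismatch, naming the
#'   offending spectrum and axis index.
#' @export
assert_common_axis <- function(series) {
  spectra <- if (inherits(series, "ir_series")) series$spectra else series
  if (length(spectra) == 0)
    abort("empty series", "atmcorr_empty_series_error")
  ref <- spectra[[1]]$wavenumbers
  for (k in seq_along(spectra)) {
    w <- spectra[[k]]$wavenumbers
    if (length(w) != length(ref) || !identical(as.numeric(w), as.numeric(ref))) {
      i <- if (length(w) == length(ref)) which(w != ref)[1] else NA_integer_
      abort(sprintf(
        "axis mismatch: spectrum %d differs from spectrum 1%s",
        k, if (!is.na(i)) sprintf(" first at index %d (%.9g vs %.9g)", i, w[i], ref[i]) else " (different length)"
      ), "atmcorr_axis_error")
    }
  }
  invisible(TRUE)
}

axis_spacing <- function(s) {
  d <- diff(s$wavenumbers)
  mean(d)
}
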