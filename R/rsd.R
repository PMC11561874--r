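#' Per-wavenumber standard deviation across replicates
#'
#' Sample (n-1 denominator) standard deviation across the replicate spectra
#' of a series at each axis point of a region.
#'
#' @param series an [ir_series] of >= 3 replicates on a common axis.
#' @param r a [wn_region].
#' @return numeric vector of standard deviations (AU), one per axis point
#'   in the region, with the wavenumbers as names-free attribute
#'   `wavenumbers`.
#' @export
pointwise_std <- function(series, r) {
  stopifnot(inherits(series, "ir_series"))
  if (length(series$spectra) < 3)
    abort("pointwise standard deviation needs at least 3 replicates",
          "atmcorr_sample_size_error")
  sl <- slice_region(series$spectra[[1]], r)
  i <- sl$idx
  mat <- vapply(series$spectra, function(s) s$absorbance[i[1]:i[2]],
                numeric(i[2] - i[1] + 1))
  out <- apply(mat, 1, stats::sd)
  attr(out, "wavenumbers") <- series$spectra[[1]]$wavenumbers[i[1]:i[2]]
  out
}

#' Relative standard deviation profile of a replicate series
#'
#' The RSD at a wavenumber is the standard deviation across replicates at
#' that point divided by the mean standard deviation over a reference region
#' devoid of spectral features (neither analyte nor atmospheric
#' absorptions), which baselines the metric against instrument noise and
#' experimental drift. An RSD close to 1 throughout an atmospheric
#' absorption region indicates that only noise and drift remain — i.e. a
#' successful correction; fluctuating interferent absorptions drive it far
#' above 1.
#'
#' "Mean standard deviation" is the arithmetic mean over the reference
#' region's wavenumbers of the per-wavenumber sample standard deviation.
#'
#' @param series an [ir_series] of >= 3 replicates.
#' @param target [wn_region] to profile — conventionally 1200-2100 cm^-1
#'   for water vapor or 2300-2400 cm^-1 for CO2.
#' @param reference feature-free [wn_region]; conventionally 4800-5000
#'   cm^-1.
#' @return an object of class `rsd_profile`: `wavenumbers`, `rsd`,
#'   `reference_region`, `reference_mean_std`.
#' @export
rsd_profile <- function(series, target = wn_region(1200, 2100),
                        reference = wn_region(4800, 5000)) {
  ref_std <- pointwise_std(series, reference)
  m <- mean(ref_std)
  if (!is.finite(m) || m <= 0)
    abort(paste0(
      "reference region has zero mean standard deviation: replicates are ",
      "identical there (noiseless synthetic data?); the RSD is undefined"),
      "atmcorr_degenerate_reference_error")
  tgt_std <- pointwise_std(series, target)
  structure(
    list(wavenumbers = attr(tgt_std, "wavenumbers"),
         rsd = as.numeric(tgt_std) / m,
         reference_region = reference,
         reference_mean_std = m),
    class = "rsd_profile"
  )
}

#' @export
print.rsd_profile <- function(x, ...) {
  cat(sprintf("<rsd_profile> %d points, median RSD = %.3g (reference mean std %.3g AU)\n",
              length(x$rsd), stats::median(x$rsd), x$reference_mean_std))
  invisible(x)
}

#' Summarize an RSD profile
#' @param object an `rsd_profile`.
#' @param ... unused.
#' @return list with `median`, `mean`, `max`.
#' @export
summary.rsd_profile <- function(object, ...) {
  list(median = stats::median(object$rsd),
       mean = mean(object$rsd),
       max = max(object$rsd))
}
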