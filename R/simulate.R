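#' Construct a comb of vapor-phase absorption lines
#'
#' Stand-in for the rotational fine structure of an atmospheric gas band:
#' a set of narrow Lorentzian lines (pressure-broadened rotational
#' transitions) at fixed centers with fixed relative intensities. The comb
#' is the time-independent interferent basis; only its multiplying
#' coefficient varies from scan to scan.
#'
#' @param centers line centers (cm^-1).
#' @param intensities peak absorbances (AU) at unit coefficient, >= 0.
#' @param fwhm full width at half maximum per line (cm^-1), > 0.
#' @param lineshape `"lorentzian"` (pressure-broadened, the default) or
#'   `"gaussian"` (Doppler-limited; tails vanish fast, useful when the
#'   basis must be negligible at region boundaries).
#' @return an object of class `line_comb`.
#' @export
line_comb <- function(centers, intensities, fwhm,
                      lineshape = c("lorentzian", "gaussian")) {
  centers <- as.numeric(centers); intensities <- as.numeric(intensities)
  lineshape <- match.arg(lineshape)
  if (length(centers) != length(intensities))
    abort("centers and intensities must have equal length", "atmcorr_shape_error")
  if (any(intensities < 0)) abort("intensities must be >= 0", "atmcorr_value_error")
  if (!is.finite(fwhm) || fwhm <= 0) abort("fwhm must be > 0", "atmcorr_value_error")
  structure(list(centers = centers, intensities = intensities, fwhm = fwhm,
                 lineshape = lineshape),
            class = "line_comb")
}

#' Render a line comb on a wavenumber axis
#'
#' Sum of Lorentzian profiles; an isolated line's peak equals its intensity
#' up to discretization error.
#'
#' @param comb a [line_comb].
#' @param wavenumbers numeric axis (cm^-1).
#' @return numeric vector of absorbances (AU) at unit coefficient.
#' @export
render_comb <- function(comb, wavenumbers) {
  stopifnot(inherits(comb, "line_comb"))
  y <- numeric(length(wavenumbers))
  if (identical(comb$lineshape %||% "lorentzian", "gaussian")) {
    k <- 4 * log(2)
    for (j in seq_along(comb$centers)) {
      y <- y + comb$intensities[j] *
        exp(-k * (wavenumbers - comb$centers[j])^2 / comb$fwhm^2)
    }
  } else {
    hw2 <- (comb$fwhm / 2)^2
    for (j in seq_along(comb$centers)) {
      y <- y + comb$intensities[j] * hw2 /
        ((wavenumbers - comb$centers[j])^2 + hw2)
    }
  }
  y
}

#' Render condensed-phase analyte bands on a wavenumber axis
#'
#' Sum of Gaussian bands, the conventional lineshape for liquid/solid-phase
#' vibrational bands. Warns when a band is narrower than twice the axis
#' spacing (under-resolved).
#'
#' @param bands data frame (or list coercible to one) with columns
#'   `center` (cm^-1), `height` (AU), `width` (FWHM, cm^-1).
#' @param wavenumbers numeric axis (cm^-1).
#' @return numeric vector of absorbances (AU).
#' @export
render_analyte <- function(bands, wavenumbers) {
  bands <- as.data.frame(bands)
  y <- numeric(length(wavenumbers))
  if (nrow(bands) == 0) return(y)
  stopifnot(all(c("center", "height", "width") %in% names(bands)))
  spacing <- if (length(wavenumbers) > 1) mean(diff(wavenumbers)) else 0
  if (any(bands$width < 2 * spacing))
    warning("analyte band(s) narrower than twice the axis spacing are under-resolved",
            call. = FALSE)
  k <- 4 * log(2)
  for (j in seq_len(nrow(bands))) {
    y <- y + bands$height[j] *
      exp(-k * (wavenumbers - bands$center[j])^2 / bands$width[j]^2)
  }
  y
}

# Gaussian instrument lineshape convolution; edge-padded with end values so
# a flat baseline stays flat. FWHM <= 0 disables convolution.
gaussian_convolve <- function(y, spacing, fwhm) {
  if (!is.finite(fwhm) || fwhm <= 0) return(y)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- max(1L, ceiling(4 * sigma / spacing))
  x <- (-h:h) * spacing
  kern <- exp(-x^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  n <- length(y)
  ypad <- c(rep(y[1], h), y, rep(y[n], h))
  out <- stats::filter(ypad, kern, method = "convolution", sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}

#' Configure a synthetic sequential-FTIR scene
#'
#' A scene is the additive ground-truth model of the measurement: each scan
#' is the analyte spectrum plus, for every interferent, a fixed basis
#' spectrum multiplied by a per-scan concentration coefficient, plus a slow
#' per-scan baseline drift, all convolved with a Gaussian instrument
#' lineshape, plus white noise.
#'
#' @param axis numeric `c(lo, hi, spacing)` in cm^-1.
#' @param analyte_bands bands for [render_analyte()] (may be empty).
#' @param interferents list of entries, each a list with elements `spec`
#'   (an [interferent_spec]), `comb` (a [line_comb]) and `coefficients`
#'   (numeric trajectory, one value per scan).
#' @param noise_sd white-noise standard deviation (AU), >= 0.
#' @param drift numeric `c(slope, curvature)`: per-scan baseline
#'   `slope * k * (1 + curvature * x^2)` with `x` the axis scaled to
#'   \[-1, 1\] and `k` the 0-based scan index.
#' @param resolution_fwhm instrument lineshape FWHM (cm^-1); 0 disables.
#' @param seed integer RNG seed.
#' @param n_scans number of scans; defaults to the trajectory length.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(axis, analyte_bands = NULL, interferents = list(),
                         noise_sd = 0, drift = c(0, 0), resolution_fwhm = 0,
                         seed = 1L, n_scans = NULL) {
  if (length(axis) != 3 || axis[3] <= 0 || axis[1] >= axis[2])
    abort("axis must be c(lo, hi, spacing) with lo < hi, spacing > 0",
          "atmcorr_config_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0", "atmcorr_config_error")
  lens <- vapply(interferents, function(it) length(it$coefficients), integer(1))
  n_scans <- n_scans %||% (if (length(lens)) lens[1] else 2L)
  if (n_scans < 2) abort("a scene needs at least 2 scans", "atmcorr_config_error")
  if (length(lens) && any(lens != n_scans))
    abort("every coefficient trajectory must have one value per scan",
          "atmcorr_config_error")
  for (it in interferents) {
    stopifnot(inherits(it$spec, "interferent_spec"), inherits(it$comb, "line_comb"))
  }
  structure(
    list(axis = as.numeric(axis), analyte_bands = analyte_bands,
         interferents = interferents, noise_sd = noise_sd,
         drift = as.numeric(drift), resolution_fwhm = resolution_fwhm,
         seed = as.integer(seed), n_scans = as.integer(n_scans)),
    class = "scene_config"
  )
}

#' Simulate a sequential series of spectra with known ground truth
#'
#' Renders the scene of a [scene_config()]: for scan k the clean spectrum is
#' `analyte + sum_j c_j(k) * basis_j + drift(k)`, convolved with the
#' instrument lineshape, with white noise added afterwards. The returned
#' ground truth carries the (convolved) analyte and interferent bases, the
#' coefficient trajectories, and the closed-form optimal scaling factor for
#' every adjacent scan pair, `gamma = c(k) / (c(k) - c(k+1))`, which a
#' perfect correction must recover.
#'
#' Reproducible: the same config (including seed) yields a bit-identical
#' series, and the caller's RNG state is left untouched.
#'
#' @param cfg a [scene_config()].
#' @return list with `series` (an [ir_series]) and `truth` (class
#'   `scene_truth`: `analyte` as `ir_spectrum`, `interferent_bases`,
#'   `coefficients`, `gamma_true`).
#' @export
simulate_series <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  w <- seq(cfg$axis[1], cfg$axis[2], by = cfg$axis[3])
  spacing <- cfg$axis[3]
  conv <- function(y) gaussian_convolve(y, spacing, cfg$resolution_fwhm)
  analyte <- conv(
    if (is.null(cfg$analyte_bands)) numeric(length(w))
    else render_analyte(cfg$analyte_bands, w))
  bases <- lapply(cfg$interferents, function(it) conv(render_comb(it$comb, w)))
  names(bases) <- vapply(cfg$interferents, function(it) it$spec$name, character(1))
  x <- (w - mean(range(w))) / (diff(range(w)) / 2)
  gamma_true <- lapply(cfg$interferents, function(it) {
    cc <- it$coefficients
    d <- cc[-length(cc)] - cc[-1]
    ifelse(d == 0, NA_real_, cc[-length(cc)] / d)
  })
  names(gamma_true) <- names(bases)
  spectra <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_scans), function(k) {
      y <- analyte
      for (j in seq_along(bases))
        y <- y + cfg$interferents[[j]]$coefficients[k] * bases[[j]]
      y <- y + cfg$drift[1] * (k - 1) * (1 + cfg$drift[2] * x^2)
      if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(w), 0, cfg$noise_sd)
      ir_spectrum(w, y, timestamp = k - 1, resolution = cfg$resolution_fwhm,
                  label = sprintf("scan_%03d", k))
    })
  })
  truth <- structure(
    list(analyte = ir_spectrum(w, analyte, timestamp = 0, label = "analyte"),
         interferent_bases = bases,
         coefficients = lapply(cfg$interferents, function(it) it$coefficients),
         gamma_true = gamma_true),
    class = "scene_truth"
  )
  names(truth$coefficients) <- names(bases)
  list(series = ir_series(spectra, sample_id = "synthetic"), truth = truth)
}

#' Rerun a scene across instrument resolutions
#'
#' The synthetic analogue of the resolution study: the same scene (same
#' coefficient trajectories, noise level and bands) is re-rendered at each
#' instrument lineshape width, with the axis spacing scaled to half the
#' width, each series is corrected, and the RSD in the target region is
#' summarized before and after correction.
#'
#' @param cfg base [scene_config()].
#' @param fwhms instrument FWHM values (cm^-1) to sweep.
#' @param target,reference regions for [rsd_profile()].
#' @param pairing passed to [correct_series()].
#' @return named list (one entry per width) with `fwhm`, `rsd_uncorrected`,
#'   `rsd_corrected` (mean RSD over the target region), `gap` (their
#'   difference) and the two series.
#' @export
resolution_sweep <- function(cfg, fwhms, target = wn_region(1200, 2100),
                             reference = wn_region(4800, 5000),
                             pairing = "next") {
  stopifnot(inherits(cfg, "scene_config"))
  specs <- lapply(cfg$interferents, function(it) it$spec)
  out <- lapply(fwhms, function(fw) {
    cfg2 <- cfg
    cfg2$resolution_fwhm <- fw
    cfg2$axis[3] <- fw / 2
    sim <- simulate_series(cfg2)
    corr <- correct_series(sim$series, interferents = specs,
                           pairing = pairing, noise_sd = cfg$noise_sd)
    r_unc <- rsd_profile(sim$series, target = target, reference = reference)
    r_cor <- rsd_profile(corr$series, target = target, reference = reference)
    list(fwhm = fw,
         rsd_uncorrected = mean(r_unc$rsd),
         rsd_corrected = mean(r_cor$rsd),
         gap = mean(r_unc$rsd) - mean(r_cor$rsd),
         uncorrected = sim$series, corrected = corr$series)
  })
  names(out) <- sprintf("%g", fwhms)
  out
}

#' Read a scene configuration from JSON
#'
#' Mirrors [scene_config()]: fields `axis`, `analyte_bands` (array of
#' objects with `center`, `height`, `width`), `interferents` (array with
#' `name`, `correct_region`, optional `gamma_region`, `centers`,
#' `intensities`, `fwhm`, `coefficients`), `noise_sd`, `drift`,
#' `resolution_fwhm`, `seed`.
#'
#' @param path JSON file path.
#' @return a [scene_config()].
#' @export
read_scene_config <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e)
                    abort(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                          "atmcorr_config_error"))
  ifs <- list()
  if (!is.null(raw$interferents)) {
    items <- if (is.data.frame(raw$interferents))
      split(raw$interferents, seq_len(nrow(raw$interferents)))
    else raw$interferents
    ifs <- lapply(items, function(it) {
      it <- as.list(it)
      unwrap <- function(v) if (is.list(v)) v[[1]] else v
      cr <- unwrap(it$correct_region); gr <- unwrap(it$gamma_region)
      list(
        spec = interferent_spec(
          unwrap(it$name), wn_region(cr[1], cr[2]),
          if (is.null(gr) || all(is.na(gr))) NULL else wn_region(gr[1], gr[2])),
        comb = line_comb(unwrap(it$centers), unwrap(it$intensities),
                         unwrap(it$fwhm)),
        coefficients = as.numeric(unwrap(it$coefficients))
      )
    })
    names(ifs) <- NULL
  }
  scene_config(
    axis = as.numeric(raw$axis),
    analyte_bands = raw$analyte_bands,
    interferents = ifs,
    noise_sd = raw$noise_sd %||% 0,
    drift = as.numeric(raw$drift %||% c(0, 0)),
    resolution_fwhm = raw$resolution_fwhm %||% 0,
    seed = raw$seed %||% 1L
  )
}
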