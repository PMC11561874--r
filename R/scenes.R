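#' Canonical fluctuating-water-vapor scene
#'
#' The package's reference validation scene: a static analyte measured
#' repeatedly while the water-vapor concentration in the chamber fluctuates
#' strongly between successive scans. The water-bend rotational comb spans
#' 1230-2050 cm^-1 (dense Lorentzian lines, seeded random intensities); the
#' coefficient trajectory alternates between a high humidity state
#' (uniform 0.8-1) and a low one (uniform 0-0.1), emulating chamber
#' air exchange between scans. Strong scan-to-scan variation is the regime
#' in which pairwise correction is well-posed: the optimal scaling factor
#' c(k)/(c(k) - c(k+1)) stays of order one, so the corrected spectrum's
#' noise is not inflated.
#'
#' The comb amplitude is calibrated so that the median per-point standard
#' deviation of the interferent contribution over the target region equals
#' `interferent_noise_ratio` times `noise_sd` — the scene's stated
#' interferent-to-noise condition, fixed before any measurement.
#'
#' @param n_scans number of sequential scans.
#' @param noise_sd white-noise standard deviation (AU).
#' @param interferent_noise_ratio target ratio of median interferent
#'   fluctuation to noise in the water region.
#' @param resolution_fwhm instrument width (cm^-1); axis spacing is half of
#'   it.
#' @param seed integer seed (controls comb intensities, trajectory, noise).
#' @param target region used for the amplitude calibration (the water RSD
#'   region).
#' @param drift per-scan baseline drift passed to [scene_config()].
#' @return a [scene_config()] whose axis spans 1100-5100 cm^-1 (so the
#'   feature-free 4800-5000 cm^-1 RSD reference region is included).
#' @export
scene_water_fluctuation <- function(n_scans = 30, noise_sd = 1e-3,
                                    interferent_noise_ratio = 10,
                                    resolution_fwhm = 4, seed = 1L,
                                    target = wn_region(1200, 2100),
                                    drift = c(0, 0)) {
  spacing <- resolution_fwhm / 2
  lo <- 1100; hi <- 5100
  centers <- seq(1230, 2050, by = 6)
  with_seed(seed, {
    intens <- stats::runif(length(centers), 0.5, 1)
    hi_states <- stats::runif(ceiling(n_scans / 2), 0.8, 1.0)
    lo_states <- stats::runif(floor(n_scans / 2), 0.0, 0.1)
    traj <- numeric(n_scans)
    traj[seq(1, n_scans, by = 2)] <- hi_states
    if (n_scans > 1) traj[seq(2, n_scans, by = 2)] <- lo_states
    comb <- line_comb(centers, intens, fwhm = 4)
    # calibrate amplitude: median interferent std over the target region
    # must equal interferent_noise_ratio * noise_sd
    w <- seq(lo, hi, by = spacing)
    b <- gaussian_convolve(render_comb(comb, w), spacing, resolution_fwhm)
    idx <- which(w >= target$lo & w <= target$hi)
    med_b <- stats::median(b[idx])
    amp <- if (noise_sd > 0 && med_b > 0)
      interferent_noise_ratio * noise_sd / (stats::sd(traj) * med_b) else 1
    comb$intensities <- comb$intensities * amp
    scene_config(
      axis = c(lo, hi, spacing),
      analyte_bands = data.frame(
        center = c(2930, 4400), height = c(0.30, 0.05), width = c(60, 80)),
      interferents = list(list(
        spec = interferent_spec("H2O-bend", wn_region(1205, 2072)),
        comb = comb, coefficients = traj)),
      noise_sd = noise_sd, drift = drift,
      resolution_fwhm = resolution_fwhm, seed = seed
    )
  })
}

#' Edge-case scene: intense analyte band inside the correction region
#'
#' Reproduces the failure mode of in-region scaling-factor estimation: an
#' analyte with a sharp, intense carbonyl-like band near 1700 cm^-1 sits
#' inside the water bending region, while the same water vapor also absorbs
#' in the clean 3231-4000 cm^-1 stretching region. The scene carries a
#' single water interferent whose basis comb spans both regions with one
#' shared coefficient trajectory, so a scaling factor estimated in the
#' stretch region transfers exactly to the bend region.
#'
#' @param n_scans number of scans.
#' @param noise_sd white-noise standard deviation (AU).
#' @param analyte_height peak absorbance of the contaminating sharp band.
#' @param seed integer seed.
#' @return list with `cfg` (a [scene_config()]), `bend` and `stretch`
#'   ([wn_region]s), and `interferent_inregion` / `interferent_transfer`
#'   (interferent specs estimating gamma in the bend region itself versus
#'   in the stretch region).
#' @export
scene_analyte_contaminated <- function(n_scans = 2, noise_sd = 2e-4,
                                       analyte_height = 1.0, seed = 1L) {
  bend <- wn_region(1205, 2072)
  stretch <- wn_region(3231, 4000)
  spacing <- 2; fwhm <- 4
  centers <- c(seq(1230, 2050, by = 6), seq(3300, 3950, by = 6))
  with_seed(seed, {
    intens <- stats::runif(length(centers), 0.3, 1) * 0.05
    traj <- stats::runif(n_scans, 0, 1)
    # enforce strong scan-to-scan change so gamma stays well-conditioned
    traj[seq(1, n_scans, by = 2)] <- stats::runif(length(seq(1, n_scans, by = 2)), 0.8, 1)
    if (n_scans > 1)
      traj[seq(2, n_scans, by = 2)] <- stats::runif(length(seq(2, n_scans, by = 2)), 0, 0.15)
    comb <- line_comb(centers, intens, fwhm = fwhm)
    cfg <- scene_config(
      axis = c(1000, 4100, spacing),
      analyte_bands = data.frame(
        center = c(1701, 2850),
        height = c(analyte_height, 0.3),
        width = c(10, 60)),
      interferents = list(list(
        spec = interferent_spec("H2O", bend),
        comb = comb, coefficients = traj)),
      noise_sd = noise_sd, resolution_fwhm = fwhm, seed = seed
    )
    list(cfg = cfg, bend = bend, stretch = stretch,
         interferent_inregion = interferent_spec("H2O", bend),
         interferent_transfer = interferent_spec("H2O", bend,
                                                 gamma_region = stretch))
  })
}
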