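test_that("difference spectrum isolates the interferent change", {
  w <- seq(1000, 1200, by = 2)
  r <- wn_region(1040, 1160)
  analyte <- 0.3 * exp(-(w - 1100)^2 / 200)
  W <- 0.05 * sin(w / 3)^2  # known interferent vector
  s1 <- ir_spectrum(w, analyte + 2 * W, timestamp = 0)
  s2 <- ir_spectrum(w, analyte + 1 * W, timestamp = 30)

  D0 <- difference_spectrum(s1, s1, r)
  expect_true(all(D0$values == 0))

  D <- difference_spectrum(s1, s2, r)
  i <- D$idx
  expect_equal(D$values, W[i[1]:i[2]])
  expect_equal(D$pair, c(0, 30))

  s3 <- ir_spectrum(w + 2, analyte + W, timestamp = 60)
  expect_error(difference_spectrum(s1, s3, r), class = "atmcorr_axis_error")
})

test_that("point-to-point length follows Pythagoras", {
  expect_equal(point_to_point_length(rep(0.7, 11), dx = 1), 10)
  expect_equal(point_to_point_length(c(0, 4), dx = 3), 5)
  expect_equal(point_to_point_length(c(0, 1, 0), dx = 1), 2 * sqrt(2))
  expect_error(point_to_point_length(0.5), class = "atmcorr_too_short_error")
  expect_error(point_to_point_length(c(1, 2), dx = 0), class = "atmcorr_value_error")

  # property: matches the literal loop oracle on random vectors
  for (seed in 1:20) {
    y <- with_seed(seed, rnorm(sample(2:200, 1), sd = runif(1, 0.001, 10)))
    dx <- with_seed(seed + 1000, runif(1, 0.01, 5))
    expect_equal(point_to_point_length(y, dx), naive_length(y, dx),
                 tolerance = 1e-12)
  }
})

test_that("length_of_corrected equals the length of the subtracted segment", {
  inst <- random_noisy_instance(42)
  expect_equal(length_of_corrected(inst$seg, inst$D, 0),
               point_to_point_length(inst$seg))
  # exact cancellation: s1_seg = c * D -> flat zero at gamma = c
  Dv <- inst$D$values
  expect_equal(length_of_corrected(3 * Dv, inst$D, 3), length(Dv) - 1)
  # grid equivalence with the naive oracle
  for (g in seq(-5, 5, length.out = 21)) {
    expect_equal(length_of_corrected(inst$seg, inst$D, g),
                 naive_length(inst$seg - g * Dv), tolerance = 1e-12)
  }
  expect_error(length_of_corrected(inst$seg[-1], inst$D, 1),
               class = "atmcorr_shape_error")
})

test_that("optimize_gamma recovers the closed-form factor on noiseless scenes", {
  for (cc in list(c(2, 1), c(1, 2))) {
    scn <- random_pair_scene(7)
    scn$cfg$interferents[[1]]$coefficients <- cc
    sim <- simulate_series(scn$cfg)
    s1 <- sim$series$spectra[[1]]; s2 <- sim$series$spectra[[2]]
    D <- difference_spectrum(s1, s2, scn$region)
    seg <- slice_region(s1, scn$region)$spectrum$absorbance
    curve <- optimize_gamma(seg, D)
    expect_equal(curve$gamma_opt, gamma_closed_form(cc[1], cc[2]),
                 tolerance = 1e-6)
    expect_false(curve$boundary)
    expect_lte(curve$length_opt, min(curve$lengths))
    expect_length(curve$gammas, 41)
  }
})

test_that("gamma is scale-equivariant in D and the correction invariant", {
  inst <- random_noisy_instance(11)
  c1 <- optimize_gamma(inst$seg, inst$D)
  D10 <- inst$D; D10$values <- 10 * D10$values
  c2 <- optimize_gamma(inst$seg, D10)
  expect_equal(c2$gamma_opt, c1$gamma_opt / 10, tolerance = 1e-6)
  expect_equal(inst$seg - c2$gamma_opt * D10$values,
               inst$seg - c1$gamma_opt * inst$D$values, tolerance = 1e-10)
})

test_that("degenerate differences and boundary optima are flagged", {
  inst <- random_noisy_instance(3)
  Dz <- inst$D; Dz$values <- rep(1e-8, length(Dz$values))
  expect_error(optimize_gamma(inst$seg, Dz),
               class = "atmcorr_degenerate_difference_error")
  # caller-supplied noise estimate raises the floor
  Dn <- inst$D; Dn$values <- rep(1e-3, length(Dn$values))
  expect_error(optimize_gamma(inst$seg, Dn, noise_sd = 1e-3),
               class = "atmcorr_degenerate_difference_error")
  # an optimum pinned at a bound is flagged, not hidden
  curve <- optimize_gamma(inst$seg, inst$D, bounds = c(5, 6))
  expect_true(curve$boundary)
})

test_that("optimize_gamma matches the brute-force grid oracle", {
  # coarse grid here; the full 1e-4 grid over [-50, 50] runs in acceptance
  for (seed in 1:10) {
    inst <- random_noisy_instance(seed)
    curve <- optimize_gamma(inst$seg, inst$D)
    oracle <- grid_min_gamma(inst$seg, inst$D$values, lo = -50, hi = 50,
                             step = 1e-3)
    expect_lt(abs(curve$gamma_opt - oracle$gamma), 1e-3)
  }
})

test_that("sampled length curves are convex whenever D is nonzero", {
  for (seed in 1:100) {
    inst <- random_noisy_instance(seed)
    curve <- optimize_gamma(inst$seg, inst$D,
                            bounds = with_seed(seed, sort(runif(2, -30, 30))))
    expect_true(is_convex_curve(curve$lengths))
  }
})

test_that("apply_correction subtracts the scaled difference over the region", {
  scn <- random_pair_scene(19)
  sim <- simulate_series(scn$cfg)
  s1 <- sim$series$spectra[[1]]; s2 <- sim$series$spectra[[2]]
  D <- difference_spectrum(s1, s2, scn$region)

  S0 <- apply_correction(s1, D, 0)
  expect_equal(S0$absorbance, slice_region(s1, scn$region)$spectrum$absorbance)

  # gamma = 1 undoes the construction s1 = s2 + D
  S1 <- apply_correction(s1, D, 1)
  expect_equal(S1$absorbance, slice_region(s2, scn$region)$spectrum$absorbance,
               tolerance = 1e-12)

  # ground truth: the closed-form gamma restores the injected analyte
  St <- apply_correction(s1, D, scn$gamma_true)
  truth_seg <- slice_region(sim$truth$analyte, scn$region)$spectrum$absorbance
  expect_equal(St$absorbance, truth_seg, tolerance = 1e-10)
})

test_that("splice matches end absorbances with a linear ramp", {
  w <- 1000:1020
  s1 <- ir_spectrum(w, sin(w / 4) * 0.1 + 0.5)
  r <- wn_region(1005, 1015)
  sl <- slice_region(s1, r)
  seg <- sl$spectrum$absorbance

  # already continuous: adjust segment so its ends equal the outside points
  seg0 <- seg
  seg0[1] <- s1$absorbance[sl$idx[1] - 1]
  seg0[length(seg0)] <- s1$absorbance[sl$idx[2] + 1]
  out0 <- splice(s1, seg0, r)
  expect_equal(out0$absorbance[sl$idx[1]:sl$idx[2]], seg0)

  # constant +0.05 offset from continuity -> constant -0.05 ramp
  outc <- splice(s1, seg0 + 0.05, r)
  expect_equal(outc$absorbance[sl$idx[1]:sl$idx[2]], seg0, tolerance = 1e-12)

  # asymmetric mismatches (+0.02, -0.02): ramp interpolates linearly
  n_seg <- length(seg0)
  mis <- seq(-0.02, 0.02, length.out = n_seg)  # what continuity must remove
  outa <- splice(s1, seg0 + mis, r)
  expect_equal(outa$absorbance[sl$idx[1]:sl$idx[2]], seg0, tolerance = 1e-12)
  # outside points untouched
  outside <- setdiff(seq_along(w), sl$idx[1]:sl$idx[2])
  expect_identical(outa$absorbance[outside], s1$absorbance[outside])

  expect_error(splice(s1, seg0[-1], r), class = "atmcorr_shape_error")
})

test_that("splice at an axis end uses a constant offset to the single join", {
  w <- 1000:1010
  s1 <- ir_spectrum(w, seq(0, 1, length.out = 11))
  r <- wn_region(1000, 1005)
  sl <- slice_region(s1, r)
  seg <- s1$absorbance[sl$idx[1]:sl$idx[2]] + 0.1
  out <- splice(s1, seg, r)
  inside <- out$absorbance[sl$idx[1]:sl$idx[2]]
  # constant offset (no ramp slope at an axis end) ...
  expect_equal(diff(inside - seg), rep(0, length(seg) - 1), tolerance = 1e-12)
  # ... chosen so the segment endpoint equals the point just outside the join
  expect_equal(inside[length(inside)], s1$absorbance[sl$idx[2] + 1],
               tolerance = 1e-12)
})

test_that("correct_pair recovers a two-interferent scene exactly", {
  r_w <- wn_region(1205, 2072)
  r_c <- wn_region(2208, 2442)
  comb_w <- line_comb(seq(1300, 1980, 8), rep(0.04, 86), 4, "gaussian")
  comb_c <- line_comb(seq(2290, 2380, 3), rep(0.06, 31), 4, "gaussian")
  cfg <- scene_config(
    axis = c(1000, 2600, 2),
    analyte_bands = data.frame(center = 1040, height = 0.4, width = 25),
    interferents = list(
      list(spec = interferent_spec("H2O-bend", r_w), comb = comb_w,
           coefficients = c(1.5, 0.4)),
      list(spec = interferent_spec("CO2", r_c), comb = comb_c,
           coefficients = c(0.3, 1.1))),
    noise_sd = 0, resolution_fwhm = 4, seed = 23)
  sim <- simulate_series(cfg)
  res <- correct_pair(sim$series$spectra[[1]], sim$series$spectra[[2]],
                      interferents = list(interferent_spec("H2O-bend", r_w),
                                          interferent_spec("CO2", r_c)))
  expect_equal(res$per_interferent[["H2O-bend"]]$gamma,
               gamma_closed_form(1.5, 0.4), tolerance = 1e-6)
  expect_equal(res$per_interferent[["CO2"]]$gamma,
               gamma_closed_form(0.3, 1.1), tolerance = 1e-6)
  for (r in list(r_w, r_c)) {
    i <- slice_region(sim$truth$analyte, r)$idx
    expect_equal(res$corrected$absorbance[i[1]:i[2]],
                 sim$truth$analyte$absorbance[i[1]:i[2]], tolerance = 1e-9)
  }
  # locality: untouched outside the two correction regions
  iw <- slice_region(sim$series$spectra[[1]], r_w)$idx
  ic <- slice_region(sim$series$spectra[[1]], r_c)$idx
  outside <- setdiff(seq_along(res$corrected$absorbance),
                     c(iw[1]:iw[2], ic[1]:ic[2]))
  expect_identical(res$corrected$absorbance[outside],
                   sim$series$spectra[[1]]$absorbance[outside])
})

test_that("an unchanged atmosphere yields gamma = 0 warnings, not failure", {
  w <- seq(1000, 2600, by = 2)
  s <- ir_spectrum(w, 0.2 + 0.1 * exp(-(w - 1500)^2 / 5000), timestamp = 0)
  res <- correct_pair(s, s, interferents = list(
    interferent_spec("H2O-bend", wn_region(1205, 2072))))
  expect_equal(res$per_interferent[["H2O-bend"]]$gamma, 0)
  expect_length(res$warnings, 1)
  expect_identical(res$corrected$absorbance, s$absorbance)
})

test_that("gamma transfer from a clean region beats in-region estimation", {
  scn <- scene_analyte_contaminated(seed = 5)
  sim <- simulate_series(scn$cfg)
  s1 <- sim$series$spectra[[1]]; s2 <- sim$series$spectra[[2]]
  i <- slice_region(sim$truth$analyte, scn$bend)$idx
  truth <- sim$truth$analyte$absorbance[i[1]:i[2]]
  err <- function(res) {
    v <- res$corrected$absorbance[i[1]:i[2]]
    sqrt(mean((v - truth)^2))
  }
  res_in <- correct_pair(s1, s2, interferents = list(scn$interferent_inregion),
                         noise_sd = 2e-4)
  res_tr <- correct_pair(s1, s2, interferents = list(scn$interferent_transfer),
                         noise_sd = 2e-4)
  expect_lt(err(res_tr), err(res_in))
  expect_equal(res_tr$per_interferent$H2O$gamma_region_used$lo, 3231)
})

test_that("monotone improvement: correction never lengthens the region", {
  for (seed in 1:25) {
    inst <- random_noisy_instance(seed, n = 61)
    res <- correct_pair(inst$s1, inst$s2,
                        interferents = list(interferent_spec("x", inst$region)))
    p <- res$per_interferent$x
    expect_lte(p$L_after, p$L_before + 1e-12)
  }
})

test_that("correct_series pairs forward or backward and drops one spectrum", {
  scn <- random_pair_scene(31, noise_sd = 5e-4, n_scans = 9)
  sim <- simulate_series(scn$cfg)
  ifs <- list(interferent_spec("H2O", scn$region))

  nxt <- correct_series(sim$series, interferents = ifs, noise_sd = 5e-4)
  expect_length(nxt$series$spectra, 8)
  expect_equal(nxt$series$spectra[[1]]$timestamp, 0)

  prv <- correct_series(sim$series, interferents = ifs, pairing = "previous",
                        noise_sd = 5e-4)
  expect_length(prv$series$spectra, 8)
  expect_equal(prv$series$spectra[[1]]$timestamp, 1)

  # recovered gammas track the ground truth pair by pair
  g_hat <- vapply(nxt$results, function(r) r$per_interferent$H2O$gamma,
                  numeric(1))
  g_true <- simulate_series(scn$cfg)$truth$gamma_true$H2O
  expect_equal(g_hat, g_true, tolerance = 0.05)

  # two identical spectra: one output equal to the first, with a warning
  w <- seq(1000, 2500, 2)
  s <- ir_spectrum(w, rep(0.1, length(w)), timestamp = 0)
  s2 <- s; s2$timestamp <- 1
  two <- correct_series(ir_series(list(s, s2)), interferents = ifs)
  expect_length(two$series$spectra, 1)
  expect_identical(two$series$spectra[[1]]$absorbance, s$absorbance)
  expect_gt(length(two$results[[1]]$warnings), 0)

  expect_error(correct_series(ir_series(list(s)), interferents = ifs),
               class = "atmcorr_pairing_error")
})

test_that("noise-driven attenuation of gamma decays with interferent strength", {
  # minimizing spectral length with a noisy difference spectrum shrinks
  # gamma toward zero (errors-in-variables); the bias falls off roughly as
  # the inverse square of the interferent-to-noise ratio
  bias_at <- function(ratio, n_seeds = 100) {
    errs <- vapply(seq_len(n_seeds), function(seed) {
      scn <- scene_water_fluctuation(n_scans = 2, noise_sd = 1e-3,
                                     interferent_noise_ratio = ratio,
                                     seed = seed)
      sim <- simulate_series(scn)
      res <- correct_pair(sim$series$spectra[[1]], sim$series$spectra[[2]],
                          interferents = list(interferent_spec(
                            "H2O-bend", wn_region(1205, 2072))),
                          noise_sd = 1e-3)
      res$per_interferent[["H2O-bend"]]$gamma -
        sim$truth$gamma_true[["H2O-bend"]][1]
    }, numeric(1))
    mean(errs)
  }
  b10 <- bias_at(10); b100 <- bias_at(100)
  expect_lt(b10, 0)                      # shrinkage, not inflation
  expect_lt(abs(b100), abs(b10) / 10)    # decay at least ~linear-squared
  expect_lt(abs(b100), 0.02)             # negligible at realistic strength
})
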