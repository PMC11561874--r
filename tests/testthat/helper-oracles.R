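# Independent oracles, kept deliberately naive: they never share code with
# the implementation paths they check.

# literal Pythagoras loop
naive_length <- function(y, dx = 1) {
  L <- 0
  for (i in seq_len(length(y) - 1)) L <- L + sqrt(dx^2 + (y[i + 1] - y[i])^2)
  L
}

# exhaustive brute-force minimizer of L(gamma) on a fixed grid, vectorized
# in chunks so the full 1e-4-step grid over [-50, 50] stays affordable
grid_min_gamma <- function(s1_seg, Dvals, lo = -50, hi = 50, step = 1e-4,
                           dx = 1, chunk = 100000L) {
  dseg <- diff(s1_seg); dD <- diff(Dvals)
  n_total <- round((hi - lo) / step) + 1L
  best_g <- NA_real_; best_L <- Inf
  done <- 0L
  while (done < n_total) {
    m <- min(chunk, n_total - done)
    gs <- lo + (done + seq_len(m) - 1L) * step
    Ls <- colSums(sqrt(dx^2 + (dseg - dD %o% gs)^2))
    j <- which.min(Ls)
    if (Ls[j] < best_L) { best_L <- Ls[j]; best_g <- gs[j] }
    done <- done + m
  }
  list(gamma = best_g, length = best_L)
}

# second-difference convexity check on a sampled curve
is_convex_curve <- function(lengths, tol = 1e-9) {
  d2 <- diff(lengths, differences = 2)
  all(d2 >= -tol * max(abs(lengths)))
}

# direct per-point local polynomial fit (least squares), the Savitzky-Golay
# oracle: fit degree-p polynomial to the window centred at i, read off twice
# the quadratic coefficient
polyfit_second_deriv_at <- function(y, i, window, polyorder) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  x <- idx - i
  fit <- lm.fit(outer(x, 0:polyorder, "^"), y[idx])
  2 * fit$coefficients[3]
}

# closed-form optimal scaling factor from the coefficient trajectory
gamma_closed_form <- function(c1, c2) c1 / (c1 - c2)

# --- scene builders ----------------------------------------------------------

# noiseless (or noisy) single-interferent scene with the water-bend region;
# the interferent basis uses Gaussian lines kept >= 90 cm-1 inside the
# region so it vanishes at the boundaries (required for exact splicing)
random_pair_scene <- function(seed, noise_sd = 0, n_scans = 2) {
  r <- wn_region(1205, 2072)
  with_seed(seed, {
    n_lines <- sample(20:60, 1)
    comb <- line_comb(
      centers = sort(runif(n_lines, 1300, 1980)),
      intensities = runif(n_lines, 0.2, 1) * runif(1, 0.02, 0.2),
      fwhm = runif(1, 2, 6), lineshape = "gaussian")
    cc <- numeric(n_scans)
    cc[1] <- runif(1, 0.2, 2)
    for (k in 2:n_scans) {
      repeat {
        cand <- runif(1, 0.2, 2)
        if (abs(cand - cc[k - 1]) >= 0.3) break
      }
      cc[k] <- cand
    }
    cfg <- scene_config(
      axis = c(1000, 2500, 2),
      analyte_bands = data.frame(
        center = c(runif(1, 1000, 1050), runif(1, 2350, 2480)),
        height = runif(2, 0.1, 0.6),
        width = runif(2, 20, 40)),
      interferents = list(list(spec = interferent_spec("H2O", r),
                               comb = comb, coefficients = cc)),
      noise_sd = noise_sd, resolution_fwhm = 4, seed = seed)
    list(cfg = cfg, region = r, coefficients = cc,
         gamma_true = gamma_closed_form(cc[1], cc[2]))
  })
}

# random short noisy segment + difference pair for optimizer/oracle checks
random_noisy_instance <- function(seed, n = 31) {
  with_seed(seed, {
    w <- seq(1000, 1000 + 2 * (n - 1), by = 2)
    base <- cumsum(rnorm(n, 0, 0.02))
    comb <- rnorm(n, 0, 0.05)
    c1 <- runif(1, 0.5, 2); c2 <- runif(1, -1, 0.4)
    s1 <- ir_spectrum(w, base + c1 * comb + rnorm(n, 0, 0.003), timestamp = 0)
    s2 <- ir_spectrum(w, base + c2 * comb + rnorm(n, 0, 0.003), timestamp = 1)
    r <- wn_region(w[1], w[n])
    list(s1 = s1, s2 = s2, region = r,
         D = difference_spectrum(s1, s2, r),
         seg = s1$absorbance)
  })
}

write_series_csvs <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(series$spectra))
    write_spectrum_csv(series$spectra[[k]],
                       file.path(dir, sprintf("scan_%03d.csv", k)))
  invisible(dir)
}

with_seed <- atmcorr:::with_seed
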