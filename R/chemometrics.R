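# Savitzky-Golay derivative coefficients: least-squares fit of a degree-
# `polyorder` polynomial on `window` points, differentiated `deriv` times.
# Positions are in index units (unit spacing).
sg_coef_row <- function(positions, polyorder, deriv, at = 0) {
  A <- outer(positions, 0:polyorder, "^")
  C <- solve(crossprod(A), t(A))        # (polyorder+1) x window
  row <- numeric(length(positions))
  for (j in deriv:polyorder) {
    fac <- prod((j - deriv + 1):j)      # j!/(j-deriv)!
    row <- row + fac * at^(j - deriv) * C[j + 1, ]
  }
  row
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Second derivative with respect to the sample index (unit spacing), the
#' standard preprocessing that resolves overlapping condensed-phase bands
#' before regression modeling. Interior points use the central filter; the
#' first and last half-windows are handled by one-sided polynomial fits
#' evaluated at the edge positions, so the output preserves the input
#' length.
#'
#' @param s an [ir_spectrum] (or numeric vector).
#' @param window odd number of points, `> polyorder`.
#' @param polyorder polynomial order, >= 2.
#' @return same type as the input with the derivative as absorbance values.
#' @export
second_derivative <- function(s, window = 11, polyorder = 3) {
  y <- if (inherits(s, "ir_spectrum")) s$absorbance else as.numeric(s)
  n <- length(y)
  if (window %% 2 == 0)
    abort("window must be odd", "atmcorr_spec_error")
  if (polyorder < 2 || window <= polyorder)
    abort("need window > polyorder >= 2", "atmcorr_spec_error")
  if (window > n)
    abort(sprintf("window (%d) exceeds spectrum length (%d)", window, n),
          "atmcorr_window_error")
  h <- (window - 1L) %/% 2L
  central <- sg_coef_row(-h:h, polyorder, 2L)
  out <- numeric(n)
  for (i in (h + 1L):(n - h)) out[i] <- sum(central * y[(i - h):(i + h)])
  lead_pos <- 0:(window - 1L)
  for (i in 1:h) {
    out[i] <- sum(sg_coef_row(lead_pos, polyorder, 2L, at = i - 1L) * y[1:window])
    out[n - i + 1L] <- sum(sg_coef_row(lead_pos, polyorder, 2L,
                                       at = window - i) * y[(n - window + 1L):n])
  }
  if (inherits(s, "ir_spectrum")) { s$absorbance <- out; s } else out
}

#' Fit a PLS1 regression model (NIPALS)
#'
#' Standard NIPALS partial least-squares factorization on mean-centered
#' predictors and response. Deterministic for fixed input.
#'
#' @param X numeric matrix, samples x variables, no missing values.
#' @param y numeric response vector (concentrations).
#' @param n_lv number of latent variables, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return an object of class `plsr_model` with weights `W`, loadings `P`,
#'   regression loadings `q`, centering vectors, and the cumulative
#'   coefficient path `B` (variables x n_lv).
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) abort("missing values are not supported", "atmcorr_value_error")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("nrow(X) must equal length(y)", "atmcorr_shape_error")
  k_max <- min(n - 1L, p)
  if (n_lv < 1 || n_lv > k_max)
    abort(sprintf("n_lv must be in [1, %d]", k_max), "atmcorr_rank_error")
  x_mean <- colMeans(X); y_mean <- mean(y)
  X0 <- sweep(X, 2, x_mean); y0 <- y - y_mean
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  Tm <- matrix(0, n, n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(X0, y0)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break  # X or y fully deflated: problem has lower rank
    w <- w / nw
    t_ <- X0 %*% w
    tt <- sum(t_^2)
    if (tt < 1e-28) break
    p_ <- crossprod(X0, t_) / tt
    q_ <- sum(y0 * t_) / tt
    X0 <- X0 - t_ %*% t(p_)
    y0 <- y0 - q_ * t_
    W[, a] <- w; P[, a] <- p_; q[a] <- q_; Tm[, a] <- t_
    a_used <- a
  }
  if (a_used == 0L) abort("predictors carry no covariance with y", "atmcorr_rank_error")
  # cumulative regression coefficients for every k <= n_lv
  B <- matrix(0, p, n_lv)
  for (k in seq_len(a_used)) {
    Wk <- W[, 1:k, drop = FALSE]; Pk <- P[, 1:k, drop = FALSE]
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), q[1:k])
  }
  if (a_used < n_lv)
    for (k in (a_used + 1L):n_lv) B[, k] <- B[, a_used]
  structure(
    list(n_lv = n_lv, n_lv_effective = a_used, W = W, P = P, q = q,
         scores = Tm, B = B, x_mean = x_mean, y_mean = y_mean),
    class = "plsr_model"
  )
}

#' Predict from a PLS1 model
#' @param object a `plsr_model`.
#' @param X new predictor matrix.
#' @param n_lv number of latent variables to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, X, n_lv = object$n_lv, ...) {
  X <- as.matrix(X)
  if (n_lv < 1 || n_lv > object$n_lv)
    abort(sprintf("n_lv must be in [1, %d]", object$n_lv), "atmcorr_rank_error")
  drop(sweep(X, 2, object$x_mean) %*% object$B[, n_lv] + object$y_mean)
}

#' PRESS by leave-one-group-out cross-validation
#'
#' All spectra of one run share atmospheric conditions, so cross-validation
#' folds are whole runs: each group is held out in turn, a model with
#' `max_lv` latent variables is fitted on the rest, and the squared
#' prediction errors on the held-out group are accumulated for every
#' candidate latent-variable count.
#'
#' @param X predictor matrix (samples x variables).
#' @param y response vector.
#' @param groups run identifier per sample (coerced to factor); >= 2 groups.
#' @param max_lv largest latent-variable count to evaluate.
#' @return numeric vector `press[k]`, k = 1..max_lv, with attribute
#'   `n_pred` (number of cross-validated predictions).
#' @export
press_by_group_cv <- function(X, y, groups, max_lv) {
  X <- as.matrix(X); y <- as.numeric(y)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    abort("group-wise cross-validation needs at least 2 groups",
          "atmcorr_group_error")
  groups <- droplevels(groups)
  press <- numeric(max_lv)
  for (g in levels(groups)) {
    test <- groups == g
    n_train <- sum(!test)
    if (n_train < max_lv + 1)
      abort(sprintf(
        "fold holding out group '%s' leaves %d training samples (< max_lv + 1 = %d)",
        g, n_train, max_lv + 1), "atmcorr_fold_size_error")
    fit <- fit_plsr(X[!test, , drop = FALSE], y[!test], max_lv)
    Xc <- sweep(X[test, , drop = FALSE], 2, fit$x_mean)
    for (k in seq_len(max_lv)) {
      yhat <- drop(Xc %*% fit$B[, k]) + fit$y_mean
      press[k] <- press[k] + sum((y[test] - yhat)^2)
    }
  }
  attr(press, "n_pred") <- length(y)
  press
}

#' Select the latent-variable count by the PRESS F-test
#'
#' The latent-variable count minimizing PRESS tends to overfit; instead,
#' every simpler model is compared against the minimum-PRESS model through
#' the ratio `F(k) = PRESS(k) / PRESS(k_min)`, referred to an F distribution
#' with `(n_pred, n_pred)` degrees of freedom. The selected count is the
#' smallest k whose exceedance probability is above `alpha` — i.e. the most
#' parsimonious model not significantly worse than the best one
#' (Haaland-Thomas convention, default `alpha = 0.25`).
#'
#' @param press PRESS vector (index = latent-variable count).
#' @param n_pred number of cross-validated predictions behind each PRESS
#'   value; defaults to `attr(press, "n_pred")`.
#' @param alpha significance threshold.
#' @return an object of class `lv_selection`: `press`, `k_min_press`,
#'   `k_selected`, `f_ratios`, `p_exceed`, `alpha`.
#' @export
select_lv_ftest <- function(press, n_pred = attr(press, "n_pred"),
                            alpha = 0.25) {
  force(n_pred)  # before the attribute is stripped below
  press <- as.numeric(press)
  if (length(press) == 0) abort("empty PRESS vector", "atmcorr_value_error")
  if (is.null(n_pred) || n_pred < 2)
    abort("n_pred must be >= 2", "atmcorr_value_error")
  k_min <- which.min(press)
  if (press[k_min] <= 0) {
    # perfect cross-validated fit: nothing simpler can be compared
    return(structure(
      list(press = press, k_min_press = k_min, k_selected = k_min,
           f_ratios = press / ifelse(press[k_min] > 0, press[k_min], 1),
           p_exceed = rep(NA_real_, length(press)), alpha = alpha),
      class = "lv_selection"))
  }
  f_ratios <- press / press[k_min]
  p_exceed <- stats::pf(f_ratios, n_pred, n_pred, lower.tail = FALSE)
  candidates <- which(seq_along(press) <= k_min & p_exceed > alpha)
  k_selected <- min(candidates)  # k_min itself always qualifies (F = 1)
  structure(
    list(press = press, k_min_press = k_min, k_selected = k_selected,
         f_ratios = f_ratios, p_exceed = p_exceed, alpha = alpha),
    class = "lv_selection"
  )
}

#' @export
print.lv_selection <- function(x, ...) {
  cat(sprintf("<lv_selection> k_selected = %d (min-PRESS at k = %d, alpha = %g)\n",
              x$k_selected, x$k_min_press, x$alpha))
  invisible(x)
}

# band sets for the two lipids; heights are AU per mM; the sets overlap
# (shared ester carbonyl near 1738, CH bends near 1467) so the regression
# problem is genuinely collinear
dppc_bands <- function(conc) data.frame(
  center = c(1738, 1467, 1202, 1065),
  height = conc * c(0.120, 0.050, 0.030, 0.080),
  width = c(25, 20, 25, 30))

sm_bands <- function(conc) data.frame(
  center = c(1738, 1645, 1467, 1085),
  height = conc * c(0.080, 0.100, 0.040, 0.060),
  width = c(25, 30, 20, 30))

#' Synthetic lecithin quantification demonstration
#'
#' End-to-end downstream demonstration on synthetic data: binary
#' lecithin (DPPC) / sphingomyelin mixtures are measured in runs of
#' sequential scans under a fluctuating water-vapor comb; each run's series
#' is corrected pairwise; corrected and uncorrected second-derivative
#' spectra are used to train PLS regressions predicting the DPPC
#' concentration, with run-wise cross-validated PRESS and F-test
#' latent-variable selection; held-out runs provide the test R-squared.
#'
#' Concentrations span 0-1.7 mM DPPC and 0-0.83 mM sphingomyelin (the
#' clinically relevant lecithin/sphingomyelin design). Both pipelines see
#' the same spectra count: the last scan of each run, lost to pairing in
#' the corrected set, is also dropped from the uncorrected set.
#'
#' @param n_runs number of measurement runs.
#' @param scans_per_run sequential scans per run (>= 2).
#' @param seed integer seed.
#' @param noise_sd white-noise standard deviation (AU).
#' @param interferent_amp peak water-comb amplitude scale (AU).
#' @param train_frac fraction of runs used for training.
#' @param alpha F-test threshold for [select_lv_ftest()].
#' @param window,polyorder Savitzky-Golay parameters.
#' @param max_lv largest latent-variable count evaluated.
#' @return list with one entry per pipeline (`corrected`, `uncorrected`),
#'   each carrying `press`, `k_min_press`, `k_selected`, `test_r2`,
#'   `predictions`; plus `design` (the run table) and `seed`.
#' @export
demo_lipid_pipeline <- function(n_runs = 40, scans_per_run = 8, seed = 1L,
                                noise_sd = 5e-4, interferent_amp = 0.04,
                                train_frac = 0.8, alpha = 0.25,
                                window = 11, polyorder = 3, max_lv = 12) {
  if (scans_per_run < 2) abort("scans_per_run must be >= 2", "atmcorr_config_error")
  axis <- c(1000, 2200, 2); fwhm <- 4
  bend <- interferent_spec("H2O-bend", wn_region(1205, 2072))
  centers <- seq(1230, 2050, by = 6)
  design <- with_seed(seed, data.frame(
    run = seq_len(n_runs),
    dppc = sample(seq(0, 1.7, length.out = n_runs)),
    sm = sample(seq(0, 0.83, length.out = n_runs))
  ))
  run_seeds <- with_seed(seed + 1L, sample.int(2^31 - 2, n_runs))
  Xc_list <- list(); Xu_list <- list(); y <- numeric(0); grp <- integer(0)
  for (r in seq_len(n_runs)) {
    comb_traj <- with_seed(run_seeds[r], {
      intens <- stats::runif(length(centers), 0.5, 1) * interferent_amp
      traj <- numeric(scans_per_run)
      traj[seq(1, scans_per_run, by = 2)] <-
        stats::runif(length(seq(1, scans_per_run, by = 2)), 0.8, 1)
      if (scans_per_run > 1)
        traj[seq(2, scans_per_run, by = 2)] <-
          stats::runif(length(seq(2, scans_per_run, by = 2)), 0, 0.1)
      list(comb = line_comb(centers, intens, fwhm = 4), traj = traj)
    })
    bands <- rbind(dppc_bands(design$dppc[r]), sm_bands(design$sm[r]))
    bands <- bands[bands$height > 0, , drop = FALSE]
    cfg <- scene_config(
      axis = axis, analyte_bands = if (nrow(bands)) bands else NULL,
      interferents = list(list(spec = bend, comb = comb_traj$comb,
                               coefficients = comb_traj$traj)),
      noise_sd = noise_sd, resolution_fwhm = fwhm, seed = run_seeds[r],
      n_scans = scans_per_run
    )
    sim <- simulate_series(cfg)
    corr <- correct_series(sim$series, interferents = list(bend),
                           noise_sd = noise_sd)
    n_kept <- length(corr$series$spectra)
    Xc_list[[r]] <- t(vapply(corr$series$spectra, function(s)
      second_derivative(s, window, polyorder)$absorbance,
      numeric(length(corr$series$spectra[[1]]$wavenumbers))))
    Xu_list[[r]] <- t(vapply(sim$series$spectra[seq_len(n_kept)], function(s)
      second_derivative(s, window, polyorder)$absorbance,
      numeric(length(sim$series$spectra[[1]]$wavenumbers))))
    y <- c(y, rep(design$dppc[r], n_kept))
    grp <- c(grp, rep(r, n_kept))
  }
  Xc <- do.call(rbind, Xc_list); Xu <- do.call(rbind, Xu_list)
  train_runs <- with_seed(seed + 2L,
                          sort(sample(n_runs, round(train_frac * n_runs))))
  in_train <- grp %in% train_runs
  run_one <- function(X) {
    press <- press_by_group_cv(X[in_train, , drop = FALSE], y[in_train],
                               grp[in_train], max_lv)
    sel <- select_lv_ftest(press, alpha = alpha)
    fit <- fit_plsr(X[in_train, , drop = FALSE], y[in_train], sel$k_selected)
    yhat <- predict(fit, X[!in_train, , drop = FALSE])
    yte <- y[!in_train]
    r2 <- 1 - sum((yte - yhat)^2) / sum((yte - mean(yte))^2)
    list(press = as.numeric(press), k_min_press = sel$k_min_press,
         k_selected = sel$k_selected, test_r2 = r2,
         predictions = data.frame(run = grp[!in_train], truth = yte,
                                  predicted = yhat))
  }
  list(corrected = run_one(Xc), uncorrected = run_one(Xu),
       design = design, train_runs = train_runs, seed = seed)
}
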