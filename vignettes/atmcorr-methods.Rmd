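---
title: "Correcting atmospheric absorptions in infrared spectra: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting atmospheric absorptions in infrared spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atmcorr)
```

## The problem

Background-corrected FTIR absorbance spectra are contaminated whenever the
water-vapor or CO~2~ content of the measurement chamber differs between the
background scan and the sample scan. The contamination is not a smooth
baseline: vapor-phase bands carry dense rotational fine structure — combs of
narrow lines — that overlap the fingerprint regions of proteins, lipids and
carbohydrates. Smoothing removes analyte information along with the lines;
least-squares fitting against libraries of calibration vapor spectra removes
the lines but demands extra measurements.

`atmcorr` implements a two-spectrum correction that needs nothing beyond
what a routine protocol already produces: two spectra of the same sample
recorded in immediate succession.

## The model

Within the short interval between two successive scans the *shape* of each
interferent spectrum is constant; only its concentration coefficient
changes. The measured spectrum at time $t$ is modeled additively:

$$S(t) = S_a + \sum_j c_j(t)\, S_j$$

with $S_a$ the analyte spectrum, $S_j$ the fixed basis spectrum of
interferent $j$ (water vapor, CO~2~, ...) and $c_j(t)$ its time-dependent
coefficient. Subtracting two successive scans inside a region where a
single interferent absorbs cancels $S_a$ and isolates

$$D = S(t_1) - S(t_2) = \left[c(t_1) - c(t_2)\right] S_w .$$

The corrected region is $S_m = S(t_1) - \gamma D$. Eliminating $S_w$
between the two expressions gives the ideal scaling factor

$$\gamma^\ast = \frac{c(t_1)}{c(t_1) - c(t_2)},$$

which is unknown because the coefficients are unknown. `atmcorr` therefore
determines $\gamma$ numerically: the spectrum is mapped to a unitless
polyline (x = sample index, y = absorbance) and its **point-to-point
length**

$$L = \sum_{i=1}^{n-1} \sqrt{\Delta x^2 + (y_{i+1} - y_i)^2}$$

is minimized over $\gamma$. A featureless spectrum attains the minimal
length $(n-1)\Delta x$; each residual rotational line adds to it. Each
summand of $L(\gamma)$ is the Euclidean norm of an affine function of
$\gamma$, so $L$ is convex and the minimizer is unique whenever $D \neq 0$.
In the package this closed form is used *only* as a ground-truth oracle in
tests (`simulate_series()` returns it as `truth$gamma_true`); the runtime
path is always the numerical minimization, as it would be on real data.

The corrected segment finally overwrites the region in the original
spectrum, with the absorbances matched at each end of the region
(see *Splicing* below). The procedure repeats per interferent, in
configuration order, each acting on the output of the previous one.

## Numerical choices

* **Euclidean mapping.** $\Delta x = 1$ (unit index spacing). Because
  $\Delta x$ is constant within a region, any fixed value yields the same
  minimizer; 1 is chosen for reproducibility. Absolute lengths reported in
  `gamma_curve` objects depend on this convention.
* **Conditioning.** Near the optimum, $L \approx (n-1)\Delta x$ dominates
  the objective and double-precision rounding flattens the curvature. The
  optimizer therefore minimizes the *excess* length
  $\sum_i \left(\sqrt{\Delta x^2 + d_i^2} - \Delta x\right)$, computed in the
  cancellation-free form $d_i^2 / (\sqrt{\Delta x^2+d_i^2}+\Delta x)$. This
  is an exact constant shift of $L$, so the minimizer is unchanged, but
  $\gamma$ resolves to machine precision instead of ~10^-5^.
* **Minimization.** Bounded scalar minimization (`stats::optimize`,
  golden-section/parabolic) over default bounds $[-50, 50]$ with tolerance
  10^-8^, followed by a few guarded Newton steps on the analytic gradient.
  Convexity makes this exact for the stated objective; the package does not
  fit a polynomial to the sampled $L(\gamma)$ curve — the 41-point curve
  returned in `gamma_curve` is diagnostic only. An optimum within tolerance
  of a search bound is flagged (`boundary = TRUE`) and surfaced as a
  warning by `correct_pair()`.
* **Degenerate differences.** When $\max|D|$ falls below
  $\max(10^{-6}\,\mathrm{AU},\ 3\hat\sigma)$ (with $\hat\sigma$ a
  caller-supplied noise estimate), the atmosphere did not change between
  the scans, the denominator of $\gamma^\ast$ vanishes, and no correction
  is the safe limit: `correct_pair()` records $\gamma = 0$ with a warning
  and leaves the region untouched.
* **Splicing.** The contract "absorbances matched at each end" is realised
  as a linear ramp added to the corrected segment so that its two endpoint
  values equal the original spectrum's values at the points immediately
  outside the region (a constant offset if the region abuts an axis end;
  nothing if it spans the whole axis). A linear ramp is the
  minimal-assumption continuous blend and is exactly invertible in tests.
  Consequence: exact analyte recovery at the boundaries requires the
  interferent to be negligible there — which is also the physical
  criterion for choosing correction regions wide enough to cover the band.
* **Axis discipline.** Spectra are stored ascending in wavenumber; regions
  map to index ranges by the nearest axis point, inclusively; series must
  share a bitwise-identical axis. No interpolation is ever performed — the
  method subtracts spectra point by point and silent resampling would
  corrupt exactly the sharp structure it targets.

## Known bias with noisy difference spectra

$D$ contains the noise of *two* scans. Minimizing $L$ then behaves like an
errors-in-variables regression: the recovered $\gamma$ is attenuated toward
zero by a factor of roughly
$\left(1 + 4\sigma^2 N / (\Delta c^2 \sum_i \Delta S_{w,i}^2)\right)^{-1}$.
The bias decays with the square of the interferent-to-noise ratio: measured
over 200 seeded scenes it is about 37% of $\gamma^\ast$ at ratio 10, 1.2%
at ratio 100, and indistinguishable from the Monte-Carlo error at 1000.
For realistic vapor lines (tens of milli-AU against sub-milli-AU noise) the
effect is negligible; at very low interferent levels the correction is
conservative — it under-subtracts rather than amplifying noise. The test
suite asserts the decay law rather than exact unbiasedness.

## Edge cases: transferring the scaling factor

A sharp, intense analyte band inside a correction region (a carbonyl band
near 1700 cm^-1^ inside the water bending region, say) biases the in-region
estimate of $\gamma$. Because the same gas absorbs elsewhere, the factor
can be estimated in an alternative clean region — 3231–4000 cm^-1^ for
water — and transferred: configure `gamma_region` in `interferent_spec()`.
The transfer is opt-in, mirroring a deliberate analyst decision; automatic
contamination detection is out of scope.

## Pairing a series

`correct_series()` corrects spectrum $k$ with spectrum $k+1$ (policy
`"next"`); the final spectrum has no successor and is dropped, so $n$ scans
yield $n-1$ corrected spectra. The mirror policy `"previous"` is provided
because "immediately before or after" are equally valid partners. The sign
of $\gamma$ flips with the pairing direction, which is why the CLI logs the
resolved file order in its manifest.

One usage requirement cannot be enforced in code: a **fresh background**
must be recorded before the sequence. Interferent absorption already
present at background time is constant across scans, cancels in $D$, and
is by construction uncorrectable.

## The RSD efficacy metric

With replicates of a static sample, the sample standard deviation (n−1
denominator) across replicates at each wavenumber measures what varies
scan to scan — noise, drift and atmospheric fluctuation. The **relative
standard deviation** normalizes it by the arithmetic mean of the
per-wavenumber standard deviation over a feature-free reference region
(default 4800–5000 cm^-1^), which carries only noise and drift.
RSD ≈ 1 across an interferent region therefore means the correction left
nothing but noise and drift; fluctuating vapor drives it far above 1.
Default targets are 1200–2100 cm^-1^ (water) and 2300–2400 cm^-1^ (CO~2~).
The "mean standard deviation" is interpreted as the mean over wavenumbers
of the pointwise standard deviation (not the standard deviation of means).
A correlation-based comparison (Fisher Z of pointwise Pearson coefficients)
is deliberately not offered: instrumental drift violates the i.i.d.
assumption it needs.

## What the simulator emulates — and what it does not

`simulate_series()` renders the additive model directly: Gaussian analyte
bands (condensed phase), Lorentzian line combs for vapor interferents
(pressure-broadened rotational lines; a Gaussian lineshape option exists
for scenes that need tail-free bases), per-scan coefficients, a slow
polynomial baseline drift, a Gaussian instrument lineshape of FWHM equal
to the nominal resolution (axis spacing = FWHM/2), and white noise.
Reproducibility is bit-exact for a fixed seed, and the caller's RNG stream
is never disturbed.

The canonical validation scene (`scene_water_fluctuation()`) alternates
the water coefficient between a high state (0.8–1.0) and a low state
(0–0.1), emulating chamber air exchange between scans, and calibrates the
comb amplitude so the median per-point interferent fluctuation is a stated
multiple (default 10×) of the noise. Strong scan-to-scan variation is the
regime where pairwise correction is well-posed: $\gamma^\ast = c_1/(c_1 -
c_2)$ stays of order one, so subtracting $\gamma D$ adds little noise. If
successive scans had nearly equal coefficients, $\gamma^\ast$ would
diverge — the degenerate-difference guard exists precisely for that limit.

Not emulated: real line lists (HITRAN), temperature- or pressure-dependent
line intensities (the method itself is invalid under rapid
temperature/pressure changes and the simulator respects that boundary),
interferogram-level instrument effects, and detector nonlinearity. A green
test on synthetic scenes therefore establishes the *algorithmic* contract
— exact recovery in the analytic limit, graceful degradation with noise —
not instrument-specific performance.

## Downstream chemometrics

The demonstration pipeline mirrors a clinical use case: predicting
lecithin (DPPC) concentration in lecithin–sphingomyelin mixtures, whose
ratio indicates fetal lung maturity. Spectra are preprocessed with a
Savitzky–Golay second derivative (default window 11 points, polynomial
order 3 — conventional values; both exposed), which resolves overlapping
condensed-phase bands but also *amplifies* narrow vapor lines, making
atmospheric correction more, not less, important for modeling.

Regression uses PLS1 (NIPALS, mean-centered, deterministic).
Cross-validation is **run-wise**: all spectra of one run share atmospheric
conditions, so folds hold out whole runs to avoid leakage. The
latent-variable count is chosen by the PRESS F-test: every model simpler
than the PRESS-minimizing one is compared through
$F(k) = \mathrm{PRESS}(k)/\mathrm{PRESS}(k_{\min})$ against an
$F(n, n)$ distribution ($n$ = number of cross-validated predictions), and
the smallest $k$ whose exceedance probability is above $\alpha = 0.25$
wins — the most parsimonious model not significantly worse than the best.
The $\alpha$ is the Haaland–Thomas convention and is exposed as a
parameter rather than hard-coded, because reported selection probabilities
in the literature are not always unambiguous about which quantity they
refer to.

## Validation strategy

Every claim the package makes is tested against an independent oracle:

* lengths against a literal Pythagoras loop;
* $\gamma$ against the closed form $c_1/(c_1-c_2)$ on noiseless scenes and
  against an exhaustive 10^-4^-step grid search over $[-50, 50]$ on noisy
  ones;
* convexity of every sampled $L(\gamma)$ curve;
* splice continuity, locality outside configured regions, and monotone
  length improvement;
* group-wise PRESS against brute-force per-fold, per-component refits;
* the F-test selection against direct F-distribution computation;
* RSD behavior against its sampling distribution under pure noise.

`scripts/acceptance.R` recomputes the headline figure — the median
corrected-series RSD in the water region of the canonical fluctuating
scene, which should be close to 1 — from scratch at any seed.

## Limitations

* Time-constant interferent residuals (stale background) are invisible to
  the method.
* The correction assumes interferent lineshapes identical across the pair;
  rapid temperature or pressure changes violate this.
* $\gamma$ attenuates at very low interferent-to-noise ratio (see above);
  the correction under-subtracts in that regime.
* Endpoint matching assumes the interferent is negligible at region
  boundaries; regions much narrower than the band will leave step
  artifacts that the linear ramp only partially hides.
* No transmittance conversion, proprietary binary formats, or resampling
  between mismatched axes.
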