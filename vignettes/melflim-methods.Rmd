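---
title: "Models and methods behind melflim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melflim)
```

# Scope

`melflim` implements the complete analysis chain used to characterize
melanin autofluorescence with multiphoton fluorescence lifetime imaging
(FLIM): simulation of time-correlated single photon counting (TCSPC) image
stacks, per-pixel bi-exponential reconvolution fitting, fit-free phasor
analysis with reference-fluorophore calibration, the phasor-distance
fraction of UVA-modified melanin (fUVA-Mel), and a statistical comparison
layer (Student t-tests, Cohen's d). No real acquisitions are bundled; the
synthetic generator reproduces the statistical structure the analysis
assumes, parameterized by published per-condition reference values.

# The forward model

A pixel's expected TCSPC histogram is the periodic convolution of a
bi-exponential decay with the instrument response function (IRF), sampled at
channel centers, plus a uniform background:

$$\mu_k = A\left[p_1 D_{\tau_1}(t_k) + (1-p_1) D_{\tau_2}(t_k)\right] + b,$$

where $D_\tau$ is the single-exponential response folded at the laser period
$T = 1/f$. For a Gaussian IRF of width $\sigma$ centered at $t_0$ the
convolution has the exponentially-modified-Gaussian closed form

$$h(t) = \tfrac12 e^{-(t-t_0)^2/2\sigma^2}\,
  \mathrm{erfcx}\!\left(\frac{\sigma/\tau - (t-t_0)/\sigma}{\sqrt2}\right),$$

and because $t_0 + 5\sigma \ll T$, all earlier pulses contribute a purely
geometric tail $e^{\sigma^2/2\tau^2} e^{-(t+T-t_0)/\tau}/(1-e^{-T/\tau})$.
`expected_decay()` is therefore exact to machine precision (the test suite
checks it against adaptive quadrature and a brute-force multi-period sum).

**Window vs. period.** The reference acquisition (783 channels of 16 ps at
80.08 MHz) declares a 12.528 ns window although the laser period is
12.4875 ns. A TCSPC unit cannot histogram beyond its sync interval, so the
trailing ~2.5 channels are treated as dark. Without this, those channels
would replay the bright rise of the next pulse and bias the phasor by ~0.01.

Photon noise is Poisson per channel with expectation proportional to
$\mu_k$, scaled so the expected pixel total equals the photon budget
(`simulate_decay_histogram()`, `render_phantom()`).

# Stated-world defaults of the generator

The generator's defaults are the published acquisition and sample
conditions; where a value is unprinted we chose once, as follows:

* **Decay presets.** The fourteen (melanin type x exposure) conditions of
  the reference table, as $(\tau_1, a_1\%, \tau_2)$ with
  $a_2\% = 100 - a_1\%$ (one printed row has $a_1\% + a_2\% = 100.52$, a
  rounding artifact).
* **IRF** — not characterized numerically in the source; default Gaussian,
  150 ps FWHM (typical hybrid-detector TCSPC), centered at 10% of the
  window. Configurable, and estimable from data (`estimate_irf()`).
* **Photon budget** — unprinted; default $10^4$ photons per 20 x 20 binned
  super-pixel (25 per raw pixel), enough for the fits to converge.
* **Fluorescein reference lifetime** — unprinted; default 4.0 ns, the
  standard literature value for fluorescein in basic buffer. Configurable
  everywhere it is used.
* **Background** — uniform per-channel dark counts, 0 for solutions, small
  for the `dark_powder` preset (whose only temporal structure is an
  IRF-shaped residual).
* **Aggregates** — melanin suspensions (DHI, Dopa, mixed eu-/pheo) contain
  bright aggregates with shorter lifetimes; they are modeled as disks with
  a x3 intensity multiplier and a shortened decay (tau x0.7/x0.8). Shape
  realism is a non-goal.

What a green test establishes: the analysis chain recovers the parameters
of data generated by its own forward model at realistic photon budgets.
What it does not establish: robustness to detector afterpulsing, pile-up,
multi-exponential decays beyond two components, or sample drift — none of
which the generator emulates.

# Bi-exponential reconvolution fitting

`fit_pixel_decay()` maximizes the Poisson likelihood (correct at the low
per-channel counts of TCSPC) of the counts against the forward model with
free $\tau_1, \tau_2, a_1, a_2$ and background. Numerical choices:

* **Initialization** — a least-squares scan over all pairs of a 14-point
  log-spaced lifetime grid (30 ps – 6 ns), solving the linear
  $(a_1, a_2, b)$ subproblem from precomputed Gram matrices shared across
  all pixels of an image.
* **Refinement** — Nelder-Mead on $(\log\tau_1, \log\tau_2, \log a_1,
  \log a_2, \log b)$, with two deterministically jittered restarts; the
  restarts are skipped once the Pearson reduced $\chi^2$ of the incumbent
  falls below 1.3. Deterministic jitters (rather than random restarts) keep
  the whole pipeline bit-reproducible under a seed.
* **Model selection** — a mono-exponential fit is always computed; the
  second component is kept only when it improves twice the log-likelihood
  by more than a BIC-like penalty $2\log n_{\text{channels}}$. Without
  this, mono-exponential inputs (fluorescein) acquire phantom components.
  Components are sorted so $\tau_1 \le \tau_2$; fits with lifetimes within
  1% collapse to mono-exponential.
* **QC** — pixels below `min_intensity` (default 100 counts per binned
  pixel; the published "noise level" threshold is unspecified) are flagged
  without fitting; fitted pixels with Pearson reduced $\chi^2 > 2$ fail QC.

Binning before fitting is sliding-window 20 x 20 pixels / 2 time channels.
Sliding (shape-preserving) rather than block binning was chosen because the
published parametric images retain full resolution; block mode exists behind
a flag. An odd trailing channel (783 = 2 x 391 + 1) is dropped and logged.
Because sliding windows make neighbors strongly correlated, `fit_image()`
accepts a `stride`; desk-scale runs fit a stride-8 grid (256 sites per
128 x 128 image), which leaves medians and ROI statistics unchanged at a
fraction of the cost of 16k correlated fits.

# Phasor analysis

The phasor of a histogram is the pair of normalized discrete cosine/sine
transforms at $\omega = 2\pi f$ over channel centers — counts are used as
weights directly, with no quadrature, because TCSPC data are histograms.
Spatial binning (sliding 10 x 10) is applied to the numerators and the
intensity separately, which is exact because the phasor is a ratio of
linear functionals. No thresholds or median filters are applied by default.

Calibration measures a mono-exponential reference (fluorescein) and applies
the unique rotation + scaling that moves its centroid onto the theoretical
semicircle position for $\tau_{\text{ref}}$; the same complex correction is
applied to every pixel. Pixels with $g \le 0$ or $m \ge 1$ after
calibration are flagged as missing, not clamped.

**fUVA-Mel** is the per-pixel Euclidean distance in the phasor plane to the
mean $(\bar g, \bar s)$ of the matched native condition, reported raw (and
x100 as a percent). Recomputing the published per-condition values from the
published condition centroids reproduces them exactly, so no hidden
normalization exists. Both condition-level summaries are computed: the mean
of per-pixel distances and the distance between condition centroids. By
Jensen's inequality the former is never smaller; they agree when the
displacement is large against pixel noise and differ at the noise floor —
which is why native (unexposed) conditions report small positive values.

A deliberate scope note: the published fit-derived and phasor-derived
parameters for the same condition are *not* mutually consistent under the
analytic phasor of the fitted model (different software, binning, IRF and
background handling in the source chain). The two families are therefore
treated as independent readouts, and no test asserts cross-family equality;
simulated phasor lifetimes derive from the fit-parameter presets and land
where the model puts them, not on the printed phasor means.

# Statistics

ROIs default to four equal-area quadrants (odd dimensions put the extra
row/column in the first half, deterministically). The statistical unit is
the ROI mean over QC-valid pixels. Effects are classic pooled-SD Cohen's d
— the published definition sentence is garbled, but the conventional
estimator matches both the name and the printed category breakpoints —
with Student's equal-variance t-test by default (Welch behind a flag) and
categories negligible (< 0.8), moderate [0.8, 1.5), strong [1.5, 2),
very strong [2, Inf). Contrasts are simple pairwise comparisons within a
melanin type; no multiple-testing correction is applied (raw p-values are
gated by effect size, as in the source analysis).

# Input/output

Canonical internal units are SI seconds; nanoseconds appear only in
reports. Stacks are 16-bit multi-page TIFF (one page per channel) with a
JSON sidecar carrying acquisition metadata and provenance; parametric maps
are 32-bit float TIFF with NaN as the missing-value sentinel. Because no R
TIFF package is available in the target environment, a minimal baseline
TIFF 6.0 codec (little-endian, uncompressed, single-sample) is implemented
in the package and cross-validated against an independent external
reader/writer in the test suite. Vendor formats (.ptu, .sdt) are out of
scope.

# Known limitations

* Two components only; no stretched-exponential or lifetime-distribution
  models, and no global multi-pixel fitting.
* The phasor discretization property (< 1e-4 agreement with the
  closed-form mono-exponential phasor) holds for lifetimes spanning at
  least ~10 channels; at 85 ps over 20 ps channels the center-sampling
  residual is ~2e-4, and the published window/period mismatch adds up to
  ~4e-4 at 4 ns on the 783-channel geometry.
* Condition means from quadrant ROIs of a single simulated image use n = 4
  replicates; the source design (3–4 regions x 4 ROIs) has more. Effect
  sizes of the magnitudes involved here are insensitive to this.
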