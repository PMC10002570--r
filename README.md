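# melflim

Multiphoton FLIM analysis of melanin autofluorescence in R.

Melanins — the eumelanin and pheomelanin pigments of human skin and hair —
are weak endogenous fluorophores whose fluorescence lifetimes change when
UVA light oxidizes, photo-degrades or crosslinks the polymer. Multiphoton
fluorescence lifetime imaging (FLIM) can therefore read out melanin
photo-modification non-invasively. `melflim` implements the full analysis
chain for time-correlated single photon counting (TCSPC) FLIM stacks of
melanin samples, for researchers who want a tested, scriptable version of
that chain and a synthetic-data generator to validate it against known
ground truth.

## What it computes

Each pixel of a TCSPC stack holds a photon-arrival histogram `I(t)`. Two
independent readouts are implemented:

**Bi-exponential reconvolution fitting.** The decay is modeled as
`I(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)`, convolved with the instrument
response function and folded at the laser period, and fit per (binned) pixel
by Poisson maximum likelihood. Reported per pixel: `tau1`, `tau2`, relative
amplitudes `a1% = 100 a1/(a1+a2)`, `a2%`, the amplitude-weighted average
`tauAvAmp = (a1 tau1 + a2 tau2)/(a1 + a2)`, the intensity-weighted average
`tauAvInt = (a1 tau1^2 + a2 tau2^2)/(a1 tau1 + a2 tau2)`, and a Pearson
reduced chi-squared with the conventional `< 2` quality rule.

**Phasor analysis.** The fit-free transform
`g = sum I_k cos(w t_k) / sum I_k`, `s = sum I_k sin(w t_k) / sum I_k`
at `w = 2 pi f` (laser fundamental), calibrated against a fluorescein
reference so mono-exponential decays land on the universal semicircle
`(g - 1/2)^2 + s^2 = 1/4`. Derived: the phase and modulation lifetimes
`tau_phi = (s/g)/w`, `tau_m = sqrt(1/(g^2+s^2) - 1)/w`, two-species mixture
fractions by projection onto the segment joining pure-species phasors, and
**fUVA-Mel** — the Euclidean phasor distance of every pixel to the mean
`(g, s)` of the matched native melanin, read as the relative fraction of
UVA-modified species.

Condition comparisons use quadrant-ROI means with Student t-tests and
pooled-SD Cohen's d, categorized as moderate [0.8, 1.5), strong [1.5, 2) or
very strong [2, Inf).

A synthetic-data module generates TCSPC stacks with the published
acquisition geometry (512 x 512 x 783 channels x 16 ps at 80.08 MHz) and
bi-exponential presets for native and UVA-exposed DHI, DHICA and Dopa
eumelanins, pheomelanin and mixed eu-/pheomelanin, plus a fluorescein
calibration sample and a dark-powder control.

## Worked example

Simulate the DHICA eumelanin UVA series at desk scale, run both analyses,
and compare conditions:

```r
library(melflim)
cfg <- run_config(presets = c("dhica_native", "dhica_uva1", "dhica_uva7"),
                  acq = acq_preset("paper", image_shape = c(64, 64)),
                  fit_stride = 8L, out_dir = "melflim_demo", seed = 1)
res <- run_pipeline(cfg)
round(res$table2[, c("tau1", "a1_pct", "tau2", "tau_av_amp",
                     "tau_phi", "tau_m", "fuva")], 3)
#>    tau1 a1_pct  tau2 tau_av_amp tau_phi tau_m  fuva
#> 1 0.085 98.404 2.063      0.117   0.394 1.135 0.009
#> 2 0.110 93.745 2.188      0.240   0.886 1.751 0.215
#> 3 0.206 81.139 2.506      0.639   1.406 2.235 0.376
```

Row 1 is the native condition: the fits recover the generating preset
(`tau1` 0.085 ns, `a1%` 98.43, `tau2` 2.096 ns) and the amplitude-weighted
lifetime (0.117 ns) to within fit noise. UVA exposure lengthens the
lifetimes, drops `a1%`, and moves the phasor: the fUVA-Mel fraction climbs
from the native noise floor (0.009) to 0.215 after 1 day and 0.376 after
7 days of simulated UVA exposure — ordered exactly as the underlying decay
models dictate. The contrast table flags those shifts:

```r
subset(res$contrasts, parameter == "fuva" & condition_a == "dhica_native",
       c(condition_b, d, category, p))
#>    condition_b         d    category            p
#> 11  dhica_uva1  -56.7208 very_strong 2.527535e-10
#> 22  dhica_uva7 -141.4963 very_strong 1.050927e-12
```

`melflim_demo/` receives the ROI summary, the condition-level report
(`table2.csv`), the contrast table, per-condition phasor scatters, the
parametric maps as 32-bit TIFF, and a JSON provenance record with the seed
and configuration.

## Layout

- `R/` — simulator (`expected_decay`, `render_phantom`, `melanin_presets`),
  fitting (`fit_pixel_decay`, `fit_image`, `estimate_irf`), phasor
  (`compute_phasor`, `calibrate`, `phasor_lifetimes`, `fraction_modified`),
  statistics (`define_rois`, `cohens_d`, `compare_conditions`), I/O
  (`read_tcspc_stack`, `write_parametric_map`) and the pipeline
  (`run_config`, `run_pipeline`, `table2_report`).
- `vignettes/melflim-methods.Rmd` — models, assumptions, numerical choices
  and limitations.
- `inst/cli/melflim.R` — `simulate | fit | phasor | stats | run`
  subcommands.
- `tests/testthat/` — unit, property and acceptance tests.
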