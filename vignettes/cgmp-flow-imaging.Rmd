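---
title: "Quantifying shear-dependent cGMP dynamics in platelet thrombi"
author: "cgflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shear-dependent cGMP dynamics in platelet thrombi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Platelets express a FRET-based cGMP indicator (a cGMP-binding domain
flanked by CFP and YFP; cGMP binding lowers FRET, so the CFP/YFP emission
ratio rises with cGMP). In a flow chamber, thrombi formed on collagen are
superfused with an NO donor while the buffer flow is switched on and off;
under flow, cGMP rises steeply, and after flow cessation it returns to the
basal level within roughly 20 seconds. In vivo, growing thrombi show
higher cGMP at their flow-exposed periphery than in the densely packed
core, and genetic removal of the cGMP-synthesizing enzyme prolongs
thrombus dissolution. `cgflow` implements the complete quantitative chain
behind such observations:

1. **Segmentation** of the dynamic thrombus from the CFP+YFP sum image,
   with a core/periphery partition.
2. **Ratiometrics**: background-corrected F480/F535 (and Fura-2 F340/F380)
   regional traces, baseline normalization, SNR-based exclusion, and a
   Hill-type sensor calibration with saturation handling.
3. **Kinetics**: thrombus growth metrics, peak areas above a linear
   baseline, and the cGMP-to-Ca2+ lead-lag.
4. **Hydrodynamics** for parallel-plate flow chambers.
5. **Statistics** used for group comparisons in such experiments.
6. A **synthetic movie generator** with pixel-exact ground truth, because
   validated recovery on known inputs is the only way to trust the chain
   end to end.

## Segmentation model

Per frame, the CFP and YFP images are summed and blurred with a Gaussian
(`blur_sigma`, default 2 px). The whole thrombus is the largest connected
component at or above an intensity threshold; the threshold is set
manually in the reference workflow, and `threshold = "otsu"` offers an
automated default computed on the brightest frame. The core is defined by
an intensity criterion: pixels of the whole mask at or above
`core_factor * threshold` (default 1.2, i.e. 20% above the segmentation
threshold); the periphery is the remainder, so core and periphery
partition the whole mask exactly in every frame. The source description of
this step mixes the language of erosion ("eroded by a user-defined
distance") with an intensity definition ("~20% higher than original
threshold intensity"); we implement the intensity criterion, because the
parenthetical defines the operation, and expose a morphological-erosion
variant (`core_method = "morphological"`) for comparison. The criterion is
applied to the blurred sum image — the same image that defines the mask.

Empty-mask frames are flagged and carried through as missing values, never
dropped. Masks use 0-based frame indices; time is `frame * dt` seconds.
Connected components come from `EBImage::bwlabel`.

## Ratiometrics and sensor calibration

Background is either a user rectangle (checked to be disjoint from every
whole mask) averaged per channel and frame, or by default the median of
all pixels outside the whole mask dilated by 5 px. Regional traces are
means of background-corrected pixels under the dynamic masks; the cGMP
ratio is `R = F480/F535`, and `dR/R` normalizes to the mean over a
baseline window (default: the 10 valid frames preceding the first flow-on
event). The signal-to-noise ratio of a trace is the peak absolute
deviation of `R` from its baseline mean within a response window, divided
by the baseline SD; traces with SNR < 2.5 are excluded, and each decision
is logged. The SNR formula itself is this package's definition (the
reference workflow states the 2.5 cutoff but not the formula), and it is
recorded in the output metadata.

The sensor is modeled as a Hill curve
`R(c) = r_min + (r_max - r_min) * c^n / (ec50^n + c^n)` with defaults
`ec50 = 0.5` µM, `n = 1`, `r_min = 1`, `r_max = 2`, and a quantification
bound `c_sat = 3` µM. The published calibration constants for this sensor
family are not printed in the source; these defaults are consistent with
the sensor's name, its saturation above 3 µM, and typical ratio swings,
and all four parameters are configuration-exposed and serialized with
every result — inverse-calibrated concentrations are model-dependent and
must be read as such. `sensor_inverse()` is the exact algebraic inverse
below saturation; at or beyond `c_sat` it reports the lower bound `c_sat`
with `saturated = TRUE` (the raw algebraic value stays available).

Ca2+ is reported as the classic Fura-2 ratio F340/F380, processed exactly
like the FRET channels; an inverted, baseline-normalized display trace
supports visual lead-lag comparison.

## Kinetics

Growth metrics follow the standard definitions: `t_max` is the earliest
time of the global area maximum; the half-dissolution time is the time
from the maximum to the first crossing of 50% of the maximum, linearly
interpolated between frames and reported as censored ("> observed span")
when never reached; the AUC is the trapezoidal integral of area minus a
baseline (default 0, the pre-injury area in a laser-injury model; the
un-subtracted integral is also reported because the original analysis
settings are not printed); `A_end` is the area at the end of the
experiment. Peak areas of `dR/R` traces subtract the linear chord between
manually chosen borders before integrating.

The lead-lag estimator cross-correlates the *first differences* of the
two traces (differencing suppresses slow drifts) over lags up to
`max_lag`, refines the peak by parabolic interpolation, and flags
estimates whose peak correlation falls below 0.5. A negative lag means the
first trace (cGMP) precedes the second (Ca2+). The quantitative estimator
is this package's addition — the original comparison was visual — and its
output is labeled accordingly.

## Flow-chamber hydrodynamics

`shear_rate_from_flow()` uses the ideal parallel-plate formula
`gamma_dot = 6 Q / (w h^2)`; manufacturer slide-specific correction
factors are not public, so a user correction factor (default 1) is
exposed instead, and chambers with `width < 10 * height` are flagged. The
default viscosity of 0.01 dyn·s/cm² (1 cP) is the only value consistent
with the printed pairing of 500 s⁻¹ with 5 dyn/cm².

## What the synthetic generator emulates

The generator encodes the study conditions as defaults: 1 Hz acquisition
for 300 s; flow on between 60 and 120 s at 500 s⁻¹; first-order cGMP
kinetics per region (`tau_on = 4` s, `tau_off = 5` s, chosen so baseline
recovery completes within ~20 s of flow cessation, i.e. 3·tau_off = 15 s
to reach the 5% band); resting cGMP 0.1 µM rising to 0.8 µM in the core
and 4 µM in the periphery (deliberately beyond the 3 µM saturation bound
so saturation handling is exercised); a thrombus growing to 500 µm² at
60 s and dissolving to 200 µm² by 300 s (2000 µm² at full 256×256 scale);
Poisson shot noise plus Gaussian read noise on a constant background,
seedable and bit-reproducible.

Geometry is a centered disc with an annular periphery of relative width
0.2. Brightness (platelet density) declines linearly from 2× the rim
value at the center to 1× at the rim and continues with the same slope
into a diffuse skirt outside the rim. This shape is chosen so that the
reference segmentation rules are *exactly* exercised: a threshold at the
rim intensity crosses the (blur-invariant, locally linear) profile at the
true radius, and 1.2× that threshold crosses at about 0.8 of the radius —
the same geometry as the annulus. Channels split a density-proportional
total emission according to the FRET ratio, `CFP = S·d·R/(1+R)` and
`YFP = S·d/(1+R)`, so that the background-corrected pixel ratio equals the
sensor curve exactly, CFP and YFP move in opposite directions on any cGMP
step, and the CFP+YFP sum used for segmentation is independent of the
cGMP state. Regional Ca2+ follows the normalized cGMP excursion with a
sign flip and a configurable delay (default 2 s, cGMP leading).

In-vivo cGMP magnitudes in periphery versus core are not published;
the default levels are plausible, not measured, and are stated as such.

What the generator does **not** emulate: photobleaching, stage drift or
motion, vessel walls, flowing-platelet streaks, embolization, spectral
bleed-through, and multi-thrombus fields. Passing tests on synthetic
movies therefore demonstrate correctness of the analysis chain under the
stated signal model, not robustness to those real-data artifacts.

## Numerical and design choices

* Thresholding on synthetic input: Otsu assumes a bimodal histogram and
  lands inside the diffuse skirt of the synthetic profile, so pipeline
  runs on simulated movies default to the generator's rim intensity
  (`rim_threshold()`), the value a manual operator would set; an explicit
  threshold always wins and is recorded.
* cGMP integration is the exact exponential update per frame
  (piecewise-constant target), so step responses are analytic; a warning
  is issued when `dt >= tau/2`.
* Ties at the area maximum resolve to the earliest frame; half-dissolution
  interpolation is linear; censored values are never imputed.
* The trapezoid rule makes AUCs exact for piecewise-linear profiles and
  additive over adjacent intervals.
* Degenerate inputs are handled explicitly: empty masks are flagged,
  zero-variance baselines yield SNR = Inf with a warning (retained),
  out-of-range ratios are clipped with a flag, zero-variance equal-mean
  group comparisons return p = 1 with a note.
* Censored bleeding times are kept at the cap as midrank ties (matching
  the assay's stopping rule), not discarded; whether the original
  analysis did the same is not stated, so both behaviors are available.
* The Welch-vs-Student choice in `auto` mode uses an F-test of variance
  equality at alpha = 0.05 (the original criterion is unstated); the
  choice is recorded in the result notes.
* Problem sizes in the validation suite: routine tests run 96×96 movies
  of 120-150 frames; ground-truth recovery is additionally verified on
  300-frame 256×256 movies, the scale of the reference recordings.

## Known limitations

* Inverse-calibrated concentrations inherit the uncertainty of the
  assumed sensor constants; report them together with the serialized
  `sensor_model` (the pipeline does this automatically).
* Region traces from *estimated* masks mix a thin band of core pixels
  into the periphery (and vice versa) near the 0.8 r boundary; with a
  saturating periphery this biases the periphery concentration estimate
  downward by a few tens of percent. Calibration-recovery accuracy is
  therefore specified against true regions, and regional mixing is bounded
  by the Jaccard requirements on the masks themselves.
* The default background estimate (median outside the dilated whole mask)
  carries a small positive bias when a diffuse skirt surrounds the
  thrombus (≤ 0.5% of the thrombus signal under default conditions); use
  an explicit background rectangle when absolute channel intensities
  matter.
* No motion correction, no multi-thrombus tracking, no 3D segmentation,
  no non-Newtonian rheology, and no absolute Ca2+ calibration.

## A complete run

```{r, eval = FALSE}
library(cgflow)
cfg <- run_config(seed = 1)        # simulate the default study conditions
bundle <- run_pipeline(cfg)
bundle$summary$regions             # flow-on dR/R per region
bundle$kinetics                    # growth metrics through the imaging chain
write_report(bundle, "cgflow_out") # CSV/JSON artifacts + MD5 manifest
```

Identical configuration and seed reproduce byte-identical reports; the
manifest records the package version, seed and per-file checksums.
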