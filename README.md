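# cgflow

Quantification of shear-dependent cGMP signaling in platelet thrombi from
multi-channel fluorescence time-lapse movies.

Platelets carry a FRET-based cGMP sensor whose CFP/YFP emission ratio
R = F480/F535 increases with intracellular cGMP. Under flow and NO, thrombi
show steep cGMP transients that collapse back to baseline within ~20 s of
flow cessation, a periphery > core cGMP gradient in growing thrombi, and
cGMP changes that precede the suppression of Ca²⁺ signaling. `cgflow`
implements the full analysis chain for such recordings:

* **Dynamic segmentation** — Gaussian-blurred CFP+YFP sum image (σ = 2 px),
  intensity threshold, largest connected component, and a core/periphery
  partition (core = pixels ≥ 1.2 × threshold; periphery = remainder).
* **Ratiometrics** — background-corrected regional traces, R = F480/F535,
  ΔR/R baseline normalization, SNR < 2.5 exclusion, Fura-2 F340/F380, and a
  Hill-type sensor calibration
  `R(c) = r_min + (r_max − r_min)·cⁿ/(EC₅₀ⁿ + cⁿ)` with an exact algebraic
  inverse that reports concentrations ≥ 3 µM as a saturated lower bound.
* **Kinetics** — time to maximal thrombus size, maximal size,
  half-dissolution time (peak → 50%, interpolated, censoring-aware),
  trapezoidal AUC, stabilized end size; linear-baseline peak areas; and a
  derivative cross-correlation lead-lag estimator for cGMP vs. Ca²⁺.
* **Hydrodynamics** — parallel-plate conversions `γ̇ = 6Q/(w·h²)` and
  `τ = η·γ̇` (500 s⁻¹ ↔ 5 dyn/cm² at 1 cP).
* **Statistics** — Student/Welch t-test with variance-based auto-selection,
  exact Mann-Whitney U with censoring at a cap, one-way ANOVA + Tukey HSD,
  and the 800–1300 × 10⁶ mL⁻¹ platelet-count inclusion filter.
* **Synthetic movies** — a seedable generator with pixel-exact ground truth
  (flow on/off schedule, first-order cGMP kinetics, periphery > core
  gradient, saturating sensor, lagged anticorrelated Ca²⁺, Poisson + read
  noise) used to validate every stage end to end.

## Worked example

```r
library(cgflow)
cfg <- run_config(seed = 1)   # default synthetic study conditions:
                              # 1 Hz, 300 s, flow on 60-120 s at 500 1/s
bundle <- run_pipeline(cfg)
bundle$summary$regions
#>      region mean_dRR_flow_on  baseline_sd responder
#> 1     whole        0.4291939 0.0004725906      TRUE
#> 2      core        0.3649864 0.0008151629      TRUE
#> 3 periphery        0.5840586 0.0008005704      TRUE
bundle$summary$settle_after_last_off_s
#> [1] 18
bundle$kinetics
#> Thrombus growth metrics
#>   t_max: 60 s   A_max: 496.75 um^2
#>   t_half_dissolution: 199.409 s
#>   AUC: 97730.8 um^2*s (baseline 0)   A_end(299 s): 198 um^2
```

Reading: during flow the periphery responds more strongly than the core
(mean ΔR/R 0.58 vs. 0.36 — the periphery > core cGMP gradient), every
region passes the SNR filter, and after flow-off the whole-thrombus ΔR/R
trace re-enters the ±5% baseline band within 18 s. The growth metrics
recover the generated profile (true maximum 500 µm² at 60 s, end size
200 µm²) through the full imaging chain. Inverse calibration of the
periphery plateau ratio (R ≈ 1.87) reports the saturation bound:

```r
rt <- bundle$ratio
plateau <- mean(rt$R[rt$region == "periphery" & rt$t >= 90 & rt$t < 120])
sensor_inverse(plateau)
#>   c    c_raw saturated clipped
#> 1 3 3.380199      TRUE   FALSE
```

Shear conversions and a thin CLI are included:

```sh
exec/cgflow shear --flow-rate 0.25
# {"flow_rate":0.25,"shear_rate":500,"shear_stress":5}
exec/cgflow run --outdir out --seed 1
```

See `vignettes/cgmp-flow-imaging.Rmd` for the model, parameter and design
documentation.

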