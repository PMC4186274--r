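# parallaxdepth

Perceived depth from motion parallax, modelled with the motion/pursuit
ratio.

## What this is for

During lateral observer translation, the visual system can recover the
relative depth of a non-fixated point from two proximal signals: its
retinal image speed *dθ* (deg/s) and the compensatory pursuit eye-movement
speed *dα* (deg/s) that maintains fixation. Geometrically,

    d/f = (dθ/dα) · 1 / (1 − dθ/dα)   ≈   dθ/dα      (for small ratios),

with *f* the viewing distance (cm). Psychophysically, however, depth from
motion parallax is strongly foreshortened — observers match it to far less
binocular disparity than the geometry predicts. This package implements
the analysis chain used to quantify that foreshortening with a 2IFC
depth-matching experiment against disparity comparison stimuli, and the
power-law transducer model that summarises it, the **empirical
motion/pursuit ratio**:

    d_mp = k · f · dθ^r / dα^e        (defaults r = 0.416, e = 0.192,
                                       k = 0.0313 with rates in deg/s)

For users in visual psychophysics it provides:

* the geometric laws and unit conversions (`exact_relative_depth()`,
  `approx_depth()`, `disparity_to_depth()` / `depth_to_disparity()`,
  `head_speed_to_pursuit_rate()`, `pixel_to_angle()`,
  `pursuit_fraction()`, `rescale_model()`);
* cumulative-normal psychometric fitting with PSE/σ and depth conversion
  (`fit_cumulative_normal()`, `pse_to_depth()`,
  `sigma_to_depth_threshold()`, `aggregate_trials()`, `fit_session()`);
* a seeded synthetic 2IFC observer for head-stationary, head-translating
  and depth-constancy control sessions (`simulation_config()`,
  `build_stimulus_grid()`, `simulate_trials()`,
  `simulate_head_translation_session()`,
  `simulate_depth_constancy_control()`);
* log-space least-squares plane fitting that recovers (r, e, k), plus a
  stereo-distortion-adjusted refit (`fit_empirical_mpr()`,
  `johnston_adjust_and_refit()`, `predict_depth_surface()`);
* an end-to-end pipeline with trial CSV I/O and a leave-one-out outlier
  screen (`run_full_pipeline()`, `read_trials()` / `write_trials()`,
  `exclude_outlier_observers()`, `analyze_depth_constancy()`), and a thin
  shell wrapper in `inst/scripts/run_pipeline.R`.

See the methods vignette source (`vignettes/motion-pursuit-depth.Rmd`) for
the model, the generator's assumptions, and all numerical choices.

## Worked example

```r
library(parallaxdepth)

# geometric prediction: ratio 0.25 at 36 cm
approx_depth(dtheta = 0.25, dalpha = 1, f = 36)
#> [1] 9

# what an observer actually perceives, per the empirical model: ~0.9 cm
empirical_depth(dtheta = 0.25 * 4.95, dalpha = 4.95, f = 36)
#> [1] 0.9056939

# depth depicted by 23.3 arcmin of disparity at 36 cm (i = 6.5 cm)
disparity_to_depth(23.3, f = 36)
#> [1] 1.351368

# simulate a reduced session and run the full analysis
cfg <- simulation_config(n_observers = 3, n_blocks = 6,
                         n_control_observers = 3, n_control_blocks = 1)
report <- run_full_pipeline(cfg, seed = 42)
report
#> == Motion-parallax depth pipeline report ==
#> seed 42 | simulated trials: 12636 | observers kept: 3 of 3
#> psychometric functions: 78 (group), 0 unconverged
#> units: depth cm, rates deg/s, disparity arcmin, natural logs
#>
#> -- head-stationary transducer plane --
#> Log-space plane fit of the empirical motion/pursuit ratio
#>   ln(d/f) = -3.464 + 0.3949 ln(dtheta) -0.1928 ln(dalpha)   (natural logs)
#>   r^2 = 0.9608 on 52 points (0 excluded)
#>   exported model: r = 0.3949, e = 0.1928, k = 0.03129 (degree-based)
#> ...
#> -- head-translating pursuit decomposition --
#>  condition_id f_cm head_speed_cm_s total_dalpha_deg_s equivalent_dalpha_deg_s
#>       trans36   36           11.01              17.53                   7.756
#>       trans72   72           12.09               9.62                   3.926
#>  pursuit_fraction_pct
#>                 44.26
#>                 40.81
#> ...
```

Reading the output: the plane fit recovers the generating transducer
(r ≈ 0.39, e ≈ 0.19, k ≈ 0.031 at this reduced session size), i.e. depth
estimates formed from 12,636 binary depth comparisons reproduce the
power-law foreshortening they were generated with. The pursuit
decomposition shows that during head translation the depth matches are
explained by roughly 40–45% of the total compensatory eye speed — the
pursuit share — and the control analysis (in the full report) shows
normalized depth-constancy matches near 1.

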