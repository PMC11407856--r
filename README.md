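# jumpnat

Projectile-motion models of the perceived naturalness of human jumping.

## The problem

When a recorded human jump is edited — made higher, lower, faster or slower —
observers often judge the result unnatural. The working hypothesis behind
this package is that observers compare the seen flight trajectory with the
trajectory a vertical projectile under Earth gravity would follow, predicted
from the jump's initial velocity. A recorded flight phase h(t) obeys

    h(t) = v0 t − ½ g t²

with initial vertical velocity v0 and gravity g. Scaling the heights by a
ratio **H** and the times by a ratio **T** yields a new trajectory whose
implied ("effective") gravity is g·H/T². It remains a valid Earth-gravity
projectile exactly on the **theoretical curve T = √H**; off that curve the
mismatch between observed and predicted motion grows, and so — under the
hypothesis — does perceived unnaturalness.

The package is aimed at researchers in motion perception and character
animation who want to score modulated jump stimuli, generate synthetic rating
studies, and run the associated rank-correlation analyses.

## What it computes

Three families of naturalness statistics for a modulated jump with recovered
initial velocity v0′, effective gravity g_eff and flight duration D:

| statistic | definition | units |
|---|---|---|
| `d_HT` | \|log T − ½ log H\| (log distance from the theoretical curve) | — |
| `RMS_height` / `RMS_vel` / `RMS_acc` | √(Σ(obs − pred)²/N) between the observed channel and the projectile prediction from v0′ under gravity g | m, m/s, m/s² |
| `tau_diff_apex` / `tau_diff_full` | \|v0′/g − D/2\| or \|2v0′/g − D\| (timing prediction error) | s |
| `h_diff` | \|v0′²/(2g) − max h\| (apex-height prediction error) | m |

For ballistic inputs these statistics obey closed-form identities, e.g.
`tau_diff_apex = (√3 / 2g) · RMS_vel` in the dense-sampling limit, and all of
them vanish exactly on the theoretical curve. Around the statistics sit:

- least-squares projectile fitting (no intercept) and flight-phase extraction
  from marker tables (`fit_projectile()`, `extract_flight_phase()`);
- the 81-condition (9 × 9, exp-spaced 0.50 … 2.01) modulation grid
  (`condition_grid()`);
- Spearman correlation of model scores with condition-averaged visual-analogue
  ratings, participant-bootstrap model comparison with Bonferroni correction,
  per-participant and per-jumper analyses, and a 0.5 g – 2 g gravity sweep
  (`spearman_correlation()`, `bootstrap_corr_difference()`,
  `gravity_sweep()`);
- a synthetic-data generator for jumps, 41-marker point-light tables and
  32-participant rating studies (`synth_jump()`, `synth_marker_table()`,
  `synth_ratings()`).

## Worked example

Slow a one-second jump to twice its duration without raising it
(H = 1, T = 2) and score it:

```r
library(jumpnat)
traj <- synth_jump(t_n = 1, g = 9.81, frame_rate = 120)
mod  <- modulate(traj, H = 1, T = 2)
fit  <- fit_projectile(mod)
fit
#> <projectile_fit> v0' = 2.4525 m/s, g_eff = 2.4525 m/s^2
#>   flight 2.0000 s, rms residual 1.46e-15 m (n = 121)
```

The slowed jump implies gravity 2.45 m/s² — a quarter of Earth's, so it looks
"moon-like". Its naturalness penalties:

```r
rms_disparity(mod, fit, channel = "velocity")  #> 8.513683   (m/s)
tau_diff(fit)                                  #> 0.75       (s)
h_diff(mod, fit)                               #> 0.9196875  (m)
model1_deviation(H = 1, T = 2)                 #> 0.6931472
```

A full synthetic study and its analysis:

```r
cfg   <- run_config(seed = 4)
paths <- cmd_simulate(cfg, "demo")           # markers, ratings.csv, sidecar
report <- cmd_analyze(cfg, paths$ratings, paths$trajectory, "demo/out")
report
#> <naturalness_report> 32 participants, 81 conditions
#>   d_HT           rho = -0.838  (p = 1.96e-22)
#>   RMS_height     rho = -0.771  (p = 3.94e-17)
#>   RMS_vel        rho = -0.880  (p = 2.71e-27)
#>   RMS_acc        rho = -0.737  (p = 4.44e-15)
#>   tau_diff_apex  rho = -0.879  (p = 4.07e-27)
#>   tau_diff_full  rho = -0.879  (p = 4.07e-27)
#>   h_diff         rho = -0.714  (p = 7.02e-14)
#>   best model by |rho|: RMS_vel
```

The synthetic observers track the velocity-disparity statistic, and the
analysis recovers it: `RMS_vel` correlates most strongly with the ratings,
with the timing statistic indistinguishable from it (the two are analytically
proportional). If you have a real rating table in the same CSV layout
(`participant_id, jumper_id, H, T, rating`), pass it to `cmd_analyze()`
directly.

A thin command-line front end over the same functions ships in
`inst/cli/jumpnat.R` (subcommands `simulate | modulate | score | analyze |
sweep`).

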