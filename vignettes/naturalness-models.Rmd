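---
title: "Projectile-motion models of jump naturalness: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projectile-motion models of jump naturalness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpnat)
```

## The model

The flight phase of a vertical jump — from takeoff to landing, with
preparatory and landing actions excluded — is treated as a vertical
projectile: height $h(t) = v_0 t - \tfrac12 g t^2$, velocity
$v(t) = v_0 - g t$, constant acceleration $-g$. A recorded jump is
*modulated* by multiplying its translation heights by a ratio $H$ and its
frame times by a ratio $T$. The modulated trajectory is again a projectile,
with

$$v_0' = \frac{H}{T} v_0, \qquad g_\mathrm{eff} = \frac{H}{T^2} g,$$

so it remains consistent with Earth gravity exactly on the **theoretical
curve** $T = \sqrt H$. The package's naturalness statistics all measure, in
different currencies, how far a modulated jump sits from that curve:

1. **Ratio deviation** `d_HT` $= |\log T - \tfrac12 \log H|$: the log-space
   distance of the condition itself from the curve. The logarithm encodes
   the assumption that the sensory response to a physical modulation ratio
   is compressive. It is defined so that it is *exactly* zero on the curve.
2. **Trajectory disparity** `RMS_height`, `RMS_vel`, `RMS_acc`: the observer
   is assumed to (i) extract the initial velocity $v_0'$ of the observed
   jump, (ii) predict the height, velocity or acceleration trajectory of a
   projectile launched at $v_0'$ under gravity $g$, and (iii) accumulate the
   root-mean-square disparity between observed and predicted channel over
   the $N$ samples of the stimulus.
3. **Feature prediction error** `tau_diff_apex` / `tau_diff_full` and
   `h_diff`: the observer predicts a single feature — time to apex
   $v_0'/g$ (or full flight time $2v_0'/g$), or apex height $v_0'^2/(2g)$ —
   and compares it with the observed value.

For ballistic inputs these families are analytically linked. Writing
$\Delta = |g - g_\mathrm{eff}|$ and $D$ for the flight duration, the
dense-sampling limits are

$$\mathrm{RMS}_{height} = \frac{\Delta D^2}{2\sqrt5}, \qquad
  \mathrm{RMS}_{vel} = \frac{\Delta D}{\sqrt3}, \qquad
  \mathrm{RMS}_{acc} = \Delta, \qquad
  \tau_\mathrm{diff}^{apex} = \frac{\sqrt3}{2g}\,\mathrm{RMS}_{vel}.$$

The last identity means the timing statistic and the velocity disparity are
rank-equivalent against any rating vector: the two cognitive stories
(continuous velocity monitoring versus a one-shot duration prediction)
cannot be separated by these stimuli. The full-flight timing convention is
exactly twice the apex one, hence also rank-equivalent; `apex` is the
default and both are exposed. The velocity disparity is asymmetric between
mirror conditions: for $H = a, T = 1/a$ versus $H = 1/a, T = a$ ($a > 1$)
the faster jump scores worse by a factor $a$, which is what makes it (and
the timing statistic) qualitatively different from the symmetric ratio
deviation.

## Parameter recovery

`fit_projectile()` estimates $(v_0', g_\mathrm{eff})$ by least squares on
the basis $(t, t^2)$ **without an intercept**: the first sample of a flight
phase is pinned to $(0, 0)$ by construction, so the origin is a definition
rather than a measurement. The normal equations are solved directly (a
$2\times2$ system); on noise-free ballistic input the recovery is exact to
machine precision, and under measurement noise the estimates coincide with
those of a standard linear-model fit, which the test suite uses as an
independent oracle. A whole-flight fit was chosen over finite differencing
of the first frames because it is exact on model-true inputs and consistent
with the analytic identities above; a finite-difference estimator would
inject $O(1/\mathrm{frame\ rate})$ bias into every downstream statistic.

Observed velocity and acceleration, by contrast, are deliberately *not*
analytic: `observed_kinematics()` uses central finite differences (one-sided
at the two ends), because the observer only ever sees sampled motion.
Central differences are exact for quadratics in the interior, so on
ballistic input the only disparity contributions on the theoretical curve
come from the two endpoint stencils.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `g` | 9.81 | m/s² | Earth gravity; every scoring function takes it explicitly, which is what the gravity sweep varies |
| frame rate | 120 | Hz | common motion-capture export rate |
| `t_n` (flight) | 1 | s | typical standing-jump flight time; sets $v_0 = g t_n / 2$ |
| grid | $e^{0.175k}$, $k=-4..4$ | — | 9 × 9 = 81 conditions spanning 0.50–2.01 on each axis, evenly spaced in log space; display labels are rounded to two decimals but computation always uses the exponents ($e^{0.35} = 1.4191$, not 1.42) |
| takeoff threshold | 0.01 | m | flight-phase detection margin above the standing baseline (median of the first 10 frames); 1 cm clears marker jitter while costing at most one frame of flight |
| `n_boot` | 10 000 | — | bootstrap resamples for model comparison |
| sweep grid | 31 log-spaced in $[0.5g, 2g]$ | m/s² | ~4.7 % spacing, fine enough to localise the correlation peak to one step |

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be exercised
and validated without motion-capture downloads or human data. It emulates:

- **Jumps** (`synth_jump()`): a pure projectile sampled at the frame rate,
  plus an optional smooth residual (random mix of the first three sine
  modes, zero at both endpoints, RMS-scaled) standing in for the small
  non-ballistic component of a real jumper's centroid motion.
- **Point-light stimuli** (`synth_marker_table()`): a fixed 41-marker body
  template translated by the jump, with standing padding frames and optional
  marker jitter, so flight-phase detection is genuinely exercised.
- **Ratings** (`synth_ratings()`): 32 participants, each assigned one of 5
  jumpers as evenly as possible, rate all 81 conditions once. A rating is a
  decreasing linear transform of a chosen ground-truth statistic
  (max-normalised over the grid), with participant-level random intercept
  and slope, optional duration bonus, trial noise, clipping to $[0,1]$ and
  quantisation to the 100-step visual-analogue grid.

The observer defaults (intercept 0.85, slope −0.65, participant SDs
0.06/0.15, trial noise SD 0.30) were fixed once by a calibration simulation
so that the truth model's condition-mean correlation magnitude falls around
0.85–0.92 with 32 participants — the regime human raters produce. The
`duration_bonus` term (default 0) reproduces, when positive, the empirical
tendency to rate longer/larger jumps as more natural even at equal implied
gravity; it exists for robustness checks, not as a cognitive claim.

What the generator does **not** emulate: posture and limb articulation
(markers translate rigidly), response biases of the rating scale beyond
clipping and quantisation, sequential/order effects, and any dependence of
ratings on jumper identity. Passing tests therefore demonstrate internal
consistency and recoverability under the model's own assumptions — not that
human raters behave this way.

## Numerical choices

- **Tie stability of the ratio statistic.** On the exponent-generated grid,
  many conditions are mathematically tied in $|\log T - \tfrac12 \log H|$
  (the grid is symmetric in log space), but floating-point `log()` noise
  splits those ties into spurious distinct ranks, corrupting rank
  correlations. `model1_deviation()` therefore snaps its result to 12
  significant digits with an absolute floor of $10^{-12}$; true differences
  anywhere near that scale are far below perceptual relevance.
- **Sampled versus continuous disparity.** The RMS statistics default to
  evaluation at the stimulus's own frames. The dense-sampling closed forms
  above are available via `method = "continuous"` and serve as oracles: the
  sampled value converges to the continuous one at $O(1/\mathrm{frame\
  rate})$, and the endpoint finite-difference stencils bound the on-curve
  residual of the sampled statistics (at most the channel's one-frame
  sensitivity: $v_0\,\mathrm{d}t$ for height, $g\,\mathrm{d}t$ for
  velocity, $g\sqrt{2/N}$ for acceleration).
- **Spearman conventions.** Mid-ranks for ties; two-sided p from the exact
  permutation distribution for $n \le 8$ and from the
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation otherwise.
- **Bootstrap.** Participants (not trials) are resampled with replacement;
  condition means and both correlations are recomputed per resample. The
  two-sided p-value is $2\min(P(d\le0), P(d\ge0))$ with +1 smoothing in
  numerator and denominator, which avoids reporting an exact zero from a
  finite bootstrap. Resamples with constant condition means (possible only
  in tiny degenerate designs) are redrawn and counted. Bonferroni factors: 3
  for the disparity-channel triple, 1 for the timing-versus-height pair, the
  pair count for jumper-group comparisons.
- **Degenerate inputs.** Constant scores or ratings raise an explicit
  undefined-correlation error (or, in the gravity sweep, yield `NA` with a
  warning); non-ballistic trajectories (fitted $g_\mathrm{eff} \le 0$) and
  trajectories with fewer than 3 samples are rejected at the fit; marker
  tables with zero or multiple airborne runs raise errors naming the count.
- **Seeds.** Every stochastic function takes an explicit seed; pipeline
  commands derive child seeds deterministically from the master seed
  (all below $2^{31}$) and echo them in the JSON sidecar.

## Open design choices

- **Reference signal.** The "translation component" of a marker table is
  taken as the vertical coordinate of the body centroid (mean over all
  markers), with an option to select a named marker instead. The centroid
  is the natural whole-body translation proxy and is robust to single-marker
  jitter.
- **Takeoff/landing detection.** First (last) frame whose reference height
  exceeds the standing baseline by the threshold, with an upward-motion
  check at takeoff. This is accurate to one frame on synthetic data, and a
  one-frame shift provably leaves the fitted $g_\mathrm{eff}$ unchanged on
  ballistic input (a time-shifted parabola re-anchored at its first sample
  is still an origin-anchored parabola with the same curvature).
- **Ratio statistic and the curve.** The deviation is measured against
  $T = \sqrt H$ — equivalently $\tfrac12\log H$, not $\log H$ — so that it
  vanishes precisely where the modulated jump preserves Earth gravity; any
  other normalisation would contradict the effective-gravity algebra above.

## Problem sizes

The test suite and the acceptance script use a 1 s, 120 Hz base jump
(121 samples), the 81-condition grid, 32-participant rating tables, 50
generator seeds with 1 000 bootstrap resamples for the recovery studies, a
31-point gravity sweep, and 200 Monte-Carlo seeds for noisy parameter
recovery. These sizes localise every check well inside its statistical
tolerance while keeping the whole suite around half a minute.

## Known limitations

- The statistics operate on pure vertical translation; horizontal drift,
  limb articulation and body rotation are outside the model.
- Human rating generation is unknown; the synthetic observer is a test
  harness, and analyses of real data should treat its calibrated defaults
  as nothing more than a plausible noise regime.
- The timing and velocity-disparity statistics are analytically confounded
  for this stimulus family (see the identity above); distinguishing them
  requires stimuli whose duration matches the prediction while the velocity
  profile deviates, which the modulation scheme cannot produce.
- The models carry no notion of humanly possible jump heights: a physically
  consistent but superhuman jump scores as perfectly natural.
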