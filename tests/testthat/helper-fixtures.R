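# Shared fixtures: a model-true 1 s jump at 120 Hz and the 81-condition grid.
base_traj <- synth_jump(t_n = 1, g = 9.81, frame_rate = 120)
grid81 <- condition_grid()
on_curve81 <- on_theoretical_curve(grid81$H, grid81$T)

# quick observer world with no noise at all
noiseless_observer <- function(truth = "RMS_vel", g = 9.81) {
  observer_model(truth_model = truth, noise_sd = 0,
                 participant_sd_intercept = 0, participant_sd_slope = 0,
                 duration_bonus = 0, g = g)
}
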