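# Default configuration of the synthetic chronosequence generator.
# Design block: the measurement protocol (14 stand ages spanning 8-32 years,
# 40 x 10 m plots cut into 16 subplots of 5 x 5 m, light at 1 m steps from
# 1 to 22 m). Allometry and light blocks: calibration constants chosen so
# that the youngest stands top out near 12 m and the oldest near 27 m, and
# understorey relative light stays in the few-percent range typical of
# closed tropical secondary forest. These are calibration choices for a
# synthetic stand-in, not estimates of any field site.

ages: [8, 10, 12, 14, 15, 17, 19, 21, 23, 25, 26, 28, 30, 32]
plot_length: 40      # m
plot_width: 10       # m
n_subplots: 16
heights: [1, 22]     # measurement ladder, 1 m steps (m)

allometry:
  stems_init: 600          # expected stems per plot extrapolated to age 0
  thinning_rate: 0.050     # per yr, self-thinning of stem density
  dbh_weibull_shape: 1.1   # reverse-J diameter distribution
  dbh_scale_base: -0.4     # cm; Weibull scale = base + rate * age (floor 0.2)
  dbh_scale_rate: 0.28     # cm per yr of stand age
  multi_stem_prob: 0.12    # per-tree chance of each extra stem (max 2)
  height_coef: 3.6         # m at DBH 1 cm, height = coef * DBH^exp
  height_exp: 0.55         # power-law height-diameter exponent
  height_max: 35           # m, hard cap on tree height
  height_noise_sd: 0.04    # lognormal height scatter at age 0
  height_disp_rate: 0.005  # per yr growth of height scatter (differentiation)
  crown_ratio_mean: 0.55   # crown length as fraction of tree height
  crown_ratio_sd: 0.10
  site_shape_sd: 0.12      # plot-level lognormal jitter of the Weibull shape
  site_crown_slope_sd: 0.20  # plot-level slope of crown ratio vs size rank
  crown_width_base: 1.2    # m
  crown_width_coef: 0.6    # m per cm^exp of DBH
  crown_width_exp: 0.75
  crown_width_noise_sd: 0.15

light:
  k: 0.5                   # extinction per m of crown path
  lad_multiplier: 0.38     # leaf-area-density scaling of the crown medium
  epsilon: 0.012           # diffuse floor, fraction of open-sky light
  noise_sd: 0.20           # lognormal measurement noise (SD of log)
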