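# Shared fixtures: small random transforms and quick scene configs.

random_small_transform <- function(max_angle_deg = 5, max_trans_mm = 20) {
  from_displacement(c(
    lr = stats::runif(1, -max_trans_mm, max_trans_mm),
    ap = stats::runif(1, -max_trans_mm, max_trans_mm),
    si = stats::runif(1, -max_trans_mm, max_trans_mm),
    pitch = stats::runif(1, -max_angle_deg, max_angle_deg),
    roll = stats::runif(1, -max_angle_deg, max_angle_deg),
    yaw = stats::runif(1, -max_angle_deg, max_angle_deg)))
}

max_transform_diff <- function(a, b) {
  max(max(abs(a$R - b$R)), max(abs(a$t - b$t)))
}

# short quiet session config: no noise sources unless asked for
quiet_cfg <- function(duration_s = 50, seed = 1, ...) {
  scene_config(seed = seed, duration_s = duration_s, pixel_noise_px = 0,
               dropout = 0, respiration = list(amp = c(lr = 0, ap = 0, si = 0)),
               thigh_amp_mm = 0, ...)
}

# closed-form gain of a length-w moving average at frequency f (cycles per
# sample): |sin(pi f w) / (w sin(pi f))|
ma_gain <- function(f, w) {
  if (abs(sin(pi * f)) < 1e-12) return(1)
  abs(sin(pi * f * w) / (w * sin(pi * f)))
}
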