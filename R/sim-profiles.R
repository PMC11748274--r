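# Per-class kinematic profiles of the synthetic oocyte model.
#
# The generator is a piecewise kinematic model (constant-rate drifts, a
# target-seeking oscillation walk, mean-reverting fluctuation) calibrated so
# that the wild-type summary statistics measured by the analysis pipeline
# (Step I ~0.17 um/min, Step III ~0.18 um/min population mean axial speed,
# 0.10 um/min peak radial speed, ~12 um retrace peak with 0.30 um/min
# return, quasi-static time-averaged |z| < 1.5 um) emerge at the default
# configuration. The constants below are calibration fixtures of the model.

# measured |axial speed| of a quasi-static chromosome at default noise;
# used to inflate the mobile-class Step I drift so the population mean
# (which includes the quasi-static share) hits axial_speed_I
QS_AXIAL_SPEED_CAL <- 0.05

# small gains compensating the attenuation of the measurement pipeline
# (equator-frame estimation error, per-frame re-centering, smoothing), so
# the pipeline-measured summary statistics land on their configured values
STEP1_DRIFT_CAL <- 0.97
RETRACE_RATE_CAL <- 1.00
RADIAL_RATE_CAL <- 1.01

# congressing oscillation: path speed (um/min, the calibration knob for
# the 0.18 um/min Step III population mean axial speed) and the range of
# the random turning-point heights as fractions of the start-of-Step-III
# offset. Per-chromosome random schedules decorrelate the equator
# crossings, so the population spread about the midplane stays well above
# the plate thickness until congression ends late in Step III.
CONGRESS_RATE_CAL <- 0.33
CONGRESS_HEIGHT_RANGE <- c(0.60, 0.90)

# Step IV settling rate toward the resting position, um/min
SETTLE_RATE_IV <- 0.08

# quasi-static mean-reverting fluctuation: AR(1) per frame
QS_AR_RHO <- 0.8
QS_STATIONARY_SD <- 0.5   # um, at quasistatic_bound = 1.5

# radial congression rate template across Step III, um/min toward the axis;
# peaks at radial_speed_max (0.10 default) for three consecutive intervals.
# The total drop leaves a metaphase plate wider than it is thick, so the
# plate normal stays identifiable by PCA.
RADIAL_RATE_TEMPLATE <- c(0, 0, 0.01, 0.04, 0.10, 0.10, 0.10,
                          0.01, 0.005, 0, 0, 0, 0, 0, 0)

# linear interpolation of a keypoint path onto the frame grid
interp_path <- function(times, key_t, key_v) {
  stats::approx(key_t, key_v, xout = times, rule = 2)$y
}

# mobile-class drift rate in Step I, inflated for the quasi-static share so
# the population mean comes out at axial_speed_I
step1_drift <- function(config) {
  w_qs <- config$class_weights[["quasi-static"]]
  if (w_qs >= 1) return(0)
  STEP1_DRIFT_CAL * (config$axial_speed_I - w_qs * QS_AXIAL_SPEED_CAL) /
    (1 - w_qs)
}

# axial path of one retracing chromosome (signed z, um), on the frame grid
retrace_z_path <- function(config, pole, z0, peak, misalign_offset = 0) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  dur3 <- config$step_durations[[3]]
  rise <- dur3 / 3
  hold <- dur3 / 15
  desc <- dur3 / 5
  depth <- desc * config$retrace_max_speed * RETRACE_RATE_CAL
  p_start <- z0 + step1_drift(config) * b[[1]]
  floor3 <- max(0.5, peak - depth - 1e-9) + misalign_offset
  key_t <- c(0, b[[1]], b[[2]], b[[2]] + rise, b[[2]] + rise + hold,
             b[[2]] + rise + hold + desc, b[[3]], b[[4]])
  key_v <- c(z0, p_start, p_start, peak, peak,
             max(peak - depth, floor3), floor3, 0.1 + misalign_offset)
  pole * interp_path(times, key_t, key_v)
}

# axial path of one congressing chromosome: a constant-path-speed
# oscillation through the equator filling all of Step III, with turning
# points drawn at random (alternating poles, heights in
# CONGRESS_HEIGHT_RANGE of the Step III start offset), then a slow Step IV
# settling onto the plate at SETTLE_RATE_IV. Random schedules and the
# start delay decorrelate equator crossings across chromosomes, so the
# chromosome spread about the midplane stays high until congression ends
# and the metaphase plate only emerges during Step IV. Draws from the
# caller's RNG stream.
congress_z_path <- function(config, pole, z0, delay_frames,
                            misalign_offset = 0) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  dt <- config$dt
  p_start <- z0 + step1_drift(config) * b[[1]]
  v <- CONGRESS_RATE_CAL * config$axial_speed_III / 0.18
  t_start <- b[[2]] + delay_frames * dt
  osc_end <- b[[3]]
  turns <- p_start
  turn_t <- t_start
  repeat {
    h <- runif(1, CONGRESS_HEIGHT_RANGE[[1]], CONGRESS_HEIGHT_RANGE[[2]]) *
      p_start
    nxt <- -sign(tail(turns, 1)) * h
    leg_dur <- abs(nxt - tail(turns, 1)) / v
    if (tail(turn_t, 1) + leg_dur >= osc_end) {
      # truncate the running leg at the end of Step III
      frac <- (osc_end - tail(turn_t, 1)) / leg_dur
      turns <- c(turns, tail(turns, 1) + frac * (nxt - tail(turns, 1)))
      turn_t <- c(turn_t, osc_end)
      break
    }
    turns <- c(turns, nxt)
    turn_t <- c(turn_t, tail(turn_t, 1) + leg_dur)
  }
  z_end <- tail(turns, 1)
  side <- if (z_end >= 0) 1 else -1
  rest <- side * (0.15 + misalign_offset)
  settle_dur <- max((abs(z_end) - abs(rest)) / SETTLE_RATE_IV, dt)
  key_t <- c(0, b[[1]], turn_t,
             min(b[[3]] + settle_dur, b[[4]] - 1e-9), b[[4]])
  key_v <- c(z0, p_start, turns, rest, rest)
  pole * interp_path(times, key_t, key_v)
}

# axial path of one quasi-static chromosome: mean-reverting AR(1)
# fluctuation about the midplane, scaled to the configured bound
quasistatic_z_path <- function(config) {
  n <- length(sim_times(config))
  sd_st <- QS_STATIONARY_SD * config$quasistatic_bound / 1.5
  z <- numeric(n)
  z[[1]] <- rnorm(1, 0, sd_st)
  innov <- rnorm(n - 1, 0, sd_st * sqrt(1 - QS_AR_RHO^2))
  for (k in 2:n) z[[k]] <- QS_AR_RHO * z[[k - 1]] + innov[[k - 1]]
  z
}

# shared cylindrical-radius path (distance to the spindle axis, um):
# outward during Step I, held in Step II, congression toward the axis with a
# peaked rate profile in Step III, held in Step IV
radial_path <- function(config, r0, rate_jitter = 1) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  n3 <- as.integer(round(config$step_durations[[3]] / config$dt))
  template <- stats::approx(seq(0, 1, length.out =
                                  length(RADIAL_RATE_TEMPLATE)),
                            RADIAL_RATE_TEMPLATE,
                            xout = seq(0, 1, length.out = n3))$y
  template <- template * RADIAL_RATE_CAL * config$radial_speed_max / 0.10
  r <- numeric(length(times))
  for (k in seq_along(times)) {
    t_k <- times[[k]]
    if (t_k <= b[[1]]) {
      r[[k]] <- r0 + 0.04 * t_k
    } else if (t_k <= b[[2]]) {
      r[[k]] <- r0 + 0.04 * b[[1]] + 0.005 * (t_k - b[[1]])
    } else if (t_k <= b[[3]]) {
      i3 <- as.integer(round((t_k - b[[2]]) / config$dt))
      drop <- if (i3 == 0) 0 else sum(template[seq_len(i3)]) * config$dt
      r[[k]] <- r[[which(times == b[[2]])]] - rate_jitter * drop
    } else {
      r[[k]] <- r[[which(times == b[[3]])]]
    }
  }
  pmax(r, 0.3)
}

# severe-knockdown axial paths ---------------------------------------------

# sluggish/stationary: scaled Step I drift then frozen with a small
# mean-reverting jitter; never congresses, so no equator forms
sluggish_z_path <- function(config, pole, z0, speed_scale) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  base <- pole * (z0 + speed_scale * step1_drift(config) *
                    pmin(times, b[[1]]))
  n <- length(times)
  jit <- numeric(n)
  innov <- rnorm(n, 0, 0.15 * sqrt(1 - QS_AR_RHO^2))
  for (k in 2:n) jit[[k]] <- QS_AR_RHO * jit[[k - 1]] + innov[[k]]
  base + jit
}

# rapid erratic movement: the Step I outward drift (microtubule ball still
# forms) followed by a nearly memoryless random walk, softly reflected so
# chromosomes stay within the cell; never congresses
erratic_z_path <- function(config, z0, pole, speed_scale,
                           direction_persistence) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  n <- length(times)
  z <- pole * (z0 + speed_scale * step1_drift(config) * pmin(times, b[[1]]))
  step_sd <- 0.8 * speed_scale
  delta <- 0
  for (k in which(times > b[[1]])) {
    delta <- direction_persistence * delta + rnorm(1, 0, step_sd)
    z[[k]] <- z[[k - 1]] + delta
    if (abs(z[[k]]) > 14) {
      z[[k]] <- sign(z[[k]]) * (28 - abs(z[[k]]))
      delta <- -delta
    }
  }
  z
}
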