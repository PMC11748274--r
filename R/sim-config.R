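#' Simulation configuration for synthetic oocyte recordings
#'
#' Parameters of the piecewise kinematic model used to generate labeled
#' 20-chromosome mouse MI oocyte recordings. Defaults encode the wild-type
#' study conditions: 10-min frames, four steps of 30/60/150/120 min, class
#' mix 15% retracing / 65% congressing / 20% quasi-static, Step I outward
#' axial drift averaging 0.17 um/min, Step III population mean axial speed
#' 0.18 um/min, retracing excursions peaking ~12 um from the midplane with a
#' 0.30 um/min return, peak radial congression speed 0.10 um/min,
#' quasi-static chromosomes within 1.5 um (time-averaged) of the midplane,
#' and a spindle that elongates by 2 um pole-to-pole while its midplane
#' radius shrinks by 2 um across Step III.
#'
#' @param n_chromosomes Chromosomes per oocyte (default 20, mouse MI).
#' @param dt Frame interval, minutes.
#' @param step_durations Durations of Steps I-IV in minutes; each must be a
#'   multiple of `dt`.
#' @param class_weights Probabilities for (retracing, congressing,
#'   quasi-static); must sum to 1.
#' @param axial_speed_I Step I population mean outward axial speed, um/min.
#' @param axial_speed_III Step III population mean axial speed target, um/min.
#' @param retrace_peak Mean peak distance from the midplane reached by
#'   retracing chromosomes, um.
#' @param retrace_max_speed Peak return speed of the retracing group,
#'   um/min.
#' @param radial_speed_max Peak population mean radial speed toward the
#'   spindle axis during Step III, um/min.
#' @param quasistatic_bound Bound on the time-averaged |distance to midplane|
#'   of quasi-static chromosomes, um.
#' @param spindle_elongation_III Pole-to-pole length increase across Step
#'   III, um.
#' @param midplane_shrink_III Midplane radius decrease across Step III, um.
#' @param noise_sd Per-frame, per-coordinate annotation noise SD, um.
#' @param n_spindle_points Spindle surface points sampled per frame (default 500).
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_chromosomes = 20,
                       dt = 10,
                       step_durations = c(30, 60, 150, 120),
                       class_weights = c(retracing = 0.15,
                                         congressing = 0.65,
                                         `quasi-static` = 0.20),
                       axial_speed_I = 0.17,
                       axial_speed_III = 0.18,
                       retrace_peak = 12,
                       retrace_max_speed = 0.30,
                       radial_speed_max = 0.10,
                       quasistatic_bound = 1.5,
                       spindle_elongation_III = 2,
                       midplane_shrink_III = 2,
                       noise_sd = 0.3,
                       n_spindle_points = 500) {
  cfg <- list(n_chromosomes = n_chromosomes, dt = dt,
              step_durations = step_durations,
              class_weights = class_weights,
              axial_speed_I = axial_speed_I,
              axial_speed_III = axial_speed_III,
              retrace_peak = retrace_peak,
              retrace_max_speed = retrace_max_speed,
              radial_speed_max = radial_speed_max,
              quasistatic_bound = quasistatic_bound,
              spindle_elongation_III = spindle_elongation_III,
              midplane_shrink_III = midplane_shrink_III,
              noise_sd = noise_sd,
              n_spindle_points = n_spindle_points)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_chromosomes) || cfg$n_chromosomes < 1) {
    abort("n_chromosomes must be a positive integer")
  }
  assert_scalar_num(cfg$dt, "dt", min = 1e-9)
  if (length(cfg$step_durations) != 4 || any(cfg$step_durations <= 0)) {
    abort("step_durations must be 4 positive durations")
  }
  if (any(abs(cfg$step_durations / cfg$dt -
              round(cfg$step_durations / cfg$dt)) > 1e-9)) {
    abort("step_durations must be multiples of dt")
  }
  w <- cfg$class_weights
  if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("class_weights must be 3 non-negative probabilities summing to 1")
  }
  names(cfg$class_weights) <- TRAJECTORY_CLASSES
  for (nm in c("axial_speed_I", "axial_speed_III", "retrace_peak",
               "retrace_max_speed", "radial_speed_max", "quasistatic_bound",
               "spindle_elongation_III", "midplane_shrink_III", "noise_sd")) {
    assert_scalar_num(cfg[[nm]], nm, min = 0)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from a flat YAML file
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(sim_config, vals)
}

# step boundary times (I->II, II->III, III->IV, end), minutes
step_boundaries <- function(config) cumsum(config$step_durations)

# frame time grid, minutes since GVBD
sim_times <- function(config) {
  seq(0, sum(config$step_durations), by = config$dt)
}

#' Kinesin-knockdown phenotype presets
#'
#' Qualitative knockdown phenotypes expressed as multipliers on the wild-type
#' kinematic model: KIF11 depletion gives sluggish/stationary chromosomes
#' with no equator formation, KIF2A depletion gives fast erratic movement
#' with no equator, KIF18A/KIF4A depletion suppresses retracing trajectories
#' (quasi-static share untouched), KIFC1 is near-control, and CENPE/KIF20A
#' leave a residual misalignment offset at Step IV.
#'
#' @param name One of `"control"`, `"KIF11"`, `"KIF2A"`, `"KIFC1"`,
#'   `"CENPE"`, `"KIF4A"`, `"KIF18A"`, `"KIF20A"`.
#' @return A `kd_phenotype` object.
#' @export
kd_phenotype <- function(name = "control") {
  presets <- list(
    control = list(speed_scale = 1,   direction_persistence = 1,
                   class_weight_override = NULL, equator_forms = TRUE,
                   misalign_offset = 0, severity = "none"),
    KIF11   = list(speed_scale = 0.2, direction_persistence = 1,
                   class_weight_override = NULL, equator_forms = FALSE,
                   misalign_offset = 0, severity = "severe"),
    KIF2A   = list(speed_scale = 2.0, direction_persistence = 0.1,
                   class_weight_override = NULL, equator_forms = FALSE,
                   misalign_offset = 0, severity = "severe"),
    KIFC1   = list(speed_scale = 0.9, direction_persistence = 1,
                   class_weight_override = NULL, equator_forms = TRUE,
                   misalign_offset = 0, severity = "mild"),
    CENPE   = list(speed_scale = 1,   direction_persistence = 1,
                   class_weight_override = NULL, equator_forms = TRUE,
                   misalign_offset = 1.5, severity = "mild"),
    KIF20A  = list(speed_scale = 1,   direction_persistence = 1,
                   class_weight_override = NULL, equator_forms = TRUE,
                   misalign_offset = 1.5, severity = "mild"),
    KIF18A  = list(speed_scale = 1,   direction_persistence = 1,
                   class_weight_override = c(retracing = 0.03,
                                             congressing = 0.77,
                                             `quasi-static` = 0.20),
                   equator_forms = TRUE, misalign_offset = 0,
                   severity = "mild"),
    KIF4A   = list(speed_scale = 1,   direction_persistence = 1,
                   class_weight_override = c(retracing = 0.03,
                                             congressing = 0.77,
                                             `quasi-static` = 0.20),
                   equator_forms = TRUE, misalign_offset = 0,
                   severity = "mild"))
  if (!name %in% names(presets)) {
    abort(sprintf("unknown phenotype '%s'; known: %s", name,
                  paste(names(presets), collapse = ", ")))
  }
  structure(c(list(name = name), presets[[name]]), class = "kd_phenotype")
}

#' Apply a knockdown phenotype to a simulation config
#'
#' Returns the config with the phenotype's class-weight override applied
#' (retracing weight folded into congressing for KIF18A/KIF4A) together with
#' the phenotype object carrying the kinematic multipliers.
#'
#' @param config A [sim_config()].
#' @param name Phenotype name, see [kd_phenotype()].
#' @return List with elements `config` and `phenotype`.
#' @export
apply_kd_phenotype <- function(config, name = "control") {
  phen <- kd_phenotype(name)
  if (!is.null(phen$class_weight_override)) {
    config$class_weights <- phen$class_weight_override
    config <- validate_sim_config(unclass(config))
  }
  list(config = config, phenotype = phen)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d chromosomes, dt = %g min, steps %s min (total %g)\n",
              x$n_chromosomes, x$dt,
              paste(x$step_durations, collapse = "/"),
              sum(x$step_durations)))
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%s %.2f", names(x$class_weights),
                            x$class_weights), collapse = ", ")))
  cat(sprintf("  noise_sd = %g um\n", x$noise_sd))
  invisible(x)
}
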