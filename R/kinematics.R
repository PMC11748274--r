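#' Decompose chromosome motion into axial, radial and tangential speeds
#'
#' Per inter-frame interval of each aligned trajectory, with cylindrical
#' radius `r = sqrt(x^2 + y^2)` about the pole-to-pole axis:
#' \itemize{
#'   \item `v_axial`: signed speed toward the equator plane,
#'     `(|z_t| - |z_(t+1)|) / dt` (positive = approaching the plane);
#'   \item `v_radial`: signed speed toward the spindle axis,
#'     `(r_t - r_(t+1)) / dt`;
#'   \item `v_tangential`: rotation about the axis, from the in-plane chord
#'     `d_xy` as `sqrt(d_xy^2 - (dr)^2) / dt` (non-negative);
#'   \item `v_axial_path`: unsigned axial path speed `|dz| / dt`;
#'   \item `v_total`: `||dposition|| / dt`.
#' }
#' The magnitudes close exactly:
#' `v_axial_path^2 + v_radial^2 + v_tangential^2 = v_total^2`. The signed
#' `v_axial` differs from `v_axial_path` only on intervals crossing the
#' equator plane.
#'
#' @param aligned Aligned trajectory tibble (see [align_trajectories()]).
#' @param dt Frame interval in minutes; inferred from `t_min` when NULL.
#' @return Speed tibble: `oocyte_id`, `chromosome_id`, `t_mid_min`, the five
#'   speed components (um/min), and `true_label` when present.
#' @export
decompose_speeds <- function(aligned, dt = NULL) {
  keep_label <- "true_label" %in% names(aligned)
  out <- aligned %>%
    arrange(.data$oocyte_id, .data$chromosome_id, .data$t_min) %>%
    group_by(.data$oocyte_id, .data$chromosome_id) %>%
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) abort("need at least 2 frames per trajectory")
      step <- dt %||% (df$t_min[[2]] - df$t_min[[1]])
      r <- sqrt(df$x_um^2 + df$y_um^2)
      dx <- diff(df$x_um); dy <- diff(df$y_um); dz <- diff(df$z_um)
      dr <- diff(r)
      d_xy2 <- dx^2 + dy^2
      res <- tibble(
        t_mid_min = (df$t_min[-nrow(df)] + df$t_min[-1]) / 2,
        v_axial = (abs(df$z_um[-nrow(df)]) - abs(df$z_um[-1])) / step,
        v_radial = -dr / step,
        v_tangential = sqrt(pmax(d_xy2 - dr^2, 0)) / step,
        v_axial_path = abs(dz) / step,
        v_total = sqrt(d_xy2 + dz^2) / step)
      if (keep_label) res$true_label <- df$true_label[-1]
      res
    }) %>%
    ungroup()
  out
}

#' Unsigned distance to the equator plane over time
#'
#' @param aligned Aligned trajectory tibble.
#' @return Tibble `oocyte_id`, `chromosome_id`, `frame`, `t_min`,
#'   `dist_equator_um` (= |z|); invariant to the sign convention of the
#'   pole-to-pole axis.
#' @export
distance_to_equator <- function(aligned) {
  aligned %>%
    mutate(dist_equator_um = abs(.data$z_um)) %>%
    select(dplyr::any_of(c("oocyte_id", "chromosome_id", "frame", "t_min",
                           "true_label")), "dist_equator_um")
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, window = 3) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Population mean speed curve over time
#'
#' Averages one speed component over chromosomes (and oocytes) per interval
#' midpoint, optionally on magnitudes, with a centered moving-average
#' smoother.
#'
#' @param speeds Speed tibble from [decompose_speeds()].
#' @param component Column to average (default `"v_axial"`).
#' @param magnitude Average |value| instead of the signed value.
#' @param window Smoothing window in frames (default 3; 1 = none).
#' @return Tibble `t_mid_min`, `mean_speed` (smoothed), `n`.
#' @export
population_speed_curve <- function(speeds, component = "v_axial",
                                   magnitude = TRUE, window = 3) {
  curve <- speeds %>%
    mutate(val = if (magnitude) abs(.data[[component]]) else
      .data[[component]]) %>%
    group_by(.data$t_mid_min) %>%
    summarise(mean_speed = mean(.data$val), n = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$t_mid_min)
  curve$mean_speed <- moving_average(curve$mean_speed, window)
  curve
}

#' Segment a recording into the four kinematic steps
#'
#' Exhaustive least-squares changepoint search: the smoothed population mean
#' |axial speed| curve is split into four contiguous segments (each at least
#' `min_length` intervals) minimizing the total within-segment variance;
#' deterministic. When an equator time is supplied, the Step III to IV
#' boundary is constrained not to exceed it. A flat profile yields a
#' degenerate segmentation at the quartiles; with no detected equator the
#' segmentation is reported as undetermined (severe knockdowns).
#'
#' @param speeds Speed tibble from [decompose_speeds()] (one or more
#'   oocytes on a common grid), or `NULL` with `status = "undetermined"`
#'   results.
#' @param equator_time Equator formation time in minutes, or NA.
#' @param window Smoothing window (frames) before the search.
#' @param min_length Minimum intervals per segment (default 3).
#' @return A `step_segmentation`: list with `boundaries` (times of the
#'   I/II, II/III, III/IV transitions, minutes), `steps` (tibble mapping
#'   each interval midpoint to a step), `status`
#'   (`"ok"`, `"degenerate"`, `"undetermined"`).
#' @export
segment_steps <- function(speeds, equator_time = NA_real_, window = 3,
                          min_length = 3) {
  if (is.null(speeds)) {
    return(structure(list(boundaries = rep(NA_real_, 3), steps = NULL,
                          status = "undetermined"),
                     class = "step_segmentation"))
  }
  curve <- population_speed_curve(speeds, "v_axial", magnitude = TRUE,
                                  window = window)
  y <- curve$mean_speed
  n <- length(y)
  if (n < 4 * min_length) {
    abort(sprintf("recording too short to segment: %d intervals < %d",
                  n, 4 * min_length))
  }
  dt <- curve$t_mid_min[[2]] - curve$t_mid_min[[1]]
  # boundary time after interval i lies on the frame edge
  edge_time <- function(i) curve$t_mid_min[[i]] + dt / 2
  if (stats::sd(y) < 1e-12) {
    qs <- round(n * (1:3) / 4)
    return(structure(list(
      boundaries = vapply(qs, edge_time, numeric(1)),
      steps = label_steps(curve, qs), status = "degenerate"),
      class = "step_segmentation"))
  }
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  seg_cost <- function(i, j) {   # SSE of y[i..j]
    s <- cs[[j]] - if (i > 1) cs[[i - 1]] else 0
    s2 <- cs2[[j]] - if (i > 1) cs2[[i - 1]] else 0
    s2 - s^2 / (j - i + 1)
  }
  k3_max <- n - min_length
  if (!is.na(equator_time)) {
    k3_cap <- max(which(vapply(seq_len(n), edge_time, numeric(1)) <=
                          equator_time + 1e-9))
    k3_max <- min(k3_max, k3_cap)
  }
  k3_hi <- min(k3_max, n - min_length)
  best <- NULL; best_cost <- Inf
  for (k1 in min_length:(k3_hi - 2 * min_length)) {
    c1 <- seg_cost(1, k1)
    for (k2 in (k1 + min_length):(k3_hi - min_length)) {
      c2 <- c1 + seg_cost(k1 + 1, k2)
      if (c2 >= best_cost) next
      for (k3 in (k2 + min_length):k3_hi) {
        cost <- c2 + seg_cost(k2 + 1, k3) + seg_cost(k3 + 1, n)
        if (cost < best_cost) {
          best_cost <- cost; best <- c(k1, k2, k3)
        }
      }
    }
  }
  if (is.null(best)) abort("no admissible segmentation under the equator constraint")
  structure(list(boundaries = vapply(best, edge_time, numeric(1)),
                 steps = label_steps(curve, best), status = "ok"),
            class = "step_segmentation")
}

label_steps <- function(curve, breaks) {
  idx <- seq_len(nrow(curve))
  step <- cut(idx, breaks = c(0, breaks, nrow(curve)),
              labels = c("I", "II", "III", "IV"))
  tibble(t_mid_min = curve$t_mid_min, step = as.character(step))
}

#' @export
print.step_segmentation <- function(x, ...) {
  if (x$status == "undetermined") {
    cat("<step_segmentation> undetermined (no equator formed)\n")
  } else {
    cat(sprintf("<step_segmentation> [%s] boundaries at %s min\n", x$status,
                paste(x$boundaries, collapse = ", ")))
  }
  invisible(x)
}

#' Attach step labels to a speed table
#'
#' @param speeds Speed tibble.
#' @param segmentation A [segment_steps()] result.
#' @return `speeds` with a `step` column (`"I"`..`"IV"`).
#' @export
assign_steps <- function(speeds, segmentation) {
  if (segmentation$status == "undetermined") {
    return(mutate(speeds, step = NA_character_))
  }
  left_join(speeds, segmentation$steps, by = "t_mid_min")
}

#' Population summary of speed components with confidence bands
#'
#' Mean and normal-approximation 95% confidence interval
#' (mean +/- 1.96 SE over series) of each speed component per time point;
#' the axial component is summarized both signed (`v_axial`) and as a
#' magnitude (`v_axial_mag`).
#'
#' @param speeds Speed tibble across chromosomes/oocytes on a common grid.
#' @param conf Confidence level (default 0.95).
#' @return Tibble `t_mid_min`, `component`, `mean`, `ci_lo`, `ci_hi`, `n`.
#'   With a single series the CI is NA (undefined) with a warning.
#' @export
summarize_population <- function(speeds, conf = 0.95) {
  zq <- qnorm(1 - (1 - conf) / 2)
  long <- speeds %>%
    mutate(v_axial_mag = abs(.data$v_axial)) %>%
    tidyr::pivot_longer(cols = c("v_axial", "v_axial_mag", "v_radial",
                                 "v_tangential", "v_total"),
                        names_to = "component", values_to = "value")
  out <- long %>%
    group_by(.data$t_mid_min, .data$component) %>%
    summarise(mean = mean(.data$value),
              se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n())
                   else NA_real_,
              n = dplyr::n(), .groups = "drop") %>%
    mutate(ci_lo = .data$mean - zq * .data$se,
           ci_hi = .data$mean + zq * .data$se) %>%
    select("t_mid_min", "component", "mean", "ci_lo", "ci_hi", "n")
  if (all(out$n == 1)) warn("single series: confidence interval undefined")
  out
}

#' Run the per-oocyte analysis pipeline on a recording
#'
#' Equator detection, equator-frame alignment (spindle-axis sign
#' reference), speed decomposition and four-step segmentation in one call.
#'
#' @param recording An `oocyte_recording`, or a canonical trajectory tibble.
#' @param spindle Spindle cloud tibble when `recording` is a plain table.
#' @return List with `aligned`, `speeds`, `segmentation`, `equator_time`,
#'   `status` (`"aligned"` or `"no_equator"`).
#' @export
analyze_oocyte <- function(recording, spindle = NULL) {
  if (inherits(recording, "oocyte_recording")) {
    traj <- recording$trajectories
    spindle <- recording$spindle
  } else {
    traj <- recording
  }
  al <- align_recording(traj, spindle)
  if (al$status == "no_equator") {
    return(list(aligned = NULL, speeds = NULL,
                segmentation = structure(list(boundaries = rep(NA_real_, 3),
                                              steps = NULL,
                                              status = "undetermined"),
                                         class = "step_segmentation"),
                equator_time = NA_real_, status = "no_equator"))
  }
  speeds <- decompose_speeds(al$aligned)
  seg <- segment_steps(speeds, equator_time = al$equator_time)
  list(aligned = al$aligned, speeds = speeds, segmentation = seg,
       equator_time = al$equator_time, status = "aligned")
}
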