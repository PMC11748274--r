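# run code with a temporary RNG state derived from `seed`; the caller's
# RNG stream is untouched, so all simulator randomness flows from the seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# uniform random rotation matrix (det +1) via QR of a Gaussian matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# spindle semi-axes (R1 >= R2 = R3, um) at time t: the microtubule ball
# expands and bipolarizes through Steps I-II, elongates by
# spindle_elongation_III pole-to-pole while the midplane radius shrinks by
# midplane_shrink_III across Step III, then keeps elongating slowly
spindle_semiaxes <- function(config, t) {
  b <- step_boundaries(config)
  r1 <- interp_path(t, c(0, b),
                    c(8, 10, 12, 12 + config$spindle_elongation_III / 2,
                      12.5 + config$spindle_elongation_III / 2))
  r23 <- interp_path(t, c(0, b),
                     c(8, 9, 9, 9 - config$midplane_shrink_III, 8.9 -
                         config$midplane_shrink_III))
  cbind(R1 = r1, R2 = r23, R3 = r23)
}

#' Sample a spindle surface point cloud for one frame
#'
#' Returns uniform-on-surface samples of the model spindle ellipsoid in the
#' canonical (axis-aligned, centered) spindle frame, with the long axis along
#' z. Sampling is by rejection with the surface-element weight, so the cloud
#' is uniform on the surface, not merely uniform in angle.
#'
#' @param config A [sim_config()].
#' @param frame Frame index (0-based).
#' @param n_points Number of points.
#' @param seed Optional seed.
#' @return Matrix with columns `x`, `y`, `z` (um); points satisfy the
#'   ellipsoid implicit equation exactly.
#' @export
simulate_spindle <- function(config, frame, n_points = config$n_spindle_points,
                             seed = NULL) {
  times <- sim_times(config)
  if (frame < 0 || frame > length(times) - 1) {
    abort(sprintf("frame %s outside recording (0..%d)", frame,
                  length(times) - 1))
  }
  ax <- spindle_semiaxes(config, times[[frame + 1]])
  with_seed(seed, sample_ellipsoid(n_points, ax[1, "R3"], ax[1, "R2"],
                                   ax[1, "R1"]))
}

# uniform samples on the surface of an axis-aligned ellipsoid with semi-axes
# (a, b, c) along (x, y, z); rejection sampling with the area element weight
sample_ellipsoid <- function(n, a, b, c) {
  out <- matrix(NA_real_, 0, 3)
  w_max <- max(a * b, a * c, b * c)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 32)
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    w <- sqrt((b * c * u[, 1])^2 + (a * c * u[, 2])^2 + (a * b * u[, 3])^2)
    keep <- runif(m) < w / w_max
    pts <- cbind(a * u[keep, 1], b * u[keep, 2], c * u[keep, 3])
    out <- rbind(out, pts)
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Simulate one oocyte recording
#'
#' Generates a labeled 4D recording: `n_chromosomes` trajectories following
#' the four-step kinematics with per-chromosome trajectory classes drawn
#' from the class weights, plus a per-frame spindle surface point cloud. A
#' random rigid rotation and a drifting translation are applied to the whole
#' scene so that downstream centering and PCA alignment are exercised;
#' annotation noise is added to every observed coordinate. Deterministic
#' given (config, phenotype, seed).
#'
#' @param config A [sim_config()].
#' @param condition Phenotype name, see [kd_phenotype()].
#' @param seed Integer seed; all randomness flows from it.
#' @param oocyte_id Identifier for the recording.
#' @return An `oocyte_recording`: list with `trajectories` (canonical
#'   trajectory tibble with `true_label`), `spindle` (per-frame point cloud
#'   tibble), `truth` (noise-free canonical axial/radial paths),
#'   `equator_time` (minutes, NA if the equator never forms), `labels`,
#'   `condition`, `config`, and the scene `rotation`/`drift`.
#' @export
simulate_oocyte <- function(config = sim_config(), condition = "control",
                            seed = 1, oocyte_id = sprintf("oocyte_%03d", seed)) {
  kd <- apply_kd_phenotype(config, condition)
  config <- kd$config
  phen <- kd$phenotype
  with_seed(seed, {
    times <- sim_times(config)
    n_t <- length(times)
    n_c <- config$n_chromosomes

    labels <- draw_labels(n_c, config$class_weights)
    signs <- balanced_signs(labels)

    # stratified angular positions: chromosomes spread evenly around the
    # spindle axis (jittered), so the plate is sampled isotropically
    phi0 <- sample(2 * pi * (seq_len(n_c) - 1) / n_c +
                     runif(n_c, 0, 2 * pi / n_c))
    paths <- purrr::map(seq_len(n_c), function(i) {
      chromosome_paths(config, phen, labels[[i]], signs[[i]], phi0[[i]])
    })
    z_true <- do.call(cbind, purrr::map(paths, "z"))   # n_t x n_c
    r_true <- do.call(cbind, purrr::map(paths, "r"))
    phi <- do.call(cbind, purrr::map(paths, "phi"))

    # severe knockdowns have no meaningful class: label NA
    if (phen$severity == "severe") labels <- rep(NA_character_, n_c)

    # canonical positions
    xs <- r_true * cos(phi)
    ys <- r_true * sin(phi)

    # scene transform: rigid rotation + drifting translation
    rot <- random_rotation()
    drift <- matrix(rnorm(3 * n_t, 0, 0.15), n_t, 3)
    drift[1, ] <- runif(3, -10, 10)
    drift <- apply(drift, 2, cumsum)

    obs <- array(NA_real_, c(n_t, n_c, 3))
    for (k in seq_len(n_t)) {
      p <- cbind(xs[k, ], ys[k, ], z_true[k, ]) %*% t(rot)
      obs[k, , ] <- p + matrix(drift[k, ], n_c, 3, byrow = TRUE) +
        matrix(rnorm(3 * n_c, 0, config$noise_sd), n_c, 3)
    }

    trajectories <- tibble(
      oocyte_id = oocyte_id,
      chromosome_id = rep(seq_len(n_c), each = n_t),
      frame = rep(seq_len(n_t) - 1L, n_c),
      t_min = rep(times, n_c),
      x_um = as.vector(sapply(seq_len(n_c), function(i) obs[, i, 1])),
      y_um = as.vector(sapply(seq_len(n_c), function(i) obs[, i, 2])),
      z_um = as.vector(sapply(seq_len(n_c), function(i) obs[, i, 3])),
      true_label = rep(labels, each = n_t))

    spindle <- purrr::map_dfr(seq_len(n_t), function(k) {
      cloud <- {
        ax <- spindle_semiaxes(config, times[[k]])
        sample_ellipsoid(config$n_spindle_points, ax[1, "R3"], ax[1, "R2"],
                         ax[1, "R1"])
      }
      pts <- cloud %*% t(rot) +
        matrix(drift[k, ], nrow(cloud), 3, byrow = TRUE) +
        matrix(rnorm(3 * nrow(cloud), 0, config$noise_sd), nrow(cloud), 3)
      tibble(frame = k - 1L, t_min = times[[k]],
             x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3])
    })

    truth <- tibble(
      chromosome_id = rep(seq_len(n_c), each = n_t),
      frame = rep(seq_len(n_t) - 1L, n_c),
      t_min = rep(times, n_c),
      z_true = as.vector(z_true),
      r_true = as.vector(r_true))

    structure(list(
      oocyte_id = oocyte_id, condition = condition, config = config,
      phenotype = phen,
      trajectories = trajectories, spindle = spindle, truth = truth,
      labels = tibble(oocyte_id = oocyte_id,
                      chromosome_id = seq_len(n_c), true_label = labels),
      equator_time = design_equator_time(config, xs, ys, z_true),
      rotation = rot, drift = drift), class = "oocyte_recording")
  })
}

# draw per-chromosome class labels from the class weights
draw_labels <- function(n, weights) {
  sample(TRAJECTORY_CLASSES, n, replace = TRUE, prob = weights)
}

# assign pole signs balanced within each class (chromosomes distribute
# evenly along the axis), odd member at random
balanced_signs <- function(labels) {
  signs <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    s <- rep(c(1L, -1L), length.out = length(idx))
    if (length(idx) %% 2 == 1 && runif(1) < 0.5) s <- -s
    signs[idx] <- s
  }
  signs
}

# deterministic + intrinsic-stochastic canonical paths for one chromosome
chromosome_paths <- function(config, phen, label, pole, phi0) {
  times <- sim_times(config)
  b <- step_boundaries(config)
  if (phen$severity == "severe") {
    z0 <- runif(1, 1.5, 3.5)
    z <- if (!is.null(phen$direction_persistence) &&
             phen$direction_persistence < 1) {
      erratic_z_path(config, z0, pole, phen$speed_scale,
                     phen$direction_persistence)
    } else {
      sluggish_z_path(config, pole, z0, phen$speed_scale)
    }
    r0 <- runif(1, 6.5, 7.5)
    r <- pmax(r0 + cumsum(rnorm(length(times), 0, 0.15)), 0.5)
  } else {
    if (label == "quasi-static") {
      z <- quasistatic_z_path(config)
    } else if (label == "retracing") {
      z0 <- runif(1, 1, 3)
      peak <- rnorm(1, config$retrace_peak, 0.5)
      z <- retrace_z_path(config, pole, z0, peak, phen$misalign_offset)
    } else {
      z0 <- runif(1, 1, 3)
      delay <- sample(0:1, 1)
      z <- congress_z_path(config, pole, z0, delay, phen$misalign_offset)
    }
    if (phen$speed_scale != 1) {
      z <- z[[1]] + phen$speed_scale * (z - z[[1]])
    }
    r <- radial_path(config, runif(1, 6.5, 7.5), runif(1, 0.92, 1.08))
    if (phen$speed_scale != 1) r <- r[[1]] + phen$speed_scale * (r - r[[1]])
  }
  omega <- rnorm(1, 0, 0.002) + sample(c(-1, 1), 1) * 0.001
  mult <- ifelse(times > b[[2]] & times <= b[[3]], 3, 1)
  phi <- phi0 + cumsum(c(0, omega * diff(times) * mult[-length(mult)]))
  list(z = z, r = r, phi = phi)
}

# configured equator time: the detection rule (RMS to the best-fit plane,
# sustained below threshold) applied to the noise-free canonical positions
design_equator_time <- function(config, xs, ys, z_true, threshold = 2,
                                persistence = 3) {
  rms <- vapply(seq_len(nrow(z_true)), function(k) {
    plane_rms(cbind(xs[k, ], ys[k, ], z_true[k, ]))
  }, numeric(1))
  first_sustained(rms < threshold, persistence, sim_times(config))
}

first_sustained <- function(below, persistence, times) {
  if (length(below) < persistence) return(NA_real_)
  run <- stats::filter(as.numeric(below), rep(1, persistence),
                       sides = 1)
  hit <- which(!is.na(run) & run == persistence)
  if (length(hit) == 0) NA_real_ else times[[hit[[1]] - persistence + 1]]
}

#' Simulate a cohort of oocytes
#'
#' @param n_oocytes Number of oocytes.
#' @param config A [sim_config()].
#' @param condition Phenotype name applied to every oocyte.
#' @param seeds Integer seeds, one per oocyte (default `seq_len(n_oocytes)`).
#' @return List of `oocyte_recording`s.
#' @export
simulate_cohort <- function(n_oocytes, config = sim_config(),
                            condition = "control",
                            seeds = seq_len(n_oocytes)) {
  stopifnot(length(seeds) == n_oocytes)
  purrr::map(seq_len(n_oocytes), function(i) {
    simulate_oocyte(config, condition, seed = seeds[[i]],
                    oocyte_id = sprintf("%s_%03d", condition, seeds[[i]]))
  })
}

#' @export
print.oocyte_recording <- function(x, ...) {
  cat(sprintf("<oocyte_recording> %s (%s): %d chromosomes x %d frames\n",
              x$oocyte_id, x$condition,
              dplyr::n_distinct(x$trajectories$chromosome_id),
              dplyr::n_distinct(x$trajectories$frame)))
  cat(sprintf("  equator time: %s\n",
              if (is.na(x$equator_time)) "never formed" else
                paste0(x$equator_time, " min")))
  invisible(x)
}

#' Write / read a recording as plain-text fixture files
#'
#' `write_fixture()` writes per-frame Vaa3D-style `frame_%04d.marker` files
#' (voxel units under the given scale), per-frame `spindle_%04d.csv` point
#' clouds (um), a `labels.csv` truth table and a `meta.yaml` describing the
#' grid, so that `read_fixture()` reproduces the observed recording.
#'
#' @param recording An `oocyte_recording`.
#' @param dir Output directory (created if needed).
#' @param scale [voxel_scale()] used to express markers in voxels.
#' @return `dir` invisibly (`write_fixture`); a list with `trajectories`,
#'   `spindle`, `labels` (`read_fixture`).
#' @export
write_fixture <- function(recording, dir, scale = voxel_scale()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- recording$trajectories
  for (f in sort(unique(traj$frame))) {
    mk <- traj %>%
      filter(.data$frame == f) %>%
      mutate(x = .data$x_um / scale[["sx"]],
             y = .data$y_um / scale[["sy"]],
             z = .data$z_um / scale[["sz"]], radius = 0)
    write_markers(mk, file.path(dir, sprintf("frame_%04d.marker", f)))
    sp <- recording$spindle %>% filter(.data$frame == f)
    readr::write_csv(sp[, c("x_um", "y_um", "z_um")],
                     file.path(dir, sprintf("spindle_%04d.csv", f)))
  }
  readr::write_csv(recording$labels, file.path(dir, "labels.csv"))
  yaml::write_yaml(list(oocyte_id = recording$oocyte_id,
                        condition = recording$condition,
                        dt = recording$config$dt,
                        scale = as.list(unclass(scale))),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  scale <- do.call(voxel_scale, meta$scale)
  markers <- read_marker_dir(dir) %>% voxels_to_microns(scale)
  traj <- link_trajectories(markers, dt = meta$dt,
                            oocyte_id = meta$oocyte_id)
  labels <- readr::read_csv(file.path(dir, "labels.csv"),
                            show_col_types = FALSE)
  traj <- left_join(traj, labels,
                    by = c("oocyte_id", "chromosome_id"))
  files <- list.files(dir, pattern = "^spindle_\\d+\\.csv$",
                      full.names = TRUE)
  frames <- as.integer(sub("^spindle_(\\d+)\\.csv$", "\\1", basename(files)))
  spindle <- purrr::map2_dfr(files[order(frames)], sort(frames), function(p, f) {
    df <- readr::read_csv(p, show_col_types = FALSE)
    mutate(df, frame = f, t_min = f * meta$dt, .before = 1)
  })
  list(trajectories = traj, spindle = spindle, labels = labels,
       condition = meta$condition)
}
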