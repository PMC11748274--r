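#' Read a Vaa3D-style marker file
#'
#' Parses one `.marker` file (one imaging frame) into a tibble of chromosome
#' marker records. The dialect is comma-separated
#' `x,y,z,radius,shape,name,comment[,r,g,b]`; lines starting with `#` are
#' comments; the `name` field carries the chromosome number. Coordinates are
#' voxel units as annotated (continuous, 0-based).
#'
#' @param path Path to the marker file.
#' @param frame_index Integer frame index to attach to every record.
#' @return A tibble with columns `frame`, `chromosome_id`, `x`, `y`, `z`,
#'   `radius` (voxel units).
#' @export
read_markers <- function(path, frame_index = 0L) {
  if (!file.exists(path)) abort(sprintf("marker file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(frame = integer(), chromosome_id = integer(),
                  x = double(), y = double(), z = double(), radius = double()))
  }
  recs <- lapply(idx, function(i) {
    fields <- strsplit(lines[[i]], ",", fixed = TRUE)[[1]]
    if (length(fields) < 6) {
      abort(sprintf("malformed marker line %d in %s: fewer than 6 fields",
                    i, path))
    }
    xyz <- suppressWarnings(as.numeric(fields[1:4]))
    id <- suppressWarnings(as.integer(fields[[6]]))
    if (anyNA(xyz[1:3]) || is.na(id)) {
      abort(sprintf("malformed marker line %d in %s: non-numeric field",
                    i, path))
    }
    tibble(frame = as.integer(frame_index), chromosome_id = id,
           x = xyz[[1]], y = xyz[[2]], z = xyz[[3]],
           radius = if (is.na(xyz[[4]])) 0 else xyz[[4]])
  })
  out <- bind_rows(recs)
  dup <- out$chromosome_id[duplicated(out$chromosome_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate chromosome_id in %s: %s", path,
                  paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write markers to a Vaa3D-style marker file
#'
#' Inverse of [read_markers()]: writes one frame's records with full numeric
#' precision so that a write/read round trip is lossless.
#'
#' @param markers Tibble with columns `chromosome_id`, `x`, `y`, `z` and
#'   optionally `radius`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  radius <- if ("radius" %in% names(markers)) markers$radius else 0
  lines <- sprintf("%s,%s,%s,%s,0,%d,",
                   format(markers$x, digits = 15, trim = TRUE),
                   format(markers$y, digits = 15, trim = TRUE),
                   format(markers$z, digits = 15, trim = TRUE),
                   format(radius, digits = 15, trim = TRUE),
                   as.integer(markers$chromosome_id))
  writeLines(c("#x,y,z,radius,shape,name,comment", lines), path)
  invisible(path)
}

#' Read a directory of per-frame marker files
#'
#' Expects files named `frame_%04d.marker`; the frame index is taken from the
#' filename.
#'
#' @param dir Directory containing marker files.
#' @return A tibble of marker records across frames (voxel units).
#' @export
read_marker_dir <- function(dir) {
  files <- list.files(dir, pattern = "^frame_\\d+\\.marker$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no frame_*.marker files in %s", dir))
  frames <- as.integer(sub("^frame_(\\d+)\\.marker$", "\\1", basename(files)))
  ord <- order(frames)
  bind_rows(purrr::map2(files[ord], frames[ord], read_markers))
}

#' Voxel scale of the imaging system
#'
#' Microns per voxel along x, y (pixel size) and z (slice spacing). The
#' defaults match light-sheet acquisition at 104 nm pixels and 1 um z-steps.
#'
#' @param sx,sy Microns per pixel in x and y. Default 0.104.
#' @param sz Microns per z slice. Default 1.
#' @return A `voxel_scale` object (named numeric vector).
#' @export
voxel_scale <- function(sx = 0.104, sy = 0.104, sz = 1) {
  s <- c(sx = sx, sy = sy, sz = sz)
  if (any(!is.finite(s)) || any(s <= 0)) abort("voxel scale must be positive")
  structure(s, class = "voxel_scale")
}

#' Convert marker coordinates from voxels to microns
#'
#' Pure componentwise scaling (no half-pixel offset): `x_um = x * sx`, etc.
#'
#' @param markers Tibble with voxel columns `x`, `y`, `z`.
#' @param scale A [voxel_scale()].
#' @return The tibble with `x`, `y`, `z` in microns.
#' @export
voxels_to_microns <- function(markers, scale = voxel_scale()) {
  if (!inherits(scale, "voxel_scale")) scale <- do.call(voxel_scale, as.list(scale))
  mutate(markers,
         x = .data$x * scale[["sx"]],
         y = .data$y * scale[["sy"]],
         z = .data$z * scale[["sz"]])
}

#' Link per-frame markers into per-chromosome trajectories
#'
#' Chromosome identity is supplied by the annotation (the marker `name`);
#' linking is therefore a regrouping, not a tracking problem. Every frame
#' must contain the same set of chromosome ids.
#'
#' @param markers Marker tibble across frames, in microns
#'   (see [voxels_to_microns()]).
#' @param dt Frame interval in minutes (default 10).
#' @param oocyte_id Identifier attached to all trajectories.
#' @return Canonical trajectory tibble: `oocyte_id`, `chromosome_id`,
#'   `frame`, `t_min`, `x_um`, `y_um`, `z_um`, ordered by chromosome then
#'   frame.
#' @export
link_trajectories <- function(markers, dt = 10, oocyte_id = "oocyte_1") {
  assert_scalar_num(dt, "dt", min = 1e-9)
  frames <- sort(unique(markers$frame))
  ids <- sort(unique(markers$chromosome_id))
  counts <- table(factor(markers$chromosome_id, levels = ids),
                  factor(markers$frame, levels = frames))
  missing <- which(counts == 0, arr.ind = TRUE)
  if (nrow(missing) > 0) {
    gaps <- sprintf("(id %s, frame %s)", ids[missing[, 1]],
                    frames[missing[, 2]])
    abort(paste0("chromosome missing in some frames: ",
                 paste(head(gaps, 10), collapse = ", ")))
  }
  markers %>%
    mutate(oocyte_id = .env$oocyte_id,
           t_min = (.data$frame - frames[[1]]) * dt) %>%
    select("oocyte_id", "chromosome_id", "frame", "t_min",
           x_um = "x", y_um = "y", z_um = "z") %>%
    arrange(.data$chromosome_id, .data$frame)
}

#' Flag candidate tracing errors
#'
#' For every inter-frame interval, the 3D displacement of each chromosome is
#' compared against a per-interval threshold of mean + 2 population standard
#' deviations over chromosomes; strictly larger displacements are flagged for
#' re-tracing. Flags are reported, never auto-corrected.
#'
#' @param trajectories Canonical trajectory tibble (microns).
#' @return Tibble of flags: `oocyte_id`, `chromosome_id`, `frame` (frame at
#'   the end of the flagged interval), `displacement_um`, `threshold_um`.
#' @export
flag_tracing_errors <- function(trajectories) {
  empty <- tibble(oocyte_id = character(), chromosome_id = integer(),
                  frame = integer(), displacement_um = double(),
                  threshold_um = double())
  out <- trajectories %>%
    group_by(.data$oocyte_id) %>%
    dplyr::group_modify(function(df, key) {
      if (dplyr::n_distinct(df$chromosome_id) < 2) {
        warn("QC skipped: need at least 2 trajectories per oocyte")
        return(empty[, -1])
      }
      disp <- df %>%
        arrange(.data$chromosome_id, .data$frame) %>%
        group_by(.data$chromosome_id) %>%
        mutate(displacement_um = sqrt(
          (.data$x_um - dplyr::lag(.data$x_um))^2 +
          (.data$y_um - dplyr::lag(.data$y_um))^2 +
          (.data$z_um - dplyr::lag(.data$z_um))^2)) %>%
        ungroup() %>%
        filter(!is.na(.data$displacement_um))
      disp %>%
        group_by(.data$frame) %>%
        mutate(threshold_um = mean(.data$displacement_um) +
                 2 * pop_sd(.data$displacement_um)) %>%
        ungroup() %>%
        filter(.data$displacement_um > .data$threshold_um) %>%
        select("chromosome_id", "frame", "displacement_um", "threshold_um")
    }) %>%
    ungroup()
  if (nrow(out) == 0) empty else out
}

# population (divide-by-n) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Read / write the canonical trajectory CSV
#'
#' Columns `oocyte_id,chromosome_id,frame,t_min,x_um,y_um,z_um` with an
#' optional `true_label`.
#'
#' @param path CSV path.
#' @return `read_trajectories()`: a trajectory tibble.
#' @export
read_trajectories <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    oocyte_id = readr::col_character(),
                    chromosome_id = readr::col_integer(),
                    frame = readr::col_integer()))
}

#' @rdname read_trajectories
#' @param trajectories Trajectory tibble to write.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path)
  invisible(path)
}
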