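# Readers and writers. All files carry um/nN units in their column names;
# stacks round-trip through multi-page TIFF with a JSON sidecar holding the
# voxel geometry and the intensity scale.

#' Write deflection fields to CSV
#'
#' Columns: time, fiber_id, node_index, position_um, dy_um, dz_um.
#'
#' @param fields named list of `deflection_field` (single timepoint) or a
#'   list of such lists (one per timepoint).
#' @param path output CSV path.
#' @export
write_deflections_csv <- function(fields, path) {
  if (length(fields) > 0L && inherits(fields[[1]], "deflection_field"))
    fields <- list(fields)
  rows <- list()
  for (t in seq_along(fields)) {
    for (fid in names(fields[[t]])) {
      f <- fields[[t]][[fid]]
      rows[[length(rows) + 1L]] <- data.frame(
        time = t, fiber_id = fid,
        node_index = seq_along(f$dy), position_um = f$positions_um,
        dy_um = f$dy, dz_um = f$dz, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read deflection fields from CSV
#' @param path file written by [write_deflections_csv()].
#' @return list over timepoints of named `deflection_field` lists.
#' @export
read_deflections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$time), function(dt) {
    out <- lapply(split(dt, dt$fiber_id), function(dd) {
      dd <- dd[order(dd$node_index), ]
      deflection_field(dd$dy_um, dd$dz_um, dd$position_um)
    })
    out
  })
}

#' Write force fields to CSV
#'
#' Columns: time, fiber_id, node_index, position_um, Fy_nN, Fz_nN,
#' magnitude_nN. Only nonzero (contact) nodes are written.
#'
#' @param fields named list of `force_field` or list of such lists per
#'   timepoint.
#' @param path output CSV path.
#' @export
write_forces_csv <- function(fields, path) {
  if (length(fields) > 0L && inherits(fields[[1]], "force_field"))
    fields <- list(fields)
  rows <- list()
  for (t in seq_along(fields)) {
    for (fid in names(fields[[t]])) {
      df <- as.data.frame(fields[[t]][[fid]])
      if (nrow(df) == 0L) next
      df <- cbind(time = t, fiber_id = fid, df)
      rows[[length(rows) + 1L]] <- df
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = integer(0), fiber_id = character(0),
               node_index = integer(0), position_um = numeric(0),
               Fy_nN = numeric(0), Fz_nN = numeric(0),
               magnitude_nN = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read force fields from CSV
#' @param path file written by [write_forces_csv()].
#' @param models named list of `beam_model` per fiber id.
#' @return list over timepoints of named `force_field` lists.
#' @export
read_forces_csv <- function(path, models) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$time), function(dt) {
    lapply(split(dt, dt$fiber_id), function(dd) {
      force_field(models[[dd$fiber_id[1]]], dd$node_index, dd$Fy_nN,
                  dd$Fz_nN)
    })
  })
}

#' Write contact sets to CSV
#' @param contacts named list of integer vectors (or list per timepoint).
#' @param path output path.
#' @export
write_contacts_csv <- function(contacts, path) {
  if (length(contacts) > 0L && is.numeric(contacts[[1]]))
    contacts <- list(contacts)
  rows <- list()
  for (t in seq_along(contacts)) {
    for (fid in names(contacts[[t]])) {
      nd <- contacts[[t]][[fid]]
      if (length(nd) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(time = t, fiber_id = fid,
                                              node_index = nd)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = integer(0), fiber_id = character(0),
               node_index = integer(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read contact sets from CSV
#' @param path file written by [write_contacts_csv()].
#' @return list over timepoints of named integer vectors.
#' @export
read_contacts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$time), function(dt)
    lapply(split(dt, dt$fiber_id), function(dd) sort(dd$node_index)))
}

#' Write a volume stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are z-slices ordered (time, channel, z); intensities are scaled to
#' 16-bit with the scale recorded in `<path>.json` so reading restores the
#' original values (to 16-bit quantization).
#'
#' @param stack a `volume_stack`.
#' @param path output .tif path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$fiber)
  mx <- max(stack$fiber, stack$cell, 1e-12)
  mn <- min(stack$fiber, stack$cell, 0)
  pages <- list()
  for (t in seq_len(d[4])) for (ch in c("fiber", "cell")) for (z in seq_len(d[3])) {
    sl <- (stack[[ch]][, , z, t] - mn) / (mx - mn)
    pages[[length(pages) + 1L]] <- t(sl)   # rows = y for conventional viewers
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(dims = d, voxel_size_um = stack$voxel_size_um,
               origin_um = stack$origin_um, channels = c("fiber", "cell"),
               intensity_min = mn, intensity_max = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume stack written by [write_stack_tiff()]
#' @param path .tif path (sidecar `<path>.json` must exist).
#' @return a `volume_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("missing stack sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  fib <- array(0, d); cel <- array(0, d)
  p <- 1L
  for (t in seq_len(d[4])) for (ch in 1:2) for (z in seq_len(d[3])) {
    sl <- t(pages[[p]]) * (meta$intensity_max - meta$intensity_min) +
      meta$intensity_min
    if (ch == 1L) fib[, , z, t] <- sl else cel[, , z, t] <- sl
    p <- p + 1L
  }
  volume_stack(fib, cel, meta$voxel_size_um, meta$origin_um)
}

#' Write a scalar volume (map) as TIFF
#' @param vol 3D numeric array.
#' @param path output path.
#' @export
write_map_tiff <- function(vol, path) {
  mx <- max(vol, 1e-12)
  pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z] / mx))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(scale_max = mx, dims = dim(vol)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Single YAML file driving the pipeline commands. Numeric fields are
#' validated against the preconditions of the owning modules at load time.
#' Defaults mirror the standard experimental conditions: 0.3/1 um voxels,
#' 80 um fibers, 10 um spacing and z-gap, 64 elements, 0.5 um contact
#' reach.
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    output_dir = "fibertfm-out",
    layout = list(kind = "two-layer", length_um = 80, spacing_um = 10),
    fiber = list(condition = "600us"),
    voxel_size_um = c(0.3, 0.3, 1),
    n_elements = 64,
    contact_reach_um = 0.5,
    central_fraction = 0.5,
    seed = 1,
    reg = list(lambda1 = 0.01, lambda2 = 0.01, tune = FALSE),
    cell = list(center_um = NULL, radii_um = c(16, 16, 9)),
    magnitude_nN = 0.67,
    noise = list(sigma_xy_um = 0.3, sigma_z_um = 1))
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$n_elements < 2) stop("config: n_elements must be >= 2",
                               call. = FALSE)
  if (any(unlist(cfg$voxel_size_um) <= 0))
    stop("config: voxel sizes must be positive", call. = FALSE)
  if (cfg$contact_reach_um < 0)
    stop("config: contact_reach_um must be >= 0", call. = FALSE)
  if (cfg$central_fraction <= 0 || cfg$central_fraction > 1)
    stop("config: central_fraction must be in (0, 1]", call. = FALSE)
  if (cfg$layout$kind == "two-layer" &&
      cfg$layout$spacing_um < MIN_SPACING_UM)
    stop(sprintf("config: spacing %g um is below the %g um fabrication limit",
                 cfg$layout$spacing_um, MIN_SPACING_UM), call. = FALSE)
  if (cfg$reg$lambda1 < 0 || cfg$reg$lambda2 < 0)
    stop("config: regularization weights must be >= 0", call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

.config_spec <- function(cfg) {
  f <- cfg$fiber
  if (!is.null(f$condition))
    preset_spec(f$condition, length_um = cfg$layout$length_um)
  else if (!is.null(f$apparent_stiffness_nN_per_um))
    fiber_spec(cfg$layout$length_um, f$width_um, f$height_um,
               f$youngs_modulus_MPa,
               tension_nN = calibrate_tension(f$apparent_stiffness_nN_per_um,
                                              cfg$layout$length_um))
  else
    fiber_spec(cfg$layout$length_um, f$width_um, f$height_um,
               f$youngs_modulus_MPa, tension_nN = f$tension_nN)
}
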