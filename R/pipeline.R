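# Pipeline commands binding the modules together. Each is a plain function
# over a run_config; the command-line script in inst/cli is a thin wrapper
# that maps errors to exit codes.

.log_msg <- function(...) message(sprintf(...))

.run_summary <- function(cfg, extra = list()) {
  c(list(package_version = as.character(utils::packageVersion("fibertfm")),
         seed = cfg$seed,
         config_hash = digest_config(cfg),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra)
}

#' Stable hash of a configuration
#'
#' Order-independent fingerprint recorded in every run summary so outputs
#' can be traced back to the exact configuration that produced them.
#' @param cfg a `run_config` (or any list).
#' @return hex string.
#' @export
digest_config <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  # polynomial rolling hash over the serialized bytes: no cryptographic
  # claim, just a stable identity
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a phantom bundle
#'
#' Generates a scaffold phantom under the configured conditions and writes
#' the rendered stack, layout, ground-truth forces, deflections and
#' contacts, the deflection map and a run summary (8 files).
#'
#' @param cfg a `run_config` (or path to one).
#' @return invisibly, the vector of written paths.
#' @export
run_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- .config_spec(cfg)
  truth <- make_phantom(seed = cfg$seed, kind = cfg$layout$kind,
                        length_um = cfg$layout$length_um,
                        spacing_um = cfg$layout$spacing_um, spec = spec,
                        cell_center_um = cfg$cell$center_um,
                        cell_radii_um = unlist(cfg$cell$radii_um),
                        magnitude_nN = cfg$magnitude_nN,
                        n_elements = cfg$n_elements)
  stack <- render_stack(truth, voxel_size_um = unlist(cfg$voxel_size_um))
  out <- file.path(cfg$output_dir, c(
    stack = "stack.tif", layout = "layout.json",
    forces = "truth_forces.csv", defl = "truth_deflections.csv",
    contacts = "truth_contacts.csv", phantom = "phantom.json",
    map = "deflection_map.tif", summary = "run_summary.json"))
  write_stack_tiff(stack, out[1])
  write_layout_json(truth$layout, out[2])
  models <- attr(truth$fields, "models")
  ffs <- lapply(names(truth$pattern$forces), function(fid) {
    f <- truth$pattern$forces[[fid]]
    force_field(models[[fid]], f$node, f$fy, f$fz)
  })
  names(ffs) <- names(truth$pattern$forces)
  write_forces_csv(ffs, out[3])
  write_deflections_csv(truth$fields, out[4])
  write_contacts_csv(truth$pattern$contacts, out[5])
  jsonlite::write_json(list(cell = truth$pattern$cell, seed = truth$seed,
                            optics = truth$optics, noise = truth$noise),
                       out[6], auto_unbox = TRUE, digits = NA)
  dmap <- deflection_map(truth$fields, truth$layout, dim(stack$fiber)[1:3],
                         stack$voxel_size_um, stack$origin_um)
  write_map_tiff(dmap, out[7])
  jsonlite::write_json(.run_summary(cfg, list(command = "simulate",
                                              n_files = length(out))),
                       out[8], auto_unbox = TRUE, digits = NA)
  .log_msg("simulate: wrote %d files to %s", length(out), cfg$output_dir)
  invisible(out)
}

#' Analyze a stack: deflection fields and contact sets
#'
#' Reads the stack and layout from the output directory (or configured
#' paths), segments fibers and cell per timepoint, extracts centerlines,
#' computes the reference-free deflection fields and contact sets, and
#' writes them as CSV plus a per-timepoint deflection map.
#'
#' @param cfg a `run_config` (or path).
#' @return invisibly, the written paths.
#' @export
run_analyze <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stack_path <- cfg$input_stack %||% file.path(cfg$output_dir, "stack.tif")
  layout_path <- cfg$layout_json %||% file.path(cfg$output_dir, "layout.json")
  stack <- read_stack_tiff(stack_path)
  layout <- read_layout_json(layout_path)
  spec <- .config_spec(cfg)
  model <- build_beam_model(spec, cfg$n_elements)
  nt <- dim(stack$fiber)[4]
  all_traces <- lapply(seq_len(nt), function(t)
    trace_fibers(stack, layout, timepoint = t))
  all_traces <- track_fibers(all_traces, layout)
  fields <- list(); contacts <- list()
  for (t in seq_len(nt)) {
    mask <- segment_cell(stack, timepoint = t)
    fields[[t]] <- lapply(all_traces[[t]], compute_deflection, model = model)
    contacts[[t]] <- lapply(all_traces[[t]], function(tr)
      contact_nodes(mask, tr, model, reach_um = cfg$contact_reach_um))
  }
  out <- file.path(cfg$output_dir,
                   c("deflections.csv", "contacts.csv",
                     "deflection_map_measured.tif", "analyze_summary.json"))
  write_deflections_csv(fields, out[1])
  write_contacts_csv(contacts, out[2])
  dmap <- deflection_map(fields[[1]], layout, dim(stack$fiber)[1:3],
                         stack$voxel_size_um, stack$origin_um)
  write_map_tiff(dmap, out[3])
  jsonlite::write_json(.run_summary(cfg, list(command = "analyze",
                                              n_timepoints = nt)),
                       out[4], auto_unbox = TRUE, digits = NA)
  .log_msg("analyze: %d timepoint(s) -> %s", nt, cfg$output_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover forces from measured deflections
#'
#' Reads the deflection and contact CSVs, recovers the nodal forces per
#' fiber and timepoint with the configured (or simulation-tuned) elastic
#' net, and writes forces, a contractility/residual time series, a summary
#' and a voxelized force-magnitude map.
#'
#' @param cfg a `run_config` (or path).
#' @return invisibly, the written paths.
#' @export
run_recover <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  fields_t <- read_deflections_csv(file.path(cfg$output_dir,
                                             "deflections.csv"))
  contacts_t <- read_contacts_csv(file.path(cfg$output_dir, "contacts.csv"))
  layout <- read_layout_json(file.path(cfg$output_dir, "layout.json"))
  spec <- .config_spec(cfg)
  model <- build_beam_model(spec, cfg$n_elements)
  outs <- character(0)
  if (isTRUE(cfg$reg$tune)) {
    all_c <- sort(unique(unlist(contacts_t[[1]])))
    if (length(all_c) == 0L) stop("no contacts to tune on", call. = FALSE)
    scan <- select_regularization(model, all_c,
                                  noise = list(sigma_xy_um = cfg$noise$sigma_xy_um,
                                               sigma_z_um = cfg$noise$sigma_z_um),
                                  seed = cfg$seed)
    reg <- scan$best
    scan_path <- file.path(cfg$output_dir, "reg_scan.csv")
    utils::write.csv(scan$table, scan_path, row.names = FALSE)
    outs <- c(outs, scan_path)
  } else {
    reg <- reg_params(cfg$reg$lambda1, cfg$reg$lambda2)
  }
  forces <- list(); series <- list()
  for (t in seq_along(fields_t)) {
    ct <- contacts_t[[as.character(t)]] %||% contacts_t[[t]]
    any_contact <- any(vapply(ct, length, integer(1)) > 0)
    if (!any_contact)
      stop("empty contact set at timepoint ", t, call. = FALSE)
    ft <- list()
    for (fid in names(fields_t[[t]])) {
      cset <- ct[[fid]]
      if (is.null(cset) || length(cset) == 0L) next
      ft[[fid]] <- recover_forces(fields_t[[t]][[fid]], model, cset, reg,
                                  seed = cfg$seed + t)
    }
    forces[[t]] <- ft
    tot <- sum(vapply(ft, contractility, numeric(1)))
    res <- colSums(do.call(rbind, lapply(ft, function(f)
      residual_force(f)$vector)))
    loss_t <- sum(vapply(ft, function(f) attr(f, "loss"), numeric(1)))
    series[[t]] <- data.frame(time = t, contractility_nN = tot,
                              residual_Fy_nN = res[1], residual_Fz_nN = res[2],
                              residual_magnitude_nN = sqrt(sum(res^2)),
                              loss = loss_t)
    .log_msg("recover t=%d: lambda1=%g lambda2=%g loss=%.4g contractility=%.3g nN",
             t, reg$lambda1, reg$lambda2, loss_t, tot)
  }
  out <- file.path(cfg$output_dir,
                   c("forces.csv", "contractility.csv",
                     "force_map.tif", "recover_summary.json"))
  write_forces_csv(forces, out[1])
  utils::write.csv(do.call(rbind, series), out[2], row.names = FALSE)
  # force map: reuse the deflection-map rasterizer on force magnitudes
  fmap_fields <- lapply(forces[[1]], function(f) {
    mag <- sqrt(f$fy^2 + f$fz^2)
    deflection_field(rep(0, length(mag)), rep(0, length(mag)),
                     f$positions_um)
  })
  for (fid in names(fmap_fields)) {
    f <- forces[[1]][[fid]]
    fmap_fields[[fid]]$dy <- abs(f$fy); fmap_fields[[fid]]$dz <- abs(f$fz)
  }
  dims <- ceiling((c(max(layout$x1), max(layout$y1), max(layout$z1)) -
                   c(min(layout$x0), min(layout$y0), min(layout$z0)) + 8) /
                  unlist(cfg$voxel_size_um))
  fmap <- deflection_map(fmap_fields, layout, dims,
                         unlist(cfg$voxel_size_um),
                         c(min(layout$x0), min(layout$y0),
                           min(layout$z0)) - 4)
  write_map_tiff(fmap, out[3])
  jsonlite::write_json(
    .run_summary(cfg, list(command = "recover",
                           lambda1 = reg$lambda1, lambda2 = reg$lambda2,
                           tuned = isTRUE(cfg$reg$tune),
                           contractility_nN = vapply(series, function(s)
                             s$contractility_nN, numeric(1)))),
    out[4], auto_unbox = TRUE, digits = NA)
  invisible(c(out, outs))
}

#' Aggregate force metrics over one or more runs
#'
#' Reads recover outputs under `dir` (or a vector of run directories),
#' computes per-run force metrics, and fits the logarithmic
#' force-versus-contacted-nodes relation when at least three runs are
#' pooled.
#'
#' @param dirs one or more output directories containing `forces.csv`.
#' @param central_fraction central-window fraction for per-node metrics.
#' @return list with `table` (one row per run) and optionally `log_fit`;
#'   written as `report.json`/`report.csv` in the first directory.
#' @export
run_report <- function(dirs, central_fraction = 0.5) {
  dirs <- dirs[file.exists(file.path(dirs, "forces.csv"))]
  if (length(dirs) == 0L)
    stop("no recover outputs found (forces.csv missing)", call. = FALSE)
  rows <- lapply(dirs, function(d) {
    df <- utils::read.csv(file.path(d, "forces.csv"),
                          stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
      return(data.frame(run = d, n_contact_nodes = 0,
                        total_force_nN = 0, force_per_node_nN = NA,
                        central_force_per_node_nN = NA))
    per_t <- split(df, df$time)
    mt <- vapply(per_t, function(dt) {
      L <- max(dt$position_um)
      lo <- L * (1 - central_fraction) / 2
      hi <- L * (1 + central_fraction) / 2
      cen <- dt$position_um > lo & dt$position_um < hi
      c(n = nrow(dt), total = sum(dt$magnitude_nN),
        central = if (any(cen)) mean(dt$magnitude_nN[cen]) else NA_real_)
    }, numeric(3))
    data.frame(run = d, n_contact_nodes = mean(mt["n", ]),
               total_force_nN = mean(mt["total", ]),
               force_per_node_nN = mean(mt["total", ] / mt["n", ]),
               central_force_per_node_nN = mean(mt["central", ],
                                                na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  out <- list(table = tab)
  if (nrow(tab) >= 3L && stats::var(log(tab$n_contact_nodes)) > 0)
    out$log_fit <- fit_log_force_vs_nodes(tab$n_contact_nodes,
                                          tab$total_force_nN)
  utils::write.csv(tab, file.path(dirs[1], "report.csv"), row.names = FALSE)
  jsonlite::write_json(out, file.path(dirs[1], "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out
}
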