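# Synthetic phantoms: ground-truth force patterns on a scaffold, exact
# forward-model deflections, and rendered noisy two-channel image stacks.
# The image-formation model is Gaussian-profile tubes along the deformed
# centerlines, an anisotropic Gaussian PSF, Poisson shot noise and additive
# Gaussian read noise, at the experimental voxel sizes (0.3 um xy, 1 um z).

#' Multi-channel 3D(+time) image volume
#'
#' Thin container for a fiber channel and a cell channel on a common voxel
#' grid. Arrays are indexed `[x, y, z, t]`; world coordinates (um) of voxel
#' centers are `origin_um + (index - 0.5) * voxel_size_um` per axis.
#'
#' @param fiber,cell numeric arrays, 3D `[x, y, z]` (coerced to one
#'   timepoint) or 4D `[x, y, z, t]`.
#' @param voxel_size_um `c(dx, dy, dz)` in um; dx = dy may differ from dz.
#' @param origin_um world coordinate of the volume corner, um.
#' @return object of class `volume_stack`.
#' @export
volume_stack <- function(fiber, cell, voxel_size_um, origin_um = c(0, 0, 0)) {
  to4 <- function(a) {
    if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L)
    if (length(dim(a)) != 4L) stop("channel arrays must be 3D or 4D",
                                   call. = FALSE)
    a
  }
  fiber <- to4(fiber); cell <- to4(cell)
  if (!identical(dim(fiber), dim(cell)))
    stop("fiber and cell channels must share one grid", call. = FALSE)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be three positive sizes", call. = FALSE)
  structure(list(fiber = fiber, cell = cell,
                 voxel_size_um = as.numeric(voxel_size_um),
                 origin_um = as.numeric(origin_um)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$fiber)
  cat(sprintf("volume_stack: %d x %d x %d voxels, %d timepoint(s), voxel %g x %g x %g um\n",
              d[1], d[2], d[3], d[4], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3]))
  invisible(x)
}

.n_timepoints <- function(stack) dim(stack$fiber)[4]

.get_channel <- function(stack, channel = c("fiber", "cell"), timepoint = 1L) {
  channel <- match.arg(channel)
  if (timepoint < 1L || timepoint > .n_timepoints(stack))
    stop("timepoint out of range", call. = FALSE)
  stack[[channel]][, , , timepoint]
}

# world coordinates (um) of voxel centers along one axis
.axis_coords <- function(n, voxel, origin) origin + (seq_len(n) - 0.5) * voxel

#' Sample a ground-truth traction force pattern on a scaffold
#'
#' Places an ellipsoidal cell region in the scaffold; every interior mesh
#' node of every fiber that falls inside the ellipsoid becomes a contact
#' node. Per-node force directions are biased centripetally (toward the
#' cell center, projected on the fiber's transverse plane, with Gaussian
#' angular jitter), emulating the peripherally concentrated, inward-pulling
#' tractions of contractile cells; magnitudes are log-normal with the given
#' scale. Fully random directions are available via `centripetal = FALSE`.
#'
#' @param layout a `scaffold_layout`.
#' @param cell_center_um,cell_radii_um ellipsoid center and semi-axes, um.
#' @param magnitude_nN log-normal magnitude scale (median), nN; the
#'   default 0.67 nN matches the published average per-node force on
#'   low-stiffness fibers.
#' @param sdlog log-normal shape parameter.
#' @param n_elements fiber mesh resolution.
#' @param centripetal bias directions toward the cell center.
#' @param angle_jitter_sd angular jitter (radians) around the centripetal
#'   direction.
#' @param seed integer seed; fixed seed gives identical output.
#' @return object of class `force_pattern`: named lists `contacts` and
#'   `angles`/`magnitudes` resolved into per-fiber `force_field`s in
#'   `forces`, plus the cell ellipsoid.
#' @export
sample_force_pattern <- function(layout, cell_center_um, cell_radii_um,
                                 magnitude_nN = 0.67, sdlog = 0.4,
                                 n_elements = 64, centripetal = TRUE,
                                 angle_jitter_sd = 0.3, seed = 1L) {
  stopifnot(inherits(layout, "scaffold_layout"))
  if (magnitude_nN <= 0) stop("'magnitude_nN' must be > 0", call. = FALSE)
  if (length(cell_center_um) != 3L || length(cell_radii_um) != 3L ||
      any(cell_radii_um <= 0))
    stop("cell center and radii must be 3-vectors (radii > 0)",
         call. = FALSE)
  withr::with_seed(seed, {
    contacts <- list(); forces <- list()
    for (i in seq_len(nrow(layout))) {
      fid <- layout$fiber_id[i]
      anc <- .layout_anchors(layout, fid)
      fr <- .fiber_frame(anc$start, anc$end)
      s <- seq(0, fr$length, length.out = n_elements + 1)
      P <- outer(s, fr$u) + rep(anc$start, each = length(s))
      r2 <- ((P[, 1] - cell_center_um[1]) / cell_radii_um[1])^2 +
            ((P[, 2] - cell_center_um[2]) / cell_radii_um[2])^2 +
            ((P[, 3] - cell_center_um[3]) / cell_radii_um[3])^2
      inside <- which(r2 <= 1)
      inside <- inside[inside > 1 & inside < length(s)]
      if (length(inside) == 0L) next
      mag <- stats::rlnorm(length(inside), meanlog = log(magnitude_nN),
                           sdlog = sdlog)
      if (centripetal) {
        v <- rep(cell_center_um, each = length(inside)) -
             P[inside, , drop = FALSE]
        vy <- v %*% fr$ey; vz <- v %*% fr$ez
        phi0 <- atan2(vz, vy)
        # nodes crossing the center have no transverse pull: randomize
        deg <- sqrt(vy^2 + vz^2) < 1e-9
        phi0[deg] <- stats::runif(sum(deg), 0, 2 * pi)
        phi <- phi0 + stats::rnorm(length(inside), 0, angle_jitter_sd)
      } else {
        phi <- stats::runif(length(inside), 0, 2 * pi)
      }
      contacts[[fid]] <- inside
      forces[[fid]] <- list(node = inside, fy = mag * cos(phi),
                            fz = mag * sin(phi))
    }
    if (length(contacts) == 0L)
      stop("cell region touches no fiber node; move or enlarge the cell",
           call. = FALSE)
    structure(list(forces = forces, contacts = contacts,
                   cell = list(center_um = cell_center_um,
                               radii_um = cell_radii_um),
                   n_elements = n_elements, seed = seed),
              class = "force_pattern")
  })
}

# Build per-fiber beam models for a layout; specs is a single fiber_spec
# (recycled, with per-fiber lengths from the layout) or a named list.
.layout_models <- function(layout, specs, n_elements) {
  models <- list()
  for (i in seq_len(nrow(layout))) {
    fid <- layout$fiber_id[i]
    sp <- if (inherits(specs, "fiber_spec")) specs else specs[[fid]]
    if (is.null(sp)) stop("no fiber spec for ", fid, call. = FALSE)
    if (abs(sp$length_um - layout$length_um[i]) > 1e-9)
      sp <- fiber_spec(layout$length_um[i], sp$width_um, sp$height_um,
                       sp$E / MPA_TO_NN_PER_UM2, sp$tension_nN)
    models[[fid]] <- build_beam_model(sp, n_elements)
  }
  models
}

#' Forward-deform a scaffold under a ground-truth force pattern
#'
#' Exact finite-element deflections of every loaded fiber; the phantom
#' ground truth the imaging and inverse stages are validated against.
#'
#' @param layout a `scaffold_layout`.
#' @param specs one `fiber_spec` (recycled across fibers) or a named list.
#' @param pattern a `force_pattern` (or named list of force specs).
#' @param n_elements mesh resolution (must match the pattern's).
#' @return named list of `deflection_field`, one per loaded fiber, with the
#'   per-fiber `beam_model`s in attribute `models`.
#' @export
forward_deform <- function(layout, specs, pattern, n_elements = 64) {
  stopifnot(inherits(layout, "scaffold_layout"))
  flist <- if (inherits(pattern, "force_pattern")) pattern$forces else pattern
  if (any(!names(flist) %in% layout$fiber_id))
    stop("force on unknown fiber: ",
         paste(setdiff(names(flist), layout$fiber_id), collapse = ", "),
         call. = FALSE)
  models <- .layout_models(layout[layout$fiber_id %in% names(flist), ,
                                  drop = FALSE], specs, n_elements)
  fields <- list()
  for (fid in names(flist)) {
    f <- flist[[fid]]
    ff <- force_field(models[[fid]], f$node, f$fy, f$fz)
    fields[[fid]] <- solve_forward(models[[fid]], ff)
  }
  attr(fields, "models") <- models
  fields
}

#' Add measurement noise to deflection fields
#'
#' Independent zero-mean Gaussian noise per interior node and axis, with
#' the in-plane and vertical scales of the deflection measurement (clamped
#' end nodes stay exactly zero). Pass `seed = NULL` to draw from the
#' current RNG state.
#'
#' @param fields one `deflection_field` or a (possibly named) list.
#' @param sigma_xy_um,sigma_z_um per-axis noise SDs, um (>= 0).
#' @param seed integer seed, or NULL.
#' @return same shape as `fields`.
#' @export
perturb_deflections <- function(fields, sigma_xy_um = 0.3, sigma_z_um = 1,
                                seed = 1L) {
  if (sigma_xy_um < 0 || sigma_z_um < 0)
    stop("noise sigmas must be >= 0", call. = FALSE)
  one <- function(f) {
    n <- length(f$dy)
    int <- 2:(n - 1)
    dy <- f$dy; dz <- f$dz
    dy[int] <- dy[int] + stats::rnorm(length(int), 0, sigma_xy_um)
    dz[int] <- dz[int] + stats::rnorm(length(int), 0, sigma_z_um)
    deflection_field(dy, dz, f$positions_um,
                     sigma_y = sigma_xy_um, sigma_z = sigma_z_um)
  }
  run <- function() {
    if (inherits(fields, "deflection_field")) one(fields)
    else lapply(fields, one)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assemble a phantom ground-truth bundle
#'
#' @param layout a `scaffold_layout`.
#' @param specs one `fiber_spec` or named list.
#' @param pattern a `force_pattern`.
#' @param fields output of [forward_deform()] for the same pattern.
#' @param optics list: `psf_sigma_um` (3-vector).
#' @param noise list: `peak_photons`, `background_photons`, `read_noise_sd`.
#' @param seed render seed.
#' @return object of class `phantom_truth`.
#' @export
phantom_truth <- function(layout, specs, pattern, fields,
                          optics = list(psf_sigma_um = c(0.25, 0.25, 1.0)),
                          noise = list(peak_photons = 150,
                                       background_photons = 10,
                                       read_noise_sd = 2),
                          seed = 1L) {
  structure(list(layout = layout, specs = specs, pattern = pattern,
                 fields = fields, optics = optics, noise = noise,
                 seed = seed),
            class = "phantom_truth")
}

#' One-call phantom builder
#'
#' Convenience wrapper: layout, force pattern, forward deformation and
#' truth bundle in one step, at the standard study conditions (two
#' orthogonal layers of 80 um fibers, 10 um spacing/z-gap, 600 us fiber
#' mechanics, a mid-scaffold ellipsoidal cell).
#'
#' @param seed master seed.
#' @param kind,length_um,spacing_um layout parameters.
#' @param spec a `fiber_spec`.
#' @param cell_center_um,cell_radii_um cell ellipsoid (defaults: centered
#'   between the two layers, radii 16 x 16 x 9 um).
#' @param magnitude_nN force magnitude scale.
#' @param n_elements mesh resolution.
#' @return a `phantom_truth`.
#' @export
make_phantom <- function(seed = 1L, kind = "two-layer", length_um = 80,
                         spacing_um = 10, spec = preset_spec("600us"),
                         cell_center_um = NULL,
                         cell_radii_um = c(16, 16, 9),
                         magnitude_nN = 0.67, n_elements = 64) {
  layout <- make_layout(kind, length_um = length_um, spacing_um = spacing_um)
  if (is.null(cell_center_um))
    cell_center_um <- c(length_um / 2, length_um / 2,
                        mean(range(layout$z0)))
  pattern <- sample_force_pattern(layout, cell_center_um, cell_radii_um,
                                  magnitude_nN = magnitude_nN,
                                  n_elements = n_elements, seed = seed)
  fields <- forward_deform(layout, spec, pattern, n_elements = n_elements)
  phantom_truth(layout, spec, pattern, fields, seed = seed)
}

# Separable Gaussian blur of a 3D array via sparse band-matrix products.
.gaussian_blur_3d <- function(a, sigma_vox) {
  d <- dim(a)
  kern_mat <- function(n, s) {
    if (s <= 1e-6) return(NULL)
    half <- max(1L, ceiling(3 * s))
    off <- -half:half
    k <- exp(-off^2 / (2 * s^2)); k <- k / sum(k)
    bands <- lapply(seq_along(off), function(j)
      rep(k[j], n - abs(off[j])))
    M <- Matrix::bandSparse(n, n, k = off, diagonals = bands)
    # renormalize rows near the edges so intensity is preserved
    rs <- Matrix::rowSums(M)
    Matrix::Diagonal(n, 1 / rs) %*% M
  }
  M1 <- kern_mat(d[1], sigma_vox[1])
  if (!is.null(M1)) a <- array(as.matrix(M1 %*% matrix(a, d[1])), d)
  M2 <- kern_mat(d[2], sigma_vox[2])
  if (!is.null(M2)) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(as.matrix(M2 %*% matrix(a, d[2])), d[c(2, 1, 3)])
    a <- aperm(a, c(2, 1, 3))
  }
  M3 <- kern_mat(d[3], sigma_vox[3])
  if (!is.null(M3)) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(as.matrix(M3 %*% matrix(a, d[3])), d[c(3, 1, 2)])
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

# Rasterize the ellipsoidal cell region into a logical volume.
.rasterize_cell <- function(cell, dims, voxel, origin) {
  xs <- .axis_coords(dims[1], voxel[1], origin[1])
  ys <- .axis_coords(dims[2], voxel[2], origin[2])
  zs <- .axis_coords(dims[3], voxel[3], origin[3])
  rx2 <- ((xs - cell$center_um[1]) / cell$radii_um[1])^2
  ry2 <- ((ys - cell$center_um[2]) / cell$radii_um[2])^2
  rz2 <- ((zs - cell$center_um[3]) / cell$radii_um[3])^2
  arr <- outer(outer(rx2, ry2, `+`), rz2, `+`)
  arr <- array(arr, dims)
  arr <- arr <= 1
  arr
}

# Draw one fiber as a Gaussian-profile tube around its deformed centerline.
# Centerline given as world-space function of the axial coordinate.
.draw_fiber <- function(vol, anc, frame, field, radius_xy_um, radius_z_um,
                        voxel, origin) {
  d <- dim(vol)
  ax_dim <- which.max(abs(frame$u[1:2]))          # 1 = x fiber, 2 = y fiber
  ax_coords <- .axis_coords(d[ax_dim], voxel[ax_dim], origin[ax_dim])
  # axial coordinate s of each voxel column along the fiber direction
  s <- (ax_coords - anc$start[ax_dim]) / frame$u[ax_dim]
  ok <- which(s >= 0 & s <= frame$length)
  dy <- stats::approx(field$positions_um, field$dy, xout = s[ok],
                      rule = 2)$y
  dz <- stats::approx(field$positions_um, field$dz, xout = s[ok],
                      rule = 2)$y
  # world centerline points
  P <- rep(anc$start, each = length(ok)) + outer(s[ok], frame$u) +
       outer(dy, frame$ey) + outer(dz, frame$ez)
  lat_dim <- if (ax_dim == 1L) 2L else 1L
  lat_coords <- .axis_coords(d[lat_dim], voxel[lat_dim], origin[lat_dim])
  z_coords <- .axis_coords(d[3], voxel[3], origin[3])
  r_lat <- max(radius_xy_um, 0.5 * voxel[lat_dim])
  r_z <- max(radius_z_um, 0.5 * voxel[3])
  lat_half <- ceiling(3.5 * r_lat / voxel[lat_dim])
  z_half <- ceiling(3.5 * r_z / voxel[3])
  for (k in seq_along(ok)) {
    ia <- ok[k]
    cl <- P[k, lat_dim]; cz <- P[k, 3]
    il <- round(cl / voxel[lat_dim] - origin[lat_dim] / voxel[lat_dim] + 0.5)
    iz <- round(cz / voxel[3] - origin[3] / voxel[3] + 0.5)
    jl <- max(1, il - lat_half):min(d[lat_dim], il + lat_half)
    jz <- max(1, iz - z_half):min(d[3], iz + z_half)
    if (length(jl) == 0L || length(jz) == 0L) next
    prof <- outer(exp(-(lat_coords[jl] - cl)^2 / (2 * r_lat^2)),
                  exp(-(z_coords[jz] - cz)^2 / (2 * r_z^2)))
    if (ax_dim == 1L) {
      vol[ia, jl, jz] <- pmax(vol[ia, jl, jz], prof)
    } else {
      vol[jl, ia, jz] <- pmax(vol[jl, ia, jz], prof)
    }
  }
  vol
}

#' Render a phantom into a noisy two-channel image stack
#'
#' Fiber channel: deformed centerlines drawn as Gaussian-profile tubes
#' (radii from the fiber cross-section, floored at half a voxel), blurred
#' with an anisotropic Gaussian PSF, scaled to photon counts, Poisson shot
#' noise, then additive Gaussian read noise. Cell channel: the smoothed
#' rasterized cell ellipsoid under the same noise model. Seeded and
#' reproducible bit-for-bit.
#'
#' @param truth a `phantom_truth`.
#' @param voxel_size_um voxel sizes, um (defaults to the experimental
#'   0.3 x 0.3 x 1 um).
#' @param margin_um empty border around the scaffold, um.
#' @param seed integer seed; defaults to the truth's render seed.
#' @return a `volume_stack` (single timepoint).
#' @export
render_stack <- function(truth, voxel_size_um = c(0.3, 0.3, 1),
                         margin_um = c(8, 8, 8), seed = truth$seed) {
  stopifnot(inherits(truth, "phantom_truth"))
  layout <- truth$layout
  lo <- c(min(layout$x0, layout$x1), min(layout$y0, layout$y1),
          min(layout$z0, layout$z1)) - margin_um
  hi <- c(max(layout$x0, layout$x1), max(layout$y0, layout$y1),
          max(layout$z0, layout$z1)) + margin_um
  dims <- pmax(ceiling((hi - lo) / voxel_size_um), 4L)
  origin <- lo
  models <- attr(truth$fields, "models")
  fib <- array(0, dims)
  for (i in seq_len(nrow(layout))) {
    fid <- layout$fiber_id[i]
    anc <- .layout_anchors(layout, fid)
    frame <- .fiber_frame(anc$start, anc$end)
    field <- truth$fields[[fid]]
    if (is.null(field)) {
      n <- 65L
      field <- deflection_field(numeric(n), numeric(n),
                                seq(0, frame$length, length.out = n))
    }
    mx <- max(abs(c(field$dy, field$dz, 0)))
    if (mx + 1.5 > min(margin_um))  # deflection plus tube halo vs border
      stop("deformed fiber ", fid, " extends outside the rendered volume; increase 'margin_um'",
           call. = FALSE)
    sp <- if (!is.null(models[[fid]])) models[[fid]]$spec else
      if (inherits(truth$specs, "fiber_spec")) truth$specs else
        truth$specs[[fid]]
    fib <- .draw_fiber(fib, anc, frame, field,
                       radius_xy_um = sp$width_um / 2,
                       radius_z_um = sp$height_um / 2,
                       voxel_size_um, origin)
  }
  cell <- .rasterize_cell(truth$pattern$cell, dims, voxel_size_um, origin) * 1
  psf_vox <- truth$optics$psf_sigma_um / voxel_size_um
  fib <- .gaussian_blur_3d(fib, psf_vox)
  cell <- .gaussian_blur_3d(cell, pmax(psf_vox, 1 / voxel_size_um))
  nz <- truth$noise
  withr::with_seed(seed, {
    add_noise <- function(img) {
      lam <- nz$background_photons + nz$peak_photons * img
      counts <- stats::rpois(length(lam), lam)
      array(counts + stats::rnorm(length(lam), 0, nz$read_noise_sd),
            dim(img))
    }
    volume_stack(add_noise(fib), add_noise(cell), voxel_size_um, origin)
  })
}
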