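# Reference-free extraction of fiber deflections and cell-fiber contacts
# from multi-channel 3D stacks. All geometry is done in um (world) space so
# anisotropic voxels need no special casing; anchors come from the scaffold
# layout (the walls are rigid and known by fabrication design), so no
# stress-free reference image is ever needed.

# Otsu's threshold on a numeric vector (maximum between-class variance on a
# fixed-bin histogram).
.otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, brk, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-(n_bins + 1L)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * w - mu)^2 / (w * (1 - w))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

# 6-connected component labeling of a logical 3D mask, via the voxel
# adjacency graph.
.label_components_3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (length(idx) == 0L) return(lab)
  map <- integer(prod(d))
  map[idx] <- seq_along(idx)
  ai <- arrayInd(idx, d)
  strides <- c(1L, d[1], d[1] * d[2])
  ee <- list()
  for (dd in 1:3) {
    sel <- ai[, dd] < d[dd]
    nb <- idx[sel] + strides[dd]
    keep <- mask[nb]
    if (any(keep))
      ee[[dd]] <- cbind(map[idx[sel][keep]], map[nb[keep]])
  }
  edges <- do.call(rbind, ee)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# Fill interior cavities: background voxels not 6-connected to the volume
# border become foreground. Works on the mask bounding box (padded by one
# voxel) since cavities cannot extend beyond it.
.fill_holes_3d <- function(mask) {
  d <- dim(mask)
  ai <- arrayInd(which(mask), d)
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  bg <- .label_components_3d(!sub)
  border_labels <- unique(c(bg[c(1, ds[1]), , ], bg[, c(1, ds[2]), ],
                            bg[, , c(1, ds[3])]))
  border_labels <- border_labels[border_labels > 0L]
  sub <- sub | (bg > 0L & !(bg %in% border_labels))
  out <- mask
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}

# Shared foreground detection: background subtraction (median level),
# light Gaussian pre-smoothing, global Otsu threshold.
.channel_foreground <- function(stack, channel, timepoint, smooth_sigma_vox,
                                threshold) {
  v <- .get_channel(stack, channel, timepoint)
  v <- v - stats::median(v)
  v[v < 0] <- 0
  if (smooth_sigma_vox > 0)
    v <- .gaussian_blur_3d(v, rep(smooth_sigma_vox, 3))
  thr <- if (is.null(threshold)) .otsu_threshold(v) else threshold
  structure(v > thr, threshold = thr, max_intensity = max(v))
}

#' Segment the fibers of a stack
#'
#' Background-subtracted (median level), lightly Gaussian-smoothed, Otsu
#' thresholded, 6-connected component labeled; components below a
#' voxel-count floor are discarded. One label per fiber is expected for
#' well-separated scaffolds.
#'
#' @param stack a `volume_stack`.
#' @param timepoint frame to segment.
#' @param min_voxels component size floor.
#' @param smooth_sigma_vox pre-smoothing Gaussian sigma, voxels.
#' @param threshold absolute intensity threshold overriding Otsu.
#' @return integer label array with attributes `threshold` and `n_labels`.
#' @export
segment_fibers <- function(stack, timepoint = 1L, min_voxels = 64L,
                           smooth_sigma_vox = 0.7, threshold = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  fgm <- .channel_foreground(stack, "fiber", timepoint, smooth_sigma_vox,
                             threshold)
  thr <- attr(fgm, "threshold")
  lab <- .label_components_3d(fgm)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0L)
    stop(sprintf(
      "empty fiber segmentation: no component above %d voxels (threshold %.3g, max intensity %.3g)",
      min_voxels, thr, attr(fgm, "max_intensity")), call. = FALSE)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dim(lab))
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  attr(out, "threshold") <- thr
  attr(out, "n_labels") <- length(keep)
  out
}

#' Fiber centerline trace
#'
#' Ordered centerline samples of one segmented fiber in world (um)
#' coordinates, with the layout anchors as first and last samples.
#'
#' @param fiber_id identifier.
#' @param s axial coordinates of the samples (from `anchor_start`), um.
#' @param points m x 3 matrix of world coordinates, um.
#' @param anchor_start,anchor_end wall anchor coordinates, um.
#' @param axis nominal axis label ("x" or "y").
#' @param nominal_length_um layout fiber length (trace span must be within
#'   20%).
#' @return object of class `fiber_trace`.
#' @export
fiber_trace <- function(fiber_id, s, points, anchor_start, anchor_end,
                        axis = "x", nominal_length_um = NULL) {
  if (is.unsorted(s, strictly = TRUE))
    stop("trace samples must be strictly ordered along the axis",
         call. = FALSE)
  if (!is.null(nominal_length_um)) {
    span <- s[length(s)] - s[1]
    if (abs(span - nominal_length_um) > 0.2 * nominal_length_um)
      stop(sprintf("trace span %.1f um deviates more than 20%% from the nominal %.1f um",
                   span, nominal_length_um), call. = FALSE)
  }
  structure(list(fiber_id = fiber_id, s = s, points = points,
                 anchor_start = anchor_start, anchor_end = anchor_end,
                 axis = axis, nominal_length_um = nominal_length_um),
            class = "fiber_trace")
}

#' Extract the centerline of one labeled fiber
#'
#' Walks one-voxel slabs along the fiber's nominal axis; in each slab the
#' intensity-weighted centroid of in-label voxels gives one centerline
#' sample. Runs of up to `max_gap` empty slabs are linearly interpolated;
#' more than 20% missing slabs aborts (badly segmented fiber). The wall
#' anchors from the layout are prepended/appended as the terminal samples.
#'
#' @param stack a `volume_stack` (intensities for the weighting).
#' @param labels label array from [segment_fibers()].
#' @param label_id which label to trace.
#' @param layout a `scaffold_layout`.
#' @param fiber_id the layout fiber this label is traced against (anchors
#'   and nominal axis).
#' @param timepoint frame.
#' @param max_gap largest interpolatable run of empty slabs.
#' @return a `fiber_trace`.
#' @export
extract_centerline <- function(stack, labels, label_id, layout, fiber_id,
                               timepoint = 1L, max_gap = 3L) {
  stopifnot(inherits(stack, "volume_stack"))
  idx <- which(labels == label_id)
  if (length(idx) == 0L)
    stop("label ", label_id, " not present in the segmentation",
         call. = FALSE)
  anc <- .layout_anchors(layout, fiber_id)
  row <- layout[layout$fiber_id == fiber_id, ]
  ax_dim <- if (row$axis == "x") 1L else 2L
  v <- .get_channel(stack, "fiber", timepoint)
  d <- dim(v)
  ai <- arrayInd(idx, d)
  w <- v[idx] - min(v[idx])
  w <- w + 1e-9
  vox <- stack$voxel_size_um; org <- stack$origin_um
  slab <- ai[, ax_dim]
  # weighted centroids per slab, in voxel-index space
  sums_w <- rowsum(w, slab)
  cx <- rowsum(w * ai[, 1], slab) / sums_w
  cy <- rowsum(w * ai[, 2], slab) / sums_w
  cz <- rowsum(w * ai[, 3], slab) / sums_w
  slabs <- as.integer(rownames(sums_w))
  full <- seq(min(slabs), max(slabs))
  missing <- setdiff(full, slabs)
  if (length(missing) / length(full) > 0.2)
    stop(sprintf("fiber %s badly segmented: %.0f%% of slabs empty",
                 fiber_id, 100 * length(missing) / length(full)),
         call. = FALSE)
  if (length(missing) > 0L) {
    runs <- rle(diff(slabs))
    if (any(runs$values > max_gap + 1L))
      stop(sprintf("fiber %s has a gap wider than %d slabs", fiber_id,
                   max_gap), call. = FALSE)
  }
  interp <- function(vals) stats::approx(slabs, vals, xout = full)$y
  P <- cbind((interp(cx) - 0.5) * vox[1] + org[1],
             (interp(cy) - 0.5) * vox[2] + org[2],
             (interp(cz) - 0.5) * vox[3] + org[3])
  frame <- .fiber_frame(anc$start, anc$end)
  s <- as.numeric((P - rep(anc$start, each = nrow(P))) %*% frame$u)
  o <- order(s)
  s <- s[o]; P <- P[o, , drop = FALSE]
  # clip to the span and attach the anchors as terminal samples
  keep <- s > 1e-6 & s < frame$length - 1e-6
  s <- c(0, s[keep], frame$length)
  P <- rbind(anc$start, P[keep, , drop = FALSE], anc$end)
  fiber_trace(fiber_id, s, P, anc$start, anc$end, axis = row$axis,
              nominal_length_um = row$length_um)
}

# Reassign segmented foreground voxels to layout fibers by nearest nominal
# line (transverse distance in um). Robust to components that merge when
# strongly deflected neighbors approach each other; unambiguous as long as
# deflections stay below about half the fiber spacing. Returns an integer
# array whose label i is the i-th layout fiber.
.assign_voxels_to_fibers <- function(stack, labels, layout,
                                     max_offset_um = 6) {
  d <- dim(labels)
  vox <- stack$voxel_size_um; org <- stack$origin_um
  fg <- which(labels > 0L)
  ai <- arrayInd(fg, d)
  W <- cbind((ai[, 1] - 0.5) * vox[1] + org[1],
             (ai[, 2] - 0.5) * vox[2] + org[2],
             (ai[, 3] - 0.5) * vox[3] + org[3])
  best_d2 <- rep(Inf, length(fg)); best_i <- integer(length(fg))
  for (i in seq_len(nrow(layout))) {
    if (layout$axis[i] == "x") {
      d2 <- (W[, 2] - layout$y0[i])^2 + (W[, 3] - layout$z0[i])^2
    } else {
      d2 <- (W[, 1] - layout$x0[i])^2 + (W[, 3] - layout$z0[i])^2
    }
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_i[upd] <- i
  }
  keep <- best_d2 <= max_offset_um^2
  out <- array(0L, d)
  out[fg[keep]] <- best_i[keep]
  out
}

#' Trace every fiber of a frame
#'
#' Segments the fiber channel, assigns foreground voxels to layout fibers
#' by nearest nominal line (which stays unambiguous even when deflected
#' neighbors touch and their connected components merge), and extracts all
#' centerlines.
#'
#' @param stack a `volume_stack`.
#' @param layout a `scaffold_layout`.
#' @param timepoint frame.
#' @param labels optional precomputed label array from [segment_fibers()].
#' @param max_offset_um largest transverse distance from a nominal fiber
#'   line at which a voxel is still attributed to that fiber.
#' @param min_voxels fibers with fewer assigned voxels are reported
#'   missing.
#' @param smooth_sigma_vox,threshold foreground detection controls, as in
#'   [segment_fibers()].
#' @return named list of `fiber_trace` (names = layout fiber ids).
#' @export
trace_fibers <- function(stack, layout, timepoint = 1L, labels = NULL,
                         max_offset_um = 6, min_voxels = 64L,
                         smooth_sigma_vox = 0.7, threshold = NULL) {
  if (is.null(labels)) {
    fgm <- .channel_foreground(stack, "fiber", timepoint, smooth_sigma_vox,
                               threshold)
    labels <- array(0L, dim(fgm)); labels[fgm] <- 1L
  }
  assign <- .assign_voxels_to_fibers(stack, labels, layout, max_offset_um)
  counts <- tabulate(assign[assign > 0L], nbins = nrow(layout))
  missing <- layout$fiber_id[counts < min_voxels]
  if (length(missing) > 0L)
    stop("fibers not found in the segmentation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  traces <- list()
  for (i in seq_len(nrow(layout))) {
    traces[[layout$fiber_id[i]]] <-
      extract_centerline(stack, assign, i, layout, layout$fiber_id[i],
                         timepoint)
  }
  traces
}

#' Track fiber identities over time
#'
#' Assigns every trace of every timepoint to its nearest layout fiber by
#' anchor distance and checks the assignment is injective per timepoint,
#' so identities persist across frames.
#'
#' @param traces_by_time list over timepoints; each element a list of
#'   `fiber_trace`.
#' @param layout a `scaffold_layout`.
#' @return list over timepoints of named trace lists (names = stable fiber
#'   ids).
#' @export
track_fibers <- function(traces_by_time, layout) {
  if (length(traces_by_time) < 1L) stop("need at least one timepoint",
                                        call. = FALSE)
  lapply(traces_by_time, function(traces) {
    ids <- vapply(traces, function(tr) {
      da <- vapply(seq_len(nrow(layout)), function(i) {
        a <- c(layout$x0[i], layout$y0[i], layout$z0[i])
        b <- c(layout$x1[i], layout$y1[i], layout$z1[i])
        min(sqrt(sum((tr$anchor_start - a)^2)) +
              sqrt(sum((tr$anchor_end - b)^2)),
            sqrt(sum((tr$anchor_start - b)^2)) +
              sqrt(sum((tr$anchor_end - a)^2)))
      }, numeric(1))
      layout$fiber_id[which.min(da)]
    }, character(1))
    if (anyDuplicated(ids))
      stop("two traces map to one layout fiber within a timepoint",
           call. = FALSE)
    names(traces) <- ids
    traces
  })
}

#' Deflection field of a traced fiber
#'
#' The reference-free deflection measurement: signed perpendicular offsets
#' of each centerline sample from the chord joining the two anchors,
#' decomposed into the in-plane (y) and vertical (z) transverse directions
#' and linearly interpolated onto the model's node positions. Translating
#' the whole trace together with its anchors leaves the field unchanged.
#'
#' @param trace a `fiber_trace`.
#' @param model a `beam_model` (its nodes receive the field).
#' @return a `deflection_field`.
#' @export
compute_deflection <- function(trace, model) {
  stopifnot(inherits(trace, "fiber_trace"), inherits(model, "beam_model"))
  frame <- .fiber_frame(trace$anchor_start, trace$anchor_end)
  V <- trace$points - rep(trace$anchor_start, each = nrow(trace$points))
  s <- as.numeric(V %*% frame$u)
  off <- V - outer(s, frame$u)
  dy_s <- as.numeric(off %*% frame$ey)
  dz_s <- as.numeric(off %*% frame$ez)
  nodes <- model$nodes_um
  dy <- stats::approx(s, dy_s, xout = nodes, rule = 2)$y
  dz <- stats::approx(s, dz_s, xout = nodes, rule = 2)$y
  n <- length(nodes)
  dy[c(1, n)] <- 0; dz[c(1, n)] <- 0
  deflection_field(dy, dz, nodes)
}

#' Segment the cell volume
#'
#' Otsu threshold on the (smoothed, background-subtracted) cell channel,
#' keep the largest connected component, fill interior holes.
#'
#' @param stack a `volume_stack`.
#' @param timepoint frame.
#' @param smooth_sigma_vox pre-smoothing sigma, voxels.
#' @param threshold absolute override of the Otsu threshold.
#' @return logical mask array with attributes `voxel_size_um`, `origin_um`.
#' @export
segment_cell <- function(stack, timepoint = 1L, smooth_sigma_vox = 1,
                         threshold = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  fgm <- .channel_foreground(stack, "cell", timepoint, smooth_sigma_vox,
                             threshold)
  lab <- .label_components_3d(fgm)
  if (max(lab) == 0L)
    stop("empty cell segmentation", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- .fill_holes_3d(mask)
  attr(mask, "voxel_size_um") <- stack$voxel_size_um
  attr(mask, "origin_um") <- stack$origin_um
  mask
}

#' Contact nodes of a fiber with the cell mask
#'
#' A mesh node is cell-contacted when its (deformed) centerline position
#' lies inside a mask voxel or within `reach_um` of a mask voxel center.
#' Clamped end nodes are excluded. An empty result is allowed; downstream
#' force recovery then refuses to run.
#'
#' @param mask logical volume from [segment_cell()] (carries voxel size and
#'   origin attributes).
#' @param trace the fiber's `fiber_trace`.
#' @param model the fiber's `beam_model`.
#' @param reach_um contact reach in um (default 0.5, about one in-plane
#'   resolution element).
#' @return sorted integer vector of interior node indices.
#' @export
contact_nodes <- function(mask, trace, model, reach_um = 0.5) {
  if (reach_um < 0) stop("'reach_um' must be >= 0", call. = FALSE)
  vox <- attr(mask, "voxel_size_um"); org <- attr(mask, "origin_um")
  if (is.null(vox) || is.null(org))
    stop("mask lacks voxel geometry attributes; use segment_cell()",
         call. = FALSE)
  frame <- .fiber_frame(trace$anchor_start, trace$anchor_end)
  field <- compute_deflection(trace, model)
  nodes <- model$nodes_um
  P <- rep(trace$anchor_start, each = length(nodes)) +
       outer(nodes, frame$u) + outer(field$dy, frame$ey) +
       outer(field$dz, frame$ez)
  d <- dim(mask)
  hits <- logical(length(nodes))
  half <- pmax(ceiling(reach_um / vox), 1L)
  for (i in 2:(length(nodes) - 1L)) {
    iv <- floor((P[i, ] - org) / vox) + 1L
    if (all(iv >= 1L & iv <= d) && mask[iv[1], iv[2], iv[3]]) {
      hits[i] <- TRUE
      next
    }
    jx <- max(1L, iv[1] - half[1]):min(d[1], iv[1] + half[1])
    jy <- max(1L, iv[2] - half[2]):min(d[2], iv[2] + half[2])
    jz <- max(1L, iv[3] - half[3]):min(d[3], iv[3] + half[3])
    if (length(jx) < 1L || length(jy) < 1L || length(jz) < 1L) next
    sub <- mask[jx, jy, jz, drop = FALSE]
    if (!any(sub)) next
    mi <- which(sub, arr.ind = TRUE)
    W <- cbind((jx[mi[, 1]] - 0.5) * vox[1] + org[1],
               (jy[mi[, 2]] - 0.5) * vox[2] + org[2],
               (jz[mi[, 3]] - 0.5) * vox[3] + org[3])
    dist2 <- rowSums((W - rep(P[i, ], each = nrow(W)))^2)
    if (min(dist2) <= reach_um^2) hits[i] <- TRUE
  }
  which(hits)
}

#' Voxelized deflection magnitude map
#'
#' Renders |dy| + |dz| (the summed transverse components) along every
#' fiber with a deflection field into a scalar volume; each fiber voxel
#' carries the value of the nearest mesh node.
#'
#' @param fields named list of `deflection_field` (names = fiber ids).
#' @param layout a `scaffold_layout`.
#' @param dims volume dimensions (voxels).
#' @param voxel_size_um,origin_um voxel geometry.
#' @return numeric array of `dims`.
#' @export
deflection_map <- function(fields, layout, dims, voxel_size_um,
                           origin_um = c(0, 0, 0)) {
  out <- array(0, dims)
  step <- min(voxel_size_um) / 2
  for (fid in names(fields)) {
    f <- fields[[fid]]
    anc <- .layout_anchors(layout, fid)
    frame <- .fiber_frame(anc$start, anc$end)
    s <- seq(0, frame$length, by = step)
    node_val <- abs(f$dy) + abs(f$dz)
    nearest <- findInterval(s, f$positions_um +
                              c(diff(f$positions_um) / 2, Inf)) + 1L
    dy <- stats::approx(f$positions_um, f$dy, xout = s, rule = 2)$y
    dz <- stats::approx(f$positions_um, f$dz, xout = s, rule = 2)$y
    P <- rep(anc$start, each = length(s)) + outer(s, frame$u) +
         outer(dy, frame$ey) + outer(dz, frame$ez)
    iv <- sweep(sweep(P, 2, origin_um), 2, voxel_size_um, "/")
    iv <- floor(iv) + 1L
    ok <- iv[, 1] >= 1 & iv[, 1] <= dims[1] &
          iv[, 2] >= 1 & iv[, 2] <= dims[2] &
          iv[, 3] >= 1 & iv[, 3] <= dims[3]
    lin <- iv[ok, 1] + (iv[ok, 2] - 1) * dims[1] +
           (iv[ok, 3] - 1) * dims[1] * dims[2]
    # max-aggregate: ascending writes make the largest value win when
    # several samples land in one voxel
    vals <- pmax(node_val[nearest[ok]], out[lin])
    o <- order(vals)
    out[lin[o]] <- vals[o]
  }
  out
}
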