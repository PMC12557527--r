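# Segmentation, centerline extraction, deflection computation, cell masks
# and contact detection, exercised on rendered phantoms.

test_that("fiber segmentation finds one component per fiber", {
  st <- straight_phantom()$stack
  lab <- segment_fibers(st)
  expect_equal(attr(lab, "n_labels"), 8L)   # 4 + 4 fibers, 30 um span

  blank <- volume_stack(array(0, c(20, 20, 8)), array(0, c(20, 20, 8)),
                        c(0.3, 0.3, 1))
  expect_error(segment_fibers(blank), "empty fiber segmentation")
})

test_that("segmented components split into two orthogonal axis groups", {
  st <- straight_phantom()$stack
  lab <- segment_fibers(st)
  d <- dim(lab)
  axes <- vapply(seq_len(attr(lab, "n_labels")), function(l) {
    ai <- arrayInd(which(lab == l), d)
    ext <- apply(ai, 2, function(x) diff(range(x)))
    if (ext[1] >= ext[2]) "x" else "y"
  }, character(1))
  expect_equal(sort(as.integer(table(axes))), c(4L, 4L))
})

test_that("centerlines of straight fibers are straight to sub-voxel RMS", {
  st <- straight_phantom()
  lab <- segment_fibers(st$stack)
  lay <- st$truth$layout
  tr <- trace_fibers(st$stack, lay, labels = lab)
  for (fid in c("L1F02", "L2F03")) {
    row <- lay[lay$fiber_id == fid, ]
    # perpendicular residual from the true straight line
    if (row$axis == "x") {
      res <- sqrt((tr[[fid]]$points[, 2] - row$y0)^2 +
                    (tr[[fid]]$points[, 3] - row$z0)^2)
    } else {
      res <- sqrt((tr[[fid]]$points[, 1] - row$x0)^2 +
                    (tr[[fid]]$points[, 3] - row$z0)^2)
    }
    expect_lt(sqrt(mean(res^2)), 0.15)
  }
  expect_error(extract_centerline(st$stack, lab, 99L, lay, "L1F01"),
               "not present")
})

test_that("a known midpoint deflection is recovered within the in-plane resolution", {
  lay <- make_layout("two-layer", 30, 10)
  sp <- spec_600(30)
  m <- build_beam_model(sp, 32)
  mid <- 17L
  Fz <- 2 * unname(apparent_stiffness(m, 15)["y"])
  fields <- forward_deform(lay, sp,
                           list(L1F02 = list(node = mid, fy = Fz, fz = 0)),
                           n_elements = 32)
  expect_equal(fields$L1F02$dy[mid], 2, tolerance = 1e-9)
  truth <- phantom_truth(lay, sp,
                         sample_force_pattern(lay, c(15, 10, 0),
                                              c(6, 6, 5), seed = 2,
                                              n_elements = 32),
                         fields, seed = 2)
  st <- render_stack(truth)
  tr <- trace_fibers(st, lay)
  d <- compute_deflection(tr$L1F02, m)
  expect_equal(d$dy[mid], 2, tolerance = 0.15)  # 0.3 um bound, absolute
  expect_lt(max(abs(d$dz)), 0.5)
})

test_that("identity tracking is stable over repeated frames and rejects duplicates", {
  st <- straight_phantom()
  lay <- st$truth$layout
  tr <- trace_fibers(st$stack, lay)
  frames <- track_fibers(list(tr, tr, tr), lay)
  expect_equal(names(frames[[1]]), names(frames[[3]]))
  dup <- c(tr, tr[1])
  expect_error(track_fibers(list(dup), lay), "one layout fiber")
})

test_that("deflection computation is reference-free and sign-correct", {
  m <- build_beam_model(spec_600(30), 32)
  s <- seq(0, 30, length.out = 41)
  straight <- cbind(s, rep(10, 41), rep(0, 41))
  tr0 <- fiber_trace("f", s, straight, c(0, 10, 0), c(30, 10, 0),
                     nominal_length_um = 30)
  d0 <- compute_deflection(tr0, m)
  expect_equal(max(abs(c(d0$dy, d0$dz))), 0)

  # rigid translation of trace plus anchors changes nothing
  off <- c(2.5, -1.25, 3)
  trT <- fiber_trace("f", s, sweep(straight, 2, -off), c(0, 10, 0) + off,
                     c(30, 10, 0) + off, nominal_length_um = 30)
  dT <- compute_deflection(trT, m)
  expect_lt(max(abs(c(dT$dy - d0$dy, dT$dz - d0$dz))), 1e-9)

  # a 1.5 um mid-span vertical bump appears in z only
  bump <- straight
  bump[, 3] <- 1.5 * sin(pi * s / 30)^2
  trB <- fiber_trace("f", s, bump, c(0, 10, 0), c(30, 10, 0),
                     nominal_length_um = 30)
  dB <- compute_deflection(trB, m)
  expect_equal(max(dB$dz), 1.5, tolerance = 1e-6)
  expect_equal(max(abs(dB$dy)), 0)
  expect_error(fiber_trace("f", s, straight, c(0, 10, 0), c(0, 10, 0)) |>
                 compute_deflection(m), "coincident")
})

test_that("cell segmentation recovers the ellipsoid and keeps the larger blob", {
  sm <- small_phantom()
  mask <- segment_cell(sm$stack)
  vox <- prod(sm$stack$voxel_size_um)
  truth_vol <- 4 / 3 * pi * prod(sm$truth$pattern$cell$radii_um)
  expect_equal(sum(mask) * vox, truth_vol, tolerance = 0.15)

  blank <- volume_stack(array(0, c(20, 20, 8)), array(0, c(20, 20, 8)),
                        c(0.3, 0.3, 1))
  expect_error(segment_cell(blank), "empty cell segmentation")

  two <- array(0, c(40, 40, 10))
  two[5:10, 5:10, 3:5] <- 10       # 108 voxels
  two[20:35, 20:35, 3:8] <- 10     # 1536 voxels
  stk <- volume_stack(array(0, dim(two)), two, c(0.5, 0.5, 1))
  mk <- segment_cell(stk, smooth_sigma_vox = 0)
  ai <- arrayInd(which(mk), dim(mk))
  expect_true(all(ai[, 1] >= 18))   # only the larger blob survives
})

test_that("contact nodes form a contiguous run under the cell and reach works", {
  sm <- small_phantom()
  lay <- sm$truth$layout
  m <- build_beam_model(spec_600(30), 32)
  mask <- segment_cell(sm$stack)
  tr <- trace_fibers(sm$stack, lay)
  fid <- names(sm$truth$pattern$contacts)[1]
  cn <- contact_nodes(mask, tr[[fid]], m, reach_um = 0.5)
  expect_gt(length(cn), 0)
  expect_true(all(diff(cn) == 1))                  # contiguous
  expect_true(all(cn > 1 & cn < m$n_nodes))        # interior only
  mid <- (m$n_nodes + 1) / 2
  expect_lt(abs(mean(cn) - mid), 6)                # centered near midpoint
  # zero reach keeps only nodes whose own voxel is masked
  cn0 <- contact_nodes(mask, tr[[fid]], m, reach_um = 0)
  expect_true(all(cn0 %in% cn))
  # a mask far from every fiber yields the empty set
  far <- array(FALSE, dim(mask))
  far[1:3, 1:3, 1:2] <- TRUE
  attr(far, "voxel_size_um") <- attr(mask, "voxel_size_um")
  attr(far, "origin_um") <- attr(mask, "origin_um")
  expect_length(contact_nodes(far, tr[[fid]], m), 0)
})

test_that("deflection maps carry the summed components along fibers only", {
  lay <- make_layout("two-layer", 30, 10)
  m <- build_beam_model(spec_600(30), 32)
  zero <- deflection_field(numeric(33), numeric(33), m$nodes_um)
  dims <- c(40, 40, 14)
  mp0 <- deflection_map(list(L1F02 = zero), lay, dims, c(1, 1, 1),
                        c(-5, -5, -2))
  expect_equal(max(mp0), 0)

  f <- solve_forward(m, force_field(m, 17L, 1.2, -0.8))
  mp <- deflection_map(list(L1F02 = f), lay, dims, c(1, 1, 1), c(-5, -5, -2))
  expect_equal(max(mp), max(abs(f$dy) + abs(f$dz)), tolerance = 1e-9)
  # nonzero voxels hug the fiber line (y = 10, z = 0 -> voxel y 15-16, z 2-3)
  nz <- arrayInd(which(mp > 0), dims)
  expect_true(all(abs(nz[, 2] - 15.5) <= 3))
  expect_true(all(abs(nz[, 3] - 2.5) <= 3))
})
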