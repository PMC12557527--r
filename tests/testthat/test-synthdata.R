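# Scaffold layouts, force patterns, forward deformation, noise injection
# and stack rendering.

test_that("two-layer layouts have orthogonal layers at the right pitch", {
  lay <- make_layout("two-layer", length_um = 80, spacing_um = 10)
  expect_equal(sort(unique(lay$layer)), c(1, 2))
  expect_equal(sum(lay$layer == 1), floor(80 / 10) + 1)
  expect_equal(sum(lay$layer == 2), floor(80 / 10) + 1)
  expect_true(all(lay$axis[lay$layer == 1] == "x"))
  expect_true(all(lay$axis[lay$layer == 2] == "y"))
  expect_equal(unique(lay$z0[lay$layer == 2]) -
                 unique(lay$z0[lay$layer == 1]), 10)
  expect_equal(diff(sort(lay$y0[lay$layer == 1])),
               rep(10, floor(80 / 10)))
  expect_error(make_layout("two-layer", 80, 4), "fabrication limit")
})

test_that("gradient layouts stagger four layers across density regions", {
  lay <- make_layout("gradient", length_um = 180)
  expect_equal(sort(unique(lay$z0)), c(0, 5, 10, 15))
  expect_equal(length(unique(lay$layer)), 4L)
  # region spacings within the first layer
  y1 <- sort(lay$y0[lay$layer == 1])
  expect_true(all(abs(diff(y1[y1 < 60])) == 15))
  expect_true(all(abs(diff(y1[y1 >= 60 & y1 < 119])) == 10))
  expect_true(all(abs(diff(y1[y1 >= 120])) == 5))
  # successive layers shifted by half the local spacing
  y2 <- sort(lay$y0[lay$layer == 2])
  expect_true(min(y2) == 7.5)
  expect_error(make_layout("gradient", 180,
                           region_spacings_um = c(15, 10, 3)),
               "fabrication limit")
})

test_that("layout serialization is deterministic and round-trips", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_layout_json(make_layout("two-layer", 80, 10), f1)
  write_layout_json(make_layout("two-layer", 80, 10), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_layout_json(f1)
  expect_equal(as.data.frame(back),
               as.data.frame(make_layout("two-layer", 80, 10)))
})

test_that("force patterns are reproducible and scale with magnitude", {
  lay <- make_layout("two-layer", 80, 10)
  p1 <- sample_force_pattern(lay, c(40, 40, 5), c(15, 15, 9), seed = 9)
  p2 <- sample_force_pattern(lay, c(40, 40, 5), c(15, 15, 9), seed = 9)
  expect_identical(p1$forces, p2$forces)
  # >= 2 fibers contacted per layer for a 15 um cell on 10 um spacing
  layers <- lay$layer[match(names(p1$contacts), lay$fiber_id)]
  expect_gte(sum(layers == 1), 2)
  expect_gte(sum(layers == 2), 2)
  # contractility ratio across a 10x magnitude change, over replicates
  ratios <- vapply(1:20, function(r) {
    lo <- sample_force_pattern(lay, c(40, 40, 5), c(15, 15, 9),
                               magnitude_nN = 0.5, seed = 100 + r)
    hi <- sample_force_pattern(lay, c(40, 40, 5), c(15, 15, 9),
                               magnitude_nN = 5, seed = 300 + r)
    tot <- function(p) sum(unlist(lapply(p$forces, function(f)
      sqrt(f$fy^2 + f$fz^2))))
    tot(hi) / tot(lo)
  }, numeric(1))
  expect_equal(mean(ratios), 10, tolerance = 0.1)
  expect_error(
    sample_force_pattern(lay, c(500, 500, 500), c(5, 5, 5), seed = 1),
    "touches no fiber")
})

test_that("forward deformation is exact, linear and validates fiber ids", {
  lay <- make_layout("two-layer", 80, 10)
  sp <- spec_600()
  zero <- forward_deform(lay, sp,
                         list(L1F05 = list(node = 33L, fy = 0, fz = 0)))
  expect_equal(max(abs(c(zero$L1F05$dy, zero$L1F05$dz))), 0)

  f1 <- forward_deform(lay, sp,
                       list(L1F05 = list(node = 33L, fy = 1, fz = 2)))
  f2 <- forward_deform(lay, sp,
                       list(L1F05 = list(node = 33L, fy = 2, fz = 4)))
  expect_equal(f2$L1F05$dy, 2 * f1$L1F05$dy, tolerance = 1e-12)
  expect_equal(f2$L1F05$dz, 2 * f1$L1F05$dz, tolerance = 1e-12)

  # a fiber calibrated to 3.55 nN/um deflects 1.00 um under 3.55 nN
  Tc <- calibrate_tension(3.55, 80, 11.32, sp$I_lateral_um4,
                          mode = "corrected")
  spc <- fiber_spec(80, sp$width_um, sp$height_um, 11.32, Tc)
  cal <- forward_deform(lay, spc,
                        list(L1F05 = list(node = 33L, fy = 0, fz = 3.55)))
  expect_equal(cal$L1F05$dz[33], 1, tolerance = 1e-4)

  expect_error(forward_deform(lay, sp,
                              list(NOPE = list(node = 3L, fy = 1, fz = 0))),
               "unknown fiber")
})

test_that("deflection noise has the requested per-axis scale", {
  n_nodes <- 10002L
  pos <- seq(0, 80, length.out = n_nodes)
  base <- sin(pi * pos / 80)
  base[c(1, n_nodes)] <- 0
  clean <- deflection_field(base, 0.5 * base, pos)
  same <- perturb_deflections(clean, 0, 0, seed = 3)
  expect_identical(same$dy, clean$dy)
  n1 <- perturb_deflections(clean, 0.3, 1, seed = 3)
  n2 <- perturb_deflections(clean, 0.3, 1, seed = 3)
  expect_identical(n1$dy, n2$dy)
  int <- 2:(n_nodes - 1L)
  expect_equal(sd(n1$dy[int] - clean$dy[int]), 0.3, tolerance = 0.03)
  expect_equal(sd(n1$dz[int] - clean$dz[int]), 1, tolerance = 0.03)
  expect_equal(n1$dy[c(1, n_nodes)], c(0, 0))
})

test_that("rendering is seeded and centers tubes on the true lines", {
  ph <- small_phantom()$truth
  s1 <- render_stack(ph, seed = 77)
  s2 <- render_stack(ph, seed = 77)
  expect_identical(s1$fiber, s2$fiber)
  expect_identical(s1$cell, s2$cell)

  # near-zero noise, near-delta PSF: the intensity ridge sits on the true
  # centerline to within half a voxel
  st <- straight_phantom()
  ph0 <- st$truth
  ph0$optics$psf_sigma_um <- c(0.01, 0.01, 0.01)
  ph0$noise <- list(peak_photons = 1e5, background_photons = 0,
                    read_noise_sd = 0)
  clean <- render_stack(ph0, seed = 1)
  lay <- ph0$layout
  row <- lay[lay$fiber_id == "L1F02", ]
  iy_true <- (row$y0 - clean$origin_um[2]) / clean$voxel_size_um[2] + 0.5
  iz_true <- (row$z0 - clean$origin_um[3]) / clean$voxel_size_um[3] + 0.5
  mid_ix <- round(dim(clean$fiber)[1] / 2)
  # restrict to a window around this fiber: the cross-section holds the
  # parallel neighbors too
  jy <- round(iy_true) + (-8:8); jz <- round(iz_true) + (-3:3)
  sl <- clean$fiber[mid_ix, jy, jz, 1]
  peak <- which(sl == max(sl), arr.ind = TRUE)[1, ]
  expect_lt(abs(jy[peak[1]] - iy_true), 1)
  expect_lt(abs(jz[peak[2]] - iz_true), 1)
})
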