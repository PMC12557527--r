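# Elastic-net force recovery: influence matrix, loss, solver properties,
# regularization selection.

test_that("influence matrix columns equal unit-load forward solves", {
  m <- model_600()
  contacts <- c(20L, 33L, 44L)
  G <- influence_matrix(m, contacts)
  int <- 2:(m$n_nodes - 1L)
  ni <- length(int)
  for (j in seq_along(contacts)) {
    dy <- solve_forward(m, force_field(m, contacts[j], 1, 0))$dy[int]
    dz <- solve_forward(m, force_field(m, contacts[j], 0, 1))$dz[int]
    expect_identical(G[seq_len(ni), j], dy)
    expect_identical(G[ni + seq_len(ni), length(contacts) + j], dz)
  }
  # plane decoupling: zero cross blocks
  expect_equal(max(abs(G[seq_len(ni), length(contacts) + seq_along(contacts)])), 0)
  expect_equal(max(abs(G[ni + seq_len(ni), seq_along(contacts)])), 0)
  # reciprocity of the square restriction to contact rows
  wrow <- match(contacts, int)
  Gyy <- G[wrow, seq_along(contacts)]
  expect_lt(max(abs(Gyy - t(Gyy))) / max(abs(Gyy)), 1e-9)
  expect_error(influence_matrix(m, integer(0)), "empty contact set")
})

test_that("loss implements the printed objective", {
  m2 <- build_beam_model(spec_600(2), 2)   # single interior node
  pos <- m2$nodes_um
  data <- deflection_field(c(0, 2, 0), c(0, 0, 0), pos)
  G <- diag(2)                              # 1 um/nN per component
  expect_equal(recovery_loss(c(1, 0), data, G, reg_params(0, 0), m2), 1)
  # p = 0: sum of absolute measured deflections
  expect_equal(recovery_loss(c(0, 0), data, G, reg_params(0, 0), m2), 2)
  zero <- deflection_field(c(0, 0, 0), c(0, 0, 0), pos)
  expect_equal(recovery_loss(c(0, 0), zero, G, reg_params(0, 0), m2), 0)
  # penalties: lambda1 * sum|p| + lambda2 * sum p^2
  expect_equal(recovery_loss(c(1, -2), zero, G, reg_params(0.5, 0.25), m2),
               (1 + 2) + 0.5 * 3 + 0.25 * 5)
  expect_error(recovery_loss(c(1, 2, 3), data, G, reg_params(), m2),
               "does not match")
})

test_that("noiseless unregularized recovery is exact", {
  m <- model_600()
  contacts <- c(25L, 33L, 40L)
  truth <- force_field(m, contacts, c(3, -2, 1.5), c(1, 4, -2))
  clean <- solve_forward(m, truth)
  rec <- recover_forces(clean, m, contacts, reg_params(0, 0), seed = 3)
  expect_lt(max(abs(rec$fy - truth$fy), abs(rec$fz - truth$fz)) /
              max(abs(c(truth$fy, truth$fz))), 1e-4)
  expect_true(attr(rec, "converged"))
  expect_lte(attr(rec, "loss"),
             recovery_loss(rep(0, 6), clean,
                           influence_matrix(m, contacts),
                           reg_params(0, 0), m))
})

test_that("solution is seed-independent (convexity) and shrinks to zero", {
  m <- model_600()
  contacts <- c(25L, 40L)
  truth <- force_field(m, contacts, c(2, -1), c(1.5, 2))
  noisy <- perturb_deflections(solve_forward(m, truth), 0.3, 1, seed = 8)
  r1 <- recover_forces(noisy, m, contacts, reg_params(0.01, 0.01), seed = 1)
  r2 <- recover_forces(noisy, m, contacts, reg_params(0.01, 0.01),
                       seed = 424242)
  scale <- max(abs(c(r1$fy, r1$fz)))
  expect_lt(max(abs(r1$fy - r2$fy), abs(r1$fz - r2$fz)) / scale, 1e-4)

  # zero data with a sparsity penalty returns the zero field
  zero <- deflection_field(numeric(m$n_nodes), numeric(m$n_nodes),
                           m$nodes_um)
  r0 <- recover_forces(zero, m, contacts, reg_params(0.5, 0), seed = 5)
  expect_lt(max(abs(c(r0$fy, r0$fz))), 1e-3)
})

test_that("recovered L1 norm is non-increasing in lambda1", {
  m <- model_600()
  contacts <- c(22L, 33L, 45L)
  truth <- force_field(m, contacts, c(2, 3, -1), c(-2, 1, 2))
  noisy <- perturb_deflections(solve_forward(m, truth), 0.3, 1, seed = 17)
  ladder <- c(0, 0.01, 0.1, 1, 10)
  l1 <- vapply(ladder, function(lam) {
    r <- suppressWarnings(
      recover_forces(noisy, m, contacts, reg_params(lam, 0), seed = 2))
    sum(abs(c(r$fy, r$fz)))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("production solver agrees with the exhaustive grid-search oracle", {
  m <- model_600()
  # wide contact spacing and a substantive ridge keep the minimizer
  # well-conditioned, so positions (not just losses) are comparable
  for (contacts in list(33L, c(21L, 45L))) {
    mC <- length(contacts)
    set.seed(50 + mC)
    truth <- force_field(m, contacts, runif(mC, -3, 3), runif(mC, -3, 3))
    noisy <- perturb_deflections(solve_forward(m, truth), 0.3, 1,
                                 seed = 60 + mC)
    reg <- reg_params(0.05, 0.5)
    p_solver <- recover_forces(noisy, m, contacts, reg, seed = 1)
    p_oracle <- oracle_grid_search(noisy, m, contacts, reg)
    expect_lt(max(abs(c(p_solver$fy[contacts], p_solver$fz[contacts]) -
                      p_oracle)), 0.01 + 1e-9)
  }
})

test_that("regularization selection prefers zero penalty on clean data and is reproducible", {
  m <- build_beam_model(spec_600(), 32)
  contacts <- c(12L, 20L)
  grid <- expand.grid(lambda1 = c(0, 0.01, 0.1), lambda2 = c(0, 0.01))
  sel <- select_regularization(m, contacts, grid,
                               pattern = list(magnitude_nN = 2, sdlog = 0.3),
                               noise = list(sigma_xy_um = 0, sigma_z_um = 0),
                               n_rep = 4, seed = 5)
  expect_equal(sel$best$lambda1, 0)
  expect_equal(sel$best$lambda2, 0)
  expect_lt(sel$table$mean_error[sel$table$lambda1 == 0 &
                                 sel$table$lambda2 == 0], 1e-4)

  sel2 <- select_regularization(m, contacts, grid,
                                pattern = list(magnitude_nN = 2, sdlog = 0.3),
                                noise = list(sigma_xy_um = 0, sigma_z_um = 0),
                                n_rep = 4, seed = 5)
  expect_identical(sel$table, sel2$table)

  expect_error(
    select_regularization(m, contacts,
                          pattern = list(magnitude_nN = 0), n_rep = 2),
    "degenerate")
})

test_that("overwhelming noise selects a strictly positive sparsity weight", {
  m <- build_beam_model(spec_600(), 32)
  grid <- data.frame(lambda1 = c(0, 1), lambda2 = 0)
  sel <- select_regularization(m, 16L, grid,
                               pattern = list(magnitude_nN = 0.05,
                                              sdlog = 0.2),
                               noise = list(sigma_xy_um = 2, sigma_z_um = 4),
                               n_rep = 20, seed = 3)
  expect_gt(sel$best$lambda1, 0)
})

test_that("point-contact forces are recovered within 20% at measurement noise", {
  m <- model_600()
  sel <- select_regularization(m, 33L,
                               pattern = list(magnitude_nN = 5, sdlog = 0.4),
                               noise = list(sigma_xy_um = 0.3,
                                            sigma_z_um = 1),
                               n_rep = 20, seed = 5)
  errs <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    node <- sample(22:44, 1)
    mag <- rlnorm(1, log(5), 0.4); phi <- runif(1, 0, 2 * pi)
    truth <- force_field(m, node, mag * cos(phi), mag * sin(phi))
    clean <- solve_forward(m, truth)
    if (max(sqrt(clean$dy^2 + clean$dz^2)) < 1) return(NA_real_)
    noisy <- perturb_deflections(clean, 0.3, 1, seed = 2000 + r)
    rec <- suppressWarnings(
      recover_forces(noisy, m, node, sel$best, seed = r))
    sqrt(sum((rec$fy - truth$fy)^2 + (rec$fz - truth$fz)^2)) /
      sqrt(sum(truth$fy^2 + truth$fz^2))
  }, numeric(1))
  expect_gt(sum(!is.na(errs)), 25)
  expect_lt(median(errs, na.rm = TRUE), 0.2)
})
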