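# Shared fixtures and independent oracles.

spec_600 <- function(length_um = 80)
  fiber_spec(length_um, 1.56, 0.073, 11.32, tension_nN = 71)

spec_800 <- function(length_um = 80)
  fiber_spec(length_um, 2.33, 0.142, 11.32, tension_nN = 374)

model_600 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_beam_model(spec_600(), 64)
    cache
  }
})

# Exhaustive multiscale grid search over the force vector: at each level an
# axis-aligned grid (9 points per dimension) is fully evaluated and the box
# shrinks around the best point until the step reaches `step_final`.
# Independent of the production solver: evaluates the loss directly.
oracle_grid_search <- function(data, model, contacts, reg,
                               half_width = 8, step_final = 0.01,
                               pts = 9L) {
  G <- influence_matrix(model, contacts)
  int <- 2:(model$n_nodes - 1L)
  d <- c(data$dy[int], data$dz[int])
  m2 <- ncol(G)
  eval_block <- function(P) {
    # P: n x m2 matrix of candidate force vectors
    R <- matrix(d, length(d), nrow(P)) - G %*% t(P)
    colSums(abs(R)) + reg$lambda1 * rowSums(abs(P)) +
      reg$lambda2 * rowSums(P^2)
  }
  center <- rep(0, m2)
  hw <- half_width
  repeat {
    grids <- lapply(seq_len(m2), function(j)
      center[j] + seq(-hw, hw, length.out = pts))
    combos <- as.matrix(expand.grid(grids))
    vals <- numeric(nrow(combos))
    for (i0 in seq(1, nrow(combos), by = 20000)) {
      i1 <- min(i0 + 19999, nrow(combos))
      vals[i0:i1] <- eval_block(combos[i0:i1, , drop = FALSE])
    }
    center <- combos[which.min(vals), ]
    step <- 2 * hw / (pts - 1)
    if (step <= step_final) break
    hw <- 1.5 * step
  }
  unname(center)
}

# Ordinary least-squares fit of F = a ln n + b, written out longhand as an
# independent check on the regression path.
oracle_log_fit <- function(n, F) {
  x <- log(n)
  a <- sum((x - mean(x)) * (F - mean(F))) / sum((x - mean(x))^2)
  b <- mean(F) - a * mean(x)
  pred <- a * x + b
  r2 <- 1 - sum((F - pred)^2) / sum((F - mean(F))^2)
  list(a = a, b = b, r_squared = r2)
}

# Small rendered phantom (8 fibers, 30 um span) reused across imaging
# tests; built once per test run.
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom(seed = 301, length_um = 30, spacing_um = 10,
                         cell_radii_um = c(9, 9, 7), n_elements = 32)
      st <- render_stack(ph)
      cache <<- list(truth = ph, stack = st)
    }
    cache
  }
})

# Straight (unloaded) phantom of the same geometry.
straight_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      layout <- make_layout("two-layer", length_um = 30, spacing_um = 10)
      pattern <- sample_force_pattern(layout, c(15, 15, 5), c(9, 9, 7),
                                      magnitude_nN = 1e-9, n_elements = 32,
                                      seed = 7)
      fields <- forward_deform(layout, spec_600(30), pattern,
                               n_elements = 32)
      truth <- phantom_truth(layout, spec_600(30), pattern, fields,
                             seed = 7)
      cache <<- list(truth = truth, stack = render_stack(truth))
    }
    cache
  }
})
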