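# Clamped Euler-Bernoulli beam under constant axial tension, discretized
# with cubic-Hermite bending elements plus the consistent geometric
# stiffness matrix. The two transverse bending planes (in-plane y, vertical
# z) are uncoupled and assembled independently; axial extension and torsion
# carry no degrees of freedom.

# Element matrices for one bending plane: dof order (w1, th1, w2, th2).
.element_bending <- function(EI, h) {
  EI / h^3 * matrix(c(
     12,    6 * h,  -12,    6 * h,
      6 * h, 4 * h^2, -6 * h, 2 * h^2,
    -12,   -6 * h,   12,   -6 * h,
      6 * h, 2 * h^2, -6 * h, 4 * h^2), 4, 4, byrow = TRUE)
}

.element_geometric <- function(T_, h) {
  T_ / (30 * h) * matrix(c(
     36,    3 * h,  -36,    3 * h,
      3 * h, 4 * h^2, -3 * h,   -h^2,
    -36,   -3 * h,   36,   -3 * h,
      3 * h,  -h^2,  -3 * h, 4 * h^2), 4, 4, byrow = TRUE)
}

# Exact element stiffness for a beam under constant axial tension. The
# homogeneous solutions of EI w'''' - T w'' = 0 are {1, x, exp(-a x),
# exp(a (x - h))} with a = sqrt(T/EI); using them as shape functions makes
# the Galerkin stiffness nodally exact, so midpoint stiffnesses are
# mesh-independent even when the clamp boundary layer sqrt(EI/T) is much
# smaller than an element. The energy integrals have stable closed forms
# (the exponentials are normalized to at most 1 on the element). For small
# a h the basis degenerates and the cubic-Hermite + consistent geometric
# matrix is used instead (its error is O((a h)^4) there).
.element_exact <- function(EI, T_, h) {
  a <- sqrt(T_ / EI)
  q <- a * h
  if (q < 1e-2)
    return(.element_bending(EI, h) + .element_geometric(T_, h))
  eq <- exp(-q)
  # dof values (w(0), w'(0), w(h), w'(h)) of the four basis functions
  M <- cbind(c(1, 0, 1, 0),
             c(0, 1, h, 1),
             c(1, -a, eq, -a * eq),
             c(eq, a * eq, 1, a))
  # energy matrix Q_ij = int EI b_i'' b_j'' + T b_i' b_j' dx; with
  # T = EI a^2 the cross term of the two exponentials cancels exactly
  e2 <- 1 - exp(-2 * q)
  e1 <- 1 - eq
  Q <- matrix(0, 4, 4)
  Q[2, 2] <- T_ * h
  Q[2, 3] <- Q[3, 2] <- -T_ * e1
  Q[2, 4] <- Q[4, 2] <- T_ * e1
  Q[3, 3] <- Q[4, 4] <- T_ * a * e2
  A <- solve(M)
  K <- t(A) %*% Q %*% A
  (K + t(K)) / 2
}

# Assemble the free-dof stiffness matrix of one bending plane. Nodes are
# 1..n+1 with both end nodes fully clamped; free dofs are (w, theta) at the
# interior nodes, ordered w_2, th_2, w_3, th_3, ..., w_n, th_n.
.assemble_plane <- function(EI, T_, L, n_elements) {
  n <- n_elements
  h <- L / n
  Ke <- .element_exact(EI, T_, h)
  ndof <- 2 * (n - 1)
  # global dof index of (node, local w/theta); 0 = constrained
  gw <- function(j) ifelse(j >= 2 & j <= n, 2 * (j - 2) + 1, 0L)
  gt <- function(j) ifelse(j >= 2 & j <= n, 2 * (j - 2) + 2, 0L)
  ii <- integer(16L * n); jj <- integer(16L * n); xx <- numeric(16L * n)
  k <- 0L
  for (e in seq_len(n)) {
    gmap <- c(gw(e), gt(e), gw(e + 1), gt(e + 1))
    keep <- which(gmap > 0)
    for (a in keep) for (b in keep) {
      k <- k + 1L
      ii[k] <- gmap[a]; jj[k] <- gmap[b]; xx[k] <- Ke[a, b]
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# Midpoint apparent stiffness of a single bending plane (closed helper used
# by calibration and summaries; snaps to the node nearest the midpoint).
.plane_midpoint_stiffness <- function(EI, T_, L, n_elements) {
  K <- .assemble_plane(EI, T_, L, n_elements)
  nodes <- seq(0, L, length.out = n_elements + 1)
  i <- which.min(abs(nodes - L / 2))      # interior since n_elements >= 2
  b <- numeric(2 * (n_elements - 1))
  b[2 * (i - 2) + 1] <- 1
  d <- Matrix::solve(K, b)
  1 / d[2 * (i - 2) + 1]
}

#' Finite-element model of one clamped fiber under tension
#'
#' Discretizes a fiber into `n_elements` equal Euler-Bernoulli beam
#' elements. Each interior node carries four degrees of freedom: transverse
#' deflections along y (in-plane) and z (vertical) and the two associated
#' rotations. The element stiffness is the cubic-Hermite bending matrix plus
#' the consistent geometric-stiffness matrix for the constant built-in
#' tension; the y plane uses `I_inplane_um4`, the z plane `I_lateral_um4`.
#' Both end nodes are fully clamped.
#'
#' @param spec a `fiber_spec`.
#' @param n_elements number of elements (>= 2); 64 meets a 0.1% mesh
#'   convergence contract on all reported stiffnesses.
#' @return object of class `beam_model` with the per-plane free-dof
#'   stiffness matrices and node positions in um.
#' @export
build_beam_model <- function(spec, n_elements = 64) {
  stopifnot(inherits(spec, "fiber_spec"))
  if (!is.numeric(n_elements) || length(n_elements) != 1L ||
      n_elements != round(n_elements) || n_elements < 2)
    stop("'n_elements' must be an integer >= 2", call. = FALSE)
  n_elements <- as.integer(n_elements)
  L <- spec$length_um
  structure(
    list(spec = spec,
         n_elements = n_elements,
         n_nodes = n_elements + 1L,
         h = L / n_elements,
         nodes_um = seq(0, L, length.out = n_elements + 1),
         Ky = .assemble_plane(spec$E * spec$I_inplane_um4, spec$tension_nN,
                              L, n_elements),
         Kz = .assemble_plane(spec$E * spec$I_lateral_um4, spec$tension_nN,
                              L, n_elements)),
    class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("beam_model: L = %g um, %d elements (h = %g um), T = %g nN\n",
              x$spec$length_um, x$n_elements, x$h, x$spec$tension_nN))
  invisible(x)
}

.interior_nodes <- function(model) seq(2L, model$n_nodes - 1L)

# free-dof index of the transverse-deflection dof at interior node i
.wdof <- function(i) 2L * (i - 2L) + 1L

#' Nodal transverse point-force field on one fiber
#'
#' Holds per-node transverse forces (Fy in-plane, Fz vertical) in nN on the
#' mesh of a `beam_model`. Forces may only sit at interior nodes; all other
#' entries are exactly zero. This is the force vector the inverse problem
#' estimates.
#'
#' @param model a `beam_model`.
#' @param node integer node indices (1-based; clamps are nodes 1 and
#'   `n_nodes`).
#' @param fy,fz force components in nN, one per entry of `node`.
#' @return object of class `force_field`: full-length `fy`, `fz` vectors
#'   plus node positions.
#' @export
force_field <- function(model, node = integer(0), fy = numeric(0),
                        fz = numeric(0)) {
  stopifnot(inherits(model, "beam_model"))
  node <- as.integer(node)
  if (length(fy) != length(node) || length(fz) != length(node))
    stop("'node', 'fy' and 'fz' must have equal length", call. = FALSE)
  if (anyDuplicated(node)) stop("duplicate node indices", call. = FALSE)
  if (any(node <= 1L | node >= model$n_nodes))
    stop("forces may only be applied at interior nodes (clamped ends carry no admissible dof)",
         call. = FALSE)
  FY <- numeric(model$n_nodes); FZ <- numeric(model$n_nodes)
  FY[node] <- fy; FZ[node] <- fz
  structure(list(fy = FY, fz = FZ, positions_um = model$nodes_um),
            class = "force_field")
}

#' @export
as.data.frame.force_field <- function(x, ...) {
  keep <- which(x$fy != 0 | x$fz != 0)
  data.frame(node_index = keep, position_um = x$positions_um[keep],
             Fy_nN = x$fy[keep], Fz_nN = x$fz[keep],
             magnitude_nN = sqrt(x$fy[keep]^2 + x$fz[keep]^2))
}

#' Per-node transverse deflection field of one fiber
#'
#' The measurement the inverse problem consumes: signed offsets of the
#' fiber centerline from the chord joining its two anchors, decomposed into
#' the in-plane (dy) and vertical (dz) directions, in um, at every mesh
#' node. Clamped end nodes are zero by definition.
#'
#' @param dy,dz deflections in um, length `n_nodes`.
#' @param positions_um node positions along the fiber axis, um.
#' @param sigma_y,sigma_z per-axis measurement-noise scales, um.
#' @return object of class `deflection_field`.
#' @export
deflection_field <- function(dy, dz, positions_um,
                             sigma_y = NA_real_, sigma_z = NA_real_) {
  n <- length(positions_um)
  if (length(dy) != n || length(dz) != n)
    stop("'dy', 'dz' and 'positions_um' must have equal length",
         call. = FALSE)
  if (!all(is.finite(dy)) || !all(is.finite(dz)))
    stop("deflections must be finite", call. = FALSE)
  if (abs(dy[1]) > 1e-12 || abs(dy[n]) > 1e-12 ||
      abs(dz[1]) > 1e-12 || abs(dz[n]) > 1e-12)
    stop("deflections at clamped end nodes must be zero", call. = FALSE)
  dy[c(1, n)] <- 0; dz[c(1, n)] <- 0
  structure(list(dy = dy, dz = dz, positions_um = positions_um,
                 sigma_y = sigma_y, sigma_z = sigma_z),
            class = "deflection_field")
}

#' Forward solve: deflections of a fiber under nodal point forces
#'
#' Solves the constrained linear system of both bending planes for the
#' given transverse nodal loads (no applied moments) and returns the
#' per-node deflection field. The map is linear in the forces and zero at
#' the clamps.
#'
#' @param model a `beam_model`.
#' @param forces a `force_field` on the same mesh.
#' @return a `deflection_field`.
#' @export
solve_forward <- function(model, forces) {
  stopifnot(inherits(model, "beam_model"), inherits(forces, "force_field"))
  if (length(forces$fy) != model$n_nodes)
    stop("force field does not match the model mesh", call. = FALSE)
  if (abs(forces$fy[1]) + abs(forces$fz[1]) +
      abs(forces$fy[model$n_nodes]) + abs(forces$fz[model$n_nodes]) > 0)
    stop("force assigned to a clamped node: no admissible dof", call. = FALSE)
  int <- .interior_nodes(model)
  ndof <- 2L * (model$n_nodes - 2L)
  by <- numeric(ndof); bz <- numeric(ndof)
  by[.wdof(int)] <- forces$fy[int]
  bz[.wdof(int)] <- forces$fz[int]
  dy <- numeric(model$n_nodes); dz <- numeric(model$n_nodes)
  dy[int] <- as.numeric(Matrix::solve(model$Ky, by))[.wdof(int)]
  dz[int] <- as.numeric(Matrix::solve(model$Kz, bz))[.wdof(int)]
  deflection_field(dy, dz, model$nodes_um)
}

# Snap a position in um to the nearest mesh node; ties resolve toward the
# lower-index clamp (which.min takes the first minimum on the ascending
# node vector). Must land on an interior node.
.snap_node <- function(model, position_um) {
  if (!is.numeric(position_um) || length(position_um) != 1L ||
      !is.finite(position_um))
    stop("'position_um' must be a single finite number", call. = FALSE)
  if (position_um <= 0 || position_um >= model$spec$length_um)
    stop("position must lie strictly between the clamps", call. = FALSE)
  i <- which.min(abs(model$nodes_um - position_um))
  if (i == 1L || i == model$n_nodes)
    stop("position snaps to a clamped node; move it inward", call. = FALSE)
  i
}

#' Apparent stiffness of a fiber at a point
#'
#' Force per unit deflection for a unit transverse point load applied at
#' the mesh node nearest `position_um`, reported per bending plane (the two
#' values coincide only when the section is symmetric). The AFM-measured
#' apparent stiffness corresponds to the midpoint.
#'
#' @param model a `beam_model`.
#' @param position_um position along the fiber, strictly between the
#'   clamps; snapped to the nearest node.
#' @return named numeric `c(y = , z = )` in nN/um.
#' @export
apparent_stiffness <- function(model, position_um) {
  stopifnot(inherits(model, "beam_model"))
  i <- .snap_node(model, position_um)
  ndof <- 2L * (model$n_nodes - 2L)
  b <- numeric(ndof); b[.wdof(i)] <- 1
  ky <- 1 / as.numeric(Matrix::solve(model$Ky, b))[.wdof(i)]
  kz <- 1 / as.numeric(Matrix::solve(model$Kz, b))[.wdof(i)]
  c(y = ky, z = kz)
}

#' Apparent-stiffness profile along a fiber
#'
#' Evaluates the per-plane apparent stiffness at a set of interior
#' positions. The profile is symmetric about the midpoint, minimal there,
#' and increases nonlinearly toward each clamp.
#'
#' @param model a `beam_model`.
#' @param positions_um interior positions, um.
#' @return data.frame with `position_um`, `k_y`, `k_z` (nN/um).
#' @export
stiffness_profile <- function(model, positions_um) {
  ks <- vapply(positions_um, function(p) apparent_stiffness(model, p),
               numeric(2))
  data.frame(position_um = positions_um, k_y = ks[1, ], k_z = ks[2, ])
}
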