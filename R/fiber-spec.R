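# Internal unit system: micrometres and nanonewtons throughout, so Young's
# moduli are carried in nN/um^2 (1 MPa = 1000 nN/um^2) and all stiffnesses
# come out in nN/um. Converters sit at the constructor boundary only.

MPA_TO_NN_PER_UM2 <- 1000

.check_positive <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nms[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Rectangular cross-section properties of a fiber
#'
#' Photopolymerized fibers have an elliptical cross-section; the mechanical
#' model approximates it by a rectangle of the measured axial width and
#' average height. Returns the area and the two second moments of area:
#' `I_inplane_um4` governs bending within the scaffold layer plane (about the
#' vertical axis) and `I_lateral_um4` governs vertical (z) bending.
#'
#' @param width_um axial (in-plane) cross-section dimension, um.
#' @param height_um average height (vertical dimension), um.
#' @return list with `area_um2`, `I_inplane_um4`, `I_lateral_um4`.
#' @examples
#' rect_section_properties(1.56, 0.073)
#' @export
rect_section_properties <- function(width_um, height_um) {
  .check_positive(width_um = width_um, height_um = height_um)
  list(
    area_um2      = width_um * height_um,
    I_inplane_um4 = height_um * width_um^3 / 12,
    I_lateral_um4 = width_um * height_um^3 / 12
  )
}

#' Structural (bending) midpoint stiffness of a clamped-clamped beam
#'
#' The elasticity-only midpoint stiffness 192 E I / L^3, which is the
#' apparent stiffness in the regime where structural elasticity dominates
#' over built-in tension.
#'
#' @param E Young's modulus, nN/um^2.
#' @param I second moment of area, um^4.
#' @param L fiber length between clamps, um.
#' @return stiffness in nN/um.
#' @export
structural_stiffness <- function(E, I, L) {
  .check_positive(E = E, I = I, L = L)
  192 * E * I / L^3
}

#' Tension-dominated midpoint stiffness of a clamped fiber
#'
#' In the taut-string regime the midpoint apparent stiffness is 4 T / L,
#' set by the built-in tensile prestress T rather than by material
#' elasticity.
#'
#' @param T built-in tension, nN (>= 0).
#' @param L fiber length, um.
#' @return stiffness in nN/um.
#' @export
tension_limit_stiffness <- function(T, L) {
  .check_positive(L = L)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0)
    stop("'T' must be a single non-negative finite number", call. = FALSE)
  4 * T / L
}

#' Axial stiffness of a fiber
#'
#' A E / L: the stiffness against stretching along the fiber axis. It is
#' independent of the stored tension and is reported as a diagnostic only;
#' axial forces are not recovered by the inverse problem.
#'
#' @param A cross-section area, um^2.
#' @param E Young's modulus, nN/um^2.
#' @param L fiber length, um.
#' @return stiffness in nN/um.
#' @export
axial_stiffness <- function(A, E, L) {
  .check_positive(A = A, E = E, L = L)
  A * E / L
}

#' Mechanical specification of one suspended fiber
#'
#' Bundles the geometry (length, rectangular-section dimensions), material
#' (Young's modulus, accepted in MPa) and built-in tensile prestress of a
#' clamped fiber, with derived section properties attached.
#'
#' @param length_um fiber length between clamps, um.
#' @param width_um axial cross-section dimension, um.
#' @param height_um average height, um.
#' @param youngs_modulus_mpa Young's modulus in MPa (1 MPa = 1000 nN/um^2).
#' @param tension_nN built-in axial tension, nN (>= 0).
#' @return object of class `fiber_spec`.
#' @examples
#' fiber_spec(80, 1.56, 0.073, 11.32, tension_nN = 71)
#' @export
fiber_spec <- function(length_um, width_um, height_um, youngs_modulus_mpa,
                       tension_nN = 0) {
  .check_positive(length_um = length_um, width_um = width_um,
                  height_um = height_um,
                  youngs_modulus_mpa = youngs_modulus_mpa)
  if (!is.numeric(tension_nN) || length(tension_nN) != 1L ||
      !is.finite(tension_nN) || tension_nN < 0)
    stop("'tension_nN' must be a single non-negative number", call. = FALSE)
  sec <- rect_section_properties(width_um, height_um)
  structure(
    list(length_um = length_um, width_um = width_um, height_um = height_um,
         E = youngs_modulus_mpa * MPA_TO_NN_PER_UM2,
         tension_nN = tension_nN,
         area_um2 = sec$area_um2,
         I_inplane_um4 = sec$I_inplane_um4,
         I_lateral_um4 = sec$I_lateral_um4),
    class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("fiber_spec: L = %g um, section %g x %g um, E = %g MPa, T = %g nN\n",
              x$length_um, x$width_um, x$height_um,
              x$E / MPA_TO_NN_PER_UM2, x$tension_nN))
  cat(sprintf("  A = %.5g um^2, I_inplane = %.5g um^4, I_lateral = %.5g um^4\n",
              x$area_um2, x$I_inplane_um4, x$I_lateral_um4))
  invisible(x)
}

#' Printed fiber fabrication presets
#'
#' Fiber conditions indexed by two-photon polymerization exposure time.
#' Dimensions are AFM-measured axial width and average/maximum height;
#' apparent stiffnesses are midpoint AFM values at 1 nN and 2 nN loads on
#' 80 um fibers; tensions follow from the tension-dominated relation
#' k = 4T/L applied to the averaged stiffness. The 700 us condition has a
#' published midpoint stiffness but no published section dimensions, so its
#' geometry columns are NA. The pooled Young's modulus is 11.32 MPa.
#'
#' @return data.frame, one row per exposure-time condition.
#' @export
fiber_presets <- function() {
  L <- 80
  df <- data.frame(
    condition        = c("600us", "700us", "800us"),
    exposure_us      = c(600, 700, 800),
    width_um         = c(1.56, NA, 2.33),
    avg_height_um    = c(0.073, NA, 0.142),
    max_height_um    = c(0.126, NA, 0.198),
    k_app_1nN        = c(3.5, 4.1, 17.6),
    k_app_2nN        = c(3.6, NA, 19.8),
    youngs_mpa       = c(11.32, 11.32, 11.32),
    length_um        = c(L, L, L),
    stringsAsFactors = FALSE)
  k_mean <- rowMeans(df[, c("k_app_1nN", "k_app_2nN")], na.rm = TRUE)
  df$k_app_mean <- k_mean
  df$tension_nN <- k_mean * df$length_um / 4
  df$aspect_ratio <- df$width_um / df$max_height_um
  df
}

#' Fiber spec from a named preset condition
#'
#' @param condition one of "600us", "700us", "800us".
#' @param length_um fiber length, um; tension is kept as calibrated on the
#'   80 um reference fibers (prestress is set by fabrication, not length).
#' @return `fiber_spec`.
#' @export
preset_spec <- function(condition = c("600us", "800us", "700us"),
                        length_um = 80) {
  condition <- match.arg(condition)
  p <- fiber_presets()
  row <- p[p$condition == condition, ]
  if (is.na(row$width_um))
    stop("no published section dimensions for condition ", condition,
         call. = FALSE)
  fiber_spec(length_um, row$width_um, row$avg_height_um, row$youngs_mpa,
             tension_nN = row$tension_nN)
}

#' Stiffness regime summary for one fiber condition
#'
#' Collects the closed-form structural (192EI/L^3), tension-limit (4T/L) and
#' axial (AE/L) stiffnesses together with the finite-element midpoint
#' apparent stiffness, and the fraction of the apparent stiffness
#' contributed by structural bending. By default the in-plane (larger)
#' second moment is used for the structural figure, giving a conservative
#' upper bound on the bending contribution.
#'
#' @param spec a `fiber_spec`.
#' @param plane "inplane" or "lateral": which bending plane's I to use for
#'   the structural stiffness and FEM midpoint value.
#' @param n_elements finite elements for the midpoint evaluation.
#' @return list of class `stiffness_summary`.
#' @export
stiffness_summary <- function(spec, plane = c("inplane", "lateral"),
                              n_elements = 64) {
  stopifnot(inherits(spec, "fiber_spec"))
  plane <- match.arg(plane)
  I <- if (plane == "inplane") spec$I_inplane_um4 else spec$I_lateral_um4
  k_struct <- structural_stiffness(spec$E, I, spec$length_um)
  k_tension <- tension_limit_stiffness(spec$tension_nN, spec$length_um)
  k_axial <- axial_stiffness(spec$area_um2, spec$E, spec$length_um)
  k_app <- .plane_midpoint_stiffness(spec$E * I, spec$tension_nN,
                                     spec$length_um, n_elements)
  structure(
    list(k_struct = k_struct, k_tension = k_tension, k_axial = k_axial,
         k_apparent_midpoint = k_app,
         structural_fraction = k_struct / k_app,
         plane = plane),
    class = "stiffness_summary")
}

#' @export
print.stiffness_summary <- function(x, ...) {
  cat(sprintf(
    "stiffness summary (%s plane), nN/um:\n  k_struct = %.4g  k_tension = %.4g  k_axial = %.4g\n  k_apparent(midpoint, FEM) = %.4g  structural fraction = %.3g\n",
    x$plane, x$k_struct, x$k_tension, x$k_axial, x$k_apparent_midpoint,
    x$structural_fraction))
  invisible(x)
}

#' @export
as.data.frame.stiffness_summary <- function(x, ...) {
  data.frame(k_struct = x$k_struct, k_tension = x$k_tension,
             k_axial = x$k_axial,
             k_apparent_midpoint = x$k_apparent_midpoint,
             structural_fraction = x$structural_fraction,
             plane = x$plane, stringsAsFactors = FALSE)
}

#' Calibrate built-in tension from a measured midpoint apparent stiffness
#'
#' Inverts the midpoint stiffness of a clamped fiber under tension for T.
#' In `"tension-only"` mode the taut-string relation k = 4T/L is inverted
#' directly (T = k L / 4), which is how the published tension values were
#' obtained since structural bending contributes less than 3% of the
#' apparent stiffness. In `"corrected"` mode the full finite-element
#' midpoint-stiffness relation (bending + geometric stiffness) is solved
#' for T by bracketed root-finding; the corrected tension is always at or
#' below the tension-only value because bending stiffens the midpoint.
#'
#' @param k_app_midpoint measured midpoint apparent stiffness, nN/um.
#' @param length_um fiber length, um.
#' @param youngs_modulus_mpa,I_um4 material/section inputs, required in
#'   "corrected" mode.
#' @param mode "tension-only" or "corrected".
#' @param n_elements finite elements for the corrected solve.
#' @param tol relative tolerance of the root search.
#' @return tension in nN.
#' @examples
#' calibrate_tension(mean(c(3.5, 3.6)), 80)   # 71 nN
#' @export
calibrate_tension <- function(k_app_midpoint, length_um,
                              youngs_modulus_mpa = NULL, I_um4 = NULL,
                              mode = c("tension-only", "corrected"),
                              n_elements = 64, tol = 1e-6) {
  mode <- match.arg(mode)
  .check_positive(k_app_midpoint = k_app_midpoint, length_um = length_um)
  if (mode == "tension-only")
    return(k_app_midpoint * length_um / 4)
  if (is.null(youngs_modulus_mpa) || is.null(I_um4))
    stop("'corrected' mode needs 'youngs_modulus_mpa' and 'I_um4'",
         call. = FALSE)
  .check_positive(youngs_modulus_mpa = youngs_modulus_mpa, I_um4 = I_um4)
  EI <- youngs_modulus_mpa * MPA_TO_NN_PER_UM2 * I_um4
  k0 <- .plane_midpoint_stiffness(EI, 0, length_um, n_elements)
  if (k_app_midpoint <= k0)
    stop(sprintf(
      "measured stiffness %.4g nN/um is not above the zero-tension structural stiffness %.4g nN/um; no tension root",
      k_app_midpoint, k0), call. = FALSE)
  T_hi <- k_app_midpoint * length_um / 4
  f <- function(T_) .plane_midpoint_stiffness(EI, T_, length_um,
                                              n_elements) - k_app_midpoint
  root <- stats::uniroot(f, lower = 0, upper = T_hi,
                         tol = tol * max(T_hi, 1))
  root$root
}
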