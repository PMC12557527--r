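# Contractility and force summary metrics.

#' Cell contractility of a force field
#'
#' The sum over contacted nodes of the per-node transverse force magnitude
#' sqrt(Fy^2 + Fz^2). Set `per_component = TRUE` to sum absolute components
#' instead (an alternative reading of "sum of the exerted forces").
#'
#' @param field a `force_field`.
#' @param per_component sum |Fy| + |Fz| instead of vector magnitudes.
#' @return total force in nN.
#' @export
contractility <- function(field, per_component = FALSE) {
  stopifnot(inherits(field, "force_field"))
  if (per_component) sum(abs(field$fy)) + sum(abs(field$fz))
  else sum(sqrt(field$fy^2 + field$fz^2))
}

#' Residual (unbalanced) force of a force field
#'
#' The vector sum of all recovered transverse forces and its magnitude. A
#' mechanically self-equilibrated cell should exert a near-zero resultant;
#' a large residual flags force components the transverse-only model cannot
#' represent, typically axial loading along the fiber.
#'
#' @param field a `force_field`.
#' @return list with `vector` (named `c(Fy, Fz)`, nN) and `magnitude` (nN).
#' @export
residual_force <- function(field) {
  stopifnot(inherits(field, "force_field"))
  v <- c(Fy = sum(field$fy), Fz = sum(field$fz))
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Time-resolved force metrics for one cell
#'
#' Per timepoint: number of contacted nodes, total force (contractility),
#' force per node, and force per node restricted to the central part of the
#' fiber span (the open window of width `central_fraction * L` around the
#' midpoint; nodes on the window boundary count as outside, toward the
#' clamp). Time averages are reported alongside.
#'
#' @param fields list of `force_field`, one per timepoint (single fibers) or
#'   list of lists (per timepoint, per fiber).
#' @param contacts optional matching structure of contact node indices;
#'   defaults to the support of each force field.
#' @param central_fraction fraction of the span counted as central, in
#'   (0, 1].
#' @return object of class `force_metrics`: list with `per_timepoint`
#'   data.frame and `means`.
#' @export
force_metrics <- function(fields, contacts = NULL, central_fraction = 0.5) {
  if (length(fields) == 0L) stop("empty time series", call. = FALSE)
  if (!(is.numeric(central_fraction) && length(central_fraction) == 1L &&
        central_fraction > 0 && central_fraction <= 1))
    stop("'central_fraction' must be in (0, 1]", call. = FALSE)
  # normalize to list-of-lists (timepoint -> fibers)
  if (inherits(fields[[1]], "force_field")) fields <- lapply(fields, list)
  rows <- lapply(seq_along(fields), function(t) {
    ffs <- fields[[t]]
    n_contact <- 0L; total <- 0; central_sum <- 0; central_n <- 0L
    for (f in ffs) {
      supp <- if (is.null(contacts)) which(f$fy != 0 | f$fz != 0)
              else contacts[[t]]
      mag <- sqrt(f$fy[supp]^2 + f$fz[supp]^2)
      n_contact <- n_contact + length(supp)
      total <- total + sum(mag)
      L <- max(f$positions_um)
      lo <- L * (1 - central_fraction) / 2
      hi <- L * (1 + central_fraction) / 2
      cen <- f$positions_um[supp] > lo & f$positions_um[supp] < hi
      central_sum <- central_sum + sum(mag[cen])
      central_n <- central_n + sum(cen)
    }
    data.frame(timepoint = t, n_contact_nodes = n_contact,
               total_force_nN = total,
               force_per_node_nN = if (n_contact > 0) total / n_contact
                                   else NA_real_,
               central_force_per_node_nN = if (central_n > 0)
                 central_sum / central_n else NA_real_)
  })
  per_t <- do.call(rbind, rows)
  means <- colMeans(per_t[, -1, drop = FALSE], na.rm = TRUE)
  structure(list(per_timepoint = per_t, means = means,
                 central_fraction = central_fraction),
            class = "force_metrics")
}

#' @export
print.force_metrics <- function(x, ...) {
  cat(sprintf("force_metrics over %d timepoints (central fraction %.2f):\n",
              nrow(x$per_timepoint), x$central_fraction))
  print(round(x$means, 3))
  invisible(x)
}

#' Logarithmic fit of total force versus contacted nodes
#'
#' Least-squares fit of F = a * ln(n) + b across cells, quantifying the
#' sublinear growth of total exerted force with the number of contacted
#' nodes.
#'
#' @param n_nodes number of contacted nodes per cell (>= 1).
#' @param total_force_nN total force per cell, nN.
#' @return list with `a`, `b`, `r_squared`, `n_points`.
#' @export
fit_log_force_vs_nodes <- function(n_nodes, total_force_nN) {
  if (length(n_nodes) != length(total_force_nN))
    stop("inputs must have equal length", call. = FALSE)
  if (length(n_nodes) < 3L)
    stop("need at least 3 points for the logarithmic fit", call. = FALSE)
  if (any(n_nodes < 1)) stop("'n_nodes' must be >= 1", call. = FALSE)
  x <- log(n_nodes)
  if (stats::var(x) == 0)
    stop("zero variance in log(n_nodes): slope not identifiable",
         call. = FALSE)
  fit <- stats::lm(total_force_nN ~ x)
  res <- stats::residuals(fit)
  tss <- sum((total_force_nN - mean(total_force_nN))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(res^2) / tss
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r_squared = r2, n_points = length(n_nodes))
}
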