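# Scaffold layouts. World coordinates are um; fibers are straight segments
# between two wall anchors. Standard scaffolds are two orthogonal layers of
# parallel fibers; the density-gradient design stacks four parallel layers
# with laterally staggered, regionally varying spacing.

MIN_SPACING_UM <- 5  # two-photon fabrication limit on lateral fiber spacing

#' Build a nominal scaffold layout
#'
#' `"two-layer"`: two layers of parallel fibers printed orthogonally
#' (layer 1 along x, layer 2 along y), separated vertically by
#' `z_gap_um` (10 um by default), with `floor(L / spacing) + 1` fibers per
#' layer spanning a square of side `length_um`.
#'
#' `"gradient"`: four layers of x-parallel fibers every `z_step_um`
#' (5 um), the span split into three equal-width density regions whose
#' lateral spacings are `region_spacings_um` (15/10/5 um), with successive
#' layers shifted laterally by half the local spacing (staggered).
#'
#' Layouts are deterministic functions of their arguments.
#'
#' @param kind "two-layer" or "gradient".
#' @param length_um fiber length (and scaffold span), um.
#' @param spacing_um lateral fiber spacing for the two-layer kind, um
#'   (>= 5, the fabrication limit).
#' @param region_spacings_um three lateral spacings, low- to high-density
#'   region, for the gradient kind.
#' @param z_gap_um vertical gap between the two orthogonal layers.
#' @param z_step_um vertical step between gradient layers.
#' @return object of class `scaffold_layout`: data.frame with one row per
#'   fiber (`fiber_id`, `layer`, `axis`, anchors `x0..z1`, `length_um`).
#' @export
make_layout <- function(kind = c("two-layer", "gradient"), length_um = 80,
                        spacing_um = 10, region_spacings_um = c(15, 10, 5),
                        z_gap_um = 10, z_step_um = 5) {
  kind <- match.arg(kind)
  .check_positive(length_um = length_um)
  L <- length_um
  if (kind == "two-layer") {
    if (spacing_um < MIN_SPACING_UM)
      stop(sprintf("lateral spacing %g um is below the %g um fabrication limit",
                   spacing_um, MIN_SPACING_UM), call. = FALSE)
    offs <- seq(0, L, by = spacing_um)
    l1 <- data.frame(layer = 1L, axis = "x",
                     x0 = 0, y0 = offs, z0 = 0,
                     x1 = L, y1 = offs, z1 = 0)
    l2 <- data.frame(layer = 2L, axis = "y",
                     x0 = offs, y0 = 0, z0 = z_gap_um,
                     x1 = offs, y1 = L, z1 = z_gap_um)
    df <- rbind(l1, l2)
  } else {
    if (length(region_spacings_um) != 3L)
      stop("'region_spacings_um' must give three region spacings",
           call. = FALSE)
    if (any(region_spacings_um < MIN_SPACING_UM))
      stop(sprintf("lateral spacing below the %g um fabrication limit",
                   MIN_SPACING_UM), call. = FALSE)
    region_w <- L / 3
    dfs <- list()
    for (layer in 1:4) {
      ys <- numeric(0)
      for (r in 1:3) {
        s <- region_spacings_um[r]
        shift <- ((layer - 1) %% 2) * s / 2   # staggered successive layers
        # half-open region: the next region supplies its own boundary fiber
        y <- seq((r - 1) * region_w + shift, r * region_w - s / 2, by = s)
        ys <- c(ys, y)
      }
      ys <- sort(unique(ys))
      dfs[[layer]] <- data.frame(layer = layer, axis = "x",
                                 x0 = 0, y0 = ys, z0 = (layer - 1) * z_step_um,
                                 x1 = L, y1 = ys, z1 = (layer - 1) * z_step_um)
    }
    df <- do.call(rbind, dfs)
  }
  df <- df[order(df$layer, df$y0, df$x0), ]
  df$fiber_id <- sprintf("L%dF%02d", as.integer(df$layer),
                         as.integer(stats::ave(seq_len(nrow(df)), df$layer,
                                               FUN = seq_along)))
  df$length_um <- L
  rownames(df) <- NULL
  df <- df[, c("fiber_id", "layer", "axis", "x0", "y0", "z0",
               "x1", "y1", "z1", "length_um")]
  structure(df, class = c("scaffold_layout", "data.frame"),
            kind = kind, spacing_um = spacing_um,
            region_spacings_um = region_spacings_um,
            z_gap_um = z_gap_um, z_step_um = z_step_um)
}

# Unit axis vector and local transverse frame of one layout fiber.
# y is the in-plane lateral direction, z the vertical; frame = (u, ey, ez).
.fiber_frame <- function(anchor_start, anchor_end) {
  u <- anchor_end - anchor_start
  len <- sqrt(sum(u^2))
  if (len < 1e-9) stop("anchors coincident", call. = FALSE)
  u <- u / len
  ez <- c(0, 0, 1) - u[3] * u
  nz <- sqrt(sum(ez^2))
  if (nz < 1e-6)
    stop("fiber axis is vertical; transverse frame undefined", call. = FALSE)
  ez <- ez / nz
  ey <- c(ez[2] * u[3] - ez[3] * u[2],
          ez[3] * u[1] - ez[1] * u[3],
          ez[1] * u[2] - ez[2] * u[1])   # ez x u
  list(u = u, ey = ey, ez = ez, length = len)
}

.layout_anchors <- function(layout, fiber_id) {
  row <- layout[layout$fiber_id == fiber_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("unknown fiber id: ", fiber_id, call. = FALSE)
  list(start = c(row$x0, row$y0, row$z0), end = c(row$x1, row$y1, row$z1))
}

#' Serialize a scaffold layout to JSON
#' @param layout a `scaffold_layout`.
#' @param path output file.
#' @export
write_layout_json <- function(layout, path) {
  obj <- list(kind = attr(layout, "kind"),
              spacing_um = attr(layout, "spacing_um"),
              region_spacings_um = attr(layout, "region_spacings_um"),
              z_gap_um = attr(layout, "z_gap_um"),
              z_step_um = attr(layout, "z_step_um"),
              fibers = as.data.frame(layout))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scaffold layout from JSON
#' @param path file written by [write_layout_json()].
#' @return a `scaffold_layout`.
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(obj$fibers)
  structure(df, class = c("scaffold_layout", "data.frame"),
            kind = obj$kind, spacing_um = obj$spacing_um,
            region_spacings_um = obj$region_spacings_um,
            z_gap_um = obj$z_gap_um, z_step_um = obj$z_step_um)
}
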