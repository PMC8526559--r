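#' Shoelace area of a planar polygon
#'
#' @param xy n x 2 matrix of polygon vertices in order.
#' @return polygon area (absolute value), in the units of `xy` squared.
#' @export
polygon_area <- function(xy) {
  stopifnot(ncol(xy) == 2)
  x <- xy[, 1]
  y <- xy[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Projected valve open area (PVOA)
#'
#' Projects the instantaneous free-edge polyline of all three leaflets onto
#' the annulus plane and returns the area of the central orifice polygon
#' (shoelace formula on the azimuthally ordered projected vertices). For the
#' package's valve construction the projected vertex set is star-shaped
#' about the annulus center, so azimuthal ordering always yields a simple
#' polygon. The area is zero when the free edges coapt (`c = 0`).
#'
#' @param geometry a [build_valve_geometry()] object.
#' @param mapping a [valve_mapping()].
#' @param c per-leaflet lumped displacement (length 3).
#' @return PVOA in cm^2.
#' @export
projected_open_area <- function(geometry, mapping, c) {
  kin <- leaflet_kinematics(geometry, mapping, rep_len(c, 3))
  idx <- unlist(geometry$free_edge)
  p <- kin$position[idx, 1:2, drop = FALSE]
  # order by azimuth about the annulus center; the free-edge vertex angles
  # are fixed by the construction, so this ordering is stable in c
  r2 <- rowSums(p^2)
  keep <- r2 > (1e-9 * geometry$radius)^2
  if (sum(keep) < 3) return(0)
  # use the reference (fully open) positions to define stable angles, so
  # coincident small-c vertices keep their azimuthal order
  pref <- geometry$x_open[idx, 1:2, drop = FALSE]
  ang <- atan2(pref[, 2], pref[, 1])
  ord <- order(ang)
  polygon_area(p[ord, , drop = FALSE]) * 1e4
}

# Quadratic-form representation of PVOA.
#
# The projected free-edge vertex of node i is P1_i * xi_{l(i)} where P1_i is
# its fully open projected position and l(i) its leaflet (closed free-edge
# positions project onto the annulus center). With the azimuthal vertex
# ordering fixed, the shoelace area is therefore exactly quadratic in the
# per-leaflet openings: A = xi' Q xi. Used by the coupled cardiac-cycle
# simulation for O(1) PVOA evaluation; agrees with projected_open_area().
pvoa_quadratic_form <- function(geometry) {
  idx <- unlist(geometry$free_edge)
  lab <- geometry$node_leaflet[idx]
  p <- geometry$x_open[idx, 1:2, drop = FALSE]
  ang <- atan2(p[, 2], p[, 1])
  ord <- order(ang)
  p <- p[ord, , drop = FALSE]
  lab <- lab[ord]
  n <- nrow(p)
  nxt <- c(2:n, 1)
  cr <- p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2]
  Q <- matrix(0, 3, 3)
  for (k in seq_len(n)) {
    i <- lab[k]
    j <- lab[nxt[k]]
    Q[i, j] <- Q[i, j] + cr[k] / 2
  }
  # symmetrize (xi' Q xi only sees the symmetric part)
  (Q + t(Q)) / 2
}

# PVOA (m^2) for a T x 3 matrix of per-leaflet openings xi
pvoa_from_xi <- function(xi, Q) {
  if (is.null(dim(xi))) xi <- matrix(xi, 1)
  rowSums((xi %*% Q) * xi)
}
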