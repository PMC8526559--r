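#' Canonical aorta dimensions
#'
#' Anatomic reference dimensions of the idealized LVOT-sinus-ascending-aorta
#' geometry (m): LVOT diameter 23.00 mm, aortic root diameter 35.65 mm, root
#' axial length 23.00 mm, root base length 7.82 mm, ascending aorta diameter
#' 28.50 mm; leaflet length 15.00 mm.
#'
#' @param lvot_diameter,root_diameter,root_axial_length,root_base_length,ascending_diameter,leaflet_length
#'   dimensions in m.
#' @param total_length axial extent of the modeled lumen surface (m).
#' @return named list of class `aorta_dims`.
#' @export
aorta_dims <- function(lvot_diameter = 0.023,
                       root_diameter = 0.03565,
                       root_axial_length = 0.023,
                       root_base_length = 0.00782,
                       ascending_diameter = 0.0285,
                       leaflet_length = 0.015,
                       total_length = 0.08) {
  d <- list(lvot_diameter = lvot_diameter, root_diameter = root_diameter,
            root_axial_length = root_axial_length,
            root_base_length = root_base_length,
            ascending_diameter = ascending_diameter,
            leaflet_length = leaflet_length, total_length = total_length)
  if (any(unlist(d) <= 0)) stop("geometry error: dimensions must be positive")
  if (root_base_length >= root_axial_length ||
      total_length <= root_axial_length) {
    stop("geometry error: inconsistent axial lengths")
  }
  structure(d, class = "aorta_dims")
}

# lumen radius profile r(z): annulus at z = 0, sinus bulge peaking at the
# base length, blending to the ascending aorta at the root axial length,
# then cylindrical
aorta_profile <- function(dims, z) {
  r0 <- dims$lvot_diameter / 2
  rb <- dims$root_diameter / 2
  ra <- dims$ascending_diameter / 2
  zb <- dims$root_base_length
  za <- dims$root_axial_length
  r <- numeric(length(z))
  up <- z <= zb
  mid <- z > zb & z <= za
  r[up] <- r0 + (rb - r0) * (1 - cos(pi * z[up] / zb)) / 2
  r[mid] <- ra + (rb - ra) * (1 + cos(pi * (z[mid] - zb) / (za - zb))) / 2
  r[!up & !mid] <- ra
  r
}

#' Discretize the canonical aorta lumen into source panels
#'
#' Builds an axisymmetric LVOT-sinus-ascending-aorta surface of revolution
#' from the reference dimensions and tiles it into `n_panels` quasi-uniform
#' quadrilateral panels (uniform in axial position and azimuth), each with a
#' centroid, outward unit normal and area. These panels carry the
#' pressure-fluctuation time series that act as acoustic sources.
#'
#' @param dims an [aorta_dims()] list.
#' @param n_panels total panel count (>= 12); default 180.
#' @return object of class `source_panels`: matrices `centroid` (n x 3) and
#'   `normal` (n x 3), vector `area` (m^2), plus the tiling (`n_axial`,
#'   `n_azimuthal`) and `dims`.
#' @export
build_canonical_aorta <- function(dims = aorta_dims(), n_panels = 180) {
  stopifnot(inherits(dims, "aorta_dims"))
  if (n_panels < 12) stop("n_panels must be at least 12")
  # near-square tiling: azimuthal count ~ circumference / axial spacing
  n_az <- max(4L, round(sqrt(n_panels * pi * mean(c(
    dims$ascending_diameter, dims$root_diameter)) / dims$total_length)))
  n_ax <- max(3L, floor(n_panels / n_az))
  while (n_ax * n_az < n_panels) n_ax <- n_ax + 1L
  # trim to exactly n_panels by dropping trailing panels of the last ring
  z_edges <- seq(0, dims$total_length, length.out = n_ax + 1)
  th_edges <- seq(0, 2 * pi, length.out = n_az + 1)
  cent <- matrix(0, 0, 3)
  nrm <- matrix(0, 0, 3)
  area <- numeric(0)
  for (i in seq_len(n_ax)) {
    z0 <- z_edges[i]
    z1 <- z_edges[i + 1]
    zc <- (z0 + z1) / 2
    rc <- aorta_profile(dims, zc)
    # meridional arc length of the ring by fine quadrature
    zq <- seq(z0, z1, length.out = 9)
    rq <- aorta_profile(dims, zq)
    arc <- sum(sqrt(diff(zq)^2 + diff(rq)^2))
    drdz <- (aorta_profile(dims, zc + 1e-7) -
               aorta_profile(dims, zc - 1e-7)) / 2e-7
    for (j in seq_len(n_az)) {
      thc <- (th_edges[j] + th_edges[j + 1]) / 2
      v <- c(cos(thc), sin(thc), -drdz)
      cent <- rbind(cent, c(rc * cos(thc), rc * sin(thc), zc))
      nrm <- rbind(nrm, v / sqrt(sum(v^2)))
      area <- c(area, arc * rc * (th_edges[j + 1] - th_edges[j]))
    }
  }
  keep <- seq_len(min(n_panels, nrow(cent)))
  structure(list(centroid = cent[keep, , drop = FALSE],
                 normal = nrm[keep, , drop = FALSE],
                 area = area[keep],
                 n_axial = n_ax, n_azimuthal = n_az, dims = dims),
            class = "source_panels")
}

#' Attach pressure-fluctuation series to source panels
#'
#' @param panels a [build_canonical_aorta()] object.
#' @param pressure N x n_panels matrix of zero-mean pressure fluctuations
#'   (Pa), rows = time samples at `fs`.
#' @param fs sampling rate, Hz.
#' @return the panel set with `pressure` and `fs` fields set.
#' @export
set_panel_pressures <- function(panels, pressure, fs) {
  stopifnot(inherits(panels, "source_panels"),
            ncol(pressure) == nrow(panels$centroid))
  panels$pressure <- pressure
  panels$fs <- fs
  panels
}
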