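#' Build an idealized three-leaflet aortic valve geometry
#'
#' Constructs a symmetric trileaflet membrane valve on a circular annulus of
#' diameter `annulus_diameter`. Each leaflet is a triangulated surface patch
#' over a 120-degree azimuthal sector, parameterized by arc-length fraction
#' `s` (0 at the attached annulus edge, 1 at the free edge) and azimuth.
#'
#' The two reference configurations use a single-parameter cylindrical-sector
#' construction:
#' \itemize{
#'   \item closed: the leaflet funnels from the annulus ring down toward the
#'     valve center, the free edges coapting on the annulus axis at depth
#'     `h_c = sqrt(L_f^2 - R^2)` below the annulus plane;
#'   \item open: the leaflet is swept onto the lumen wall, lying along the
#'     annulus cylinder in the downstream (+z) direction.
#' }
#' Both configurations preserve the leaflet length `L_f` along `s`. The
#' per-node range-of-motion vector is `b = x_open - x_close`; it vanishes on
#' the attached edge (`s = 0`) and is largest at the free edge.
#'
#' Coordinates: valve center at the origin, +z downstream along the annulus
#' axis, +y anterior.
#'
#' @param annulus_diameter annulus (LVOT) diameter in m; default 0.023.
#' @param leaflet_length leaflet length `L_f` in m; default 0.015. Must
#'   exceed the annulus radius so the free edges can coapt at the center.
#' @param nodes_per_leaflet approximate node count per leaflet (>= 16).
#' @return an object of class `valve_geometry`: node matrices `x_close`,
#'   `x_open`, `b` (n x 3, all leaflets stacked), `node_leaflet`,
#'   `node_s`, triangle index matrix `tri` with `tri_leaflet`, per-element
#'   unit `normals` and areas `ds` (closed configuration), per-leaflet
#'   free-edge node indices `free_edge` (in azimuthal order), `radius`,
#'   `leaflet_length`, `axis`, `origin`.
#' @export
build_valve_geometry <- function(annulus_diameter = 0.023,
                                 leaflet_length = 0.015,
                                 nodes_per_leaflet = 64) {
  stopifnot(annulus_diameter > 0, leaflet_length > 0)
  if (nodes_per_leaflet < 16) {
    stop("nodes_per_leaflet must be at least 16")
  }
  R <- annulus_diameter / 2
  Lf <- leaflet_length
  if (Lf <= R) {
    stop("geometry error: leaflet_length must exceed the annulus radius ",
         "for the free edges to coapt at the valve center")
  }
  h_close <- sqrt(Lf^2 - R^2) # coaptation depth below the annulus plane

  # grid resolution: n_s radial stations x n_t azimuthal stations
  n_s <- max(4L, round(sqrt(nodes_per_leaflet / 2)))
  n_t <- max(6L, ceiling(nodes_per_leaflet / n_s))

  s <- seq(0, 1, length.out = n_s)
  x_close <- x_open <- matrix(0, 0, 3)
  node_leaflet <- integer(0)
  node_s <- numeric(0)
  tri <- matrix(0L, 0, 3)
  tri_leaflet <- integer(0)
  free_edge <- vector("list", 3)

  for (l in 1:3) {
    th0 <- (l - 1) * 2 * pi / 3
    theta <- seq(th0, th0 + 2 * pi / 3, length.out = n_t)
    sv <- rep(s, each = n_t)
    tv <- rep(theta, times = n_s)
    # closed: radius shrinks linearly to 0, drooping to depth h_close
    rc <- R * (1 - sv)
    xc <- cbind(rc * cos(tv), rc * sin(tv), -sv * h_close)
    # open: swept onto the lumen wall, running downstream
    xo <- cbind(R * cos(tv), R * sin(tv), sv * Lf)
    offset <- nrow(x_close)
    x_close <- rbind(x_close, xc)
    x_open <- rbind(x_open, xo)
    node_leaflet <- c(node_leaflet, rep(l, n_s * n_t))
    node_s <- c(node_s, sv)
    # triangulate the structured grid
    for (i in 1:(n_s - 1)) {
      for (j in 1:(n_t - 1)) {
        a <- offset + (i - 1) * n_t + j
        b <- a + 1
        cc <- a + n_t
        d <- cc + 1
        tri <- rbind(tri, c(a, b, cc), c(b, d, cc))
        tri_leaflet <- c(tri_leaflet, l, l)
      }
    }
    free_edge[[l]] <- offset + (n_s - 1) * n_t + seq_len(n_t)
  }

  b <- x_open - x_close
  # pin the attached edge exactly
  b[node_s == 0, ] <- 0

  # element normals and areas on the open (reference) configuration -- the
  # configuration the ejection pressure load acts on; the closed funnel is
  # degenerate at the coaptation apex
  p1 <- x_open[tri[, 1], , drop = FALSE]
  p2 <- x_open[tri[, 2], , drop = FALSE]
  p3 <- x_open[tri[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  nrm <- sqrt(rowSums(cr^2))
  ds <- nrm / 2
  normals <- cr / nrm
  # orient outward (away from the annulus axis), the direction a positive
  # transvalvular pressure pushes the leaflet
  ctr <- (p1 + p2 + p3) / 3
  rad <- cbind(ctr[, 1], ctr[, 2], 0)
  rad <- rad / sqrt(rowSums(rad^2))
  flip <- rowSums(normals * rad) < 0
  normals[flip, ] <- -normals[flip, ]

  structure(list(
    x_close = x_close, x_open = x_open, b = b,
    node_leaflet = node_leaflet, node_s = node_s,
    tri = tri, tri_leaflet = tri_leaflet,
    normals = normals, ds = ds,
    free_edge = free_edge,
    radius = R, leaflet_length = Lf,
    coapt_depth = h_close,
    axis = c(0, 0, 1), origin = c(0, 0, 0),
    n_leaflets = 3L
  ), class = "valve_geometry")
}

# row-wise cross product of n x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Leaflet opening mapping functions
#'
#' The mapping function `xi(x, c)` interpolates each surface node between its
#' closed (`xi = 0`) and open (`xi = 1`) position as a function of the lumped
#' leaflet displacement `c(t)`. Two kinds are supported: `linear`,
#' `xi = c`, and `power`, `xi = c^beta(x)` with `beta > 0` (possibly varying
#' over the leaflet surface), which produces belly-first opening shapes.
#'
#' @param kind `"linear"` or `"power"`.
#' @param beta exponent for the power mapping (scalar, recycled per node, or
#'   a function of the arc-length coordinate `s`); must be positive.
#' @return an object of class `valve_mapping`.
#' @export
valve_mapping <- function(kind = c("linear", "power"), beta = 2) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.numeric(beta) && any(beta <= 0)) {
      stop("parameter error: beta must be positive")
    }
  }
  structure(list(kind = kind, beta = beta), class = "valve_mapping")
}

# per-node beta values for a geometry (power mapping)
mapping_beta <- function(mapping, s) {
  if (is.function(mapping$beta)) mapping$beta(s) else
    rep_len(mapping$beta, length(s))
}

#' Evaluate a mapping function and its derivatives in c
#'
#' Returns `xi(c)`, `d xi / dc` and `d^2 xi / dc^2` at displacement `c`.
#' For the power mapping with `beta < 2` the derivatives are singular at
#' `c = 0`; they are evaluated at `max(c, 1e-6)` (documented
#' regularization). `xi` itself is always exact.
#'
#' @param mapping a [valve_mapping()].
#' @param c lumped displacement in `[0, 1]` (scalar).
#' @param s arc-length coordinate(s) of the node(s), used when `beta`
#'   varies over the surface; default 0.5.
#' @return list with vectors `xi`, `dxi`, `d2xi` (one entry per node).
#' @export
evaluate_mapping <- function(mapping, c, s = 0.5) {
  stopifnot(inherits(mapping, "valve_mapping"))
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  n <- length(s)
  if (mapping$kind == "linear") {
    return(list(xi = rep(c, n), dxi = rep(1, n), d2xi = rep(0, n)))
  }
  beta <- mapping_beta(mapping, s)
  if (any(beta <= 0)) stop("parameter error: beta must be positive")
  creg <- max(c, 1e-6)
  list(
    xi = c^beta,
    dxi = beta * creg^(beta - 1),
    d2xi = beta * (beta - 1) * creg^(beta - 2)
  )
}

#' Instantaneous leaflet displacement and velocity fields
#'
#' Applies the kinematic ansatz: node displacement
#' `d_v(x, t) = b(x) * xi(x, c(t))` and velocity
#' `v_v(x, t) = (dc/dt) * (d xi/dc) * b(x)`, per leaflet.
#'
#' @param geometry a [build_valve_geometry()] object.
#' @param mapping a [valve_mapping()].
#' @param c per-leaflet lumped displacement (length 3, values in `[0, 1]`).
#' @param dcdt per-leaflet displacement rate (length 3, 1/s).
#' @return list with n x 3 matrices `displacement`, `velocity`, `position`
#'   (position = closed configuration + displacement).
#' @export
leaflet_kinematics <- function(geometry, mapping, c, dcdt = rep(0, 3)) {
  stopifnot(inherits(geometry, "valve_geometry"))
  c <- rep_len(c, geometry$n_leaflets)
  dcdt <- rep_len(dcdt, geometry$n_leaflets)
  n <- nrow(geometry$x_close)
  xi <- dxi <- numeric(n)
  for (l in seq_len(geometry$n_leaflets)) {
    idx <- geometry$node_leaflet == l
    ev <- evaluate_mapping(mapping, c[l], geometry$node_s[idx])
    xi[idx] <- ev$xi
    dxi[idx] <- ev$dxi * dcdt[l]
  }
  disp <- geometry$b * xi
  vel <- geometry$b * dxi
  list(displacement = disp, velocity = vel,
       position = geometry$x_close + disp)
}
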