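#' Homogeneous Kelvin-Voigt tissue medium
#'
#' The thorax between the aorta and the epidermal monitor point is modeled
#' as a homogeneous, isotropic, viscoelastic (Kelvin-Voigt) medium with
#' density `rho_s`, Lame parameters `lambda`, `mu` and viscosity `eta`.
#' Two derived speeds are stored: the bulk-modulus compression speed
#' `c_bulk = sqrt(K / rho_s)` with `K = lambda + 2 mu / 3`, and the P-wave
#' speed `c_p = sqrt((lambda + 2 mu) / rho_s)` used by the longitudinal
#' wavenumber. Both are kept because they are distinct physical quantities;
#' wave propagation uses `c_p`.
#'
#' Defaults are soft-tissue calibration values: `rho_s = 1000 kg/m^3`,
#' `mu = 2.5 kPa` (shear speed ~1.6 m/s), `lambda` chosen so that
#' `c_bulk ~ 30 m/s`, `eta = 1 Pa s`.
#'
#' @param rho_s density, kg/m^3.
#' @param lambda first Lame parameter, Pa (>= 0).
#' @param mu shear modulus, Pa (> 0).
#' @param eta Kelvin-Voigt shear viscosity, Pa s (>= 0).
#' @return object of class `tissue_medium` with fields `rho_s`, `lambda`,
#'   `mu`, `eta`, `K`, `c_bulk`, `c_p`, `c_s`.
#' @export
make_medium <- function(rho_s = 1000, lambda = 9e5 - 2 * 2500 / 3,
                        mu = 2500, eta = 1) {
  if (mu <= 0) stop("parameter error: mu must be positive")
  stopifnot(rho_s > 0, lambda >= 0, eta >= 0)
  K <- lambda + 2 * mu / 3
  structure(list(
    rho_s = rho_s, lambda = lambda, mu = mu, eta = eta,
    K = K,
    c_bulk = sqrt(K / rho_s),
    c_p = sqrt((lambda + 2 * mu) / rho_s),
    c_s = sqrt(mu / rho_s)
  ), class = "tissue_medium")
}

#' Longitudinal and shear wavenumbers of a viscoelastic medium
#'
#' Viscosity enters through the complex Kelvin-Voigt moduli
#' `mu* = mu - i omega eta` (and `lambda* = lambda`; the viscous stress has
#' the shear form), so for `eta > 0` the wavenumbers are complex with
#' positive imaginary part -- outgoing waves `exp(i k r)` decay.
#'
#' @param medium a [make_medium()] object.
#' @param omega angular frequency, rad/s (vectorized).
#' @return list with complex vectors `k_p = omega / sqrt((lambda* + 2 mu*)
#'   / rho_s)` and `k_s = omega / sqrt(mu* / rho_s)`, and the complex moduli
#'   `lambda_c`, `mu_c`.
#' @export
wavenumbers <- function(medium, omega) {
  stopifnot(inherits(medium, "tissue_medium"))
  mu_c <- medium$mu - 1i * omega * medium$eta
  lambda_c <- medium$lambda + 0i
  k_p <- omega / sqrt((lambda_c + 2 * mu_c) / medium$rho_s)
  k_s <- omega / sqrt(mu_c / medium$rho_s)
  # pick the decaying branch (Im k >= 0)
  k_p <- ifelse(Im(k_p) < 0, -k_p, k_p)
  k_s <- ifelse(Im(k_s) < 0, -k_s, k_s)
  list(k_p = k_p, k_s = k_s, lambda_c = lambda_c, mu_c = mu_c)
}

#' Spherical Hankel functions of the first kind (orders 0-2)
#'
#' Closed forms valid for complex argument:
#' `h0(z) = -i exp(iz) / z`,
#' `h1(z) = -(z + i) exp(iz) / z^2`,
#' `h2(z) = (i z^2 - 3 z - 3 i) exp(iz) / z^3`.
#'
#' @param n order (0, 1 or 2).
#' @param z complex argument (vectorized), nonzero.
#' @return complex vector.
#' @export
sph_hankel1 <- function(n, z) {
  e <- exp(1i * z)
  switch(as.character(n),
    "0" = -1i * e / z,
    "1" = -(z + 1i) * e / z^2,
    "2" = (1i * z^2 - 3 * z - 3i) * e / z^3,
    stop("order must be 0, 1 or 2")
  )
}

#' Free-space elastodynamic Green's tensor
#'
#' Frequency-domain displacement response at separation `r_vec` from a unit
#' point force in an unbounded isotropic (visco)elastic medium, in the
#' `exp(-i omega t)` time convention:
#' \deqn{G_{ij} = \frac{i k_p}{12\pi(\lambda+2\mu)}
#'   [\delta_{ij} h_0(k_p r) + \Delta_{ij} h_2(k_p r)] +
#'   \frac{i k_s}{12\pi\mu}
#'   [2 \delta_{ij} h_0(k_s r) - \Delta_{ij} h_2(k_s r)]}
#' with \eqn{\Delta_{ij} = \delta_{ij} - 3 x_i x_j / r^2} and `h_n` the
#' spherical Hankel functions of the first kind. The tensor is symmetric and
#' decays as `1/r` in the far field. For `eta > 0` the Lame parameters are
#' the complex Kelvin-Voigt moduli.
#'
#' @param r_vec length-3 separation vector (m), nonzero.
#' @param omega angular frequency (rad/s), nonzero.
#' @param medium a [make_medium()] object.
#' @return complex 3 x 3 matrix.
#' @export
greens_tensor <- function(r_vec, omega, medium) {
  r <- sqrt(sum(r_vec^2))
  if (r <= 0) stop("singularity error: source and receiver coincide")
  if (omega == 0) stop("omega must be nonzero (DC handled by caller)")
  kk <- wavenumbers(medium, omega)
  xhat <- r_vec / r
  Delta <- diag(3) - 3 * outer(xhat, xhat)
  I3 <- diag(3)
  zp <- kk$k_p * r
  zs <- kk$k_s * r
  term_p <- (1i * kk$k_p / (12 * pi * (kk$lambda_c + 2 * kk$mu_c))) *
    (I3 * sph_hankel1(0, zp) + Delta * sph_hankel1(2, zp))
  term_s <- (1i * kk$k_s / (12 * pi * kk$mu_c)) *
    (2 * I3 * sph_hankel1(0, zs) - Delta * sph_hankel1(2, zs))
  term_p + term_s
}
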