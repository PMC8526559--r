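#' Monitor point on the epidermis
#'
#' Default auscultation location for the aortic valve: 4 cm downstream of
#' (+z) and 8 cm anterior of (+y) the valve center, i.e. `(0, 0.08, 0.04)` m.
#'
#' @param coords length-3 position (m).
#' @return numeric length-3 vector of class `monitor_point`.
#' @export
monitor_point <- function(coords = c(0, 0.08, 0.04)) {
  stopifnot(length(coords) == 3)
  structure(as.numeric(coords), class = "monitor_point")
}

#' Surface-acceleration record
#'
#' @param a acceleration series (m/s^2).
#' @param fs sampling rate (Hz).
#' @param meta optional named list of metadata (scenario label, seed, ...).
#' @return object of class `acoustic_record` with fields `a`, `fs`, `time`,
#'   `meta`.
#' @export
acoustic_record <- function(a, fs, meta = list()) {
  structure(list(a = as.numeric(a), fs = fs,
                 time = seq_along(a) / fs - 1 / fs, meta = meta),
            class = "acoustic_record")
}

# Frequency-domain transfer matrix from panel pressures to one acceleration
# component at the monitor: H[f, k] = 2 (-i w)^2 G_nj(r_k, w) n_jk dA_k,
# in the exp(-i w t) physics convention. Rows = the requested positive
# angular frequencies, columns = panels. Cacheable across records that share
# panels/monitor/medium.
acoustic_transfer <- function(panels, monitor, medium, omegas,
                              component = 2L) {
  np <- nrow(panels$centroid)
  rvec <- -sweep(panels$centroid, 2, as.numeric(monitor)) # source -> monitor
  r <- sqrt(rowSums(rvec^2))
  if (any(r <= 0)) stop("singularity error: monitor coincides with a panel")
  xh <- rvec / r
  H <- matrix(0 + 0i, length(omegas), np)
  n <- panels$normal
  dA <- panels$area
  cN <- component
  for (f in seq_along(omegas)) {
    w <- omegas[f]
    kk <- wavenumbers(medium, w)
    zp <- kk$k_p * r
    zs <- kk$k_s * r
    h0p <- sph_hankel1(0, zp)
    h2p <- sph_hankel1(2, zp)
    h0s <- sph_hankel1(0, zs)
    h2s <- sph_hankel1(2, zs)
    ap <- 1i * kk$k_p / (12 * pi * (kk$lambda_c + 2 * kk$mu_c))
    as_ <- 1i * kk$k_s / (12 * pi * kk$mu_c)
    # G[cN, j] n_j summed over j, vectorized over panels:
    # delta part: (ap*h0p + 2*as_*h0s) * n_cN
    # Delta part: (ap*h2p - as_*h2s) * (n_cN - 3 xh_cN (xh . n))
    xn <- rowSums(xh * n)
    Gn <- (ap * h0p + 2 * as_ * h0s) * n[, cN] +
      (ap * h2p - as_ * h2s) * (n[, cN] - 3 * xh[, cN] * xn)
    H[f, ] <- 2 * (-1i * w)^2 * Gn * dA
  }
  H
}

#' Propagate panel pressure fluctuations to a monitor point
#'
#' Transforms each panel's pressure series to the frequency domain, applies
#' the per-panel elastodynamic transfer function
#' `a_n(w) = 2 sum_k (-i w)^2 G_nj(r_k, w) n_jk P_k(w) dA_k` over positive
#' frequencies up to `f_max` (DC zeroed: the sources are zero-mean
#' fluctuations and the tensor is singular at `w = 0`), enforces conjugate
#' symmetry and inverse-transforms to a real acceleration series.
#'
#' R's FFT synthesizes with `exp(+i w t)`; the tensor is defined in the
#' `exp(-i w t)` convention, so the positive-frequency bins are multiplied
#' by the conjugate transfer function.
#'
#' @param panels a [source_panels] object carrying `pressure` and `fs`
#'   (see [set_panel_pressures()]).
#' @param monitor a [monitor_point()].
#' @param medium a [make_medium()] object.
#' @param f_max upper frequency bound, Hz (default 1000; must be <= fs/2).
#' @param component acceleration axis: 1, 2 or 3 (or "x"/"y"/"z"); default
#'   the anterior (y) axis, normal to the chest wall.
#' @param transfer optional precomputed [acoustic_transfer] matrix for the
#'   retained bins (advanced use: amortizes the tensor evaluation over many
#'   records sharing geometry).
#' @return an [acoustic_record()].
#' @export
propagate <- function(panels, monitor = monitor_point(),
                      medium = make_medium(), f_max = 1000,
                      component = "y", transfer = NULL) {
  stopifnot(inherits(panels, "source_panels"))
  if (is.null(panels$pressure)) stop("input error: panels carry no pressure")
  fs <- panels$fs
  if (f_max > fs / 2) stop("f_max must not exceed fs/2")
  comp <- if (is.character(component)) match(component, c("x", "y", "z")) else
    as.integer(component)
  P <- panels$pressure
  N <- nrow(P)
  freqs <- (seq_len(N) - 1) * fs / N
  nbin <- max(which(freqs <= f_max & seq_len(N) <= floor(N / 2) + 1))
  bins <- 2:nbin # positive frequencies, DC excluded
  omegas <- 2 * pi * freqs[bins]
  if (is.null(transfer)) {
    transfer <- acoustic_transfer(panels, monitor, medium, omegas, comp)
  }
  Phat <- stats::mvfft(P)
  spec <- complex(length.out = N)
  spec[bins] <- rowSums(Conj(transfer) * Phat[bins, , drop = FALSE])
  spec[N + 2 - bins] <- Conj(spec[bins])
  a <- Re(stats::fft(spec, inverse = TRUE)) / N
  acoustic_record(a, fs)
}

#' Zero-phase band limiting of an acoustic record
#'
#' Removes spectral content above `f_max` by zeroing FFT bins (brickwall,
#' zero phase), the same convention the propagation step uses.
#'
#' @param record an [acoustic_record()].
#' @param f_max cutoff frequency, Hz (< fs/2); default 1000.
#' @return the filtered [acoustic_record()].
#' @export
band_limit <- function(record, f_max = 1000) {
  stopifnot(inherits(record, "acoustic_record"))
  record$a <- fft_lowpass(record$a, record$fs, f_max)
  record
}

# brickwall zero-phase low-pass via FFT bin zeroing (keeps DC)
fft_lowpass <- function(x, fs, f_max) {
  N <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(N) - 1) * fs / N
  f <- pmin(f, fs - f) # two-sided frequency magnitude
  X[f > f_max] <- 0
  Re(stats::fft(X, inverse = TRUE)) / N
}

# brickwall zero-phase band-pass (zero-mean output)
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  N <- if (is.matrix(x)) nrow(x) else length(x)
  X <- if (is.matrix(x)) stats::mvfft(x) else stats::fft(x)
  f <- (seq_len(N) - 1) * fs / N
  f <- pmin(f, fs - f)
  kill <- f < f_lo | f > f_hi
  if (is.matrix(x)) {
    X[kill, ] <- 0
    Re(stats::mvfft(X, inverse = TRUE)) / N
  } else {
    X[kill] <- 0
    Re(stats::fft(X, inverse = TRUE)) / N
  }
}
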