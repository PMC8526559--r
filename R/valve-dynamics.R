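#' Valve model parameters
#'
#' Lumped inertia and stiffness of the reduced degree-of-freedom valve
#' model. Healthy baseline: areal inertia `alpha = 40 kg/m^2` and stiffness
#' `kappa = 10,600 Pa/m`. Stenosis (reduced leaflet motion) is modeled by
#' per-leaflet multipliers (>= 1) on the stiffness.
#'
#' @param alpha leaflet areal inertia, kg/m^2.
#' @param kappa leaflet stiffness, Pa/m.
#' @param stiffness_multipliers length-3 vector of per-leaflet multipliers
#'   on `kappa`; all 1 for a healthy valve.
#' @return object of class `valve_params`.
#' @export
valve_params <- function(alpha = 40, kappa = 10600,
                         stiffness_multipliers = c(1, 1, 1)) {
  stopifnot(alpha > 0, kappa > 0)
  m <- rep_len(stiffness_multipliers, 3)
  if (any(m < 1)) stop("stiffness multipliers must be >= 1")
  structure(list(alpha = alpha, kappa = kappa,
                 stiffness_multipliers = m),
            class = "valve_params")
}

# per-leaflet element-level precomputation used by the force evaluation:
# element s-coordinate, b.n ds, and ds
element_tables <- function(geometry) {
  lapply(seq_len(geometry$n_leaflets), function(l) {
    el <- which(geometry$tri_leaflet == l)
    tr <- geometry$tri[el, , drop = FALSE]
    s_el <- (geometry$node_s[tr[, 1]] + geometry$node_s[tr[, 2]] +
               geometry$node_s[tr[, 3]]) / 3
    b_el <- (geometry$b[tr[, 1], , drop = FALSE] +
               geometry$b[tr[, 2], , drop = FALSE] +
               geometry$b[tr[, 3], , drop = FALSE]) / 3
    bn <- rowSums(b_el * geometry$normals[el, , drop = FALSE])
    list(elements = el, s = s_el, bn_ds = bn * geometry$ds[el],
         ds = geometry$ds[el])
  })
}

#' Lumped generalized forces of the valve ODE
#'
#' Surface integrals (element-wise midpoint quadrature) entering the lumped
#' displacement equation
#' `d2c/dt2 = (F_P - F_S - F_mV) / (alpha * int((dxi/dc) b.n ds))`:
#' \itemize{
#'   \item `F_P = int(dp ds)` -- transvalvular pressure load;
#'   \item `F_S = int(kappa (xi(c) - xi(0)) b.n ds)` -- elastic restoring
#'     force;
#'   \item `F_mV = alpha int((d2xi/dc2) (dc/dt)^2 b.n ds)` -- inertial term
#'     from nonlinear mappings (identically zero for the linear mapping).
#' }
#'
#' @param geometry a [build_valve_geometry()] object.
#' @param mapping a [valve_mapping()].
#' @param params a [valve_params()].
#' @param c,dcdt per-leaflet lumped displacement and rate (length 3).
#' @param dp transvalvular pressure difference: scalar, length-3 per-leaflet
#'   vector, or a per-element vector over all triangles (Pa).
#' @return data.frame with one row per leaflet: `F_P`, `F_S`, `F_mV` (N) and
#'   `denominator` (the `alpha int((dxi/dc) b.n ds)` term).
#' @export
lumped_forces <- function(geometry, mapping, params, c, dcdt = rep(0, 3),
                          dp = 0) {
  tabs <- element_tables(geometry)
  lumped_forces_fast(tabs, mapping, params, rep_len(c, 3),
                     rep_len(dcdt, 3), dp, geometry)
}

lumped_forces_fast <- function(tabs, mapping, params, c, dcdt, dp,
                               geometry = NULL) {
  n_el_total <- sum(vapply(tabs, function(t) length(t$elements), 1L))
  per_element <- length(dp) == n_el_total && n_el_total > 3
  out <- matrix(0, length(tabs), 4)
  for (l in seq_along(tabs)) {
    tab <- tabs[[l]]
    ev <- evaluate_mapping(mapping, clamp01(c[l])[1], tab$s)
    xi0 <- if (mapping$kind == "linear") rep(0, length(tab$s)) else
      0^mapping_beta(mapping, tab$s)
    kap <- params$kappa * params$stiffness_multipliers[l]
    dpl <- if (per_element) dp[tab$elements] else rep_len(dp, length(tabs))[l]
    F_P <- sum(dpl * tab$ds)
    F_S <- kap * sum((ev$xi - xi0) * tab$bn_ds)
    F_mV <- params$alpha * dcdt[l]^2 * sum(ev$d2xi * tab$bn_ds)
    denom <- params$alpha * sum(ev$dxi * tab$bn_ds)
    out[l, ] <- c(F_P, F_S, F_mV, denom)
  }
  df <- as.data.frame(out)
  names(df) <- c("F_P", "F_S", "F_mV", "denominator")
  df$leaflet <- seq_along(tabs)
  df
}

#' Integrate the lumped valve displacement ODE
#'
#' Advances `d2c/dt2 = (F_P - F_S - F_mV) / denominator` per leaflet with an
#' explicit RK4 scheme at step `dt`. The displacement is clamped to `[0, 1]`
#' with the rate zeroed on contact (perfectly inelastic stop) -- the sound
#' sources in this pipeline are pressure fluctuations, not leaflet impacts.
#'
#' @param geometry a [build_valve_geometry()] object.
#' @param mapping a [valve_mapping()].
#' @param params a [valve_params()].
#' @param dp driving transvalvular pressure: `function(t, c, dcdt)`
#'   returning a scalar or per-leaflet Pa value (functions of `t` only are
#'   also accepted).
#' @param t_span length-2 time interval (s).
#' @param dt time step (s); also the output grid spacing. Default 1e-4
#'   (matches the 10 kHz acoustic sampling grid).
#' @param c0,dcdt0 initial per-leaflet displacement and rate.
#' @return object of class `valve_trajectory`: `time`, matrices `c` and
#'   `dcdt` (T x 3), `pvoa_cm2`, and the geometry/mapping/params used.
#' @export
integrate_valve <- function(geometry, mapping, params, dp,
                            t_span = c(0, 0.5), dt = 1e-4,
                            c0 = rep(0, 3), dcdt0 = rep(0, 3)) {
  stopifnot(dt > 0, length(t_span) == 2, t_span[2] > t_span[1])
  tabs <- element_tables(geometry)
  dp_fun <- if (length(formals(dp)) >= 3) dp else function(t, c, dcdt) dp(t)
  nl <- geometry$n_leaflets
  c <- clamp01(rep_len(c0, nl))
  v <- rep_len(dcdt0, nl)

  # fast scalar path: reduce the surface integrals once when xi is uniform
  # over each leaflet (linear mapping, or power mapping with scalar beta)
  uniform <- mapping$kind == "linear" ||
    (is.numeric(mapping$beta) && length(mapping$beta) == 1)
  S_l <- vapply(tabs, function(t) sum(t$ds), 1)
  B_l <- vapply(tabs, function(t) sum(t$bn_ds), 1)
  kap <- params$kappa * params$stiffness_multipliers
  beta <- if (mapping$kind == "power") mapping$beta[1] else 1

  deriv <- function(t, c, v) {
    cc <- clamp01(c)
    dpl <- rep_len(dp_fun(t, cc, v), nl)
    if (uniform) {
      if (mapping$kind == "linear") {
        acc <- (dpl * S_l - kap * cc * B_l) / (params$alpha * B_l)
      } else {
        cr <- pmax(cc, 1e-6)
        F_P <- dpl * S_l
        F_S <- kap * cc^beta * B_l
        F_mV <- params$alpha * beta * (beta - 1) * cr^(beta - 2) * v^2 * B_l
        den <- params$alpha * beta * cr^(beta - 1) * B_l
        acc <- (F_P - F_S - F_mV) / den
      }
    } else {
      ff <- lumped_forces_fast(tabs, mapping, params, cc, v, dpl)
      acc <- (ff$F_P - ff$F_S - ff$F_mV) / ff$denominator
    }
    if (any(abs(B_l) < .Machine$double.eps)) {
      stop("singular-configuration error: zero denominator integral")
    }
    acc
  }

  n_steps <- round((t_span[2] - t_span[1]) / dt)
  time <- t_span[1] + dt * (0:n_steps)
  C <- matrix(0, n_steps + 1, nl)
  V <- matrix(0, n_steps + 1, nl)
  C[1, ] <- c
  V[1, ] <- v
  for (k in seq_len(n_steps)) {
    t <- time[k]
    a1 <- deriv(t, c, v)
    c2 <- c + dt / 2 * v
    v2 <- v + dt / 2 * a1
    a2 <- deriv(t + dt / 2, c2, v2)
    c3 <- c + dt / 2 * v2
    v3 <- v + dt / 2 * a2
    a3 <- deriv(t + dt / 2, c3, v3)
    c4 <- c + dt * v3
    v4 <- v + dt * a3
    a4 <- deriv(t + dt, c4, v4)
    c <- c + dt / 6 * (v + 2 * v2 + 2 * v3 + v4)
    v <- v + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4)
    if (any(!is.finite(c)) || any(!is.finite(v))) {
      stop(sprintf("integration-failure error at t = %.6g s", t + dt))
    }
    # contact: clamp and zero the rate
    hi <- c > 1
    lo <- c < 0
    c[hi] <- 1
    c[lo] <- 0
    v[hi & (v > 0)] <- 0
    v[lo & (v < 0)] <- 0
    C[k + 1, ] <- c
    V[k + 1, ] <- v
  }

  Q <- pvoa_quadratic_form(geometry)
  xi_traj <- if (mapping$kind == "linear") C else C^beta
  pvoa <- pvoa_from_xi(xi_traj, Q)

  structure(list(
    time = time, c = C, dcdt = V,
    pvoa_cm2 = pvoa * 1e4,
    dt = dt, geometry = geometry, mapping = mapping, params = params
  ), class = "valve_trajectory")
}

#' Detect kinematic valve events
#'
#' Finds, per leaflet, the first direction-reversal instant (first sign
#' change of `dc/dt` from positive to negative after opening onset), the
#' closure instant (first time after peak opening with `c` below the closure
#' tolerance) and the halfway-closure instant (first time after peak opening
#' with `c` below half the leaflet's peak value). A leaflet that never opens
#' (peak below tolerance) reports all events as `NA`.
#'
#' @param trajectory a [integrate_valve()] result.
#' @param closure_tol displacement below which the leaflet counts as closed
#'   (fraction of full range); default 0.02.
#' @param halfway_frac fraction of peak displacement defining halfway
#'   closure; default 0.5.
#' @return data.frame with columns `leaflet`, `reversal`, `closure`,
#'   `halfway`, `peak_c`, `peak_time` (times in s, `NA` when absent).
#' @export
detect_events <- function(trajectory, closure_tol = 0.02,
                          halfway_frac = 0.5) {
  tt <- trajectory$time
  nl <- ncol(trajectory$c)
  out <- data.frame(leaflet = seq_len(nl), reversal = NA_real_,
                    closure = NA_real_, halfway = NA_real_,
                    peak_c = NA_real_, peak_time = NA_real_)
  for (l in seq_len(nl)) {
    c <- trajectory$c[, l]
    v <- trajectory$dcdt[, l]
    pk <- which.max(c)
    out$peak_c[l] <- c[pk]
    out$peak_time[l] <- tt[pk]
    if (c[pk] < closure_tol) next # never opens
    onset <- which(c > closure_tol)[1]
    # first + -> - transition of the rate after opening onset
    if (onset < length(v)) {
      vv <- v[onset:length(v)]
      hit <- which(cumsum(vv > 0) > 0 & vv < 0)
      if (length(hit) > 0) out$reversal[l] <- tt[onset + hit[1] - 1]
    }
    if (pk < length(c)) {
      cl <- which(c[(pk + 1):length(c)] < closure_tol)
      if (length(cl) > 0) out$closure[l] <- tt[pk + cl[1]]
      hw <- which(c[(pk + 1):length(c)] < halfway_frac * c[pk])
      if (length(hw) > 0) out$halfway[l] <- tt[pk + hw[1]]
    }
  }
  out
}
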