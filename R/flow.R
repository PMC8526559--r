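#' Systolic flow-rate waveform
#'
#' Smooth two-piece raised-cosine ejection pulse: flow rises from zero at
#' `t = 0` to its peak at `t/T = 0.12` (peak systole), falls back to zero at
#' `t/T = 0.35` (end of systolic ejection) and stays zero through diastole.
#' The pulse is scaled so its time integral over the beat equals the stroke
#' volume, hence mean flow = SV / T (72 ml at 60 bpm gives a 4.32 l/min
#' cardiac output; 60 ml gives 3.6 l/min).
#'
#' @param sv_ml stroke volume, ml.
#' @param T_beat beat period, s (default 1.0, i.e. 60 bpm).
#' @param fs sampling rate, Hz.
#' @param t_peak,t_end peak and end of ejection as fractions of `T_beat`.
#' @return object of class `flow_waveform`: sampled `time` (s) and `Q`
#'   (m^3/s) over one beat, plus analytic evaluators `Q_fun(t)` and
#'   `dQdt_fun(t)` and the scalar parameters.
#' @export
flow_waveform <- function(sv_ml = 72, T_beat = 1.0, fs = 10000,
                          t_peak = 0.12, t_end = 0.35) {
  stopifnot(sv_ml >= 0, T_beat > 0, t_peak > 0, t_end > t_peak)
  sv <- sv_ml * 1e-6 # m^3
  tp <- t_peak * T_beat
  te <- t_end * T_beat
  # integral of the two raised-cosine lobes is Qp * te / 2
  Qp <- 2 * sv / te
  Q_fun <- function(t) {
    t <- t %% T_beat
    q <- numeric(length(t))
    up <- t <= tp
    dn <- t > tp & t <= te
    q[up] <- Qp * (1 - cos(pi * t[up] / tp)) / 2
    q[dn] <- Qp * (1 + cos(pi * (t[dn] - tp) / (te - tp))) / 2
    q
  }
  dQdt_fun <- function(t) {
    t <- t %% T_beat
    g <- numeric(length(t))
    up <- t <= tp
    dn <- t > tp & t <= te
    g[up] <- Qp * pi / (2 * tp) * sin(pi * t[up] / tp)
    g[dn] <- -Qp * pi / (2 * (te - tp)) * sin(pi * (t[dn] - tp) / (te - tp))
    g
  }
  time <- seq(0, T_beat - 1 / fs, by = 1 / fs)
  structure(list(time = time, Q = Q_fun(time),
                 Q_fun = Q_fun, dQdt_fun = dQdt_fun,
                 sv_ml = sv_ml, T_beat = T_beat, fs = fs,
                 t_peak = t_peak, t_end = t_end, Q_peak = Qp),
            class = "flow_waveform")
}

#' Quasi-steady orifice pressure-drop surrogate
#'
#' Surrogate transvalvular load driving the valve ODE: a Bernoulli orifice
#' term plus a lumped inertial (inertance) term,
#' `dp = 0.5 rho0 (Q / A_eff)^2 sign(Q) + L dQ/dt`,
#' with the effective orifice area floored at `area_floor` to keep the drop
#' finite at valve closure. `L = rho0 * inertance_length / inertance_area`
#' models the acceleration of the blood column through the valve.
#'
#' @param Q flow rate series, m^3/s.
#' @param pvoa projected valve open area series, m^2 (same length or scalar).
#' @param dQdt flow-rate derivative series, m^3/s^2 (default: central
#'   differences of `Q` require `fs`).
#' @param rho0 blood density, kg/m^3 (default 1060).
#' @param area_floor minimum effective area, m^2 (default 1.5 cm^2: the
#'   residual LVOT/leak relief area seen by the blood column when the valve
#'   itself is closed).
#' @param inertance_length,inertance_area effective blood-column length (m)
#'   and area (m^2) of the inertance.
#' @param fs sampling rate (Hz), used only when `dQdt` is not supplied.
#' @return pressure-drop series, Pa.
#' @export
orifice_pressure_drop <- function(Q, pvoa, dQdt = NULL, rho0 = 1060,
                                  area_floor = 1.5e-4,
                                  inertance_length = 0.01,
                                  inertance_area = 3e-4, fs = NULL) {
  if (any(pvoa < 0)) stop("input error: negative PVOA")
  A <- pmax(pvoa, area_floor)
  if (is.null(dQdt)) {
    if (is.null(fs)) stop("supply dQdt or fs")
    n <- length(Q)
    dQdt <- c(Q[2] - Q[1], (Q[3:n] - Q[1:(n - 2)]) / 2, Q[n] - Q[n - 1]) * fs
  }
  L <- rho0 * inertance_length / inertance_area
  0.5 * rho0 * (Q / A)^2 * sign(Q) + L * dQdt
}
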