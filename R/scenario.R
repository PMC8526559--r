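#' Hemodynamic scenario definition
#'
#' Bundles the valve condition and flow settings of one simulated beat.
#' `"healthy"` leaves all three leaflets at baseline stiffness; `"rlm1"`
#' stiffens one leaflet and `"rlm2"` two (reduced leaflet motion), by the
#' stiffness `multiplier`. Murmur gain and noise floor scale the turbulent
#' panel-pressure synthesis.
#'
#' @param label `"healthy"`, `"rlm1"`, `"rlm2"` or `"custom"`.
#' @param multiplier stiffness multiplier (>= 1) applied to the affected
#'   leaflets (ignored for `"healthy"`).
#' @param multipliers explicit length-3 multiplier vector (overrides
#'   `label`/`multiplier`; required for `"custom"`).
#' @param sv_ml stroke volume, ml (60 or 72 in the default grid).
#' @param murmur_gain turbulent murmur pressure per unit total stiffness
#'   excess, Pa (default 0.5).
#' @param murmur_coherence fraction of murmur energy carried by the
#'   phase-locked coherent component (large-scale jet structures repeatable
#'   across beats and panels), vs panel-independent fine-scale turbulence;
#'   default 0.5.
#' @param click_gain ejection-click pressure per unit peak stiffness excess,
#'   Pa (default 1.5).
#' @param s2_gain closure (S2) impulse pressure, Pa (default 40).
#' @param noise_floor broadband background pressure RMS, Pa (default 2).
#' @param seed RNG seed for the stochastic panel synthesis.
#' @return object of class `hemo_scenario`.
#' @export
hemodynamic_scenario <- function(label = c("healthy", "rlm1", "rlm2",
                                           "custom"),
                                 multiplier = 8, multipliers = NULL,
                                 sv_ml = 72, murmur_gain = 0.5,
                                 murmur_coherence = 0.5,
                                 click_gain = 1.5, s2_gain = 40,
                                 noise_floor = 2, seed = 0L) {
  label <- match.arg(label)
  if (is.null(multipliers)) {
    multipliers <- switch(label,
      healthy = c(1, 1, 1),
      rlm1 = c(multiplier, 1, 1),
      rlm2 = c(multiplier, multiplier, 1),
      custom = stop("custom scenarios need explicit multipliers")
    )
  }
  multipliers <- rep_len(multipliers, 3)
  if (any(multipliers < 1)) stop("multipliers must be >= 1")
  if (label == "healthy" && any(multipliers != 1)) {
    stop("healthy scenario must have all multipliers equal to 1")
  }
  stopifnot(murmur_coherence >= 0, murmur_coherence <= 1)
  structure(list(label = label, multipliers = multipliers, sv_ml = sv_ml,
                 murmur_gain = murmur_gain,
                 murmur_coherence = murmur_coherence,
                 click_gain = click_gain,
                 s2_gain = s2_gain, noise_floor = noise_floor,
                 seed = as.integer(seed)),
            class = "hemo_scenario")
}

#' Simulate one cardiac cycle of coupled valve motion
#'
#' Integrates the lumped valve ODE with the orifice pressure-drop surrogate
#' evaluated self-consistently inside the integrator: at each step the
#' current leaflet openings give the projected open area (exact quadratic
#' form), which with the instantaneous flow rate yields the leaflet-uniform
#' transvalvular load.
#'
#' @param scenario a [hemodynamic_scenario()].
#' @param geometry a [build_valve_geometry()] object.
#' @param mapping a [valve_mapping()] (default linear).
#' @param params baseline [valve_params()]; the scenario's stiffness
#'   multipliers are applied on top.
#' @param fs sampling rate, Hz.
#' @param duration simulated record length, s (default 0.5: systole plus
#'   early diastole of a 1 s beat).
#' @param T_beat beat period, s.
#' @return a `valve_trajectory` (see [integrate_valve()]) with the flow
#'   waveform attached as attribute `flow`.
#' @export
simulate_valve_cycle <- function(scenario, geometry = build_valve_geometry(),
                                 mapping = valve_mapping("linear"),
                                 params = valve_params(),
                                 fs = 10000, duration = 0.5, T_beat = 1.0) {
  stopifnot(inherits(scenario, "hemo_scenario"))
  params$stiffness_multipliers <- scenario$multipliers
  flow <- flow_waveform(sv_ml = scenario$sv_ml, T_beat = T_beat, fs = fs)
  Qf <- pvoa_quadratic_form(geometry)
  beta <- if (mapping$kind == "power") mapping$beta[1] else 1
  dp <- function(t, c, dcdt) {
    xi <- if (mapping$kind == "linear") clamp01(c) else clamp01(c)^beta
    A <- max(sum((xi %*% Qf) * xi), 0)
    orifice_pressure_drop(flow$Q_fun(t), A, dQdt = flow$dQdt_fun(t))
  }
  traj <- integrate_valve(geometry, mapping, params, dp,
                          t_span = c(0, duration), dt = 1 / fs)
  attr(traj, "flow") <- flow
  attr(traj, "scenario") <- scenario
  traj
}

# fixed coherent murmur fine-structure: a band-limited, unit-variance
# waveform deterministic in (N, fs, band) -- the repeatable, flow-phase-
# locked part of the jet pressure, identical for every case and panel
murmur_reference_waveform <- function(N, fs, band) {
  m0 <- with_seed(902781L, stats::rnorm(N))
  m0 <- fft_bandpass(m0, fs, band[1], band[2])
  m0 / stats::sd(m0)
}

# critically damped impulse wavelet g(u) = (u/tau) exp(1 - u/tau), peak 1 at
# u = tau; effective width ~4 tau
impulse_wavelet <- function(time, t0, tau = 0.00125, amp = 1) {
  u <- time - t0
  w <- numeric(length(time))
  pos <- u >= 0
  w[pos] <- (u[pos] / tau) * exp(1 - u[pos] / tau)
  amp * w
}

#' Piecewise-linear stenotic murmur envelope
#'
#' The crescendo-decrescendo ("diamond") envelope of the systolic murmur:
#' zero before `t/T = 0.06`, rising linearly to 1 at `t/T = 0.18`, falling
#' linearly back to zero at `t/T = 0.35`, zero afterwards.
#'
#' @param time sample times, s.
#' @param T_beat beat period, s.
#' @param onset,peak,end envelope breakpoints as fractions of `T_beat`.
#' @return non-negative envelope series (unit peak).
#' @export
murmur_envelope <- function(time, T_beat = 1.0, onset = 0.06, peak = 0.18,
                            end = 0.35) {
  stopifnot(onset < peak, peak < end)
  x <- (time / T_beat)
  e <- numeric(length(x))
  up <- x >= onset & x <= peak
  dn <- x > peak & x <= end
  e[up] <- (x[up] - onset) / (peak - onset)
  e[dn] <- (end - x[dn]) / (end - peak)
  e
}

#' Synthesize panel pressure fluctuations for a scenario
#'
#' Paints onto each lumen panel the surrogate acoustic source field
#' reproducing the phenomenology of healthy and stenotic beats:
#' \itemize{
#'   \item a stenotic murmur: envelope-modulated, band-limited (100-600 Hz)
#'     pressure with amplitude `murmur_gain * (sum(multipliers) - 3)` --
#'     zero for a healthy valve. A fraction `murmur_coherence` of its energy
#'     is a fixed, flow-phase-locked waveform shared by all panels (the
#'     repeatable large-scale jet-impingement structures); the remainder is
#'     fine-scale turbulence independent across panels and cases;
#'   \item an ejection click at the stiffest leaflet's first
#'     direction-reversal instant, amplitude
#'     `click_gain * (max(multipliers) - 1)`, coherent across panels;
#'   \item S2 closure impulses at each leaflet's closure instant, coherent
#'     across panels, attenuated by `exp(-delay / s2_decay)` where `delay`
#'     is the closure lag past the end of systolic ejection (`t/T = 0.35`)
#'     -- late-closing leaflets sound diminished;
#'   \item a broadband background noise floor, independent across panels.
#' }
#' Every panel series is made exactly zero-mean. Deterministic given the
#' scenario seed.
#'
#' @param scenario a [hemodynamic_scenario()].
#' @param trajectory the matching [simulate_valve_cycle()] result.
#' @param panels a [build_canonical_aorta()] panel set.
#' @param fs sampling rate, Hz.
#' @param T_beat beat period, s.
#' @param s2_decay attenuation time constant for late closure, in t/T units
#'   (default 0.035).
#' @param murmur_band murmur noise band, Hz.
#' @return the panel set with an N x n_panels `pressure` matrix attached.
#' @export
synthesize_panel_pressures <- function(scenario, trajectory, panels,
                                       fs = 10000, T_beat = 1.0,
                                       s2_decay = 0.035,
                                       murmur_band = c(100, 600)) {
  stopifnot(inherits(scenario, "hemo_scenario"),
            inherits(trajectory, "valve_trajectory"),
            inherits(panels, "source_panels"))
  time <- trajectory$time[-1] # output grid, N = duration * fs samples
  N <- length(time)
  np <- nrow(panels$centroid)
  events <- detect_events(trajectory)
  excess_total <- sum(scenario$multipliers) - 3
  excess_peak <- max(scenario$multipliers) - 1

  P <- with_seed(scenario$seed, {
    # background noise floor, independent per panel
    noise <- matrix(stats::rnorm(N * np), N, np)
    noise <- fft_bandpass(noise, fs, 20, 900)
    noise <- sweep(noise, 2, apply(noise, 2, stats::sd), "/") *
      scenario$noise_floor
    # murmur: envelope-modulated band pressure, coherent + incoherent parts
    if (excess_total > 0) {
      coh <- scenario$murmur_coherence
      w <- matrix(stats::rnorm(N * np), N, np)
      w <- fft_bandpass(w, fs, murmur_band[1], murmur_band[2])
      w <- sweep(w, 2, apply(w, 2, stats::sd), "/") * sqrt(1 - coh)
      if (coh > 0) {
        m0 <- murmur_reference_waveform(N, fs, murmur_band)
        w <- w + sqrt(coh) * m0
      }
      env <- murmur_envelope(time, T_beat)
      noise <- noise + (scenario$murmur_gain * excess_total) * (w * env)
    }
    noise
  })

  # deterministic impulses, coherent across panels
  imp <- numeric(N)
  if (excess_peak > 0) {
    stiffest <- which.max(scenario$multipliers)
    t_click <- events$reversal[stiffest]
    if (!is.na(t_click)) {
      imp <- imp + impulse_wavelet(time, t_click,
                                   amp = scenario$click_gain * excess_peak)
    }
  }
  t_cl <- events$closure
  if (any(is.na(t_cl))) {
    warning("missing closure events: S2 impulses omitted for leaflets ",
            paste(which(is.na(t_cl)), collapse = ", "))
  }
  for (t0 in unique(stats::na.omit(t_cl))) {
    delay <- max(0, t0 / T_beat - 0.35)
    imp <- imp + impulse_wavelet(time, t0,
                                 amp = scenario$s2_gain *
                                   exp(-delay / s2_decay))
  }
  P <- P + imp
  P <- sweep(P, 2, colMeans(P)) # enforce zero time mean per panel
  set_panel_pressures(panels, P, fs)
}
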