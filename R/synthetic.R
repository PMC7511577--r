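#' Specification of a synthetic coupled theta-gamma signal
#'
#' Ground-truth test signal for the coupling metrics: a slow (theta)
#' carrier plus a fast (gamma) oscillation whose amplitude envelope is
#' modulated by the theta phase with controllable depth, plus additive
#' white Gaussian noise.  The generated signal is
#' `x(t) = A_th sin(2 pi f_th t)
#'        + A_ga * [1 - chi_c + chi_c (1 + cos(theta(t) - phi_c))/2]
#'          * sin(2 pi f_ga t) + noise`,
#' where `theta(t)` is the theta phase under the package's default
#' ascending-zero convention (0 degrees at the upward zero-crossing of the
#' theta carrier, matching [decompose()]), so the gamma envelope is
#' maximal at theta phase `phi_c`.  `chi_c = 0` gives a constant envelope (no coupling);
#' `chi_c = 1` gives full modulation (envelope reaches 0), aligning the
#' height ratio's \[0, 1\] range with the coupling depth.
#'
#' @param theta_freq,theta_amp Theta frequency (Hz) and amplitude (mV).
#' @param gamma_freq,gamma_amp Gamma frequency (Hz) and base amplitude
#'   (mV).
#' @param coupling_depth chi_c in \[0, 1\].
#' @param coupling_phase_deg phi_c: theta phase (deg) of maximal gamma
#'   envelope.
#' @param noise_sd Additive white Gaussian noise SD, mV.
#' @param duration_ms Duration, ms.
#' @param fs Sampling rate, Hz (>= 20x the gamma frequency).
#' @param seed Integer seed; the generated series is deterministic given
#'   the spec.
#' @return A `coupled_signal_spec` list.
#' @export
coupled_signal_spec <- function(theta_freq = 4, theta_amp = 5,
                                gamma_freq = 40, gamma_amp = 1,
                                coupling_depth = 0.5,
                                coupling_phase_deg = 270,
                                noise_sd = 0, duration_ms = 3000,
                                fs = 1000, seed = 1L) {
  if (coupling_depth < 0 || coupling_depth > 1)
    stop("coupling_depth must lie in [0, 1]")
  if (fs < 20 * gamma_freq)
    stop("sampling rate must be at least 20x the gamma frequency")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(theta_freq = theta_freq, theta_amp = theta_amp,
                 gamma_freq = gamma_freq, gamma_amp = gamma_amp,
                 coupling_depth = coupling_depth,
                 coupling_phase_deg = coupling_phase_deg,
                 noise_sd = noise_sd, duration_ms = duration_ms,
                 fs = fs, seed = as.integer(seed)),
            class = "coupled_signal_spec")
}

#' Generate a synthetic coupled theta-gamma signal
#'
#' @param spec A [coupled_signal_spec()].
#' @return data.frame with `time_ms` and `v_mV`; the ground truth
#'   (`spec`, and the noiseless `envelope`) is attached as attributes.
#' @export
#' @examples
#' x <- generate_coupled(coupled_signal_spec(coupling_depth = 1))
#' r <- compute_cfc(x)
#' r$height_ratio   # ~1: envelope reaches zero once per theta cycle
generate_coupled <- function(spec) {
  stopifnot(inherits(spec, "coupled_signal_spec"))
  t_s <- seq(0, spec$duration_ms / 1000, by = 1 / spec$fs)
  t_s <- t_s[-length(t_s)]
  # ascending-zero theta phase: for a sine carrier this is simply the
  # carrier argument
  theta_phase <- (360 * spec$theta_freq * t_s) %% 360
  chi <- spec$coupling_depth
  env <- spec$gamma_amp *
    (1 - chi + chi * (1 + cos((theta_phase - spec$coupling_phase_deg) *
                                pi / 180)) / 2)
  x <- spec$theta_amp * sin(2 * pi * spec$theta_freq * t_s) +
    env * sin(2 * pi * spec$gamma_freq * t_s)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    x <- x + stats::rnorm(length(x), sd = spec$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(data.frame(time_ms = t_s * 1000, v_mV = x),
            spec = spec, envelope = env)
}

#' Closed-form passive-membrane (RC) response fixture
#'
#' Exact response of a single-compartment passive membrane (resistance `R`,
#' capacitance `C`, resting potential `v_rest`) to step and sinusoidal
#' current sources, sampled on the simulator time base.  Steps follow
#' `v_rest + I R (1 - exp(-t/RC))` from their onset; sinusoids follow the
#' impedance solution with steady-state amplitude `I R / sqrt(1 + (w R
#' C)^2)` and phase lag `atan(w R C)`, plus the decaying transient that
#' makes the response start from rest.  Used as an independent oracle for
#' the cable integrator.
#'
#' @param R Membrane resistance, MOhm.
#' @param C Membrane capacitance, nF.
#' @param protocol An `injection_protocol` (sites are ignored: all sources
#'   drive the single compartment).
#' @param duration_ms,dt Sampling window and step, ms.
#' @param v_rest Resting potential, mV.
#' @return data.frame with `time_ms`, `v_mV`.
#' @export
generate_passive_fixture <- function(R, C, protocol, duration_ms,
                                     dt = 0.5, v_rest = 0) {
  if (R <= 0 || C <= 0) stop("R and C must be positive")
  t <- seq(0, duration_ms, by = dt)
  tau <- R * C                                   # MOhm * nF = ms
  v <- rep(v_rest, length(t))
  for (s in seq_len(nrow(protocol))) {
    on <- protocol$onset_ms[s]
    off <- protocol$offset_ms[s]
    amp <- protocol$amplitude_nA[s]
    tt <- pmax(t - on, 0)
    active <- t >= on & t < off
    if (protocol$waveform[s] == "step") {
      v <- v + active * amp * R * (1 - exp(-tt / tau))
    } else {
      w <- 2 * pi * protocol$frequency_Hz[s] * 1e-3   # rad/ms
      ph0 <- protocol$phase_deg[s] * pi / 180
      gain <- amp * R / sqrt(1 + (w * tau)^2)
      lag <- atan(w * tau)
      # particular solution plus transient chosen so v(onset) = rest and
      # dv/dt matches the ODE
      vp <- gain * sin(w * tt + ph0 - lag)
      v0 <- gain * sin(ph0 - lag)
      v <- v + active * (vp - v0 * exp(-tt / tau))
    }
  }
  data.frame(time_ms = t, v_mV = v)
}
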