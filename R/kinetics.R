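#' Default gating-kinetics configuration
#'
#' One configuration object holds every voltage- (and calcium-) dependent
#' gating law used by the models, so an alternative kinetics set (e.g. an
#' exact published rate-equation set for this cell class) can be swapped
#' in without touching code.  Each channel has a reversal-potential name, a list of gates, and
#' two flags: `ca_gated` (open probability is additionally multiplied by the
#' Michaelis factor chi/(chi + kd) of the intracellular calcium pool) and
#' `ca_current` (the channel's current feeds the calcium pool).  Each gate
#' has an integer `power`, a Boltzmann steady state
#' `1/(1 + exp((v_half - V)/k))` (negative `k` gives a gate that closes with
#' depolarization, as for Ih and inactivation gates), and a time constant
#' that is either constant or bell-shaped in voltage,
#' `tau_min + amp/(exp((V - v_peak)/k1) + exp(-(V - v_peak)/k2))` (ms).
#'
#' The centerpiece is the anomalous-rectifier Ih gate: hyperpolarization-
#' activated (half-activation -75 mV, slope 5.5 mV) with a bell-shaped time
#' constant peaking at ~210 ms near rest, so Ih gating follows the 4 Hz
#' theta modulation with a lag but cannot follow the 40 Hz signal at all.
#' The remaining channels use standard Hodgkin-Huxley sigmoid/bell defaults
#' of the regular-spiking pyramidal-cell lineage, with the potassium
#' channels' activation placed steeply near/above threshold so that they
#' are quiescent over the subthreshold operating range and Ih is the
#' dominant slow subthreshold conductance; the fast sodium channel is
#' absent because its density is zero at every level.
#'
#' @param version Character tag recorded in outputs so results can cite the
#'   kinetics set used.
#' @return A nested list: `$channels`, `$ca_pool`, `$reversals`, `$version`.
#' @export
kinetics_defaults <- function(version = "ihcfc-default-1") {
  gate <- function(power, v_half, k, tau) {
    list(power = power, v_half = v_half, k = k, tau = tau)
  }
  tau_const <- function(ms) list(type = "const", tau = ms)
  tau_bell <- function(v_peak, k1, k2, amp, tau_min) {
    list(type = "bell", v_peak = v_peak, k1 = k1, k2 = k2, amp = amp,
         tau_min = tau_min)
  }
  list(
    version = version,
    reversals = c(E_Na = 50, E_K = -95, E_Ca = 125, E_h = -40),
    ca_pool = list(gain = 50, tau = 50, kd = 250),
    channels = list(
      h = list(reversal = "E_h", ca_gated = FALSE, ca_current = FALSE,
               gates = list(m = gate(1, -75, -5.5,
                                     tau_bell(-70, 20, 20, 380, 20)))),
      NaP = list(reversal = "E_Na", ca_gated = FALSE, ca_current = FALSE,
                 gates = list(m = gate(1, -45, 4,
                                       tau_bell(-40, 10, 10, 3, 1)))),
      KDR = list(reversal = "E_K", ca_gated = FALSE, ca_current = FALSE,
                 gates = list(n = gate(2, -25, 5,
                                       tau_bell(-25, 15, 15, 6, 1)))),
      KA = list(reversal = "E_K", ca_gated = FALSE, ca_current = FALSE,
                gates = list(a = gate(1, -30, 5, tau_const(5)),
                             b = gate(1, -70, -6, tau_const(20)))),
      KM = list(reversal = "E_K", ca_gated = FALSE, ca_current = FALSE,
                gates = list(m = gate(1, -30, 5,
                                      tau_bell(-30, 15, 15, 900, 50)))),
      K2 = list(reversal = "E_K", ca_gated = TRUE, ca_current = FALSE,
                gates = list(m = gate(1, -30, 5, tau_const(1000)))),
      KC = list(reversal = "E_K", ca_gated = TRUE, ca_current = FALSE,
                gates = list(m = gate(1, -20, 8, tau_const(2)))),
      CaH = list(reversal = "E_Ca", ca_gated = FALSE, ca_current = TRUE,
                 gates = list(m = gate(2, -10, 6, tau_const(2)))),
      CaL = list(reversal = "E_Ca", ca_gated = FALSE, ca_current = TRUE,
                 gates = list(m = gate(1, -40, 5, tau_const(3)),
                              h = gate(1, -80, -6.4, tau_const(100))))
    )
  )
}

# Density-table column for each kinetics channel (Ih column chosen at model
# build time).
.channel_density_column <- c(
  NaP = "g_NaP", KDR = "g_KDR", KC = "g_KC", KA = "g_KA", KM = "g_KM",
  K2 = "g_K2", CaH = "g_CaH", CaL = "g_CaL"
)

#' Gate steady state
#'
#' Boltzmann steady-state activation of a single gate, bounded in \[0, 1\].
#'
#' @param gate A gate spec from [kinetics_defaults()].
#' @param v Membrane potential, mV (vectorized).
#' @return Open fraction in \[0, 1\].
#' @export
gate_steady_state <- function(gate, v) {
  1 / (1 + exp((gate$v_half - v) / gate$k))
}

#' Gate time constant
#'
#' @inheritParams gate_steady_state
#' @return Time constant, ms (> 0).
#' @export
gate_time_constant <- function(gate, v) {
  tau <- gate$tau
  switch(tau$type,
    const = rep(tau$tau, length(v)),
    bell = tau$tau_min + tau$amp /
      (exp((v - tau$v_peak) / tau$k1) + exp(-(v - tau$v_peak) / tau$k2)),
    stop("unknown time-constant type: ", tau$type)
  )
}

#' Ih (anomalous rectifier) steady-state activation
#'
#' Monotonically decreasing sigmoid of voltage: the channel activates on
#' hyperpolarization, saturating at 1 for strongly negative potentials and
#' 0 for depolarized potentials.
#'
#' @param v Membrane potential, mV (vectorized).
#' @param kinetics Kinetics configuration, default [kinetics_defaults()].
#' @return Activation fraction in \[0, 1\].
#' @export
#' @examples
#' ih_activation(c(-120, -75, -40))
ih_activation <- function(v, kinetics = kinetics_defaults()) {
  gate_steady_state(kinetics$channels$h$gates$m, v)
}

#' Ih activation time constant
#'
#' Bell-shaped in voltage, peaking at hundreds of milliseconds near rest.
#' Throughout the subthreshold operating range the gate is far slower than
#' one 40 Hz period, so Ih gating tracks the 4 Hz modulation (with a lag)
#' while the 40 Hz component is strongly attenuated by the gate's first-
#' order low-pass behaviour.
#'
#' @inheritParams ih_activation
#' @return Time constant, ms.
#' @export
ih_time_constant <- function(v, kinetics = kinetics_defaults()) {
  gate_time_constant(kinetics$channels$h$gates$m, v)
}

#' Ionic current of one channel
#'
#' Standard conductance-based current `g * prod(gate^power) * (V - E)`,
#' positive outward, optionally scaled by the calcium-pool Michaelis factor
#' for calcium-gated potassium channels.
#'
#' @param channel Channel name in `kinetics$channels`.
#' @param density Conductance density or absolute conductance `g`; the
#'   current is returned in the corresponding units (e.g. uS * mV = nA).
#' @param gate_states Named numeric vector of gate open fractions in
#'   \[0, 1\], one per gate of the channel.
#' @param v Membrane potential, mV.
#' @param chi Calcium-pool activity (dimensionless), used only for
#'   calcium-gated channels.
#' @param kinetics Kinetics configuration.
#' @param reversals Named reversal potentials, default taken from
#'   `kinetics$reversals`.
#' @return Current (positive = outward), in `density` units times mV.
#' @export
channel_current <- function(channel, density, gate_states, v, chi = 0,
                            kinetics = kinetics_defaults(),
                            reversals = kinetics$reversals) {
  spec <- kinetics$channels[[channel]]
  if (is.null(spec)) stop("unknown channel name: ", channel)
  if (any(gate_states < 0 | gate_states > 1))
    stop("gate states must lie in [0, 1]")
  open <- 1
  for (gn in names(spec$gates))
    open <- open * gate_states[[gn]]^spec$gates[[gn]]$power
  if (isTRUE(spec$ca_gated))
    open <- open * chi / (chi + kinetics$ca_pool$kd)
  density * open * (v - reversals[[spec$reversal]])
}
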