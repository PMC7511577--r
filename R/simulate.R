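#' Integrate a model under an injection protocol
#'
#' Runs the compartmental cable integrator (implicit voltage update with
#' staggered exponential gate updates) and returns the membrane potential of
#' every compartment on a fixed recording time base.  Unless an explicit
#' initial `state` is given, the model is first relaxed to rest so the
#' protocol starts from the resting state.
#'
#' @param model An `ih_model` from [build_model()].
#' @param protocol An `injection_protocol`, or `NULL` for no injection.
#' @param duration_ms Simulated time, ms.
#' @param dt Integration step, ms (must be <= 0.05).
#' @param record_dt Recording interval, ms (a multiple of `dt`).
#' @param state Optional initial state (as returned in `$state` of a
#'   previous trace, or from [resting_state()]'s `attr(, "state")`);
#'   `NULL` relaxes to rest first.
#' @return A `sim_trace`: list with `time` (ms), `v` (matrix, time x
#'   compartment, mV, columns named by compartment id), `state` (final
#'   integrator state), and provenance (`ih_mode`, `protocol`, `dt`).
#' @export
#' @examples
#' \donttest{
#' m <- build_model("uniform")
#' tr <- simulate_model(m, study_protocol("distal", "base"), 500)
#' range(tr$v[, "apdend11"])
#' }
simulate_model <- function(model, protocol, duration_ms, dt = 0.025,
                           record_dt = 0.5, state = NULL) {
  stopifnot(inherits(model, "ih_model"))
  if (dt > 0.05) stop("dt must be <= 0.05 ms")
  record_every <- as.integer(round(record_dt / dt))
  if (abs(record_every * dt - record_dt) > 1e-9)
    stop("record_dt must be an integer multiple of dt")
  if (is.null(state)) {
    rs <- resting_state(model, dt = dt)
    state <- attr(rs, "state")
  }
  pm <- pack_model(model)
  src <- pack_protocol(if (is.null(protocol)) NULL else protocol, model)
  out <- cpp_simulate(pm, src, duration_ms, dt, record_every,
                      if (is.null(state)) list() else state)
  v <- out$v
  colnames(v) <- model$morphology$id
  structure(list(time = out$time, v = v, state = out$state,
                 ih_mode = model$ih_mode, protocol = protocol, dt = dt,
                 record_dt = record_dt),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace>", length(x$time), "samples x", ncol(x$v),
      "compartments;", x$ih_mode, "Ih; dt =", x$dt, "ms\n")
  invisible(x)
}

#' Extract one compartment's trace as a two-column data.frame
#'
#' @param trace A `sim_trace`.
#' @param compartment Compartment id.
#' @return data.frame with columns `time_ms`, `v_mV`.
#' @export
trace_channel <- function(trace, compartment) {
  if (!compartment %in% colnames(trace$v))
    stop("unknown compartment: ", compartment)
  data.frame(time_ms = trace$time, v_mV = trace$v[, compartment])
}

#' Resting membrane potential of every compartment
#'
#' Relaxes the model with no injected current until the voltage change per
#' unit time falls below `tol` (mV/ms) in every compartment.
#'
#' @param model An `ih_model`.
#' @param dt Integration step, ms.
#' @param max_ms Maximum simulated relaxation time before erroring.
#' @param tol Convergence tolerance on |dV/dt|, mV/ms.
#' @param bias Optional constant bias currents: a named vector of nA values
#'   by compartment id (used by [input_resistance()]).
#' @param init Optional initial integrator state to relax from (warm
#'   start).
#' @return Named numeric vector of resting potentials (mV), with the full
#'   integrator state in `attr(, "state")`.
#' @export
resting_state <- function(model, dt = 0.025, max_ms = 10000, tol = 1e-6,
                          bias = NULL, init = NULL) {
  pm <- pack_model(model)
  src <- if (is.null(bias)) {
    matrix(numeric(0), 0, 7)
  } else {
    pack_protocol(do.call(injection_protocol, lapply(names(bias), function(s)
      step_source(s, bias[[s]]))), model)
  }
  out <- cpp_relax(pm, src, max_ms, dt, tol,
                   if (is.null(init)) list() else init)
  if (!out$converged)
    stop("resting state did not converge within ", max_ms, " ms")
  structure(stats::setNames(as.numeric(out$v), model$morphology$id),
            state = out$state)
}

#' Input resistance at a compartment
#'
#' Voltage response per unit injected current at a site, in megaohms
#' (mV / nA).  Two probe protocols are available:
#'
#' * `method = "impedance_4hz"` (default): the impedance magnitude at the
#'   modulation frequency — a small 4 Hz sinusoid is injected from rest
#'   and the fundamental of the local voltage response is extracted after
#'   the transient.  At 4 Hz the slow Ih gate barely follows the probe, so
#'   this measures the chord (instantaneous) conductance state of the
#'   membrane, matching a bridge measurement made with the modulation
#'   itself.
#' * `method = "dc"`: steady-state deflection for a small constant current
#'   step, with both steady states obtained by full relaxation, so slow
#'   conductances (notably Ih) are fully equilibrated and contribute their
#'   phenomenological slope conductance.
#'
#' @param model An `ih_model`.
#' @param compartment Compartment id at which to inject and record.
#' @param step_nA Probe amplitude, nA (small and hyperpolarizing by
#'   default; the sign is irrelevant for `impedance_4hz`).
#' @param dt Integration step, ms.
#' @param method Probe protocol, see Details.
#' @param probe_freq_Hz Probe frequency for the impedance method.
#' @return Input resistance, MOhm.
#' @export
#' @examples
#' \donttest{
#' input_resistance(build_model("none"), "soma")
#' }
input_resistance <- function(model, compartment, step_nA = -0.1,
                             dt = 0.025,
                             method = c("impedance_4hz", "dc"),
                             probe_freq_Hz = 4) {
  method <- match.arg(method)
  if (!compartment %in% model$morphology$id)
    stop("unknown compartment: ", compartment)
  if (method == "dc") {
    v0 <- resting_state(model, dt = dt)[compartment]
    bias <- stats::setNames(step_nA, compartment)
    v1 <- resting_state(model, dt = dt, bias = bias)[compartment]
    return(unname((v1 - v0) / step_nA))
  }
  rest <- resting_state(model, dt = dt)
  period <- 1000 / probe_freq_Hz
  proto <- injection_protocol(
    sine_source(compartment, abs(step_nA), probe_freq_Hz))
  # two settling periods, then four probe cycles for the fundamental fit
  tr <- simulate_model(model, proto, 6 * period, dt = dt,
                       record_dt = 0.5, state = attr(rest, "state"))
  keep <- tr$time > 2 * period
  v <- tr$v[keep, compartment]
  ph <- 2 * pi * probe_freq_Hz * tr$time[keep] / 1000
  a <- 2 * mean((v - mean(v)) * sin(ph))
  b <- 2 * mean((v - mean(v)) * cos(ph))
  sqrt(a^2 + b^2) / abs(step_nA)
}
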