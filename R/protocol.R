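#' Sinusoidal and step current sources
#'
#' Constructors for the two waveform types used by the injection protocols.
#' A sinusoid is `amplitude * sin(2 pi f (t - onset) + phase)` nA while
#' `onset <= t < offset`, zero otherwise; a step is a constant `amplitude`
#' nA over the same window.
#'
#' @param site Compartment id receiving the current.
#' @param amplitude_nA Peak amplitude (sinusoid) or level (step), nA.
#' @param frequency_Hz Sinusoid frequency, Hz.
#' @param phase_deg Sinusoid phase offset at onset, degrees.
#' @param onset_ms,offset_ms Active window, ms (offset may be `Inf`).
#' @return A one-row data.frame describing the source.
#' @export
sine_source <- function(site, amplitude_nA, frequency_Hz, phase_deg = 0,
                        onset_ms = 0, offset_ms = Inf) {
  data.frame(site = site, waveform = "sine", amplitude_nA = amplitude_nA,
             frequency_Hz = frequency_Hz, phase_deg = phase_deg,
             onset_ms = onset_ms, offset_ms = offset_ms,
             stringsAsFactors = FALSE)
}

#' @rdname sine_source
#' @export
step_source <- function(site, amplitude_nA, onset_ms = 0, offset_ms = Inf) {
  data.frame(site = site, waveform = "step", amplitude_nA = amplitude_nA,
             frequency_Hz = 0, phase_deg = 0,
             onset_ms = onset_ms, offset_ms = offset_ms,
             stringsAsFactors = FALSE)
}

#' Assemble an injection protocol
#'
#' Binds one or more sources (from [sine_source()] / [step_source()]) into
#' an `injection_protocol` object, validating amplitudes and fields.
#' Site existence is checked against the model at simulation time.
#'
#' @param ... Source data.frames.
#' @return An `injection_protocol` (a validated data.frame).
#' @export
#' @examples
#' injection_protocol(sine_source("apdend13", 1.5, 4),
#'                    sine_source("apdend1", 1.5, 40))
injection_protocol <- function(...) {
  src <- do.call(rbind, list(...))
  if (is.null(src) || nrow(src) == 0) stop("protocol has no sources")
  if (any(!is.finite(src$amplitude_nA)))
    stop("source amplitudes must be finite")
  if (any(src$waveform == "sine" & src$frequency_Hz <= 0))
    stop("sinusoid frequency must be positive")
  if (any(src$onset_ms >= src$offset_ms))
    stop("source onset must precede offset")
  class(src) <- c("injection_protocol", "data.frame")
  src
}

# Canonical 40 Hz injection sites along the apical shaft: base of the
# apical dendrite (centre 37.5 um from soma), middle apical (midpoint of
# the 13-compartment shaft), distal apical (12th compartment, 825 um).
gamma_site_ids <- function() {
  c(base = "apdend1", middle = "apdend7", distal = "apdend12")
}

#' The study's dual-sinusoid injection protocol
#'
#' Builds the canonical protocol: a 4 Hz theta modulation injected either
#' distally (`apdend13`, the most distal apical shaft compartment) or
#' perisomatically (soma), plus a simultaneous 40 Hz injection at the base
#' (`apdend1`, 37.5 um), middle (`apdend7`) or distal (`apdend12`, 825 um)
#' apical dendrite.
#'
#' @param modulation `"distal"` or `"perisomatic"`: site of the 4 Hz
#'   injection.
#' @param gamma_site `"base"`, `"middle"` or `"distal"`: site of the 40 Hz
#'   injection.
#' @param amp4_nA,amp40_nA Amplitudes of the 4 and 40 Hz sinusoids, nA.
#' @return An `injection_protocol` with exactly two sinusoidal sources.
#' @export
study_protocol <- function(modulation = c("distal", "perisomatic"),
                           gamma_site = c("base", "middle", "distal"),
                           amp4_nA = 1.5, amp40_nA = 1.5) {
  modulation <- match.arg(modulation)
  gamma_site <- match.arg(gamma_site)
  theta_site <- if (modulation == "distal") "apdend13" else "soma"
  injection_protocol(
    sine_source(theta_site, amp4_nA, 4),
    sine_source(gamma_site_ids()[[gamma_site]], amp40_nA, 40)
  )
}

# protocol -> numeric matrix for the compiled integrator
pack_protocol <- function(protocol, model) {
  if (is.null(protocol) || nrow(protocol) == 0)
    return(matrix(numeric(0), 0, 7))
  comp <- match(protocol$site, model$morphology$id)
  if (anyNA(comp))
    stop("protocol site(s) not in model: ",
         paste(protocol$site[is.na(comp)], collapse = ", "))
  cbind(comp - 1L,
        ifelse(protocol$waveform == "sine", 1, 0),
        protocol$amplitude_nA, protocol$frequency_Hz, protocol$phase_deg,
        protocol$onset_ms, protocol$offset_ms)
}
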