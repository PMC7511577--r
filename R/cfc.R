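#' @title Theta-gamma phase-amplitude coupling metrics
#' @description
#' The quantification pipeline: band decomposition of a membrane-potential
#' trace into a theta component (with instantaneous phase) and a gamma
#' component (with amplitude envelope), phase binning of the envelope into
#' a normalized phase-amplitude distribution, and the scalar metrics
#' computed from it (modulation index, height ratio, amplitude ratio,
#' theta phase of the envelope extrema).
#' @name cfc
NULL

# Zero-phase band-pass: FFT-domain mask with raised-cosine transitions of
# width `transition` Hz on each edge.  Exactly zero phase by construction;
# edge-contaminated samples are handled by the caller trimming `edge_ms`.
bandpass_fft <- function(x, fs, band, transition = 1) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  lo <- band[1]; hi <- band[2]
  mask <- numeric(n)
  rise <- f >= lo - transition & f < lo
  fall <- f > hi & f <= hi + transition
  mask[f >= lo & f <= hi] <- 1
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / transition))
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / transition))
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Decompose a trace into theta and gamma components
#'
#' Zero-phase band-pass filters the signal into a theta and a gamma
#' component, then derives the instantaneous theta phase and the gamma
#' amplitude envelope from the analytic signal of each component.  Phase is
#' reported in degrees in \[0, 360) under the convention selected by
#' `phase_zero`.  `edge_ms` of data at each end — contaminated by the
#' circular filtering — are dropped from all returned series.
#'
#' @param x A numeric vector (mV), a two-column data.frame (`time_ms`,
#'   `v_mV`), or a `sim_trace` (then `compartment` selects the channel).
#' @param fs Sampling rate, Hz (ignored when `x` carries a time base).
#' @param compartment Compartment id when `x` is a `sim_trace`.
#' @param theta_band,gamma_band Band edges, Hz.
#' @param transition Filter transition width, Hz.
#' @param edge_ms Edge trim after filtering, ms.
#' @param phase_zero Phase-zero convention: `"ascending"` (default; 0
#'   degrees at the upward zero-crossing of the theta component, i.e. the
#'   phase of theta written as a sine, so the peak falls at 90 and the
#'   trough at 270), `"trough"` (0 at the theta minimum) or `"peak"` (0 at
#'   the maximum).  Reported absolute phases shift by a quarter or half
#'   cycle between conventions.
#' @return A `band_decomposition`: list with `time_ms`, `theta`, `gamma`
#'   (mV), `phase_deg` in \[0, 360), `envelope` (mV, >= 0), `fs` and the
#'   band definitions.
#' @export
decompose <- function(x, fs = NULL, compartment = NULL,
                      theta_band = c(2, 6), gamma_band = c(30, 50),
                      transition = 1, edge_ms = 250,
                      phase_zero = c("ascending", "trough", "peak")) {
  phase_zero <- match.arg(phase_zero)
  if (inherits(x, "sim_trace")) {
    if (is.null(compartment))
      stop("compartment must be given for a sim_trace")
    x <- trace_channel(x, compartment)
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("trace data.frame needs time and voltage columns")
    fs <- 1000 / stats::median(diff(x[[1]]))
    x <- x[[2]]
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric trace")
  if (max(theta_band, gamma_band) >= fs / 2)
    stop("band edges exceed the Nyquist frequency")
  if (fs < 20 * mean(gamma_band))
    stop("sampling rate too low for the gamma band")
  n <- length(x)
  if (n / fs < 2 / theta_band[1])
    stop("window too short: need at least two cycles of the slow band")

  theta <- bandpass_fft(x - mean(x), fs, theta_band, transition)
  gamma <- bandpass_fft(x - mean(x), fs, gamma_band,
                        transition = max(transition, 2))
  offset <- switch(phase_zero, ascending = 90, trough = 180, peak = 0)
  phase <- (Arg(analytic_signal(theta)) * 180 / pi + offset) %% 360
  env <- Mod(analytic_signal(gamma))

  keep <- seq_len(n)
  ntrim <- round(edge_ms * fs / 1000)
  if (2 * ntrim >= n) stop("edge trim removes the whole window")
  if (ntrim > 0) keep <- (ntrim + 1):(n - ntrim)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  structure(list(time_ms = t_ms[keep], theta = theta[keep],
                 gamma = gamma[keep], phase_deg = phase[keep],
                 envelope = env[keep], fs = fs,
                 theta_band = theta_band, gamma_band = gamma_band),
            class = "band_decomposition")
}

#' Phase-amplitude profile: binned normalized envelope distribution
#'
#' Bins the theta phase into `n_bins` equal bins (bin j covers
#' \[(j-1) 360/N, j 360/N)), averages the gamma envelope within each bin,
#' and normalizes by the sum over bins to give the discrete distribution
#' P(j) that the coupling metrics are computed from.
#'
#' @param decomp A `band_decomposition`, or a list/data.frame with
#'   `phase_deg` and `envelope` elements.
#' @param n_bins Number of phase bins N (default 72, i.e. 5 degree bins).
#' @return A `phase_amplitude_profile`: list with `n_bins`, `breaks_deg`,
#'   `centers_deg`, `mean_envelope` and normalized `p` (sums to 1).
#' @export
phase_amplitude_profile <- function(decomp, n_bins = 72) {
  if (n_bins < 2) stop("need at least 2 phase bins")
  phase <- decomp$phase_deg
  env <- decomp$envelope
  if (length(phase) != length(env)) stop("phase/envelope length mismatch")
  bin <- pmin(floor(phase / (360 / n_bins)) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  if (any(counts == 0))
    stop("empty phase bin(s) ", paste(which(counts == 0), collapse = ", "),
         ": use a longer analysis window or fewer bins")
  mean_env <- as.numeric(tapply(env, factor(bin, levels = seq_len(n_bins)),
                                mean))
  total <- sum(mean_env)
  if (total <= 0) stop("all-zero envelope: no fast-band signal to bin")
  structure(list(n_bins = n_bins,
                 breaks_deg = seq(0, 360, length.out = n_bins + 1),
                 centers_deg = (seq_len(n_bins) - 0.5) * 360 / n_bins,
                 mean_envelope = mean_env,
                 p = mean_env / total),
            class = "phase_amplitude_profile")
}

# Accept either a profile object or a bare probability vector.
profile_p <- function(profile) {
  if (inherits(profile, "phase_amplitude_profile")) return(profile$p)
  p <- as.numeric(profile)
  if (any(p < 0)) stop("profile values must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("profile sums to zero")
  p / s
}

#' Modulation index
#'
#' Normalized entropy deficit of the phase-amplitude distribution:
#' `MI = (log N + sum_j P(j) log P(j)) / log N`, with the convention
#' `0 log 0 = 0` and natural logarithms (any fixed base gives the same
#' value).  0 for a uniform distribution (no coupling), 1 when all
#' amplitude falls in a single phase bin.
#'
#' @param profile A `phase_amplitude_profile` or a non-negative vector
#'   (normalized internally).
#' @return MI in \[0, 1\].
#' @export
#' @examples
#' modulation_index(rep(1, 72))        # 0
#' modulation_index(c(1, 0, 0, 0))     # 1
modulation_index <- function(profile) {
  p <- profile_p(profile)
  n <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  (log(n) + sum(plogp)) / log(n)
}

#' Height ratio
#'
#' `(h_max - h_min) / h_max` where h_max and h_min are the largest and
#' smallest values of the normalized phase-amplitude distribution.  0 for a
#' uniform distribution, 1 when some phase bin has zero amplitude.
#' Invariant to rescaling of the raw envelope.
#'
#' @inheritParams modulation_index
#' @return Height ratio in \[0, 1\].
#' @export
#' @examples
#' height_ratio(c(0.4, 0.3, 0.2, 0.1))  # 0.75
height_ratio <- function(profile) {
  p <- profile_p(profile)
  hmax <- max(p)
  if (hmax <= 0) stop("all-zero profile")
  (hmax - min(p)) / hmax
}

#' Amplitude ratio of theta to gamma membrane-potential fluctuations
#'
#' Ratio of the theta-component amplitude to the gamma-component amplitude
#' over the analysis window, with amplitude defined as `sqrt(2) * RMS` of
#' the band-passed component (equal to the peak amplitude for a pure
#' sinusoid).  An index of how differently the cable filters the slow and
#' fast injected signals at a given compartment.
#'
#' @param decomp A `band_decomposition`.
#' @return Positive scalar, Vm(theta) / Vm(gamma).
#' @export
amplitude_ratio <- function(decomp) {
  a_th <- sqrt(2 * mean(decomp$theta^2))
  a_ga <- sqrt(2 * mean(decomp$gamma^2))
  if (a_ga <= 1e-9 * max(a_th, .Machine$double.xmin))
    stop("zero gamma component: amplitude ratio undefined")
  a_th / a_ga
}

#' Theta phase of the gamma-envelope extrema
#'
#' Bin-centre phases at which the normalized phase-amplitude distribution
#' attains its maximum and minimum.  Ties are broken toward the earlier
#' phase.
#'
#' @inheritParams modulation_index
#' @param profile A `phase_amplitude_profile`.
#' @return Named list: `phase_max`, `phase_min` (degrees).
#' @export
phase_of_extrema <- function(profile) {
  if (!inherits(profile, "phase_amplitude_profile"))
    stop("phase_of_extrema needs a phase_amplitude_profile (bin centres)")
  list(phase_max = profile$centers_deg[which.max(profile$p)],
       phase_min = profile$centers_deg[which.min(profile$p)])
}

#' Full CFC quantification of one compartment trace
#'
#' Convenience wrapper: decompose, bin, and compute all scalar metrics.
#'
#' @inheritParams decompose
#' @param n_bins Number of phase bins.
#' @param transient_ms Initial transient to discard before analysis, ms
#'   (applied only when `x` carries a time base starting at 0).
#' @param ... Passed to [decompose()].
#' @return A `cfc_result`: one-row data.frame with `mi`, `height_ratio`,
#'   `h_max`, `h_min`, `amplitude_ratio`, `phase_max_deg`, `phase_min_deg`,
#'   `n_bins`, and `compartment`.
#' @export
compute_cfc <- function(x, fs = NULL, compartment = NULL, n_bins = 72,
                        transient_ms = 0, ...) {
  if (inherits(x, "sim_trace")) {
    if (is.null(compartment))
      stop("compartment must be given for a sim_trace")
    x <- trace_channel(x, compartment)
  }
  if (is.data.frame(x) && transient_ms > 0)
    x <- x[x[[1]] >= transient_ms, ]
  d <- decompose(x, fs = fs, ...)
  prof <- phase_amplitude_profile(d, n_bins)
  ext <- phase_of_extrema(prof)
  res <- data.frame(
    compartment = if (is.null(compartment)) NA_character_ else compartment,
    mi = modulation_index(prof),
    height_ratio = height_ratio(prof),
    h_max = max(prof$p), h_min = min(prof$p),
    amplitude_ratio = amplitude_ratio(d),
    phase_max_deg = ext$phase_max, phase_min_deg = ext$phase_min,
    n_bins = n_bins,
    stringsAsFactors = FALSE
  )
  class(res) <- c("cfc_result", "data.frame")
  res
}
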