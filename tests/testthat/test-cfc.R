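fs <- 1000
t_s <- seq(0, 3, by = 1 / fs)[-3001]

test_that("band decomposition recovers pure tones and AM envelopes", {
  # pure 40 Hz: envelope ~ amplitude, theta component ~ 0
  d <- decompose(2 * sin(2 * pi * 40 * t_s), fs = fs)
  expect_equal(d$envelope, rep(2, length(d$envelope)), tolerance = 0.01)
  expect_lt(max(abs(d$theta)), 0.01)

  # pure 4 Hz: phase advances 360 deg per 250 ms, gamma envelope ~ 0
  d <- decompose(sin(2 * pi * 4 * t_s), fs = fs)
  expect_lt(max(d$envelope), 0.01)
  unwrapped <- d$phase_deg + 360 * cumsum(c(0, diff(d$phase_deg) < -180))
  rate <- stats::coef(stats::lm(unwrapped ~ d$time_ms))[[2]]
  expect_equal(rate * 250, 360, tolerance = 0.001)

  # AM signal: recovered envelope matches 1 + 0.5 sin(2 pi 4 t) within 2%
  x <- (1 + 0.5 * sin(2 * pi * 4 * t_s)) * sin(2 * pi * 40 * t_s)
  d <- decompose(x, fs = fs)
  truth <- 1 + 0.5 * sin(2 * pi * 4 * d$time_ms / 1000)
  expect_lt(sqrt(mean((d$envelope - truth)^2)) / sqrt(mean(truth^2)), 0.02)

  expect_error(decompose(x, fs = 400), "sampling rate")
  expect_error(decompose(x[1:300], fs = fs), "window too short")
  expect_error(decompose(x, fs = fs, gamma_band = c(30, 600)), "Nyquist")
})

test_that("phase binning yields a normalized distribution", {
  # constant envelope over a full phase sweep: exactly uniform
  dec <- list(phase_deg = seq(0, 359.9, by = 0.1),
              envelope = rep(3, 3600))
  prof <- phase_amplitude_profile(dec, 72)
  expect_equal(prof$p, rep(1 / 72, 72), tolerance = 1e-12)
  expect_equal(sum(prof$p), 1, tolerance = 1e-12)

  # envelope concentrated in bin 3 -> one-hot
  dec$envelope <- as.numeric(dec$phase_deg >= 10 & dec$phase_deg < 15)
  prof <- phase_amplitude_profile(dec, 72)
  expect_equal(prof$p[3], 1)
  expect_true(all(prof$p[-3] == 0))

  # cosine envelope, N = 4: quadrature oracle over each quadrant
  dec <- list(phase_deg = seq(0, 359.99, by = 0.01),
              envelope = 1 + 0.5 * cos(seq(0, 359.99, by = 0.01) *
                                         pi / 180))
  prof <- phase_amplitude_profile(dec, 4)
  oracle <- vapply(seq_len(4), function(j) {
    stats::integrate(function(ph) 1 + 0.5 * cos(ph * pi / 180),
                     (j - 1) * 90, j * 90)$value / 90
  }, 0)
  expect_equal(prof$p, oracle / sum(oracle), tolerance = 1e-4)

  # an unpopulated bin is an error, never imputed
  dec <- list(phase_deg = rep(c(10, 100, 200), 50), envelope = rep(1, 150))
  expect_error(phase_amplitude_profile(dec, 72), "empty phase bin")
})

test_that("modulation index matches its definition and limits", {
  expect_equal(modulation_index(rep(1, 72)), 0)
  expect_equal(modulation_index(c(1, rep(0, 17))), 1)
  # direct evaluation for P = (0.4, 0.3, 0.2, 0.1), natural log
  p <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(modulation_index(p),
               (log(4) + sum(p * log(p))) / log(4))
  # the same value in any log base (the base cancels)
  expect_equal(modulation_index(p),
               (log10(4) + sum(p * log10(p))) / log10(4))
  # brute-force oracle: KL divergence from uniform, for random profiles
  set.seed(42)
  for (n in c(4, 5, 8)) {
    for (rep in 1:5) {
      p <- stats::runif(n); p <- p / sum(p)
      kl <- sum(p * log(p / (1 / n)))
      expect_equal(modulation_index(p), kl / log(n), tolerance = 1e-12)
    }
  }
})

test_that("height ratio matches its definition and is scale invariant", {
  expect_equal(height_ratio(rep(1, 72)), 0)
  expect_equal(height_ratio(c(0.4, 0.3, 0.2, 0.1)), 0.75)
  expect_equal(height_ratio(c(1, rep(0, 9))), 1)
  p <- c(5, 3, 2, 7, 1)
  expect_equal(height_ratio(p), height_ratio(p * 1e3))
  expect_equal(modulation_index(p), modulation_index(p * 1e3))
  expect_error(height_ratio(rep(0, 4)), "zero")
})

test_that("amplitude ratio follows closed-form filter gains", {
  x <- sin(2 * pi * 4 * t_s) + sin(2 * pi * 40 * t_s)
  expect_equal(amplitude_ratio(decompose(x, fs = fs)), 1, tolerance = 0.02)
  x <- 10 * sin(2 * pi * 4 * t_s) + 2 * sin(2 * pi * 40 * t_s)
  expect_equal(amplitude_ratio(decompose(x, fs = fs)), 5, tolerance = 0.02)
  # single-pole RC low-pass with 10 Hz cutoff applied to an equal sum:
  # ratio = sqrt(1 + (40/10)^2) / sqrt(1 + (4/10)^2)
  g <- function(f) 1 / sqrt(1 + (f / 10)^2)
  x <- g(4) * sin(2 * pi * 4 * t_s) + g(40) * sin(2 * pi * 40 * t_s)
  expect_equal(amplitude_ratio(decompose(x, fs = fs)),
               sqrt(1 + 16) / sqrt(1 + 0.16), tolerance = 0.02)
  expect_error(amplitude_ratio(decompose(sin(2 * pi * 4 * t_s), fs = fs)),
               "zero gamma")
})

test_that("extrema phases are bin centres with earlier-phase tie-break", {
  ph <- seq(0, 359.9, by = 0.1)
  dec <- list(phase_deg = ph,
              envelope = 1 + 0.5 * cos((ph - 270) * pi / 180))
  prof <- phase_amplitude_profile(dec, 72)
  ext <- phase_of_extrema(prof)
  expect_lte(min(abs(c(ext$phase_max - 270, ext$phase_max - 270 + 360,
                       ext$phase_max - 270 - 360))), 2.5)
  expect_lte(min(abs(c(ext$phase_min - 90, ext$phase_min - 90 + 360))), 2.5)
  # one-hot: max at that bin centre, min at the earliest zero bin
  dec <- list(phase_deg = ph, envelope = as.numeric(ph >= 20 & ph < 25))
  ext <- phase_of_extrema(phase_amplitude_profile(dec, 72))
  expect_equal(ext$phase_max, 22.5)
  expect_equal(ext$phase_min, 2.5)      # ties broken toward earlier phase
})
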