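test_that("coupling depth maps onto the metrics as designed", {
  # no coupling: constant envelope, MI essentially zero downstream
  r0 <- compute_cfc(generate_coupled(coupled_signal_spec(
    coupling_depth = 0)))
  expect_lt(r0$mi, 1e-6)
  expect_lt(r0$height_ratio, 1e-3)
  # full coupling: envelope touches zero, height ratio ~ 1
  r1 <- compute_cfc(generate_coupled(coupled_signal_spec(
    coupling_depth = 1)))
  expect_equal(r1$height_ratio, 1, tolerance = 0.01)
  # chi = 0.5 at phi_c = 270: analytic envelope, quadrature per 5-deg bin
  x <- generate_coupled(coupled_signal_spec(coupling_depth = 0.5,
                                            coupling_phase_deg = 270))
  r <- compute_cfc(x)
  expect_lte(min(abs(c(r$phase_max_deg - 270, r$phase_max_deg + 90))), 2.5)
  env_fun <- function(ph)
    1 - 0.5 + 0.5 * (1 + cos((ph - 270) * pi / 180)) / 2
  p_oracle <- vapply(seq_len(72), function(j)
    stats::integrate(env_fun, (j - 1) * 5, j * 5)$value, 0)
  p_oracle <- p_oracle / sum(p_oracle)
  expect_equal(r$height_ratio, height_ratio(p_oracle), tolerance = 0.01)
})

test_that("generation is deterministic given spec and seed", {
  sp <- coupled_signal_spec(coupling_depth = 0.3, noise_sd = 0.5,
                            seed = 7L)
  x1 <- generate_coupled(sp)
  x2 <- generate_coupled(sp)
  expect_identical(x1$v_mV, x2$v_mV)
  x3 <- generate_coupled(coupled_signal_spec(coupling_depth = 0.3,
                                             noise_sd = 0.5, seed = 8L))
  expect_false(identical(x1$v_mV, x3$v_mV))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_coupled(sp)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("invalid specs are rejected", {
  expect_error(coupled_signal_spec(coupling_depth = 1.2), "0, 1")
  expect_error(coupled_signal_spec(fs = 300), "20x")
  expect_error(coupled_signal_spec(noise_sd = -1), "non-negative")
})

test_that("coupling recovery under noise: height ratio is monotone in
           depth and the coupling phase is recovered within one bin", {
  depths <- c(0, 0.25, 0.5, 0.75, 1)
  hr <- vapply(depths, function(chi) {
    r <- compute_cfc(generate_coupled(coupled_signal_spec(
      coupling_depth = chi, coupling_phase_deg = 225, noise_sd = 0.3,
      duration_ms = 6000, seed = 11L)))
    if (chi >= 0.5)
      expect_lte(min(abs(c(r$phase_max_deg - 225,
                           r$phase_max_deg - 225 + 360,
                           r$phase_max_deg - 225 - 360))), 5)
    r$height_ratio
  }, 0)
  expect_true(all(diff(hr) > 0))
})

test_that("the RC fixture reproduces the impedance closed forms", {
  R <- 50; C <- 0.2   # tau = 10 ms
  # long step: V -> I R
  fx <- generate_passive_fixture(R, C, injection_protocol(
    step_source("x", 0.2)), 200, dt = 0.1)
  expect_equal(fx$v_mV[fx$time_ms == 200], 0.2 * R, tolerance = 1e-6)
  # sinusoid: steady amplitude I R / sqrt(1 + (wRC)^2), lag atan(wRC)
  f <- 20; w <- 2 * pi * f / 1000
  fx <- generate_passive_fixture(R, C, injection_protocol(
    sine_source("x", 0.2, f)), 1000, dt = 0.1)
  ss <- fx$v_mV[fx$time_ms > 500]
  expect_equal(max(abs(ss)), 0.2 * R / sqrt(1 + (w * R * C)^2),
               tolerance = 1e-3)
  # low-frequency limit: amplitude -> I R
  fx <- generate_passive_fixture(R, C, injection_protocol(
    sine_source("x", 0.2, 0.5)), 6000, dt = 0.5)
  expect_equal(max(abs(fx$v_mV)), 0.2 * R, tolerance = 0.01)
  expect_error(generate_passive_fixture(-1, C,
    injection_protocol(step_source("x", 1)), 10), "positive")
})
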