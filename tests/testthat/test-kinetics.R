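vv <- seq(-120, 50, by = 0.5)

test_that("Ih activation is a decreasing sigmoid with the right limits", {
  act <- ih_activation(vv)
  expect_true(all(diff(act) < 0))
  expect_equal(ih_activation(-1e4), 1, tolerance = 1e-10)
  expect_equal(ih_activation(1e4), 0, tolerance = 1e-10)
  # more activated at the hyperpolarized end of the resting range
  expect_gt(ih_activation(-85), ih_activation(-56))
})

test_that("every gate is bounded and every time constant positive", {
  kin <- kinetics_defaults()
  for (cn in names(kin$channels)) {
    for (gn in names(kin$channels[[cn]]$gates)) {
      g <- kin$channels[[cn]]$gates[[gn]]
      inf <- gate_steady_state(g, vv)
      expect_true(all(inf >= 0 & inf <= 1), label = paste(cn, gn, "inf"))
      expect_true(all(gate_time_constant(g, vv) > 0),
                  label = paste(cn, gn, "tau"))
    }
  }
})

test_that("Ih gating is slow: it cannot follow the 40 Hz signal", {
  v_op <- seq(-90, -55, by = 0.5)
  tau <- ih_time_constant(v_op)
  expect_true(all(tau > 25))            # slower than one 40 Hz period
  # single-pole low-pass gain at 40 Hz is below 0.1 everywhere in the
  # operating range: >10x attenuation of gamma-frequency modulation
  gain40 <- 1 / sqrt(1 + (2 * pi * 40 * tau / 1000)^2)
  gain4 <- 1 / sqrt(1 + (2 * pi * 4 * tau / 1000)^2)
  expect_true(all(gain40 < 0.1))
  expect_true(all(gain4 > 2 * gain40))  # theta passes far more than gamma
})

test_that("a gate driven by a 4 Hz voltage oscillation responds at 4 Hz
           with a lag in (0, 90) degrees", {
  kin <- kinetics_defaults()
  g <- kin$channels$h$gates$m
  dt <- 0.01
  t <- seq(0, 2000, by = dt)
  v <- -70 + 10 * sin(2 * pi * 4 * t / 1000)
  m <- gate_steady_state(g, v[1])
  out <- numeric(length(t))
  for (i in seq_along(t)) {   # fine explicit integration as oracle
    m <- m + dt * (gate_steady_state(g, v[i]) - m) /
      gate_time_constant(g, v[i])
    out[i] <- m
  }
  keep <- t > 1000            # discard transient, analyze 4 cycles
  y <- out[keep] - mean(out[keep])
  ph <- 2 * pi * 4 * t[keep] / 1000
  # the gate's quasi-steady drive is m_inf(V(t)), anti-phase to V for a
  # hyperpolarization-activated gate: measure the lag relative to -sin
  a <- 2 * mean(y * -sin(ph)); b <- 2 * mean(y * cos(ph))
  lag_deg <- (atan2(b, a) * 180 / pi) %% 360
  amp <- sqrt(a^2 + b^2)
  expect_gt(amp, 0)                       # oscillates at the drive freq
  expect_gt(lag_deg, 0)
  expect_lt(lag_deg, 90)
  # linearized first-order prediction of the lag at the mean potential
  tau0 <- ih_time_constant(-70)
  expect_equal(lag_deg, atan(2 * pi * 4 * tau0 / 1000) * 180 / pi,
               tolerance = 0.15)
})

test_that("relaxation at fixed voltage follows the first-order closed
           form", {
  kin <- kinetics_defaults()
  g <- kin$channels$KM$gates$m
  v <- -60
  inf <- gate_steady_state(g, v); tau <- gate_time_constant(g, v)
  m0 <- 0.9
  t <- seq(0, 5 * tau, length.out = 200)
  closed <- inf + (m0 - inf) * exp(-t / tau)
  # step the exponential update used by the integrator
  dt <- diff(t)[1]
  m <- numeric(length(t)); m[1] <- m0
  for (i in 2:length(t))
    m[i] <- m[i - 1] + (inf - m[i - 1]) * (1 - exp(-dt / tau))
  expect_equal(m, closed, tolerance = 1e-10)
})

test_that("channel currents follow the conductance-based form", {
  expect_equal(channel_current("KDR", 0, c(n = 0.7), -20), 0)
  expect_equal(channel_current("NaP", 3, c(m = 1), 50), 0)  # V = E_Na
  # Ih at half activation, hyperpolarized: inward (negative) current
  i_h <- channel_current("h", 52.9971, c(m = 0.5), -80)
  expect_equal(i_h, 52.9971 * 0.5 * (-80 - (-40)))
  expect_lt(i_h, 0)
  # linear in density
  expect_equal(channel_current("h", 2 * 52.9971, c(m = 0.5), -80), 2 * i_h)
  # calcium-gated channels carry no current when the pool is empty
  expect_equal(channel_current("KC", 9, c(m = 1), -20, chi = 0), 0)
  expect_equal(channel_current("K2", 10, c(m = 1), -20, chi = 0), 0)
  expect_gt(channel_current("K2", 10, c(m = 1), -20, chi = 500), 0)
  expect_error(channel_current("NaF", 1, c(m = 1), 0), "unknown channel")
  expect_error(channel_current("h", 1, c(m = 1.2), -70), "0, 1")
})
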