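test_that("an isolated passive compartment follows the RC closed forms", {
  m <- isolated_passive_model(g_leak = 0.1, e_leak = -70)
  area <- m$morphology["soma", "area_cm2"]
  R <- 1 / (0.1 * area * 1000)            # MOhm
  C <- m$cm_nF[["soma"]]                  # nF
  # analytic input resistance: DC probe equals R (to the ~1e-4 residual
  # axial loading of the near-isolated compartment), 4 Hz impedance probe
  # equals the closed-form |Z| = R / sqrt(1 + (wRC)^2)
  expect_equal(input_resistance(m, "soma", method = "dc"), R,
               tolerance = 5e-4)
  w <- 2 * pi * 4 / 1000
  expect_equal(input_resistance(m, "soma"),
               R / sqrt(1 + (w * R * C)^2), tolerance = 1e-3)

  # step response: V(t) = V_rest + I R (1 - exp(-t/RC)) within 1%
  proto <- injection_protocol(step_source("soma", 0.3))
  tr <- simulate_model(m, proto, 5 * R * C)
  oracle <- generate_passive_fixture(R, C, proto, 5 * R * C,
                                     dt = tr$record_dt, v_rest = -70)
  expect_equal(tr$v[, "soma"], oracle$v_mV, tolerance = 0.01)
  expect_lt(abs(tr$v[nrow(tr$v), "soma"] - (-70 + 0.3 * R)),
            0.01 * 0.3 * R)

  # sinusoidal steady state: amplitude I R / sqrt(1 + (wRC)^2) within 1%
  for (f in c(4, 40)) {
    proto <- injection_protocol(sine_source("soma", 0.3, f))
    dur <- 2000
    tr <- simulate_model(m, proto, dur, record_dt = 0.25)
    ss <- tr$v[tr$time > dur - 1000, "soma"] + 70
    pred <- 0.3 * R / sqrt(1 + (2 * pi * f * R * C / 1000)^2)
    expect_equal((max(ss) - min(ss)) / 2, pred, tolerance = 0.01,
                 label = paste0("amplitude at ", f, " Hz"))
  }
})

test_that("passive steady states solve the cable linear system exactly", {
  # DC into apdend1 of a passive tree: the steady state must satisfy
  # G V = I with G assembled independently from leak + axial conductances
  m <- build_model("none",
                   passive = list(density_scale = 0, g_leak = 0.05,
                                  e_leak = -70))
  morph <- m$morphology
  n <- nrow(morph)
  G <- diag(m$g_leak_uS)
  for (i in seq_len(n)) {
    pa <- match(morph$parent[i], morph$id)
    if (is.na(pa)) next
    g <- m$g_ax_uS[i]
    G[i, i] <- G[i, i] + g; G[pa, pa] <- G[pa, pa] + g
    G[i, pa] <- G[i, pa] - g; G[pa, i] <- G[pa, i] - g
  }
  inj <- numeric(n); inj[match("apdend1", morph$id)] <- 0.2
  v_pred <- -70 + solve(G, inj)
  rs <- resting_state(m, bias = c(apdend1 = 0.2))
  expect_equal(as.numeric(rs), as.numeric(v_pred), tolerance = 1e-5)
  # passive rest with no injection is E_leak everywhere
  expect_equal(as.numeric(resting_state(m)), rep(-70, n), tolerance = 1e-6)
})

test_that("resting potentials are ordered by Ih density and lie in the
           subthreshold operating range", {
  r_none <- cached_rest("none")
  r_unif <- cached_rest("uniform")
  r_exp <- cached_rest("exp_gradient")
  # Ih depolarizes rest: none < uniform compartment-wise
  expect_true(all(r_none < r_unif))
  # distally the exponential gradient outweighs the uniform density
  expect_gt(r_exp[["tuft3"]], r_unif[["tuft3"]])
  all_rest <- c(r_none, r_unif, r_exp)
  expect_true(all(all_rest >= -86.5 & all_rest <= -55))
})

test_that("input resistance decreases as Ih density increases, at both
           probe sites", {
  for (cid in c("soma", "apdend13")) {
    r <- vapply(c("none", "uniform", "exp_gradient"),
                function(mode) input_resistance(cached_model(mode), cid),
                0)
    expect_true(all(diff(r) < 0), label = cid)   # none > unif > exp
    expect_true(all(r > 0))
  }
})

test_that("halving dt leaves the steady state essentially unchanged", {
  m <- cached_model("exp_gradient")
  r1 <- resting_state(m, dt = 0.05)
  r2 <- resting_state(m, dt = 0.025)
  expect_lt(max(abs(r1 - r2)), 0.1)
})

test_that("study-protocol traces are finite, bounded and reproducible", {
  # the Ih-laden model stays within the subthreshold operating range even
  # at the high-impedance distal injection site
  m <- cached_model("exp_gradient")
  tr <- simulate_model(m, study_protocol("distal", "middle"), 800)
  expect_false(anyNA(tr$v))
  expect_true(all(tr$v > -120 & tr$v < 60))
  tr2 <- simulate_model(m, study_protocol("distal", "middle"), 800)
  expect_identical(tr$v, tr2$v)          # determinism
  expect_error(simulate_model(m, study_protocol(), 100, dt = 0.2),
               "dt must be")
  bad <- injection_protocol(sine_source("nowhere", 1, 4))
  expect_error(simulate_model(m, bad, 100), "not in model")
})
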