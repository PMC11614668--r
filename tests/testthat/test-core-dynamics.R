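test_that("gating steady state hits its analytic anchor points", {
  m <- ra_neuron_params()$gates$m
  expect_equal(gating_steady_state(m$v_half, m), 0.5)
  # one slope-width above half-activation: 1/2 + 1/2 tanh(1)
  expect_equal(gating_steady_state(-20.5, m), 0.5 + 0.5 * tanh(1),
               tolerance = 1e-12)
  expect_equal(gating_steady_state(-20.5, m), 0.880797, tolerance = 1e-6)
  expect_lt(gating_steady_state(1e4, m), 1 + 1e-15)
  expect_gt(gating_steady_state(1e4, m), 1 - 1e-9)
})

test_that("gating time constant is a bell between tau0 and tau0 + tau1", {
  h <- ra_neuron_params()$gates$h
  expect_equal(gating_time_constant(h$v_half, h), h$tau0 + h$tau1)
  # one slope-width below half-activation: tau0 + tau1 * sech^2(1)
  expect_equal(gating_time_constant(-52, h), 0.1 + 0.75 * (1 - tanh(1)^2),
               tolerance = 1e-12)
  expect_equal(gating_time_constant(-52, h), 0.414981, tolerance = 1e-6)
  expect_equal(gating_time_constant(1e4, h), h$tau0, tolerance = 1e-9)
})

test_that("eta is monotone and tau bounded over the physiological range", {
  set.seed(42)
  p <- int_neuron_params()
  v <- sort(runif(400, -120, 60))
  for (nm in names(p$gates)) {
    sp <- p$gates[[nm]]
    eta <- gating_steady_state(v, sp)
    expect_true(all(eta > 0 & eta < 1), label = paste("eta bounds", nm))
    d <- diff(eta)
    if (sp$dv_eta > 0) expect_true(all(d >= 0), label = paste("eta up", nm))
    else expect_true(all(d <= 0), label = paste("eta down", nm))
    tau <- gating_time_constant(v, sp)
    expect_true(all(tau >= sp$tau0 - 1e-12 &
                    tau <= sp$tau0 + sp$tau1 + 1e-12),
                label = paste("tau bounds", nm))
  }
})

test_that("GHK flux factor handles the V = 0 singularity and reversal", {
  p <- int_neuron_params()
  vt <- 1000 * 8.314462618 * 310 / (2 * 96485.33212)  # RT/ZF in mV
  # limit at V = 0: (RT/ZF) (Ca_ext - Ca)
  expect_equal(ghk_factor(0, 1.11, p), vt * (2500 - 1.11),
               tolerance = 1e-9)
  # direct evaluation at x = -1
  expect_equal(ghk_factor(-vt, 1.11, p),
               -vt * (2500 * exp(1) - 1.11) / (1 - exp(1)),
               tolerance = 1e-12)
  expect_equal(ghk_factor(-vt, 1.11, p), 5.281e4, tolerance = 1e-3)
  # zero exactly at the Nernst-type reversal
  v_rev <- 20
  ca_rev <- 2500 * exp(-v_rev / vt)
  expect_equal(ghk_factor(v_rev, ca_rev, p), 0, tolerance = 1e-9)
  # continuity across 0: the straddling difference shrinks linearly with
  # eps (the factor is smooth there, slope ~1250 per mV)
  eps <- 10^seq(-5, -9)
  gap <- abs(ghk_factor(eps, 1.11, p) - ghk_factor(-eps, 1.11, p))
  expect_true(all(gap < 3000 * eps))
  expect_lt(gap[length(gap)], 1e-4)
  x_edge <- 1e-4 * vt
  direct <- x_edge * (2500 * exp(-1e-4) - 1.11) / (1 - exp(-1e-4))
  expect_equal(ghk_factor(x_edge * (1 - 1e-9), 1.11, p), direct,
               tolerance = 1e-6)
  expect_error(ghk_factor(0, -1, p), "calcium")
})

test_that("membrane currents follow the depolarizing-positive convention", {
  p <- ra_neuron_params()
  st <- neuron_state(p, v = -80,
                     gates = c(m = 0.5, h = 0.5, n = 0.5))
  cur <- membrane_currents(st, p)
  expect_equal(cur[["na"]], 1050 * 0.5^3 * 0.5 * (55 + 80))  # 8859.375 pA
  expect_equal(cur[["na"]], 8859.375)
  # zero gate product and zero driving force
  st0 <- neuron_state(p, v = -80, gates = c(m = 0, h = 0.3, n = 0.5))
  expect_equal(membrane_currents(st0, p)[["na"]], 0)
  st_na <- neuron_state(p, v = 55, gates = c(m = 0.5, h = 0.5, n = 0.5))
  expect_equal(membrane_currents(st_na, p)[["na"]], 0)
  # calcium/H channels do not exist in a projection neuron
  expect_error(membrane_currents(st, p, channels = c("na", "cat")),
               "not present")
})

test_that("state derivative vanishes at a true equilibrium", {
  p <- ra_neuron_params(g_na = 0, g_k = 0)
  st <- neuron_state(p)   # V = e_l, gates at steady state
  d <- state_derivative(st, p)
  expect_equal(d$v, 0)
  expect_equal(unname(d$gates), rep(0, 3))
})

test_that("leak-only membrane relaxes with the closed-form exponential", {
  p <- ra_neuron_params(g_na = 0, g_k = 0)
  net <- build_single_neuron(p, i_background = 0, v0 = -60)
  tr <- simulate_network(net, sim_config(duration = 20, dt = 0.02))
  tau <- p$capacitance / p$g_l               # 10/3 ms
  expect_equal(tau, 10 / 3)
  v_exact <- -80 + 20 * exp(-tr$time / tau)
  expect_lt(max(abs(tr$v[, 1] - v_exact) / abs(v_exact)), 1e-6)
})
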