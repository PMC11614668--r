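test_that("transmitter release sigmoid has the stated anchor values", {
  rp <- release_params()
  expect_equal(release_concentration(rp$v_p, rp), 2.84 / 2)
  expect_equal(release_concentration(7, rp), 2.84 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(release_concentration(7, rp), 2.07621, tolerance = 1e-5)
  expect_lt(release_concentration(-1e3, rp), 1e-12)
  v <- seq(-100, 60, by = 1)
  expect_true(all(diff(release_concentration(v, rp)) > 0))
})

test_that("receptor kinetics relax to alpha T / (alpha T + beta)", {
  gaba <- receptor_params("GABA_A")
  ampa <- receptor_params("AMPA")
  expect_equal(receptor_derivative(0, 0, gaba), 0)   # absorbing at rest
  r_inf <- function(rp, t) rp$alpha * t / (rp$alpha * t + rp$beta)
  expect_equal(r_inf(gaba, 2.84), 14.2 / 14.38)
  expect_equal(r_inf(gaba, 2.84), 0.987483, tolerance = 1e-6)
  expect_equal(r_inf(ampa, 2.84), 3.124 / 3.314)
  expect_equal(r_inf(ampa, 2.84), 0.942668, tolerance = 1e-6)
  expect_equal(receptor_derivative(r_inf(gaba, 2.84), 2.84, gaba), 0,
               tolerance = 1e-12)
  expect_error(receptor_derivative(0.5, -1, gaba), "nonnegative")
})

test_that("synaptic current signs: AMPA excites, GABA_A inhibits", {
  gsyn <- synapse_spec(1L, 2L, "GABA_A", 8)
  asyn <- synapse_spec(1L, 2L, "AMPA", 7)
  expect_equal(synaptic_current(gsyn, -50, r = 0.5), 8 * 0.5 * (-80 + 50))
  expect_equal(synaptic_current(gsyn, -50, r = 0.5), -120)
  expect_equal(synaptic_current(gsyn, -80, r = 0.7), 0)    # reversal
  expect_equal(synaptic_current(asyn, -50, r = 0), 0)
  expect_gt(synaptic_current(asyn, -50, r = 0.3), 0)
  expect_error(synapse_spec(3L, 3L, "AMPA", 1), "itself")
})

test_that("pulse response matches the two-phase closed form", {
  # presynaptic step to +55 mV for 5 ms, then back to -80 mV
  gaba <- receptor_params("GABA_A")
  rp <- release_params()
  t_hi <- release_concentration(55, rp)
  t_lo <- release_concentration(-80, rp)
  r0 <- gaba$alpha * t_lo / (gaba$alpha * t_lo + gaba$beta)
  sol <- deSolve::ode(
    y = c(r = r0), times = seq(0, 30, 0.01),
    func = function(t, y, p) {
      tc <- if (t < 5) t_hi else t_lo
      list(receptor_derivative(y, tc, gaba))
    }, rtol = 1e-10, atol = 1e-12)
  r_num <- sol[, "r"]
  tgrid <- sol[, "time"]
  k_on <- gaba$alpha * t_hi + gaba$beta
  r_inf_hi <- gaba$alpha * t_hi / k_on
  rise <- r_inf_hi + (r0 - r_inf_hi) * exp(-k_on * tgrid)
  r5 <- r_inf_hi + (r0 - r_inf_hi) * exp(-k_on * 5)
  k_off <- gaba$alpha * t_lo + gaba$beta
  r_inf_lo <- gaba$alpha * t_lo / k_off
  fall <- r_inf_lo + (r5 - r_inf_lo) * exp(-k_off * (tgrid - 5))
  r_exact <- ifelse(tgrid < 5, rise, fall)
  expect_lt(max(abs(r_num - r_exact) / r_exact), 1e-4)
  expect_gt(max(r_num), 0.98)                  # approaches 0.987
  expect_equal(1 / k_off, 1 / gaba$beta, tolerance = 1e-3)  # ~5.56 ms decay
})

test_that("open fraction stays in [0, 1] for arbitrary spiky drive", {
  set.seed(7)
  rp <- release_params()
  for (kind in c("AMPA", "GABA_A")) {
    rec <- receptor_params(kind)
    for (rep in 1:5) {
      spike_times <- sort(runif(15, 0, 40))
      vpre <- function(t) {
        -70 + 130 * sum(exp(-(t - spike_times)^2 / (2 * 0.25^2)))
      }
      sol <- deSolve::ode(
        y = c(r = runif(1)), times = seq(0, 50, 0.05),
        func = function(t, y, p) {
          list(receptor_derivative(y, release_concentration(vpre(t), rp), rec))
        }, rtol = 1e-8, atol = 1e-10)
      expect_true(all(sol[, "r"] >= -1e-9 & sol[, "r"] <= 1 + 1e-9))
    }
  }
})

test_that("composed release-receptor steady state is exact at fixed v_pre", {
  rp <- release_params()
  for (kind in c("AMPA", "GABA_A")) {
    rec <- receptor_params(kind)
    for (v in c(-70, -20, 0, 20)) {
      tc <- release_concentration(v, rp)
      r_star <- rec$alpha * tc / (rec$alpha * tc + rec$beta)
      expect_equal(receptor_derivative(r_star, tc, rec), 0, tolerance = 1e-14)
    }
  }
})
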