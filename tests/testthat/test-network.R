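test_that("microcircuit construction matches the wiring diagram", {
  uni <- build_microcircuit(bidirectional = FALSE)
  bi <- build_microcircuit(bidirectional = TRUE)
  expect_length(uni$neurons, 2)
  expect_length(uni$synapses, 2)
  expect_length(bi$synapses, 3)
  g <- vapply(bi$synapses, function(s) s$g_max, 0)
  kinds <- vapply(bi$synapses, function(s) s$receptor$kind, "")
  expect_equal(g, c(8, 8, 7))
  expect_equal(kinds, c("GABA_A", "GABA_A", "AMPA"))
  expect_equal(bi$neurons[[2]]$i_background, 300)
})

test_that("chain construction: counts, backgrounds, edge conductances", {
  net <- build_chain_network(n_ra = 50)
  expect_length(net$neurons, 51)
  expect_length(net$synapses, 52)
  ra_edges <- net$synapses[4:52]
  g <- vapply(ra_edges, function(s) s$g_max, 0)
  expect_equal(g, c(10, rep(8.2, 48)))
  bg <- vapply(net$neurons, function(n) n$i_background, 0)
  expect_equal(bg[2], 300)
  expect_equal(unique(bg[3:51]), 50)
  expect_length(ra_neuron_ids(net), 50)
  # per-edge conductance list applies to edges after the first
  gl <- seq(8.1, 8.3, length.out = 48)
  net2 <- build_chain_network(n_ra = 50, g_chain = gl)
  g2 <- vapply(net2$synapses[5:52], function(s) s$g_max, 0)
  expect_equal(g2, gl)
  expect_error(build_chain_network(n_ra = 1), "at least 2")
  expect_error(build_chain_network(n_ra = 50, g_chain = c(8, 8)), "length")
})

test_that("network validation catches dangling and trigger-less synapses", {
  n1 <- list(id = 1L, params = ra_neuron_params(), i_background = 0)
  expect_error(hvc_network(list(n1), list(synapse_spec(1L, 9L, "AMPA", 1))),
               "not a neuron id")
  expect_error(hvc_network(list(n1), list(synapse_spec(0L, 1L, "GABA_A", 1))),
               "trigger")
  expect_error(hvc_network(list(n1, n1)), "unique")
})

test_that("config files round-trip to bit-identical simulations", {
  net <- build_microcircuit(TRUE)
  cfg <- sim_config(duration = 25, settle = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_config(net, path, cfg)
  loaded <- read_network_config(path)
  expect_equal(loaded$cfg$duration, 25)
  expect_equal(loaded$cfg$settle, 5)
  tr1 <- simulate_network(net, cfg)
  tr2 <- simulate_network(loaded$network, loaded$cfg)
  expect_identical(tr1$v, tr2$v)
  # serialize-load-serialize is a fixed point
  path2 <- withr::local_tempfile(fileext = ".json")
  write_network_config(loaded$network, path2, loaded$cfg)
  expect_identical(readLines(path), readLines(path2))
})

test_that("parameter constructors agree with the shipped parameter table", {
  tab <- parameter_table()
  ra <- ra_neuron_params()
  ip <- int_neuron_params()
  val <- function(block, par) tab$value[tab$block == block &
                                        tab$parameter == par]
  expect_equal(ra$g_na, val("ra_neuron", "g_na"))
  expect_equal(ra$gates$m$dv_eta, val("ra_neuron", "m.dv_eta"))
  expect_equal(ra$gates$h$tau1, val("ra_neuron", "h.tau1"))
  expect_equal(ip$g_cat, val("int_neuron", "g_cat"))
  expect_equal(ip$phi, val("int_neuron", "phi"))
  expect_equal(ip$gates$H$dv_eta, val("int_neuron", "H.dv_eta"))
  expect_equal(ip$gates$H$dv_tau, val("int_neuron", "H.dv_tau"))
  expect_equal(release_params()$t_max, val("synapse", "t_max"))
  expect_equal(receptor_params("GABA_A")$alpha, val("synapse", "alpha_gaba"))
  expect_equal(trigger_params()$tau_r, val("trigger", "tau_r"))
})
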