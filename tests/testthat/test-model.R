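test_that("membrane derivatives match the model equations", {
  pv <- neuron_params("PV")
  pc <- neuron_params("PC")

  # LIF equilibrium: PV at rest with no input has zero drift
  d <- membrane_derivatives(V = -70, w = 0, g_e = 0, g_i = 0, params_row = pv)
  expect_equal(d$dV_dt, 0)
  expect_equal(d$dw_dt, 0)

  # zero driving force: synaptic current vanishes at its reversal potential
  d0 <- membrane_derivatives(V = -85, w = 0, g_e = 0, g_i = 5, params_row = pc)
  dref <- membrane_derivatives(V = -85, w = 0, g_e = 0, g_i = 0, params_row = pc)
  expect_equal(d0$dV_dt, dref$dV_dt)

  # independent scalar re-evaluation of the right-hand side for an adapting
  # cell at rest with w = 4 pA and zero conductances
  d4 <- membrane_derivatives(V = -70, w = 4, g_e = 0, g_i = 0, params_row = pc)
  exp_term <- pc$g_L * pc$Delta_T * exp((-70 - pc$V_th) / pc$Delta_T)
  expect_equal(d4$dV_dt, (exp_term - 4) / pc$C_m, tolerance = 1e-12)
  expect_equal(d4$dw_dt, -4 / 120)

  # the PV row carries no exponential term: dV/dt is exactly linear in V
  v <- c(-70, -60, -50)
  dv <- membrane_derivatives(V = v, w = 0, g_e = 0, g_i = 0, params_row = pv)$dV_dt
  expect_equal(diff(dv, differences = 2), 0, tolerance = 1e-12)
})

test_that("membrane derivatives reject bad state", {
  pc <- neuron_params("PC")
  expect_error(membrane_derivatives(NaN, 0, 0, 0, pc), class = "spikevar_bad_state")
  expect_error(membrane_derivatives(-60, 0, -1, 0, pc), class = "spikevar_bad_state")
  expect_error(membrane_derivatives(0, 0, 0, 0, pc), class = "spikevar_bad_state")
})

test_that("parameter validation enforces the invariants", {
  p <- neuron_params()
  expect_s3_class(p, "neuron_params")
  bad <- p
  bad$V_r[1] <- bad$V_th[1] + 1
  expect_error(validate_neuron_params(bad), class = "spikevar_bad_params")
  bad2 <- p
  bad2$a[1] <- NA # partial adaptation block
  expect_error(validate_neuron_params(bad2), class = "spikevar_bad_params")
  expect_error(neuron_params("XX"), class = "spikevar_bad_population")
})

test_that("conductance decay is exponential, additive, and a semigroup", {
  expect_equal(decay_conductance(1, dt = 5, tau = 5), exp(-1))
  expect_equal(decay_conductance(1, dt = 0, tau = 5), 1)
  # simultaneous spikes superpose additively
  expect_equal(decay_conductance(0.2 + 0.2, dt = 0, tau = 5), 0.4)
  # dt1 + dt2 equals sequential application, at machine precision
  g <- 2.34
  for (pair in list(c(0.3, 1.7), c(1, 1), c(0.05, 9))) {
    expect_equal(decay_conductance(g, sum(pair), tau = 3.3),
                 decay_conductance(decay_conductance(g, pair[1], tau = 3.3),
                                   pair[2], tau = 3.3),
                 tolerance = 1e-15)
  }
  expect_error(decay_conductance(1, dt = -1, tau = 5), class = "spikevar_bad_dt")
})

test_that("psp peak is zero at zero input and monotone in conductance", {
  pc <- neuron_params("PC")
  expect_equal(psp_peak(0, pc$tau_e, pc$E_e, pc), 0)
  expect_equal(psp_peak(1, pc$tau_e, E_rev = -55, pc, V_hold = -55), 0)
  # sign follows the driving force
  expect_gt(psp_peak(0.5, pc$tau_e, pc$E_e, pc, V_hold = -55), 0)
  expect_lt(psp_peak(0.5, pc$tau_i, pc$E_i, pc, V_hold = -55), 0)
  # strictly increasing magnitude along a geometric ladder of g_peak
  ladder <- 0.05 * 2^(0:6)
  peaks <- vapply(ladder, function(g)
    abs(psp_peak(g, pc$tau_e, pc$E_e, pc, V_hold = -55)), numeric(1))
  expect_true(all(diff(peaks) > 0))
  # sublinear in g for conductance-based synapses (saturation toward E_rev)
  expect_lt(peaks[7] / peaks[1], 64)
})

test_that("single neurons spike, reset, adapt, and respect refractoriness", {
  # constant-current LIF rate matches the closed-form interspike interval
  p <- neuron_params("PV")
  p$I_e <- 3000
  cfg <- network_config(sizes = c(PV = 1),
                        conn_prob = matrix(0, 1, 1, dimnames = list("PV", "PV")),
                        conductance = matrix(0, 1, 1, dimnames = list("PV", "PV")),
                        params = p, excitatory = "PV")
  net <- build_network(cfg, seed = 1)
  prot <- trial_protocol(1000, 0, 0, 1000)
  rec <- run_trial(net, input_spec(base_rates = c(PV = 0)), protocol = prot,
                   seed = 1)
  tau_m <- p$C_m / p$g_L
  V_inf <- p$E_L + p$I_e / p$g_L
  isi <- tau_m * log((V_inf - p$V_r) / (V_inf - p$V_th)) + p$t_r
  expect_equal(nrow(rec$spikes) / 1.0, 1000 / isi, tolerance = 0.02)
  # refractoriness: every interspike interval is at least t_r
  expect_true(all(diff(rec$spikes$time_ms) >= p$t_r))

  # spike-triggered adaptation (b > 0) slows an adapting neuron down:
  # interspike intervals lengthen over the spike train
  pa <- neuron_params("PC")
  pa$I_e <- 700
  cfga <- network_config(sizes = c(PC = 1),
                         conn_prob = matrix(0, 1, 1, dimnames = list("PC", "PC")),
                         conductance = matrix(0, 1, 1, dimnames = list("PC", "PC")),
                         params = pa)
  neta <- build_network(cfga, seed = 1)
  reca <- run_trial(neta, input_spec(base_rates = c(PC = 0)), protocol = prot,
                    seed = 1)
  isis <- diff(reca$spikes$time_ms)
  expect_gt(length(isis), 5)
  expect_gt(isis[length(isis)], isis[1])
})
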