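test_that("parameter constructors enforce their invariants", {
  np <- neuron_params()
  expect_equal(np$C, 120)
  expect_equal(np$g_L, 7.14)
  expect_equal(np$tau_e, 1)
  expect_error(neuron_params(tau_e = 0), "time constants")
  expect_error(neuron_params(V_r = -80), "E_i < V_r")
  expect_error(network_params(CP_e = 1.2), "probabilities")
  expect_error(network_params(nu_bkg_e = -5), "rates")
  expect_error(perturbation_spec("selective_e", fraction = 2), "fraction")
  ps <- perturbation_spec("selective_i", fraction = 0.3)
  # selective drive to inhibitory units is twice the excitatory-unit rate
  expect_equal(ps$rate_exc_to_i, 2 * perturbation_spec("selective_e")$rate_exc_to_e)
  expect_equal(ps$fraction_e, 0)
  sys <- perturbation_spec("systemic", fraction = 0.5)
  expect_equal(sys$rate_exc_to_e, 29500)
  expect_equal(sys$rate_inh_to_e, 27000)
  expect_equal(sys$fraction_i, 0.5)
})

test_that("alpha kernel matches its closed form and peaks at J", {
  expect_equal(alpha_kernel(0, J = 1, tau = 1), 0)
  expect_equal(alpha_kernel(-3, J = 1, tau = 1), 0)
  expect_equal(alpha_kernel(1, J = 3, tau = 1), 3)
  expect_equal(alpha_kernel(5, J = 1, tau = 1), 5 * exp(-4))
  expect_error(alpha_kernel(1, J = 1, tau = 0), "tau")
  # peak location/value identity over a parameter grid
  for (J in c(0.5, 1, 3)) for (tau in c(0.5, 1, 2)) {
    tt <- seq(0, 10 * tau, by = tau / 500)
    g <- alpha_kernel(tt, J, tau)
    expect_equal(max(g), J, tolerance = 1e-5)
    expect_equal(tt[which.max(g)], tau, tolerance = tau / 100)
  }
})

test_that("poisson input generator has the right count and interval statistics", {
  expect_identical(make_poisson_input(0, 1000, seed = 1), numeric(0))
  expect_error(make_poisson_input(-1, 1000), "rate")
  # count oracle: rate 970 Hz over 10 s
  counts <- vapply(1:20, function(s) length(make_poisson_input(970, 10000, seed = s)), 1)
  expect_lt(abs(mean(counts) - 9700), 4 * sqrt(9700) / sqrt(20))
  # interval distribution: KS against Exponential(rate)
  ev <- make_poisson_input(1000, 1e4 * 1.05, seed = 42)[1:10001]
  ks <- suppressWarnings(stats::ks.test(diff(ev), "pexp", rate = 1))  # 1000 Hz = 1/ms
  expect_gt(ks$p.value, 0.01)
  # events stay inside [0, duration)
  expect_true(all(ev >= 0 & ev < 1e4 * 1.05))
})

test_that("network construction matches binomial and clipped-Gaussian oracles", {
  netp <- network_params()
  expect_equal(sum(build_network(network_params(CP_e = 0), seed = 1)$weights[1:160, ] > 0), 0)
  # out-degree oracle over repeated seeds
  deg_e <- c(); deg_i <- c(); w_all <- c()
  for (s in 1:30) {
    net <- build_network(netp, seed = s)
    A <- net$weights > 0
    deg_e <- c(deg_e, rowSums(A)[1:160])
    deg_i <- c(deg_i, rowSums(A)[161:200])
    w_all <- c(w_all, net$weights[1:160, ][net$weights[1:160, ] > 0])
  }
  se <- sqrt(199 * 0.15 * 0.85 / length(deg_e))
  expect_lt(abs(mean(deg_e) - 0.15 * 199), 3 * se)
  expect_true(all(deg_i == 199))          # CP_i = 1: inhibitory units hit every target
  expect_true(all(diag(build_network(netp, seed = 3)$weights) == 0))
  # clipped Gaussian(1, 0.2): clipping is negligible, mean stays at J_e
  expect_lt(abs(mean(w_all) - 1), 3 * 0.2 / sqrt(length(w_all)))
  expect_true(all(w_all >= 0))
  # determinism of construction
  expect_identical(build_network(netp, seed = 7)$weights,
                   build_network(netp, seed = 7)$weights)
})

test_that("with no input the resting state is a fixed point", {
  net <- quiet_single_unit()
  r <- simulate_network(net, neuron_params(), duration = 200, dt = 0.1,
                        seed = 1, record_dt = 1)
  expect_equal(nrow(r$spikes), 0)
  expect_true(all(abs(r$traces$V - neuron_params()$E_L) < 1e-12))
  expect_true(all(r$traces$G_e == 0) && all(r$traces$G_i == 0))
})

test_that("passive decay follows the closed-form membrane solution", {
  np <- neuron_params()
  r <- simulate_network(quiet_single_unit(), np, duration = 100, dt = 0.01,
                        v0 = -55, seed = 1, record_dt = 0.01)
  v_ref <- np$E_L + (-55 - np$E_L) * exp(-r$traces$time * np$g_L / np$C)
  expect_lt(max(abs(r$traces$V[, 1] - v_ref)), 0.1)
  # membrane time constant sanity: C/g_L ~ 16.8 ms
  expect_equal(np$C / np$g_L, 16.81, tolerance = 1e-3)
})

test_that("single synaptic event response matches a fine-step reference", {
  np <- neuron_params()
  # two-unit chain: unit 1 starts above threshold, spikes once, and delivers
  # a single excitatory event with known weight to unit 2
  netp <- network_params(N_e = 2, N_i = 0, CP_e = 1, nu_bkg_e = 0, nu_bkg_i = 0)
  net <- build_network(netp, seed = 1)
  net$weights[,] <- 0
  net$weights[1, 2] <- 1
  dt <- 0.01
  r <- simulate_network(net, np, duration = 30, dt = dt,
                        v0 = c(np$E_T + 1, np$E_L), seed = 1, record_dt = dt)
  expect_equal(nrow(r$spikes), 1)          # only the forced source spike
  t_event <- r$spikes$t[1] + dt            # delivery on the following step
  peak_impl <- max(r$traces$V[, 2])
  peak_ref <- reference_single_event_peak(np, J = 1, t0 = t_event,
                                          t_end = 30, dt = 0.001)
  depol_impl <- peak_impl - np$E_L
  depol_ref <- peak_ref - np$E_L
  expect_lt(abs(depol_impl - depol_ref) / depol_ref, 0.01)
})

test_that("refractoriness and Dale's law hold on a driven network run", {
  np <- neuron_params()
  net <- build_network(network_params(), seed = 11)
  expect_true(all(net$weights >= 0))
  r <- simulate_network(net, np, duration = 3000, dt = 0.1, seed = 21)
  expect_gt(nrow(r$spikes), 100)           # regime check: network is active
  isi <- unlist(tapply(r$spikes$t, r$spikes$unit, function(x) diff(sort(x))))
  expect_true(all(isi >= np$t_ref))
  # conductance traces are nonnegative throughout
  r2 <- simulate_network(net, np, duration = 500, dt = 0.1, seed = 3, record_dt = 0.5)
  expect_true(all(r2$traces$G_e >= 0) && all(r2$traces$G_i >= 0))
})

test_that("identical parameters and seeds give bit-identical spike output", {
  net <- build_network(network_params(), seed = 5)
  a <- simulate_network(net, neuron_params(), duration = 1000, dt = 0.1, seed = 9)
  b <- simulate_network(net, neuron_params(), duration = 1000, dt = 0.1, seed = 9)
  expect_identical(a$spikes, b$spikes)
  # and a perturbed run with explicit activated set is deterministic too
  pert <- perturbation_spec("systemic", fraction = 0.5)
  act <- select_activated(net, pert, seed = 2)
  p1 <- simulate_network(net, neuron_params(), duration = 1000, dt = 0.1,
                         seed = 9, perturbation = pert, activated = act)
  p2 <- simulate_network(net, neuron_params(), duration = 1000, dt = 0.1,
                         seed = 9, perturbation = pert, activated = act)
  expect_identical(p1$spikes, p2$spikes)
})

test_that("halving the integration step changes the population rate by < 5%", {
  net <- build_network(network_params(), seed = 4)
  r1 <- simulate_network(net, neuron_params(), duration = 8000, dt = 0.1, seed = 13)
  r2 <- simulate_network(net, neuron_params(), duration = 8000, dt = 0.05, seed = 13)
  rate1 <- nrow(r1$spikes) / 200 / 8
  rate2 <- nrow(r2$spikes) / 200 / 8
  expect_lt(abs(rate1 - rate2) / rate1, 0.05)
})

test_that("dt must resolve the synaptic kernel and windows must be recorded", {
  net <- quiet_single_unit()
  expect_error(simulate_network(net, neuron_params(), duration = 10, dt = 1),
               "dt must be smaller")
  r <- simulate_network(net, neuron_params(), duration = 100, dt = 0.1, seed = 1)
  expect_error(measure_conductance_and_rate(r, list(a = c(0, 50))),
               "not recorded")
})

test_that("window summaries report conductance and rate changes with the right signs", {
  np <- neuron_params()
  netp <- network_params()
  net <- build_network(netp, seed = 2)
  stim <- stimulus_spec(onsets = 1500, duration = 500)
  windows <- list(pre = c(500, 1500), stim = c(1500, 2000))
  r0 <- simulate_network(net, np, duration = 2000, dt = 0.1, stimulus = stim,
                         seed = 6, record_dt = 1)
  m0 <- measure_conductance_and_rate(r0, windows)
  # stimulus adds excitatory drive: G_e rises in the stimulus window
  expect_gt(m0$G_e[m0$window == "stim" & m0$population == "E"],
            m0$G_e[m0$window == "pre" & m0$population == "E"])
  # systemic activation raises both baseline conductances
  pert <- perturbation_spec("systemic", fraction = 0.5)
  r1 <- simulate_network(net, np, duration = 2000, dt = 0.1, stimulus = stim,
                         seed = 6, perturbation = pert, select_seed = 2,
                         record_dt = 1)
  m1 <- measure_conductance_and_rate(r1, windows)
  for (p in c("E", "I")) {
    expect_gt(m1$G_e[m1$window == "pre" & m1$population == p],
              m0$G_e[m0$window == "pre" & m0$population == p])
    expect_gt(m1$G_i[m1$window == "pre" & m1$population == p],
              m0$G_i[m0$window == "pre" & m0$population == p])
  }
  # zero-input run: everything zero
  mq <- measure_conductance_and_rate(
    simulate_network(quiet_single_unit(), np, duration = 500, dt = 0.1,
                     seed = 1, record_dt = 1),
    list(all = c(0, 500)))
  expect_equal(mq$G_e, 0)
  expect_equal(mq$G_i, 0)
  expect_equal(mq$rate, 0)
})
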