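test_that("threshold crossings are bracketed and refined", {
  p <- ref_params()   # beta = delta = 0.5: E0 family, no E1 drive
  cell <- make_reference_cell("adapting", seed = 2)
  p <- cell$params
  n <- nondimensionalize(p, 600)
  ic <- first_spike_conditions(p, n, 600)
  cr <- solve_to_threshold(n, ic, 0, 400 / n$tau, n$Vth_tilde)
  expect_false(is.null(cr))
  V_at <- general_integral(n, list(V = ic$V0, I_adap = ic$I_adap0,
                                   I_dep = ic$I_dep0), 0, cr)$V
  expect_lt(abs(V_at - n$Vth_tilde), 1e-9)

  # from the stable subthreshold equilibrium there is no crossing
  n0 <- nondimensionalize(p, 0.5 * p$I_th)
  e <- equilibria(n0)[[1]]
  expect_null(solve_to_threshold(n0, list(V = e$V_star,
                                          I_adap = e$I_adap_star,
                                          I_dep = 0),
                                 0, 1000 / n0$tau, n0$Vth_tilde))
})

test_that("zero current leaves the membrane at rest", {
  cell <- make_reference_cell("adapting", seed = 2)
  out <- simulate_constant(cell, 0, 100)
  expect_length(out$spikes$spike_times, 0)
  expect_true(out$spikes$never_fired)
  expect_true(all(abs(out$trace$V_mV - cell$params$E_L) < 1e-9))
})

test_that("hyperpolarizing current relaxes toward the clamped equilibrium", {
  cell <- make_reference_cell("adapting", seed = 2)
  out <- simulate_constant(cell, cell$params$I_stim_neg, 2000)
  expect_length(out$spikes$spike_times, 0)
  expect_equal(utils::tail(out$trace$V_mV, 1), cell$params$V_min,
               tolerance = 1e-6)
})

test_that("an adapting cell fires with non-decreasing intervals", {
  cell <- make_reference_cell("adapting", seed = 2)
  for (I in c(200, 600)) {
    spk <- simulate_constant(cell, I, 400)$spikes$spike_times
    expect_gt(length(spk), 3)
    expect_true(all(diff(diff(spk)) > -1e-9))
    expect_true(all(diff(spk) > cell$params$dt_ref))
  }
})

test_that("sampled potential never exceeds threshold between spikes", {
  cell <- make_reference_cell("adapting", seed = 2)
  out <- simulate_constant(cell, 600, 200)
  expect_true(all(out$trace$V_mV <= cell$params$V_th + 1e-6))
})

test_that("spike times are invariant under halving the scan step", {
  cell <- make_reference_cell("adapting", seed = 2)
  s1 <- simulate_constant(cell, 600, 300, coarse_ms = 0.05)$spikes$spike_times
  s2 <- simulate_constant(cell, 600, 300, coarse_ms = 0.025)$spikes$spike_times
  expect_length(s2, length(s1))
  expect_true(all(abs(s1 - s2) < 1e-6))
})

test_that("a block cutoff terminates the train at the cutoff", {
  cell <- make_reference_cell("blocking", seed = 2)
  cut <- block_cutoff(cell$block, 800)
  out <- simulate_constant(cell, 800, 400)$spikes
  expect_equal(out$blocked_at, cut)
  expect_true(all(out$spike_times < cut))
  # a current outside the validity region keeps firing to the end
  out2 <- simulate_constant(cell, 600, 400)$spikes
  expect_true(is.na(out2$blocked_at))
  expect_gt(utils::tail(out2$spike_times, 1), 380)
})

test_that("the after-step correction factor matches hand arithmetic", {
  th <- theta_star(-0.8, -0.85, dt = 0.1, delta = 0.1, alpha_bb = 0.5)
  expect_equal(th$theta, -0.04)
  expect_equal(th$theta_star, 0)
  expect_equal(theta_star(-0.5, -0.9, 0.1, 0.1, 0.5)$theta_star,
               theta_star(-0.5, -0.9, 0.1, 0.1, 0.5)$theta)
  # with equal consecutive samples the expression collapses
  Vp <- -0.7; d <- 0.2; ab <- 0.4
  expect_equal(theta_star(Vp, Vp, 0.05, d, ab)$theta,
               -d * (Vp + 1) / ab - 1)
})

test_that("the stimulation-onset shift reproduces the worked value", {
  expect_equal(t_start_shift(100, I_prev = 400, I_th = 200), 150)
  expect_equal(t_start_shift(0, 400, 200), 0)
})

test_that("a single-segment protocol equals the constant simulation", {
  cell <- make_reference_cell("adapting", seed = 2)
  a <- simulate_constant(cell, 600, 400)$spikes$spike_times
  b <- simulate_piecewise(cell,
                          stimulus_protocol(0, 400, 600))$spikes$spike_times
  expect_identical(a, b)
})

test_that("concatenating two identical segments equals one long segment", {
  cell <- make_reference_cell("adapting", seed = 2)
  one <- simulate_piecewise(cell, stimulus_protocol(0, 400, 600))
  two <- simulate_piecewise(cell, stimulus_protocol(c(0, 200), c(200, 400),
                                                    c(600, 600)))
  expect_equal(one$spikes$spike_times, two$spikes$spike_times,
               tolerance = 1e-9)
})

test_that("a downward step to zero silences the segment", {
  cell <- make_reference_cell("adapting", seed = 2)
  prot <- stimulus_protocol(c(0, 200), c(200, 400), c(600, 0))
  out <- simulate_piecewise(cell, prot)
  expect_true(all(out$spikes$spike_times < 200 + cell$params$dt_ref))
  late <- out$trace[out$trace$t_ms > 360, ]
  expect_lt(max(abs(late$V_mV - cell$params$E_L)), 1)
})

test_that("suprathreshold steps in both directions keep the train valid", {
  cell <- make_reference_cell("adapting", seed = 2)
  prot <- stimulus_protocol(c(0, 150, 300), c(150, 300, 450),
                            c(400, 800, 400))
  out <- simulate_piecewise(cell, prot)
  expect_true(all(diff(out$spikes$spike_times) > cell$params$dt_ref))
  expect_true(all(out$trace$V_mV <= cell$params$V_th + 1e-6))
  # spikes occur in every suprathreshold segment
  for (k in 1:3) {
    seg <- out$spikes$spike_times >= prot$t_begin_ms[k] &
      out$spikes$spike_times < prot$t_end_ms[k]
    expect_gt(sum(seg), 0)
  }
})

test_that("malformed protocols are rejected", {
  expect_error(stimulus_protocol(c(0, 100), c(100, 90), c(1, 2)), "t_end")
  expect_error(stimulus_protocol(c(0, 150), c(100, 250), c(1, 2)),
               "contiguous")
  expect_error(stimulus_protocol(c(100, 0), c(200, 100), c(1, 2)), "sorted")
})

test_that("subthreshold currents never elicit spikes when constraints hold", {
  set.seed(77)
  for (k in 1:5) {
    cell <- make_reference_cell("adapting", seed = 100 + k)
    p <- cell$params
    I <- runif(1, 1, p$I_th - 1)
    n <- nondimensionalize(p, I)
    expect_true(check_constraints(n)$passed)
    expect_null(solve_to_threshold(n, list(V = -1, I_adap = 0, I_dep = 0),
                                   0, 1e4 / n$tau, n$Vth_tilde))
  }
})
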