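test_that("the Monod update evaluates its limits and values", {
  m <- monod_coefficients(2, 0, 1, 5)
  expect_equal(monod_value(m, 0, 500), 1)              # chi -> 0+ gives c
  expect_equal(monod_value(m, 5, 500), 2)              # c + a/2 at chi = d
  expect_equal(monod_value(m, 1e9, 500), 3, tolerance = 1e-8)  # plateau
  expect_error(monod_coefficients(1, 0, 0, 0), "positive")
  expect_error(monod_value(m, -1, 500))
})

test_that("monotonicity and positivity verdicts follow the coefficient signs", {
  r1 <- monod_properties(monod_coefficients(1, 0.001, 0.5, 10))
  expect_equal(r1$monotone_in_chi, "increasing")
  expect_equal(r1$monotone_in_I, "increasing")
  expect_equal(r1$positivity_verdict, "global")

  r2 <- monod_properties(monod_coefficients(-1, -0.01, 1.5, 10))
  expect_equal(r2$monotone_in_chi, "decreasing")
  expect_equal(r2$positivity_verdict, "global")

  r3 <- monod_properties(monod_coefficients(-1, 0.01, 0.2, 10))
  expect_equal(r3$positivity_verdict, "fails")
  # the plateau indeed goes negative at large currents
  expect_lt(r3$plateau_fn(1000), 0)
})

test_that("positivity verdicts agree with brute-force minimization", {
  set.seed(31)
  for (k in 1:60) {
    m <- monod_coefficients(a = runif(1, -2, 2), b = runif(1, -3e-3, 3e-3),
                            c = runif(1, -1, 2), d = runif(1, 1, 200))
    if (m$a == 0) next
    verdict <- monod_properties(m, I_range = c(200, 1000))$positivity_verdict
    chi <- c(seq(1e-6, 1, length.out = 20), seq(1, 1e4, length.out = 200))
    Is <- seq(1, 2000, length.out = 80)
    vals <- outer(chi, Is, function(x, i) monod_value(m, x, i))
    global_min <- min(vals)
    if (verdict == "global") expect_gte(global_min, -1e-9)
    if (global_min >= 0) expect_true(verdict %in% c("global",
                                                    "range_restricted"))
  }
})

test_that("Monod monotonicity holds numerically on random draws", {
  set.seed(32)
  chi <- seq(0.1, 500, length.out = 100)
  for (k in 1:40) {
    m <- monod_coefficients(a = sample(c(-1, 1), 1) * runif(1, 0.1, 2),
                            b = runif(1, -2e-3, 2e-3),
                            c = runif(1, 0, 2), d = runif(1, 1, 150))
    v <- monod_value(m, chi, 600)
    if (m$a > 0) expect_true(all(diff(v) > 0)) else
      expect_true(all(diff(v) < 0))
    vI <- vapply(seq(100, 1500, length.out = 100),
                 function(I) monod_value(m, 50, I), numeric(1))
    if (m$a * m$b > 0) expect_true(all(diff(vI) > 0))
    if (m$a * m$b < 0) expect_true(all(diff(vI) < 0))
  }
})

test_that("the admissibility bound H is computed and increases with current", {
  expect_equal(threshold_H(nondim(0.2, 0.4, 0.1), 0, -1), 0.5)
  expect_equal(threshold_H(nondim(0, 0.4, 0.1), 0, -1), 0)
  p <- ref_params()
  Hs <- vapply(seq(100, 1000, by = 50), function(I) {
    n <- nondimensionalize(p, I)
    threshold_H(n, 0.1, n$Vr_tilde)
  }, numeric(1))
  expect_true(all(diff(Hs) > 0))
  # slope per pA is 1/(K beta)
  n <- nondimensionalize(p, 0)
  expect_equal(diff(Hs)[1] / 50, 1 / (p$K * n$beta), tolerance = 1e-12)
})

test_that("out-of-range correction translates the Monod function", {
  n <- nondim(0.2, 0.4, 0.1)
  ok <- monod_coefficients(1, 1e-3, 0.5, 20)
  expect_identical(adjust_monod_out_of_range(ok, n, 1500, 0, -1), ok)

  # eta = 0 reproduces the closed-form intercept
  neg <- monod_coefficients(1e-3, 1e-3, -0.2, 20)
  adj <- adjust_monod_out_of_range(neg, n, 100, I_dep0 = 0, V0 = -1,
                                   chi_first = 10)
  info <- attr(adj, "adjusted")
  expect_equal(info$path, "eta_translation")
  c_eta0 <- n$alpha / n$beta - neg$a * exp(neg$b * 100)
  if (info$eta == 0) expect_equal(adj$c, c_eta0)
  expect_gte(adj$c, 0)

  # when no eta gives positivity, the first-spike value is zeroed
  deep <- monod_coefficients(1, 0, -0.5, 20)
  adj2 <- adjust_monod_out_of_range(deep, n, 1500, I_dep0 = 0, V0 = -1,
                                    chi_first = 12)
  expect_equal(attr(adj2, "adjusted")$path, "first_spike_zero")
  expect_equal(monod_value(adj2, 12, 1500), 0, tolerance = 1e-12)
})

test_that("first-spike conditions seed the depolarizing current", {
  p <- ref_params()
  for (I in c(0, 100, 200)) {   # at or below the rheobase
    ic <- first_spike_conditions(p, nondimensionalize(p, I), I)
    expect_equal(ic$V0, -1)
    expect_equal(ic$I_adap0, 0)
    expect_equal(ic$I_dep0, 0)
  }
  ic <- first_spike_conditions(p, nondimensionalize(p, 300), 300)
  # proportional to the 100 pA excess, rescaled
  expect_equal(ic$I_dep0, -p$k_2 * p$I_dep_start * 100 / (p$E_L * p$k_adap))
  ic2 <- first_spike_conditions(p, nondimensionalize(p, 400), 400)
  expect_equal(ic2$I_dep0 / ic$I_dep0, 2)
})

test_that("after-spike conditions clip at zero and flag the H bound", {
  p <- ref_params()
  n <- nondimensionalize(p, 400)
  m <- monod_coefficients(0.05, 1e-4, 0.02, 30)
  ic <- after_spike_conditions(p, n, m, t_spk_plus = 50, t_start = 0,
                               I_stim = 400)
  expect_equal(ic$V0, n$Vr_tilde)
  expect_equal(ic$I_adap0, monod_value(m, 50, 400))
  expect_false(ic$flag_H)
  # limit chi -> 0+ returns the intercept
  ic0 <- after_spike_conditions(p, n, m, t_spk_plus = 1e-12, t_start = 0,
                                I_stim = 400)
  expect_equal(ic0$I_adap0, m$c, tolerance = 1e-10)
  # a negative Monod value is clipped, positivity prioritized
  mneg <- monod_coefficients(0.05, 1e-4, -1, 30)
  icn <- after_spike_conditions(p, n, mneg, 50, 0, 400)
  expect_equal(icn$I_adap0, 0)
  # values above H are flagged, not rejected
  mbig <- monod_coefficients(5, 1e-4, 5, 30)
  expect_true(after_spike_conditions(p, n, mbig, 50, 0, 400)$flag_H)
})

test_that("firing-block detection implements the two-interval rule", {
  expect_true(detect_firing_block(c(100, 260, 300), 400)$blocked)
  expect_false(detect_firing_block(c(100, 320, 350), 400)$blocked)
  s <- detect_firing_block(c(120), 400)
  expect_false(s$blocked); expect_false(s$never_fired)
  e <- detect_firing_block(numeric(0), 400)
  expect_false(e$blocked); expect_true(e$never_fired)
})

test_that("block rules reproduce the worked interneuron examples", {
  # first cell: blocks at 200, 600, 800 pA; fires at 400; silent at 1000
  r1 <- rbind(raster_row(200, 230, 59.90),    # anchor 259.95
              raster_row(400, 390, 12.20),    # anchor 396.10, not blocked
              raster_row(600, 250, 55.70),    # anchor 277.85
              raster_row(800, 220, 48.70))    # anchor 244.35
  rule1 <- build_block_rule(r1, 400)
  expect_length(rule1$lines, 2)
  l1 <- rule1$lines[[1]]; l2 <- rule1$lines[[2]]
  expect_equal(round(l1$A, 2), 0.68)
  expect_equal(l1$B, 123.80, tolerance = 1e-9)
  expect_equal(l1$threshold, 300)
  expect_equal(l1$validity, "le")
  expect_equal(round(l2$A, 2), -0.17)
  expect_equal(l2$B, 378.35, tolerance = 1e-9)
  expect_equal(l2$threshold, 500)
  expect_equal(l2$validity, "ge")
  expect_equal(rule1$I_fire, c(400, 400))

  # cutoffs: inside the first validity region, between regions, beyond
  expect_equal(block_cutoff(rule1, 250), l1$A * 250 + l1$B)
  expect_null(block_cutoff(rule1, 400))
  expect_true(is.numeric(block_cutoff(rule1, 900)))

  # second cell: single block interval [400, 600], fires at 800 and 1000
  r2 <- rbind(raster_row(400, 200, 41.00),    # anchor 220.50
              raster_row(600, 290, 50.30),    # anchor 315.15
              raster_row(800, 380, 15),
              raster_row(1000, 385, 12))
  rule2 <- build_block_rule(r2, 400)
  expect_length(rule2$lines, 1)
  l <- rule2$lines[[1]]
  expect_equal(round(l$A, 2), 0.47)
  expect_equal(l$B, 31.20, tolerance = 1e-9)
  expect_equal(l$threshold, 700)
  expect_equal(l$validity, "le")
  expect_equal(rule2$block_intervals[[1]], c(400, 600))
  expect_equal(rule2$I_fire, 800)
})

test_that("degenerate and empty rasters are handled explicitly", {
  # a single-spike current is excluded with a warning
  r <- rbind(raster_row(200, 230, 59.90),
             raster_row(400, 390, 12.20),
             data.frame(cell_id = "c", I_pA = 600, spike_time_ms = 100))
  expect_warning(build_block_rule(r, 400), "single spike")
  # no blocking current: empty rule
  r2 <- rbind(raster_row(200, 390, 12), raster_row(400, 392, 10))
  expect_length(build_block_rule(r2, 400)$lines, 0)
  # all currents block: no I_fire available
  r3 <- rbind(raster_row(200, 100, 20), raster_row(400, 110, 20))
  expect_error(build_block_rule(r3, 400), "I_fire")
})
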