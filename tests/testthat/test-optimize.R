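make_dataset <- function(cell, currents = seq(200, 1000, 200), T_end = 400) {
  raster <- generate_constant_raster(cell, currents = currents, T_end = T_end)
  spike_dataset(raster, T_end = T_end, E_L = cell$params$E_L,
                V_r = cell$params$V_r, V_th = cell$params$V_th,
                currents = currents)
}

test_that("the ISI band brackets every admissible adaptation value", {
  cell <- make_reference_cell("adapting", seed = 2)
  p <- cell$params
  n <- nondimensionalize(p, 600)
  I_dep0 <- -p$k_2 * p$I_dep0 / (p$E_L * p$k_adap)
  b <- isi_bounds(p, n, I_dep0, n$Vr_tilde)
  expect_lt(b$ISI_min, b$ISI_max)
  expect_equal(b$I_adap0_min, 0)
  H <- threshold_H(n, I_dep0, n$Vr_tilde)
  expect_equal(b$I_adap0_max, H)
  # intermediate values give intermediate, monotone interspike intervals
  isis <- vapply(seq(0.05, 0.95, length.out = 10) * H, function(Ia0) {
    cr <- solve_to_threshold(n, list(V = n$Vr_tilde, I_adap = Ia0,
                                     I_dep = I_dep0),
                             0, 1e4 / n$tau, n$Vth_tilde)
    cr * n$tau + p$dt_ref
  }, numeric(1))
  expect_true(all(isis > b$ISI_min - 1e-6 & isis < b$ISI_max + 1e-6))
  expect_true(all(diff(isis) > 0))
})

test_that("the spike-timing cost is exact on constructed cases", {
  cell <- make_reference_cell("adapting", seed = 2)
  ds <- make_dataset(cell)
  base <- spike_cost(cell$params, ds)
  expect_lt(base, 0.01)   # the generating cell is inside its own bands

  # shifting one first spike by 3 ms adds 3 ms of cost (ISIs unchanged)
  ds3 <- ds
  ds3$trains[["600"]] <- ds3$trains[["600"]] + 3
  expect_equal(spike_cost(cell$params, ds3) - base, 3, tolerance = 1e-3)

  # an ISI pushed above the band adds exactly the excess
  n <- nondimensionalize(cell$params, 600)
  I_dep0 <- -cell$params$k_2 * cell$params$I_dep0 /
    (cell$params$E_L * cell$params$k_adap)
  b <- isi_bounds(cell$params, n, I_dep0, n$Vr_tilde)
  t1 <- ds$trains[["600"]][1]
  ds2 <- ds
  ds2$trains[["600"]] <- c(t1, t1 + b$ISI_max + 5)
  expect_equal(spike_cost(cell$params, ds2) - spike_cost(cell$params,
    spike_dataset(data.frame(I_pA = rep(600, 1), spike_time_ms = t1),
                  400, cell$params$E_L, cell$params$V_r, cell$params$V_th,
                  currents = ds$currents)),
    5, tolerance = 1e-2)
})

test_that("the genetic algorithm is reproducible and monotone", {
  cell <- make_reference_cell("adapting", seed = 2)
  ds <- make_dataset(cell, currents = c(400, 600), T_end = 150)
  cfg <- ga_config(population = 12, max_generations = 8, seed = 42,
                   refine = FALSE)
  f1 <- fit_cell_ga(ds, cfg)
  f2 <- fit_cell_ga(ds, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$monod[c("a", "b", "c", "d")],
                   f2$monod[c("a", "b", "c", "d")])
  # elitism: the best cost never increases across generations
  expect_true(all(diff(f1$diagnostics$best_history) <= 1e-12))
  # fitted parameters satisfy the stability constraints by construction
  expect_true(check_constraints(nondimensionalize(f1$params, 0))$passed)
})

test_that("inverted adaptation sequences reproduce the experimental ISIs", {
  cell <- make_reference_cell("adapting", seed = 2)
  ds <- make_dataset(cell, currents = c(400, 600), T_end = 200)
  seqs <- aglif:::.invert_adaptation_sequences(cell$params, ds)
  expect_gt(nrow(seqs), 4)
  expect_true(all(!seqs$clipped))
  # under the generating parameters the inversion recovers the generating
  # Monod values
  expect_equal(seqs$I_adap0,
               monod_value(cell$monod, seqs$chi_ms, seqs$I_pA)[
                 seq_len(nrow(seqs))],
               tolerance = 1e-6)
})

test_that("noiseless Monod sequences are recovered to numerical precision", {
  truth <- monod_coefficients(2, 0.001, 0.5, 30)
  grid <- expand.grid(chi_ms = c(5, 15, 30, 60, 120, 240),
                      I_pA = c(400, 600, 800))
  grid$I_adap0 <- monod_value(truth, grid$chi_ms, grid$I_pA)
  fit <- fit_monod(grid)
  expect_lt(attr(fit, "fit")$rms, 1e-6)
  fitted <- monod_value(fit, grid$chi_ms, grid$I_pA)
  expect_equal(fitted, grid$I_adap0, tolerance = 1e-6)
})

test_that("degenerate Monod data are flagged or rejected", {
  const <- data.frame(chi_ms = c(5, 10, 20, 40), I_pA = c(400, 400, 600, 600),
                      I_adap0 = rep(0.7, 4))
  fit <- fit_monod(const)
  expect_identical(attr(fit, "degenerate"), "constant_isi")
  expect_equal(fit$a, 0)
  expect_equal(fit$c, 0.7)

  same_chi <- data.frame(chi_ms = rep(10, 4), I_pA = c(4, 4, 6, 6),
                         I_adap0 = 1:4)
  expect_error(fit_monod(same_chi), "degenerate")
  expect_error(fit_monod(const[1:3, ]), "4 data points")
  expect_error(fit_monod(data.frame(chi_ms = 1:4, I_pA = rep(400, 4),
                                    I_adap0 = 1:4)), "2 distinct currents")
})

test_that("noisy Monod sequences leave a residual near the noise level", {
  truth <- monod_coefficients(2, 0.001, 0.5, 30)
  set.seed(9)
  grid <- expand.grid(chi_ms = seq(5, 300, length.out = 10),
                      I_pA = c(400, 600, 800))
  grid$I_adap0 <- monod_value(truth, grid$chi_ms, grid$I_pA) +
    rnorm(nrow(grid), 0, 0.01)
  fit <- fit_monod(grid)
  expect_lt(attr(fit, "fit")$rms, 0.02)
  expect_gt(attr(fit, "fit")$rms, 0.003)
})

test_that("spike-train validation separates shifted from identical rasters", {
  cell <- make_reference_cell("adapting", seed = 2)
  r <- generate_constant_raster(cell)[, c("I_pA", "spike_time_ms")]
  same <- validate_spike_trains(r, r)
  expect_true(same$pass)
  expect_gt(same$pooled$p, 0.9)

  shifted <- r
  shifted$spike_time_ms <- shifted$spike_time_ms + 200
  diffv <- validate_spike_trains(shifted, r)
  expect_false(diffv$pass)
  expect_lt(diffv$pooled$p, 0.05)

  small <- data.frame(I_pA = 200, spike_time_ms = c(10, 20))
  w <- capture_warnings(validate_spike_trains(small, small))
  expect_match(w, "fewer than 3", all = TRUE)
  expect_error(validate_spike_trains(r, r[r$I_pA > 200, ]), "same currents")
})
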