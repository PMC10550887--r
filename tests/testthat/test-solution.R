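test_that("auxiliary terms satisfy their boundary identities", {
  a0 <- auxiliary_terms(0.3, 0.2, 0)
  expect_equal(a0$H1, 0)
  expect_equal(a0$H2, 2)
  expect_equal(a0$B_cal, 0)
  expect_equal(a0$C_cal, 0)

  # real trig branch equals the complex-arithmetic evaluation of the same
  # exponential expressions (independent path)
  for (par in list(c(0.3, 0.2, 1), c(2, 0.5, 3), c(0.9, 0.9, 2))) {
    beta <- par[1]; delta <- par[2]; h <- par[3]
    got <- auxiliary_terms(beta, delta, h)
    sA <- sqrt(as.complex((delta + 1)^2 - 4 * beta))
    B <- -0.5 * (sA - delta + 1) * h
    C <- sA * h
    expect_lt(Mod(exp(B) * (exp(C) - 1) / sA - got$H1), 1e-12)
    expect_lt(Mod(exp(B) * (exp(C) + 1) - got$H2), 1e-12)
  }
})

test_that("the degenerate discriminant limit matches nearby evaluations", {
  delta <- 0.4
  beta0 <- (1 + delta)^2 / 4           # A exactly zero
  for (h in c(0.5, 2, 7)) {
    lim <- auxiliary_terms(beta0, delta, h)
    expect_equal(lim$H1, h * exp((delta - 1) * h / 2), tolerance = 1e-8)
    up <- auxiliary_terms(beta0 + 1e-12 / 4, delta, h)  # A = -1e-12
    dn <- auxiliary_terms(beta0 - 1e-12 / 4, delta, h)  # A = +1e-12
    expect_lt(abs(lim$H1 - up$H1), 1e-8)
    expect_lt(abs(lim$H1 - dn$H1), 1e-8)
  }
})

test_that("the general integral collapses to the initial data at t0", {
  n <- nondim(alpha = 0.2, beta = 0.7, delta = 0.4)
  init <- list(V = -0.8, I_adap = 0.3, I_dep = 0.4)
  s <- general_integral(n, init, t0 = 5, t = 5)
  expect_equal(s$V, -0.8)
  expect_equal(s$I_adap, 0.3)
  expect_equal(s$I_dep, 0.4)
  expect_error(general_integral(n, init, t0 = 5, t = 4), "precede")
})

test_that("the depolarizing current decays exactly exponentially", {
  n <- nondim(alpha = 0, beta = 0.5, delta = 0.2)
  s <- general_integral(n, list(V = -1, I_adap = 0, I_dep = 1), 0, 2)
  expect_equal(s$I_dep, exp(-1), tolerance = 1e-14)
})

test_that("closed form matches a fourth-order integration", {
  set.seed(21)
  for (k in 1:30) {
    tr <- random_stable_triplet()
    V0 <- runif(1, -1.5, 0); Ia0 <- runif(1, -0.5, 1); Id0 <- runif(1, 0, 1)
    h <- round(runif(1, 0.5, 30), 3)   # a multiple of the oracle step
    n <- nondim(tr["alpha"], tr["beta"], tr["delta"])
    ana <- general_integral(n, list(V = V0, I_adap = Ia0, I_dep = Id0), 0, h)
    num <- rk4_batch(tr["alpha"], tr["beta"], tr["delta"], V0, Ia0, Id0, h)
    expect_lt(abs(ana$V - num$V), 1e-6)
    expect_lt(abs(ana$I_adap - num$I_adap), 1e-6)
    expect_lt(abs(ana$I_dep - num$I_dep), 1e-6)
  }
})

test_that("the RK4 oracle itself agrees with deSolve", {
  skip_if_not_installed("deSolve")
  rhs <- function(t, y, p) {
    list(c(p[1] + p[2] * (y[3] - y[2]) + p[3] * (1 + y[1]),
           1 - y[2] + y[1],
           -p[2] * y[3]))
  }
  out <- deSolve::ode(c(-0.9, 0.2, 0.5), c(0, 10), rhs, c(0.2, 0.6, 0.3),
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  mine <- rk4_batch(0.2, 0.6, 0.3, -0.9, 0.2, 0.5, 10)
  expect_equal(unname(out[2, 2:4]),
               c(mine$V, mine$I_adap, mine$I_dep), tolerance = 1e-9)
})

test_that("near the removable singularities the guarded branch is the limit", {
  init <- list(V = -0.9, I_adap = 0.2, I_dep = 0.6)
  for (h in c(1, 6)) {
    # beta = delta
    b <- 0.35
    exact <- general_integral(nondim(0.1, b, b), init, 0, h)
    for (eps in c(-1e-7, 1e-7)) {
      near <- general_integral(nondim(0.1, b + eps, b), init, 0, h)
      expect_lt(abs(exact$V - near$V), 1e-5)
      expect_lt(abs(exact$I_adap - near$I_adap), 1e-5)
    }
    # beta^2 + (beta-1) delta = 0
    b <- 0.4; d <- b^2 / (1 - b)
    exact <- general_integral(nondim(0.1, b, d), init, 0, h)
    for (eps in c(-1e-7, 1e-7)) {
      near <- general_integral(nondim(0.1, b + eps, d), init, 0, h)
      expect_lt(abs(exact$V - near$V), 1e-5)
    }
  }
})

test_that("equilibria match the closed-form steady states", {
  e1 <- equilibria(nondim(0.1, 0.3, 0.1))[[1]]
  expect_equal(e1$kind, "E1")
  expect_equal(c(e1$V_star, e1$I_adap_star, e1$I_dep_star), c(-0.5, 0.5, 0))
  expect_equal(e1$I_adap_star - e1$V_star, 1)

  e0 <- equilibria(nondim(0, 0.5, 0.5))[[1]]
  expect_equal(e0$kind, "E0_family")
  expect_equal(e0$family(-1), c(-1, 0, 0))

  e1b <- equilibria(nondim(0, 0.4, 0.6))[[1]]
  expect_equal(c(e1b$V_star, e1b$I_adap_star, e1b$I_dep_star), c(-1, 0, 0))
})

test_that("eigenvalues follow the characteristic roots", {
  ev <- glif_eigenvalues(0.3, 0.2)
  expect_equal(ev[1], -0.3)
  expect_equal(ev[2], (-0.8 + sqrt(0.24)) / 2, tolerance = 1e-12)
  evc <- glif_eigenvalues(2, 1)
  expect_equal(evc[2], complex(real = 0, imaginary = 1), tolerance = 1e-12)
  expect_equal(evc[3], complex(real = 0, imaginary = -1), tolerance = 1e-12)

  # numeric Jacobian cross-check; independent of alpha by construction
  set.seed(8)
  for (k in 1:50) {
    beta <- runif(1, 0.05, 3); delta <- runif(1, 0.05, 3)
    M <- rbind(c(delta, -beta, beta), c(1, -1, 0), c(0, 0, -beta))
    lam <- eigen(M, only.values = TRUE)$values
    got <- glif_eigenvalues(beta, delta)
    expect_equal(sort(Re(as.complex(got))), sort(Re(lam)), tolerance = 1e-10)
    expect_equal(sort(abs(Im(as.complex(got)))), sort(abs(Im(lam))),
                 tolerance = 1e-10)
  }
})

test_that("stability labels match their defining regions", {
  expect_equal(classify_stability(0.3, 0.2)$label, "stable_node_real")
  expect_equal(classify_stability(1.0, 0.5)$label, "stable_focus_damped")
  expect_equal(classify_stability(2, 1.5)$label, "unstable")
  expect_equal(classify_stability(0.25, 0.5)$label, "unstable")
  expect_equal(classify_stability(2, 1)$label, "center_sustained")
  expect_equal(classify_stability(0.5, 0.5)$label, "boundary_degenerate")
})

test_that("voltage sensitivities carry the proved signs", {
  n <- nondim(0.1, 0.3, 0.2)
  init <- list(V = -0.9, I_adap = 0.1, I_dep = 0.2)
  s0 <- voltage_sensitivities(n, init, 0, 0)
  expect_equal(s0$dV_dIadap0, 0)
  expect_equal(s0$dV_dIdep0, 0, tolerance = 1e-8)
  s5 <- voltage_sensitivities(n, init, 0, 5)
  expect_lt(s5$dV_dIadap0, 0)
  expect_gt(s5$dV_dIdep0, 0)
  # the closed form is the derivative of the general integral
  eps <- 1e-6
  up <- general_integral(n, list(V = -0.9, I_adap = 0.1 + eps, I_dep = 0.2),
                         0, 5)$V
  dn <- general_integral(n, list(V = -0.9, I_adap = 0.1 - eps, I_dep = 0.2),
                         0, 5)$V
  expect_equal(s5$dV_dIadap0, (up - dn) / (2 * eps), tolerance = 1e-6)
})

test_that("the clamped equilibrium interpolates to the floor potential", {
  p <- ref_params()
  expect_equal(clamped_equilibrium(0, p)$V_mV, -70)
  expect_equal(clamped_equilibrium(-185, p)$V_mV, -90)
  expect_equal(clamped_equilibrium(-92.5, p)$V_mV, -80)
  expect_equal(clamped_equilibrium(-300, p)$V_mV, -90)
  expect_error(clamped_equilibrium(250, p), "subthreshold")
})
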