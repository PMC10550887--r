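# Shared fixtures and oracles. Everything is generated in code; no files.

# a consistent dimensional parameter set used across unit tests
ref_params <- function() {
  aglif_parameters(E_L = -70, V_r = -60, V_th = -50, C_m = 100, tau_m = 20,
                   I_th = 200, K = 700, k_1 = 0.05,
                   I_dep_start = 0.5, I_dep0 = 30)
}

# assemble a nondimensional parameter object directly (bypassing the
# dimensional layer) for tests stated in nondimensional coordinates
nondim <- function(alpha, beta, delta, Vth_tilde = -0.7, Vr_tilde = -0.85,
                   alpha_th = 0.01, tau = 1) {
  structure(list(alpha = alpha, beta = beta, gamma = beta, delta = delta,
                 tau = tau, Vth_tilde = Vth_tilde, Vr_tilde = Vr_tilde,
                 alpha_th = alpha_th),
            class = "aglif_nondim")
}

# draw a random consistent dimensional parameter set (not necessarily inside
# the spiking-silence region)
random_params <- function() {
  E_L <- runif(1, -80, -60)
  V_th <- runif(1, E_L + 5, -5)
  V_r <- runif(1, max(E_L - 5, -89), -5)
  aglif_parameters(E_L = E_L, V_r = V_r, V_th = V_th,
                   C_m = runif(1, 50, 300), tau_m = runif(1, 5, 40),
                   I_th = runif(1, 20, 600), K = runif(1, 500, 40000),
                   k_1 = runif(1, 0.005, 1))
}

# draw (alpha, beta, delta) with the equilibrium asymptotically stable
# (real-eigenvalue node or damped focus)
random_stable_triplet <- function() {
  delta <- runif(1, 0.05, 0.95)
  if (runif(1) < 0.5) {
    beta <- delta + runif(1, 0.05, 1) * (1 - delta)^2 / 4  # node
  } else {
    beta <- runif(1, (1 + delta)^2 / 4 + 0.01,
                  (1 + delta)^2 / 4 + 1)                   # damped focus
  }
  c(alpha = runif(1, -0.5, 0.5), beta = beta, delta = delta)
}

# classical fixed-step RK4 for the nondimensional system, vectorized across
# draws: every argument may be a vector over independent systems
rk4_batch <- function(alpha, beta, delta, V0, Ia0, Id0, horizon,
                      step = 1e-3) {
  V <- V0; Ia <- Ia0; Id <- Id0
  n_steps <- round(horizon / step)
  fV <- function(V, Ia, Id) alpha + beta * (Id - Ia) + delta * (1 + V)
  fA <- function(V, Ia) 1 - Ia + V
  fD <- function(Id) -beta * Id
  for (i in seq_len(n_steps)) {
    k1V <- fV(V, Ia, Id); k1A <- fA(V, Ia); k1D <- fD(Id)
    V2 <- V + step / 2 * k1V; A2 <- Ia + step / 2 * k1A
    D2 <- Id + step / 2 * k1D
    k2V <- fV(V2, A2, D2); k2A <- fA(V2, A2); k2D <- fD(D2)
    V3 <- V + step / 2 * k2V; A3 <- Ia + step / 2 * k2A
    D3 <- Id + step / 2 * k2D
    k3V <- fV(V3, A3, D3); k3A <- fA(V3, A3); k3D <- fD(D3)
    V4 <- V + step * k3V; A4 <- Ia + step * k3A; D4 <- Id + step * k3D
    k4V <- fV(V4, A4, D4); k4A <- fA(V4, A4); k4D <- fD(D4)
    V <- V + step / 6 * (k1V + 2 * k2V + 2 * k3V + k4V)
    Ia <- Ia + step / 6 * (k1A + 2 * k2A + 2 * k3A + k4A)
    Id <- Id + step / 6 * (k1D + 2 * k2D + 2 * k3D + k4D)
  }
  list(V = V, I_adap = Ia, I_dep = Id)
}

# raster with hand-placed last spikes so that the anchor t_last + ISI_last/2
# takes a prescribed value; three spikes keep the train non-degenerate
raster_row <- function(I, t_last, isi_last) {
  data.frame(cell_id = "c", I_pA = I,
             spike_time_ms = c(10, t_last - isi_last, t_last))
}
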