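# Draw ranges for ground-truth cells. Centralized so fixtures are stable:
# resting potential around -70 mV, threshold ~18 mV above rest, reset ~10 mV
# above rest, capacitance 120-220 pF, membrane time constant 12-25 ms and a
# small effective leak rate delta, which places the cells deep inside the
# real-eigenvalue asymptotic-stability region as in recorded CA1 cells.
.synth_ranges <- list(
  E_L = c(-73, -67),
  V_th_above_EL = c(16, 22),
  V_r_above_EL = c(8, 12),
  C_m = c(120, 220),
  tau_m = c(30, 60),
  delta = c(0.02, 0.04),
  I_dep_start = c(0.2, 0.6),
  I_dep0 = c(10, 60),
  # Monod levels are drawn relative to the admissibility bound H at the
  # lowest firing current: the intercept c as a fraction of H, the plateau
  # as a larger fraction, so adaptation visibly slows the train without
  # stalling it
  beta_frac = c(0.88, 0.96),
  monod_c_frac = c(0.05, 0.15),
  monod_plateau_frac = c(0.78, 0.88),
  monod_d = c(60, 120),
  sat_b = c(3e-4, 6e-4),
  flat_b = c(1e-5, 5e-5)
)

#' Generate a ground-truth A-GLIF reference cell
#'
#' Draws a complete cell (parameters, Monod rule and, for the blocking
#' phenotype, a firing-block rule) from documented physiological ranges. The
#' construction guarantees the spiking-silence constraints: \eqn{\delta} is
#' drawn small, \eqn{\alpha_{th}} strictly inside its admissible bound, and
#' \eqn{\beta} is placed between its lower admissibility bound and the value
#' at which the lowest intended firing current reaches threshold, so the cell
#' is silent below the rheobase and fires at every intended current.
#'
#' Phenotypes: \code{"adapting"} (Monod increasing in time and current,
#' a>0, b>0); \code{"adapting_saturating"} (a>0, b<0: adaptation decreases
#' with current); \code{"non_adapting"} (small a: near-constant inter-spike
#' intervals); \code{"blocking"} (adapting plus a firing-block rule cutting
#' off firing at high currents); \code{"high_threshold"} (rheobase at 500 pA,
#' silent at 200-400 pA).
#'
#' @param phenotype one of the labels above.
#' @param seed integer seed; the same seed yields the identical cell.
#' @return An \code{"aglif_cell"} whose \code{phenotype} field carries the
#'   base label (\code{adapting}/\code{non_adapting}/\code{blocking}).
#' @export
make_reference_cell <- function(phenotype = c("adapting",
                                              "adapting_saturating",
                                              "non_adapting", "blocking",
                                              "high_threshold"),
                                seed = 1) {
  phenotype <- match.arg(phenotype)
  r <- .synth_ranges
  draw <- function(rg) stats::runif(1, rg[1], rg[2])
  cell <- .local_seed(seed, {
    E_L <- draw(r$E_L)
    V_th <- E_L + draw(r$V_th_above_EL)
    V_r <- E_L + draw(r$V_r_above_EL)
    C_m <- draw(r$C_m)
    delta <- draw(r$delta)
    I_th <- if (phenotype == "high_threshold") 500 else 120
    I_fire_min <- if (phenotype == "high_threshold") 600 else 200
    Vth_tilde <- -V_th / E_L
    vth1 <- 1 + Vth_tilde
    # beta sits near the top of its admissible window, where the two slow
    # eigenvalues are close and the inter-spike interval is strongly
    # sensitive to the after-spike adaptation value (pronounced
    # accommodation); K follows from the current at which the equilibrium
    # reaches threshold, floored so alpha_th stays inside its bound; the
    # membrane time constant follows from K through the structural identity
    I_star <- 0.95 * I_fire_min  # equilibrium reaches threshold here
    beta_span <- (1 + delta)^2 / 4 - delta
    beta_frac <- draw(r$beta_frac)
    K <- max(I_star / (beta_frac * beta_span * vth1),
             I_th / (0.85 * vth1 * (delta - 1)^2 / 4))
    beta <- delta + I_star / (K * vth1)
    k_2 <- -K / (C_m * E_L)
    tau_m <- 1 / (k_2 * delta)
    k_1 <- beta * k_2
    p <- aglif_parameters(E_L = E_L, V_r = V_r, V_th = V_th, C_m = C_m,
                          tau_m = tau_m, I_th = I_th, K = K, k_1 = k_1,
                          I_dep_start = draw(r$I_dep_start),
                          I_dep0 = draw(r$I_dep0))
    # Monod levels relative to the admissibility bound H: intercept low
    # (early interval near its minimum), plateau a large fraction of H; for
    # the adapting phenotypes the current sensitivity b is chosen so the
    # plateau tracks the growth of H with the stimulation, keeping the
    # accommodation visible across the whole current range
    Idep0_nd <- -p$k_2 * p$I_dep0 / (p$E_L * p$k_adap)
    Vr_tilde <- -V_r / E_L
    H_min <- threshold_H(nondimensionalize(p, I_fire_min), Idep0_nd, Vr_tilde)
    H_max <- threshold_H(nondimensionalize(p, 1000), Idep0_nd, Vr_tilde)
    mc <- draw(r$monod_c_frac) * H_min
    md <- draw(r$monod_d)
    p_frac <- draw(r$monod_plateau_frac)
    mb <- switch(phenotype,
      adapting_saturating = -draw(r$sat_b),
      non_adapting = draw(r$flat_b),
      log((p_frac * H_max - mc) / (p_frac * H_min - mc)) / (1000 - I_fire_min))
    ma <- if (phenotype == "non_adapting") 0.05 * H_min / exp(mb * I_fire_min)
          else (p_frac * H_min - mc) / exp(mb * I_fire_min)
    m <- monod_coefficients(ma, mb, mc, md)
    block <- NULL
    if (phenotype == "blocking") {
      # cut firing off at 800 and 1000 pA; the nearest firing current (600)
      # puts the validity threshold at 700 pA
      t1 <- stats::runif(1, 240, 280)
      t2 <- t1 - stats::runif(1, 20, 40)
      A <- (t2 - t1) / 200
      B <- t1 - A * 800
      block <- structure(list(
        lines = list(list(A = A, B = B, validity = "ge", threshold = 700,
                          P1 = c(I = 800, t = t1), P2 = c(I = 1000, t = t2))),
        block_intervals = list(c(800, 1000)), I_fire = 600,
        blocking_currents = c(800, 1000)), class = "aglif_block_rule")
    }
    label <- switch(phenotype,
                    non_adapting = "non_adapting",
                    blocking = "blocking",
                    "adapting")
    aglif_cell(p, m, block, phenotype = label,
               id = paste0("synthetic_", phenotype, "_", seed))
  })
  stopifnot(check_constraints(nondimensionalize(cell$params, 0))$passed)
  cell
}

#' Generate a constant-step raster from a ground-truth cell
#'
#' Simulates the standard constant-step protocol (by default 200 to 1000 pA
#' in 200 pA increments, 400 ms steps) and optionally perturbs the spike
#' times with truncated Gaussian jitter that preserves spike ordering, the
#' refractory separation and the per-current spike counts.
#'
#' @param cell an \code{"aglif_cell"}.
#' @param currents stimulation currents (pA); default
#'   \code{seq(200, 1000, by = 200)}.
#' @param T_end step duration (ms); default 400.
#' @param jitter_sd jitter standard deviation (ms); default 0 (noiseless).
#' @param seed seed for the jitter; ignored when \code{jitter_sd = 0}.
#' @return A data.frame raster (\code{cell_id, I_pA, spike_time_ms}) with
#'   attribute \code{"T_end"}.
#' @export
generate_constant_raster <- function(cell, currents = seq(200, 1000, by = 200),
                                     T_end = 400, jitter_sd = 0, seed = 1) {
  stopifnot(inherits(cell, "aglif_cell"), all(currents > 0))
  rows <- lapply(currents, function(I) {
    spk <- simulate_constant(cell, I, T_end)$spikes$spike_times
    data.frame(cell_id = rep(cell$id, length(spk)),
               I_pA = rep(I, length(spk)), spike_time_ms = spk)
  })
  raster <- do.call(rbind, rows)
  if (jitter_sd > 0 && nrow(raster)) {
    raster$spike_time_ms <- .local_seed(seed, {
      unlist(lapply(split(raster$spike_time_ms, raster$I_pA), function(s) {
        s2 <- s + pmax(pmin(stats::rnorm(length(s), 0, jitter_sd),
                            3 * jitter_sd), -3 * jitter_sd)
        gap <- cell$params$dt_ref + 1e-6
        for (j in seq_along(s2)) {
          if (j > 1L && s2[j] <= s2[j - 1L] + gap) s2[j] <- s2[j - 1L] + gap
        }
        pmin(s2, T_end)
      })[as.character(unique(raster$I_pA))], use.names = FALSE)
    })
  }
  attr(raster, "T_end") <- T_end
  raster
}

#' Generate a piecewise-protocol fixture with its ground-truth response
#'
#' Builds a random step protocol containing upward steps, downward steps and
#' zero/subthreshold epochs, and pairs it with the simulated ground-truth
#' spike train.
#'
#' @param cell an \code{"aglif_cell"}.
#' @param n_segments number of segments (at least 2).
#' @param seed integer seed.
#' @param segment_ms segment duration (ms); default 200.
#' @return list with \code{protocol} (an \code{"aglif_protocol"}) and
#'   \code{train} (the simulated \code{"aglif_spike_train"}).
#' @export
generate_piecewise_fixture <- function(cell, n_segments, seed = 1,
                                       segment_ms = 200) {
  stopifnot(inherits(cell, "aglif_cell"), n_segments >= 2)
  levels_supra <- c(400, 600, 800)
  prot <- .local_seed(seed, {
    I <- numeric(n_segments)
    I[1] <- sample(levels_supra, 1)
    for (k in 2:n_segments) {
      I[k] <- sample(c(0, 0.5 * cell$params$I_th, levels_supra), 1)
      if (k == 2 && I[2] == I[1]) I[2] <- 0   # force at least one change
    }
    tb <- (seq_len(n_segments) - 1) * segment_ms
    stimulus_protocol(tb, tb + segment_ms, I)
  })
  sim <- simulate_piecewise(cell, prot)
  list(protocol = prot, train = sim$spikes)
}
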