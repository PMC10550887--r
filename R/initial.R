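# Initial conditions for the Cauchy problems between spikes. All values are
# nondimensional; times are kept in ms at the call sites and rescaled there.

.nondim_current <- function(p, I_pA) {
  -p$k_2 * I_pA / (p$E_L * p$k_adap)
}

#' Initial conditions for the first spike
#'
#' From rest, the membrane starts at the resting potential
#' (\code{V0 = -1} nondimensionally) with zero adaptation current; the
#' depolarizing current is seeded proportionally to the suprathreshold excess,
#' \eqn{I_{dep} = I_{dep}^{start} (I_{stim}-I_{th})\,\theta(I_{stim}-I_{th})}
#' (pA), then rescaled.
#'
#' @param p an \code{"aglif_parameters"} object.
#' @param n the matching \code{"aglif_nondim"} at \code{I_stim}.
#' @param I_stim stimulation current (pA).
#' @return An object of class \code{"aglif_init"}: list with \code{V0},
#'   \code{I_adap0}, \code{I_dep0} (nondimensional), \code{provenance}.
#' @export
first_spike_conditions <- function(p, n, I_stim) {
  stopifnot(inherits(p, "aglif_parameters"), inherits(n, "aglif_nondim"))
  excess <- if (I_stim > p$I_th) I_stim - p$I_th else 0
  structure(list(V0 = -1,
                 I_adap0 = 0,
                 I_dep0 = .nondim_current(p, p$I_dep_start * excess),
                 provenance = "first_spike"),
            class = "aglif_init")
}

#' After-spike initial conditions
#'
#' After the refractory interval following a spike the potential restarts at
#' the reset value, the depolarizing current at its after-spike constant, and
#' the adaptation current at the Monod update evaluated at
#' \eqn{\chi = t_{spk}^+ - t_{start}} (ms). The Monod value is clipped at
#' zero (positivity is prioritized); exceeding the admissibility bound
#' \code{H} is advisory and reported via the \code{flag_H} field, since the
#' bound is only enforced inside the fitted current range during
#' optimization.
#'
#' @param p an \code{"aglif_parameters"} object.
#' @param n the matching \code{"aglif_nondim"} at \code{I_stim}.
#' @param m an \code{"aglif_monod"} update rule.
#' @param t_spk_plus spike time plus refractory interval (ms).
#' @param t_start last instant at which the stimulation was at or below the
#'   rheobase (ms).
#' @param I_stim stimulation current (pA).
#' @return An \code{"aglif_init"} with fields \code{V0}, \code{I_adap0},
#'   \code{I_dep0}, \code{provenance}, \code{flag_H}.
#' @export
after_spike_conditions <- function(p, n, m, t_spk_plus, t_start, I_stim) {
  stopifnot(inherits(p, "aglif_parameters"), inherits(n, "aglif_nondim"),
            inherits(m, "aglif_monod"), t_spk_plus >= t_start)
  I_dep0 <- .nondim_current(p, p$I_dep0)
  raw <- monod_value(m, t_spk_plus - t_start, I_stim)
  I_adap0 <- max(0, raw)
  H <- threshold_H(n, I_dep0, n$Vr_tilde)
  structure(list(V0 = n$Vr_tilde,
                 I_adap0 = I_adap0,
                 I_dep0 = I_dep0,
                 provenance = "after_spike",
                 flag_H = I_adap0 >= H),
            class = "aglif_init")
}
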