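#' Physiological parameters of an A-GLIF cell
#'
#' Builds and validates the full dimensional parameter set of the adaptive
#' generalized leaky integrate-and-fire (A-GLIF) model. Two structural
#' identities tie the rate constants together and are enforced here rather
#' than fitted: the adaptation constant satisfies
#' \code{k_adap = C_m * k_1 * k_2}, which makes the ratio of the two current
#' decay rates equal for the depolarizing and adaptation currents, and the
#' adaptation decay rate is expressed through a positive scaling constant
#' \code{K} as \code{k_2 = -K / (C_m * E_L)}. If \code{k_2} or \code{k_adap}
#' are supplied they are cross-checked against the derived values (relative
#' tolerance 1e-9) and an inconsistency is an error, never silently adjusted.
#'
#' Units are fixed throughout the dimensional layer: mV for potentials, ms for
#' times, pA for currents, pF for capacitance; \code{k_1}, \code{k_2} are in
#' 1/ms and \code{k_adap} in pA/(mV ms) (the unit making the adaptation
#' equation dimensionally consistent).
#'
#' @param E_L resting potential (mV, negative).
#' @param V_r reset potential (mV), strictly between \code{V_min} and 0.
#' @param V_th threshold potential (mV), strictly between \code{V_min} and 0
#'   and above \code{E_L}.
#' @param C_m membrane capacitance (pF, positive).
#' @param tau_m membrane time constant (ms, positive).
#' @param I_th threshold (rheobase) current (pA, positive).
#' @param K scaling constant (pA, positive).
#' @param k_1 decay rate of the depolarizing current (1/ms, positive).
#' @param k_2 optional decay rate of the adaptation current (1/ms); derived
#'   from \code{K} when omitted.
#' @param k_adap optional adaptation constant; derived when omitted.
#' @param I_dep_start dimensionless multiplier for the first-spike
#'   depolarizing current.
#' @param I_dep0 after-spike depolarizing current constant (pA).
#' @param dt_ref refractory interval (ms), default 2.
#' @param V_min floor potential (mV), default -90.
#' @param I_stim_neg current at which the cell relaxes to \code{V_min} (pA),
#'   default -185.
#' @return An object of class \code{"aglif_parameters"}.
#' @seealso [complete_parameters()] for construction from a named list,
#'   [nondimensionalize()], [check_constraints()].
#' @examples
#' p <- aglif_parameters(E_L = -70, V_r = -60, V_th = -50, C_m = 100,
#'                       tau_m = 20, I_th = 200, K = 700, k_1 = 0.05)
#' p$k_2    # 0.1 ms^-1
#' p$k_adap # 0.5
#' @export
aglif_parameters <- function(E_L, V_r, V_th, C_m, tau_m, I_th, K, k_1,
                             k_2 = NULL, k_adap = NULL,
                             I_dep_start = 0, I_dep0 = 0,
                             dt_ref = 2, V_min = -90, I_stim_neg = -185) {
  for (nm in c("E_L", "V_r", "V_th", "C_m", "tau_m", "I_th", "K", "k_1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a finite numeric scalar")
  }
  if (E_L >= 0) stop("E_L must be negative")
  for (nm in c("C_m", "tau_m", "I_th", "K", "k_1")) {
    if (get(nm) <= 0) stop("'", nm, "' must be positive")
  }
  if (!(V_r > V_min && V_r < 0))
    stop("V_r must lie strictly between V_min and 0")
  if (!(V_th > V_min && V_th < 0))
    stop("V_th must lie strictly between V_min and 0")
  if (V_th <= E_L) stop("V_th must exceed E_L")
  if (dt_ref <= 0) stop("dt_ref must be positive")
  if (I_dep_start < 0) stop("I_dep_start must be non-negative")

  k_2_derived <- -K / (C_m * E_L)
  if (!is.null(k_2) && !.rel_close(k_2, k_2_derived, 1e-9))
    stop("supplied k_2 = ", k_2, " contradicts -K/(C_m*E_L) = ", k_2_derived)
  k_2 <- k_2_derived
  k_adap_derived <- C_m * k_1 * k_2
  if (!is.null(k_adap) && !.rel_close(k_adap, k_adap_derived, 1e-9))
    stop("supplied k_adap = ", k_adap, " contradicts C_m*k_1*k_2 = ",
         k_adap_derived)
  k_adap <- k_adap_derived

  structure(list(E_L = E_L, V_r = V_r, V_th = V_th, C_m = C_m, tau_m = tau_m,
                 I_th = I_th, K = K, k_1 = k_1, k_2 = k_2, k_adap = k_adap,
                 I_dep_start = I_dep_start, I_dep0 = I_dep0,
                 dt_ref = dt_ref, V_min = V_min, I_stim_neg = I_stim_neg),
            class = "aglif_parameters")
}

.rel_close <- function(x, y, tol) {
  abs(x - y) <= tol * max(abs(x), abs(y), 1e-300)
}

#' Complete a partial parameter set
#'
#' Derives \code{k_2} and \code{k_adap} from the structural identities and
#' validates the result. At least \code{E_L, C_m, tau_m, K, k_1, V_r, V_th,
#' I_th} must be present in \code{raw}.
#'
#' @param raw named list of parameter values (e.g. parsed from YAML/JSON).
#' @return An \code{"aglif_parameters"} object.
#' @export
complete_parameters <- function(raw) {
  required <- c("E_L", "C_m", "tau_m", "K", "k_1", "V_r", "V_th", "I_th")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required parameters: ", paste(missing, collapse = ", "))
  known <- names(formals(aglif_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter fields: ", paste(unknown, collapse = ", "))
  do.call(aglif_parameters, raw)
}

#' @export
print.aglif_parameters <- function(x, ...) {
  cat("A-GLIF cell parameters (mV, ms, pA, pF)\n")
  cat(sprintf("  E_L=%.3f  V_r=%.3f  V_th=%.3f  V_min=%.3f\n",
              x$E_L, x$V_r, x$V_th, x$V_min))
  cat(sprintf("  C_m=%.3f  tau_m=%.3f  dt_ref=%.3f\n", x$C_m, x$tau_m, x$dt_ref))
  cat(sprintf("  I_th=%.3f  K=%.3f  I_stim_neg=%.3f\n", x$I_th, x$K, x$I_stim_neg))
  cat(sprintf("  k_1=%.6g  k_2=%.6g  k_adap=%.6g\n", x$k_1, x$k_2, x$k_adap))
  cat(sprintf("  I_dep_start=%.4g  I_dep0=%.4g pA\n", x$I_dep_start, x$I_dep0))
  invisible(x)
}

#' Nondimensional parameters at a given stimulation current
#'
#' Rescales the dimensional system: \code{alpha = I_stim/K} is the scaled
#' injected current, \code{beta = k_1/k_2} the ratio of the depolarizing to
#' adaptation decay rates, \code{delta = 1/(k_2*tau_m)} the effective rate of
#' change of the membrane potential, and \code{tau = 1/k_2} (ms) the time
#' scale. Under the structural identity \code{k_adap = C_m k_1 k_2} the decay
#' ratio of the depolarizing current equals \code{beta} (the \code{gamma}
#' entry is always identical to \code{beta}, never stored independently).
#' Potentials rescale as \code{Vtilde = -V/E_L}.
#'
#' @param p an \code{"aglif_parameters"} object.
#' @param I_stim stimulation current (pA); may be negative or zero.
#' @return An object of class \code{"aglif_nondim"} with fields
#'   \code{alpha, beta, gamma, delta, tau, Vth_tilde, Vr_tilde, alpha_th}.
#' @export
nondimensionalize <- function(p, I_stim) {
  stopifnot(inherits(p, "aglif_parameters"))
  if (!is.numeric(I_stim) || length(I_stim) != 1L || !is.finite(I_stim))
    stop("I_stim must be a finite numeric scalar")
  beta <- p$k_1 / p$k_2
  structure(list(alpha = I_stim / p$K,
                 beta = beta,
                 gamma = beta,
                 delta = 1 / (p$k_2 * p$tau_m),
                 tau = 1 / p$k_2,
                 Vth_tilde = -p$V_th / p$E_L,
                 Vr_tilde = -p$V_r / p$E_L,
                 alpha_th = p$I_th / p$K),
            class = "aglif_nondim")
}

#' Model state at a time point
#'
#' @param t time (ms if dimensional, rescaled units otherwise).
#' @param V membrane potential.
#' @param I_adap adaptation current.
#' @param I_dep depolarizing current.
#' @param units either \code{"dimensional"} or \code{"nondimensional"}.
#' @return An object of class \code{"aglif_state"}.
#' @export
aglif_state <- function(t, V, I_adap, I_dep,
                        units = c("dimensional", "nondimensional")) {
  units <- match.arg(units)
  structure(list(t = t, V = V, I_adap = I_adap, I_dep = I_dep, units = units),
            class = "aglif_state")
}

#' Convert a model state between unit systems
#'
#' Applies the rescaling \code{t~ = t/tau}, \code{V~ = -V/E_L},
#' \code{I~ = -k_2 I / (E_L k_adap)} for both currents, or its inverse.
#' The round trip is the identity to 1e-12 relative precision.
#'
#' @param s an \code{"aglif_state"}.
#' @param p an \code{"aglif_parameters"} object.
#' @param direction \code{"to_nondimensional"} or \code{"to_dimensional"}.
#' @return The converted \code{"aglif_state"}.
#' @export
convert_state <- function(s, p,
                          direction = c("to_nondimensional", "to_dimensional")) {
  stopifnot(inherits(s, "aglif_state"), inherits(p, "aglif_parameters"))
  direction <- match.arg(direction)
  cur_scale <- -p$k_2 / (p$E_L * p$k_adap)
  tau <- 1 / p$k_2
  if (direction == "to_nondimensional") {
    if (s$units != "dimensional")
      stop("state is already nondimensional")
    aglif_state(s$t / tau, -s$V / p$E_L,
                s$I_adap * cur_scale, s$I_dep * cur_scale,
                units = "nondimensional")
  } else {
    if (s$units != "nondimensional")
      stop("state is already dimensional")
    aglif_state(s$t * tau, -s$V * p$E_L,
                s$I_adap / cur_scale, s$I_dep / cur_scale,
                units = "dimensional")
  }
}

#' Check the spiking-silence parameter constraints
#'
#' Evaluates, with signed margins, the conditions under which the cell cannot
#' reach threshold for any subthreshold current: (i) \code{0 < delta < 1};
#' (ii) \code{alpha_th < (1+Vth_tilde)(delta-1)^2/4}; (iii)
#' \code{alpha_th/(1+Vth_tilde) + delta < beta <= (1+delta)^2/4}. A positive
#' margin means the condition holds. When the dimensional parameter set is
#' supplied, the equivalent dimensional inequalities (a lower bound on
#' \code{K} and a window on \code{k_adap}) are evaluated as redundant
#' cross-checks; their pass/fail verdicts agree with the nondimensional ones.
#'
#' @param n an \code{"aglif_nondim"} object.
#' @param p optional \code{"aglif_parameters"} for the dimensional cross-check.
#' @return An object of class \code{"aglif_constraints"}: list with
#'   \code{passed} (logical), \code{conditions} (data.frame of name, margin,
#'   passed), \code{violated} (character vector) and, if \code{p} was given,
#'   \code{dimensional} (data.frame) plus \code{dimensional_agrees}.
#' @export
check_constraints <- function(n, p = NULL) {
  stopifnot(inherits(n, "aglif_nondim"))
  d <- n$delta; b <- n$beta; ath <- n$alpha_th; vth1 <- 1 + n$Vth_tilde
  margins <- c(
    delta_range      = min(d, 1 - d),
    alpha_th_bound   = vth1 * (d - 1)^2 / 4 - ath,
    beta_lower_bound = b - (ath / vth1 + d),
    beta_upper_bound = (1 + d)^2 / 4 - b
  )
  ok <- c(margins[1] > 0, margins[2] > 0, margins[3] > 0, margins[4] >= 0)
  conditions <- data.frame(condition = names(margins),
                           margin = as.numeric(margins),
                           passed = as.logical(ok),
                           row.names = NULL)
  out <- list(passed = all(ok),
              conditions = conditions,
              violated = conditions$condition[!conditions$passed])
  if (!is.null(p)) {
    stopifnot(inherits(p, "aglif_parameters"))
    rad <- p$I_th^2 - p$I_th * p$C_m * (p$V_th - p$E_L) / p$tau_m
    K_lower <- if (rad < 0) -Inf else {
      -p$C_m * p$E_L / p$tau_m +
        2 * p$E_L / (p$E_L - p$V_th) * (p$I_th + sqrt(rad))
    }
    ka_lower <- p$K / (p$E_L * p$tau_m) *
      (p$I_th * p$tau_m / (p$C_m * (p$E_L - p$V_th)) - 1)
    ka_upper <- (p$C_m * p$E_L - p$K * p$tau_m)^2 /
      (4 * p$C_m * p$E_L^2 * p$tau_m^2)
    dim_df <- data.frame(
      condition = c("K_lower_bound", "k_adap_lower_bound",
                    "k_adap_upper_bound"),
      margin = c(p$K - K_lower, p$k_adap - ka_lower, ka_upper - p$k_adap),
      passed = c(p$K > K_lower, p$k_adap > ka_lower, p$k_adap <= ka_upper),
      row.names = NULL)
    out$dimensional <- dim_df
    # dimensional system restates (ii) and (iii); (i) has no dimensional twin
    out$dimensional_agrees <-
      (all(dim_df$passed) && ok[1]) == out$passed
  }
  structure(out, class = "aglif_constraints")
}

#' @export
print.aglif_constraints <- function(x, ...) {
  cat("A-GLIF parameter constraints:",
      if (x$passed) "PASSED" else "FAILED", "\n")
  print(x$conditions, row.names = FALSE)
  if (!is.null(x$dimensional)) {
    cat("dimensional cross-checks:\n")
    print(x$dimensional, row.names = FALSE)
  }
  invisible(x)
}
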