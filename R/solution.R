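#' Auxiliary exponential terms of the closed-form trajectory
#'
#' The closed-form solution of the nondimensional system is expressed through
#' the discriminant-like quantity \eqn{A = (\delta+1)^2 - 4\beta} and the two
#' combined exponentials
#' \eqn{H_1 = e^{B}(e^{C}-1)/\sqrt{A}}, \eqn{H_2 = e^{B}(e^{C}+1)} with
#' \eqn{B = -\tfrac12(\sqrt{A}-\delta+1)\,\Delta t}, \eqn{C = \sqrt{A}\,\Delta t}.
#' For \eqn{A<0} the equivalent real trigonometric forms
#' \eqn{H_1 = 2e^{(\delta-1)\Delta t/2}\sin(w\Delta t/2)/w},
#' \eqn{H_2 = 2e^{(\delta-1)\Delta t/2}\cos(w\Delta t/2)} with
#' \eqn{w=\sqrt{-A}} are used so outputs stay exactly real; for
#' \eqn{|A| < 10^{-10}} the analytic series limit
#' \eqn{H_1 \to \Delta t\, e^{(\delta-1)\Delta t/2}} (with first-order
#' correction) is evaluated.
#'
#' @param beta,delta nondimensional parameters (positive).
#' @param elapsed elapsed nondimensional time(s) \eqn{\Delta t \ge 0};
#'   vectorized.
#' @return list with components \code{A_cal}, \code{B_cal}, \code{C_cal}
#'   (complex when \code{A_cal < 0}), \code{H1}, \code{H2} (always real).
#' @export
auxiliary_terms <- function(beta, delta, elapsed) {
  stopifnot(beta > 0, delta > 0, all(elapsed >= 0))
  A <- (delta + 1)^2 - 4 * beta
  pre <- exp((delta - 1) * elapsed / 2)
  if (abs(A) < 1e-10) {
    H1 <- pre * elapsed * (1 + A * elapsed^2 / 24)
    H2 <- 2 * pre * (1 + A * elapsed^2 / 8)
  } else if (A > 0) {
    s <- sqrt(A)
    H1 <- 2 * pre * sinh(s * elapsed / 2) / s
    H2 <- 2 * pre * cosh(s * elapsed / 2)
  } else {
    w <- sqrt(-A)
    H1 <- 2 * pre * sin(w * elapsed / 2) / w
    H2 <- 2 * pre * cos(w * elapsed / 2)
  }
  sqrtA <- sqrt(as.complex(A))
  B <- -0.5 * (sqrtA - delta + 1) * elapsed
  C <- sqrtA * elapsed
  if (A >= 0) { B <- Re(B); C <- Re(C) }
  list(A_cal = A, B_cal = B, C_cal = C, H1 = H1, H2 = H2)
}

# Closed-form propagation of (V, I_adap, I_dep), vectorized over elapsed time.
# `elapsed` in nondimensional units. Uses the corrected I_dep^0 -> V term
# (factor beta on the H1 bracket; see the methods vignette).
.aglif_traj <- function(alpha, beta, delta, V0, Ia0, Id0, elapsed) {
  den <- beta^2 + (beta - 1) * delta
  bd <- beta - delta
  if (abs(bd) < 1e-10 * max(1, beta) || abs(den) < 1e-10 * max(1, beta^2)) {
    return(.aglif_traj_expm(alpha, beta, delta, V0, Ia0, Id0, elapsed))
  }
  aux <- auxiliary_terms(beta, delta, elapsed)
  H1 <- aux$H1; H2 <- aux$H2
  eb <- exp(-beta * elapsed)
  V <- -Ia0 * beta * H1 +
    Id0 * beta * ((beta - 1) * (H2 - 2 * eb) +
                    H1 * ((beta - 1) * (delta + 1) + 2 * beta)) / (2 * den) +
    (V0 / 2) * ((delta + 1) * H1 + H2) +
    (H1 / 2) * (alpha * (beta - 1) / bd + alpha + delta + 1) -
    (H2 - 2) * (alpha - beta + delta) / (2 * bd)
  Ia <- 0.5 * Ia0 * (H2 - (delta + 1) * H1) +
    Id0 * (beta / 2) * ((2 * eb + H1 * (2 * beta + delta - 1) - H2) / den) +
    V0 * H1 -
    (alpha / 2) * ((1 - delta) * H1 + H2 - 2) / bd +
    H1
  list(V = V, I_adap = Ia, I_dep = Id0 * eb)
}

# Exact evaluation through the augmented-matrix exponential; covers the
# removable singularities of the closed form (beta = delta, and
# beta^2 + (beta-1) delta = 0) including non-diagonalizable Jacobians.
.aglif_traj_expm <- function(alpha, beta, delta, V0, Ia0, Id0, elapsed) {
  M <- rbind(c(delta, -beta, beta, alpha + delta),
             c(1, -1, 0, 1),
             c(0, 0, -beta, 0),
             c(0, 0, 0, 0))
  V <- Ia <- Id <- numeric(length(elapsed))
  for (i in seq_along(elapsed)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(M * elapsed[i])))
    x <- E %*% c(V0, Ia0, Id0, 1)
    V[i] <- x[1]; Ia[i] <- x[2]; Id[i] <- x[3]
  }
  list(V = V, I_adap = Ia, I_dep = Id)
}

#' Closed-form trajectory of the nondimensional system
#'
#' Evaluates the membrane potential, adaptation current and depolarizing
#' current at arbitrary times without numerical integration, from the general
#' integral of the linear system. The depolarizing current decays exactly as
#' \eqn{I_{dep}(t) = I_{dep}^0 e^{-\beta (t-t_0)}}. Within \code{1e-10} of the
#' removable singularities of the written-out solution (\eqn{\beta=\delta},
#' \eqn{\beta^2+(\beta-1)\delta = 0}) the exact limit is evaluated through the
#' matrix exponential of the augmented system.
#'
#' @param n an \code{"aglif_nondim"} object.
#' @param init initial data: an \code{"aglif_state"} in nondimensional units,
#'   or a list with \code{V}, \code{I_adap}, \code{I_dep}.
#' @param t0 initial nondimensional time.
#' @param t evaluation time(s), all \code{>= t0}; vectorized.
#' @return For scalar \code{t}, an \code{"aglif_state"} (nondimensional);
#'   for vector \code{t}, a data.frame with columns \code{t, V, I_adap, I_dep}.
#' @export
general_integral <- function(n, init, t0, t) {
  stopifnot(inherits(n, "aglif_nondim"))
  if (inherits(init, "aglif_state") && init$units != "nondimensional")
    stop("init must be a nondimensional state")
  if (any(t < t0)) stop("t must not precede t0")
  tr <- .aglif_traj(n$alpha, n$beta, n$delta,
                    init$V, init$I_adap, init$I_dep, t - t0)
  if (length(t) == 1L)
    aglif_state(t, tr$V, tr$I_adap, tr$I_dep, units = "nondimensional")
  else
    data.frame(t = t, V = tr$V, I_adap = tr$I_adap, I_dep = tr$I_dep)
}

#' Equilibria of the nondimensional system
#'
#' For \code{alpha = 0} with \code{beta = delta} there is a line of equilibria
#' \eqn{(\bar V,\, 1+\bar V,\, 0)} (the resting member has \eqn{\bar V = -1});
#' otherwise the unique equilibrium is
#' \eqn{E_1 = (\alpha/(\beta-\delta) - 1,\ \alpha/(\beta-\delta),\ 0)}.
#' The depolarizing component is always zero and, for \eqn{E_1},
#' \eqn{I^*_{adap} - V^* = 1}.
#'
#' @param n an \code{"aglif_nondim"} object.
#' @return A list of equilibria; each element is a list with \code{kind}
#'   (\code{"E0_family"} or \code{"E1"}), \code{V_star}, \code{I_adap_star},
#'   \code{I_dep_star}, and \code{stability_label}.
#' @export
equilibria <- function(n) {
  stopifnot(inherits(n, "aglif_nondim"))
  label <- classify_stability(n$beta, n$delta)$label
  if (n$alpha == 0 && n$beta == n$delta) {
    list(list(kind = "E0_family", V_star = -1, I_adap_star = 0,
              I_dep_star = 0, parameterized_by = "V_bar",
              family = function(V_bar) c(V_bar, 1 + V_bar, 0),
              stability_label = label))
  } else {
    v <- n$alpha / (n$beta - n$delta)
    list(list(kind = "E1", V_star = v - 1, I_adap_star = v, I_dep_star = 0,
              stability_label = label))
  }
}

#' Eigenvalues of the Jacobian
#'
#' The Jacobian of the nondimensional system has eigenvalues
#' \eqn{\lambda_1 = -\beta} and
#' \eqn{\lambda_{2,3} = \tfrac12\big(\delta - 1 \pm \sqrt{\Delta}\big)} with
#' \eqn{\Delta = (1+\delta)^2 - 4\beta}; they do not depend on the injected
#' current.
#'
#' @param beta,delta nondimensional parameters (positive).
#' @return A numeric vector of length 3, or complex when \eqn{\Delta < 0}.
#' @export
glif_eigenvalues <- function(beta, delta) {
  stopifnot(beta > 0, delta > 0)
  Delta <- (1 + delta)^2 - 4 * beta
  if (Delta >= 0) {
    s <- sqrt(Delta)
    c(-beta, (delta - 1 + s) / 2, (delta - 1 - s) / 2)
  } else {
    s <- sqrt(as.complex(Delta))
    c(as.complex(-beta), (delta - 1 + s) / 2, (delta - 1 - s) / 2)
  }
}

#' Stability classification in the (beta, delta) plane
#'
#' Classifies the unique equilibrium of the suprathreshold system by the sign
#' pattern of the Jacobian eigenvalues: a stable node with real eigenvalues
#' when \eqn{\delta < \beta \le (1+\delta)^2/4} with \eqn{0<\delta<1}; damped
#' oscillations (stable focus) when \eqn{\beta > (1+\delta)^2/4} with
#' \eqn{0<\delta<1}; sustained oscillations (center) when \eqn{\beta>1},
#' \eqn{\delta=1}; instability when \eqn{\beta<\delta} with \eqn{\delta\le 1}
#' or for any \eqn{\beta} when \eqn{\delta>1} (the latter region corresponds
#' to rebound spiking and is excluded from fitting). Measure-zero boundaries
#' not covered by those open regions are reported as
#' \code{"boundary_degenerate"} rather than force-fitted.
#'
#' @param beta,delta nondimensional parameters (positive).
#' @return An object of class \code{"aglif_stability"}: list with
#'   \code{eigenvalues}, \code{label}, \code{region_conditions}.
#' @export
classify_stability <- function(beta, delta) {
  stopifnot(beta > 0, delta > 0)
  ev <- glif_eigenvalues(beta, delta)
  parab <- (1 + delta)^2 / 4
  if (delta > 1) {
    label <- "unstable"
    region <- if (beta > parab) "complex_pair_positive_real_part"
              else "real_eigenvalue_positive"
  } else if (delta == 1) {
    if (beta > 1) {
      label <- "center_sustained"; region <- "pure_imaginary_pair"
    } else if (beta < 1) {
      label <- "unstable"; region <- "real_eigenvalue_positive"
    } else {
      label <- "boundary_degenerate"; region <- "repeated_zero_eigenvalue"
    }
  } else {
    if (beta < delta) {
      label <- "unstable"; region <- "real_eigenvalue_positive"
    } else if (beta == delta) {
      label <- "boundary_degenerate"; region <- "zero_eigenvalue"
    } else if (beta <= parab) {
      label <- "stable_node_real"; region <- "real_eigenvalues_negative"
    } else {
      label <- "stable_focus_damped"; region <- "complex_pair_negative_real_part"
    }
  }
  structure(list(eigenvalues = ev, label = label, region_conditions = region),
            class = "aglif_stability")
}

#' @export
print.aglif_stability <- function(x, ...) {
  cat("stability:", x$label, "(", x$region_conditions, ")\n")
  cat("eigenvalues:", format(x$eigenvalues, digits = 6), "\n")
  invisible(x)
}

#' Sensitivity of the membrane potential to the after-spike initial currents
#'
#' The potential is a strictly decreasing function of the after-spike
#' adaptation current and an increasing function of the after-spike
#' depolarizing current (for parameters in the asymptotic-stability region).
#' The first derivative has the closed form \eqn{dV/dI_{adap}^0 = -\beta H_1};
#' the second is evaluated by central finite differences on the general
#' integral.
#'
#' @param n an \code{"aglif_nondim"} object.
#' @param init initial state (nondimensional), as in [general_integral()].
#' @param t0,t initial and evaluation nondimensional times, \code{t >= t0}.
#' @return list with \code{dV_dIadap0} and \code{dV_dIdep0}.
#' @export
voltage_sensitivities <- function(n, init, t0, t) {
  stopifnot(inherits(n, "aglif_nondim"), t >= t0)
  aux <- auxiliary_terms(n$beta, n$delta, t - t0)
  dIa <- -n$beta * aux$H1
  h <- 1e-6
  up <- .aglif_traj(n$alpha, n$beta, n$delta, init$V, init$I_adap,
                    init$I_dep + h, t - t0)$V
  dn <- .aglif_traj(n$alpha, n$beta, n$delta, init$V, init$I_adap,
                    init$I_dep - h, t - t0)$V
  list(dV_dIadap0 = dIa, dV_dIdep0 = (up - dn) / (2 * h))
}

#' Long-time membrane potential under subthreshold or negative current
#'
#' For currents between the measured hyperpolarizing reference current
#' \code{I_stim_neg} and zero, the steady state is interpolated linearly in
#' the scaled current between the resting potential and the physiological
#' floor \code{V_min} (the potassium reversal potential); below
#' \code{I_stim_neg} the potential is clamped at \code{V_min}. For
#' \code{0 < I_stim < I_th} the unclamped equilibrium
#' \eqn{V_1^* = \alpha/(\beta-\delta) - 1} applies.
#'
#' @param I_stim stimulation current (pA), must satisfy
#'   \code{I_stim < I_th}.
#' @param p an \code{"aglif_parameters"} object.
#' @return list with \code{V_star} (nondimensional) and \code{V_mV}.
#' @export
clamped_equilibrium <- function(I_stim, p) {
  stopifnot(inherits(p, "aglif_parameters"))
  if (I_stim >= p$I_th)
    stop("clamped_equilibrium applies only to subthreshold currents")
  n <- nondimensionalize(p, I_stim)
  V_min_star <- -p$V_min / p$E_L
  if (I_stim > 0) {
    v <- n$alpha / (n$beta - n$delta) - 1
  } else if (I_stim >= p$I_stim_neg) {
    alpha_neg <- p$I_stim_neg / p$K
    v <- -1 + (1 + V_min_star) * n$alpha / alpha_neg
  } else {
    v <- V_min_star
  }
  list(V_star = v, V_mV = -v * p$E_L)
}
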