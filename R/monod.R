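#' Monod coefficients of the after-spike adaptation update
#'
#' The initial value of the adaptation current assigned after each spike is
#' interpolated across spike times and stimulation currents by a saturating
#' Monod-type function
#' \deqn{I_{adap}^0(\chi, I) = c + a\, e^{bI}\, \chi / (d + \chi),}
#' where \eqn{\chi} is the elapsed time (ms) since the last instant the
#' stimulation was at or below the rheobase. \code{d > 0} is required
#' whenever \code{a != 0} (the degenerate cases \code{a = 0} and \code{d = 0}
#' produce constant inter-spike intervals).
#'
#' @param a,b,c,d real coefficients; \code{b} in 1/pA, \code{d} in ms.
#' @return An object of class \code{"aglif_monod"}.
#' @export
monod_coefficients <- function(a, b, c, d) {
  for (v in list(a, b, c, d))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("Monod coefficients must be finite numeric scalars")
  if (a != 0 && d <= 0)
    stop("d must be positive when a is nonzero")
  if (d < 0) stop("d must be non-negative")
  structure(list(a = a, b = b, c = c, d = d), class = "aglif_monod")
}

#' Evaluate the Monod update function
#'
#' @param m an \code{"aglif_monod"} object.
#' @param chi elapsed time(s) since stimulation onset (ms, \code{>= 0});
#'   vectorized.
#' @param I_stim stimulation current (pA).
#' @return \code{c + a e^{b I} chi / (d + chi)}.
#' @export
monod_value <- function(m, chi, I_stim) {
  stopifnot(inherits(m, "aglif_monod"), all(chi >= 0))
  if (any(m$d + chi == 0))
    stop("singularity: d + chi = 0")
  m$c + m$a * exp(m$b * I_stim) * chi / (m$d + chi)
}

#' Monotonicity and positivity report for a Monod rule
#'
#' Reports the monotonicity of the update function in elapsed time
#' (increasing iff \code{a > 0}) and in current (increasing iff
#' \code{a*b > 0}), the plateau function
#' \eqn{P(I) = c + a e^{bI}} reached as \eqn{\chi \to \infty}, and a
#' positivity verdict: \code{"global"} when positivity holds for all
#' \eqn{\chi > 0, I > 0} (either \code{a>0, c>=0} or \code{a<0, b<0, c>=-a});
#' \code{"range_restricted"} when only the necessary conditions for the
#' supplied current range hold (\code{a>0} requires \code{P(I)>0} there,
#' \code{a<0} requires \code{c>0}); \code{"fails"} otherwise.
#'
#' @param m an \code{"aglif_monod"} with \code{a != 0} and \code{d > 0}.
#' @param I_range currents (pA) over which range-restricted positivity is
#'   assessed; default \code{c(200, 1000)}.
#' @return list with \code{monotone_in_chi}, \code{monotone_in_I},
#'   \code{plateau_fn}, \code{positivity_verdict}.
#' @export
monod_properties <- function(m, I_range = c(200, 1000)) {
  stopifnot(inherits(m, "aglif_monod"))
  if (m$a == 0 || m$d <= 0)
    stop("monod_properties requires a != 0 and d > 0")
  plateau <- function(I) m$c + m$a * exp(m$b * I)
  global <- (m$a > 0 && m$c >= 0) ||
    (m$a < 0 && m$b < 0 && m$c >= -m$a)
  # the plateau is monotone in I, so range positivity is checked at the
  # endpoints; for a < 0 the function decreases from c towards the plateau,
  # so both the intercept and the plateau must stay positive over the range
  range_ok <- if (m$a > 0) all(plateau(I_range) > 0)
              else m$c > 0 && all(plateau(range(I_range)) >= 0)
  verdict <- if (global) "global" else if (range_ok) "range_restricted" else "fails"
  list(monotone_in_chi = if (m$a > 0) "increasing" else "decreasing",
       monotone_in_I = if (m$a * m$b > 0) "increasing" else
         if (m$a * m$b < 0) "decreasing" else "constant",
       plateau_fn = plateau,
       positivity_verdict = verdict)
}

#' Upper admissibility bound for the after-spike adaptation current
#'
#' For the potential to increase after a reset, the after-spike adaptation
#' current must stay below
#' \deqn{H = \alpha/\beta + I_{dep}^0 + (\delta/\beta)(1 + V^0),}
#' with all quantities nondimensional. \code{H} is monotonically increasing
#' in the stimulation current (slope \eqn{1/(K\beta)} per pA).
#'
#' @param n an \code{"aglif_nondim"} object.
#' @param I_dep0 nondimensional after-spike depolarizing current.
#' @param V0 nondimensional reset potential (\code{-1} before the first
#'   spike, \code{-V_r/E_L} afterwards).
#' @return The bound \code{H}.
#' @export
threshold_H <- function(n, I_dep0, V0) {
  stopifnot(inherits(n, "aglif_nondim"), n$beta != 0)
  n$alpha / n$beta + I_dep0 + (n$delta / n$beta) * (1 + V0)
}

#' Out-of-range correction of a Monod rule
#'
#' When a stimulation current outside the fitted range makes the Monod update
#' negative, the function is translated along the vertical axis. For the main
#' case \code{a > 0} (negativity occurs near \eqn{\chi = 0^+}, i.e.
#' \code{c < 0}) the replacement intercept is
#' \deqn{c^* = \alpha/\beta + \eta I_{dep}^0 + (\delta/\beta)(1+V^0)
#'       - a e^{bI},\quad \eta \in [0,1],}
#' with \eqn{\eta} chosen on a grid to minimize \eqn{|c^* - c|} subject to
#' positivity (\code{c* >= 0}); if no grid point qualifies, the fallback
#' \eqn{c^* = c - L} is applied with \eqn{L} the (negative) Monod value at
#' the first spike time, which zeroes the function there. For \code{a < 0}
#' (update decreasing towards the plateau) the documented fallback lifts the
#' plateau to zero when it is negative. Positivity is prioritized over the
#' admissibility bound \code{H}.
#'
#' @param m an \code{"aglif_monod"} object.
#' @param n an \code{"aglif_nondim"} at the current of interest.
#' @param I_stim stimulation current (pA).
#' @param I_dep0 nondimensional after-spike depolarizing current.
#' @param V0 nondimensional reset potential.
#' @param chi_first elapsed time of the first spike (ms); required for the
#'   fallback when \code{a > 0}.
#' @param eta_grid number of grid points for \eqn{\eta}; default 101.
#' @return An \code{"aglif_monod"}; unchanged when no adjustment is needed,
#'   otherwise with attribute \code{"adjusted"} describing the path taken.
#' @export
adjust_monod_out_of_range <- function(m, n, I_stim, I_dep0, V0,
                                      chi_first = NULL, eta_grid = 101) {
  stopifnot(inherits(m, "aglif_monod"), inherits(n, "aglif_nondim"))
  if (m$a > 0) {
    if (m$c >= 0) return(m)
    eta <- seq(0, 1, length.out = eta_grid)
    cstar <- n$alpha / n$beta + eta * I_dep0 +
      (n$delta / n$beta) * (1 + V0) - m$a * exp(m$b * I_stim)
    ok <- cstar >= 0
    if (any(ok)) {
      pick <- which(ok)[which.min(abs(cstar[ok] - m$c))]
      out <- monod_coefficients(m$a, m$b, cstar[pick], m$d)
      attr(out, "adjusted") <- list(path = "eta_translation", eta = eta[pick])
      return(out)
    }
    if (is.null(chi_first))
      stop("chi_first is required for the fallback translation")
    L <- monod_value(m, chi_first, I_stim)
    if (L >= 0) return(m)
    out <- monod_coefficients(m$a, m$b, m$c - L, m$d)
    attr(out, "adjusted") <- list(path = "first_spike_zero", L = L)
    out
  } else {
    P <- m$c + m$a * exp(m$b * I_stim)
    if (P >= 0 && m$c >= 0) return(m)
    shift <- min(P, m$c, 0)
    out <- monod_coefficients(m$a, m$b, m$c - shift, m$d)
    attr(out, "adjusted") <- list(path = "plateau_lift", L = shift)
    out
  }
}
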