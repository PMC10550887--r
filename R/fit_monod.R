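#' Fit a Monod update rule to adaptation sequences
#'
#' Least-squares interpolation of per-spike adaptation values
#' \eqn{(\chi, I, I_{adap}^0)} by the saturating form
#' \eqn{c + a e^{bI} \chi/(d+\chi)}, minimizing the summed squared residuals
#' over all currents simultaneously. The solver is a bounded
#' Levenberg-Marquardt local optimizer (\pkg{minpack.lm}) launched from a
#' deterministic multi-start grid around method-of-moments guesses (intercept
#' from the earliest spikes, plateau from the latest, saturation scale from
#' the spread of \eqn{\chi}); the best converged start satisfying the
#' positivity requirements is returned, falling back to the best overall with
#' a warning when none qualifies.
#'
#' Constant sequences are the degenerate constant-ISI case: the fit is
#' flagged (\code{attr(., "degenerate") == "constant_isi"}) and returns
#' \code{a = 0} with \code{c} at the common value.
#'
#' @param sequences data.frame with columns \code{chi_ms}, \code{I_pA} and a
#'   value column (\code{I_adap0} or the third column).
#' @param n_starts number of starting points; default 16.
#' @param seed seed controlling the start jitter; default 1.
#' @return An \code{"aglif_monod"} with attribute \code{"fit"} carrying
#'   \code{rss}, \code{rms} and \code{n}.
#' @export
fit_monod <- function(sequences, n_starts = 16, seed = 1) {
  stopifnot(is.data.frame(sequences), ncol(sequences) >= 3L)
  chi <- sequences$chi_ms
  I <- sequences$I_pA
  y <- if ("I_adap0" %in% names(sequences)) sequences$I_adap0
       else sequences[[3L]]
  if (length(chi) < 4L) stop("at least 4 data points are required")
  if (length(unique(I)) < 2L) stop("at least 2 distinct currents are required")
  if (length(unique(chi)) == 1L)
    stop("degenerate data: all elapsed times identical")

  if (stats::sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    out <- monod_coefficients(0, 0, mean(y), 1)
    attr(out, "degenerate") <- "constant_isi"
    attr(out, "fit") <- list(rss = 0, rms = 0, n = length(y))
    return(out)
  }

  resid_fn <- function(par) {
    par["c"] + par["a"] * exp(par["b"] * I) * chi / (par["d"] + chi) - y
  }

  # moment-style anchors for the starts
  early <- y[chi <= stats::quantile(chi, 0.25)]
  late <- y[chi >= stats::quantile(chi, 0.75)]
  c0 <- mean(early); a0 <- mean(late) - mean(early)
  if (abs(a0) < 1e-8) a0 <- stats::sd(y)
  d_grid <- stats::median(chi) * c(0.25, 1, 4)
  b_grid <- c(-1e-3, -2e-4, 2e-4, 1e-3)

  starts <- list()
  for (d0 in d_grid) for (b0 in b_grid)
    starts[[length(starts) + 1L]] <- c(a = a0, b = b0, c = c0, d = d0)
  starts <- .local_seed(seed, {
    while (length(starts) < n_starts) {
      starts[[length(starts) + 1L]] <-
        c(a = a0 * stats::runif(1, 0.3, 3) * sample(c(-1, 1), 1),
          b = stats::runif(1, -2e-3, 2e-3),
          c = c0 * stats::runif(1, 0.5, 2),
          d = stats::median(chi) * stats::runif(1, 0.1, 5))
    }
    starts[seq_len(n_starts)]
  })

  fits <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = c(a = -Inf, b = -Inf, c = -Inf, d = 1e-6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) stop("Monod fit failed from every start")
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))

  ok <- vapply(fits, function(f) {
    par <- f$par
    if (par[["a"]] == 0) return(FALSE)
    m <- monod_coefficients(par[["a"]], par[["b"]], par[["c"]], par[["d"]])
    monod_properties(m, I_range = range(I))$positivity_verdict != "fails"
  }, logical(1))
  pick <- if (any(ok)) which(ok)[which.min(rss[ok])] else {
    warning("no converged fit satisfies the positivity conditions; ",
            "returning the best unconstrained fit")
    which.min(rss)
  }
  par <- fits[[pick]]$par
  out <- monod_coefficients(par[["a"]], par[["b"]], par[["c"]], par[["d"]])
  attr(out, "fit") <- list(rss = rss[pick],
                           rms = sqrt(rss[pick] / length(y)),
                           n = length(y))
  out
}
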