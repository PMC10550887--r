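#' Detect a firing block in a spike train
#'
#' A neuron is considered to have entered a firing block when it stops firing
#' long before the stimulation ends and never recovers; operationally, when
#' \eqn{t^{last}_{spk} + 2\, ISI_{last} < T}, consistent with the observed
#' maximum late/early inter-spike-interval ratio of about 2. Trains with
#' fewer than two spikes have no defined last ISI and are reported as not
#' blocked; a separate \code{never_fired} flag distinguishes empty trains.
#'
#' @param spikes ordered spike times (ms).
#' @param T_end end of the stimulation window (ms).
#' @return list with logicals \code{blocked} and \code{never_fired}.
#' @export
detect_firing_block <- function(spikes, T_end) {
  spikes <- sort(spikes)
  if (length(spikes) == 0L)
    return(list(blocked = FALSE, never_fired = TRUE))
  if (length(spikes) < 2L)
    return(list(blocked = FALSE, never_fired = FALSE))
  isi_last <- diff(utils::tail(spikes, 2))
  list(blocked = utils::tail(spikes, 1) + 2 * isi_last < T_end,
       never_fired = FALSE)
}

# anchor point of the block line at one current: (I, t_last + ISI_last/2)
.block_anchor <- function(spikes) {
  spikes <- sort(spikes)
  t_last <- utils::tail(spikes, 1)
  t_last + diff(utils::tail(spikes, 2)) / 2
}

#' Build the firing-block rule from a raster
#'
#' From the per-current spike trains, identifies the currents at which a
#' firing block occurs, groups them into maximal intervals of consecutive
#' tested currents, and for each interval constructs the straight line
#' \eqn{t = A\,I + B} through the anchor points
#' \eqn{P_i = (I,\ t_{last}(I) + ISI_{last}(I)/2)} at the interval endpoints.
#' \code{I_fire} is the nearest tested non-blocking, firing current outside
#' the interval. When only a single current blocks, the interval is extended
#' to \code{I_fire} and the anchor at \code{I_fire} is used as the second
#' point. The validity region of each line is one-sided: the cutoff applies
#' to currents on the blocking side of the threshold current midway between
#' \code{I_fire} and the blocking endpoint adjacent to it (this midpoint rule
#' reproduces the worked validity thresholds for both degenerate and
#' two-current intervals).
#'
#' Currents with fewer than two spikes cannot define a last ISI; they are
#' excluded from block detection with a warning (empty trains silently, as
#' never-fired).
#'
#' @param raster a data.frame with columns \code{I_pA} and
#'   \code{spike_time_ms} (a \code{cell_id} column is allowed and must refer
#'   to a single cell).
#' @param T_end end of the stimulation window (ms).
#' @return An object of class \code{"aglif_block_rule"}: list with
#'   \code{lines} (each with \code{A}, \code{B}, \code{validity} =
#'   \code{"le"}/\code{"ge"}, \code{threshold}, \code{P1}, \code{P2}),
#'   \code{block_intervals}, \code{I_fire}, \code{blocking_currents}. When no
#'   current blocks, a rule with zero lines.
#' @export
build_block_rule <- function(raster, T_end) {
  stopifnot(is.data.frame(raster),
            all(c("I_pA", "spike_time_ms") %in% names(raster)))
  if ("cell_id" %in% names(raster) && length(unique(raster$cell_id)) > 1L)
    stop("build_block_rule expects a single cell")
  currents <- sort(unique(raster$I_pA))
  spikes_of <- function(I) sort(raster$spike_time_ms[raster$I_pA == I])
  status <- vapply(currents, function(I) {
    s <- spikes_of(I)
    if (length(s) == 0L) return("never_fired")
    if (length(s) == 1L) return("degenerate")
    if (detect_firing_block(s, T_end)$blocked) "blocking" else "firing"
  }, character(1))
  if (any(status == "degenerate"))
    warning("currents with a single spike excluded from block detection: ",
            paste(currents[status == "degenerate"], collapse = ", "))
  blocking <- currents[status == "blocking"]
  firing <- currents[status == "firing"]
  empty <- structure(list(lines = list(), block_intervals = list(),
                          I_fire = numeric(0), blocking_currents = blocking),
                     class = "aglif_block_rule")
  if (length(blocking) == 0L) return(empty)
  if (length(firing) == 0L)
    stop("no non-blocking current available to serve as I_fire")

  # group blocking currents into runs of consecutive tested currents
  idx <- match(blocking, currents)
  runs <- split(blocking, cumsum(c(1, diff(idx) != 1)))

  lines <- list(); intervals <- list(); fires <- numeric(0)
  for (run in runs) {
    lo <- min(run); hi <- max(run)
    cand <- firing[firing > hi | firing < lo]
    if (length(cand) == 0L)
      stop("no non-blocking current adjacent to block interval [",
           lo, ", ", hi, "]")
    I_fire <- cand[which.min(pmin(abs(cand - hi), abs(cand - lo)))]
    if (length(run) >= 2L) {
      I1 <- lo; I2 <- hi
    } else if (I_fire > run) {
      I1 <- run; I2 <- I_fire
    } else {
      I1 <- I_fire; I2 <- run
    }
    P1 <- c(I = I1, t = .block_anchor(spikes_of(I1)))
    P2 <- c(I = I2, t = .block_anchor(spikes_of(I2)))
    A <- (P2[["t"]] - P1[["t"]]) / (P2[["I"]] - P1[["I"]])
    B <- P1[["t"]] - A * P1[["I"]]
    if (I_fire > hi) {
      validity <- "le"; threshold <- (I_fire + hi) / 2
    } else {
      validity <- "ge"; threshold <- (I_fire + lo) / 2
    }
    lines[[length(lines) + 1L]] <-
      list(A = A, B = B, validity = validity, threshold = threshold,
           P1 = P1, P2 = P2)
    intervals[[length(intervals) + 1L]] <- c(I1, I2)
    fires <- c(fires, I_fire)
  }
  structure(list(lines = lines, block_intervals = intervals, I_fire = fires,
                 blocking_currents = blocking),
            class = "aglif_block_rule")
}

#' @export
print.aglif_block_rule <- function(x, ...) {
  if (length(x$lines) == 0L) {
    cat("firing-block rule: no blocking currents\n")
    return(invisible(x))
  }
  cat("firing-block rule:\n")
  for (ln in x$lines) {
    cat(sprintf("  t = %.2f I + %.2f  for I %s %g pA\n",
                ln$A, ln$B, if (ln$validity == "le") "<=" else ">=",
                ln$threshold))
  }
  invisible(x)
}

#' Firing cutoff time implied by a block rule
#'
#' If the stimulation current falls in the validity region of one of the
#' block lines, the Monod update is undefined past \eqn{t = A\,I + B} and the
#' neuron stops firing at that time; otherwise no cutoff applies. Full
#' precision is used (coefficients are rounded only for display).
#'
#' @param rule an \code{"aglif_block_rule"}.
#' @param I_stim stimulation current (pA).
#' @return The cutoff time (ms), or \code{NULL} when the current lies outside
#'   every validity region. If several lines apply, the earliest cutoff wins.
#' @export
block_cutoff <- function(rule, I_stim) {
  if (is.null(rule)) return(NULL)
  stopifnot(inherits(rule, "aglif_block_rule"))
  cuts <- numeric(0)
  for (ln in rule$lines) {
    applies <- if (ln$validity == "le") I_stim <= ln$threshold
               else I_stim >= ln$threshold
    if (applies) cuts <- c(cuts, ln$A * I_stim + ln$B)
  }
  if (length(cuts) == 0L) NULL else min(cuts)
}
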