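#' Piecewise-constant stimulation protocol
#'
#' @param t_begin,t_end,I numeric vectors of equal length: segment start and
#'   end times (ms) and currents (pA). Segments must be sorted, contiguous
#'   and non-overlapping.
#' @return An object of class \code{"aglif_protocol"} (a data.frame with
#'   columns \code{t_begin_ms}, \code{t_end_ms}, \code{I_pA}).
#' @export
stimulus_protocol <- function(t_begin, t_end, I) {
  if (!(length(t_begin) == length(t_end) && length(t_end) == length(I)))
    stop("t_begin, t_end and I must have equal length")
  if (any(t_end <= t_begin)) stop("each segment must have t_end > t_begin")
  if (is.unsorted(t_begin, strictly = TRUE))
    stop("segments must be sorted by t_begin")
  if (length(t_begin) > 1L &&
      any(abs(t_begin[-1L] - t_end[-length(t_end)]) > 1e-9))
    stop("segments must be contiguous: t_end(i) = t_begin(i+1)")
  structure(data.frame(t_begin_ms = t_begin, t_end_ms = t_end, I_pA = I),
            class = c("aglif_protocol", "data.frame"))
}

#' First threshold crossing of the closed-form trajectory
#'
#' Scans the closed-form membrane potential on a coarse grid, brackets the
#' first up-crossing of the threshold and refines it by bisection. Because
#' the trajectory between events is smooth and cheap to evaluate, the coarse
#' step only has to be fine enough to bracket; the refined crossing is
#' independent of it.
#'
#' @param n an \code{"aglif_nondim"} object.
#' @param init initial data (\code{"aglif_init"}, \code{"aglif_state"} in
#'   nondimensional units, or a plain list with \code{V0/I_adap0/I_dep0} or
#'   \code{V/I_adap/I_dep} fields).
#' @param t0 start time (nondimensional).
#' @param t_max scan horizon (nondimensional), \code{> t0}.
#' @param Vth_tilde nondimensional threshold potential.
#' @param coarse_ms coarse scan step in ms (dimensional equivalent);
#'   default 0.05.
#' @param refine_tol_ms bisection tolerance in ms; default 1e-9.
#' @return The crossing time (nondimensional) or \code{NULL}.
#' @export
solve_to_threshold <- function(n, init, t0, t_max, Vth_tilde,
                               coarse_ms = 0.05, refine_tol_ms = 1e-9) {
  stopifnot(inherits(n, "aglif_nondim"), t_max > t0)
  s <- .init_fields(init)
  .first_crossing(n$alpha, n$beta, n$delta, s$V, s$Ia, s$Id,
                  t0, t_max, Vth_tilde,
                  step = coarse_ms / n$tau,
                  tol = refine_tol_ms / n$tau,
                  refine = TRUE)
}

.init_fields <- function(init) {
  if (!is.null(init$V0))
    list(V = init$V0, Ia = init$I_adap0, Id = init$I_dep0)
  else
    list(V = init$V, Ia = init$I_adap, Id = init$I_dep)
}

# Chunked coarse scan + optional bisection. Times are nondimensional offsets
# handled internally; returns absolute time of first up-crossing or NULL.
.first_crossing <- function(alpha, beta, delta, V0, Ia0, Id0,
                            t0, t_max, Vth, step, tol,
                            refine = TRUE, chunk = 400L) {
  if (V0 >= Vth) return(t0)
  h_total <- t_max - t0
  n_steps <- ceiling(h_total / step)
  done <- 0L
  V_prev <- V0
  while (done < n_steps) {
    take <- min(chunk, n_steps - done)
    hs <- (done + seq_len(take)) * step
    hs[length(hs)] <- min(hs[length(hs)], h_total)
    V <- .aglif_traj(alpha, beta, delta, V0, Ia0, Id0, hs)$V
    hit <- which(V >= Vth)
    if (length(hit)) {
      i <- hit[1L]
      lo <- if (i == 1L) (done) * step else hs[i - 1L]
      hi <- hs[i]
      V_lo <- if (i == 1L) V_prev else V[i - 1L]
      if (!refine) {
        # linear interpolation of the bracketing pair
        w <- (Vth - V_lo) / (V[i] - V_lo)
        return(t0 + lo + w * (hi - lo))
      }
      f <- function(h) .aglif_traj(alpha, beta, delta, V0, Ia0, Id0, h)$V - Vth
      r <- stats::uniroot(f, c(lo, hi), tol = tol)
      return(t0 + r$root)
    }
    V_prev <- V[take]
    done <- done + take
  }
  NULL
}

#' Stimulation-onset shift at an upward current step
#'
#' When the current rises between two suprathreshold values, the reference
#' time entering the Monod update moves forward:
#' \eqn{t_{start} \leftarrow t_{start}\,(1 + (I_{prev}-I_{th})/I_{prev})},
#' reducing the effective elapsed time and hence the adaptation assigned
#' after subsequent spikes.
#'
#' @param t_start current stimulation-onset reference (ms).
#' @param I_prev current before the step (pA), suprathreshold.
#' @param I_th rheobase current (pA).
#' @return The updated \code{t_start} (ms).
#' @export
t_start_shift <- function(t_start, I_prev, I_th) {
  stopifnot(I_prev > 0)
  t_start * (1 + (I_prev - I_th) / I_prev)
}

#' After-step continuity correction factor
#'
#' At a downward current step that stays above the rheobase, the membrane
#' potential should keep increasing. The depolarizing current is re-seeded as
#' \eqn{I_{dep}^0 = I_{adap}^0 + \Theta^* \bar\alpha/\beta}, where
#' \eqn{\Theta^* = \max(\Theta, 0)} and
#' \deqn{\Theta = \frac{V(\bar t - \Delta t)}{\bar{\bar\alpha}}
#'   \Big(\frac{1}{\Delta t} - \delta\Big)
#'   - \frac{V(\bar t - 2\Delta t)}{\bar{\bar\alpha}\,\Delta t}
#'   - \frac{\delta}{\bar{\bar\alpha}} - 1,}
#' with \eqn{\bar{\bar\alpha}} the scaled current before the step. All
#' quantities are nondimensional (\code{dt} included).
#'
#' @param V_prev membrane potential one sampling step before the boundary.
#' @param V_prev2 membrane potential two sampling steps before the boundary.
#' @param dt sampling step (nondimensional), positive.
#' @param delta nondimensional leak parameter.
#' @param alpha_bb scaled current before the step (nonzero).
#' @return list with \code{theta} and \code{theta_star}.
#' @export
theta_star <- function(V_prev, V_prev2, dt, delta, alpha_bb) {
  stopifnot(dt > 0, alpha_bb != 0)
  theta <- (V_prev / alpha_bb) * (1 / dt - delta) -
    V_prev2 / (alpha_bb * dt) - delta / alpha_bb - 1
  list(theta = theta, theta_star = max(theta, 0))
}

# ---------------------------------------------------------------------------
# event-driven engine shared by simulate_constant and simulate_piecewise
# ---------------------------------------------------------------------------

# Episodes describe the trajectory piecewise so the trace can be sampled
# afterwards: type "flow" (closed form from init at t0 with given alpha) or
# "refractory" (V held at reset). Times in ms.
.aglif_engine <- function(cell, protocol, coarse_ms = 0.05,
                          refine_tol_ms = 1e-9) {
  p <- cell$params
  n0 <- nondimensionalize(p, 0)
  tau <- n0$tau
  beta <- n0$beta; delta <- n0$delta

  spikes_I <- numeric(0); spikes_t <- numeric(0)
  blocked_at <- NA_real_
  episodes <- list()
  push_ep <- function(ep) episodes[[length(episodes) + 1L]] <<- ep

  state <- list(V = -1, Ia = 0, Id = 0)      # nondimensional, at t_cur
  t_cur <- protocol$t_begin_ms[1L]
  t_start <- t_cur                            # last instant with I <= I_th
  prev_I <- NA_real_
  prev_sub <- TRUE                            # at rest before the protocol
  pending_plus <- NA_real_                    # end of an open refractory gap
  last_flow <- NULL                           # for boundary Theta evaluation
  theta_dt_ms <- 0.1                          # sampling step entering Theta

  for (k in seq_len(nrow(protocol))) {
    tb <- protocol$t_begin_ms[k]
    te <- protocol$t_end_ms[k]
    I <- protocol$I_pA[k]
    suprath <- I > p$I_th
    n <- nondimensionalize(p, I)

    in_refractory <- !is.na(pending_plus) && pending_plus > tb

    if (!in_refractory) {
      if (!suprath) {
        # carry state; subthreshold relaxation handled below
      } else if (prev_sub) {
        ic <- first_spike_conditions(p, n, I)
        state <- list(V = ic$V0, Ia = ic$I_adap0, Id = ic$I_dep0)
        t_start <- tb
      } else if (I > prev_I) {
        # continuity; stimulation-onset reference shifts forward
        t_start <- t_start_shift(t_start, prev_I, p$I_th)
      } else if (I < prev_I) {
        # downward step above rheobase: re-seed the depolarizing current
        dt_nd <- theta_dt_ms / tau
        Vm1 <- .flow_V(last_flow, (tb - theta_dt_ms) / tau, beta, delta)
        Vm2 <- .flow_V(last_flow, (tb - 2 * theta_dt_ms) / tau, beta, delta)
        th <- theta_star(Vm1, Vm2, dt_nd, delta, prev_I / p$K)
        state$Id <- state$Ia + th$theta_star * (I / p$K) / beta
      }                                        # equal currents: continue
    }

    if (!suprath) {
      # relax toward the (possibly clamped) subthreshold equilibrium
      v_star <- clamped_equilibrium(min(I, p$I_th - 1e-9), p)$V_star
      alpha_eff <- (beta - delta) * (1 + v_star)
      if (in_refractory && pending_plus <= te) {
        push_ep(list(type = "refractory", t0 = t_cur, t1 = pending_plus,
                     V = n0$Vr_tilde))
        t_cur <- pending_plus
        pending_plus <- NA_real_
        state <- list(V = n0$Vr_tilde, Ia = state$Ia, Id = state$Id)
      }
      fl <- list(alpha = alpha_eff, t0 = t_cur / tau, state = state)
      push_ep(list(type = "flow", t0 = t_cur, t1 = te, flow = fl))
      st <- .aglif_traj(alpha_eff, beta, delta, state$V, state$Ia, state$Id,
                        (te - t_cur) / tau)
      state <- list(V = st$V, Ia = st$I_adap, Id = st$I_dep)
      last_flow <- fl
      t_cur <- te
      t_start <- te
      prev_sub <- TRUE
      prev_I <- I
      next
    }

    # suprathreshold segment ------------------------------------------------
    cutoff <- block_cutoff(cell$block, I)      # ms, relative to t_start
    blocked_here <- FALSE

    if (in_refractory) {
      if (pending_plus > te) {                 # refractory spans the segment
        push_ep(list(type = "refractory", t0 = t_cur, t1 = te,
                     V = n0$Vr_tilde))
        t_cur <- te; prev_sub <- FALSE; prev_I <- I
        next
      }
      push_ep(list(type = "refractory", t0 = t_cur, t1 = pending_plus,
                   V = n0$Vr_tilde))
      # boundary update deferred to the end of the refractory gap; the
      # stimulation-onset shift of an upward step still applies
      if (k > 1L && !prev_sub && I > prev_I)
        t_start <- t_start_shift(t_start, prev_I, p$I_th)
      ic <- after_spike_conditions(p, n, cell$monod, pending_plus, t_start, I)
      state <- list(V = ic$V0, Ia = ic$I_adap0, Id = ic$I_dep0)
      t_cur <- pending_plus
      pending_plus <- NA_real_
    }

    repeat {
      if (!is.null(cutoff) && t_cur - t_start >= cutoff) {
        blocked_at <- t_start + cutoff
        blocked_here <- TRUE
      }
      fl <- list(alpha = n$alpha, t0 = t_cur / tau, state = state)
      if (blocked_here) {
        # past the cutoff the update rule is undefined: freeze firing,
        # let the trace relax (no further threshold events)
        push_ep(list(type = "flow", t0 = t_cur, t1 = te, flow = fl))
        st <- .aglif_traj(n$alpha, beta, delta, state$V, state$Ia, state$Id,
                          (te - t_cur) / tau)
        state <- list(V = st$V, Ia = st$I_adap, Id = st$I_dep)
        last_flow <- fl
        t_cur <- te
        break
      }
      cross <- .first_crossing(n$alpha, beta, delta,
                               state$V, state$Ia, state$Id,
                               t_cur / tau, te / tau, n$Vth_tilde,
                               step = coarse_ms / tau,
                               tol = refine_tol_ms / tau)
      if (is.null(cross)) {
        push_ep(list(type = "flow", t0 = t_cur, t1 = te, flow = fl))
        st <- .aglif_traj(n$alpha, beta, delta, state$V, state$Ia, state$Id,
                          (te - t_cur) / tau)
        state <- list(V = st$V, Ia = st$I_adap, Id = st$I_dep)
        last_flow <- fl
        t_cur <- te
        break
      }
      t_spk <- cross * tau
      if (!is.null(cutoff) && t_spk - t_start >= cutoff) {
        # crossing past the cutoff: discard the spike, terminate the train
        blocked_at <- t_start + cutoff
        push_ep(list(type = "flow", t0 = t_cur, t1 = te, flow = fl))
        st <- .aglif_traj(n$alpha, beta, delta, state$V, state$Ia, state$Id,
                          (te - t_cur) / tau)
        state <- list(V = st$V, Ia = st$I_adap, Id = st$I_dep)
        last_flow <- fl
        t_cur <- te
        break
      }
      push_ep(list(type = "flow", t0 = t_cur, t1 = t_spk, flow = fl))
      st <- .aglif_traj(n$alpha, beta, delta, state$V, state$Ia, state$Id,
                        (t_spk - t_cur) / tau)
      last_flow <- fl
      spikes_I <- c(spikes_I, I); spikes_t <- c(spikes_t, t_spk)
      t_plus <- t_spk + p$dt_ref
      if (t_plus > te) {
        push_ep(list(type = "refractory", t0 = t_spk, t1 = te,
                     V = n0$Vr_tilde))
        state <- list(V = n0$Vr_tilde, Ia = st$I_adap, Id = st$I_dep)
        pending_plus <- t_plus
        t_cur <- te
        break
      }
      push_ep(list(type = "refractory", t0 = t_spk, t1 = t_plus,
                   V = n0$Vr_tilde))
      ic <- after_spike_conditions(p, n, cell$monod, t_plus, t_start, I)
      state <- list(V = ic$V0, Ia = ic$I_adap0, Id = ic$I_dep0)
      t_cur <- t_plus
    }
    prev_sub <- FALSE
    prev_I <- I
  }

  list(spike_I = spikes_I, spike_t = spikes_t, blocked_at = blocked_at,
       episodes = episodes, tau = tau, beta = beta, delta = delta)
}

.flow_V <- function(flow, t_nd, beta, delta) {
  h <- max(t_nd - flow$t0, 0)
  .aglif_traj(flow$alpha, beta, delta,
              flow$state$V, flow$state$Ia, flow$state$Id, h)$V
}

# sample the dimensional trace from the episode list
.sample_trace <- function(engine, p, trace_step) {
  t0 <- engine$episodes[[1L]]$t0
  t1 <- utils::tail(engine$episodes, 1L)[[1L]]$t1
  tg <- seq(t0, t1, by = trace_step)
  V <- Ia <- Id <- numeric(length(tg))
  tau <- engine$tau
  n_ep <- length(engine$episodes)
  for (j in seq_len(n_ep)) {
    ep <- engine$episodes[[j]]
    sel <- if (j == n_ep) which(tg >= ep$t0 & tg <= ep$t1)
           else which(tg >= ep$t0 & tg < ep$t1)
    if (!length(sel)) next
    if (ep$type == "refractory") {
      V[sel] <- ep$V
      Ia[sel] <- NA_real_; Id[sel] <- NA_real_
    } else {
      fl <- ep$flow
      st <- .aglif_traj(fl$alpha, engine$beta, engine$delta,
                        fl$state$V, fl$state$Ia, fl$state$Id,
                        tg[sel] / tau - fl$t0)
      V[sel] <- st$V; Ia[sel] <- st$I_adap; Id[sel] <- st$I_dep
    }
  }
  cur_scale <- -p$k_2 / (p$E_L * p$k_adap)
  data.frame(t_ms = tg,
             V_mV = -V * p$E_L,
             Iadap_pA = Ia / cur_scale,
             Idep_pA = Id / cur_scale)
}

#' Simulate a constant-current injection
#'
#' Event-driven simulation built on the closed-form trajectory: from rest,
#' the first-spike initial conditions are applied; each threshold crossing is
#' located by bracketing and bisection; after the refractory interval the
#' after-spike update (Monod rule) re-initializes the system. Currents at or
#' below the rheobase produce no spikes and the trace relaxes toward the
#' (possibly clamped) subthreshold equilibrium. If the cell carries a
#' firing-block rule whose cutoff applies at this current, no spikes are
#' generated after the cutoff time and \code{blocked_at} is set (a crossing
#' exactly at the cutoff is discarded).
#'
#' @param cell an \code{"aglif_cell"}.
#' @param I_stim stimulation current (pA).
#' @param T_end stimulation duration (ms); stimulation starts at 0.
#' @param trace_step trace sampling step (ms); default 0.1.
#' @param coarse_ms coarse threshold-scan step (ms); default 0.05.
#' @return list with \code{spikes} (an \code{"aglif_spike_train"}: fields
#'   \code{I_stim}, \code{spike_times}, \code{blocked_at},
#'   \code{never_fired}) and \code{trace} (data.frame \code{t_ms, V_mV,
#'   Iadap_pA, Idep_pA}; \code{V_mV} is held at the reset potential during
#'   refractory gaps where the currents are undefined).
#' @export
simulate_constant <- function(cell, I_stim, T_end, trace_step = 0.1,
                              coarse_ms = 0.05) {
  stopifnot(inherits(cell, "aglif_cell"), T_end > 0)
  prot <- stimulus_protocol(0, T_end, I_stim)
  eng <- .aglif_engine(cell, prot, coarse_ms = coarse_ms)
  train <- structure(list(I_stim = I_stim,
                          spike_times = eng$spike_t,
                          blocked_at = eng$blocked_at,
                          never_fired = length(eng$spike_t) == 0L),
                     class = "aglif_spike_train")
  list(spikes = train, trace = .sample_trace(eng, cell$params, trace_step))
}

#' Simulate a piecewise-constant stimulation protocol
#'
#' Within each segment the dynamics follow the constant-current engine with
#' carried-over state. At a boundary where the current decreases but stays
#' above the rheobase, the potential and adaptation current are continuous
#' and the depolarizing current is re-seeded through the \eqn{\Theta^*}
#' correction (see [theta_star()]); where it increases, the state is carried
#' over and the stimulation-onset reference \code{t_start} entering the Monod
#' update is shifted forward by the factor
#' \eqn{1 + (I_{prev}-I_{th})/I_{prev}}; where it falls to or below the
#' rheobase, the trace relaxes toward the clamped equilibrium, \code{t_start}
#' resets to the end of the subthreshold epoch and first-spike conditions
#' apply at the next suprathreshold onset. A boundary falling inside a
#' refractory gap is handled at the end of the gap.
#'
#' @param cell an \code{"aglif_cell"}.
#' @param protocol an \code{"aglif_protocol"} (see [stimulus_protocol()]).
#' @param trace_step trace sampling step (ms); default 0.1.
#' @param coarse_ms coarse threshold-scan step (ms); default 0.05.
#' @return As [simulate_constant()]; the spike train additionally carries a
#'   \code{spike_I} vector giving the segment current of each spike.
#' @export
simulate_piecewise <- function(cell, protocol, trace_step = 0.1,
                               coarse_ms = 0.05) {
  stopifnot(inherits(cell, "aglif_cell"))
  if (!inherits(protocol, "aglif_protocol"))
    protocol <- stimulus_protocol(protocol$t_begin_ms, protocol$t_end_ms,
                                  protocol$I_pA)
  eng <- .aglif_engine(cell, protocol, coarse_ms = coarse_ms)
  train <- structure(list(I_stim = unique(protocol$I_pA),
                          spike_times = eng$spike_t,
                          spike_I = eng$spike_I,
                          blocked_at = eng$blocked_at,
                          never_fired = length(eng$spike_t) == 0L),
                     class = "aglif_spike_train")
  list(spikes = train, trace = .sample_trace(eng, cell$params, trace_step))
}

#' @export
print.aglif_spike_train <- function(x, ...) {
  cat("spike train:", length(x$spike_times), "spikes")
  if (!is.na(x$blocked_at)) cat(", blocked at", round(x$blocked_at, 2), "ms")
  cat("\n")
  if (length(x$spike_times))
    cat(" ", paste(round(x$spike_times, 2), collapse = ", "), "\n")
  invisible(x)
}
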