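# Elementary operations of the circuit model, plus a pure-R single-step
# integrator.  The compiled engine in src/engine.cpp implements the same
# dynamics for trial ensembles and populations; the functions here are the
# readable reference against which the engine is tested.

#' Sensory derivative of the concentration history
#'
#' The chemosensor input is a windowed derivative of the recent attractant
#' concentration: the mean of the newest \code{N} samples minus the mean of
#' the \code{M} samples preceding them.
#'
#' @param history numeric vector of concentration samples, oldest first.
#'   Must hold at least \code{N + M} samples; only the newest \code{N + M}
#'   are used.
#' @param N,M positive integer window lengths (in samples) for the rise and
#'   decay windows.
#' @return the perceived concentration change \code{d} (concentration units).
#' @export
sensor_derivative <- function(history, N, M) {
  if (length(history) == 0) stop("empty concentration history")
  if (N < 1 || M < 1) stop("N and M must be >= 1")
  L <- length(history)
  if (L < N + M) stop("history holds fewer than N + M samples")
  newest <- history[(L - N + 1):L]
  older <- history[(L - N - M + 1):(L - N)]
  mean(newest) - mean(older)
}

#' Idealized ON/OFF chemosensor outputs
#'
#' ASEL-like ON cell reports positive perceived concentration changes, the
#' ASER-like OFF cell reports (sign-flipped) non-positive ones; exactly one
#' of the two can be active at any instant.
#'
#' @param d perceived concentration change.
#' @return named numeric vector \code{c(V_ON, V_OFF)}.
#' @export
sensor_outputs <- function(d) {
  if (!is.finite(d)) stop("d must be finite")
  if (d > 0) c(V_ON = d, V_OFF = 0) else c(V_ON = 0, V_OFF = -d)
}

#' Synaptic transfer function
#'
#' Chemical synapses transmit a logistic function of presynaptic potential
#' plus bias, \eqn{\sigma(V + \theta) = 1 / (1 + e^{-(V+\theta)})}.
#'
#' @param x presynaptic membrane potential.
#' @param theta bias shifting the sensitive range.
#' @return synaptic output in (0, 1).
#' @export
synaptic_output <- function(x, theta = 0) {
  stats::plogis(x + theta)
}

#' Neck angular velocity from motor neuron outputs
#'
#' The neck muscles difference the summed dorsal and ventral SMB outputs,
#' scaled by the neuromuscular junction weight.
#'
#' @param smb named numeric vector of the four SMB synaptic outputs, with
#'   names \code{SMBDL, SMBDR, SMBVL, SMBVR}.
#' @param w_NMJ motor-to-muscle weight.
#' @return neck angular velocity (radians/s).
#' @export
neck_velocity <- function(smb, w_NMJ) {
  w_NMJ * ((smb[["SMBDL"]] + smb[["SMBDR"]]) - (smb[["SMBVL"]] + smb[["SMBVR"]]))
}

#' Initial circuit state
#'
#' All membrane potentials start at zero, the body at the origin with zero
#' heading, and the concentration history pre-filled with the initial
#' concentration so the perceived derivative is zero at t = 0.
#'
#' @param params a \code{circuit_params} object.
#' @param c0 initial concentration used to fill the sensory history buffer.
#' @param t starting simulation time in seconds (sets the pattern-generator
#'   phase, \code{sin(2*pi*t/T)}).
#' @return an object of class \code{circuit_state}.
#' @export
circuit_state <- function(params, c0 = 1, t = 0) {
  stopifnot(inherits(params, "circuit_params"))
  V <- stats::setNames(numeric(8), .cells)
  structure(list(
    conc_history = rep(c0, params[["N"]] + params[["M"]]),
    V = V, V_ON = 0, V_OFF = 0, t = t,
    mu = 0, phi = 0, x = 0, y = 0
  ), class = "circuit_state")
}

#' Advance the circuit by one integration step
#'
#' One explicit-Euler step of the full model: the new concentration sample is
#' appended to the sensory history, the windowed derivative and ON/OFF
#' outputs are computed, the eight membrane potentials are advanced, and the
#' neck velocity, heading and position are updated.  Ventral SMB cells
#' receive the pattern-generator drive \code{+sin(2*pi*t/T)}, dorsal cells
#' the antiphase signal.
#'
#' @param state a \code{circuit_state}.
#' @param params a \code{circuit_params}.
#' @param c_t concentration sample at the current time.
#' @param dt integration step (s); must be small against \code{tau}.
#' @param lesions a \code{lesion_set}.
#' @return the updated \code{circuit_state} (time advanced by \code{dt}).
#' @export
step_circuit <- function(state, params, c_t, dt = 0.01,
                         lesions = lesion_set()) {
  stopifnot(inherits(state, "circuit_state"), dt > 0)
  bad <- !vapply(state$V, is.finite, TRUE)
  if (any(bad)) stop("non-finite membrane potential in ", .cells[bad][1])
  N <- params[["N"]]; M <- params[["M"]]
  hist <- c(state$conc_history, c_t)
  hist <- hist[(length(hist) - N - M + 1):length(hist)]
  d <- sensor_derivative(hist, N, M)
  so <- sensor_outputs(d)
  V <- state$V
  sig <- synaptic_output(V, params[paste0("theta_", .cells)])
  g_aiy <- if (lesions$block_gap_AIY) 0 else params[["g_AIY"]]
  g_aiz <- if (lesions$block_gap_AIZ) 0 else params[["g_AIZ"]]
  pg <- sin(2 * pi * state$t / params[["T"]])
  p <- function(k) params[[k]]
  dV <- c(
    AIYL = -V[["AIYL"]] + p("w_ON_AIYL") * so[["V_ON"]] +
      p("w_OFF_AIYL") * so[["V_OFF"]] + g_aiy * (V[["AIYR"]] - V[["AIYL"]]),
    AIYR = -V[["AIYR"]] + p("w_ON_AIYR") * so[["V_ON"]] +
      p("w_OFF_AIYR") * so[["V_OFF"]] + g_aiy * (V[["AIYL"]] - V[["AIYR"]]),
    AIZL = -V[["AIZL"]] + p("w_AIYL_AIZL") * sig[["AIYL"]] +
      g_aiz * (V[["AIZR"]] - V[["AIZL"]]),
    AIZR = -V[["AIZR"]] + p("w_AIYR_AIZR") * sig[["AIYR"]] +
      g_aiz * (V[["AIZL"]] - V[["AIZR"]]),
    SMBDL = -V[["SMBDL"]] + p("w_AIZL_SMBDL") * sig[["AIZL"]] +
      p("w_SMBDL_SMBDL") * sig[["SMBDL"]] + p("w_PG") * (-pg),
    SMBDR = -V[["SMBDR"]] + p("w_AIZR_SMBDR") * sig[["AIZR"]] +
      p("w_SMBDR_SMBDR") * sig[["SMBDR"]] + p("w_PG") * (-pg),
    SMBVL = -V[["SMBVL"]] + p("w_AIZL_SMBVL") * sig[["AIZL"]] +
      p("w_SMBVL_SMBVL") * sig[["SMBVL"]] + p("w_PG") * pg,
    SMBVR = -V[["SMBVR"]] + p("w_AIZR_SMBVR") * sig[["AIZR"]] +
      p("w_SMBVR_SMBVR") * sig[["SMBVR"]] + p("w_PG") * pg
  )
  phi <- neck_velocity(sig[c("SMBDL", "SMBDR", "SMBVL", "SMBVR")], p("w_NMJ"))
  state$conc_history <- hist
  state$V <- V + dV * dt / params[["tau"]]
  state$V_ON <- so[["V_ON"]]; state$V_OFF <- so[["V_OFF"]]
  state$phi <- phi
  state$x <- state$x + params[["v"]] * cos(state$mu) * dt
  state$y <- state$y + params[["v"]] * sin(state$mu) * dt
  state$mu <- state$mu + phi * dt
  state$t <- state$t + dt
  state
}

#' @export
print.circuit_state <- function(x, ...) {
  cat(sprintf("Circuit state at t = %.3f s\n", x$t))
  cat(sprintf("  V_ON = %.4g, V_OFF = %.4g\n", x$V_ON, x$V_OFF))
  print(round(x$V, 4))
  cat(sprintf("  heading mu = %.3f rad, phi = %.3f rad/s, pos = (%.3f, %.3f) cm\n",
              x$mu, x$phi, x$x, x$y))
  invisible(x)
}

# Run the compiled open-loop engine for one circuit over a matrix of
# precomputed sensory drives.  von/voff: n_trials x n_steps.
open_loop_engine <- function(params, von, voff, v_init, t0, dt,
                             lesions = lesion_set(), record_v = FALSE) {
  cpp_open_loop(von, voff, pack_params(params), v_init, t0, dt,
                lesions$block_gap_AIY, lesions$block_gap_AIZ, record_v)
}

# Settle the circuit onto its unstimulated attractor (interneuron fixed
# point, SMB periodic orbit) by integrating with zero sensory drive for
# `cycles` locomotion cycles starting from V = 0 at t = 0.
warm_up <- function(params, dt = 0.01, cycles = 12,
                    lesions = lesion_set()) {
  nt <- ceiling(cycles * params[["T"]] / dt)
  z <- matrix(0, 1, nt)
  res <- open_loop_engine(params, z, z, rep(0, 8), 0, dt, lesions)
  list(V = as.numeric(res$v_final), t_end = nt * dt)
}
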