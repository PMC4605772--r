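# Open-loop stimulation protocols.  Both assays exploit the linearity of the
# sensory stage: the windowed derivative of a unit step (or unit ramp) is
# computed once with sensor_derivative() and scaled per trial, after which the
# compiled engine integrates the whole trial ensemble.

.rec_vars <- c("V_ON", "V_OFF", paste0("sigma_", .cells), "phi")

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Stimulus ensemble for the open-loop assays
#'
#' Describes the set of stimuli presented across trials: concentration steps
#' (\code{"step"}) of size \eqn{\Delta c}, or concentration-change clamps
#' (\code{"clamp"}) of rate \eqn{\dot c} held for the whole recording.
#' Stimulus values are drawn uniformly from \code{range} (the default
#' \code{c(-0.01, 0.01)} matches the range of concentration changes a
#' klinotaxis-competent model worm experiences), or from a model-generated
#' empirical distribution of perceived concentration changes.
#'
#' @param kind \code{"step"} or \code{"clamp"}.
#' @param n_trials number of stimulus presentations (>= 2); 2200 is the
#'   full analysis scale, 220 a fast mode.
#' @param distribution \code{"uniform"} or \code{"empirical"}.
#' @param range stimulus range for the uniform distribution.
#' @param empirical a \code{cdot_distribution} object (required when
#'   \code{distribution = "empirical"}); values are drawn by sampling a bin
#'   and then uniformly within it.
#' @param values explicit stimulus values, overriding random sampling.
#' @param seed RNG seed for reproducible draws.
#' @return an object of class \code{stimulus_ensemble}.
#' @export
stimulus_ensemble <- function(kind = c("step", "clamp"), n_trials = 2200,
                              distribution = c("uniform", "empirical"),
                              range = c(-0.01, 0.01), empirical = NULL,
                              values = NULL, seed = NULL) {
  kind <- match.arg(kind)
  distribution <- match.arg(distribution)
  if (is.null(values)) {
    if (n_trials < 2) stop("n_trials must be >= 2")
    values <- if (distribution == "uniform") {
      with_seed(seed, stats::runif(n_trials, range[1], range[2]))
    } else {
      if (is.null(empirical) || !inherits(empirical, "cdot_distribution"))
        stop("distribution = \"empirical\" needs a cdot_distribution object")
      with_seed(seed, sample_cdot(empirical, n_trials))
    }
  } else if (length(values) < 2) {
    stop("need at least 2 stimulus values")
  }
  structure(list(kind = kind, values = as.numeric(values),
                 distribution = distribution,
                 range = range(values)),
            class = "stimulus_ensemble")
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  cat(sprintf("Stimulus ensemble: %s, %d trials, %s in [%.4g, %.4g]\n",
              x$kind, length(x$values), x$distribution,
              x$range[1], x$range[2]))
  invisible(x)
}

# Windowed derivative response to a unit concentration step delivered at the
# first recorded sample (history pre-filled with the baseline).
unit_step_d <- function(N, M, n_steps) {
  conc <- c(rep(0, N + M), rep(1, n_steps))
  vapply(seq_len(n_steps),
         function(k) sensor_derivative(conc[seq_len(N + M + k)], N, M),
         0)
}

# Windowed derivative response to a unit ramp (1 concentration unit per
# second) starting at the first sample; settles to dt * (N + M) / 2.
unit_ramp_d <- function(N, M, n_steps, dt) {
  conc <- c(rep(0, N + M), (seq_len(n_steps) - 1) * dt)
  vapply(seq_len(n_steps),
         function(k) sensor_derivative(conc[seq_len(N + M + k)], N, M),
         0)
}

new_recording <- function(s, traces, dt, t0, assay, lesions, onset_phase,
                          extra = list()) {
  dimnames(traces) <- list(NULL, NULL, .rec_vars)
  structure(c(list(
    s = s, traces = traces, variables = .rec_vars, dt = dt,
    time = (seq_len(dim(traces)[2]) - 1) * dt,
    onset_time = t0, onset_phase = onset_phase,
    assay = assay, lesions = lesions
  ), extra), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Open-loop recording: %s assay, %d trials x %d steps (dt = %g s)\n",
              x$assay, dim(x$traces)[1], dim(x$traces)[2], x$dt))
  cat(sprintf("  stimulus in [%.4g, %.4g]; onset phase %.3f rad\n",
              min(x$s), max(x$s), x$onset_phase))
  print(x$lesions)
  invisible(x)
}

# Shared machinery: settle the circuit, advance to the requested
# pattern-generator phase, integrate the trial ensemble over precomputed
# sensory drives, and assemble the recording.
run_open_loop_assay <- function(params, ens, lesions, d_unit, n_rec, dt,
                                onset_phase, warm_cycles, assay,
                                skip_steps = 0) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(ens, "stimulus_ensemble"),
            inherits(lesions, "lesion_set"))
  w <- warm_up(params, dt = dt, cycles = warm_cycles, lesions = lesions)
  Tp <- params[["T"]]
  # recording starts at PG phase `onset_phase`, skip_steps after drive onset
  t_rec0 <- ceiling((w$t_end + skip_steps * dt) / Tp) * Tp +
    onset_phase * Tp / (2 * pi)
  t_on <- t_rec0 - skip_steps * dt
  extra <- round((t_on - w$t_end) / dt)
  V <- w$V
  if (extra > 0) {
    z <- matrix(0, 1, extra)
    V <- as.numeric(open_loop_engine(params, z, z, V, w$t_end, dt,
                                     lesions)$v_final)
  }
  s <- ens$values
  n_steps <- skip_steps + n_rec
  von <- outer(pmax(s, 0), d_unit[seq_len(n_steps)])
  voff <- outer(pmax(-s, 0), d_unit[seq_len(n_steps)])
  res <- open_loop_engine(params, von, voff, V, t_on, dt, lesions)
  keep <- (skip_steps + 1):n_steps
  traces <- array(0, c(length(s), n_rec, length(.rec_vars)))
  traces[, , 1] <- von[, keep, drop = FALSE]
  traces[, , 2] <- voff[, keep, drop = FALSE]
  traces[, , 3:10] <- res$sig[, keep, , drop = FALSE]
  traces[, , 11] <- res$phi[, keep, drop = FALSE]
  new_recording(s, traces, dt, t_rec0, assay, lesions, onset_phase,
                extra = list(phi_range =
                               sort(params[["w_NMJ"]] * c(-2, 2))))
}

#' Concentration step assay
#'
#' Each trial delivers an instantaneous concentration jump \eqn{\Delta c} at
#' a fixed pattern-generator phase after the circuit has settled under a
#' constant baseline, then records all observed variables in open loop
#' (sensor potentials, the eight synaptic outputs, and the neck velocity)
#' for \code{record_cycles} locomotion cycles.
#'
#' @param params a \code{circuit_params} object.
#' @param ens a \code{stimulus_ensemble} of kind \code{"step"}.
#' @param lesions a \code{lesion_set}.
#' @param record_cycles recording window in locomotion cycles (default 2).
#' @param onset_phase pattern-generator phase (radians, relative to the
#'   ventral drive \code{sin(2*pi*t/T)}) at which the step is delivered.
#' @param dt integration step in seconds.
#' @param warm_cycles settling run length before stimulation, in cycles.
#' @return a \code{recording}.
#' @export
concentration_step_assay <- function(params, ens, lesions = lesion_set(),
                                     record_cycles = 2, onset_phase = 0,
                                     dt = 0.01, warm_cycles = 12) {
  if (ens$kind != "step") stop("ensemble kind must be \"step\"")
  n_rec <- round(record_cycles * params[["T"]] / dt)
  d_unit <- unit_step_d(params[["N"]], params[["M"]], n_rec)
  run_open_loop_assay(params, ens, lesions, d_unit, n_rec, dt, onset_phase,
                      warm_cycles, "step")
}

#' Information clamp assay
#'
#' Each trial ramps the concentration linearly at rate \eqn{\dot c}
#' (concentration units per second) so that the chemosensors settle to a
#' constant output; the recording covers one full locomotion cycle after the
#' sensory transient (the \code{N + M} settling steps are excluded), which
#' isolates the role of the oscillatory pattern-generator input in gating
#' information through the motor neurons.
#'
#' @inheritParams concentration_step_assay
#' @param ens a \code{stimulus_ensemble} of kind \code{"clamp"}.
#' @param record_cycles recording window in locomotion cycles (default 1).
#' @return a \code{recording}.
#' @export
information_clamp_assay <- function(params, ens, lesions = lesion_set(),
                                    record_cycles = 1, onset_phase = 0,
                                    dt = 0.01, warm_cycles = 12) {
  if (ens$kind != "clamp") stop("ensemble kind must be \"clamp\"")
  n_rec <- round(record_cycles * params[["T"]] / dt)
  settle <- params[["N"]] + params[["M"]]
  d_unit <- unit_ramp_d(params[["N"]], params[["M"]], settle + n_rec, dt)
  run_open_loop_assay(params, ens, lesions, d_unit, n_rec, dt, onset_phase,
                      warm_cycles, "clamp", skip_steps = settle)
}

#' Phase sweep of the concentration step assay
#'
#' Repeats the step assay with the stimulus onset at evenly spaced
#' pattern-generator phases, to expose the phase-dependent gating of
#' stimulus information through the SMB motor neurons.
#'
#' @inheritParams concentration_step_assay
#' @param n_phases number of onset phases, evenly spaced over [0, 2*pi).
#' @param delay reference read-out delay (s) after the step, stored for
#'   downstream gating analysis.
#' @param record_cycles recording window per onset (default 1 cycle, enough
#'   for delay-averaged gating curves).
#' @return an object of class \code{phase_sweep}: a list of recordings with
#'   the phase grid and delay attached.
#' @export
phase_sweep <- function(params, ens, lesions = lesion_set(), n_phases = 16,
                        delay = 0.05, record_cycles = 1, dt = 0.01,
                        warm_cycles = 12) {
  stopifnot(n_phases >= 1, delay >= dt)
  phases <- seq(0, 2 * pi, length.out = n_phases + 1)[seq_len(n_phases)]
  recs <- lapply(phases, function(ph)
    concentration_step_assay(params, ens, lesions,
                             record_cycles = record_cycles,
                             onset_phase = ph, dt = dt,
                             warm_cycles = warm_cycles))
  structure(list(recordings = recs, phases = phases, delay = delay,
                 dt = dt), class = "phase_sweep")
}

#' Persist a recording as plain-text files
#'
#' Writes one CSV per observed variable (trials x time) together with the
#' stimulus vector and a JSON metadata file into a directory.
#'
#' @param rec a \code{recording}.
#' @param dir destination directory (created if needed).
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(stimulus = rec$s),
                   file.path(dir, "stimulus.csv"), row.names = FALSE)
  for (v in rec$variables)
    utils::write.csv(rec$traces[, , v],
                     file.path(dir, paste0("trace_", v, ".csv")),
                     row.names = FALSE)
  meta <- list(assay = rec$assay, dt = rec$dt, variables = rec$variables,
               onset_time = rec$onset_time, onset_phase = rec$onset_phase,
               lesions = unclass(rec$lesions))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a recording written by \code{write_recording}
#' @param dir directory containing the recording files.
#' @return a \code{recording}.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  s <- utils::read.csv(file.path(dir, "stimulus.csv"))$stimulus
  mats <- lapply(meta$variables, function(v)
    as.matrix(utils::read.csv(file.path(dir, paste0("trace_", v, ".csv")))))
  traces <- array(0, c(length(s), ncol(mats[[1]]), length(meta$variables)))
  for (i in seq_along(mats)) traces[, , i] <- mats[[i]]
  les <- do.call(lesion_set, as.list(meta$lesions))
  new_recording(s, traces, meta$dt, meta$onset_time, meta$assay, les,
                meta$onset_phase)
}
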