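# Chemical environments and closed-loop klinotaxis simulation.

#' Radial attractant gradient
#'
#' A radially symmetric concentration field with a single peak.  The conical
#' profile decays linearly with distance from the peak (constant gradient
#' slope \code{c_peak / length_scale} until the concentration reaches zero);
#' the gaussian profile decays as \eqn{\exp(-d^2 / 2\ell^2)}.  Defaults give
#' a constant slope of about 0.45 concentration units per cm, so that a worm
#' moving at 0.022 cm/s perceives concentration changes of at most about
#' 0.01 per second -- the range sampled by the open-loop assays.
#'
#' @param type \code{"conical"}, \code{"gaussian"} or \code{"flat"}.
#' @param peak peak position \code{c(x, y)} in cm.
#' @param c_peak peak concentration.
#' @param length_scale decay length in cm.
#' @return an object of class \code{gradient_field}.
#' @export
gradient_field <- function(type = c("conical", "gaussian", "flat"),
                           peak = c(0, 0), c_peak = 2, length_scale = 4.4) {
  type <- match.arg(type)
  stopifnot(c_peak > 0, length_scale > 0)
  structure(list(type = type, peak = peak, c_peak = c_peak,
                 length_scale = length_scale),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("%s gradient field: peak %.2f at (%.2f, %.2f), length scale %.2f cm\n",
              x$type, x$c_peak, x$peak[1], x$peak[2], x$length_scale))
  invisible(x)
}

#' Concentration at a point
#' @param field a \code{gradient_field}.
#' @param x,y coordinates in cm (vectorized).
#' @return concentration value(s), non-negative.
#' @export
field_concentration <- function(field, x, y) {
  d <- sqrt((x - field$peak[1])^2 + (y - field$peak[2])^2)
  switch(field$type,
         conical = pmax(0, field$c_peak * (1 - d / field$length_scale)),
         gaussian = field$c_peak * exp(-d^2 / (2 * field$length_scale^2)),
         flat = rep(field$c_peak, length(d)))
}

# Local magnitude of the concentration gradient (per cm) for the bearing map.
field_slope <- function(field, dist) {
  switch(field$type,
         conical = ifelse(dist < field$length_scale,
                          field$c_peak / field$length_scale, 0),
         gaussian = field$c_peak * dist / field$length_scale^2 *
           exp(-dist^2 / (2 * field$length_scale^2)),
         flat = rep(0, length(dist)))
}

field_code <- function(field) {
  match(field$type, c("flat", "conical", "gaussian")) - 1L
}

#' Closed-loop klinotaxis run
#'
#' Embeds the circuit in a gradient field: at every step the concentration is
#' sampled at the worm's position, the circuit advances one Euler step, and
#' the heading and position are updated.  A worm leaving the arena truncates
#' the run with a warning.
#'
#' @param params a \code{circuit_params}.
#' @param field a \code{gradient_field}.
#' @param duration run length in seconds.
#' @param seed RNG seed for the random start pose (ignored when
#'   \code{start} is given).
#' @param start optional list with elements \code{x}, \code{y}, \code{mu}
#'   fixing the start pose.
#' @param start_distance distance of the (random-bearing) start point from
#'   the peak, in cm.
#' @param dt integration step (s).
#' @param arena_radius truncation radius (cm).
#' @return an object of class \code{trajectory}: a data frame with columns
#'   \code{t, c, d, V_ON, V_OFF}, the eight membrane potentials
#'   \code{V_*}, the eight synaptic outputs \code{sigma_*}, and
#'   \code{phi, mu, x, y}.
#' @export
run_closed_loop <- function(params, field, duration = 500, seed = NULL,
                            start = NULL, start_distance = 2, dt = 0.01,
                            arena_radius = 10) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(field, "gradient_field"), duration > 2 * params[["T"]])
  if (is.null(start)) {
    start <- with_seed(seed, {
      ang <- stats::runif(1, 0, 2 * pi)
      list(x = field$peak[1] + start_distance * cos(ang),
           y = field$peak[2] + start_distance * sin(ang),
           mu = stats::runif(1, 0, 2 * pi))
    })
  }
  n_steps <- round(duration / dt)
  res <- cpp_closed_loop(matrix(pack_params(params), 1), field_code(field),
                         field$peak[1], field$peak[2], field$c_peak,
                         field$length_scale, start$x, start$y, start$mu,
                         n_steps, dt, arena_radius,
                         record_traj = TRUE, record_dc = TRUE)
  used <- res$steps_used[1]
  if (res$truncated[1])
    warning("worm left the arena; trajectory truncated at t = ",
            round(used * dt, 2), " s")
  k <- seq_len(used)
  out <- data.frame(
    t = (k - 1) * dt, c = res$c[1, k], d = res$d[1, k]
  )
  out$V_ON <- pmax(out$d, 0)
  out$V_OFF <- pmax(-out$d, 0)
  for (i in seq_along(.cells)) out[[paste0("V_", .cells[i])]] <- res$v[1, k, i]
  for (i in seq_along(.cells))
    out[[paste0("sigma_", .cells[i])]] <- res$sig[1, k, i]
  out$phi <- res$phi[1, k]
  out$mu <- res$mu[1, k]
  out$x <- res$x[1, k]
  out$y <- res$y[1, k]
  structure(out, class = c("trajectory", "data.frame"),
            field = field, dt = dt, dc_per_s = res$dc[1, k])
}

#' Chemotaxis index of a trajectory
#'
#' Behavioral score used as evolutionary fitness: one minus the ratio of the
#' time-averaged distance to the gradient peak over the initial distance,
#' clipped to [0, 1].  A worm parked at the peak scores 1; a worm that never
#' approaches scores 0.
#'
#' @param traj a \code{trajectory} (or any data frame with \code{x, y}).
#' @param field the \code{gradient_field} the run was performed in.
#' @return scalar in [0, 1].
#' @export
chemotaxis_index <- function(traj, field) {
  if (nrow(traj) == 0) stop("empty trajectory")
  d <- sqrt((traj$x - field$peak[1])^2 + (traj$y - field$peak[2])^2)
  if (d[1] == 0) stop("zero initial distance to the peak")
  max(0, min(1, 1 - mean(d) / d[1]))
}

#' Empirical distribution of perceived concentration changes
#'
#' Pools the per-step concentration change (rescaled to concentration units
#' per second) over repeated closed-loop runs with random start poses, and
#' returns a normalized histogram.  For a klinotaxis-competent circuit the
#' distribution peaks near zero with a bias toward positive changes.
#'
#' @param params a \code{circuit_params}.
#' @param field a \code{gradient_field}.
#' @param n_runs number of independent runs.
#' @param seed RNG seed controlling all start poses.
#' @param duration run length per run (s).
#' @param n_bins number of histogram bins.
#' @inheritParams run_closed_loop
#' @return an object of class \code{cdot_distribution}: list with bin
#'   \code{breaks}, \code{mids}, probability masses \code{p} (summing to 1)
#'   and the pooled sample size.
#' @export
empirical_cdot_distribution <- function(params, field, n_runs = 10,
                                        seed = NULL, duration = 500,
                                        start_distance = 2, dt = 0.01,
                                        n_bins = 50, arena_radius = 10) {
  stopifnot(n_runs >= 1)
  starts <- with_seed(seed, {
    ang <- stats::runif(n_runs, 0, 2 * pi)
    list(x = field$peak[1] + start_distance * cos(ang),
         y = field$peak[2] + start_distance * sin(ang),
         mu = stats::runif(n_runs, 0, 2 * pi))
  })
  n_steps <- round(duration / dt)
  P <- matrix(rep(pack_params(params), each = n_runs), n_runs)
  res <- cpp_closed_loop(P, field_code(field), field$peak[1], field$peak[2],
                         field$c_peak, field$length_scale,
                         starts$x, starts$y, starts$mu, n_steps, dt,
                         arena_radius, record_traj = FALSE, record_dc = TRUE)
  dc <- unlist(lapply(seq_len(n_runs), function(w)
    res$dc[w, seq_len(res$steps_used[w])]))
  rng <- range(dc)
  if (rng[1] == rng[2]) rng <- rng + c(-1, 1) * 1e-12  # point mass (flat field)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(dc, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, mids = h$mids,
                 p = h$counts / sum(h$counts), n = length(dc)),
            class = "cdot_distribution")
}

# Draw stimulus values from the empirical histogram: sample a bin by its
# mass, then uniformly within the bin.
sample_cdot <- function(dist, n) {
  bins <- sample.int(length(dist$p), n, replace = TRUE, prob = dist$p)
  stats::runif(n, dist$breaks[bins], dist$breaks[bins + 1])
}

#' @export
print.cdot_distribution <- function(x, ...) {
  cat(sprintf("Perceived concentration-change distribution: %d samples, %d bins\n",
              x$n, length(x$p)))
  cat(sprintf("  mode at %.4g per s; P(positive) = %.2f\n",
              x$mids[which.max(x$p)], sum(x$p[x$mids > 0])))
  invisible(x)
}

#' Map time-averaged neck information from stimulus to bearing
#'
#' In closed loop, the perceived concentration change is tied to the worm's
#' bearing relative to the gradient peak by
#' \eqn{\dot c = v \, |\nabla C| \cos(\beta)}: heading straight at the peak
#' (0 degrees) gives the largest positive change, moving perpendicular (90
#' degrees) gives none.  This re-parameterizes a time-averaged specific
#' information profile over \eqn{\dot c} as a function of bearing in
#' [0, 180] degrees (bearings outside the range fold by symmetry).
#'
#' @param specific_profile numeric vector of time-averaged specific
#'   information values per stimulus bin.
#' @param s_mids stimulus bin centres matching \code{specific_profile}.
#' @param field a \code{gradient_field}; the local slope is evaluated at
#'   \code{distance}.
#' @param distance distance from the peak (cm) at which the mapping is
#'   evaluated.
#' @param v forward speed (cm/s).
#' @param bearings bearing grid in degrees.
#' @return data frame with columns \code{bearing}, \code{cdot}, \code{info}.
#' @export
orientation_info_map <- function(specific_profile, s_mids, field,
                                 distance = 1, v = 0.022,
                                 bearings = seq(0, 180, by = 2)) {
  b <- abs(((bearings + 180) %% 360) - 180)  # fold to [0, 180]
  slope <- field_slope(field, distance)
  cdot <- v * slope * cos(b * pi / 180)
  idx <- vapply(cdot, function(cc) which.min(abs(s_mids - cc)), 1L)
  data.frame(bearing = b, cdot = cdot, info = specific_profile[idx])
}
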