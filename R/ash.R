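# Average-shifted-histogram (ASH) density estimation on a fixed grid.
#
# A sample is binned on n_shifts grids per dimension, each shifted left by
# k/n_shifts of one bin width (k = 0 .. n_shifts-1, indices clamped to the
# grid); the joint table is the average over all shift combinations.  Because
# the largest shift is less than one bin width, every point falls into one of
# two adjacent bins across shifts, so the average is stored as a two-bin
# soft assignment per point and joints of any dimension are accumulated from
# products of per-dimension assignments.

# Soft bin assignment of x on [lo, hi] with n_bins bins and n_shifts shifted
# grids.  Returns integer bins b1, b2 = b1 + 1 (clamped) and their averaged
# weights.
ash_assign <- function(x, lo, hi, n_bins, n_shifts) {
  n <- length(x)
  if (hi <= lo) {  # degenerate range: all mass in one bin
    return(list(b1 = rep(1L, n), b2 = rep(1L, n),
                w1 = rep(1, n), w2 = rep(0, n)))
  }
  w <- (hi - lo) / n_bins
  u <- (x - lo) / w
  b0 <- floor(u)
  k <- numeric(n)
  for (a in seq_len(n_shifts) - 1)  # count shifts pushing x into bin b0 + 1
    k <- k + (floor(u + a / n_shifts) > b0)
  b1 <- pmin(pmax(b0, 0), n_bins - 1) + 1L
  b2 <- pmin(b0 + 1, n_bins - 1) + 1L
  w2 <- k / n_shifts
  merged <- b1 == b2
  list(b1 = as.integer(b1), b2 = as.integer(b2),
       w1 = ifelse(merged, 1, 1 - w2), w2 = ifelse(merged, 0, w2))
}

# Combine per-dimension soft assignments into flat cell indices and weights
# (n x 2^d matrices) over a joint grid with the given dimension sizes.
combine_assign <- function(assigns, dims) {
  IDX <- cbind(assigns[[1]]$b1, assigns[[1]]$b2)
  W <- cbind(assigns[[1]]$w1, assigns[[1]]$w2)
  for (d in seq_along(assigns)[-1]) {
    a <- assigns[[d]]
    IDX <- cbind((IDX - 1L) * dims[d] + a$b1, (IDX - 1L) * dims[d] + a$b2)
    W <- cbind(W * a$w1, W * a$w2)
  }
  list(idx = IDX, w = W, n_cells = prod(dims))
}

# Dense probability array from combined assignments.
accumulate_joint <- function(comb, dims) {
  p <- numeric(comb$n_cells)
  idx <- as.vector(comb$idx)
  wt <- as.vector(comb$w)
  keep <- wt > 0
  agg <- rowsum(wt[keep], idx[keep])
  p[as.integer(rownames(agg))] <- agg[, 1]
  p <- p / nrow(comb$idx)
  # flat index has the first dimension slowest: permute into R array order
  arr <- array(p, rev(dims))
  aperm(arr, rev(seq_along(dims)))
}

#' Construct a joint stimulus-response distribution table
#'
#' Low-level constructor for an exact (analytic) joint distribution over
#' stimulus rows and response columns, in the same form the ASH estimator
#' produces; used for worked values and oracle checks.
#'
#' @param p numeric matrix of probabilities (rows: stimulus bins, columns:
#'   response bins) summing to 1.
#' @param s_mids,r_mids optional bin centres.
#' @return an object of class \code{joint_dist}.
#' @export
joint_dist <- function(p, s_mids = NULL, r_mids = NULL) {
  p <- as.matrix(p)
  if (any(p < 0)) stop("negative probabilities")
  if (abs(sum(p) - 1) > 1e-9) stop("joint distribution must sum to 1")
  structure(list(p = p, s_mids = s_mids, r_mids = r_mids,
                 meta = list(estimator = "exact")),
            class = "joint_dist")
}

#' @export
print.joint_dist <- function(x, ...) {
  cat(sprintf("Joint stimulus-response distribution: %d x %d bins (%s)\n",
              nrow(x$p), ncol(x$p), x$meta$estimator))
  invisible(x)
}

# Binning range of a recorded variable.  Synaptic outputs live on their
# physical range (0, 1) and the neck velocity on its anatomical range
# set by w_NMJ, so a cell saturating against its transfer function (or a
# motor neuron pinned by the pattern generator) occupies few bins and
# carries little information -- the semantics the saturation-gating
# analysis relies on.  Sensor potentials (and any variable with an
# explicit override in rec$ranges) are binned over their observed range.
var_range <- function(rec, variable) {
  if (!is.null(rec$ranges) && variable %in% names(rec$ranges))
    return(rec$ranges[[variable]])
  if (startsWith(variable, "sigma_")) return(c(0, 1))
  if (variable == "phi" && !is.null(rec$phi_range))
    return(rec$phi_range)
  range(rec$traces[, , variable])
}

stimulus_assign <- function(rec, s_bins, n_shifts) {
  s <- rec$s
  if (max(s) == min(s)) stop("constant stimulus: H(S) = 0, normalization undefined")
  ash_assign(s, min(s), max(s), s_bins, n_shifts)
}

response_assign <- function(rec, variables, time_index, n_bins, n_shifts,
                            ranges = NULL) {
  lapply(seq_along(variables), function(i) {
    rng <- if (is.null(ranges)) var_range(rec, variables[i]) else ranges[[i]]
    ash_assign(rec$traces[, time_index, variables[i]], rng[1], rng[2],
               n_bins, n_shifts)
  })
}

# Default per-dimension response bin count: joint responses are coarsened so
# the total number of response cells stays near 50^2 (e.g. 7 bins/dim for
# the four SMB cells).
default_response_bins <- function(n_dims, n_bins = 50) {
  if (n_dims == 1) n_bins else max(2L, floor(2500^(1 / n_dims)))
}

#' Estimate the joint stimulus-response distribution at one time index
#'
#' Bins the (stimulus, response) pairs of all trials at a single recorded
#' time step on a fixed grid, averaging over \code{n_shifts} shifted grids
#' per dimension (average shifted histogram).  Multiple response variables
#' are binned jointly with a reduced per-dimension resolution.
#'
#' @param rec a \code{recording}.
#' @param variable response variable name (or a vector of names for a joint
#'   response).
#' @param time_index time step (1-based) at which to take the response.
#' @param n_bins response bins per dimension (default 50 for a single
#'   variable, coarser for joint responses).
#' @param n_shifts number of ASH shifts per dimension (default 12).
#' @param s_bins stimulus bins (default 50 over the sampled range).
#' @return an object of class \code{joint_dist} with the stimulus on rows.
#' @export
estimate_joint <- function(rec, variable, time_index, n_bins = NULL,
                           n_shifts = 12, s_bins = 50) {
  stopifnot(inherits(rec, "recording"), n_shifts >= 1, s_bins >= 2)
  if (dim(rec$traces)[1] < 2) stop("need at least 2 trials")
  if (is.null(n_bins)) n_bins <- default_response_bins(length(variable))
  if (n_bins < 2) stop("n_bins must be >= 2")
  sa <- stimulus_assign(rec, s_bins, n_shifts)
  ra <- response_assign(rec, variable, time_index, n_bins, n_shifts)
  dims <- c(s_bins, rep(n_bins, length(variable)))
  comb <- combine_assign(c(list(sa), ra), dims)
  arr <- accumulate_joint(comb, dims)
  p <- if (length(variable) == 1) arr else
    array(arr, c(s_bins, prod(dim(arr)[-1])))  # flatten joint response
  s_edges <- seq(min(rec$s), max(rec$s), length.out = s_bins + 1)
  structure(list(p = p,
                 s_mids = (s_edges[-1] + s_edges[-length(s_edges)]) / 2,
                 r_mids = NULL,
                 meta = list(estimator = "ash", n_bins = n_bins,
                             n_shifts = n_shifts, variable = variable,
                             time_index = time_index)),
            class = "joint_dist")
}
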