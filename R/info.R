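# Information measures over joint distributions and recordings.  All
# quantities are in bits (log base 2); normalized values divide by the
# entropy H(S) of the sampled stimulus feature, so 0 means the stimulus is
# indistinguishable from the response and 1 means it is uniquely determined.

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information of a joint stimulus-response distribution
#'
#' \eqn{I(S;R) = \sum_{i,j} p(s_i, r_j) \log_2 \frac{p(s_i,r_j)}{p(s_i)p(r_j)}},
#' with the \eqn{0 \log 0 = 0} convention, plus the value normalized by the
#' stimulus entropy \eqn{H(S)}.
#'
#' @param joint a \code{joint_dist} (or plain probability matrix with
#'   stimulus on rows).
#' @return list with elements \code{bits}, \code{normalized} and \code{H_s}.
#' @export
mutual_information <- function(joint) {
  p <- if (inherits(joint, "joint_dist")) joint$p else as.matrix(joint)
  ps <- rowSums(p)
  pr <- colSums(p)
  nz <- p > 0
  denom <- outer(ps, pr)
  bits <- sum(p[nz] * log2(p[nz] / denom[nz]))
  H_s <- entropy_bits(ps)
  list(bits = bits, normalized = if (H_s > 0) bits / H_s else NaN, H_s = H_s)
}

# Specific information for every stimulus bin at once (NA where p(s) = 0).
specific_information_profile <- function(p) {
  ps <- rowSums(p)
  pr <- colSums(p)
  out <- rep(NA_real_, length(ps))
  for (i in which(ps > 0)) {
    j <- which(p[i, ] > 0)
    # sum_j p(r|s) [log 1/p(s) - log 1/p(s|r)] with p(s|r) = p(s,r)/p(r)
    out[i] <- sum(p[i, j] / ps[i] * log2(p[i, j] / (pr[j] * ps[i])))
  }
  out
}

#' Specific information about one stimulus value
#'
#' The expected reduction in surprise about a particular stimulus value
#' \eqn{s} given the response:
#' \eqn{I(S=s;R) = \sum_j p(r_j|s)\,[\log 1/p(s) - \log 1/p(s|r_j)]}.
#' Averaging over \eqn{p(s)} recovers the mutual information.
#'
#' @param joint a \code{joint_dist} or probability matrix (stimulus rows).
#' @param s_value stimulus value; the nearest stimulus bin is used (requires
#'   bin centres on the joint).  Alternatively give \code{s_index} directly.
#' @param s_index stimulus bin index.
#' @return specific information in bits.
#' @export
specific_information <- function(joint, s_value = NULL, s_index = NULL) {
  p <- if (inherits(joint, "joint_dist")) joint$p else as.matrix(joint)
  if (is.null(s_index)) {
    if (is.null(s_value)) stop("give s_value or s_index")
    mids <- if (inherits(joint, "joint_dist")) joint$s_mids else NULL
    if (is.null(mids)) stop("joint has no stimulus bin centres; use s_index")
    s_index <- which.min(abs(mids - s_value))
  }
  ps <- rowSums(p)
  if (ps[s_index] == 0) stop("p(s) = 0 for the requested stimulus bin")
  specific_information_profile(p)[s_index]
}

#' Conditional mutual information I(X; Y | Z) of a discrete joint
#'
#' @param p 3-dimensional probability array with dimensions ordered
#'   \code{[x, y, z]}.
#' @return conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(p) {
  stopifnot(length(dim(p)) == 3)
  d <- dim(p)
  pyz <- colSums(p)                              # (y, z)
  pxz <- colSums(aperm(p, c(2, 1, 3)))           # (x, z)
  pz <- colSums(pyz)                             # (z)
  # expand the conditionals back to full (x, y, z) arrays
  pxz_f <- aperm(array(pxz, c(d[1], d[3], d[2])), c(1, 3, 2))
  pyz_f <- aperm(array(pyz, c(d[2], d[3], d[1])), c(3, 1, 2))
  pz_f <- rep(pz, each = d[1] * d[2])
  nz <- p > 0
  sum(p[nz] * log2(p[nz] * pz_f[nz] / (pxz_f[nz] * pyz_f[nz])))
}

#' Transfer entropy between two recorded variables at one time index
#'
#' Lag-1 transfer entropy \eqn{T_{Y \to X} = I(X_t; Y_{t-1} | X_{t-1})}
#' estimated across the trial ensemble: the directed information the
#' previous state of the source provides about the next state of the target
#' beyond the target's own previous state.  The model being deterministic,
#' only the previous state of each process is conditioned on.
#'
#' @param rec a \code{recording}.
#' @param source,target variable names (source is Y, target is X).
#' @param time_index time step t (>= 2).
#' @param n_bins bins per dimension for the (X_t, Y_{t-1}, X_{t-1}) triple
#'   (default 20, keeping the cell count near 50^2 scale).
#' @param n_shifts ASH shifts per dimension.
#' @param ranges optional precomputed list with elements \code{target} and
#'   \code{source} giving the global bin ranges (used by profile loops).
#' @return transfer entropy in bits.
#' @export
transfer_entropy <- function(rec, source, target, time_index, n_bins = 20,
                             n_shifts = 12, ranges = NULL) {
  stopifnot(inherits(rec, "recording"), time_index >= 2)
  if (dim(rec$traces)[1] < 2) stop("need at least 2 trials")
  rx <- if (is.null(ranges)) var_range(rec, target) else ranges$target
  ry <- if (is.null(ranges)) var_range(rec, source) else ranges$source
  a_xt <- ash_assign(rec$traces[, time_index, target], rx[1], rx[2],
                     n_bins, n_shifts)
  a_yl <- ash_assign(rec$traces[, time_index - 1, source], ry[1], ry[2],
                     n_bins, n_shifts)
  a_xl <- ash_assign(rec$traces[, time_index - 1, target], rx[1], rx[2],
                     n_bins, n_shifts)
  dims <- rep(n_bins, 3)
  comb <- combine_assign(list(a_xt, a_yl, a_xl), dims)
  conditional_mutual_information(accumulate_joint(comb, dims))
}

new_info_profile <- function(time, bits, H_s, measure, variables,
                             source = NULL) {
  df <- data.frame(time = time, bits = bits,
                   normalized = if (H_s > 0) bits / H_s else NaN)
  structure(df, class = c("info_profile", "data.frame"),
            measure = measure, variables = variables, source = source,
            H_s = H_s)
}

#' @export
print.info_profile <- function(x, ...) {
  cat(sprintf("Time-resolved %s profile for %s%s: %d time points, H(S) = %.3f bits\n",
              attr(x, "measure"),
              paste(attr(x, "variables"), collapse = "+"),
              if (!is.null(attr(x, "source")))
                paste0(" (source ", attr(x, "source"), ")") else "",
              nrow(x), attr(x, "H_s")))
  cat(sprintf("  normalized range [%.3f, %.3f], time average %.3f\n",
              min(x$normalized), max(x$normalized), mean(x$normalized)))
  invisible(x)
}

#' Time-resolved information measures over a recording
#'
#' Applies mutual information, specific information, or transfer entropy at
#' every recorded time step (optionally strided), turning the trial ensemble
#' into a time-varying joint distribution at each step.
#'
#' @param rec a \code{recording}.
#' @param measure \code{"mi"}, \code{"specific"} or \code{"transfer"}.
#' @param variables response variable name(s); several names are binned as a
#'   joint response (e.g. a dorsal/ventral SMB pair).
#' @param source source variable for \code{measure = "transfer"}.
#' @param time_stride stride over time steps (1 = every step).
#' @param n_bins response bins per dimension; default 50 for single
#'   variables (coarser for joint responses), 20 for transfer entropy.
#' @param s_bins stimulus bins.
#' @param n_shifts ASH shifts per dimension.
#' @return for \code{"mi"} and \code{"transfer"}: an \code{info_profile}
#'   data frame with columns \code{time}, \code{bits}, \code{normalized};
#'   for \code{"specific"}: an \code{info_surface} with a time x stimulus
#'   matrix of bits.
#' @export
time_resolved <- function(rec, measure = c("mi", "specific", "transfer"),
                          variables, source = NULL, time_stride = 1,
                          n_bins = NULL, s_bins = 50, n_shifts = 12) {
  measure <- match.arg(measure)
  stopifnot(inherits(rec, "recording"))
  nt <- dim(rec$traces)[2]
  if (measure == "transfer") {
    if (is.null(source)) stop("transfer entropy needs a source variable")
    if (is.null(n_bins)) n_bins <- 20
    tidx <- seq(2, nt, by = time_stride)
    rngs <- list(target = var_range(rec, variables),
                 source = var_range(rec, source))
    bits <- vapply(tidx, function(t)
      transfer_entropy(rec, source, variables, t, n_bins, n_shifts, rngs), 0)
    sa <- stimulus_assign(rec, s_bins, n_shifts)
    ps <- numeric(s_bins)
    agg <- rowsum(c(sa$w1, sa$w2), c(sa$b1, sa$b2))
    ps[as.integer(rownames(agg))] <- agg[, 1]
    H_s <- entropy_bits(ps / length(sa$b1))
    return(new_info_profile(rec$time[tidx], bits, H_s, "transfer",
                            variables, source))
  }
  if (is.null(n_bins)) n_bins <- default_response_bins(length(variables))
  sa <- stimulus_assign(rec, s_bins, n_shifts)
  ranges <- lapply(variables, function(v) var_range(rec, v))
  dims <- c(s_bins, rep(n_bins, length(variables)))
  tidx <- seq(1, nt, by = time_stride)
  first <- TRUE
  H_s <- NA_real_
  if (measure == "mi") {
    bits <- vapply(tidx, function(t) {
      ra <- response_assign(rec, variables, t, n_bins, n_shifts, ranges)
      arr <- accumulate_joint(combine_assign(c(list(sa), ra), dims), dims)
      p <- array(arr, c(s_bins, prod(dims[-1])))
      if (first) { H_s <<- entropy_bits(rowSums(p)); first <<- FALSE }
      mutual_information(p)$bits
    }, 0)
    return(new_info_profile(rec$time[tidx], bits, H_s, "mi", variables))
  }
  # specific information surface
  mat <- matrix(NA_real_, length(tidx), s_bins)
  for (i in seq_along(tidx)) {
    ra <- response_assign(rec, variables, tidx[i], n_bins, n_shifts, ranges)
    arr <- accumulate_joint(combine_assign(c(list(sa), ra), dims), dims)
    p <- array(arr, c(s_bins, prod(dims[-1])))
    if (first) { H_s <- entropy_bits(rowSums(p)); first <- FALSE }
    mat[i, ] <- specific_information_profile(p)
  }
  s_edges <- seq(min(rec$s), max(rec$s), length.out = s_bins + 1)
  structure(list(time = rec$time[tidx],
                 s_mids = (s_edges[-1] + s_edges[-length(s_edges)]) / 2,
                 bits = mat, normalized = mat / H_s, H_s = H_s,
                 variables = variables),
            class = "info_surface")
}

#' @export
print.info_surface <- function(x, ...) {
  cat(sprintf("Specific-information surface for %s: %d time x %d stimulus bins\n",
              paste(x$variables, collapse = "+"), nrow(x$bits),
              ncol(x$bits)))
  cat(sprintf("  time-averaged specific information peaks at s = %.4g\n",
              x$s_mids[which.max(colMeans(x$bits))]))
  invisible(x)
}

#' Layer-by-layer information preservation under the information clamp
#'
#' Treats the circuit as an information channel and measures, at every time
#' step of a clamp recording, the normalized mutual information between the
#' stimulus and each layer's joint response: the ASE sensor pair, the AIY
#' pair, the AIZ pair, the SMB quadruple, and the neck.  The ASE layer
#' carries all the stimulus information by construction; downstream layers
#' show what each stage preserves.
#'
#' @param rec a clamp-assay \code{recording}.
#' @param time_stride stride over time steps.
#' @param s_bins,n_shifts estimator settings.
#' @return named list of \code{info_profile}s (ASE, AIY, AIZ, SMB, Neck).
#' @export
layer_preservation <- function(rec, time_stride = 1, s_bins = 50,
                               n_shifts = 12) {
  layers <- list(
    ASE = c("V_ON", "V_OFF"),
    AIY = c("sigma_AIYL", "sigma_AIYR"),
    AIZ = c("sigma_AIZL", "sigma_AIZR"),
    SMB = paste0("sigma_", c("SMBDL", "SMBDR", "SMBVL", "SMBVR")),
    Neck = "phi"
  )
  lapply(layers, function(vars)
    time_resolved(rec, "mi", vars, time_stride = time_stride,
                  s_bins = s_bins, n_shifts = n_shifts))
}

#' Export information profiles as a tidy table
#'
#' @param profiles named list of \code{info_profile}s.
#' @param path optional CSV destination; when given the table is written.
#' @return data frame with columns \code{time, variable, measure, bits,
#'   normalized} (invisibly when written).
#' @export
profiles_to_table <- function(profiles, path = NULL) {
  out <- do.call(rbind, lapply(names(profiles), function(nm) {
    pr <- profiles[[nm]]
    data.frame(time = pr$time, variable = nm,
               measure = attr(pr, "measure"), bits = pr$bits,
               normalized = pr$normalized)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
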