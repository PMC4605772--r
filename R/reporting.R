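# Derived summaries: information-architecture graph, left/right symmetry
# diagnostics, SMB gating curves, response timing, and ensemble statistics.

#' Left/right information symmetry index
#'
#' Ratio of the smaller to the larger time-averaged mutual information of
#' two profiles: values near 1 indicate an informationally symmetric pair
#' (both cells carry similar information, as in AIZ), values near 0 a
#' strongly asymmetric pair (one cell dominates, as in AIY).
#'
#' @param left,right \code{info_profile}s of equal length.
#' @return value in [0, 1]; defined as 1 when both averages are zero.
#' @export
symmetry_index <- function(left, right) {
  stopifnot(nrow(left) == nrow(right))
  a <- mean(left$bits)
  b <- mean(right$bits)
  if (a == 0 && b == 0) return(1)
  min(a, b) / max(a, b)
}

#' Phase-dependent information gating curves for the SMB motor neurons
#'
#' From a phase sweep of the concentration step assay, computes for each SMB
#' cell the normalized mutual information about the step size as a function
#' of the onset phase: once at a fixed delay after the step, and once
#' averaged over all delays spanning a locomotion cycle.  Saturating
#' transfer functions driven in antiphase make each cell pass stimulus
#' information at some phases and block it at others.
#'
#' @param sweep a \code{phase_sweep}.
#' @param delay read-out delay in seconds (default: the sweep's stored
#'   delay, nominally 0.05 s).
#' @param cells variables to analyse (default the four SMB outputs).
#' @param average_stride time stride used for the delay-averaged curve.
#' @param s_bins,n_bins,n_shifts estimator settings.
#' @return object of class \code{gating_curves}: list with the phase grid
#'   and two phases x cells matrices, \code{fixed_delay} and
#'   \code{delay_averaged}, of normalized mutual information.
#' @export
gating_curves <- function(sweep, delay = NULL,
                          cells = paste0("sigma_", c("SMBDL", "SMBDR",
                                                     "SMBVL", "SMBVR")),
                          average_stride = 5, s_bins = 50, n_bins = 50,
                          n_shifts = 12) {
  stopifnot(inherits(sweep, "phase_sweep"))
  if (is.null(delay)) delay <- sweep$delay
  k_delay <- round(delay / sweep$dt) + 1
  fixed <- matrix(0, length(sweep$phases), length(cells),
                  dimnames = list(NULL, cells))
  avg <- fixed
  for (i in seq_along(sweep$recordings)) {
    rec <- sweep$recordings[[i]]
    sa <- stimulus_assign(rec, s_bins, n_shifts)
    for (cl in cells) {
      rng <- var_range(rec, cl)
      one_mi <- function(t) {
        ra <- response_assign(rec, cl, t, n_bins, n_shifts, list(rng))
        p <- accumulate_joint(combine_assign(c(list(sa), ra),
                                             c(s_bins, n_bins)),
                              c(s_bins, n_bins))
        mutual_information(p)
      }
      m <- one_mi(k_delay)
      fixed[i, cl] <- m$normalized
      tgrid <- seq(1, dim(rec$traces)[2], by = average_stride)
      avg[i, cl] <- mean(vapply(tgrid, function(t) one_mi(t)$normalized, 0))
    }
  }
  structure(list(phases = sweep$phases, fixed_delay = fixed,
                 delay_averaged = avg, delay = delay),
            class = "gating_curves")
}

#' @export
print.gating_curves <- function(x, ...) {
  cat(sprintf("SMB gating curves over %d onset phases (delay %.3f s)\n",
              length(x$phases), x$delay))
  cat("  fixed-delay normalized MI range per cell:\n")
  rng <- apply(x$fixed_delay, 2, range)
  for (cl in colnames(rng))
    cat(sprintf("    %s: [%.3f, %.3f]\n", cl, rng[1, cl], rng[2, cl]))
  invisible(x)
}

#' Response timing metrics from a concentration step recording
#'
#' Detects, by threshold crossings of normalized mutual information, the
#' four landmark events of the step response: stimulus onset (a), onset of
#' the neck response (b), end of the sensor response (c), and end of the
#' neck response (d); returns the derived durations a-b (propagation delay),
#' a-c (sensor information duration), c-d (persistence after sensor offset)
#' and b-d (neck response duration).
#'
#' @param rec a step-assay \code{recording} spanning at least two cycles.
#' @param threshold normalized-MI crossing level (default 0.05).
#' @param time_stride stride for the underlying profiles.
#' @param s_bins,n_shifts estimator settings.
#' @return object of class \code{timing_metrics}: list of the four
#'   durations in seconds (\code{NA} when a crossing is absent) plus the
#'   event times.
#' @export
timing_metrics <- function(rec, threshold = 0.05, time_stride = 1,
                           s_bins = 50, n_shifts = 12) {
  stopifnot(inherits(rec, "recording"))
  sensor <- time_resolved(rec, "mi", c("V_ON", "V_OFF"),
                          time_stride = time_stride, s_bins = s_bins,
                          n_shifts = n_shifts)
  neck <- time_resolved(rec, "mi", "phi", time_stride = time_stride,
                        s_bins = s_bins, n_shifts = n_shifts)
  above <- function(pr) pr$time[pr$normalized >= threshold]
  t_sensor <- above(sensor)
  t_neck <- above(neck)
  a <- 0
  b <- if (length(t_neck)) t_neck[1] else NA_real_
  cc <- if (length(t_sensor)) t_sensor[length(t_sensor)] else NA_real_
  d <- if (length(t_neck)) t_neck[length(t_neck)] else NA_real_
  structure(list(propagation_delay = b - a,
                 sensor_duration = cc - a,
                 persistence = d - cc,
                 neck_duration = d - b,
                 events = c(a = a, b = b, c = cc, d = d),
                 threshold = threshold),
            class = "timing_metrics")
}

#' @export
print.timing_metrics <- function(x, ...) {
  cat(sprintf("Step-response timing (normalized-MI threshold %.2f):\n",
              x$threshold))
  cat(sprintf("  propagation delay (a-b): %.2f s\n", x$propagation_delay))
  cat(sprintf("  sensor information duration (a-c): %.2f s\n",
              x$sensor_duration))
  cat(sprintf("  persistence after sensor offset (c-d): %.2f s\n",
              x$persistence))
  cat(sprintf("  neck response duration (b-d): %.2f s\n", x$neck_duration))
  invisible(x)
}

# Directed edges of the wiring diagram, as recorded-variable pairs.
.edges <- rbind(
  data.frame(from = c("V_ON", "V_ON", "V_OFF", "V_OFF"),
             to = paste0("sigma_AIY", c("L", "R", "L", "R")),
             kind = "chemical", assay = "step"),
  data.frame(from = paste0("sigma_AIY", c("L", "R")),
             to = paste0("sigma_AIY", c("R", "L")),
             kind = "gap", assay = "step"),
  data.frame(from = paste0("sigma_AIY", c("L", "R")),
             to = paste0("sigma_AIZ", c("L", "R")),
             kind = "chemical", assay = "step"),
  data.frame(from = paste0("sigma_AIZ", c("L", "R")),
             to = paste0("sigma_AIZ", c("R", "L")),
             kind = "gap", assay = "step"),
  data.frame(from = paste0("sigma_AIZ", c("L", "L", "R", "R")),
             to = paste0("sigma_SMB", c("DL", "VL", "DR", "VR")),
             kind = "chemical", assay = "clamp"),
  data.frame(from = paste0("sigma_SMB", c("DL", "VL", "DR", "VR")),
             to = "phi", kind = "neuromuscular", assay = "clamp")
)

#' Information architecture of a circuit
#'
#' Static summary of the information flow: per node (sensor cells,
#' interneurons, motor neurons, neck) the time-averaged normalized mutual
#' information about the stimulus and the split of time-averaged specific
#' information between positive and negative concentration changes; per
#' directed connection of the wiring diagram the time-averaged transfer
#' entropy.  Sensor and interneuron quantities come from the concentration
#' step assay, motor-neuron and neck quantities from the information clamp
#' assay.
#'
#' @param rec_step a step-assay \code{recording}.
#' @param rec_clamp a clamp-assay \code{recording}.
#' @param time_stride stride for all time-resolved estimates.
#' @param s_bins,n_shifts,te_bins estimator settings.
#' @return object of class \code{info_architecture}: list with data frames
#'   \code{nodes} (node, mi, pos_split, neg_split, assay) and \code{edges}
#'   (from, to, kind, te, assay).
#' @export
build_architecture <- function(rec_step, rec_clamp, time_stride = 5,
                               s_bins = 50, n_shifts = 12, te_bins = 20) {
  stopifnot(inherits(rec_step, "recording"), rec_step$assay == "step",
            inherits(rec_clamp, "recording"), rec_clamp$assay == "clamp")
  node_vars <- c(V_ON = "step", V_OFF = "step",
                 sigma_AIYL = "step", sigma_AIYR = "step",
                 sigma_AIZL = "step", sigma_AIZR = "step",
                 sigma_SMBDL = "clamp", sigma_SMBDR = "clamp",
                 sigma_SMBVL = "clamp", sigma_SMBVR = "clamp",
                 phi = "clamp")
  for (v in names(node_vars)) {
    present <- v %in% rec_step$variables && v %in% rec_clamp$variables
    if (!present) stop("recording is missing variable ", v)
  }
  nodes <- do.call(rbind, lapply(names(node_vars), function(v) {
    rec <- if (node_vars[[v]] == "step") rec_step else rec_clamp
    prof <- time_resolved(rec, "mi", v, time_stride = time_stride,
                          s_bins = s_bins, n_shifts = n_shifts)
    surf <- time_resolved(rec, "specific", v, time_stride = time_stride,
                          s_bins = s_bins, n_shifts = n_shifts)
    avg <- colMeans(surf$bits)
    pos <- mean(avg[surf$s_mids > 0])
    neg <- mean(avg[surf$s_mids < 0])
    tot <- pos + neg
    data.frame(node = v, mi = mean(prof$normalized),
               pos_split = if (tot > 0) pos / tot else 0.5,
               neg_split = if (tot > 0) neg / tot else 0.5,
               assay = node_vars[[v]])
  }))
  edges <- .edges
  edges$te <- vapply(seq_len(nrow(edges)), function(i) {
    rec <- if (edges$assay[i] == "step") rec_step else rec_clamp
    prof <- time_resolved(rec, "transfer", edges$to[i],
                          source = edges$from[i], time_stride = time_stride,
                          n_bins = te_bins, s_bins = s_bins,
                          n_shifts = n_shifts)
    mean(prof$bits)
  }, 0)
  structure(list(nodes = nodes, edges = edges),
            class = "info_architecture")
}

#' @export
print.info_architecture <- function(x, ...) {
  cat("Information architecture\n  nodes (time-averaged normalized MI, +/- split):\n")
  for (i in seq_len(nrow(x$nodes)))
    cat(sprintf("    %-12s mi = %.3f  (+%.0f%% / -%.0f%%)  [%s assay]\n",
                x$nodes$node[i], x$nodes$mi[i],
                100 * x$nodes$pos_split[i], 100 * x$nodes$neg_split[i],
                x$nodes$assay[i]))
  cat("  edges (time-averaged transfer entropy, bits):\n")
  ord <- order(x$edges$te, decreasing = TRUE)
  for (i in ord)
    cat(sprintf("    %-12s -> %-12s %.4f  (%s)\n", x$edges$from[i],
                x$edges$to[i], x$edges$te[i], x$edges$kind[i]))
  invisible(x)
}

#' Serialize an information architecture as JSON
#' @param arch an \code{info_architecture}.
#' @param path destination file.
#' @export
write_architecture <- function(arch, path) {
  writeLines(jsonlite::toJSON(list(nodes = arch$nodes, edges = arch$edges),
                              digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' Per-circuit information summary used for ensemble comparisons
#'
#' Runs both assays on one circuit and condenses the analyses the ensemble
#' comparison needs: per-cell step-assay MI profiles, AIY/AIZ symmetry
#' indices, the transfer-entropy routes into each AIY and AIZ cell, the neck
#' clamp MI profile, and which AIY cell dominates.
#'
#' @param params a \code{circuit_params}.
#' @param n_trials stimulus presentations per assay.
#' @param time_stride stride for time-resolved estimates.
#' @param seed seed for the stimulus draws.
#' @param s_bins,n_shifts,te_bins estimator settings.
#' @param dt integration step (s).
#' @return object of class \code{circuit_info_summary}.
#' @export
architecture_summary <- function(params, n_trials = 2200, time_stride = 5,
                                 seed = 1, s_bins = 50, n_shifts = 12,
                                 te_bins = 20, dt = 0.01) {
  ens_step <- stimulus_ensemble("step", n_trials, seed = seed)
  ens_clamp <- stimulus_ensemble("clamp", n_trials, seed = seed + 1)
  rec_step <- concentration_step_assay(params, ens_step, dt = dt)
  rec_clamp <- information_clamp_assay(params, ens_clamp, dt = dt)
  prof <- lapply(stats::setNames(nm = c("sigma_AIYL", "sigma_AIYR",
                                        "sigma_AIZL", "sigma_AIZR")),
                 function(v) time_resolved(rec_step, "mi", v,
                                           time_stride = time_stride,
                                           s_bins = s_bins,
                                           n_shifts = n_shifts))
  neck <- time_resolved(rec_clamp, "mi", "phi", time_stride = time_stride,
                        s_bins = s_bins, n_shifts = n_shifts)
  dom_aiy <- if (mean(prof$sigma_AIYL$bits) >= mean(prof$sigma_AIYR$bits))
    "L" else "R"
  te_mean <- function(rec, from, to)
    mean(time_resolved(rec, "transfer", to, source = from,
                       time_stride = time_stride, n_bins = te_bins,
                       s_bins = s_bins, n_shifts = n_shifts)$bits)
  dom <- paste0("sigma_AIY", dom_aiy)
  oth <- paste0("sigma_AIY", setdiff(c("L", "R"), dom_aiy))
  aiz_dom <- paste0("sigma_AIZ", dom_aiy)           # downstream of dominant AIY
  aiz_oth <- paste0("sigma_AIZ", setdiff(c("L", "R"), dom_aiy))
  te <- c(
    ase_chem_dom = max(te_mean(rec_step, "V_ON", dom),
                       te_mean(rec_step, "V_OFF", dom)),
    aiy_gap_dom = te_mean(rec_step, oth, dom),
    aiz_chem_oth = te_mean(rec_step, oth, aiz_oth),
    aiz_gap_oth = te_mean(rec_step, aiz_dom, aiz_oth)
  )
  structure(list(profiles = prof, neck = neck, dominant_AIY = dom_aiy,
                 symmetry_AIY = symmetry_index(prof$sigma_AIYL,
                                               prof$sigma_AIYR),
                 symmetry_AIZ = symmetry_index(prof$sigma_AIZL,
                                               prof$sigma_AIZR),
                 te = te, rec_clamp_onset_phase = rec_clamp$onset_phase,
                 T = params[["T"]]),
            class = "circuit_info_summary")
}

#' Ensemble mean and dispersion of information profiles
#'
#' Aligns the per-circuit summaries by the dominant AIY cell (the cell with
#' the higher cumulative mutual information first, the AIZ cell downstream
#' of it first) and returns the ensemble mean and standard deviation of each
#' profile, plus the fraction of circuits showing AIY asymmetry together
#' with AIZ symmetry.
#'
#' @param summaries list of \code{circuit_info_summary} objects (>= 2).
#' @return object of class \code{ensemble_report}: list with
#'   \code{time}, matrices of mean and sd normalized MI for the aligned
#'   AIY/AIZ cells and the neck, and the per-circuit symmetry indices.
#' @export
ensemble_report <- function(summaries) {
  stopifnot(length(summaries) >= 2)
  aligned <- function(s, layer) {
    first <- paste0("sigma_", layer, s$dominant_AIY)
    second <- paste0("sigma_", layer,
                     setdiff(c("L", "R"), s$dominant_AIY))
    cbind(s$profiles[[first]]$normalized, s$profiles[[second]]$normalized)
  }
  stack <- function(f) {
    arrs <- lapply(summaries, f)
    array(unlist(arrs), c(dim(arrs[[1]]), length(arrs)))
  }
  aiy <- stack(function(s) aligned(s, "AIY"))
  aiz <- stack(function(s) aligned(s, "AIZ"))
  neck <- stack(function(s) cbind(s$neck$normalized))
  stats_of <- function(a) list(mean = apply(a, c(1, 2), mean),
                               sd = apply(a, c(1, 2), stats::sd))
  structure(list(
    time = summaries[[1]]$profiles[[1]]$time,
    AIY = stats_of(aiy), AIZ = stats_of(aiz), Neck = stats_of(neck),
    symmetry_AIY = vapply(summaries, `[[`, 0, "symmetry_AIY"),
    symmetry_AIZ = vapply(summaries, `[[`, 0, "symmetry_AIZ")
  ), class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  n <- length(x$symmetry_AIY)
  cat(sprintf("Ensemble report over %d circuits\n", n))
  cat(sprintf("  AIY symmetry index: mean %.3f;  AIZ: mean %.3f\n",
              mean(x$symmetry_AIY), mean(x$symmetry_AIZ)))
  cat(sprintf("  circuits with AIY asymmetry < AIZ symmetry: %d/%d\n",
              sum(x$symmetry_AIY < x$symmetry_AIZ), n))
  invisible(x)
}
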