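# Shared test fixtures, built in code.

# A deterministic, hand-specified dorsal/ventral-symmetric circuit used where
# a specific evolved circuit is not required.
toy_params <- function(...) {
  args <- list(
    w_ON_AIYL = 800, w_ON_AIYR = -400, w_OFF_AIYL = -600,
    w_OFF_AIYR = 300,
    w_AIYL_AIZL = 7, w_AIYR_AIZR = 5,
    w_AIZL_SMBDL = 6, w_AIZL_SMBVL = 6, w_AIZR_SMBDR = -5,
    w_AIZR_SMBVR = -5,
    w_SMBDL_SMBDL = 2, w_SMBVL_SMBVL = 2, w_SMBDR_SMBDR = 1,
    w_SMBVR_SMBVR = 1,
    g_AIY = 0.8, g_AIZ = 1.2,
    theta_AIYL = -1, theta_AIYR = 2, theta_AIZL = -2, theta_AIZR = -1.5,
    theta_SMBDL = -1, theta_SMBVL = -1, theta_SMBDR = 0.5,
    theta_SMBVR = 0.5,
    w_PG = 4, w_NMJ = 1, tau = 0.5, N = 12, M = 24
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(circuit_params, args)
}

# Brute-force average shifted histogram: average the n_shifts (per
# dimension) plain histograms on grids whose origin is shifted left by
# a/n_shifts of one bin width, indices clamped to the grid.
ash_oracle_2d <- function(s, r, s_rng, r_rng, ns, nr, n_shifts) {
  bin1 <- function(x, lo, hi, nb, shift) {
    w <- (hi - lo) / nb
    pmin(pmax(floor((x - lo) / w + shift), 0), nb - 1) + 1
  }
  p <- matrix(0, ns, nr)
  for (a in seq_len(n_shifts) - 1) {
    for (b in seq_len(n_shifts) - 1) {
      i <- bin1(s, s_rng[1], s_rng[2], ns, a / n_shifts)
      j <- bin1(r, r_rng[1], r_rng[2], nr, b / n_shifts)
      for (k in seq_along(s)) p[i[k], j[k]] <- p[i[k], j[k]] + 1
    }
  }
  p / (length(s) * n_shifts^2)
}

# Exhaustive-enumeration information measures on exact discrete joints.
mi_oracle <- function(p) {
  ps <- rowSums(p); pr <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) tot <- tot + p[i, j] * log2(p[i, j] / (ps[i] * pr[j]))
  tot
}

specific_oracle <- function(p, i) {
  ps <- rowSums(p); pr <- colSums(p)
  tot <- 0
  for (j in seq_len(ncol(p))) if (p[i, j] > 0)
    tot <- tot + p[i, j] / ps[i] *
      (log2(1 / ps[i]) - log2(pr[j] / p[i, j]))
  tot
}

cmi_oracle <- function(p) {
  d <- dim(p)
  pz <- apply(p, 3, sum); pxz <- apply(p, c(1, 3), sum)
  pyz <- apply(p, c(2, 3), sum)
  tot <- 0
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3]))
    if (p[x, y, z] > 0)
      tot <- tot + p[x, y, z] *
        log2(p[x, y, z] * pz[z] / (pxz[x, z] * pyz[y, z]))
  tot
}

# Build a recording object directly from a traces array (for estimator
# tests on hand-made data).
make_recording <- function(s, traces_list, dt = 0.01) {
  vars <- c("V_ON", "V_OFF", paste0("sigma_", c("AIYL", "AIYR", "AIZL",
            "AIZR", "SMBDL", "SMBDR", "SMBVL", "SMBVR")), "phi")
  nt <- ncol(traces_list[[1]])
  traces <- array(0, c(length(s), nt, length(vars)))
  for (nm in names(traces_list)) traces[, , match(nm, vars)] <- traces_list[[nm]]
  # hand-made data: bin every supplied variable over its observed range
  ranges <- lapply(traces_list, range)
  klinfo:::new_recording(s, traces, dt, 0, "step",
                         lesion_set(), 0,
                         extra = list(ranges = ranges))
}
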