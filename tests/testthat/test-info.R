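# Information measures: worked values, identities, and oracle equivalence.

test_that("mutual information matches hand-computed joints", {
  # constant response carries nothing
  expect_equal(mutual_information(matrix(c(0.5, 0.5), 2, 1))$bits, 0)
  # identity channel over K equiprobable bins
  for (K in c(2, 5, 8)) {
    m <- mutual_information(diag(K) / K)
    expect_equal(m$bits, log2(K), tolerance = 1e-12)
    expect_equal(m$normalized, 1, tolerance = 1e-12)
  }
  # binary symmetric-style joint, evaluated by the enumeration oracle
  p <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, 2)
  expect_equal(mutual_information(p)$bits, mi_oracle(p), tolerance = 1e-14)
  expect_equal(mutual_information(p)$bits, 0.2781, tolerance = 1e-3)
})

test_that("specific information averages to the mutual information", {
  set.seed(21)
  for (rep in 1:100) {
    p <- matrix(rexp(6 * 5), 6, 5)
    p <- p / sum(p)
    si <- klinfo:::specific_information_profile(p)
    ps <- rowSums(p)
    expect_equal(sum(ps * si), mutual_information(p)$bits,
                 tolerance = 1e-9)
  }
})

test_that("specific information matches enumeration and degenerate cases", {
  set.seed(22)
  p <- matrix(rexp(4 * 4), 4, 4)
  p <- p / sum(p)
  for (i in 1:4)
    expect_equal(specific_information(p, s_index = i),
                 specific_oracle(p, i), tolerance = 1e-12)
  # response independent of stimulus: zero for every stimulus value
  q <- outer(c(0.2, 0.3, 0.5), c(0.6, 0.4))
  for (i in 1:3)
    expect_equal(specific_information(q, s_index = i), 0,
                 tolerance = 1e-12)
  q2 <- rbind(q, 0)
  expect_error(specific_information(q2, s_index = 4), "p\\(s\\) = 0")
})

test_that("an OFF-type threshold response yields exactly one bit for undetected stimuli", {
  # uniform stimulus over +/-0.01, response = ReLU(s): every negative
  # stimulus maps to the single zero-response bin, so observing zero rules
  # out exactly half of the stimulus values
  K <- 50
  p <- matrix(0, K, K)
  mids <- seq(-0.01 + 0.01 / K, 0.01 - 0.01 / K, length.out = K)
  for (i in seq_len(K))
    p[i, if (mids[i] <= 0) 1 else i] <- 1 / K
  jd <- joint_dist(p, s_mids = mids)
  for (s in c(-0.009, -0.004, -0.0001))
    expect_equal(specific_information(jd, s_value = s), 1,
                 tolerance = 1e-12)
})

test_that("transfer entropy matches exhaustive enumeration on discrete systems", {
  # deterministic-ish three-variable system with <= 4 states per variable,
  # replicated into trials; unit-spaced values make each state its own bin
  set.seed(31)
  n <- 4000
  y_prev <- sample(0:3, n, replace = TRUE)
  x_prev <- sample(0:2, n, replace = TRUE)
  x_next <- (x_prev + y_prev) %% 4
  s <- runif(n)  # stimulus unused by TE itself
  rec <- make_recording(s, list(
    V_ON = cbind(y_prev, y_prev),
    sigma_AIYL = cbind(x_prev, x_next)))
  te <- transfer_entropy(rec, "V_ON", "sigma_AIYL", 2, n_bins = 4,
                         n_shifts = 1)
  # enumeration oracle over the empirical joint of (x_next, y_prev, x_prev)
  p3 <- array(0, c(4, 4, 4))
  for (k in seq_len(n))
    p3[x_next[k] + 1, y_prev[k] + 1, x_prev[k] + 1] <-
      p3[x_next[k] + 1, y_prev[k] + 1, x_prev[k] + 1] + 1 / n
  expect_equal(te, cmi_oracle(p3), tolerance = 1e-12)
  expect_equal(conditional_mutual_information(p3), cmi_oracle(p3),
               tolerance = 1e-12)
})

test_that("transfer entropy identities: copy channel and constant source", {
  # exact product ensemble: every (y_prev, x_prev) combination equally often
  n <- 160
  y_prev <- rep(0:3, times = 40)
  x_prev <- rep(rep(0:3, each = 4), 10)
  rec <- make_recording(runif(n), list(
    V_ON = cbind(y_prev, y_prev),
    sigma_AIYL = cbind(x_prev, y_prev)))  # X_t copies Y_{t-1}
  te <- transfer_entropy(rec, "V_ON", "sigma_AIYL", 2, n_bins = 4,
                         n_shifts = 1)
  expect_equal(te, 2, tolerance = 1e-12)  # H(Y_{t-1}) = log2(4)
  rec2 <- make_recording(runif(n), list(
    V_ON = matrix(1, n, 2),
    sigma_AIYL = cbind(x_prev, (x_prev + 1) %% 4)))
  expect_equal(transfer_entropy(rec2, "V_ON", "sigma_AIYL", 2,
                                n_bins = 4, n_shifts = 1), 0,
               tolerance = 1e-12)
})

test_that("time-resolved profiles behave for stimulated and unstimulated variables", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", 220, seed = 5)
  rec <- concentration_step_assay(p, ens, record_cycles = 1)
  prof_on <- time_resolved(rec, "mi", "V_ON", time_stride = 10)
  expect_true(all(prof_on$normalized <= 1 + 1e-6))
  expect_gt(max(prof_on$normalized), 0.4)  # sensors carry step information
  # sigma_SMBVR responds, phi responds, but a variable with no pathway from
  # the stimulus would be flat; emulate by analysing a lesioned-off variable:
  # the stimulus assigned to shuffled responses carries no information
  shuffled <- rec
  set.seed(1)
  shuffled$s <- sample(rec$s)
  prof_shuf <- time_resolved(shuffled, "mi", "sigma_AIYL", time_stride = 40)
  expect_lt(mean(prof_shuf$normalized), 0.08)
  # specific-information surface is consistent with its mutual information
  surf <- time_resolved(rec, "specific", "V_ON", time_stride = 40)
  prof40 <- time_resolved(rec, "mi", "V_ON", time_stride = 40)
  ps <- rowSums(estimate_joint(rec, "V_ON", 1)$p)
  for (i in seq_along(surf$time)) {
    si <- surf$bits[i, ]
    expect_equal(sum(ps * si), prof40$bits[i], tolerance = 1e-9)
  }
})

test_that("clamp assay shows layerwise information loss down the circuit", {
  p <- toy_params()
  ens <- stimulus_ensemble("clamp", 220, seed = 6)
  rec <- information_clamp_assay(p, ens)
  lp <- layer_preservation(rec, time_stride = 20)
  # the sensor pair determines the clamp rate: its profile sits at the
  # estimator's resolution ceiling for a noiseless invertible readout and
  # is constant over time (the clamp removes the transient)
  expect_true(all(lp$ASE$normalized > 0.8))
  expect_lt(diff(range(lp$ASE$normalized)), 1e-9)
  # open-loop chain: downstream layers cannot exceed the sensors
  tol <- 0.05
  expect_true(all(lp$AIY$normalized <= lp$ASE$normalized + tol))
  expect_true(all(lp$SMB$normalized <= lp$ASE$normalized + tol))
  expect_true(all(vapply(lp, function(pr) all(pr$normalized <= 1 + 1e-6),
                         TRUE)))
})
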