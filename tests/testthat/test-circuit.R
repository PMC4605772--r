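# Elementary circuit operations and single-step dynamics.

test_that("sensor derivative is the difference of window means", {
  expect_equal(sensor_derivative(rep(5, 10), 3, 4), 0)
  expect_equal(sensor_derivative(c(0, 0, 1, 1), 2, 2), 1)
  expect_gt(sensor_derivative(seq(0, 1, length.out = 20), 5, 5), 0)
  # hand case with unequal windows
  expect_equal(sensor_derivative(c(2, 4, 6, 9), 1, 3), 9 - mean(c(2, 4, 6)))
  expect_error(sensor_derivative(numeric(0), 1, 1), "empty")
  expect_error(sensor_derivative(1:4, 0, 2), ">= 1")
  expect_error(sensor_derivative(1:3, 2, 2), "fewer")
})

test_that("ON/OFF chemosensors are complementary", {
  expect_equal(sensor_outputs(0.004), c(V_ON = 0.004, V_OFF = 0))
  expect_equal(sensor_outputs(-0.004), c(V_ON = 0, V_OFF = 0.004))
  expect_equal(sensor_outputs(0), c(V_ON = 0, V_OFF = 0))
  expect_error(sensor_outputs(NaN), "finite")
  for (d in seq(-0.01, 0.01, length.out = 21)) {
    so <- sensor_outputs(d)
    expect_gte(so[["V_ON"]], 0)
    expect_gte(so[["V_OFF"]], 0)
    expect_identical(so[["V_ON"]] * so[["V_OFF"]], 0)
  }
})

test_that("synaptic transfer function is a shifted logistic", {
  expect_equal(synaptic_output(0, 0), 0.5)
  expect_equal(synaptic_output(2, -2), 0.5)
  expect_equal(synaptic_output(1e3), 1)
  expect_equal(synaptic_output(-1e3), 0)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(synaptic_output(x, 1)) > 0))
})

test_that("neck velocity differences dorsal and ventral output sums", {
  smb <- c(SMBDL = 0.3, SMBDR = 0.4, SMBVL = 0.3, SMBVR = 0.4)
  expect_equal(neck_velocity(smb, 1.7), 0)
  expect_equal(neck_velocity(c(SMBDL = 1, SMBDR = 1, SMBVL = 0,
                               SMBVR = 0), 1), 2)
  smb2 <- c(SMBDL = 0.8, SMBDR = 0.1, SMBVL = 0.5, SMBVR = 0.2)
  expect_equal(neck_velocity(smb2, -2), -neck_velocity(smb2, 2))
})

test_that("with zero weights every potential decays with time constant tau", {
  p <- toy_params(w_ON_AIYL = 0, w_ON_AIYR = 0, w_OFF_AIYL = 0,
                  w_OFF_AIYR = 0, w_AIYL_AIZL = 0, w_AIYR_AIZR = 0,
                  w_AIZL_SMBDL = 0, w_AIZL_SMBVL = 0, w_AIZR_SMBDR = 0,
                  w_AIZR_SMBVR = 0, w_SMBDL_SMBDL = 0, w_SMBVL_SMBVL = 0,
                  w_SMBDR_SMBDR = 0, w_SMBVR_SMBVR = 0, w_PG = 0,
                  g_AIY = 1e-9, g_AIZ = 1e-9)
  st <- circuit_state(p, c0 = 1)
  st$V[] <- 2
  dt <- 0.01
  for (k in 1:50) st <- step_circuit(st, p, 1, dt)
  # discrete-time leak: V(t) = 2 (1 - dt/tau)^k
  expect_equal(unname(st$V), rep(2 * (1 - dt / p[["tau"]])^50, 8),
               tolerance = 1e-6)
})

test_that("a strong gap junction equalizes the AIY potentials", {
  p <- toy_params(g_AIY = 50, w_ON_AIYL = 5, w_ON_AIYR = 5)
  st <- circuit_state(p, c0 = 1)
  st$V["AIYL"] <- 1
  st$V["AIYR"] <- -1
  gaps <- numeric(30)
  for (k in 1:30) {
    gaps[k] <- abs(st$V[["AIYL"]] - st$V[["AIYR"]])
    st <- step_circuit(st, p, 1, 0.001)
  }
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[30], gaps[1] / 10)
})

test_that("gap-junction coupling terms are exact negatives", {
  V <- c(AIYL = 0.37, AIYR = -1.22)
  g <- 0.8
  expect_identical(g * (V[["AIYR"]] - V[["AIYL"]]),
                   -(g * (V[["AIYL"]] - V[["AIYR"]])))
})

test_that("step_circuit rejects non-finite state naming the cell", {
  p <- toy_params()
  st <- circuit_state(p, c0 = 1)
  st$V["AIZR"] <- NaN
  expect_error(step_circuit(st, p, 1), "AIZR")
})

test_that("compiled engine reproduces the reference R stepper", {
  p <- toy_params()
  field <- gradient_field("conical")
  traj <- run_closed_loop(p, field, duration = 9,
                          start = list(x = 1.2, y = 0.4, mu = 0.3))
  st <- circuit_state(p, c0 = field_concentration(field, 1.2, 0.4))
  st$x <- 1.2; st$y <- 0.4; st$mu <- 0.3
  err <- 0
  for (k in 1:800) {
    cxy <- field_concentration(field, st$x, st$y)
    err <- max(err,
               max(abs(st$V - as.numeric(traj[k, paste0("V_", klinfo:::.cells)]))),
               abs(st$x - traj$x[k]), abs(st$y - traj$y[k]),
               abs(st$mu - traj$mu[k]))
    st <- step_circuit(st, p, cxy, 0.01)
  }
  expect_lt(err, 1e-10)
})

test_that("dorsal and ventral traces mirror at half-cycle shift without stimulus", {
  p <- toy_params()
  z <- matrix(0, 1, 4200)  # 10 cycles of zero drive
  res <- klinfo:::open_loop_engine(p, z, z, rep(0, 8), 0, 0.01)
  half <- 210  # T/2 in steps
  late <- 2101:3990  # post-transient window
  dl <- res$sig[1, late, 5]
  vl <- res$sig[1, late + half, 7]
  expect_equal(dl, vl, tolerance = 1e-6)
  dr <- res$sig[1, late, 6]
  vr <- res$sig[1, late + half, 8]
  expect_equal(dr, vr, tolerance = 1e-6)
})

test_that("trajectories stay bounded and converge at first order in dt", {
  p <- toy_params()
  field <- gradient_field("conical")
  run_dt <- function(dt) run_closed_loop(p, field, duration = 20,
                                         start = list(x = 1, y = 0, mu = 0),
                                         dt = dt)
  t1 <- run_dt(0.01)
  expect_true(all(is.finite(as.matrix(t1[-1]))))
  expect_lt(max(abs(t1[paste0("V_", klinfo:::.cells)])), 50)
  t2 <- run_dt(0.005)
  t4 <- run_dt(0.0025)
  # compare mu at matched times; halving dt should roughly halve the error
  idx1 <- seq(1, nrow(t1))
  e1 <- max(abs(t1$mu - t2$mu[seq(1, nrow(t2), by = 2)]))
  e2 <- max(abs(t2$mu[seq(1, nrow(t2), by = 2)] -
                  t4$mu[seq(1, nrow(t4), by = 4)]))
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.4)
})
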