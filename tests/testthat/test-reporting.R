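# Derived summaries: symmetry, gating, timing, architecture bookkeeping.

test_that("symmetry index contracts time-averaged MI ratios to [0, 1]", {
  mk <- function(bits) klinfo:::new_info_profile(seq_along(bits) * 0.01,
                                                 bits, 1, "mi", "x")
  a <- mk(c(0.2, 0.4, 0.6))
  expect_equal(symmetry_index(a, a), 1)
  z <- mk(c(0, 0, 0))
  expect_equal(symmetry_index(a, z), 0)
  expect_equal(symmetry_index(z, z), 1)
  b <- mk(c(0.1, 0.2, 0.3))
  expect_equal(symmetry_index(a, b), 0.5)
  expect_equal(symmetry_index(b, a), 0.5)
})

test_that("timing metrics detect onset ordering on a responsive circuit", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", 220, seed = 2)
  rec <- concentration_step_assay(p, ens)
  tm <- timing_metrics(rec, time_stride = 4)
  expect_s3_class(tm, "timing_metrics")
  expect_gt(tm$sensor_duration, 0)
  # the sensor window is set by N + M plus the estimator's detection limit
  expect_lt(abs(tm$sensor_duration -
                  (p[["N"]] + p[["M"]]) * rec$dt), 0.3)
  # causality: the neck cannot respond before the stimulus
  expect_gte(tm$propagation_delay, 0)
  expect_gte(tm$neck_duration, 0)
  # a circuit whose motor layer never crosses the threshold reports the
  # neck metrics as undefined, not zero
  dead <- toy_params(w_AIZL_SMBDL = 0, w_AIZL_SMBVL = 0,
                     w_AIZR_SMBDR = 0, w_AIZR_SMBVR = 0)
  rec0 <- concentration_step_assay(dead, ens)
  tm0 <- timing_metrics(rec0, time_stride = 8)
  expect_true(is.na(tm0$propagation_delay))
  expect_true(is.na(tm0$neck_duration))
})

test_that("architecture of a disconnected circuit carries no interneuron information", {
  p <- toy_params(w_ON_AIYL = 0, w_ON_AIYR = 0, w_OFF_AIYL = 0,
                  w_OFF_AIYR = 0, w_AIYL_AIZL = 0, w_AIYR_AIZR = 0,
                  w_AIZL_SMBDL = 0, w_AIZL_SMBVL = 0, w_AIZR_SMBDR = 0,
                  w_AIZR_SMBVR = 0)
  ens_s <- stimulus_ensemble("step", 220, seed = 3)
  ens_c <- stimulus_ensemble("clamp", 220, seed = 4)
  rec_s <- concentration_step_assay(p, ens_s, record_cycles = 1)
  rec_c <- information_clamp_assay(p, ens_c)
  arch <- build_architecture(rec_s, rec_c, time_stride = 15)
  non_sensor <- !arch$nodes$node %in% c("V_ON", "V_OFF")
  expect_true(all(arch$nodes$mi[non_sensor] < 0.02))
  # the sensors still respond during the N + M window
  expect_true(all(arch$nodes$mi[!non_sensor] >
                    max(arch$nodes$mi[non_sensor])))
  # an ON-type sensor reports mostly positive concentration changes
  expect_gt(arch$nodes$pos_split[arch$nodes$node == "V_ON"], 0.5)
  # bookkeeping: node value equals the time-averaged profile it came from
  prof <- time_resolved(rec_s, "mi", "sigma_AIYL", time_stride = 15)
  expect_equal(arch$nodes$mi[arch$nodes$node == "sigma_AIYL"],
               mean(prof$normalized), tolerance = 1e-12)
})

test_that("architecture is equivariant under left/right relabelling", {
  p <- toy_params()
  q <- circuit_params(
    w_ON_AIYL = p[["w_ON_AIYR"]], w_ON_AIYR = p[["w_ON_AIYL"]],
    w_OFF_AIYL = p[["w_OFF_AIYR"]], w_OFF_AIYR = p[["w_OFF_AIYL"]],
    w_AIYL_AIZL = p[["w_AIYR_AIZR"]], w_AIYR_AIZR = p[["w_AIYL_AIZL"]],
    w_AIZL_SMBDL = p[["w_AIZR_SMBDR"]], w_AIZL_SMBVL = p[["w_AIZR_SMBVR"]],
    w_AIZR_SMBDR = p[["w_AIZL_SMBDL"]], w_AIZR_SMBVR = p[["w_AIZL_SMBVL"]],
    w_SMBDL_SMBDL = p[["w_SMBDR_SMBDR"]],
    w_SMBVL_SMBVL = p[["w_SMBVR_SMBVR"]],
    w_SMBDR_SMBDR = p[["w_SMBDL_SMBDL"]],
    w_SMBVR_SMBVR = p[["w_SMBVL_SMBVL"]],
    g_AIY = p[["g_AIY"]], g_AIZ = p[["g_AIZ"]],
    theta_AIYL = p[["theta_AIYR"]], theta_AIYR = p[["theta_AIYL"]],
    theta_AIZL = p[["theta_AIZR"]], theta_AIZR = p[["theta_AIZL"]],
    theta_SMBDL = p[["theta_SMBDR"]], theta_SMBVL = p[["theta_SMBVR"]],
    theta_SMBDR = p[["theta_SMBDL"]], theta_SMBVR = p[["theta_SMBVL"]],
    w_PG = p[["w_PG"]], w_NMJ = p[["w_NMJ"]], tau = p[["tau"]],
    N = p[["N"]], M = p[["M"]])
  ens_s <- stimulus_ensemble("step", 220, seed = 5)
  rec_p <- concentration_step_assay(p, ens_s, record_cycles = 1)
  rec_q <- concentration_step_assay(q, ens_s, record_cycles = 1)
  for (pair in list(c("sigma_AIYL", "sigma_AIYR"),
                    c("sigma_AIZL", "sigma_AIZR"),
                    c("sigma_SMBDL", "sigma_SMBDR"))) {
    expect_equal(rec_p$traces[, , pair[1]], rec_q$traces[, , pair[2]],
                 tolerance = 1e-12)
  }
})

test_that("gating curves are flat when the pattern generator is silent", {
  p <- toy_params(w_PG = 0)
  ens <- stimulus_ensemble("step", 220, seed = 6)
  sw <- phase_sweep(p, ens, n_phases = 4)
  gc <- gating_curves(sw, average_stride = 20)
  expect_true(all(gc$fixed_delay >= -1e-9 &
                    gc$fixed_delay <= 1 + 1e-6))
  # without the oscillatory drive the onset phase is irrelevant
  for (cl in colnames(gc$fixed_delay))
    expect_lt(diff(range(gc$fixed_delay[, cl])), 0.02)
})

test_that("ensemble report of duplicated circuits has zero dispersion", {
  p <- toy_params()
  s1 <- architecture_summary(p, n_trials = 120, time_stride = 30, seed = 9)
  rep2 <- ensemble_report(list(s1, s1))
  expect_true(all(rep2$AIY$sd == 0))
  expect_true(all(rep2$Neck$sd == 0))
  expect_equal(rep2$symmetry_AIY[1], rep2$symmetry_AIY[2])
})
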