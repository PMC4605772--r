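# Open-loop stimulation protocols.

test_that("stimulus ensembles respect their constraints", {
  ens <- stimulus_ensemble("step", 100, seed = 1)
  expect_true(all(ens$values >= -0.01 & ens$values <= 0.01))
  expect_identical(stimulus_ensemble("step", 100, seed = 1)$values,
                   ens$values)
  expect_error(stimulus_ensemble("step", 1), "n_trials")
  expect_error(stimulus_ensemble("clamp", values = 0.005), "at least 2")
})

test_that("zero step reproduces baseline and equal steps are identical", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", values = c(0, 0.006, 0.006, -0.004))
  rec <- concentration_step_assay(p, ens, record_cycles = 1)
  # the zero-stimulus trial never sees a sensory drive: its motor traces
  # must equal the unstimulated attractor traces of any other circuit run
  expect_true(all(rec$traces[1, , "V_ON"] == 0))
  expect_true(all(rec$traces[1, , "V_OFF"] == 0))
  # determinism: identical stimuli give bit-identical traces
  expect_identical(rec$traces[2, , ], rec$traces[3, , ])
  # positive step drives only the ON sensor, negative only the OFF sensor
  expect_gt(max(rec$traces[2, , "V_ON"]), 0)
  expect_true(all(rec$traces[2, , "V_OFF"] == 0))
  expect_true(all(rec$traces[4, , "V_ON"] == 0))
  expect_gt(max(rec$traces[4, , "V_OFF"]), 0)
  # sensor pulse width is set by the N + M window (the step leaves the
  # averaging windows after N + M - 1 samples)
  on <- rec$traces[2, , "V_ON"]
  expect_equal(sum(on > 1e-12), p[["N"]] + p[["M"]] - 1)
})

test_that("the sensory stage is invariant to the baseline concentration", {
  h1 <- c(rep(1, 6), rep(1.004, 4))
  h2 <- c(rep(7, 6), rep(7.004, 4))
  expect_equal(sensor_derivative(h1, 4, 6), sensor_derivative(h2, 4, 6),
               tolerance = 1e-12)
})

test_that("clamp drives the sensors to the closed-form constant", {
  p <- toy_params()
  cdots <- c(0.004, 0.008, -0.006, 0.002)
  ens <- stimulus_ensemble("clamp", values = cdots)
  rec <- information_clamp_assay(p, ens)
  dt <- rec$dt
  expected <- cdots * dt * (p[["N"]] + p[["M"]]) / 2
  for (i in seq_along(cdots)) {
    trace <- if (cdots[i] > 0) rec$traces[i, , "V_ON"] else
      -rec$traces[i, , "V_OFF"]
    expect_equal(unname(trace), rep(expected[i], length(trace)),
                 tolerance = 1e-9)
  }
  # steady sensor output is proportional to the clamp rate
  expect_equal(max(rec$traces[2, , "V_ON"]) / max(rec$traces[1, , "V_ON"]),
               2, tolerance = 1e-6)
})

test_that("recorded traces are independent of any gradient field (open loop)", {
  # the assays never consult a field: stimulating twice yields identical
  # recordings regardless of environment settings used elsewhere
  p <- toy_params()
  ens <- stimulus_ensemble("step", values = c(-0.002, 0.005))
  r1 <- concentration_step_assay(p, ens, record_cycles = 1)
  r2 <- concentration_step_assay(p, ens, record_cycles = 1)
  expect_identical(r1$traces, r2$traces)
})

test_that("lesions act locally: gap block leaves the sensors untouched", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", values = c(-0.002, 0.005, 0.008))
  intact <- concentration_step_assay(p, ens, record_cycles = 1)
  cut <- concentration_step_assay(p, ens,
                                  lesions = lesion_set(block_gap_AIY = TRUE),
                                  record_cycles = 1)
  expect_identical(cut$traces[, , "V_ON"], intact$traces[, , "V_ON"])
  expect_identical(cut$traces[, , "V_OFF"], intact$traces[, , "V_OFF"])
  # but AIY itself changes
  expect_false(isTRUE(all.equal(cut$traces[, , "sigma_AIYL"],
                                intact$traces[, , "sigma_AIYL"])))
})

test_that("phase sweep reduces to a single assay and respects periodicity", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", values = c(-0.004, 0.004, 0.009))
  sw <- phase_sweep(p, ens, n_phases = 1, record_cycles = 1)
  single <- concentration_step_assay(p, ens, record_cycles = 1,
                                     onset_phase = 0)
  expect_equal(sw$recordings[[1]]$traces, single$traces, tolerance = 1e-12)
  # onset phase 2*pi is the same circuit state as phase 0
  wrap <- concentration_step_assay(p, ens, record_cycles = 1,
                                   onset_phase = 2 * pi)
  expect_equal(single$traces, wrap$traces, tolerance = 1e-8)
})

test_that("recordings round-trip through the plain-text format", {
  p <- toy_params()
  ens <- stimulus_ensemble("step", values = c(-0.003, 0.007))
  rec <- concentration_step_assay(p, ens, record_cycles = 1)
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$traces, rec$traces, tolerance = 1e-12)
  expect_equal(back$s, rec$s)
  expect_identical(back$assay, "step")
})
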