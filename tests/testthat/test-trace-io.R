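test_that("trace and protocol constructors enforce their invariants", {
  expect_error(trace(1, 1e-4, "mV", "membrane_voltage"), "length >= 2")
  expect_error(trace(c(-70, -70), -1, "mV", "membrane_voltage"), "positive")
  expect_error(trace(c(-70, -70), 1e-4, "pA", "membrane_voltage"),
    "inconsistent")
  expect_error(step_protocol(0, 0.5, 0.1, 10), "step_onset")
  expect_error(step_protocol(0, 0.1, 0.5, c(10, 10, 20)), "monotone")
  tr <- trace(rep(-70, 10), 1e-3, "mV", "membrane_voltage")
  expect_error(sweep_series(list(tr), step_protocol(0, 0.001, 0.1, c(1, 2))),
    "one sweep per")
  expect_error(sweep_series(list(), step_protocol(0, 0.001, 0.005, 1)),
    "non-empty")
  tr2 <- trace(rep(-70, 12), 1e-3, "mV", "membrane_voltage")
  expect_error(sweep_series(list(tr, tr2), step_protocol(0, 0.001, 0.005, c(1, 2))),
    "share dt and length")
})

test_that("recording files echo their header and round-trip losslessly", {
  # 11-sweep current-clamp family sampled at 250 kHz (dt = 4 us)
  sweeps <- lapply(1:11, function(i)
    trace(rnorm(250, -70), 4e-6, "mV", "membrane_voltage",
      lowpass_cutoff = 1e4))
  ser <- sweep_series(sweeps, step_protocol(0, 1e-4, 9e-4, seq(0, 100, 10)),
    metadata = list(access_resistance = 15, temperature = 33,
      blockers = c("ttx", "picrotoxin")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_recording(ser, path)
  back <- read_recording(path)
  expect_length(back$sweeps, 11)
  expect_identical(back$sweeps[[1]]$dt, 4e-6)
  for (i in 1:11) {
    expect_identical(back$sweeps[[i]]$samples, ser$sweeps[[i]]$samples)
  }
  expect_identical(back$protocol, ser$protocol)
  expect_identical(back$metadata$access_resistance, 15)
  expect_identical(back$metadata$blockers, c("ttx", "picrotoxin"))
  expect_false(back$metadata$junction_corrected)
})

test_that("round trip is lossless for random sweep series", {
  set.seed(11)
  for (rep in 1:5) {
    ns <- sample(2:6, 1)
    len <- sample(50:200, 1)
    role <- sample(c("membrane_voltage", "membrane_current"), 1)
    units <- if (role == "membrane_voltage") "mV" else "pA"
    sweeps <- lapply(seq_len(ns), function(i)
      trace(rnorm(len, -50, 30), dt = 10^runif(1, -6, -3), units, role))
    # force common dt
    dt <- sweeps[[1]]$dt
    sweeps <- lapply(sweeps, function(s) { s$dt <- dt; s })
    dur <- len * dt
    ser <- sweep_series(sweeps,
      step_protocol(runif(1, -80, 0), dur * 0.1, dur * 0.9,
        sort(runif(ns, -130, 100))),
      metadata = list(junction_corrected = FALSE,
        access_resistance = runif(1, 5, 40)))
    path <- withr::local_tempfile()
    write_recording(ser, path)
    back <- read_recording(path)
    expect_identical(back$protocol, ser$protocol)
    for (i in seq_len(ns)) {
      expect_identical(back$sweeps[[i]]$samples, ser$sweeps[[i]]$samples)
    }
  }
})

test_that("malformed files raise named format and structural errors", {
  path <- withr::local_tempfile()
  writeLines(c("patchkit-recording v1", "dt: 1e-4", "units: mV",
    "role: membrane_voltage", "---", "1\t2", "3\t4"), path)
  expect_error(read_recording(path), "protocol_holding")
  path2 <- withr::local_tempfile()
  writeLines(c("patchkit-recording v1", "dt: 1e-4", "units: mV",
    "role: membrane_voltage", "protocol_holding: 0",
    "protocol_step_onset: 0.0001", "protocol_step_offset: 0.0002",
    "protocol_step_levels: 1,2", "---", "1\t2", "3"), path2)
  expect_error(read_recording(path2), "unequal")
  expect_error(read_recording(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("junction correction shifts voltages once, and only voltages", {
  sweeps <- lapply(1:2, function(i) trace(rep(-60, 20), 1e-3, "mV",
    "membrane_voltage"))
  cc <- sweep_series(sweeps, step_protocol(0, 0.001, 0.019, c(10, 20)))
  cor <- apply_junction_correction(cc, jp = 10)
  expect_equal(cor$sweeps[[1]]$samples, rep(-70, 20))
  expect_equal(cor$protocol$step_levels, c(10, 20))  # pA levels untouched
  expect_true(cor$metadata$junction_corrected)
  expect_error(apply_junction_correction(cor), "twice")
  # voltage-clamp family: samples are currents, command levels shift
  vsw <- lapply(1:2, function(i) trace(rep(-120, 20), 1e-3, "pA",
    "membrane_current"))
  vc <- sweep_series(vsw, step_protocol(-60, 0.001, 0.019, c(-70, -80)))
  vcor <- apply_junction_correction(vc, jp = 10)
  expect_equal(vcor$sweeps[[1]]$samples, rep(-120, 20))
  expect_equal(vcor$protocol$step_levels, c(-80, -90))
  expect_equal(vcor$protocol$holding, -70)
  # jp = 0 is the identity on the data
  id <- apply_junction_correction(cc, jp = 0)
  expect_equal(id$sweeps[[1]]$samples, cc$sweeps[[1]]$samples)
})

test_that("QC applies the 25 MOhm access-resistance rule", {
  sweeps <- list(trace(rep(-70, 10), 1e-3, "mV", "membrane_voltage"))
  mk <- function(md) sweep_series(sweeps, step_protocol(0, 0.001, 0.009, 0), md)
  ok <- qc_recording(mk(list(access_resistance = 18)))
  expect_true(ok$pass)
  expect_length(ok$reasons[[1]], 0)
  bad <- qc_recording(mk(list(access_resistance = 30)))
  expect_false(bad$pass)
  expect_identical(bad$reasons[[1]], "access_resistance")
  missing <- qc_recording(mk(list()))
  expect_false(missing$pass)
  expect_identical(missing$reasons[[1]], "indeterminate")
  # the limit itself is inclusive ("below 25": 25 passes as boundary)
  expect_true(qc_recording(mk(list(access_resistance = 25)))$pass)
})
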