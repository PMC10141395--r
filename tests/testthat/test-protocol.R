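test_that("default protocol yields exactly 80,000 samples over 4.0 s", {
  p <- protocol_spec(test_voltage = -100)
  expect_identical(p$n_samples, 80000L)
  g <- gating_spec(open_rate = 50, close_rate = 150)
  r <- assemble_protocol_recording(p, g, g, seed = 1)
  expect_s3_class(r, "recording")
  expect_length(r$current, 80000)
  expect_equal(length(r$current) * r$dt, 4.0)
  expect_equal(r$voltage_mV, -100)
})

test_that("degenerate protocol with no holding phase is pure test phase", {
  p <- protocol_spec(test_voltage = 60, holding_duration = 0,
                     test_duration = 0.1)
  g <- gating_spec(open_rate = 50, close_rate = 150)
  r <- assemble_protocol_recording(p, g, g, seed = 1)
  expect_length(r$current, p$n_test)
})

test_that("replicate sweeps differ only in trace and replicate id", {
  p <- protocol_spec(test_voltage = 100, holding_duration = 0.05,
                     test_duration = 0.2)
  g <- gating_spec(open_rate = 80, close_rate = 160)
  recs <- lapply(1:5, function(s) {
    assemble_protocol_recording(p, g, g, replicate = s, seed = s)
  })
  traces <- lapply(recs, `[[`, "current")
  expect_length(unique(traces), 5)
  expect_identical(vapply(recs, `[[`, 0, "voltage_mV"), rep(100, 5))
  expect_identical(vapply(recs, `[[`, "", "condition"), rep("control", 5))
  expect_identical(vapply(recs, `[[`, 0L, "replicate"), 1:5)
})

test_that("protocol and gating validation fire", {
  p <- protocol_spec(test_voltage = -100)
  g_bad <- gating_spec(open_rate = 50, close_rate = 150, dt = 1e-4)
  g_ok <- gating_spec(open_rate = 50, close_rate = 150)
  expect_error(assemble_protocol_recording(p, g_ok, g_bad), "share `dt`")
  expect_error(protocol_spec(test_voltage = -42), "not in the protocol set")
  expect_silent(protocol_spec(test_voltage = -42, voltage_set = NULL))
})

test_that("analysis window honours count and time conventions", {
  p <- protocol_spec(test_voltage = -100)
  g <- gating_spec(open_rate = 50, close_rate = 150)
  r <- assemble_protocol_recording(p, g, g, seed = 3)
  # package defaults: start at first sample at/after 0.501 s, 59,600 samples
  w <- extract_analysis_window(r)
  expect_length(w, 59600)
  expect_identical(w, r$current[10021:69620])
  # identity window by time
  expect_identical(extract_analysis_window(r, t_start = 0, n_samples = NULL),
                   r$current)
  expect_error(extract_analysis_window(r, t_start = 2, n_samples = NULL,
                                       t_end = 1), "t_start")
  expect_error(extract_analysis_window(r, t_start = 5, n_samples = 10),
               "beyond")
  short <- recording(rnorm(100), dt = 1e-3)
  expect_error(extract_analysis_window(short, t_start = 0.501,
                                       n_samples = 59600), "beyond")
})

test_that("recording constructor rejects invalid inputs", {
  expect_error(recording(c(1, NA, 3), dt = 1e-4), "index 2")
  expect_error(recording(1, dt = 1e-4), "length >= 2")
  expect_error(recording(c(1, 2), dt = -1), "positive")
})
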