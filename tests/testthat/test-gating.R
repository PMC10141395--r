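# Dwell lengths of one state from a 0/1 (scaled) trace, interior dwells only.
extract_dwells <- function(states, state_value) {
  r <- rle(states)
  keep <- r$values == state_value
  keep[1] <- FALSE
  keep[length(keep)] <- FALSE
  r$lengths[keep]
}

test_that("gating spec validates kinetic parameters", {
  expect_error(gating_spec(open_rate = -1, close_rate = 100), ">= 0")
  expect_error(gating_spec(open_rate = 10, close_rate = 0), "> 0")
  expect_error(gating_spec(open_rate = 10, close_rate = 100, dt = 0), "dt")
  g <- gating_spec(open_rate = 10, close_rate = 100, dt = 1e-2)
  expect_warning(simulate_channel_current(g, 100, seed = 1), "dt \\* rate")
})

test_that("zero opening rate keeps the channel closed at baseline", {
  g <- gating_spec(open_rate = 0, close_rate = 100,
                   baseline_current = 3e-12, noise_sd = 0.1e-12)
  x <- simulate_channel_current(g, 20000, seed = 1)
  expect_lt(abs(mean(x) - 3e-12), 3 * g$noise_sd / sqrt(length(x)))
})

test_that("time-averaged open fraction matches the stationary probability", {
  g <- gating_spec(open_rate = 50, close_rate = 150, noise_sd = 0, dt = 5e-5)
  p_open <- vapply(1:20, function(s) {
    mean(simulate_channel_current(g, 80000, seed = s)) / g$unitary_current
  }, numeric(1))
  # stationary p = 50/200 = 0.25; binomial-style band on the 20-seed mean
  expect_lt(abs(mean(p_open) - 0.25), 0.02)
})

test_that("open dwell times are exponential with mean 1/close_rate", {
  g <- gating_spec(open_rate = 200, close_rate = 200, noise_sd = 0, dt = 5e-5)
  reject <- 0L
  pooled <- c()
  for (s in 1:20) {
    x <- simulate_channel_current(g, 80000, seed = s)
    states <- as.integer(x / g$unitary_current > 0.5)
    d <- extract_dwells(states, 1L) * g$dt
    # de-discretise: dwells are multiples of dt, add the sub-sample remainder
    d <- d + stats::runif(length(d), 0, g$dt)
    expect_gte(length(d), 200)
    pooled <- c(pooled, d)
    if (stats::ks.test(d, "pexp", rate = g$close_rate)$p.value <= 0.01) {
      reject <- reject + 1L
    }
  }
  expect_lte(reject, 1L)
  se <- stats::sd(pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - 1 / g$close_rate), 3 * se + g$dt)
})

test_that("multi-channel currents superpose independent channels", {
  g <- gating_spec(open_rate = 100, close_rate = 100, noise_sd = 0,
                   n_channels = 3L)
  x <- simulate_channel_current(g, 40000, seed = 2)
  counts <- round(x / g$unitary_current)
  expect_true(all(counts %in% 0:3))
  expect_lt(abs(mean(counts) - 1.5), 0.15)  # 3 channels x p = 0.5
})

test_that("the gating simulator is a pure function of its seed", {
  g <- gating_spec(open_rate = 50, close_rate = 150)
  expect_identical(simulate_channel_current(g, 5000, seed = 9),
                   simulate_channel_current(g, 5000, seed = 9))
})
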