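q_grid <- seq(-6, 6, 0.25)

test_that("constant H(q) collapses the spectrum to a single point", {
  h <- data.frame(q = q_grid, H = rep(0.7, length(q_grid)))
  s <- singularity_spectrum(h)
  expect_equal(s$alpha, rep(0.7, length(q_grid)))
  expect_equal(s$f_alpha, rep(1, length(q_grid)))
  ss <- spectrum_summary(s)
  expect_equal(ss$width_alpha, 0)
  expect_equal(ss$width_H, 0)
})

test_that("f(alpha) equals 1 at q = 0 by construction", {
  set.seed(3)
  for (rep in 1:5) {
    # random smooth decreasing H(q) curve
    h <- data.frame(q = q_grid,
                    H = 0.5 + runif(1, 0.2, 1) / (1 + exp(q_grid / 2)))
    s <- singularity_spectrum(h)
    expect_lt(abs(s$f_alpha[s$q == 0] - 1), 1e-12)
  }
})

test_that("analytic cascade spectrum has the hand-computed apex and width", {
  h <- data.frame(q = q_grid, H = cascade_hurst(q_grid, 0.75))
  s <- singularity_spectrum(h)
  # finite differences on a smooth curve: apex within the grid resolution
  expect_equal(s$alpha[s$q == 0], CASCADE75_ALPHA0, tolerance = 1e-2)
  expect_equal(cascade_alpha(0, 0.75), CASCADE75_ALPHA0, tolerance = 1e-6)
  expect_equal(cascade_alpha(-6, 0.75) - cascade_alpha(6, 0.75),
               CASCADE75_DALPHA_Q6, tolerance = 1e-6)
  ss <- spectrum_summary(s)
  # estimated width off the finite-difference alpha, against analytic width
  expect_equal(ss$width_alpha, CASCADE75_DALPHA_Q6, tolerance = 0.05)
  # alpha decreases with q for a genuine multifractal
  expect_true(all(diff(s$alpha) <= 1e-12))
})

test_that("the Legendre transform inverts back to H(q)", {
  h <- data.frame(q = q_grid, H = cascade_hurst(q_grid, 0.7))
  s <- singularity_spectrum(h)
  nz <- s$q != 0
  h_back <- (s$q[nz] * s$alpha[nz] - s$f_alpha[nz] + 1) / s$q[nz]
  expect_equal(h_back, h$H[nz], tolerance = 1e-9)
})

test_that("left endpoint sits at the largest q (smallest alpha)", {
  h <- data.frame(q = q_grid, H = cascade_hurst(q_grid, 0.75))
  s <- singularity_spectrum(h)
  ss <- spectrum_summary(s)
  expect_equal(ss$endpoint_alpha, s$alpha[s$q == 6])
  expect_equal(ss$endpoint_f, s$f_alpha[s$q == 6])
  expect_equal(ss$endpoint_alpha, min(s$alpha))
})

test_that("spectrum input contracts are enforced", {
  expect_error(singularity_spectrum(data.frame(q = 1:2, H = c(1, 2))),
               "at least 3")
  expect_error(singularity_spectrum(data.frame(a = 1:5)), "columns q and H")
})

test_that("spectrum of a fitted mfdfa object carries through", {
  fit <- mfdfa(simulate_fgn(0.5, 4096, seed = 4), n_scales = 15)
  s <- singularity_spectrum(fit)
  expect_s3_class(s, "singularity_spectrum")
  expect_equal(s$H, fit$hurst$H)
  expect_lt(abs(s$f_alpha[s$q == 0] - 1), 1e-12)
})
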