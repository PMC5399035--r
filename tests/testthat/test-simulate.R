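# Synthetic phase/signal generation.

test_that("coupled phases reproduce their target PLV structure", {
  tp <- matrix(c(1, 0.7, 0.3,
                 0.7, 1, 0.3,
                 0.3, 0.3, 1), 3, 3)
  ph <- simulate_coupled_phases(3, tp, 40000, rate = 1000, center_freq = 10,
                                ar_tau = 0.02, seed = 42)
  est <- c(plv_pair(ph[1, ], ph[2, ]),
           plv_pair(ph[1, ], ph[3, ]),
           plv_pair(ph[2, ], ph[3, ]))
  expect_true(all(abs(est - c(0.7, 0.3, 0.3)) < 0.05))
  # phases advance on average at the center frequency
  d <- diff(ph[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d) * 1000 / (2 * pi), 10, tolerance = 0.02)
  # values in the principal interval
  expect_true(all(ph > -pi & ph <= pi))
})

test_that("independent and perfectly locked targets hit their limits", {
  ph0 <- simulate_coupled_phases(3, diag(3), 30000, ar_tau = 0.02, seed = 1)
  expect_lt(plv_pair(ph0[1, ], ph0[2, ]), 0.05)
  tp1 <- matrix(c(1, 1, 1, 1), 2, 2)
  ph1 <- simulate_coupled_phases(2, tp1, 5000, ar_tau = 0.02, seed = 2)
  expect_equal(plv_pair(ph1[1, ], ph1[2, ]), 1.0, tolerance = 1e-12)
})

test_that("infeasible targets raise errors naming the problem", {
  # below the achievable floor
  tp <- matrix(c(1, 1e-6, 1e-6, 1), 2, 2)
  expect_error(simulate_coupled_phases(2, tp, 100, seed = 1),
               "achievable floor")
  # non-PSD: three mutually near-independent-but-anticorrelated demands
  floor_p <- exp(-2 * 4) * 1.01
  tp2 <- matrix(floor_p, 3, 3)
  diag(tp2) <- 1
  expect_error(simulate_coupled_phases(3, tp2, 100, seed = 1),
               "not positive semidefinite")
  expect_error(simulate_coupled_phases(2, matrix(c(1, 2, 2, 1), 2, 2), 100),
               "\\[0, 1\\]")
})

test_that("plv estimation error shrinks like 1/sqrt(n)", {
  tp <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  err <- vapply(c(2000, 32000), function(n) {
    e <- vapply(1:6, function(s) {
      ph <- simulate_coupled_phases(2, tp, n, ar_tau = 0.02, seed = s)
      abs(plv_pair(ph[1, ], ph[2, ]) - 0.4)
    }, numeric(1))
    mean(e)
  }, numeric(1))
  # 16x the samples: error should drop by roughly 4; accept > 2
  expect_gt(err[1] / err[2], 2)
})

test_that("phases_to_source_signals follows its stated contract", {
  # constant phase, unit amplitude, no noise -> constant 1
  ph <- matrix(0, 2, 100)
  expect_equal(phases_to_source_signals(ph), matrix(1, 2, 100))
  # linear phase -> pure cosine
  tt <- (0:999) / 1000
  ph10 <- matrix(2 * pi * 10 * tt, 1)
  expect_equal(phases_to_source_signals(ph10)[1, ], cos(2 * pi * 10 * tt),
               tolerance = 1e-12)
  # SNR: signal variance a^2/2, noise variance noise_sd^2
  set.seed(5)
  phr <- matrix(runif(2 * 20000, -pi, pi), 2)
  a <- 1
  x <- phases_to_source_signals(phr, amplitude = a, noise_sd = 2 * a, seed = 9)
  noise <- x - a * cos(phr)
  snr <- (a^2 / 2) / var(as.vector(noise))
  expect_equal(snr, 0.125, tolerance = 0.2 * 0.125)
  expect_error(phases_to_source_signals(ph, noise_sd = -1), "non-negative")
})

test_that("same seed gives bit-identical phases", {
  tp <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  a <- simulate_coupled_phases(2, tp, 1000, seed = 77)
  b <- simulate_coupled_phases(2, tp, 1000, seed = 77)
  expect_identical(a, b)
})
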