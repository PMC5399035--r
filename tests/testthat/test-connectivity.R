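# Hilbert phases, PLV, area averaging, analytic significance, RSN means.

test_that("hilbert phases track a tone and fixed phase offsets", {
  rate <- 1000
  tt <- (0:3999) / rate
  x <- rbind(cos(2 * pi * 10 * tt), sin(2 * pi * 10 * tt))
  ph <- hilbert_phase(x, rate = rate)
  # unwrapped slope = 2 pi f
  mid <- 500:3500
  d <- diff(ph$phase[1, mid])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d) * rate / (2 * pi), 10, tolerance = 0.02)
  # sin lags cos by pi/2
  dp <- ph$phase[1, mid] - ph$phase[2, mid]
  dp <- (dp + pi) %% (2 * pi) - pi
  expect_equal(mean(dp), pi / 2, tolerance = 0.02)
  expect_error(hilbert_phase(matrix(1, 1, 100), rate = rate), "constant")
})

test_that("narrowband-noise phase increments center on the carrier frequency", {
  tp <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  phs <- simulate_coupled_phases(2, tp, 8000, rate = 1000, center_freq = 10,
                                 ar_tau = 0.3, seed = 21)
  sig <- phases_to_source_signals(phs)
  ph <- hilbert_phase(sig, rate = 1000)
  d <- diff(ph$phase[1, ])
  d <- (d + pi) %% (2 * pi) - pi
  expect_equal(mean(d) * 1000 / (2 * pi), 10, tolerance = 0.5)
})

test_that("plv_pair obeys its exact limit cases and symmetries", {
  set.seed(31)
  a <- runif(500, -pi, pi)
  expect_equal(plv_pair(a, a), 1.0)
  expect_equal(plv_pair(c(0, 0), c(0, pi)), 0.0)
  b <- runif(500, -pi, pi)
  # symmetry and global-offset invariance
  expect_identical(plv_pair(a, b), plv_pair(b, a))
  expect_equal(plv_pair(a + 1.3, b + 1.3), plv_pair(a, b), tolerance = 1e-12)
  expect_error(plv_pair(a, b[-1]), "equal length")
})

test_that("independent uniform phases give the Rayleigh-resultant mean PLV", {
  # E |mean of T unit phasors| -> sqrt(pi / (4 T)) for uniform phases
  T_ <- 1000
  set.seed(32)
  vals <- replicate(100, plv_pair(runif(T_, -pi, pi), runif(T_, -pi, pi)))
  expect_lt(abs(mean(vals) - sqrt(pi / (4 * T_))), 0.1 * sqrt(pi / (4 * T_)))
})

test_that("area PLV equals the brute-force double summation", {
  set.seed(33)
  for (rep in 1:10) {
    n_a <- sample(2:3, 1); n_b <- sample(2:3, 1); T_ <- 200
    labels <- c(rep("A", n_a), rep("B", n_b))
    ph <- matrix(runif((n_a + n_b) * T_, -pi, pi), n_a + n_b, T_)
    conn <- plv_area(ph, labels)
    acc <- 0
    for (k in seq_len(n_a)) for (l in n_a + seq_len(n_b)) {
      acc <- acc + abs(mean(exp(-1i * (ph[k, ] - ph[l, ]))))
    }
    expect_equal(conn$plv["A", "B"], acc / (n_a * n_b), tolerance = 1e-12)
  }
})

test_that("area PLV collapses correctly for degenerate memberships", {
  set.seed(34)
  ph <- matrix(runif(2 * 300, -pi, pi), 2, 300)
  conn1 <- plv_area(ph, c("A", "B"))
  expect_equal(conn1$plv["A", "B"], plv_pair(ph[1, ], ph[2, ]), tolerance = 1e-12)
  # duplicating each source within its area leaves the estimate unchanged
  ph2 <- ph[c(1, 1, 2, 2), ]
  conn2 <- plv_area(ph2, c("A", "A", "B", "B"))
  expect_equal(conn2$plv["A", "B"], conn1$plv["A", "B"], tolerance = 1e-12)
  expect_error(plv_area(ph, c("A")), "one label per source")
})

test_that("analytic PLV significance matches a Monte-Carlo null", {
  # null: independent uniform phases; compare P(PLV >= x) to the formula
  T_ <- 64
  set.seed(35)
  null_plv <- replicate(10000, abs(mean(exp(1i * runif(T_, -pi, pi)))))
  for (x in c(0.15, 0.2, 0.25)) {
    p_mc <- mean(null_plv >= x)
    p_an <- plv_significance(x, T_)
    expect_lt(abs(p_an - p_mc), 0.2 * p_mc)
  }
  expect_equal(plv_significance(0, 100), 1, tolerance = 0.01)
  expect_lt(plv_significance(1, 100), 1e-10)
  # monotone decreasing in plv at fixed T
  grid <- plv_significance(seq(0, 0.9, by = 0.05), 250)
  expect_true(all(diff(grid) <= 1e-12))
})

test_that("RSN averages are within-network link means", {
  m <- matrix(0.2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 0.5
  m["c", "d"] <- m["d", "c"] <- 0.1
  diag(m) <- 1
  conn <- structure(list(plv = m, area_names = letters[1:4],
                         n_sources_per_area = rep(1L, 4),
                         n_epochs_used = 1L, T = 100L),
                    class = "area_connectivity")
  expect_equal(rsn_average(conn, c("a", "b")), 0.5)
  expect_equal(rsn_average(conn, c("a", "b", "c", "d")),
               mean(c(0.5, 0.2, 0.2, 0.2, 0.2, 0.1)))
  expect_error(rsn_average(conn, c("a", "zz")), "zz")
  expect_error(rsn_average(conn, "a"), "at least 2")
})
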