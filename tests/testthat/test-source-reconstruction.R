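# Source labeling, covariance, LCMV weights, leakage diagnostics.

test_that("sources are labeled by area and strays are masked out", {
  atlas <- toy_atlas()
  src <- place_area_sources(atlas, 2L, seed = 4)
  ss <- label_sources(src$positions, atlas)
  expect_true(all(ss$retained_mask))
  expect_equal(as.vector(table(ss$atlas_label)[atlas$area]),
               rep(2L, nrow(atlas)))
  # one far-away point is left unlabeled
  pos2 <- rbind(src$positions, c(0, 0, 0))
  ss2 <- label_sources(pos2, atlas)
  expect_false(ss2$retained_mask[nrow(pos2)])
  expect_equal(sum(ss2$retained_mask), nrow(src$positions))
  expect_error(label_sources(src$positions, atlas[0, ]), "empty")
})

test_that("epoch covariance averages per-epoch sample covariances", {
  sen <- cap_sensor_array(3)
  set.seed(6)
  x <- matrix(rnorm(3 * 400), 3)
  d <- array(0, c(4, 3, 400))
  for (e in 1:4) d[e, , ] <- x      # identical epochs
  ep <- sensor_epochs(d, 100, sen$positions, sen$orientations)
  C <- epoch_covariance(ep)
  expect_equal(C, cov(t(x)), tolerance = 1e-12)
  expect_true(isSymmetric(C))
  expect_gte(min(eigen(C, symmetric = TRUE)$values), -1e-12)
  # long uncorrelated unit-variance channels -> near identity
  n <- 20000
  ep2 <- sensor_epochs(array(rnorm(2 * n), c(1, 2, n)), 100,
                       cap_sensor_array(2)$positions,
                       cap_sensor_array(2)$orientations)
  expect_equal(epoch_covariance(ep2), diag(2), tolerance = 3 / sqrt(n) * 3)
  # zero data -> zero matrix
  ep0 <- sensor_epochs(array(0, c(2, 3, 50)), 100, sen$positions,
                       sen$orientations)
  expect_equal(epoch_covariance(ep0), matrix(0, 3, 3))
})

test_that("LCMV weights satisfy unit gain and reduce to the pseudo-inverse", {
  geom <- toy_geometry()
  # identity covariance (zero loading): w proportional to pinv rows
  bf <- lcmv_weights(geom$L, diag(nrow(geom$L)), regularization = 0)
  gains <- diag(bf$weights %*% geom$L)
  expect_equal(gains, rep(1, ncol(geom$L)), tolerance = 1e-6)
  w1_expected <- geom$L[, 1] / sum(geom$L[, 1]^2)
  # for identity C the single-source formula is l / (l'l) plus
  # cross-source terms; check the one-source case exactly
  bf1 <- lcmv_weights(geom$L[, 1, drop = FALSE], diag(nrow(geom$L)), 0)
  expect_equal(as.vector(bf1$weights), w1_expected, tolerance = 1e-10)
})

test_that("a single active source is recovered nearly perfectly", {
  geom <- toy_geometry()
  set.seed(9)
  tt <- (0:1999) / 250
  x <- cos(2 * pi * 9 * tt) * (1 + 0.3 * sin(2 * pi * 0.5 * tt))
  sens <- geom$L[, 3, drop = FALSE] %*% matrix(x, 1)
  C <- cov(t(sens)) + 1e-4 * mean(diag(cov(t(sens)))) * diag(nrow(sens))
  bf <- lcmv_weights(geom$L, C, regularization = 0.001)
  recon <- as.vector(bf$weights[3, , drop = FALSE] %*% sens)
  expect_gte(cor(recon, x), 0.99)
})

test_that("apply_weights is a linear per-epoch map with dimension checks", {
  geom <- toy_geometry()
  bf <- lcmv_weights(geom$L, diag(nrow(geom$L)), 0.01)
  zero <- array(0, c(2, nrow(geom$L), 100))
  sen <- cap_sensor_array(60)
  ep <- sensor_epochs(zero, 250, sen$positions, sen$orientations)
  out <- apply_weights(bf, ep)
  expect_equal(max(abs(out)), 0)
  expect_equal(dim(out), c(2, ncol(geom$L), 100))
  bad <- sensor_epochs(array(0, c(1, 3, 10)), 250,
                       cap_sensor_array(3)$positions,
                       cap_sensor_array(3)$orientations)
  expect_error(apply_weights(bf, bad), "disagree")
})

test_that("regularization inflates output variance monotonically", {
  geom <- toy_geometry()
  set.seed(10)
  x <- matrix(rnorm(8 * 3000), 8)
  sens <- geom$L %*% x + matrix(rnorm(60 * 3000, sd = 1e-6), 60)
  C <- cov(t(sens))
  # output variance of the s-th filter at increasing loading, all
  # evaluated against the *unloaded* covariance
  v <- vapply(c(0, 0.01, 0.05, 0.2), function(lam) {
    bf <- lcmv_weights(geom$L, C, lam)
    mean(diag(bf$weights %*% C %*% t(bf$weights)))
  }, numeric(1))
  expect_true(all(diff(v) >= -1e-12))
})

test_that("max-power orientation recovers the simulated dipole axis", {
  geom <- toy_geometry()
  Lfree <- sphere_leadfield(geom$src$positions, NULL,
                            geom$sen$positions, geom$sen$orientations)
  set.seed(12)
  x <- matrix(rnorm(8 * 4000), 8)
  sens <- geom$L %*% x
  sens <- sens + matrix(rnorm(length(sens), sd = 0.01 * sd(sens)), nrow(sens))
  C <- cov(t(sens))
  coll <- max_power_orientation(Lfree, C, 0.01)
  cosines <- abs(rowSums(coll$orientations * geom$src$orientations))
  expect_gte(min(cosines), 0.9)
})

test_that("weight correlations are bounded and detect identical filters", {
  geom <- toy_geometry()
  bf <- lcmv_weights(geom$L, diag(nrow(geom$L)), 0.01)
  wc <- weight_correlation_matrix(bf, geom$src$labels)
  expect_true(all(wc >= -1 & wc <= 1))
  expect_true(isSymmetric(wc))
  # duplicate-weight filter: within-pair correlation exactly 1
  bf2 <- bf
  bf2$weights[2, ] <- bf2$weights[1, ]
  wc2 <- stats::cor(t(bf2$weights))
  expect_equal(wc2[1, 2], 1)
  bf3 <- bf
  bf3$weights[1, ] <- 0
  expect_error(weight_correlation_matrix(bf3, geom$src$labels), "zero-norm")
})
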