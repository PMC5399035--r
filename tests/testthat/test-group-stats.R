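# ANCOVA, permutation machinery, FDR, Tukey contrasts, correlations.

mk_design <- function(n_per = 8, seed = 1) {
  set.seed(seed)
  make_design(group = rep(c("HC", "SCD", "MCI"), each = n_per),
              age = round(rnorm(3 * n_per, 71, 4), 1))
}

test_that("ancova_f matches the closed-form least-squares oracle", {
  d <- make_design(group = rep(c("HC", "SCD", "MCI"), each = 4),
                   age = c(70, 72, 68, 71, 74, 69, 73, 70, 75, 72, 71, 74))
  set.seed(41)
  y <- rnorm(12) + c(rep(0, 4), rep(0.5, 4), rep(1, 4)) + 0.05 * d$age
  # oracle: explicit normal-equations fits of the two nested models
  X0 <- cbind(1, d$age)
  X1 <- cbind(X0, d$group == "SCD", d$group == "MCI")
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  f_oracle <- ((rss(X0) - rss(X1)) / 2) / (rss(X1) / (12 - 4))
  expect_equal(ancova_f(y, d), f_oracle, tolerance = 1e-10)
  # and against anova() on lm as a second, independent route
  f_lm <- anova(lm(y ~ d$age), lm(y ~ d$age + d$group))$F[2]
  expect_equal(ancova_f(y, d), f_lm, tolerance = 1e-10)
})

test_that("ancova_f handles degenerate inputs and relabeling invariance", {
  d <- mk_design(6, seed = 2)
  expect_equal(ancova_f(rep(1, nrow(d)), d), 0)
  set.seed(42)
  y <- rnorm(nrow(d))
  # permuting whole subjects (value, age, group together) leaves F unchanged
  perm <- sample(nrow(d))
  d2 <- make_design(group = d$group[perm], age = d$age[perm])
  expect_equal(ancova_f(y[perm], d2), ancova_f(y, d), tolerance = 1e-10)
  dd <- d
  dd$age <- as.numeric(dd$group)   # age perfectly confounded with group
  expect_error(ancova_f(y, dd), "rank-deficient")
})

test_that("permutation p-values are valid under the null and hit the floor", {
  d <- mk_design(10, seed = 3)
  set.seed(43)
  Y <- matrix(rnorm(nrow(d) * 120), nrow(d))
  pa <- permutation_ancova(Y, d, n_perm = 200, seed = 7)
  expect_true(all(pa$p >= 1 / 201 & pa$p <= 1))
  # validity: P(p <= alpha) <= alpha + binomial slack on a grid
  for (alpha in c(0.05, 0.1, 0.25)) {
    emp <- mean(pa$p <= alpha)
    expect_lte(emp, alpha + 3 * sqrt(alpha * (1 - alpha) / 120))
  }
  # massive effect -> floor
  y_big <- c(rnorm(10), rnorm(10) + 50, rnorm(10) - 50)
  pb <- permutation_ancova(y_big, d, n_perm = 300, seed = 8)
  expect_equal(pb$p, 1 / 301)
  # determinism
  pa2 <- permutation_ancova(Y, d, n_perm = 200, seed = 7)
  expect_identical(pa$p, pa2$p)
  expect_error(permutation_ancova(Y, d, n_perm = 50), "at least 100")
})

test_that("fdr_bh agrees with direct enumeration of the step-up rule", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), Q = 0.05)
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_bh(rep(1, 10))$rejected, rep(FALSE, 10))
  expect_length(fdr_bh(numeric(0))$rejected, 0)
  set.seed(44)
  for (rep in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    got <- fdr_bh(p, 0.05)$rejected
    # direct enumeration
    m <- length(p)
    o <- order(p)
    k <- suppressWarnings(max(which(p[o] <= seq_len(m) * 0.05 / m)))
    want <- rep(FALSE, m)
    if (is.finite(k)) want[o[seq_len(k)]] <- TRUE
    expect_identical(got, want)
  }
})

test_that("Tukey contrasts find the shifted group with the right sign", {
  d <- mk_design(10, seed = 5)
  set.seed(45)
  y <- rnorm(nrow(d), sd = 0.5)
  y[d$group == "MCI"] <- y[d$group == "MCI"] + 4
  pw <- tukey_pairwise_permuted(matrix(y, ncol = 1), d, n_perm = 300, seed = 9)
  expect_setequal(pw$pair, c("HC-SCD", "HC-MCI", "SCD-MCI"))
  p_hc_mci <- pw$p_corrected[pw$pair == "HC-MCI"]
  p_scd_mci <- pw$p_corrected[pw$pair == "SCD-MCI"]
  p_hc_scd <- pw$p_corrected[pw$pair == "HC-SCD"]
  expect_equal(p_hc_mci, 1 / 301)
  expect_equal(p_scd_mci, 1 / 301)
  expect_gt(p_hc_scd, 0.05)
  expect_gt(pw$difference[pw$pair == "HC-MCI"], 0)
  expect_gt(pw$difference[pw$pair == "SCD-MCI"], 0)
})

test_that("null Tukey contrasts are rarely significant", {
  set.seed(46)
  hits <- vapply(1:15, function(s) {
    d <- mk_design(8, seed = 100 + s)
    y <- rnorm(nrow(d))
    pw <- tukey_pairwise_permuted(matrix(y, ncol = 1), d, n_perm = 150,
                                  seed = s)
    any(pw$p_corrected < 0.05)
  }, logical(1))
  expect_lte(sum(hits), 3)
})

test_that("score correlations recover exact and signed relations", {
  d <- mk_design(12, seed = 6)
  set.seed(47)
  E <- matrix(rnorm(nrow(d) * 3), ncol = 3,
              dimnames = list(NULL, c("e1", "e2", "e3")))
  S <- cbind(s1 = E[, 1], s2 = -E[, 2] + rnorm(nrow(d), sd = 0.1))
  out <- correlate_scores(E, S)
  expect_equal(out$r[out$edge == "e1" & out$score == "s1"], 1)
  expect_lt(out$r[out$edge == "e2" & out$score == "s2"], -0.9)
  expect_true(all(out$r >= -1 & out$r <= 1))
  expect_error(correlate_scores(cbind(e = rep(1, nrow(d))), S),
               "zero-variance")
})

test_that("scalar ANCOVA recovers a lowered MCI volume and respects the null", {
  d <- mk_design(15, seed = 7)
  set.seed(48)
  vol <- rnorm(nrow(d), 5e-3, 0.5e-3)
  vol[d$group == "MCI"] <- rnorm(15, 4.2e-3, 0.5e-3)
  out <- compare_scalar_ancova(vol, d, n_perm = 300, seed = 10)
  expect_lt(out$p, 0.01)
  pw <- out$pairwise
  expect_lt(pw$p_corrected[pw$pair == "HC-MCI"], 0.05)
  expect_lt(pw$p_corrected[pw$pair == "SCD-MCI"], 0.05)
  expect_gt(pw$p_corrected[pw$pair == "HC-SCD"], 0.05)
  expect_lt(pw$difference[pw$pair == "HC-MCI"], 0)
  # constant volumes: degenerate F handled as 0
  out0 <- compare_scalar_ancova(rep(5e-3, nrow(d)), d, n_perm = 100, seed = 1)
  expect_equal(unname(out0$F), 0)
})
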