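# Epoch segmentation, artifact rejection, inclusion rule, FIR filtering.

test_that("segmentation cuts non-overlapping epochs and drops the tail", {
  sen <- cap_sensor_array(3)
  mk <- function(secs, rate = 1000) {
    x <- matrix(seq_len(3 * secs * rate), nrow = 3)
    segment_epochs(x, rate, 4, sen$positions, sen$orientations)
  }
  ep <- mk(240)
  expect_equal(dim(ep$data), c(60, 3, 4000))
  # consecutive, order-preserving
  expect_equal(ep$data[2, 1, 1], ep$data[1, 1, 4000] + 3)
  ep9 <- mk(9)
  expect_equal(dim(ep9$data)[1], 2)
  expect_error(mk(3), "too short")
})

test_that("artifact rejection keeps clean data and catches spikes", {
  ep <- noise_epochs(n_ep = 20, n_ch = 5, n_s = 500, seed = 2)
  out <- reject_artifact_epochs(ep, 6, 6)
  # Gaussian tails: expected max |z| over 5 x 500 x 20 draws is ~4.5,
  # so nearly everything survives at z = 6
  expect_gte(dim(out$epochs$data)[1], 19)

  spiked <- ep
  spiked$data[7, 3, 100] <- 50 * max(abs(ep$data))
  out2 <- reject_artifact_epochs(spiked, 6, 6)
  expect_true(7 %in% out2$log$epoch)
  expect_false(7 %in% out2$kept)
  expect_equal(setdiff(out$kept, out2$kept), 7)

  all_bad <- ep
  all_bad$data[, 1, 250] <- 100 * max(abs(ep$data))
  out3 <- reject_artifact_epochs(all_bad, 6, 6)
  expect_equal(dim(out3$epochs$data)[1], 0)
  expect_setequal(out3$log$epoch, 1:20)
})

test_that("the 15-epoch inclusion rule is a sharp boundary", {
  expect_true(enforce_min_epochs(15))
  expect_false(enforce_min_epochs(14))
  expect_true(enforce_min_epochs(47))
})

test_that("the band-pass preserves in-band tones and kills out-of-band ones", {
  band <- define_band(9.4)     # 6.9 - 11.4 Hz
  rate <- 1000
  h <- design_fir_bandpass(band, rate)
  expect_length(h, 1801)
  # two-pass response: flat in band, >= 20 dB down 1.5 Hz outside
  resp <- fir_response(h, c(9, 6.9 - 1.5, 11.4 + 1.5, 20), rate, passes = 2)
  expect_equal(resp[1], 1, tolerance = 0.05)
  expect_lt(20 * log10(resp[2]), -20)
  expect_lt(20 * log10(resp[3]), -20)
  expect_lt(20 * log10(resp[4]), -20)

  tt <- (0:5999) / rate
  tone9 <- matrix(cos(2 * pi * 9 * tt), 1)
  y9 <- bandpass_fir(tone9, band, rate = rate)
  mid <- 2000:4000
  expect_equal(max(abs(y9[1, mid])), 1, tolerance = 0.05)
  tone20 <- matrix(cos(2 * pi * 20 * tt), 1)
  y20 <- bandpass_fir(tone20, band, rate = rate)
  expect_lt(20 * log10(max(abs(y20[1, mid]))), -20)
  # linearity: zero in, zero out
  expect_equal(bandpass_fir(matrix(0, 1, 6000), band, rate = rate),
               matrix(0, 1, 6000))
})

test_that("two-pass filtering is zero-phase for an in-band tone", {
  band <- define_band(9.4)
  rate <- 1000
  tt <- (0:5999) / rate
  x <- cos(2 * pi * 9 * tt)
  y <- bandpass_fir(matrix(x, 1), band, rate = rate)[1, ]
  cc <- ccf(x[1000:5000], y[1000:5000], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter order scales with the sampling rate and epochs can be too short", {
  h250 <- design_fir_bandpass(define_band(9.4), 250)
  expect_length(h250, 451)
  expect_error(bandpass_fir(matrix(rnorm(100), 1), define_band(9.4),
                            rate = 1000, pad_samples = 100),
               "too short")
})
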