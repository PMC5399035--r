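# Shared fixtures, generated in code at test time.

# Four-area toy geometry (two anterior, two posterior areas, two sources
# each) with a 60-magnetometer cap.
toy_geometry <- function(seed = 3) {
  atlas <- toy_atlas()[c(1, 3, 7, 9), ]
  atlas$area <- c("A", "B", "C", "D")
  atlas$region <- c("anterior", "anterior", "posterior", "posterior")
  src <- place_area_sources(atlas, 2L, seed = seed)
  sen <- cap_sensor_array(60)
  L <- sphere_leadfield(src$positions, src$orientations,
                        sen$positions, sen$orientations)
  list(atlas = atlas, src = src, sen = sen, L = L)
}

# Epochs of pure Gaussian white noise.
noise_epochs <- function(n_ep = 5, n_ch = 4, n_s = 500, rate = 250, seed = 1) {
  set.seed(seed)
  sen <- cap_sensor_array(n_ch)
  sensor_epochs(array(rnorm(n_ep * n_ch * n_s), c(n_ep, n_ch, n_s)),
                rate, sen$positions, sen$orientations)
}

# Epochs containing pure tones on every channel.
tone_epochs <- function(freqs, n_ep = 3, n_ch = 4, rate = 250, secs = 4,
                        amp = 1) {
  sen <- cap_sensor_array(n_ch)
  n_s <- rate * secs
  tt <- (seq_len(n_s) - 1) / rate
  x <- Reduce(`+`, lapply(freqs, function(f) amp * cos(2 * pi * f * tt)))
  data <- array(rep(x, each = n_ep * n_ch), c(n_ep, n_ch, n_s))
  sensor_epochs(data, rate, sen$positions, sen$orientations)
}

# Small cohort specification used by several pipeline-level tests.
small_spec <- function(seed, n_per_group = 8, n_epochs = 15, rate = 250, ...) {
  ground_truth_spec(
    n_subjects = c(HC = n_per_group, SCD = n_per_group, MCI = n_per_group),
    n_epochs = n_epochs, rate = rate, seed = seed, ...
  )
}

canon_edge <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "--")
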