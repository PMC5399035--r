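#' Epoched multi-channel sensor data
#'
#' Container for epoched MEG-like magnetometer recordings: a numeric
#' array of field values `[epochs x channels x samples]` together with
#' the sampling rate and the sensor geometry (positions and unit
#' orientation vectors in the head frame, meters).
#'
#' @param data numeric array `[epochs x channels x samples]`.
#' @param rate sampling rate in Hz.
#' @param channel_positions numeric matrix `channels x 3` (m).
#' @param channel_orientations numeric matrix `channels x 3`, unit norm.
#' @param channel_names optional character vector of channel names.
#' @return an object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, rate, channel_positions, channel_orientations,
                          channel_names = NULL) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array [epochs x channels x samples]", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a positive scalar (Hz)", call. = FALSE)
  }
  n_chan <- dim(data)[2]
  channel_positions <- as.matrix(channel_positions)
  channel_orientations <- as.matrix(channel_orientations)
  if (nrow(channel_positions) != n_chan || ncol(channel_positions) != 3L) {
    stop("`channel_positions` must be a channels x 3 matrix", call. = FALSE)
  }
  if (nrow(channel_orientations) != n_chan || ncol(channel_orientations) != 3L) {
    stop("`channel_orientations` must be a channels x 3 matrix", call. = FALSE)
  }
  nrm <- row_norms(channel_orientations)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("channel orientations must be unit-norm", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- sprintf("MAG%03d", seq_len(n_chan))
  }
  structure(
    list(
      data = data,
      rate = rate,
      channel_positions = channel_positions,
      channel_orientations = channel_orientations,
      channel_names = as.character(channel_names),
      epoch_length = dim(data)[3] / rate
    ),
    class = "sensor_epochs"
  )
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sensor_epochs> %d epoch(s) x %d channel(s) x %d sample(s) @ %g Hz (%.3g s/epoch)\n",
    d[1], d[2], d[3], x$rate, x$epoch_length
  ))
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[1]

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts a continuous multi-channel recording into non-overlapping,
#' consecutive epochs of `epoch_seconds` (default 4 s, the segment
#' length used for covariance and PLV estimation). A trailing remainder
#' shorter than one epoch is discarded.
#'
#' @param continuous numeric matrix `channels x samples`.
#' @param rate sampling rate in Hz.
#' @param epoch_seconds epoch duration in seconds.
#' @inheritParams sensor_epochs
#' @return a [sensor_epochs] object.
#' @export
segment_epochs <- function(continuous, rate, epoch_seconds = 4,
                           channel_positions, channel_orientations,
                           channel_names = NULL) {
  continuous <- as.matrix(continuous)
  len <- round(epoch_seconds * rate)
  if (ncol(continuous) < len) {
    stop(sprintf("recording too short: %d samples, need at least %d for one %g-s epoch",
                 ncol(continuous), len, epoch_seconds), call. = FALSE)
  }
  n_ep <- ncol(continuous) %/% len
  n_chan <- nrow(continuous)
  data <- array(0, dim = c(n_ep, n_chan, len))
  for (e in seq_len(n_ep)) {
    data[e, , ] <- continuous[, ((e - 1L) * len + 1L):(e * len)]
  }
  sensor_epochs(data, rate, channel_positions, channel_orientations, channel_names)
}

#' Reject artifact-contaminated epochs by amplitude and jump z-scores
#'
#' Stand-in for interactive artifact screening: each epoch is scored by
#' (a) its maximum absolute amplitude z-score and (b) the maximum
#' z-score of the first difference (signal jumps), both relative to the
#' per-channel mean and standard deviation pooled over all epochs.
#' Epochs exceeding either threshold are dropped; order of survivors is
#' preserved.
#'
#' @param epochs a [sensor_epochs] object.
#' @param amplitude_z_threshold positive z threshold for raw amplitude.
#' @param jump_z_threshold positive z threshold for sample-to-sample jumps.
#' @return a list with elements `epochs` (survivors, a [sensor_epochs])
#'   and `log` (data.frame: epoch, reason, statistic for each rejection).
#' @export
reject_artifact_epochs <- function(epochs, amplitude_z_threshold = 6,
                                   jump_z_threshold = 6) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  if (amplitude_z_threshold <= 0 || jump_z_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  d <- epochs$data
  n_ep <- dim(d)[1]; n_ch <- dim(d)[2]; n_s <- dim(d)[3]
  # per-channel pooled center/scale
  mu <- apply(d, 2, mean)
  sdv <- apply(d, 2, stats::sd)
  sdv[sdv == 0] <- 1
  amp_z <- jump_z <- numeric(n_ep)
  dmu <- numeric(n_ch); dsd <- numeric(n_ch)
  diffs <- array(0, dim = c(n_ep, n_ch, n_s - 1L))
  for (ch in seq_len(n_ch)) {
    diffs[, ch, ] <- t(apply(d[, ch, , drop = FALSE][, 1, ], 1, diff))
    dmu[ch] <- mean(diffs[, ch, ])
    dsd[ch] <- stats::sd(as.vector(diffs[, ch, ]))
  }
  dsd[dsd == 0] <- 1
  for (e in seq_len(n_ep)) {
    za <- abs(sweep(sweep(d[e, , , drop = FALSE][1, , ], 1, mu), 1, sdv, `/`))
    amp_z[e] <- max(za)
    zj <- abs(sweep(sweep(diffs[e, , , drop = FALSE][1, , ], 1, dmu), 1, dsd, `/`))
    jump_z[e] <- max(zj)
  }
  bad_amp <- amp_z > amplitude_z_threshold
  bad_jump <- jump_z > jump_z_threshold
  bad <- bad_amp | bad_jump
  log <- data.frame(
    epoch = which(bad),
    reason = ifelse(bad_amp[bad], "amplitude", "jump"),
    statistic = ifelse(bad_amp[bad], amp_z[bad], jump_z[bad]),
    stringsAsFactors = FALSE
  )
  keep <- which(!bad)
  kept <- epochs
  kept$data <- epochs$data[keep, , , drop = FALSE]
  list(epochs = kept, log = log, n_rejected = sum(bad), kept = keep)
}

#' Minimum clean-epoch inclusion rule
#'
#' Subjects enter the group analysis only if they retain at least
#' `minimum` clean epochs (default 15).
#'
#' @param epochs a [sensor_epochs] object or an epoch count.
#' @param minimum required number of clean epochs.
#' @return logical; `TRUE` if the subject passes.
#' @export
enforce_min_epochs <- function(epochs, minimum = 15L) {
  n <- if (inherits(epochs, "sensor_epochs")) n_epochs(epochs) else as.integer(epochs)
  n >= minimum
}
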