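# Phase-locking-value (PLV) connectivity.
#
# For a pair of signals k, l with instantaneous phases phi_k, phi_l, the
# PLV of one data segment of T samples is the norm of the average unit
# phasor of the phase difference:
#
#   PLV_kl = | 1/T sum_t exp(-j (phi_k(t) - phi_l(t))) |   in [0, 1].
#
# Per-subject PLV is the arithmetic mean of segment PLVs.  Area-level
# connectivity averages the per-source-pair PLV magnitudes over all
# N_A x N_B cross-area source pairs.

#' Instantaneous phases via the Hilbert analytic signal
#'
#' Computes the phase of the analytic signal of every source series.
#' Each epoch is extended by reflection padding (2,000 samples at
#' 1,000 Hz, scaled with the rate) before the transform and trimmed
#' afterwards to suppress edge effects.
#'
#' @param source_epochs array `[epochs x sources x samples]` or matrix
#'   `sources x samples`.
#' @param pad_samples padding at 1,000 Hz (default 2000), scaled by
#'   `rate / 1000`; capped at `samples - 1` for short epochs.
#' @param rate sampling rate in Hz (used only to scale the padding).
#' @return a `phase_series`: list with `phase` (same shape as input,
#'   radians in `(-pi, pi]`) and `T` (samples per segment).
#' @export
hilbert_phase <- function(source_epochs, pad_samples = 2000L, rate = 1000) {
  one <- is.matrix(source_epochs)
  arr <- if (one) {
    array(source_epochs, dim = c(1L, dim(source_epochs)))
  } else source_epochs
  n_s <- dim(arr)[3]
  if (n_s <= 2L) stop("epoch length must exceed 2 samples", call. = FALSE)
  pad <- min(round(pad_samples * rate / 1000), n_s - 1L)
  out <- array(0, dim = dim(arr))
  for (e in seq_len(dim(arr)[1])) {
    x <- matrix(arr[e, , , drop = FALSE][1, , ], nrow = dim(arr)[2])
    if (any(apply(x, 1, function(r) max(r) == min(r)))) {
      stop("constant (zero-amplitude) signal: instantaneous phase undefined",
           call. = FALSE)
    }
    xp <- reflect_pad(x, pad)
    an <- analytic_signal(xp)
    out[e, , ] <- Arg(an[, pad + seq_len(n_s), drop = FALSE])
  }
  structure(list(phase = if (one) out[1, , , drop = TRUE] else out, T = n_s),
            class = "phase_series")
}

#' PLV between two phase series
#'
#' Segment-wise modulus of the mean phase-difference phasor, averaged
#' over segments (epochs) when matrices are given.
#'
#' @param phase_k,phase_l numeric vectors (one segment) or matrices
#'   `epochs x samples` of phases in radians.
#' @return scalar PLV in `[0, 1]`.
#' @export
plv_pair <- function(phase_k, phase_l) {
  if (is.null(dim(phase_k))) phase_k <- matrix(phase_k, nrow = 1)
  if (is.null(dim(phase_l))) phase_l <- matrix(phase_l, nrow = 1)
  if (!all(dim(phase_k) == dim(phase_l))) {
    stop("phase series must have equal length", call. = FALSE)
  }
  mean(abs(rowMeans(exp(-1i * (phase_k - phase_l)))))
}

# Per-epoch source x source PLV matrix averaged over epochs.
plv_source_matrix <- function(phase) {
  arr <- if (length(dim(phase)) == 2L) array(phase, dim = c(1L, dim(phase))) else phase
  n_src <- dim(arr)[2]
  TT <- dim(arr)[3]
  acc <- matrix(0, n_src, n_src)
  for (e in seq_len(dim(arr)[1])) {
    E <- exp(1i * matrix(arr[e, , , drop = FALSE][1, , ], nrow = n_src))
    acc <- acc + abs(E %*% Conj(t(E))) / TT
  }
  acc / dim(arr)[1]
}

#' Area-averaged PLV connectivity
#'
#' Averages per-source-pair PLV magnitudes over all cross-area source
#' pairs: for areas A and B with N_A and N_B sources, the area PLV is
#' `1/(N_A N_B) * sum_{k in A} sum_{l in B} PLV_kl` (magnitudes are
#' averaged, not complex phasors). Segment PLVs are averaged over
#' epochs first.
#'
#' @param phase a `phase_series` (from [hilbert_phase]) or a phase array.
#' @param labels character vector, atlas area per source.
#' @return an `area_connectivity`: list with `plv` (area x area,
#'   symmetric, unit diagonal), `area_names`, `n_sources_per_area`,
#'   `n_epochs_used`.
#' @export
plv_area <- function(phase, labels) {
  arr <- if (inherits(phase, "phase_series")) phase$phase else phase
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(1L, dim(arr)))
  n_src <- dim(arr)[2]
  if (length(labels) != n_src) stop("one label per source required", call. = FALSE)
  areas <- unique(labels)
  counts <- table(factor(labels, levels = areas))
  if (any(counts == 0L)) stop("empty area", call. = FALSE)
  S <- plv_source_matrix(arr)
  n_a <- length(areas)
  out <- matrix(1, n_a, n_a, dimnames = list(areas, areas))
  for (a in seq_len(n_a)) {
    for (b in seq_len(n_a)) {
      if (a < b) {
        ia <- which(labels == areas[a]); ib <- which(labels == areas[b])
        out[a, b] <- out[b, a] <- mean(S[ia, ib])
      }
    }
  }
  structure(
    list(plv = out, area_names = areas,
         n_sources_per_area = as.integer(counts),
         n_epochs_used = dim(arr)[1], T = dim(arr)[3]),
    class = "area_connectivity"
  )
}

#' @export
print.area_connectivity <- function(x, ...) {
  cat(sprintf("<area_connectivity> %d areas, %d epoch(s), T = %d\n",
              length(x$area_names), x$n_epochs_used, x$T))
  invisible(x)
}

#' Analytic significance of a PLV value
#'
#' P-value for the null hypothesis of independent, uniformly distributed
#' phase differences (Rayleigh resultant test on T points): with
#' `Z = T * PLV^2`, the classical series approximation
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4T) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288T^2)]`
#' is used, clipped to `[0, 1]`. Narrowband signals have fewer effective
#' degrees of freedom than nominal samples; pass an autocorrelation-
#' deflated `T_effective` when appropriate.
#'
#' @param plv PLV in `[0, 1]` (vectorized).
#' @param T_effective number of (effectively independent) samples, >= 2.
#' @return p-value(s), monotone decreasing in `plv` at fixed `T`.
#' @export
plv_significance <- function(plv, T_effective) {
  if (any(plv < 0 | plv > 1)) stop("`plv` must lie in [0, 1]", call. = FALSE)
  if (any(T_effective < 2)) stop("`T_effective` must be >= 2", call. = FALSE)
  TT <- T_effective
  Z <- TT * plv^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * TT) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * TT^2))
  pmin(1, pmax(p, 0))
}

#' Mean connectivity over a resting-state network
#'
#' Average of the area-pair PLVs over all within-network pairs of
#' member areas.
#'
#' @param conn an `area_connectivity`.
#' @param members character vector of member areas (>= 2).
#' @return scalar mean PLV.
#' @export
rsn_average <- function(conn, members) {
  stopifnot(inherits(conn, "area_connectivity"))
  if (length(members) < 2L) stop("a network needs at least 2 members", call. = FALSE)
  missing <- setdiff(members, conn$area_names)
  if (length(missing) > 0L) {
    stop("network member(s) not in connectivity matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(members, conn$area_names)
  sub <- conn$plv[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Long-form edge table of an area connectivity matrix
#'
#' @param conn an `area_connectivity` (or plain symmetric matrix with
#'   dimnames).
#' @param file optional CSV path.
#' @return data.frame with `area_a`, `area_b`, `plv` (upper triangle).
#' @export
connectivity_to_table <- function(conn, file = NULL) {
  m <- if (inherits(conn, "area_connectivity")) conn$plv else conn
  ut <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(area_a = rownames(m)[ut[, 1]], area_b = colnames(m)[ut[, 2]],
                   plv = m[ut], stringsAsFactors = FALSE)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
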