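# LCMV beamformer: spatial filters minimizing output variance subject
# to unit gain at each source's leadfield.

#' Epoch-averaged sensor covariance
#'
#' Average of the per-epoch sample covariance matrices of band-limited
#' sensor data (sample covariance about the per-epoch channel means).
#'
#' @param epochs a [sensor_epochs] object.
#' @return symmetric positive semidefinite `channels x channels` matrix.
#' @export
epoch_covariance <- function(epochs) {
  stopifnot(inherits(epochs, "sensor_epochs"))
  d <- epochs$data
  n_ep <- dim(d)[1]
  if (n_ep < 1L) stop("need at least one epoch", call. = FALSE)
  n_ch <- dim(d)[2]
  C <- matrix(0, n_ch, n_ch)
  for (e in seq_len(n_ep)) {
    x <- matrix(d[e, , , drop = FALSE][1, , ], nrow = n_ch)
    x <- x - rowMeans(x)
    C <- C + tcrossprod(x) / (ncol(x) - 1L)
  }
  C / n_ep
}

#' LCMV beamformer weights
#'
#' Computes, per source, the spatial filter
#' `w_s = (l_s' C^-1 l_s)^-1 l_s' C^-1` from the (regularized)
#' epoch-averaged covariance and the source's leadfield column, so that
#' the filter has unit gain at its own source. The covariance is
#' diagonally loaded with `regularization * trace(C) / n_channels`.
#'
#' @param leadfield `channels x sources` matrix (fixed orientation; use
#'   [max_power_orientation] first to collapse a free-orientation
#'   leadfield).
#' @param covariance `channels x channels` PSD matrix.
#' @param regularization diagonal-loading fraction (default 0.05).
#' @return a `beamformer_filter`: list with `weights`
#'   (`sources x channels`), `covariance_used`, `regularization`.
#' @export
lcmv_weights <- function(leadfield, covariance, regularization = 0.05) {
  L <- as.matrix(leadfield)
  C <- as.matrix(covariance)
  if (nrow(C) != ncol(C) || nrow(C) != nrow(L)) {
    stop("covariance must be channels x channels matching the leadfield", call. = FALSE)
  }
  if (regularization < 0) stop("`regularization` must be >= 0", call. = FALSE)
  Creg <- C + regularization * (sum(diag(C)) / nrow(C)) * diag(nrow(C))
  CiL <- tryCatch(solve(Creg, L), error = function(e) {
    stop("regularized covariance is singular; increase `regularization`",
         call. = FALSE)
  })
  gains <- colSums(L * CiL)           # l_s' C^-1 l_s per source
  if (any(gains <= 0)) {
    stop("regularized covariance is not positive definite; increase `regularization`",
         call. = FALSE)
  }
  W <- t(CiL) / gains                 # sources x channels
  structure(
    list(weights = W, covariance_used = Creg, regularization = regularization,
         leadfield = L),
    class = "beamformer_filter"
  )
}

#' @export
print.beamformer_filter <- function(x, ...) {
  cat(sprintf("<beamformer_filter> %d source(s) x %d channel(s), diagonal loading %.3g\n",
              nrow(x$weights), ncol(x$weights), x$regularization))
  invisible(x)
}

#' Collapse a free-orientation leadfield to the max-power orientation
#'
#' For each source with a 3-column leadfield block, selects the dipole
#' orientation maximizing beamformer output power, i.e. the generalized
#' eigenvector minimizing `eta' (L' C^-1 L) eta` within the subspace
#' where the source is actually visible. In a spherical conductor the
#' radial orientation is magnetically silent; directions whose leadfield
#' norm falls below `rank_tol` times the strongest direction are
#' excluded before the eigen-decomposition.
#'
#' @param leadfield_free `channels x (3 sources)` matrix.
#' @param covariance sensor covariance.
#' @param regularization diagonal-loading fraction.
#' @param rank_tol relative leadfield-norm threshold for silent
#'   directions.
#' @return list with `leadfield` (`channels x sources`, collapsed) and
#'   `orientations` (`sources x 3`).
#' @export
max_power_orientation <- function(leadfield_free, covariance,
                                  regularization = 0.05, rank_tol = 1e-4) {
  L <- as.matrix(leadfield_free)
  if (ncol(L) %% 3L != 0L) stop("free leadfield must have 3 columns per source", call. = FALSE)
  n_src <- ncol(L) / 3L
  C <- as.matrix(covariance)
  Creg <- C + regularization * (sum(diag(C)) / nrow(C)) * diag(nrow(C))
  out_L <- matrix(0, nrow(L), n_src)
  out_ori <- matrix(0, n_src, 3)
  for (s in seq_len(n_src)) {
    Ls <- L[, (3L * (s - 1L) + 1L):(3L * s), drop = FALSE]
    # basis of visible directions
    sv <- svd(Ls)
    keep <- sv$d > rank_tol * sv$d[1]
    V <- sv$v[, keep, drop = FALSE]
    Lv <- Ls %*% V
    M <- crossprod(Lv, solve(Creg, Lv))
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    eta_v <- ev$vectors[, which.min(ev$values)]
    eta <- as.numeric(V %*% eta_v)
    eta <- eta / sqrt(sum(eta^2))
    out_ori[s, ] <- eta
    out_L[, s] <- Ls %*% eta
  }
  list(leadfield = out_L, orientations = out_ori)
}

#' Apply beamformer weights to sensor epochs
#'
#' @param filter a `beamformer_filter`.
#' @param epochs a [sensor_epochs] object or a `channels x samples`
#'   matrix.
#' @return array `[epochs x sources x samples]` (or matrix for matrix
#'   input).
#' @export
apply_weights <- function(filter, epochs) {
  W <- filter$weights
  if (inherits(epochs, "sensor_epochs")) {
    d <- epochs$data
    if (dim(d)[2] != ncol(W)) stop("channel dimensions disagree", call. = FALSE)
    out <- array(0, dim = c(dim(d)[1], nrow(W), dim(d)[3]))
    for (e in seq_len(dim(d)[1])) {
      out[e, , ] <- W %*% matrix(d[e, , , drop = FALSE][1, , ], nrow = ncol(W))
    }
    out
  } else {
    x <- as.matrix(epochs)
    if (nrow(x) != ncol(W)) stop("channel dimensions disagree", call. = FALSE)
    W %*% x
  }
}

#' Beamformer-weight correlations per area pair (source-leakage diagnostic)
#'
#' Spurious connectivity differences can arise when the beamformer's
#' spatial filters, not the underlying sources, differ between groups.
#' As a diagnostic, the Pearson correlation between the weight vectors
#' of every cross-area source pair is computed and averaged per area
#' pair, giving one correlation per link per subject; the resulting
#' per-link values are then compared across groups with the same
#' permutation ANCOVA machinery as the connectivity itself.
#'
#' @param filter a `beamformer_filter`.
#' @param labels area label per source.
#' @return symmetric area x area matrix of mean weight correlations.
#' @export
weight_correlation_matrix <- function(filter, labels) {
  W <- filter$weights
  if (ncol(W) < 2L) stop("need at least 2 channels", call. = FALSE)
  nrm <- sqrt(colSums(scale(t(W), scale = FALSE)^2))
  if (any(nrm == 0)) {
    stop("zero-norm beamformer weight vector: correlation undefined", call. = FALSE)
  }
  R <- stats::cor(t(W))
  areas <- unique(labels)
  out <- matrix(1, length(areas), length(areas), dimnames = list(areas, areas))
  for (a in seq_along(areas)) {
    for (b in seq_along(areas)) {
      if (a < b) {
        ia <- which(labels == areas[a]); ib <- which(labels == areas[b])
        out[a, b] <- out[b, a] <- mean(R[ia, ib])
      }
    }
  }
  out
}
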