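# Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package accept an explicit `seed`;
#' this helper guarantees they neither depend on nor disturb the caller's
#' random-number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific child seed from a master seed so that every
# stage of a run is reproducible in isolation.  Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 7919) %% 2147483629)
}

# Wrap angles into the principal interval (-pi, pi].
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Mirror (reflection) padding of the rows of a matrix [series x samples].
# Used before FIR filtering and the Hilbert transform to suppress edge
# effects on finite epochs; the padding is removed again downstream.
reflect_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  n <- ncol(x)
  if (pad > n - 1L) {
    stop(sprintf("reflection padding of %d samples needs at least %d samples per epoch",
                 pad, pad + 1L), call. = FALSE)
  }
  left <- x[, pad:1, drop = FALSE]
  right <- x[, n:(n - pad + 1L), drop = FALSE]
  cbind(left, x, right)
}

# Analytic signal of every row of a real matrix via the frequency-domain
# construction: keep DC and Nyquist, double positive frequencies, zero
# negative ones.
analytic_signal <- function(x) {
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  X <- sweep(X, 2, h, `*`)
  t(stats::mvfft(t(X), inverse = TRUE)) / n
}

# Linear convolution of every row of `x` with kernel `h` by FFT,
# returning the full convolution (ncol(x) + length(h) - 1 columns).
fft_convolve_rows <- function(x, h) {
  n_out <- ncol(x) + length(h) - 1L
  nfft <- stats::nextn(n_out, 2)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  xp <- cbind(x, matrix(0, nrow(x), nfft - ncol(x)))
  Y <- t(stats::mvfft(t(xp)))
  Y <- sweep(Y, 2, H, `*`)
  y <- Re(t(stats::mvfft(t(Y), inverse = TRUE))) / nfft
  y[, seq_len(n_out), drop = FALSE]
}

# Row-wise norms of a 3-column matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Normalize rows of a matrix to unit norm.
unit_rows <- function(m) m / row_norms(m)

`%||%` <- function(a, b) if (is.null(a)) b else a
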