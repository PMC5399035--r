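# Analytic spherical-conductor magnetometer forward model.
#
# The magnetic field of a current dipole inside a homogeneous conducting
# sphere has the closed-form solution of Sarvas (geophysical convention:
# field outside the sphere depends only on dipole position/moment and
# the sphere center, not on the conductivity profile).  Two classical
# properties follow directly and are used as tests: a dipole at the
# center produces no field, and a radially oriented dipole produces no
# external field at all.

#' Leadfield of current dipoles in a conducting sphere (Sarvas formula)
#'
#' Computes the magnetic field per unit dipole moment at magnetometer
#' sensors for sources inside a spherical volume conductor.
#'
#' @param source_positions matrix `n_sources x 3` (m, head frame).
#' @param source_orientations matrix `n_sources x 3` unit dipole moment
#'   directions, or `NULL` for a free-orientation leadfield (3 columns
#'   per source, x/y/z moments).
#' @param sensor_positions matrix `n_channels x 3` (m).
#' @param sensor_orientations matrix `n_channels x 3`, unit norm; each
#'   magnetometer measures the field component along its orientation.
#' @param center sphere center (default origin).
#' @return matrix `n_channels x n_sources` (fixed orientations) or
#'   `n_channels x (3 n_sources)` (free orientations), in T per (A m).
#' @export
sphere_leadfield <- function(source_positions, source_orientations,
                             sensor_positions, sensor_orientations,
                             center = c(0, 0, 0)) {
  src <- sweep(as.matrix(source_positions), 2, center)
  sen <- sweep(as.matrix(sensor_positions), 2, center)
  sen_ori <- as.matrix(sensor_orientations)
  if (any(abs(row_norms(sen_ori) - 1) > 1e-6)) {
    stop("sensor orientations must be unit-norm", call. = FALSE)
  }
  r_sensor_min <- min(row_norms(sen))
  r_src <- row_norms(src)
  if (any(r_src >= r_sensor_min)) {
    stop(sprintf("source(s) %s lie at or outside the sensor radius (%.3g m)",
                 paste(which(r_src >= r_sensor_min), collapse = ", "),
                 r_sensor_min), call. = FALSE)
  }
  free <- is.null(source_orientations)
  if (!free) {
    ori <- as.matrix(source_orientations)
    if (any(abs(row_norms(ori) - 1) > 1e-6)) {
      stop("source orientations must be unit-norm", call. = FALSE)
    }
  }
  n_src <- nrow(src)
  n_sen <- nrow(sen)
  L <- matrix(0, n_sen, if (free) 3L * n_src else n_src)
  basis <- diag(3)
  for (s in seq_len(n_src)) {
    r0 <- src[s, ]
    if (free) {
      for (k in 1:3) {
        L[, 3L * (s - 1L) + k] <- sarvas_field(r0, basis[k, ], sen, sen_ori)
      }
    } else {
      L[, s] <- sarvas_field(r0, ori[s, ], sen, sen_ori)
    }
  }
  L
}

# Field component along each sensor orientation for one dipole (r0, Q),
# sensors relative to the sphere center.  mu0 / 4 pi = 1e-7 in SI units.
sarvas_field <- function(r0, Q, sen, sen_ori) {
  qxr0 <- c(Q[2] * r0[3] - Q[3] * r0[2],
            Q[3] * r0[1] - Q[1] * r0[3],
            Q[1] * r0[2] - Q[2] * r0[1])
  a_vec <- sweep(sen, 2, r0)        # r - r0
  a <- row_norms(a_vec)
  r <- row_norms(sen)
  a_dot_r <- rowSums(a_vec * sen)
  r0_dot_r <- as.vector(sen %*% r0)
  FF <- a * (r * a + r^2 - r0_dot_r)
  # grad F = (a^2/r + a.r/a + 2a + 2r) r - (a + 2r + a.r/a) r0
  c1 <- a^2 / r + a_dot_r / a + 2 * a + 2 * r
  c2 <- a + 2 * r + a_dot_r / a
  gradF <- sweep(sen, 1, c1, `*`) - outer(c2, r0)
  qxr0_dot_r <- as.vector(sen %*% qxr0)
  B <- sweep(matrix(qxr0, nrow(sen), 3, byrow = TRUE), 1, FF, `*`) -
    sweep(gradF, 1, qxr0_dot_r, `*`)
  B <- B * (1e-7 / FF^2)
  rowSums(B * sen_ori)
}

#' Project source time series to magnetometer sensors
#'
#' Applies the spherical-conductor leadfield to source activity,
#' optionally per epoch. The mapping is linear in the source amplitudes.
#'
#' @param source_signals matrix `n_sources x samples`, or 3-d array
#'   `[epochs x n_sources x samples]`.
#' @param source_positions,source_orientations source geometry (fixed
#'   orientations required here).
#' @param sensor_positions,sensor_orientations sensor geometry.
#' @param center sphere center.
#' @param rate sampling rate in Hz (attached to the output).
#' @return a [sensor_epochs] object.
#' @export
forward_project_sphere <- function(source_signals, source_positions,
                                   source_orientations, sensor_positions,
                                   sensor_orientations, center = c(0, 0, 0),
                                   rate) {
  L <- sphere_leadfield(source_positions, source_orientations,
                        sensor_positions, sensor_orientations, center)
  if (length(dim(source_signals)) == 3L) {
    n_ep <- dim(source_signals)[1]
    n_s <- dim(source_signals)[3]
    data <- array(0, dim = c(n_ep, nrow(L), n_s))
    for (e in seq_len(n_ep)) {
      data[e, , ] <- L %*% source_signals[e, , , drop = FALSE][1, , ]
    }
  } else {
    x <- as.matrix(source_signals)
    data <- array(0, dim = c(1L, nrow(L), ncol(x)))
    data[1, , ] <- L %*% x
  }
  sensor_epochs(data, rate, sensor_positions, sensor_orientations)
}

#' Magnetometer positions on a spherical cap
#'
#' Places `n` radially oriented magnetometers on the upper cap of a
#' sphere using a Fibonacci spiral, mimicking a whole-head magnetometer
#' layout at a sensor radius of 12 cm.
#'
#' @param n number of sensors (default 60).
#' @param radius sensor shell radius in m.
#' @param cap_fraction fraction of the sphere covered from the top
#'   (default 0.55: down to about 10 degrees below the equator).
#' @return list with `positions` and `orientations` (`n x 3` matrices).
#' @export
cap_sensor_array <- function(n = 60L, radius = 0.12, cap_fraction = 0.55) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * cap_fraction * i / n          # cos(theta) from 1 downward
  phi_g <- pi * (1 + sqrt(5)) * i            # golden-angle longitudes
  st <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(st * cos(phi_g), st * sin(phi_g), z)
  list(positions = pos, orientations = unit_rows(pos))
}
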