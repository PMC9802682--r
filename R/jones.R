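# Retarder algebra on unit-determinant Jones matrices and Stokes-space
# rotation vectors. Conventions used throughout the package:
#
#   * Jones vectors are (Ex, Ey); Stokes components are
#     Q = |Ex|^2 - |Ey|^2, U = 2 Re(conj(Ex) Ey), V = 2 Im(conj(Ex) Ey),
#     i.e. Q = horizontal - vertical, U = +45deg - -45deg, V = right - left
#     circular.
#   * A retarder with Stokes rotation vector r (radians) is the SU(2) element
#     exp(-i |r|/2 (rhat . sigma)) with sigma = (sigma1, sigma2, sigma3) in the
#     basis above; it rotates Stokes states by |r| about rhat (right-handed).
#   * Jones matrices are stored det-normalized: PSOCT is insensitive to a
#     common phase, and fixing det = 1 makes the SU(2) <-> SO(3) correspondence
#     unambiguous up to the overall sign of the matrix.
#   * The optic-axis angle theta is measured from the first in-plane reference
#     direction of the local frame, counterclockwise, and reported in
#     [-pi/2, pi/2); a linear retarder with axis theta has rotation vector
#     phi * (cos 2 theta, sin 2 theta, 0).

#' Construct a unitary Jones matrix
#'
#' Validates unitarity and normalizes the determinant to 1 (principal branch
#' of sqrt(det)); the class is a thin wrapper around a 2x2 complex matrix.
#'
#' @param m 2x2 complex matrix, unitary up to a scalar phase
#' @param tol unitarity tolerance
#' @return object of class `unitary_jones`
#' @export
unitary_jones <- function(m, tol = 1e-9) {
  m <- matrix(as.complex(m), 2L, 2L)
  g <- m %*% Conj(t(m))
  if (max(Mod(g - diag(2))) > tol) {
    stop("matrix is not unitary within tolerance")
  }
  d <- m[1L, 1L] * m[2L, 2L] - m[1L, 2L] * m[2L, 1L]
  m <- m / sqrt(d)
  structure(m, class = "unitary_jones")
}

#' @export
print.unitary_jones <- function(x, ...) {
  cat("<unitary_jones> det-normalized 2x2 Jones matrix\n")
  print(unclass(x), ...)
  r <- retardance_vector(x)
  cat(sprintf(
    "retardance %.6g rad, axis (Q,U,V) = (%.4g, %.4g, %.4g)\n",
    sqrt(sum(r^2)), r[1L], r[2L], r[3L]
  ))
  invisible(x)
}

#' Linear retarder
#'
#' Jones matrix of a homogeneous linear retarder with single-pass retardation
#' `phi` and in-plane optic axis `theta`. Its Stokes rotation vector is
#' `phi * (cos 2 theta, sin 2 theta, 0)` (for `phi <= pi` this is also the
#' principal-branch value returned by [retardance_vector()]). The matrix is
#' transpose-symmetric, reflecting the reciprocity of a linear retarder.
#'
#' @param phi single-pass retardation, radians, >= 0
#' @param theta optic-axis angle, radians, interpreted modulo pi
#' @return `unitary_jones`
#' @export
#' @examples
#' linear_retarder(pi / 2, pi / 4)
linear_retarder <- function(phi, theta) {
  stopifnot(length(phi) == 1L, length(theta) == 1L, is.finite(phi), phi >= 0)
  s <- j2_linear_retarder(phi, theta)
  structure(
    matrix(c(s$a, s$c, s$b, s$d), 2L, 2L),
    class = "unitary_jones"
  )
}

#' Retarder from a Stokes rotation vector
#'
#' Inverse of [retardance_vector()] on the principal branch; accepts any
#' rotation vector (including a circular V component).
#'
#' @param r numeric length-3 rotation vector (Q, U, V), radians
#' @return `unitary_jones`
#' @export
jones_from_vector <- function(r) {
  stopifnot(length(r) == 3L, all(is.finite(r)))
  phi <- sqrt(sum(r^2))
  if (phi == 0) {
    return(structure(diag(2) + 0i, class = "unitary_jones"))
  }
  k <- r / phi
  ch <- cos(phi / 2)
  sh <- sin(phi / 2)
  m <- matrix(c(
    complex(real = ch, imaginary = -sh * k[1L]),
    complex(real = 0, imaginary = -sh * k[2L]) + sh * k[3L],
    complex(real = 0, imaginary = -sh * k[2L]) - sh * k[3L],
    complex(real = ch, imaginary = sh * k[1L])
  ), 2L, 2L)
  structure(m, class = "unitary_jones")
}

#' Internal: rotation angle and axis*sin term of a det-1 unitary
#'
#' Writes J = cos(phi/2) I - i sin(phi/2) (k . sigma) and returns the full
#' SU(2) angle phi in [0, 2 pi) together with sin(phi/2) * k.
#' @noRd
su2_log_parts <- function(j) {
  m <- unclass(j)
  c0 <- Re(m[1L, 1L] + m[2L, 2L]) / 2
  s1 <- -Im(m[1L, 1L] - m[2L, 2L]) / 2
  s2 <- -Im(m[1L, 2L] + m[2L, 1L]) / 2
  s3 <- Re(m[2L, 1L] - m[1L, 2L]) / 2
  s <- sqrt(s1^2 + s2^2 + s3^2)
  list(phi = 2 * atan2(s, c0), sk = c(s1, s2, s3), s = s)
}

#' Stokes rotation vector of a retarder
#'
#' Matrix logarithm of a det-normalized unitary Jones matrix, reduced to the
#' principal branch: the returned vector has norm in `[0, pi]`. At retardation
#' exactly pi the axis sign is degenerate; the representative with V >= 0
#' (then U >= 0, then Q >= 0) is returned.
#'
#' @param j `unitary_jones` (or plain 2x2 unitary matrix)
#' @return numeric length-3 vector (Q, U, V) in radians
#' @export
#' @examples
#' retardance_vector(linear_retarder(0.3, 0.2))
retardance_vector <- function(j) {
  if (!inherits(j, "unitary_jones")) j <- unitary_jones(j)
  p <- su2_log_parts(j)
  if (p$s < 1e-300) {
    if (p$phi > pi) {
      # -I: angle 2 pi, principal branch collapses to zero rotation
      return(c(0, 0, 0))
    }
    return(c(0, 0, 0))
  }
  k <- p$sk / p$s
  phi <- p$phi
  if (phi > pi + 1e-14) {
    phi <- 2 * pi - phi
    k <- -k
  }
  v <- phi * k
  if (abs(phi - pi) <= 1e-12) {
    flip <- v[3L] < 0 ||
      (v[3L] == 0 && (v[2L] < 0 || (v[2L] == 0 && v[1L] < 0)))
    if (flip) v <- -v
  }
  v
}

#' Round-trip Jones matrix
#'
#' Given the cumulative one-way transmission `j_cum`, returns the round trip
#' `t(j_cum) %*% j_cum`. The result is transpose-symmetric, which in Stokes
#' space means its rotation axis lies in the QU plane: a round trip through
#' reciprocal retarders always has linearly polarized eigenstates.
#'
#' @param j_cum `unitary_jones`
#' @return `unitary_jones`
#' @export
roundtrip <- function(j_cum) {
  if (!inherits(j_cum, "unitary_jones")) j_cum <- unitary_jones(j_cum)
  m <- unclass(j_cum)
  structure(t(m) %*% m, class = "unitary_jones")
}

#' Retarder square root
#'
#' Halves the rotation vector on the full SU(2) branch (angle in [0, 2 pi)),
#' so the square root of a round trip recovers the one-way retarder even when
#' the round-trip retardation exceeds pi. Near retardation 2 pi the axis is
#' unrecoverable and an error is raised.
#'
#' @param j2 `unitary_jones`
#' @param tol branch-ambiguity guard around retardation 2 pi
#' @return `unitary_jones` whose square equals `j2`
#' @export
retarder_sqrt <- function(j2, tol = 1e-6) {
  if (!inherits(j2, "unitary_jones")) j2 <- unitary_jones(j2)
  p <- su2_log_parts(j2)
  if (2 * pi - p$phi < tol && p$phi > pi) {
    stop("retardation within tolerance of 2 pi: square-root branch ambiguous")
  }
  if (p$s < 1e-300) {
    return(structure(diag(2) + 0i, class = "unitary_jones"))
  }
  jones_from_vector((p$phi / 2) * (p$sk / p$s))
}

#' Project a rotation vector onto linear-retarder form
#'
#' Zeroes the circular (V) component, leaving Q and U untouched; idempotent.
#' This enforces the linear-eigenstate constraint satisfied by any reciprocal
#' round trip.
#'
#' @param r numeric length-3 rotation vector
#' @return numeric length-3 with `r[3] == 0`
#' @export
project_linear <- function(r) {
  stopifnot(length(r) == 3L)
  c(r[1L], r[2L], 0)
}

#' Optic axis and birefringence from a local rotation vector
#'
#' Converts a single-pass, per-layer linear rotation vector into the optic
#' axis angle and the dimensionless birefringence. Inverse of the simulator's
#' per-layer phase accrual `phi = 2 pi dn delta_z / lambda_c`.
#'
#' @param r numeric length-3 linear rotation vector (V component ignored
#'   after [project_linear()])
#' @param delta_z depth-pixel size, micrometers
#' @param lambda_c center wavelength, nanometers
#' @return list with `theta` (radians in `[-pi/2, pi/2)`; 0 by convention for
#'   zero retardance) and `dn` (>= 0)
#' @export
#' @examples
#' axis_and_birefringence(c(0, 0.1, 0), delta_z = 4.8, lambda_c = 1300)
axis_and_birefringence <- function(r, delta_z, lambda_c = 1300) {
  stopifnot(length(r) == 3L)
  if (delta_z <= 0) stop("delta_z must be positive")
  phi <- sqrt(r[1L]^2 + r[2L]^2)
  dn <- phi * (lambda_c * 1e-3) / (2 * pi * delta_z)
  theta <- if (phi == 0) 0 else wrap_axis_angle(0.5 * atan2(r[2L], r[1L]))
  list(theta = theta, dn = dn)
}

#' Fold an axis angle into [-pi/2, pi/2)
#' @param theta radians
#' @return radians in `[-pi/2, pi/2)`
#' @export
wrap_axis_angle <- function(theta) {
  out <- (theta + pi / 2) %% pi - pi / 2
  out[out >= pi / 2] <- -pi / 2
  out
}

#' Stokes rotation matrix of a unitary Jones matrix
#'
#' The SO(3) image acting on (Q, U, V); both signs of the det-normalized
#' matrix map to the same rotation.
#'
#' @param j `unitary_jones`
#' @return 3x3 rotation matrix
#' @export
su2_to_so3 <- function(j) {
  if (!inherits(j, "unitary_jones")) j <- unitary_jones(j)
  p <- su2_log_parts(j)
  if (p$s < 1e-300) {
    return(diag(3))
  }
  rotm_from_vec(matrix(p$phi * p$sk / p$s, ncol = 1L))[, , 1L]
}

#' Stokes state of a Jones field vector
#'
#' @param e complex length-2 field (Ex, Ey)
#' @return named numeric (i, q, u, v)
#' @export
stokes_state <- function(e) {
  s <- stokes_from_field(e[1L], e[2L])
  c(i = s$i, q = s$q, u = s$u, v = s$v)
}

#' Random det-1 unitary (Haar) Jones matrices
#'
#' Draws from the Haar measure on SU(2) via a normalized complex Gaussian
#' pair; used to model unknown static system transmissions in tests and
#' simulations. Uses the current RNG state.
#'
#' @param n number of matrices
#' @return list of `unitary_jones` (a single matrix if `n = 1`)
#' @export
random_unitary <- function(n = 1L) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    z <- complex(
      real = stats::rnorm(2L),
      imaginary = stats::rnorm(2L)
    )
    z <- z / sqrt(sum(Mod(z)^2))
    m <- matrix(c(z[1L], -Conj(z[2L]), z[2L], Conj(z[1L])), 2L, 2L)
    out[[i]] <- structure(m, class = "unitary_jones")
  }
  if (n == 1L) out[[1L]] else out
}

#' Compose a stack of retarders into a cumulative one-way Jones matrix
#'
#' @param layers list of `unitary_jones`, ordered from the first layer entered
#'   to the last; the product applies the first layer first.
#' @return `unitary_jones`
#' @export
compose_layers <- function(layers) {
  stopifnot(length(layers) >= 1L)
  m <- diag(2) + 0i
  for (j in layers) {
    m <- unclass(j) %*% m
  }
  structure(m, class = "unitary_jones")
}
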