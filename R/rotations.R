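# Batched SO(3) rotation algebra on 3 x 3 x n arrays and 3 x n rotation-vector
# matrices. All reconstruction-side polarimetry runs in Stokes (Q,U,V) space
# with these helpers; they are vectorized across pixels so that whole tomogram
# planes are processed with elementwise arithmetic rather than per-pixel loops.

#' Stack of identity rotations
#' @param n number of matrices
#' @return 3 x 3 x n array
#' @noRd
rotm_identity <- function(n) {
  out <- array(0, dim = c(3L, 3L, n))
  out[1L, 1L, ] <- 1
  out[2L, 2L, ] <- 1
  out[3L, 3L, ] <- 1
  out
}

#' Batched matrix product of rotation stacks
#' @param a,b 3 x 3 x n arrays
#' @noRd
rotm_mult <- function(a, b) {
  n <- dim(a)[3L]
  out <- array(0, dim = c(3L, 3L, n))
  for (i in 1:3) {
    for (j in 1:3) {
      out[i, j, ] <- a[i, 1L, ] * b[1L, j, ] +
        a[i, 2L, ] * b[2L, j, ] +
        a[i, 3L, ] * b[3L, j, ]
    }
  }
  out
}

#' Batched transpose (= inverse for rotations)
#' @noRd
rotm_t <- function(a) aperm(a, c(2L, 1L, 3L))

#' Transpose image in Stokes space
#'
#' For a Jones matrix J with Stokes rotation R, the Jones transpose t(J) maps
#' to D R^T D with D = diag(1, 1, -1): same rotation angle, axis with the V
#' component flipped. A transpose-symmetric Jones matrix therefore has
#' D R^T D = R, i.e. a rotation axis in the QU plane. This is the algebraic
#' core of the round-trip symmetry.
#' @noRd
rotm_tau <- function(a) {
  out <- aperm(a, c(2L, 1L, 3L))
  out[1L, 3L, ] <- -out[1L, 3L, ]
  out[2L, 3L, ] <- -out[2L, 3L, ]
  out[3L, 1L, ] <- -out[3L, 1L, ]
  out[3L, 2L, ] <- -out[3L, 2L, ]
  out
}

#' Apply a single 3x3 matrix on the left/right of a stack
#' @noRd
rotm_lmult <- function(m, a) {
  n <- dim(a)[3L]
  out <- array(0, dim = c(3L, 3L, n))
  for (i in 1:3) {
    for (j in 1:3) {
      out[i, j, ] <- m[i, 1L] * a[1L, j, ] + m[i, 2L] * a[2L, j, ] +
        m[i, 3L] * a[3L, j, ]
    }
  }
  out
}

#' @noRd
rotm_rmult <- function(a, m) {
  n <- dim(a)[3L]
  out <- array(0, dim = c(3L, 3L, n))
  for (i in 1:3) {
    for (j in 1:3) {
      out[i, j, ] <- a[i, 1L, ] * m[1L, j] + a[i, 2L, ] * m[2L, j] +
        a[i, 3L, ] * m[3L, j]
    }
  }
  out
}

#' Rodrigues map: rotation vectors to rotation matrices, batched
#'
#' @param v 3 x n matrix of rotation vectors (axis * angle, radians)
#' @return 3 x 3 x n array
#' @noRd
rotm_from_vec <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 3L)
  n <- ncol(v)
  phi <- sqrt(colSums(v^2))
  # Guard the axis at phi ~ 0; sin/cos terms below stay exact in the limit.
  safe <- pmax(phi, .Machine$double.eps)
  kx <- v[1L, ] / safe
  ky <- v[2L, ] / safe
  kz <- v[3L, ] / safe
  c1 <- cos(phi)
  s1 <- sin(phi)
  omc <- 1 - c1
  out <- array(0, dim = c(3L, 3L, n))
  out[1L, 1L, ] <- c1 + kx * kx * omc
  out[1L, 2L, ] <- kx * ky * omc - kz * s1
  out[1L, 3L, ] <- kx * kz * omc + ky * s1
  out[2L, 1L, ] <- ky * kx * omc + kz * s1
  out[2L, 2L, ] <- c1 + ky * ky * omc
  out[2L, 3L, ] <- ky * kz * omc - kx * s1
  out[3L, 1L, ] <- kz * kx * omc - ky * s1
  out[3L, 2L, ] <- kz * ky * omc + kx * s1
  out[3L, 3L, ] <- c1 + kz * kz * omc
  out
}

#' Inverse Rodrigues map, batched, principal branch
#'
#' Returns rotation vectors with norm in [0, pi]. Near angle pi the skew part
#' degenerates, so the axis is recovered from the symmetric part
#' (R + I)/2 = k k^T at phi = pi; the sign tie-break there keeps the V
#' component non-negative (then U, then Q).
#'
#' @param r 3 x 3 x n array of rotation matrices
#' @return 3 x n matrix
#' @noRd
vec_from_rotm <- function(r) {
  n <- dim(r)[3L]
  tr <- r[1L, 1L, ] + r[2L, 2L, ] + r[3L, 3L, ]
  # Skew part gives axis * sin(phi)
  ax <- 0.5 * (r[3L, 2L, ] - r[2L, 3L, ])
  ay <- 0.5 * (r[1L, 3L, ] - r[3L, 1L, ])
  az <- 0.5 * (r[2L, 1L, ] - r[1L, 2L, ])
  s <- sqrt(pmin(pmax(ax^2 + ay^2 + az^2, 0), 1))
  c <- pmax(pmin((tr - 1) / 2, 1), -1)
  phi <- atan2(s, c)
  out <- matrix(0, nrow = 3L, ncol = n)
  reg <- s > 1e-7
  if (any(reg)) {
    f <- phi[reg] / s[reg]
    out[1L, reg] <- ax[reg] * f
    out[2L, reg] <- ay[reg] * f
    out[3L, reg] <- az[reg] * f
  }
  # Near phi = pi: use sqrt of diagonal of (R + I)/2, signs from off-diagonals.
  deg <- !reg & (c < 0)
  if (any(deg)) {
    idx <- which(deg)
    for (i in idx) {
      m <- r[, , i]
      kk <- (m + diag(3)) / 2
      k <- sqrt(pmax(diag(kk), 0))
      # Fix relative signs from the largest component
      j <- which.max(k)
      if (k[j] > 0) {
        sgn <- kk[j, ] / (k[j] * pmax(k, .Machine$double.eps))
        k <- k * sign(ifelse(seq_len(3) == j, 1, sgn))
      }
      # Tie-break: V >= 0, else U >= 0, else Q >= 0
      if (k[3L] < 0 || (k[3L] == 0 && (k[2L] < 0 || (k[2L] == 0 && k[1L] < 0)))) {
        k <- -k
      }
      out[, i] <- k * phi[i]
    }
  }
  out
}

#' Nearest rotation matrix (orthogonal Procrustes projection)
#'
#' Projects a single 3x3 matrix onto SO(3) via SVD, enforcing det = +1.
#'
#' @param m numeric 3x3 matrix
#' @return 3x3 rotation matrix
#' @export
#' @examples
#' nearest_rotation(diag(3) + 1e-3 * matrix(rnorm(9), 3))
nearest_rotation <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Rotation about the V (circular) Stokes axis
#' @param angle radians
#' @noRd
rot_about_v <- function(angle) {
  c1 <- cos(angle)
  s1 <- sin(angle)
  matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), nrow = 3L)
}

# ---------------------------------------------------------------------------
# Batched 2x2 complex (Jones) algebra. A stack is a list with complex vectors
# a, b, c, d laid out as [[a, b], [c, d]]; used by the forward simulator where
# the field-level model lives in SU(2).

#' @noRd
j2_stack <- function(a, b, c, d) list(a = a, b = b, c = c, d = d)

#' @noRd
j2_identity <- function(n) {
  one <- rep(1 + 0i, n)
  zero <- rep(0 + 0i, n)
  j2_stack(one, zero, zero, one)
}

#' @noRd
j2_mult <- function(x, y) {
  j2_stack(
    a = x$a * y$a + x$b * y$c,
    b = x$a * y$b + x$b * y$d,
    c = x$c * y$a + x$d * y$c,
    d = x$c * y$b + x$d * y$d
  )
}

#' @noRd
j2_t <- function(x) j2_stack(a = x$a, b = x$c, c = x$b, d = x$d)

#' Batched linear retarder stack in SU(2)
#'
#' exp(-i phi/2 (cos 2 theta sigma1 + sin 2 theta sigma2)) elementwise.
#' @param phi,theta numeric vectors (recycled to common length)
#' @noRd
j2_linear_retarder <- function(phi, theta) {
  nn <- max(length(phi), length(theta))
  phi <- rep_len(phi, nn)
  theta <- rep_len(theta, nn)
  ch <- cos(phi / 2)
  sh <- sin(phi / 2)
  r1 <- cos(2 * theta)
  r2 <- sin(2 * theta)
  j2_stack(
    a = complex(real = ch, imaginary = -sh * r1),
    b = complex(real = 0, imaginary = -sh * r2),
    c = complex(real = 0, imaginary = -sh * r2),
    d = complex(real = ch, imaginary = sh * r1)
  )
}

#' Apply a Jones stack to a fixed Jones vector, batched
#' @param x j2 stack, e length-2 complex
#' @return list(ex, ey) complex vectors
#' @noRd
j2_apply <- function(x, e) {
  list(
    ex = x$a * e[1L] + x$b * e[2L],
    ey = x$c * e[1L] + x$d * e[2L]
  )
}

#' Single-matrix helper: j2 stack from one 2x2 complex matrix
#' @noRd
j2_from_matrix <- function(m, n = 1L) {
  j2_stack(
    a = rep(m[1L, 1L], n), b = rep(m[1L, 2L], n),
    c = rep(m[2L, 1L], n), d = rep(m[2L, 2L], n)
  )
}

#' Stokes parameters of a batch of Jones field vectors
#'
#' Convention: Q = |Ex|^2 - |Ey|^2, U = 2 Re(conj(Ex) Ey),
#' V = 2 Im(conj(Ex) Ey).
#' @param ex,ey complex vectors
#' @return list(i, q, u, v) numeric vectors
#' @noRd
stokes_from_field <- function(ex, ey) {
  px <- Re(ex * Conj(ex))
  py <- Re(ey * Conj(ey))
  cr <- Conj(ex) * ey
  list(i = px + py, q = px - py, u = 2 * Re(cr), v = 2 * Im(cr))
}

#' Separable box filter with shrinking edge windows
#'
#' Moving average over a (rows x cols) window; near edges the window shrinks
#' and the mean is taken over the available samples, so no energy is invented.
#' @param m numeric matrix
#' @param k integer length-2, c(row window, col window), odd
#' @noRd
box_filter2 <- function(m, k) {
  k <- as.integer(rep_len(k, 2L))
  if (any(k < 1L)) stop("box filter window must be >= 1")
  if (any(k > dim(m))) stop("box filter window exceeds image size")
  out <- m
  ones <- matrix(1, nrow(m), ncol(m))
  if (k[1L] > 1L) {
    out <- apply_box_1d(out, k[1L])
    ones <- apply_box_1d(ones, k[1L])
  }
  if (k[2L] > 1L) {
    out <- t(apply_box_1d(t(out), k[2L]))
    ones <- t(apply_box_1d(t(ones), k[2L]))
  }
  out / ones
}

#' Column-wise running sum over window k (rows direction)
#' @noRd
apply_box_1d <- function(m, k) {
  h <- (k - 1L) %/% 2L
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(m))
  n <- nrow(m)
  upper <- pmin(seq_len(n) + h, n)
  lower <- seq_len(n) - h - 1L
  top <- cs[upper, , drop = FALSE]
  bot <- matrix(0, n, ncol(m))
  pos <- lower >= 1L
  if (any(pos)) bot[pos, ] <- cs[lower[pos], , drop = FALSE]
  top - bot
}
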