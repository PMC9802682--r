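# Direct per-layer reference solver. Used to validate the batched layer
# peeling: it walks the same recursion but solves every layer by direct
# complex 2x2 algebra - eigendecomposition of the local round trip rather
# than the Rodrigues rotation-vector formulas - so the two routes share no
# numerical code path.

#' Direct per-layer solver for one A-line (reference implementation)
#'
#' Given the sequence of cumulative round-trip Jones matrices of a single
#' A-line, solves each layer by direct matrix algebra: N_m = T_m T_(m-1)^-1
#' is un-conjugated with the transpose of the accumulated single-pass
#' product, then the local retarder's retardation and axis are read off its
#' eigendecomposition (eigenvalues exp(-/+ i phi/2), fast-axis eigenvector's
#' Stokes vector). Scales linearly and is intended for validation, not
#' production use; [peel_layers()] is the batched equivalent.
#'
#' @param roundtrips list of `unitary_jones`, cumulative round trips
#'   T_1 ... T_M of one A-line
#' @param delta_z depth pixel, micrometers
#' @param lambda_c center wavelength, nm
#' @return list with numeric vectors `phi` (single-pass per-layer
#'   retardation, radians), `theta` (radians in `[-pi/2, pi/2)`), `dn`
#' @export
solve_layers_direct <- function(roundtrips, delta_z, lambda_c = 1300) {
  m_tot <- length(roundtrips)
  phi_out <- numeric(m_tot)
  theta_out <- numeric(m_tot)
  v_single <- diag(2) + 0i  # accumulated one-way product
  t_prev <- diag(2) + 0i
  for (m in seq_len(m_tot)) {
    t_m <- unclass(roundtrips[[m]])
    n_m <- t_m %*% solve(t_prev)
    tv <- t(v_single)
    l2 <- solve(tv) %*% n_m %*% tv
    # det-normalize on the principal branch
    l2 <- l2 / sqrt(l2[1L, 1L] * l2[2L, 2L] - l2[1L, 2L] * l2[2L, 1L])
    eg <- eigen(l2)
    args <- Arg(eg$values)
    k <- which.min(args)  # eigenvalue exp(-i phi2/2), phi2 in [0, 2 pi)
    phi2 <- -2 * args[k]
    if (phi2 > pi) {
      # principal branch: flip to the other eigenvector
      k <- 3L - k
      phi2 <- -2 * args[k]
      if (phi2 < 0) phi2 <- phi2 + 2 * pi  # defensive; not expected
    }
    ev <- eg$vectors[, k]
    axis <- stokes_state(ev)
    kvec <- axis[2:4] / axis[1L]
    vec2 <- phi2 * kvec
    # linear-eigenstate projection, halve for single pass
    q <- vec2[1L] / 2
    u <- vec2[2L] / 2
    phi_out[m] <- sqrt(q^2 + u^2)
    theta_out[m] <- if (phi_out[m] == 0) 0 else {
      wrap_axis_angle(0.5 * atan2(u, q))
    }
    d_j <- unclass(linear_retarder(phi_out[m], theta_out[m]))
    v_single <- d_j %*% v_single
    t_prev <- t_m
  }
  list(
    phi = phi_out, theta = theta_out,
    dn = phi_out * (lambda_c * 1e-3) / (2 * pi * delta_z)
  )
}
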