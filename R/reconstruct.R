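# Depth-resolved reconstruction. The pipeline mirrors the measurement model:
#
#   1. estimate_rotations: per spectral bin, the SO(3) rotation mapping the
#      two launched Stokes states to the measured (filtered, normalized)
#      output states at every pixel.
#   2. symmetrize_system: per bin, estimate static corrections such that the
#      corrected round-trip rotations have axes in the QU plane (linearly
#      polarized eigenstates) and the peeled local layers are linear
#      retarders; this removes the static system transmissions up to a
#      global optic-axis offset.
#   3. compensate_catheter: halve the ball-lens round trip and sandwich its
#      inverse around the measurement to isolate the sample round trip
#      (per bin; identity for benchtop raster scans).
#   4. fuse_spectral_bins: align the per-bin axis frames and average the
#      rotation vectors.
#   5. peel_layers: iterative layer peeling of the cumulative round trips
#      into local birefringence and optic-axis orientation.
#   6. compute_dop / apply_mask / reference_axis: validity masking and
#      global axis referencing.

#' Reconstruction configuration
#'
#' @param stokes_kernel averaging window (depth px, A-lines) applied to the
#'   measured Stokes components before rotation estimation
#' @param dop_kernel averaging window (depth px, A-lines) for the degree of
#'   polarization
#' @param local_kernel averaging window (depth px, A-lines) applied to the
#'   extracted doubled local rotation vectors before conversion to
#'   birefringence and axis (validity-weighted vector mean); `c(1, 1)`
#'   disables it
#' @param dop_threshold DOP below which pixels are masked, in [0, 1]
#' @param axis_reference list: `mode` one of "none", "manual", "sheath";
#'   `offset` (radians) for manual mode; `known` (radians) and optional
#'   `rows` (depth indices of the sheath) for sheath mode
#' @param symmetrize logical: estimate and apply the static system correction
#' @param sym_sample approximate number of A-lines used by the correction fit
#' @param sym_depth_window contiguous depth window used by the local-layer
#'   linearity objective
#' @param sym_restarts extra random restarts if the fit residual stays high
#' @param wrap_tol local doubled retardation within this of pi raises the
#'   wrap flag
#' @param min_valid minimum number of valid pixels required by the fit
#' @return object of class `psoct_reconconfig`
#' @export
recon_config <- function(stokes_kernel = c(5L, 5L),
                         local_kernel = c(5L, 5L),
                         dop_kernel = c(5L, 5L),
                         dop_threshold = 0.7,
                         axis_reference = list(mode = "none"),
                         symmetrize = TRUE,
                         sym_sample = 24L,
                         sym_depth_window = 96L,
                         sym_restarts = 2L,
                         wrap_tol = 1e-4,
                         min_valid = 50L) {
  if (dop_threshold < 0 || dop_threshold > 1) {
    stop("dop_threshold must be in [0, 1]")
  }
  structure(
    list(
      stokes_kernel = as.integer(rep_len(stokes_kernel, 2L)),
      local_kernel = as.integer(rep_len(local_kernel, 2L)),
      dop_kernel = as.integer(rep_len(dop_kernel, 2L)),
      dop_threshold = dop_threshold,
      axis_reference = axis_reference,
      symmetrize = isTRUE(symmetrize),
      sym_sample = as.integer(sym_sample),
      sym_depth_window = as.integer(sym_depth_window),
      sym_restarts = as.integer(sym_restarts),
      wrap_tol = wrap_tol,
      min_valid = as.integer(min_valid)
    ),
    class = "psoct_reconconfig"
  )
}

#' Launched Stokes unit vectors of the two input states
#' @noRd
input_stokes <- function(config) {
  vapply(config$input_states, function(e) {
    s <- stokes_state(e)
    as.numeric(s[2:4] / s[1L])
  }, numeric(3L))
}

#' Estimate per-pixel Stokes rotations
#'
#' For every spectral bin, computes the rotation that maps the two launched
#' Stokes states onto the measured output states. The measured Stokes
#' components are box-filtered over `stokes_kernel`, normalized, brought to
#' an exactly orthonormal pair by symmetric orthonormalization (the nearest
#' rotation for two equally weighted states), and completed by the cross
#' product. Zero-intensity pixels are flagged invalid.
#'
#' @param tomogram `psoct_tomogram`
#' @param config `psoct_reconconfig`
#' @return list with `rotations` (list per bin of 3 x 3 x n arrays, pixel
#'   index = aline + n_alines * (depth - 1)), `valid` matrix, and per-bin
#'   ball-lens rotations (helical)
#' @export
estimate_rotations <- function(tomogram, config = recon_config()) {
  geom <- tomogram$geometry
  na <- geom$n_alines
  nz <- geom$depth_pixels
  nb <- dim(tomogram$stokes)[4L]
  sin_ <- input_stokes(tomogram$config)
  s3 <- cross3(sin_[, 1L], sin_[, 2L])
  sbasis <- cbind(sin_[, 1L], sin_[, 2L], s3)
  k <- config$stokes_kernel  # (depth, alines)
  valid <- matrix(TRUE, na, nz)
  rots <- vector("list", nb)
  ball <- if (is.null(tomogram$ball_lens)) NULL else vector("list", nb)
  for (b in seq_len(nb)) {
    ob <- vector("list", 2L)
    for (s in 1:2) {
      q <- box_filter2(tomogram$stokes[, , s, b, 2L], c(k[2L], k[1L]))
      u <- box_filter2(tomogram$stokes[, , s, b, 3L], c(k[2L], k[1L]))
      v <- box_filter2(tomogram$stokes[, , s, b, 4L], c(k[2L], k[1L]))
      i <- box_filter2(tomogram$stokes[, , s, b, 1L], c(k[2L], k[1L]))
      nrm <- sqrt(q^2 + u^2 + v^2)
      ok <- nrm > 1e-12 & i > 1e-12
      valid <- valid & ok
      nrm[!ok] <- 1
      ob[[s]] <- rbind(as.numeric(q / nrm), as.numeric(u / nrm),
                       as.numeric(v / nrm))
    }
    rots[[b]] <- triad_rotation(ob[[1L]], ob[[2L]], sbasis)
    if (!is.null(ball)) {
      bo <- vector("list", 2L)
      for (s in 1:2) {
        q <- tomogram$ball_lens[, s, b, 2L]
        u <- tomogram$ball_lens[, s, b, 3L]
        v <- tomogram$ball_lens[, s, b, 4L]
        nrm <- pmax(sqrt(q^2 + u^2 + v^2), 1e-12)
        bo[[s]] <- rbind(q / nrm, u / nrm, v / nrm)
      }
      ball[[b]] <- triad_rotation(bo[[1L]], bo[[2L]], sbasis)
    }
  }
  list(rotations = rots, ball = ball, valid = valid,
       n_alines = na, depth_pixels = nz, mode = geom$mode)
}

#' @noRd
cross3 <- function(a, b) {
  if (is.null(dim(a))) {
    return(c(
      a[2L] * b[3L] - a[3L] * b[2L],
      a[3L] * b[1L] - a[1L] * b[3L],
      a[1L] * b[2L] - a[2L] * b[1L]
    ))
  }
  rbind(
    a[2L, ] * b[3L, ] - a[3L, ] * b[2L, ],
    a[3L, ] * b[1L, ] - a[1L, ] * b[3L, ],
    a[1L, ] * b[2L, ] - a[2L, ] * b[1L, ]
  )
}

#' Rotation from two measured orthonormal-target states, batched
#'
#' Symmetric orthonormalization: u = (o1 + o2)/|.|, w = (o1 - o2)/|.| are
#' exactly orthogonal, and a1 = (u + w)/sqrt(2), a2 = (u - w)/sqrt(2) is the
#' orthonormal pair nearest to (o1, o2) with equal weights.
#' @param o1,o2 3 x n matrices; sbasis fixed 3x3 of launched states
#' @noRd
triad_rotation <- function(o1, o2, sbasis) {
  u <- o1 + o2
  u <- u / rep(pmax(sqrt(colSums(u^2)), 1e-12), each = 3L)
  w <- o1 - o2
  w <- w / rep(pmax(sqrt(colSums(w^2)), 1e-12), each = 3L)
  a1 <- (u + w) / sqrt(2)
  a2 <- (u - w) / sqrt(2)
  a3 <- cross3(a1, a2)
  n <- ncol(o1)
  m <- array(0, dim = c(3L, 3L, n))
  m[, 1L, ] <- a1
  m[, 2L, ] <- a2
  m[, 3L, ] <- a3
  # R = [a1 a2 a3] %*% t(sbasis)
  rotm_rmult(m, t(sbasis))
}

#' Asymmetry energy: squared deviation from QU-plane axis form
#' @noRd
asym_energy <- function(r) {
  mean(
    (r[1L, 2L, ] - r[2L, 1L, ])^2 +
    (r[1L, 3L, ] + r[3L, 1L, ])^2 +
    (r[2L, 3L, ] + r[3L, 2L, ])^2
  )
}

#' Estimate the static system correction for one spectral bin
#'
#' Finds left/right SO(3) corrections (G_out, G_in) such that the corrected
#' rotations G_out R G_in satisfy the round-trip symmetry (axis in the QU
#' plane) and, to fix the residual gauge, such that the local layers peeled
#' from the corrected (and, for helical scans, catheter-compensated) stack
#' are linear retarders. The remaining ambiguity is a global rotation about
#' the V axis, i.e. a constant optic-axis offset, resolved later by
#' [reference_axis()].
#'
#' @param rarr 3 x 3 x (na * nz) measured rotations (aline-fastest)
#' @param ballarr per-A-line reference-reflection rotations or NULL
#' @param valid logical matrix [na, nz]
#' @param na,nz dimensions
#' @param mode "raster" or "helical": for raster the corrected surface
#'   reference must equal the identity (it carries no retardance), which
#'   anchors the gauge; for helical the ball lens carries the unknown
#'   catheter round trip, and the gauge is anchored by requiring the peeled
#'   local layers after catheter compensation to be linear retarders
#' @param config `psoct_reconconfig`
#' @return list(G_out, G_in, residual_asym, residual_local)
#' @export
fit_system_correction <- function(rarr, ballarr, valid, na, nz,
                                  mode = "raster",
                                  config = recon_config()) {
  if (sum(valid) < config$min_valid) {
    stop("insufficient valid pixels for the symmetrization fit")
  }
  a_idx <- unique(round(seq(1L, na, length.out = min(na, config$sym_sample))))
  nw <- min(nz, config$sym_depth_window)
  d_idx <- seq_len(nw)
  pix <- as.integer(outer(a_idx, (d_idx - 1L) * na, `+`))
  rsub <- rarr[, , pix, drop = FALSE]
  vsub <- as.numeric(valid[cbind(
    rep(a_idx, times = nw), rep(d_idx, each = length(a_idx))
  )])
  nsub <- length(a_idx)
  ballsub <- if (is.null(ballarr)) NULL else {
    ballarr[, , a_idx, drop = FALSE]
  }

  apply_corr <- function(p) {
    g_out <- rotm_from_vec(matrix(p[1:3], ncol = 1L))[, , 1L]
    g_in <- rotm_from_vec(matrix(p[4:6], ncol = 1L))[, , 1L]
    rotm_rmult(rotm_lmult(g_out, rsub), g_in)
  }
  f_asym <- function(p) {
    r <- apply_corr(p)
    mean(vsub * (
      (r[1L, 2L, ] - r[2L, 1L, ])^2 +
      (r[1L, 3L, ] + r[3L, 1L, ])^2 +
      (r[2L, 3L, ] + r[3L, 2L, ])^2
    ))
  }
  f_anchor <- function(p) {
    if (is.null(ballsub)) {
      return(0)
    }
    g_out <- rotm_from_vec(matrix(p[1:3], ncol = 1L))[, , 1L]
    g_in <- rotm_from_vec(matrix(p[4:6], ncol = 1L))[, , 1L]
    bc <- rotm_rmult(rotm_lmult(g_out, ballsub), g_in)
    idm <- rotm_identity(dim(bc)[3L])
    mean((bc - idm)^2)
  }
  # For raster data the tissue-free surface reference carries no retardance,
  # so its corrected rotation must be the identity: this anchors the gauge
  # left open by the symmetry constraint. For helical data no anchor is
  # needed here: the ball-lens compensation forces the residual gauge to a
  # per-A-line rotation about V (G tau(G) = I), which leaves birefringence
  # untouched and is removed by sheath referencing of the axis.
  f_joint <- if (mode != "helical" && !is.null(ballsub)) {
    function(p) f_asym(p) + f_anchor(p)
  } else {
    f_asym
  }

  run_fit <- function(p0) {
    fit1 <- stats::optim(p0, f_asym,
      method = "BFGS",
      control = list(maxit = 400, reltol = 1e-16)
    )
    fit2 <- stats::optim(fit1$par, f_joint,
      method = "BFGS",
      control = list(maxit = 400, reltol = 1e-16)
    )
    # Nelder-Mead polish helps when BFGS stalls on a flat gauge direction
    fit3 <- stats::optim(fit2$par, f_joint,
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-16)
    )
    if (fit3$value < fit2$value) fit3 else fit2
  }

  best <- run_fit(rep(0, 6L))
  # Noise sets the attainable floor; restart only while the fit looks stuck
  # well above it relative to the uncorrected objective.
  floor_tol <- max(1e-10, 1e-3 * f_joint(rep(0, 6L)))
  tries <- 0L
  while (best$value > floor_tol && tries < config$sym_restarts) {
    tries <- tries + 1L
    p0 <- stats::rnorm(6L, sd = 1.0)
    cand <- run_fit(p0)
    if (cand$value < best$value) best <- cand
  }
  g_out <- rotm_from_vec(matrix(best$par[1:3], ncol = 1L))[, , 1L]
  g_in <- rotm_from_vec(matrix(best$par[4:6], ncol = 1L))[, , 1L]
  list(
    G_out = g_out, G_in = g_in,
    residual_asym = f_asym(best$par),
    residual_anchor = f_anchor(best$par)
  )
}

#' Apply a known static system correction
#'
#' When the static system transmissions A (out) and B (in) are known -
#' for instance in a simulation study - the measured rotations can be
#' corrected directly instead of fitting: corrected = R_A^-1 R R_B^-1.
#'
#' @param est output of [estimate_rotations()]
#' @param a,b `unitary_jones` system matrices, or lists of them (one per
#'   spectral bin)
#' @return `est` with corrected rotations (and reference-reflection
#'   rotations)
#' @export
apply_system_correction <- function(est, a, b) {
  nb <- length(est$rotations)
  if (inherits(a, "unitary_jones")) a <- replicate(nb, a, simplify = FALSE)
  if (inherits(b, "unitary_jones")) b <- replicate(nb, b, simplify = FALSE)
  for (bin in seq_len(nb)) {
    ga <- t(su2_to_so3(a[[bin]]))
    gb <- t(su2_to_so3(b[[bin]]))
    est$rotations[[bin]] <- rotm_rmult(rotm_lmult(ga, est$rotations[[bin]]), gb)
    if (!is.null(est$ball)) {
      est$ball[[bin]] <- rotm_rmult(rotm_lmult(ga, est$ball[[bin]]), gb)
    }
  }
  est
}

#' Symmetrize the measured rotations
#'
#' Applies [fit_system_correction()] per spectral bin and returns the
#' corrected rotation stacks (and corrected ball-lens rotations).
#'
#' @param est output of [estimate_rotations()]
#' @param config `psoct_reconconfig`
#' @return `est` with corrected rotations plus per-bin `corrections`
#' @export
symmetrize_system <- function(est, config = recon_config()) {
  nb <- length(est$rotations)
  corr <- vector("list", nb)
  for (b in seq_len(nb)) {
    fit <- fit_system_correction(
      est$rotations[[b]],
      if (is.null(est$ball)) NULL else est$ball[[b]],
      est$valid, est$n_alines, est$depth_pixels,
      mode = est$mode %||% "raster", config = config
    )
    est$rotations[[b]] <-
      rotm_rmult(rotm_lmult(fit$G_out, est$rotations[[b]]), fit$G_in)
    if (!is.null(est$ball)) {
      est$ball[[b]] <-
        rotm_rmult(rotm_lmult(fit$G_out, est$ball[[b]]), fit$G_in)
    }
    corr[[b]] <- fit
  }
  est$corrections <- corr
  est
}

#' Compensate the rotating catheter using the ball-lens reflection
#'
#' The ball-lens round trip equals the catheter round trip; its retarder
#' square root H is removed by sandwiching every depth: sample round trip =
#' H^-1 measured H^-1. Applied per spectral bin, before bin fusion, because
#' the per-bin axis frames only become depth-independent after compensation.
#' For raster (benchtop) data the operation is the identity. A-lines whose
#' ball-lens retardation is within `branch_tol` of pi (square-root branch
#' ambiguity) get H interpolated from neighboring A-lines and are flagged.
#'
#' @param est output of [symmetrize_system()] (or [estimate_rotations()])
#' @param branch_tol branch-ambiguity guard, radians
#' @return `est` with compensated per-bin rotations and `ball_flagged`
#' @export
compensate_catheter <- function(est, branch_tol = 1e-3) {
  if (is.null(est$ball) || !identical(est$mode, "helical")) {
    est$ball_flagged <- integer(0)
    return(est)
  }
  na <- est$n_alines
  nz <- est$depth_pixels
  flagged <- integer(0)
  for (b in seq_along(est$rotations)) {
    bv <- vec_from_rotm(est$ball[[b]])
    ang <- sqrt(colSums(bv^2))
    bad <- which(ang > pi - branch_tol)
    if (length(bad) > 0L) {
      good <- setdiff(seq_len(na), bad)
      for (j in bad) {
        # nearest valid neighbors, circular in the A-line index
        d <- pmin(abs(good - j), na - abs(good - j))
        nbr <- good[order(d)[seq_len(min(2L, length(good)))]]
        bv[, j] <- rowMeans(bv[, nbr, drop = FALSE])
      }
      flagged <- union(flagged, bad)
    }
    h <- rotm_from_vec(bv / 2)
    ht <- rotm_t(h)
    for (m in seq_len(nz)) {
      idx <- (m - 1L) * na + seq_len(na)
      est$rotations[[b]][, , idx] <- rotm_mult(
        rotm_mult(ht, est$rotations[[b]][, , idx, drop = FALSE]), ht
      )
    }
  }
  est$compensated <- TRUE
  est$ball_flagged <- sort(flagged)
  est
}

#' Fuse spectral bins
#'
#' Each symmetrized bin carries its own unknown optic-axis offset. Bins are
#' aligned to the middle bin by the weighted circular mean of the QU-azimuth
#' difference of their cumulative rotation vectors - per A-line for helical
#' scans (the per-bin frames differ by per-A-line rotations about V after
#' catheter compensation), globally for raster scans - then the aligned
#' rotation vectors are averaged and re-expressed as rotations.
#'
#' @param est output of [compensate_catheter()] (or [symmetrize_system()] /
#'   [estimate_rotations()] for raster data)
#' @return list with fused `rotations` (single 3 x 3 x n array), `valid`,
#'   and the alignment angles `offsets`
#' @export
fuse_spectral_bins <- function(est) {
  nb <- length(est$rotations)
  mode <- est$mode %||% "raster"
  na <- est$n_alines
  nz <- est$depth_pixels
  if (nb == 1L) {
    return(list(
      rotations = est$rotations[[1L]],
      valid = est$valid, offsets = 0,
      n_alines = na, depth_pixels = nz,
      mode = mode, ball_flagged = est$ball_flagged %||% integer(0)
    ))
  }
  ref <- (nb + 1L) %/% 2L
  vref <- vec_from_rotm(est$rotations[[ref]])
  wref <- vref[1L, ]^2 + vref[2L, ]^2
  vs <- as.numeric(est$valid)
  per_aline <- identical(mode, "helical")
  offsets <- vector("list", nb)
  vsum <- NULL
  for (b in seq_len(nb)) {
    vb <- vec_from_rotm(est$rotations[[b]])
    if (b != ref) {
      wb <- vb[1L, ]^2 + vb[2L, ]^2
      w <- sqrt(wb * wref) * vs
      dot <- w * (vb[1L, ] * vref[1L, ] + vb[2L, ] * vref[2L, ])
      crs <- w * (vb[1L, ] * vref[2L, ] - vb[2L, ] * vref[1L, ])
      # a bin can land in the mirrored axis frame; detect it by comparing
      # the alignment resultants of the direct and reflected hypotheses
      dot_f <- w * (vb[1L, ] * vref[1L, ] - vb[2L, ] * vref[2L, ])
      crs_f <- w * (vb[1L, ] * vref[2L, ] + vb[2L, ] * vref[1L, ])
      if (sum(dot_f)^2 + sum(crs_f)^2 > sum(dot)^2 + sum(crs)^2) {
        vb[2L, ] <- -vb[2L, ]
        vb[3L, ] <- -vb[3L, ]
        dot <- dot_f
        crs <- crs_f
      }
      if (per_aline) {
        dd <- rowSums(matrix(dot, na, nz))
        cc <- rowSums(matrix(crs, na, nz))
        delta <- rep(atan2(cc, dd), times = nz)
      } else {
        delta <- rep(atan2(sum(crs), sum(dot)), ncol(vb))
      }
      offsets[[b]] <- delta[seq_len(if (per_aline) na else 1L)]
      cs <- cos(delta)
      sn <- sin(delta)
      vb <- rbind(
        cs * vb[1L, ] - sn * vb[2L, ],
        sn * vb[1L, ] + cs * vb[2L, ],
        vb[3L, ]
      )
    } else {
      offsets[[b]] <- 0
    }
    vsum <- if (is.null(vsum)) vb else vsum + vb
  }
  list(
    rotations = rotm_from_vec(vsum / nb),
    valid = est$valid, offsets = offsets,
    n_alines = na, depth_pixels = nz,
    mode = mode, ball_flagged = est$ball_flagged %||% integer(0)
  )
}

#' Iterative layer peeling
#'
#' Recursively extracts the per-pixel local retarder from the cumulative
#' round-trip rotations: with accumulated single-pass V (V0 = identity),
#' N_m = T_m T_(m-1)^-1 is the round trip of layer m conjugated by the
#' transpose image of V_(m-1); un-conjugating yields the doubled local
#' rotation vector, which is projected onto linear form, halved, and
#' converted to birefringence and axis angle.
#'
#' @param fused output of [fuse_spectral_bins()]
#' @param delta_z depth pixel, micrometers
#' @param lambda_c center wavelength, nm
#' @param config `psoct_reconconfig`
#' @return object of class `psoct_polmap` with matrices `dn`, `theta`
#'   `[n_alines, depth_pixels]`, `wrap_flag`, and the local V components in
#'   `v_residual`
#' @export
peel_layers <- function(fused, delta_z, lambda_c = 1300,
                        config = recon_config()) {
  na <- fused$n_alines
  nz <- fused$depth_pixels
  scale <- (lambda_c * 1e-3) / (2 * pi * delta_z)
  q2 <- matrix(0, na, nz)
  u2 <- matrix(0, na, nz)
  vres <- matrix(0, na, nz)
  wrap <- matrix(FALSE, na, nz)
  rv <- rotm_identity(na)
  tprev <- rotm_identity(na)
  for (m in seq_len(nz)) {
    tm <- fused$rotations[, , (m - 1L) * na + seq_len(na), drop = FALSE]
    nm <- rotm_mult(tm, rotm_t(tprev))
    w <- rotm_tau(rv)
    l2 <- rotm_mult(rotm_mult(rotm_t(w), nm), w)
    v2 <- vec_from_rotm(l2)
    ang2 <- sqrt(colSums(v2^2))
    wrap[, m] <- ang2 > pi - config$wrap_tol
    vres[, m] <- v2[3L, ]
    q2[, m] <- v2[1L, ]
    u2[, m] <- v2[2L, ]
    # the recursion always advances on the raw (projected, halved) layer
    v <- v2 / 2
    v[3L, ] <- 0
    rv <- rotm_mult(rotm_from_vec(v), rv)
    tprev <- tm
  }
  # validity-weighted spatial average of the doubled local vectors
  lk <- config$local_kernel
  if (any(lk > 1L)) {
    wgt <- if (is.null(fused$valid)) matrix(1, na, nz) else fused$valid * 1
    den <- box_filter2(wgt, c(lk[2L], lk[1L]))
    den[den == 0] <- 1
    q2 <- box_filter2(q2 * wgt, c(lk[2L], lk[1L])) / den
    u2 <- box_filter2(u2 * wgt, c(lk[2L], lk[1L])) / den
  }
  phi <- sqrt(q2^2 + u2^2) / 2
  dn <- phi * scale
  theta <- wrap_axis_angle(0.5 * atan2(u2, q2))
  theta[phi == 0] <- 0
  structure(
    list(
      dn = dn, theta = theta, wrap_flag = wrap, v_residual = vres,
      valid = fused$valid, delta_z = delta_z, lambda_c = lambda_c
    ),
    class = "psoct_polmap"
  )
}

#' @export
print.psoct_polmap <- function(x, ...) {
  cat(sprintf(
    "<psoct_polmap> %d A-lines x %d depth px; dn range [%g, %g]%s\n",
    nrow(x$dn), ncol(x$dn), min(x$dn), max(x$dn),
    if (!is.null(x$mask)) sprintf("; %.1f%% masked", 100 * mean(!x$mask))
    else ""
  ))
  invisible(x)
}

#' Degree of polarization
#'
#' Per input state, DOP = |mean (Q, U, V)| / mean I over the averaging
#' kernel; the returned DOP is the mean over the two states. Spectral bins
#' are summed before averaging.
#'
#' @param tomogram `psoct_tomogram`
#' @param config `psoct_reconconfig`
#' @return matrix `[n_alines, depth_pixels]` in [0, 1] (up to noise)
#' @export
compute_dop <- function(tomogram, config = recon_config()) {
  k <- config$dop_kernel  # (depth, alines)
  dims <- dim(tomogram$stokes)
  if (k[1L] > dims[2L] || k[2L] > dims[1L]) {
    stop("DOP kernel larger than the image")
  }
  nb <- dims[4L]
  dop <- 0
  for (s in 1:2) {
    q <- u <- v <- i <- 0
    for (b in seq_len(nb)) {
      i <- i + tomogram$stokes[, , s, b, 1L]
      q <- q + tomogram$stokes[, , s, b, 2L]
      u <- u + tomogram$stokes[, , s, b, 3L]
      v <- v + tomogram$stokes[, , s, b, 4L]
    }
    qf <- box_filter2(q, c(k[2L], k[1L]))
    uf <- box_filter2(u, c(k[2L], k[1L]))
    vf <- box_filter2(v, c(k[2L], k[1L]))
    if_ <- box_filter2(i, c(k[2L], k[1L]))
    dop <- dop + sqrt(qf^2 + uf^2 + vf^2) / pmax(if_, 1e-12)
  }
  dop / 2
}

#' Apply the DOP validity mask
#'
#' @param map `psoct_polmap`
#' @param dop matrix from [compute_dop()]
#' @param config `psoct_reconconfig`
#' @return `map` with `dop`, logical `mask` (TRUE = valid) and masked
#'   pixels zeroed in `dn` for display; flags are preserved
#' @export
apply_mask <- function(map, dop, config = recon_config()) {
  mask <- dop >= config$dop_threshold
  if (!is.null(map$valid)) mask <- mask & map$valid
  map$dop <- dop
  map$mask <- mask
  map$dn_unmasked <- map$dn
  map$dn[!mask] <- 0
  map
}

#' Reference the optic-axis orientation
#'
#' The reconstruction recovers theta up to a global offset (and, because a
#' round-trip measurement cannot distinguish a frame from its mirror image,
#' possibly a global sign flip). Modes: "none" leaves the map untouched;
#' "manual" subtracts a given offset; "sheath" estimates the offset as the
#' circular mean axis over the sheath depth rows (known orientation `known`,
#' default 0 = longitudinal) and subtracts it. Offsets act modulo pi; double
#' application with the same observed reference is idempotent.
#'
#' A mirror-symmetric reference (such as the sheath at 0 degrees) cannot
#' resolve the sign flip. Supplying `flip_check = list(rows =, known =)`
#' inside `axis_reference` - the depth rows of a second structure of known
#' orientation (`known` a scalar or a `[n_alines, length(rows)]` matrix) -
#' tests both hypotheses and keeps the one with the smaller circular
#' residual against that structure.
#'
#' @param map `psoct_polmap`
#' @param config `psoct_reconconfig` (`axis_reference` field)
#' @param sheath_rows depth rows of the sheath signal (overrides config)
#' @return `map` with referenced `theta`, the applied `axis_offset`, and
#'   `axis_flipped`
#' @export
reference_axis <- function(map, config = recon_config(), sheath_rows = NULL) {
  ref <- config$axis_reference
  mode <- ref$mode %||% "none"
  if (mode == "none") {
    map$axis_offset <- 0
    map$axis_flipped <- FALSE
    return(map)
  }
  w_all <- map$dn_unmasked %||% map$dn
  if (!is.null(map$mask)) w_all <- w_all * map$mask

  # Per-A-line offset: after catheter compensation the recovered frame can
  # carry an A-line-dependent rotation about V, so the sheath (whose axis is
  # longitudinal at every rotation angle) is read out per A-line.
  sheath_offset <- function(theta) {
    rows <- sheath_rows %||% ref$rows
    if (is.null(rows)) stop("sheath referencing requires sheath depth rows")
    known <- ref$known %||% 0
    th <- theta[, rows, drop = FALSE]
    w <- w_all[, rows, drop = FALSE]
    if (sum(w) <= 0) stop("no usable sheath signal for axis referencing")
    sn <- rowSums(w * sin(2 * th))
    cs <- rowSums(w * cos(2 * th))
    smooth <- ref$smooth %||% 1L
    if (smooth > 1L) {
      sn <- as.numeric(box_filter2(matrix(sn), c(smooth, 1L)))
      cs <- as.numeric(box_filter2(matrix(cs), c(smooth, 1L)))
    }
    obs <- 0.5 * atan2(sn, cs)
    # A-lines with no sheath signal fall back to the global mean offset
    none <- (sn == 0 & cs == 0)
    if (any(none)) {
      obs[none] <- 0.5 * atan2(sum(sn), sum(cs))
    }
    obs - known
  }

  candidates <- list(list(flip = FALSE, theta = map$theta))
  if (!is.null(ref$flip_check)) {
    candidates[[2L]] <- list(flip = TRUE, theta = wrap_axis_angle(-map$theta))
  }
  best <- NULL
  for (cand in candidates) {
    off <- if (mode == "manual") {
      ref$offset %||% 0
    } else if (mode == "sheath") {
      sheath_offset(cand$theta)
    } else {
      stop("unknown axis reference mode")
    }
    theta_ref <- wrap_axis_angle(cand$theta - off)
    score <- 0
    if (!is.null(ref$flip_check)) {
      fr <- ref$flip_check
      known <- fr$known
      th <- theta_ref[, fr$rows, drop = FALSE]
      w <- w_all[, fr$rows, drop = FALSE]
      d <- wrap_axis_angle(th - known)
      score <- sum(w * d^2) / max(sum(w), 1e-12)
    }
    if (is.null(best) || score < best$score) {
      best <- list(theta = theta_ref, off = off, flip = cand$flip,
                   score = score)
    }
  }
  map$theta <- best$theta
  map$axis_offset <- best$off
  map$axis_flipped <- best$flip
  map
}

#' Full reconstruction pipeline
#'
#' Runs rotation estimation, symmetrization, spectral-bin fusion, catheter
#' compensation, layer peeling, DOP masking and axis referencing.
#'
#' @param tomogram `psoct_tomogram`
#' @param config `psoct_reconconfig`
#' @return `psoct_polmap` with `dn`, `theta`, `dop`, `mask`
#' @export
reconstruct_tomogram <- function(tomogram, config = recon_config()) {
  est <- estimate_rotations(tomogram, config)
  if (config$symmetrize) {
    est <- symmetrize_system(est, config)
  }
  est <- compensate_catheter(est)
  fused <- fuse_spectral_bins(est)
  map <- peel_layers(
    fused, tomogram$geometry$delta_z, tomogram$config$lambda_c, config
  )
  dop <- compute_dop(tomogram, config)
  map <- apply_mask(map, dop, config)
  sheath_rows <- if (!is.null(tomogram$geometry$sheath)) {
    seq_len(tomogram$geometry$sheath$n_px)
  } else {
    NULL
  }
  map <- reference_axis(map, config, sheath_rows = sheath_rows)
  map$geometry <- tomogram$geometry
  map
}
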