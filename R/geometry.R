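# Scan geometries. Each A-line has a world-frame pose: an origin, a unit beam
# direction, and a local frame basis (e1, e2) orthogonal to the beam that
# defines the optic-axis reference: theta_local is measured from e1 toward e2.
#
# Benchtop raster: beam along +z, e1 = +x (fast galvo direction),
# e2 = +y (slow stage direction).
#
# Endoscopic helical: the probe rotates inside a rigid cannula whose axis is
# parallel to world x while being pulled back along it; the beam points
# radially outward, e1 = +x (longitudinal), e2 = circumferential, matching the
# convention of referencing the axis to the longitudinal and circumferential
# directions of the cannula surface.

#' Scan geometry constructor
#'
#' @param mode "raster" or "helical"
#' @param ... mode parameters. Raster: `n_fast`, `n_slow`, `pitch` (um,
#'   length 2), `depth_pixels`, `delta_z` (um), `origin` (um, length 3).
#'   Helical: `aline_rate` (1/s), `rotation_rate` (rev/s), `pullback_speed`
#'   (mm/s), `n_rev`, `depth_pixels`, `delta_z`, `probe_od` (um),
#'   `axis_center` (y, z world um of the cannula axis), `x_start` (um),
#'   `ball_lens_depth_index`, `sheath` (optional list: `n_px`, `dn`,
#'   `reflectivity`; its local axis is longitudinal, theta = 0)
#' @return object of class `psoct_geometry`
#' @export
make_scan_geometry <- function(mode = c("raster", "helical"), ...) {
  mode <- match.arg(mode)
  p <- list(...)
  if (mode == "raster") make_raster_geometry(p) else make_helical_geometry(p)
}

#' @noRd
make_raster_geometry <- function(p) {
  n_fast <- as.integer(p$n_fast %||% 64L)
  n_slow <- as.integer(p$n_slow %||% 64L)
  pitch <- rep_len(p$pitch %||% c(25, 25), 2L)
  depth_pixels <- as.integer(p$depth_pixels %||% 128L)
  delta_z <- p$delta_z %||% 4.8
  origin0 <- rep_len(p$origin %||% c(0, 0, 0), 3L)
  if (depth_pixels < 1L || n_fast < 1L || n_slow < 1L) {
    stop("raster geometry requires positive counts")
  }
  fast <- (seq_len(n_fast) - 0.5) * pitch[1L]
  slow <- (seq_len(n_slow) - 0.5) * pitch[2L]
  grid <- expand.grid(fast = fast, slow = slow)  # fast index varies fastest
  n <- nrow(grid)
  origins <- cbind(origin0[1L] + grid$fast, origin0[2L] + grid$slow, origin0[3L])
  structure(
    list(
      mode = "raster", n_alines = n, depth_pixels = depth_pixels,
      delta_z = delta_z, n_fast = n_fast, n_slow = n_slow, pitch = pitch,
      origins = origins,
      beam = matrix(rep(c(0, 0, 1), each = n), n, 3L),
      e1 = matrix(rep(c(1, 0, 0), each = n), n, 3L),
      e2 = matrix(rep(c(0, 1, 0), each = n), n, 3L),
      r_start = 0, sheath = p$sheath
    ),
    class = "psoct_geometry"
  )
}

#' @noRd
make_helical_geometry <- function(p) {
  aline_rate <- p$aline_rate %||% 103600
  rotation_rate <- p$rotation_rate %||% 50
  pullback_speed <- p$pullback_speed %||% 1
  n_rev <- p$n_rev %||% 3L
  depth_pixels <- as.integer(p$depth_pixels %||% 256L)
  delta_z <- p$delta_z %||% 4.8
  probe_od <- p$probe_od %||% 870
  if (aline_rate <= 0 || rotation_rate <= 0 || pullback_speed <= 0) {
    stop("helical rates must be positive")
  }
  # A-lines per revolution: exact ratio, rounded once here and used as the
  # integer sampling grid everywhere downstream.
  alines_per_rev <- as.integer(round(aline_rate / rotation_rate))
  n <- alines_per_rev * as.integer(n_rev)
  pitch_per_rev <- pullback_speed * 1000 / rotation_rate  # um per revolution
  idx <- seq_len(n) - 1L
  alpha <- 2 * pi * (idx %% alines_per_rev) / alines_per_rev
  x <- (p$x_start %||% 0) + pitch_per_rev * idx / alines_per_rev
  axis_center <- rep_len(p$axis_center %||% c(0, 0), 2L)
  origins <- cbind(x, axis_center[1L], axis_center[2L])
  beam <- cbind(0, cos(alpha), sin(alpha))
  e1 <- matrix(rep(c(1, 0, 0), each = n), n, 3L)
  e2 <- cbind(0, -sin(alpha), cos(alpha))
  structure(
    list(
      mode = "helical", n_alines = n, depth_pixels = depth_pixels,
      delta_z = delta_z,
      aline_rate = aline_rate, rotation_rate = rotation_rate,
      pullback_speed = pullback_speed, n_rev = as.integer(n_rev),
      alines_per_rev = alines_per_rev, pitch_per_rev = pitch_per_rev,
      probe_od = probe_od,
      probe_gauge_fr = round(3 * probe_od / 1000, 1),
      ball_lens_depth_index = as.integer(p$ball_lens_depth_index %||% 1L),
      axis_center = axis_center, alpha = alpha, pullback = x,
      origins = origins, beam = beam, e1 = e1, e2 = e2,
      r_start = probe_od / 2, sheath = p$sheath
    ),
    class = "psoct_geometry"
  )
}

#' @export
print.psoct_geometry <- function(x, ...) {
  if (x$mode == "raster") {
    cat(sprintf(
      "<psoct_geometry> raster %d x %d A-lines, %d depth px (dz %g um)\n",
      x$n_fast, x$n_slow, x$depth_pixels, x$delta_z
    ))
  } else {
    cat(sprintf(
      paste0(
        "<psoct_geometry> helical: %d rev x %d A-lines/rev, %d depth px ",
        "(dz %g um)\n  pitch %g um/rev, probe OD %g um (%.1f Fr)\n"
      ),
      x$n_rev, x$alines_per_rev, x$depth_pixels, x$delta_z,
      x$pitch_per_rev, x$probe_od, x$probe_gauge_fr
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample per-A-line ground truth from a phantom
#'
#' Samples the phantom along every beam at `delta_z` spacing: trilinear
#' interpolation for `dn` and `reflectivity`, nearest-neighbor for `theta`
#' and `label` (the axis angle is circular; averaging it across a tissue
#' boundary is meaningless). The world-frame axis is re-expressed in each
#' A-line's local frame as `theta_local = atan2(a . e2, a . e1)` and the
#' sampled `dn` is scaled by the squared in-plane projection of the axis
#' (cos^2 of the out-of-plane angle), so out-of-plane fibers show reduced
#' apparent birefringence. Points outside the phantom return background.
#'
#' If the geometry carries a `sheath`, its pixels overwrite the first
#' `sheath$n_px` depth rows with the sheath's birefringence and a local axis
#' along the longitudinal direction (`theta_local = 0`).
#'
#' @param phantom `psoct_phantom`
#' @param geometry `psoct_geometry`
#' @return object of class `psoct_truth`: matrices `[n_alines, depth_pixels]`
#'   `dn`, `theta` (local frame), `reflectivity`, plus the geometry
#' @export
sample_ground_truth <- function(phantom, geometry) {
  na <- geometry$n_alines
  nz <- geometry$depth_pixels
  depth <- geometry$r_start + (seq_len(nz) - 0.5) * geometry$delta_z
  # world sample points: [na * nz, 3], depth index varies slowest
  px <- outer(geometry$origins[, 1L], rep(1, nz)) +
    outer(geometry$beam[, 1L], depth)
  py <- outer(geometry$origins[, 2L], rep(1, nz)) +
    outer(geometry$beam[, 2L], depth)
  pz <- outer(geometry$origins[, 3L], rep(1, nz)) +
    outer(geometry$beam[, 3L], depth)
  dn <- interp_grid(phantom$dn, phantom, px, py, pz, mode = "trilinear")
  refl <- interp_grid(phantom$reflectivity, phantom, px, py, pz,
    mode = "trilinear"
  )
  thw <- interp_grid(phantom$theta, phantom, px, py, pz, mode = "nearest")
  # axis world vector projected into the local frame
  ax <- cos(thw)
  ay <- sin(thw)
  c1 <- ax * geometry$e1[, 1L] + ay * geometry$e1[, 2L]
  c2 <- ax * geometry$e2[, 1L] + ay * geometry$e2[, 2L]
  inplane2 <- c1^2 + c2^2
  theta_local <- wrap_axis_angle(atan2(c2, c1))
  theta_local[inplane2 < 1e-12] <- 0
  dn_eff <- dn * inplane2
  dn_eff[dn == 0] <- 0
  out <- list(
    dn = dn_eff, theta = theta_local, reflectivity = refl,
    geometry = geometry
  )
  if (!is.null(geometry$sheath)) {
    sh <- geometry$sheath
    rows <- seq_len(min(sh$n_px, nz))
    out$dn[, rows] <- sh$dn
    out$theta[, rows] <- 0
    out$reflectivity[, rows] <- sh$reflectivity %||% 1
    out$sheath_rows <- rows
  }
  structure(out, class = "psoct_truth")
}

#' Trilinear / nearest-neighbor sampling of a voxel grid
#'
#' @param g 3D array; px,py,pz matrices of world coordinates (um)
#' @noRd
interp_grid <- function(g, phantom, px, py, pz,
                        mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  dims <- dim(g)
  pit <- phantom$voxel_pitch
  org <- phantom$origin
  # continuous voxel coordinates: voxel centers at (i - 0.5) * pitch
  fx <- (as.numeric(px) - org[1L]) / pit[1L] + 0.5
  fy <- (as.numeric(py) - org[2L]) / pit[2L] + 0.5
  fz <- (as.numeric(pz) - org[3L]) / pit[3L] + 0.5
  if (mode == "nearest") {
    ix <- round(fx)
    iy <- round(fy)
    iz <- round(fz)
    ok <- ix >= 1 & ix <= dims[1L] & iy >= 1 & iy <= dims[2L] &
      iz >= 1 & iz <= dims[3L]
    out <- numeric(length(fx))
    if (any(ok)) {
      lin <- (ix[ok] - 1) + dims[1L] * ((iy[ok] - 1) + dims[2L] * (iz[ok] - 1))
      out[ok] <- g[lin + 1]
    }
    dim(out) <- dim(px)
    return(out)
  }
  # voxel centers sit at integer values of (fx, fy, fz)
  i0 <- floor(fx)
  wx <- fx - i0
  j0 <- floor(fy)
  wy <- fy - j0
  k0 <- floor(fz)
  wz <- fz - k0
  out <- numeric(length(fx))
  gather <- function(i, j, k) {
    ok <- i >= 1 & i <= dims[1L] & j >= 1 & j <= dims[2L] &
      k >= 1 & k <= dims[3L]
    v <- numeric(length(i))
    if (any(ok)) {
      lin <- (i[ok] - 1) + dims[1L] * ((j[ok] - 1) + dims[2L] * (k[ok] - 1))
      v[ok] <- g[lin + 1]
    }
    v
  }
  for (dx in 0:1) {
    for (dy in 0:1) {
      for (dz in 0:1) {
        w <- (if (dx == 0) 1 - wx else wx) *
          (if (dy == 0) 1 - wy else wy) *
          (if (dz == 0) 1 - wz else wz)
        out <- out + w * gather(i0 + dx, j0 + dy, k0 + dz)
      }
    }
  }
  dim(out) <- dim(px)
  out
}
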