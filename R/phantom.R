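# Ground-truth birefringent tissue phantoms. A phantom is a set of co-located
# voxel grids: local birefringence dn (dimensionless), in-plane optic-axis
# angle theta (radians, world frame), linear backscatter reflectivity, and a
# tissue label (0 background, 1 gray, 2 white). The world frame is
# right-handed with grids indexed [x, y, z] and half-open voxel intervals;
# voxel centers sit at origin + (index - 1/2) * pitch.

DN_SANITY_MAX <- 5e-3

#' Construct a phantom from voxel grids
#'
#' @param dn 3D array of local birefringence, >= 0
#' @param theta 3D array of in-plane optic-axis angles (radians, world frame)
#' @param reflectivity 3D array of linear backscatter weights, >= 0
#' @param label 3D integer array: 0 background, 1 gray, 2 white
#' @param voxel_pitch micrometers per voxel, length 3 (x, y, z)
#' @param origin world coordinates (micrometers) of the grid corner
#' @return object of class `psoct_phantom`
#' @export
psoct_phantom <- function(dn, theta, reflectivity, label = NULL,
                          voxel_pitch = c(20, 20, 4.8),
                          origin = c(0, 0, 0)) {
  dims <- dim(dn)
  if (length(dims) != 3L) stop("phantom grids must be 3D arrays")
  for (g in list(theta, reflectivity)) {
    if (!identical(dim(g), dims)) stop("phantom grids must share shape")
  }
  if (is.null(label)) {
    label <- array(1L, dims)
    label[dn > 1e-4] <- 2L
    label[reflectivity == 0] <- 0L
  }
  if (!identical(dim(label), dims)) stop("phantom grids must share shape")
  if (any(dn < 0)) stop("dn must be non-negative")
  if (any(dn > DN_SANITY_MAX)) {
    stop(sprintf("dn exceeds sanity bound %g", DN_SANITY_MAX))
  }
  if (any(reflectivity < 0)) stop("reflectivity must be non-negative")
  structure(
    list(
      dn = dn, theta = theta, reflectivity = reflectivity,
      label = storage_int(label),
      voxel_pitch = as.numeric(rep_len(voxel_pitch, 3L)),
      origin = as.numeric(rep_len(origin, 3L))
    ),
    class = "psoct_phantom"
  )
}

#' @noRd
storage_int <- function(x) {
  storage.mode(x) <- "integer"
  x
}

#' @export
print.psoct_phantom <- function(x, ...) {
  d <- dim(x$dn)
  cat(sprintf(
    "<psoct_phantom> %d x %d x %d voxels, pitch (%g, %g, %g) um\n",
    d[1L], d[2L], d[3L], x$voxel_pitch[1L], x$voxel_pitch[2L], x$voxel_pitch[3L]
  ))
  cat(sprintf(
    "  dn range [%g, %g]; white fraction %.3f\n",
    min(x$dn), max(x$dn), mean(x$label == 2L)
  ))
  invisible(x)
}

#' Layered slab phantom
#'
#' Stack of uniform layers, either planar (stacked along world z, for raster
#' scanning) or cylindrical (concentric shells around an axis parallel to
#' world x, for helical scanning: the layer coordinate is the radial distance
#' from the axis, starting at `r_inner`).
#'
#' @param layers data.frame (or list of rows) with columns `thickness` (um),
#'   `dn`, `theta` (radians, world frame), `reflectivity`
#' @param stacking "planar" or "cylindrical"
#' @param lateral_extent for planar: (x, y) extent in micrometers
#' @param voxel_pitch micrometers per voxel
#' @param axis_center for cylindrical: (y, z) world position of the cannula
#'   axis; the grid is sized to contain `r_inner + sum(thickness)` around it
#' @param r_inner for cylindrical: radius (um) where the first layer starts
#'   (typically the probe or cannula surface)
#' @param x_extent for cylindrical: extent along the axis (um)
#' @return `psoct_phantom`
#' @export
make_layered_phantom <- function(layers,
                                 stacking = c("planar", "cylindrical"),
                                 lateral_extent = c(400, 400),
                                 voxel_pitch = c(20, 20, 4.8),
                                 axis_center = NULL,
                                 r_inner = 0,
                                 x_extent = 400) {
  stacking <- match.arg(stacking)
  layers <- as.data.frame(layers)
  if (nrow(layers) == 0L) stop("layer list must not be empty")
  req <- c("thickness", "dn", "theta", "reflectivity")
  if (!all(req %in% names(layers))) {
    stop("layers need columns thickness, dn, theta, reflectivity")
  }
  if (any(layers$thickness <= 0)) stop("layer thicknesses must be positive")
  voxel_pitch <- rep_len(voxel_pitch, 3L)
  total <- sum(layers$thickness)
  bounds <- cumsum(layers$thickness)

  layer_at <- function(r) {
    # half-open intervals [prev, next); beyond the stack -> 0 (background)
    idx <- findInterval(r, c(0, bounds), left.open = FALSE)
    idx[r >= total | r < 0] <- 0L
    idx
  }

  if (stacking == "planar") {
    nx <- max(2L, ceiling(lateral_extent[1L] / voxel_pitch[1L]))
    ny <- max(2L, ceiling(lateral_extent[2L] / voxel_pitch[2L]))
    # full voxels only, so every voxel center lies inside the stack
    nz <- max(2L, floor(total / voxel_pitch[3L]))
    zc <- (seq_len(nz) - 0.5) * voxel_pitch[3L]
    li <- layer_at(zc)
    dnz <- ifelse(li > 0L, layers$dn[pmax(li, 1L)], 0)
    thz <- ifelse(li > 0L, layers$theta[pmax(li, 1L)], 0)
    rfz <- ifelse(li > 0L, layers$reflectivity[pmax(li, 1L)], 0)
    dn <- array(rep(dnz, each = nx * ny), c(nx, ny, nz))
    theta <- array(rep(thz, each = nx * ny), c(nx, ny, nz))
    refl <- array(rep(rfz, each = nx * ny), c(nx, ny, nz))
    return(psoct_phantom(dn, theta, refl, voxel_pitch = voxel_pitch))
  }

  # cylindrical: axis parallel to x through axis_center = (y0, z0)
  r_max <- r_inner + total
  half <- r_max + voxel_pitch[2L]
  nx <- max(2L, ceiling(x_extent / voxel_pitch[1L]))
  ny <- max(2L, ceiling(2 * half / voxel_pitch[2L]))
  nz <- max(2L, ceiling(2 * half / voxel_pitch[3L]))
  if (is.null(axis_center)) {
    axis_center <- c(ny * voxel_pitch[2L] / 2, nz * voxel_pitch[3L] / 2)
  }
  yc <- (seq_len(ny) - 0.5) * voxel_pitch[2L] - axis_center[1L]
  zc <- (seq_len(nz) - 0.5) * voxel_pitch[3L] - axis_center[2L]
  rr <- sqrt(outer(yc^2, zc^2, `+`))
  li <- layer_at(as.numeric(rr) - r_inner)
  dn2 <- ifelse(li > 0L, layers$dn[pmax(li, 1L)], 0)
  th2 <- ifelse(li > 0L, layers$theta[pmax(li, 1L)], 0)
  rf2 <- ifelse(li > 0L, layers$reflectivity[pmax(li, 1L)], 0)
  dn <- array(rep(dn2, each = nx), c(nx, ny, nz))
  theta <- array(rep(th2, each = nx), c(nx, ny, nz))
  refl <- array(rep(rf2, each = nx), c(nx, ny, nz))
  ph <- psoct_phantom(dn, theta, refl, voxel_pitch = voxel_pitch)
  ph$cylindrical <- list(
    axis_center = axis_center + 0, r_inner = r_inner,
    layers = layers, total_thickness = total
  )
  ph
}

#' White-matter-tract-like phantom
#'
#' Low-birefringence "gray matter" background with `n_tracts` ribbon-like,
#' strongly scattering, highly birefringent tracts whose optic-axis field
#' follows the tract centerline (in-plane projection). Deterministic given
#' `seed`; the generated centerlines are attached as attribute
#' `"centerlines"` for geometric validation.
#'
#' @param seed integer seed (local RNG; the global RNG state is restored)
#' @param size voxel counts, length 3, each >= 32
#' @param n_tracts number of tracts (0 gives a pure gray phantom)
#' @param voxel_pitch micrometers per voxel
#' @param dn_gray,dn_white_range background / tract birefringence
#' @return `psoct_phantom` with attribute `centerlines`
#' @export
make_wmt_phantom <- function(seed, size = c(48, 48, 48), n_tracts = 3L,
                             voxel_pitch = c(20, 20, 4.8),
                             dn_gray = 5e-5,
                             dn_white_range = c(0.8e-3, 1.3e-3)) {
  size <- as.integer(rep_len(size, 3L))
  if (any(size < 32L)) stop("phantom size must be at least 32 voxels per axis")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  pitch <- rep_len(voxel_pitch, 3L)
  dn <- array(dn_gray, size)
  theta <- array(0, size)
  refl <- array(1, size)
  label <- array(1L, size)
  centerlines <- list()
  ext <- size * pitch
  for (tr in seq_len(n_tracts)) {
    # centerline: straight base direction in the xy plane plus smooth wiggle
    base_ang <- stats::runif(1, -pi, pi)
    d0 <- c(cos(base_ang), sin(base_ang), stats::runif(1, -0.15, 0.15))
    d0 <- d0 / sqrt(sum(d0^2))
    p0 <- c(
      stats::runif(1, 0.25, 0.75) * ext[1L],
      stats::runif(1, 0.25, 0.75) * ext[2L],
      stats::runif(1, 0.3, 0.7) * ext[3L]
    )
    amp <- stats::runif(1, 0.02, 0.08) * min(ext[1:2])
    per <- stats::runif(1, 0.5, 1.2) * min(ext[1:2])
    phase <- stats::runif(1, 0, 2 * pi)
    # orthogonal in-plane direction for the wiggle
    dperp <- c(-d0[2L], d0[1L], 0)
    dperp <- dperp / sqrt(sum(dperp^2))
    tmax <- sqrt(sum(ext^2))
    ts <- seq(-tmax, tmax, by = min(pitch) / 2)
    pts <- t(vapply(ts, function(t) {
      p0 + d0 * t + dperp * amp * sin(2 * pi * t / per + phase)
    }, numeric(3L)))
    tans <- t(vapply(ts, function(t) {
      v <- d0 + dperp * amp * (2 * pi / per) * cos(2 * pi * t / per + phase)
      v / sqrt(sum(v^2))
    }, numeric(3L)))
    inside <- pts[, 1L] > 0 & pts[, 1L] < ext[1L] &
      pts[, 2L] > 0 & pts[, 2L] < ext[2L] &
      pts[, 3L] > 0 & pts[, 3L] < ext[3L]
    if (!any(inside)) next
    pts <- pts[inside, , drop = FALSE]
    tans <- tans[inside, , drop = FALSE]
    radius <- stats::runif(1, 2.5, 4) * min(pitch)
    dn_tract <- stats::runif(1, dn_white_range[1L], dn_white_range[2L])
    refl_tract <- stats::runif(1, 2, 3)
    rad_vox <- ceiling(radius / pitch)
    for (s in seq_len(nrow(pts))) {
      ci <- pmin(pmax(round(pts[s, ] / pitch + 0.5), 1L), size)
      xr <- max(1L, ci[1L] - rad_vox[1L]):min(size[1L], ci[1L] + rad_vox[1L])
      yr <- max(1L, ci[2L] - rad_vox[2L]):min(size[2L], ci[2L] + rad_vox[2L])
      zr <- max(1L, ci[3L] - rad_vox[3L]):min(size[3L], ci[3L] + rad_vox[3L])
      cx <- (xr - 0.5) * pitch[1L] - pts[s, 1L]
      cy <- (yr - 0.5) * pitch[2L] - pts[s, 2L]
      cz <- (zr - 0.5) * pitch[3L] - pts[s, 3L]
      d2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
      hit <- which(d2 <= radius^2, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      ii <- cbind(xr[hit[, 1L]], yr[hit[, 2L]], zr[hit[, 3L]])
      th <- wrap_axis_angle(atan2(tans[s, 2L], tans[s, 1L]))
      dn[ii] <- dn_tract
      theta[ii] <- th
      refl[ii] <- refl_tract
      label[ii] <- 2L
    }
    centerlines[[length(centerlines) + 1L]] <-
      list(points = pts, tangents = tans, radius = radius)
  }
  ph <- psoct_phantom(dn, theta, refl, label, voxel_pitch = pitch)
  attr(ph, "centerlines") <- centerlines
  ph
}
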