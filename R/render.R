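# Display products: composite hue/brightness maps of optic-axis orientation
# and birefringence, and the standard view geometries (en-face,
# cross-sectional, rotational, unwrapped, tangential) extracted as mean
# projections over stated extents.

#' Composite hue/brightness image
#'
#' Maps the optic-axis orientation to a cyclic HSV hue (period pi in the
#' axis angle: theta and theta + pi render identically) and birefringence to
#' brightness, clipped at `dn_max`; masked pixels are black. The default
#' brightness range 0-1.3e-3 matches the conventional white-matter display
#' maximum.
#'
#' @param map `psoct_polmap` (fields `dn`, `theta`, optional `mask`)
#' @param dn_max brightness saturation birefringence, > 0
#' @return array `[n_alines, depth, 3]` of RGB in [0, 1]; attributes
#'   `colorbar` (hue wheel metadata) and `dn_max`
#' @export
composite_map <- function(map, dn_max = 1.3e-3) {
  if (dn_max <= 0) stop("dn_max must be positive")
  dn <- if (is.matrix(map)) map else map$dn
  theta <- if (is.matrix(map)) {
    stop("composite_map expects a psoct_polmap")
  } else {
    map$theta
  }
  bright <- pmin(pmax(dn / dn_max, 0), 1)
  if (!is.matrix(map) && !is.null(map$mask)) bright[!map$mask] <- 0
  hue <- ((theta + pi / 2) / pi) %% 1  # cyclic over a period of pi
  rgb <- hsv_to_rgb(hue, 1, bright)
  out <- array(0, dim = c(nrow(dn), ncol(dn), 3L))
  out[, , 1L] <- rgb$r
  out[, , 2L] <- rgb$g
  out[, , 3L] <- rgb$b
  attr(out, "dn_max") <- dn_max
  attr(out, "colorbar") <- list(
    hue_period = "pi in axis angle",
    hue_zero = "axis at -90 degrees maps to hue 0 (red)",
    brightness = c(0, dn_max)
  )
  out
}

#' Vectorized HSV -> RGB on matrices
#' @noRd
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  sel <- i == 0
  r[sel] <- v[sel]; g[sel] <- t[sel]; b[sel] <- p[sel]
  sel <- i == 1
  r[sel] <- q[sel]; g[sel] <- v[sel]; b[sel] <- p[sel]
  sel <- i == 2
  r[sel] <- p[sel]; g[sel] <- v[sel]; b[sel] <- t[sel]
  sel <- i == 3
  r[sel] <- p[sel]; g[sel] <- q[sel]; b[sel] <- v[sel]
  sel <- i == 4
  r[sel] <- t[sel]; g[sel] <- p[sel]; b[sel] <- v[sel]
  sel <- i == 5
  r[sel] <- v[sel]; g[sel] <- p[sel]; b[sel] <- q[sel]
  list(r = r, g = g, b = b)
}

#' Arrange a reconstructed map as a 3D volume in scan coordinates
#'
#' Raster maps become `[fast, slow, depth]` volumes; helical maps become
#' `[angle, pullback, depth]` volumes (one column per revolution). Returns a
#' list of volumes (`dn`, `theta`, `dop`, `mask`, and `intensity_db` when
#' supplied) plus coordinate metadata in micrometers/degrees.
#'
#' @param map `psoct_polmap` with its `geometry`
#' @param intensity_db optional intensity matrix to carry along
#' @return object of class `psoct_volume`
#' @export
as_volume <- function(map, intensity_db = NULL) {
  geom <- map$geometry
  if (is.null(geom)) stop("map carries no geometry")
  fields <- list(dn = map$dn, theta = map$theta)
  if (!is.null(map$dop)) fields$dop <- map$dop
  if (!is.null(map$mask)) fields$mask <- map$mask * 1
  if (!is.null(intensity_db)) fields$intensity_db <- intensity_db
  nz <- geom$depth_pixels
  if (geom$mode == "raster") {
    d1 <- geom$n_fast
    d2 <- geom$n_slow
    coord <- list(
      dims = c("fast", "slow", "depth"),
      pitch = c(geom$pitch[1L], geom$pitch[2L], geom$delta_z),
      units = c("um", "um", "um")
    )
  } else {
    d1 <- geom$alines_per_rev
    d2 <- geom$n_rev
    coord <- list(
      dims = c("angle", "pullback", "depth"),
      pitch = c(360 / geom$alines_per_rev, geom$pitch_per_rev, geom$delta_z),
      units = c("deg", "um", "um")
    )
  }
  vols <- lapply(fields, function(m) array(m, dim = c(d1, d2, nz)))
  structure(
    list(volumes = vols, coord = coord, mode = geom$mode, geometry = geom),
    class = "psoct_volume"
  )
}

#' View specification
#'
#' @param kind one of "enface", "cross_fast", "cross_slow", "rot_cross",
#'   "pullback_cross", "unwrapped_enface", "tangential"
#' @param position center of the view along its out-of-plane direction
#'   (micrometers, or degrees for "pullback_cross")
#' @param extent mean-projection extent centered on `position` (same units);
#'   conventional values: 30 um en-face, 70 um benchtop cross-sections,
#'   2.5 deg pullback cross-sections, 140 um endoscopic rotational views,
#'   60 um deep-brain rotational views, 30 um tangential views
#' @return object of class `psoct_viewspec`
#' @export
view_spec <- function(kind, position, extent) {
  kinds <- c(
    "enface", "cross_fast", "cross_slow", "rot_cross",
    "pullback_cross", "unwrapped_enface", "tangential"
  )
  kind <- match.arg(kind, kinds)
  if (extent <= 0) stop("projection extent must be positive")
  structure(list(kind = kind, position = position, extent = extent),
            class = "psoct_viewspec")
}

#' Extract a 2D view from a volume
#'
#' Mean projection over the view specification's extent centered at its
#' position, along
#' the out-of-plane direction implied by the view kind. Circular fields
#' (`field = "theta"`) are averaged as doubled-angle vectors. Masked pixels
#' are excluded from the means when a mask volume is present; pixels whose
#' entire window is masked return `NA`.
#'
#' @param vol `psoct_volume`
#' @param spec `psoct_viewspec`
#' @param field which volume to project (default "dn")
#' @return 2D matrix with attribute `axes` naming its dimensions
#' @export
extract_view <- function(vol, spec, field = "dn") {
  stopifnot(inherits(vol, "psoct_volume"), inherits(spec, "psoct_viewspec"))
  g <- vol$volumes[[field]]
  if (is.null(g)) stop(sprintf("volume has no field '%s'", field))
  mask <- vol$volumes$mask
  circ <- identical(field, "theta")
  kind <- spec$kind
  mode <- vol$mode
  ax_ok <- function(need) {
    if (!identical(mode, need)) {
      stop(sprintf("view '%s' requires a %s volume", kind, need))
    }
  }
  # map the view kind to the projected dimension of the [d1, d2, depth] cube
  proj_dim <- switch(kind,
    enface = 3L,
    unwrapped_enface = 3L,
    cross_fast = 2L,   # image [fast, depth], projected along slow
    cross_slow = 1L,   # image [slow, depth], projected along fast
    rot_cross = 2L,    # image [angle, depth], projected along pullback
    pullback_cross = 1L,  # image [pullback, depth], projected along angle
    tangential = NA_integer_
  )
  if (kind %in% c("cross_fast", "cross_slow")) ax_ok("raster")
  if (kind %in% c("rot_cross", "pullback_cross", "unwrapped_enface",
                  "tangential")) {
    ax_ok("helical")
  }
  if (identical(kind, "tangential")) {
    return(tangential_view(vol, spec, field))
  }
  pitch <- vol$coord$pitch[proj_dim]
  nproj <- dim(g)[proj_dim]
  # select pixels whose centers fall in the half-open projection window
  lo <- (spec$position - spec$extent / 2) / pitch + 0.5
  hi <- (spec$position + spec$extent / 2) / pitch + 0.5
  idx <- seq_len(nproj)
  sel <- idx[idx > lo + 1e-9 & idx <= hi + 1e-9]
  if (spec$position < 0 || spec$position > nproj * pitch) {
    stop("view position outside the volume")
  }
  if (length(sel) == 0L) {
    # window narrower than a pixel: take the nearest plane
    sel <- min(max(as.integer(round(spec$position / pitch + 0.5)), 1L), nproj)
  }
  slab <- switch(proj_dim,
    g[sel, , , drop = FALSE],
    g[, sel, , drop = FALSE],
    g[, , sel, drop = FALSE]
  )
  mslab <- if (is.null(mask)) NULL else switch(proj_dim,
    mask[sel, , , drop = FALSE],
    mask[, sel, , drop = FALSE],
    mask[, , sel, drop = FALSE]
  )
  img <- project_mean(slab, proj_dim, circ, mslab)
  attr(img, "axes") <- switch(kind,
    enface = vol$coord$dims[1:2],
    unwrapped_enface = vol$coord$dims[1:2],
    cross_fast = c(vol$coord$dims[1L], "depth"),
    cross_slow = c(vol$coord$dims[2L], "depth"),
    rot_cross = c(vol$coord$dims[1L], "depth"),
    pullback_cross = c(vol$coord$dims[2L], "depth")
  )
  img
}

#' Mean projection of a slab along one dimension
#' @noRd
project_mean <- function(slab, proj_dim, circ = FALSE, mask = NULL) {
  w <- if (is.null(mask)) array(1, dim(slab)) else mask
  if (circ) {
    cs <- apply(w * cos(2 * slab), setdiff(1:3, proj_dim), sum)
    sn <- apply(w * sin(2 * slab), setdiff(1:3, proj_dim), sum)
    tot <- apply(w, setdiff(1:3, proj_dim), sum)
    out <- 0.5 * atan2(sn, cs)
    out[tot == 0] <- NA_real_
    return(out)
  }
  num <- apply(w * slab, setdiff(1:3, proj_dim), sum)
  den <- apply(w, setdiff(1:3, proj_dim), sum)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Tangential cross-section of a helical volume
#'
#' Samples the cylinder on a plane parallel to the cannula axis at distance
#' `position` from it, over lateral offsets spanning the cylinder; mean
#' projection over `extent` along the plane normal. Bilinear in (angle,
#' depth), nearest in pullback.
#' @noRd
tangential_view <- function(vol, spec, field = "dn") {
  g <- vol$volumes[[field]]
  geom <- vol$geometry
  nang <- dim(g)[1L]
  nrev <- dim(g)[2L]
  nz <- dim(g)[3L]
  r0 <- geom$r_start
  rmax <- r0 + nz * geom$delta_z
  if (spec$position < r0 || spec$position > rmax) {
    stop("view position outside the volume")
  }
  ylim <- sqrt(max(rmax^2 - spec$position^2, 0))
  ys <- seq(-ylim, ylim, by = geom$delta_z)
  xs <- seq_len(nrev)
  nrm <- 3L
  ds <- spec$position + seq(-spec$extent / 2, spec$extent / 2,
                            length.out = nrm)
  acc <- matrix(0, length(xs), length(ys))
  cnt <- matrix(0, length(xs), length(ys))
  for (d in ds) {
    r <- sqrt(d^2 + ys^2)
    phi <- atan2(ys, d) %% (2 * pi)
    zc <- (r - r0) / geom$delta_z + 0.5
    ai <- phi / (2 * pi) * nang + 1
    ok <- zc >= 1 & zc <= nz
    a0 <- floor(ai)
    fa <- ai - a0
    z0 <- floor(zc)
    fz <- zc - z0
    a1 <- (a0 %% nang) + 1L  # a0 wrapped
    a2 <- (a1 %% nang) + 1L
    z1 <- pmin(pmax(z0, 1L), nz)
    z2 <- pmin(z1 + 1L, nz)
    for (xi in seq_along(xs)) {
      vals <- (1 - fa) * (1 - fz) * g[cbind(a1, xs[xi], z1)] +
        fa * (1 - fz) * g[cbind(a2, xs[xi], z1)] +
        (1 - fa) * fz * g[cbind(a1, xs[xi], z2)] +
        fa * fz * g[cbind(a2, xs[xi], z2)]
      acc[xi, ok] <- acc[xi, ok] + vals[ok]
      cnt[xi, ok] <- cnt[xi, ok] + 1
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  attr(out, "axes") <- c("pullback", "lateral")
  out
}
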