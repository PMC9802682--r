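# Forward PSOCT measurement model. A-lines are illuminated with two input
# polarization states that are orthogonal on the Poincare sphere (not
# antipodal), and the detected field for state s at depth pixel m is
#
#   E = A_b t(C) T_m C B_b e_s * sqrt(reflectivity) * g + n
#
# with T_m = t(J_m) J_m the tissue round trip, J_m = dJ_m ... dJ_1 the
# cumulative one-way product of per-pixel linear retarders
# dJ_k = linear_retarder(2 pi dn_k dz / lambda_c, theta_k), C the rotating
# catheter transmission, A_b / B_b per-spectral-bin static system
# transmissions, g a circular-Gaussian speckle weight shared between states,
# and n additive circular-Gaussian noise. The simulator emits depth-domain
# data directly; only the axial PSF touches the spectral domain.

#' Measurement configuration
#'
#' @param lambda_c center wavelength, nm
#' @param sweep_range wavelength sweep range, nm
#' @param spectral_window spectral shape: "hann", "rect" or "gaussian"
#' @param n_tissue tissue group refractive index
#' @param snr_db per-pixel signal-to-noise (dB) at unit reflectivity;
#'   `Inf` disables additive noise
#' @param speckle logical: multiply each pixel by a circular-Gaussian
#'   complex speckle weight (shared between input states and bins)
#' @param n_spectral_bins number of spectral bins carrying independent
#'   static system transmissions
#' @param seed integer seed for system draws, speckle and noise
#' @param input_states list of two complex length-2 Jones vectors whose
#'   Stokes vectors are orthogonal (dot product 0) on the Poincare sphere
#' @param system "identity", "random", or a list (length `n_spectral_bins`)
#'   of `list(A = , B = )` unitary Jones matrices
#' @param system_bin_spread rotation-vector spread (radians) of the per-bin
#'   perturbation around the common random system transmission
#' @param catheter `NULL` for none, or a list with fields `ret_mean`,
#'   `ret_amp`, `axis_mean`, `axis_amp`, `phase`, `circ_amp` describing a
#'   slowly varying linear retarder (retardation and axis sinusoidal in the
#'   rotation angle) with an optional small circular component
#' @return object of class `psoct_measconfig`
#' @export
measurement_config <- function(lambda_c = 1300, sweep_range = 110,
                               spectral_window = "hann", n_tissue = 1.35,
                               snr_db = 30, speckle = TRUE,
                               n_spectral_bins = 5L, seed = 1L,
                               input_states = NULL,
                               system = "identity",
                               system_bin_spread = 0.2,
                               catheter = NULL) {
  if (is.null(input_states)) {
    input_states <- list(
      c(1 + 0i, 0 + 0i),              # horizontal linear
      c(1 + 0i, 1 + 0i) / sqrt(2)      # +45 deg linear
    )
  }
  s1 <- stokes_state(input_states[[1L]])
  s2 <- stokes_state(input_states[[2L]])
  d <- sum(s1[2:4] * s2[2:4]) / (s1[1L] * s2[1L])
  if (abs(d) > 1e-10) {
    stop("input states must be orthogonal on the Poincare sphere")
  }
  structure(
    list(
      lambda_c = lambda_c, sweep_range = sweep_range,
      spectral_window = spectral_window, n_tissue = n_tissue,
      snr_db = snr_db, speckle = isTRUE(speckle),
      n_spectral_bins = as.integer(n_spectral_bins), seed = as.integer(seed),
      input_states = input_states, system = system,
      system_bin_spread = system_bin_spread, catheter = catheter
    ),
    class = "psoct_measconfig"
  )
}

#' Axial point-spread-function width
#'
#' Full width at half maximum (in tissue, micrometers) of the squared
#' magnitude of the depth response of a single reflector: the Fourier
#' transform of the spectral window expressed over wavenumber, with the
#' round-trip factor 2 and the tissue refractive index. Computed numerically
#' on a fine grid.
#'
#' @param lambda_c center wavelength, nm
#' @param sweep_range wavelength sweep range, nm (> 0)
#' @param window "hann", "rect" or "gaussian"
#' @param n_tissue refractive index
#' @param n_k,n_z grid sizes for the wavenumber window and the depth search
#' @return FWHM in micrometers
#' @export
#' @examples
#' axial_psf_fwhm(1300, 110, "hann", 1.35)
axial_psf_fwhm <- function(lambda_c = 1300, sweep_range = 110,
                           window = "hann", n_tissue = 1.35,
                           n_k = 2048L, n_z = 4096L) {
  if (sweep_range <= 0) stop("sweep_range must be positive")
  # sweep expressed over wavenumber, symmetric about k_c (swept sources are
  # close to linear in k): delta_k = 2 pi delta_lambda / lambda_c^2
  k_c <- 2 * pi / lambda_c  # nm^-1
  dk <- 2 * pi * sweep_range / lambda_c^2
  k <- seq(k_c - dk / 2, k_c + dk / 2, length.out = n_k)
  t <- (k - k[1L]) / (k[n_k] - k[1L])
  w <- switch(window,
    hann = 0.5 * (1 - cos(2 * pi * t)),
    rect = rep(1, length(t)),
    gaussian = {
      # intensity FWHM of the window = half the sweep, truncated at the edges
      sigma <- 0.25 / (2 * sqrt(log(2)))
      exp(-0.5 * ((t - 0.5) / sigma)^2)
    },
    stop(sprintf("unknown spectral window '%s'", window))
  )
  # depth response |sum w(k) exp(2 i n k z)|^2; peak at z = 0
  zmax <- 40 * lambda_c / n_tissue  # nm, generous search range
  z <- seq(0, zmax, length.out = n_z)
  kc <- k - mean(k)  # common phase does not affect the magnitude
  a2 <- vapply(z, function(zz) {
    ph <- 2 * n_tissue * kc * zz
    Mod(sum(w * exp(1i * ph)))^2
  }, numeric(1L))
  a2 <- a2 / a2[1L]
  below <- which(a2 < 0.5)
  if (length(below) == 0L) stop("depth grid too short for FWHM")
  i <- below[1L]
  # linear interpolation of the half-max crossing
  frac <- (a2[i - 1L] - 0.5) / (a2[i - 1L] - a2[i])
  zhalf <- z[i - 1L] + frac * (z[i] - z[i - 1L])
  2 * zhalf * 1e-3  # nm -> um
}

#' Catheter one-way Jones stack at rotation angles alpha
#' @noRd
catheter_stack <- function(catheter, alpha) {
  n <- length(alpha)
  if (is.null(catheter)) {
    return(j2_identity(n))
  }
  ret <- catheter$ret_mean +
    (catheter$ret_amp %||% 0) * sin(alpha + (catheter$phase %||% 0))
  ax <- (catheter$axis_mean %||% 0) +
    (catheter$axis_amp %||% 0) * sin(alpha + (catheter$phase %||% 0) + 1)
  cj <- j2_linear_retarder(ret, ax)
  circ <- catheter$circ_amp %||% 0
  if (circ != 0) {
    psi <- circ * sin(alpha)
    rotj <- j2_stack(
      a = complex(real = cos(psi)), b = complex(real = -sin(psi)),
      c = complex(real = sin(psi)), d = complex(real = cos(psi))
    )
    cj <- j2_mult(cj, rotj)
  }
  cj
}

#' Per-bin system Jones matrices
#' @noRd
system_matrices <- function(config) {
  nb <- config$n_spectral_bins
  if (is.list(config$system)) {
    stopifnot(length(config$system) == nb)
    return(config$system)
  }
  if (identical(config$system, "identity")) {
    id <- structure(diag(2) + 0i, class = "unitary_jones")
    return(replicate(nb, list(A = id, B = id), simplify = FALSE))
  }
  if (!identical(config$system, "random")) {
    stop("system must be 'identity', 'random', or an explicit list")
  }
  a0 <- random_unitary()
  b0 <- random_unitary()
  lapply(seq_len(nb), function(b) {
    da <- jones_from_vector(stats::rnorm(3L, sd = config$system_bin_spread))
    db <- jones_from_vector(stats::rnorm(3L, sd = config$system_bin_spread))
    list(
      A = compose_layers(list(a0, da)),
      B = compose_layers(list(db, b0))
    )
  })
}

#' Synthesize a polarimetric tomogram
#'
#' Forward-simulates the detected polarization states for every A-line,
#' depth pixel, input state and spectral bin, plus the ball-lens reference
#' reflection for helical geometries. Deterministic given `config$seed`.
#'
#' @param phantom `psoct_phantom`, or a `psoct_truth` from
#'   [sample_ground_truth()] (then `geometry` may be omitted)
#' @param geometry `psoct_geometry`
#' @param config `psoct_measconfig`
#' @return object of class `psoct_tomogram` with `stokes`
#'   `[aline, depth, state, bin, 4]`, `intensity_db` `[aline, depth]`,
#'   `ball_lens` `[aline, state, bin, 4]` (helical), geometry and config
#' @export
synthesize_tomogram <- function(phantom, geometry = NULL, config) {
  truth <- if (inherits(phantom, "psoct_truth")) {
    phantom
  } else {
    sample_ground_truth(phantom, geometry)
  }
  geometry <- truth$geometry
  na <- geometry$n_alines
  nz <- geometry$depth_pixels
  nb <- config$n_spectral_bins
  lam <- config$lambda_c
  dz_nm <- geometry$delta_z * 1000
  phi_grid <- 2 * pi * truth$dn * dz_nm / lam
  if (max(phi_grid) >= pi / 2) {
    warning("per-layer retardation reaches pi/2: phase wrapping likely")
  }

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  sys <- system_matrices(config)
  alpha <- if (geometry$mode == "helical") geometry$alpha else numeric(na)
  cath <- catheter_stack(config$catheter, alpha)
  cath_t <- j2_t(cath)

  # Precompute, per bin and state: input vector through B then catheter,
  # and the output-side stack A t(C).
  in_vec <- vector("list", nb)
  out_stack <- vector("list", nb)
  for (b in seq_len(nb)) {
    bs <- j2_from_matrix(unclass(sys[[b]]$B), na)
    as_ <- j2_from_matrix(unclass(sys[[b]]$A), na)
    out_stack[[b]] <- j2_mult(as_, cath_t)
    in_vec[[b]] <- lapply(config$input_states, function(e) {
      ve <- j2_apply(bs, e)
      list(
        ex = cath$a * ve$ex + cath$b * ve$ey,
        ey = cath$c * ve$ex + cath$d * ve$ey
      )
    })
  }

  sig2 <- if (is.finite(config$snr_db)) 10^(-config$snr_db / 10) / 2 else 0
  noise <- function(n) {
    if (sig2 == 0) {
      return(rep(0 + 0i, n))
    }
    complex(real = stats::rnorm(n, sd = sqrt(sig2)),
            imaginary = stats::rnorm(n, sd = sqrt(sig2)))
  }

  stokes <- array(0, dim = c(na, nz, 2L, nb, 4L))
  intensity <- matrix(0, na, nz)
  jc <- j2_identity(na)
  for (m in seq_len(nz)) {
    dj <- j2_linear_retarder(phi_grid[, m], truth$theta[, m])
    jc <- j2_mult(dj, jc)
    tm <- j2_mult(j2_t(jc), jc)
    amp <- sqrt(truth$reflectivity[, m])
    if (config$speckle) {
      amp <- amp * complex(
        real = stats::rnorm(na, sd = sqrt(0.5)),
        imaginary = stats::rnorm(na, sd = sqrt(0.5))
      )
    }
    for (b in seq_len(nb)) {
      os <- out_stack[[b]]
      for (s in 1:2) {
        v <- in_vec[[b]][[s]]
        mx <- tm$a * v$ex + tm$b * v$ey
        my <- tm$c * v$ex + tm$d * v$ey
        ex <- (os$a * mx + os$b * my) * amp + noise(na)
        ey <- (os$c * mx + os$d * my) * amp + noise(na)
        st <- stokes_from_field(ex, ey)
        stokes[, m, s, b, 1L] <- st$i
        stokes[, m, s, b, 2L] <- st$q
        stokes[, m, s, b, 3L] <- st$u
        stokes[, m, s, b, 4L] <- st$v
        intensity[, m] <- intensity[, m] + st$i
      }
    }
  }
  intensity <- intensity / (2 * nb)
  # Reference reflection with no tissue in the path: the ball-lens signal
  # for helical scans (A t(C) C B), the specular surface reference for
  # raster scans (A B). Both calibrate the static/rotating system parts.
  ball <- array(0, dim = c(na, 2L, nb, 4L))
  {
    for (b in seq_len(nb)) {
      os <- out_stack[[b]]
      for (s in 1:2) {
        v <- in_vec[[b]][[s]]
        ex <- os$a * v$ex + os$b * v$ey + noise(na)
        ey <- os$c * v$ex + os$d * v$ey + noise(na)
        st <- stokes_from_field(ex, ey)
        ball[, s, b, 1L] <- st$i
        ball[, s, b, 2L] <- st$q
        ball[, s, b, 3L] <- st$u
        ball[, s, b, 4L] <- st$v
      }
    }
  }
  structure(
    list(
      stokes = stokes,
      intensity_db = 10 * log10(pmax(intensity, 1e-12)),
      ball_lens = ball,
      geometry = geometry, config = config
    ),
    class = "psoct_tomogram"
  )
}

#' @export
print.psoct_tomogram <- function(x, ...) {
  d <- dim(x$stokes)
  cat(sprintf(
    "<psoct_tomogram> %d A-lines x %d depth px, 2 states, %d spectral bin(s)%s\n",
    d[1L], d[2L], d[4L],
    if (!is.null(x$ball_lens)) ", ball-lens reference" else ""
  ))
  invisible(x)
}

#' Log-scaled intensity image
#'
#' @param tomogram `psoct_tomogram`
#' @param clip display range in dB, default the conventional 0-40 dB
#' @return matrix `[aline, depth]` of dB values clipped to `clip`, with the
#'   range stored in attribute `"clip"`
#' @export
intensity_image <- function(tomogram, clip = c(0, 40)) {
  img <- pmin(pmax(tomogram$intensity_db, clip[1L]), clip[2L])
  attr(img, "clip") <- clip
  img
}
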