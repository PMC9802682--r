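# Shared fixtures: small phantoms, geometries and configurations built in
# code. Sizes are kept small; the acceptance tests use the full-scale study
# conditions.

two_layer_table <- function() {
  data.frame(
    thickness = c(250, 250),
    dn = c(5e-4, 1.2e-3),
    theta = c(20, -60) * pi / 180,
    reflectivity = c(1, 2)
  )
}

small_raster <- function(n_fast = 8L, n_slow = 4L, depth = 96L) {
  make_scan_geometry(
    "raster",
    n_fast = n_fast, n_slow = n_slow, pitch = c(25, 25),
    depth_pixels = depth, delta_z = 4.8
  )
}

#' Helical geometry scaled down in A-line rate (fewer A-lines per rev)
small_helical <- function(alines_per_rev = 128L, n_rev = 2L, depth = 96L,
                          sheath = list(n_px = 2L, dn = 8e-4,
                                        reflectivity = 2),
                          axis_center = NULL, x_start = 80) {
  # x_start keeps the pullback away from the phantom x boundary
  make_scan_geometry(
    "helical",
    aline_rate = alines_per_rev * 50, rotation_rate = 50,
    pullback_speed = 1, n_rev = n_rev, depth_pixels = depth,
    delta_z = 4.8, probe_od = 870, x_start = x_start,
    sheath = sheath, axis_center = axis_center
  )
}

#' Cylindrical two-layer phantom matched to a helical geometry
two_layer_cyl_phantom <- function(geom_sheath_px = 2L, depth = 96L) {
  gtmp <- small_helical(depth = depth)
  make_layered_phantom(
    two_layer_table(),
    stacking = "cylindrical",
    r_inner = gtmp$r_start + geom_sheath_px * gtmp$delta_z,
    voxel_pitch = c(20, 10, 10),
    x_extent = 200
  )
}

noiseless_config <- function(system = "identity", seed = 1L, ...) {
  measurement_config(
    snr_db = Inf, speckle = FALSE, n_spectral_bins = 1L,
    system = system, seed = seed, ...
  )
}

exact_recon_config <- function(...) {
  recon_config(stokes_kernel = c(1L, 1L), local_kernel = c(1L, 1L), ...)
}

#' Random stack of linear retarders and its cumulative round trips
random_retarder_stack <- function(n_layers, phi_max = 0.5) {
  phis <- stats::runif(n_layers, 0, phi_max)
  thetas <- stats::runif(n_layers, -pi / 2, pi / 2)
  v <- diag(2) + 0i
  rts <- vector("list", n_layers)
  for (m in seq_len(n_layers)) {
    v <- unclass(linear_retarder(phis[m], thetas[m])) %*% v
    rts[[m]] <- roundtrip(unitary_jones(v))
  }
  list(phi = phis, theta = thetas, roundtrips = rts)
}

#' Frobenius-type distance between Jones matrices modulo the sign class
jones_dist <- function(a, b) {
  a <- unclass(a)
  b <- unclass(b)
  min(max(Mod(a - b)), max(Mod(a + b)))
}

circ_axis_diff <- function(a, b) abs(wrap_axis_angle(a - b))

#' Reproduce the seeded random system matrices the simulator draws
with_seed_system <- function(seed, n_bins = 1L, spread = 0.2) {
  cfg <- measurement_config(
    n_spectral_bins = n_bins, seed = seed,
    system = "random", system_bin_spread = spread
  )
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sys <- psoct:::system_matrices(cfg)
  if (n_bins == 1L) list(A = sys[[1]]$A, B = sys[[1]]$B) else sys
}

#' Mean squared deviation from transpose-symmetric (QU-axis) form
sym_resid <- function(rarr) psoct:::asym_energy(rarr)
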