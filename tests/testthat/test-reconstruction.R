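# Reconstruction pipeline: rotation estimation, symmetrization, catheter
# compensation, layer peeling, DOP masking and axis referencing.

make_noiseless_raster <- function(system = "identity", seed = 1L,
                                  n_fast = 8L, n_slow = 4L, depth = 96L) {
  ph <- make_layered_phantom(two_layer_table(), lateral_extent = c(300, 300))
  geom <- small_raster(n_fast, n_slow, depth)
  truth <- sample_ground_truth(ph, geom)
  tomo <- synthesize_tomogram(truth, config = noiseless_config(system, seed))
  list(truth = truth, tomo = tomo, geom = geom)
}

test_that("noiseless rotation estimates match the forward model exactly", {
  fx <- make_noiseless_raster()
  est <- estimate_rotations(fx$tomo, exact_recon_config())
  # oracle: rebuild the round trip from the sampled truth in SU(2)
  lam <- 1300 * 1e-3
  for (al in c(1, 17)) {
    v <- diag(2) + 0i
    for (m in c(3, 40, 90)) {
      v <- diag(2) + 0i
      for (k in seq_len(m)) {
        phi <- 2 * pi * fx$truth$dn[al, k] * 4.8 / lam
        v <- unclass(linear_retarder(phi, fx$truth$theta[al, k])) %*% v
      }
      want <- su2_to_so3(roundtrip(unitary_jones(v)))
      got <- est$rotations[[1]][, , (m - 1) * fx$geom$n_alines + al]
      expect_equal(got, want, tolerance = 1e-8)
    }
  }
  expect_true(all(est$valid))
})

test_that("known system correction restores the tissue-only forward model", {
  fx <- make_noiseless_raster(system = "random", seed = 13)
  sys <- with_seed_system(13)
  est <- estimate_rotations(fx$tomo, exact_recon_config())
  est <- apply_system_correction(est, sys$A, sys$B)
  # corrected rotations are transpose-symmetric (QU-plane axes) ...
  expect_lt(sym_resid(est$rotations[[1]]), 1e-8)
  # ... and equal the tissue-only model: peeling recovers the truth exactly
  fused <- fuse_spectral_bins(est)
  map <- peel_layers(fused, 4.8, 1300, exact_recon_config())
  expect_lt(max(abs(map$dn - fx$truth$dn)), 1e-8)
  sel <- fx$truth$dn > 1e-4
  expect_lt(max(circ_axis_diff(map$theta[sel], fx$truth$theta[sel])),
            1e-6)
})

test_that("fitted symmetrization drives the asymmetry to zero", {
  # identity system: the fitted correction is (close to) the identity
  fx <- make_noiseless_raster()
  est <- estimate_rotations(fx$tomo, exact_recon_config())
  fit <- fit_system_correction(
    est$rotations[[1]], est$ball[[1]], est$valid,
    est$n_alines, est$depth_pixels, mode = "raster",
    config = exact_recon_config()
  )
  expect_lt(fit$residual_asym, 1e-12)
  expect_lt(max(abs(fit$G_out %*% fit$G_in - diag(3))), 1e-5)

  # random systems: corrected asymmetry far below the uncorrected one
  for (seed in c(3, 17)) {
    fx <- make_noiseless_raster(system = "random", seed = seed)
    est <- estimate_rotations(fx$tomo, exact_recon_config())
    before <- sym_resid(est$rotations[[1]])
    est2 <- symmetrize_system(est, exact_recon_config())
    expect_lt(est2$corrections[[1]]$residual_asym, 1e-12)
    after <- sym_resid(est2$rotations[[1]])
    expect_lt(after, before * 1e-6 + 1e-12)
  }
})

test_that("symmetrization refuses degenerate inputs", {
  fx <- make_noiseless_raster(n_fast = 4L, n_slow = 1L, depth = 8L)
  est <- estimate_rotations(fx$tomo, exact_recon_config())
  est$valid[] <- FALSE
  expect_error(
    fit_system_correction(est$rotations[[1]], NULL, est$valid,
                          est$n_alines, est$depth_pixels,
                          config = exact_recon_config()),
    "insufficient"
  )
})

test_that("catheter compensation isolates the sample round trip", {
  ph <- two_layer_cyl_phantom()
  geom <- small_helical(alines_per_rev = 48, n_rev = 1, depth = 80,
                        axis_center = ph$cylindrical$axis_center)
  truth <- sample_ground_truth(ph, geom)
  cath <- list(ret_mean = 0.5, ret_amp = 0.3, axis_mean = 0.2,
               axis_amp = 0.5, phase = 1.1)
  tomo <- synthesize_tomogram(truth, config = noiseless_config(catheter = cath))
  est <- estimate_rotations(tomo, exact_recon_config())
  est <- compensate_catheter(est)
  fused <- fuse_spectral_bins(est)
  map <- peel_layers(fused, 4.8, 1300, exact_recon_config())
  expect_lt(max(abs(map$dn - truth$dn)), 1e-8)
  sel <- truth$dn > 1e-4
  expect_lt(max(circ_axis_diff(map$theta[sel], truth$theta[sel])), 1e-6)

  # without a catheter, compensation is a no-op on raster data
  fx <- make_noiseless_raster()
  est <- estimate_rotations(fx$tomo, exact_recon_config())
  est2 <- compensate_catheter(est)
  expect_identical(est$rotations, est2$rotations)
})

test_that("layer peeling matches the direct per-layer reference solver", {
  set.seed(31)
  for (rep in 1:10) {
    stack <- random_retarder_stack(20, phi_max = 0.4)
    rarr <- array(0, c(3, 3, 20))
    for (m in 1:20) rarr[, , m] <- su2_to_so3(stack$roundtrips[[m]])
    fused <- list(rotations = rarr, valid = matrix(TRUE, 1, 20),
                  n_alines = 1L, depth_pixels = 20L, mode = "raster")
    map <- peel_layers(fused, 4.8, 1300, exact_recon_config())
    ref <- solve_layers_direct(stack$roundtrips, 4.8, 1300)
    expect_equal(as.numeric(map$dn), ref$dn, tolerance = 1e-8)
    expect_lt(max(circ_axis_diff(as.numeric(map$theta), ref$theta)), 1e-8)
    # both agree with the generating stack
    expect_equal(ref$phi, stack$phi, tolerance = 1e-8)
  }
  # identity round trips peel to zero birefringence
  fused <- list(rotations = rotm_identity(12), valid = matrix(TRUE, 1, 12),
                n_alines = 1L, depth_pixels = 12L, mode = "raster")
  map <- peel_layers(fused, 4.8, 1300, exact_recon_config())
  expect_true(all(map$dn == 0))
})

test_that("DOP is 1 for clean data, low for noise, and unitary-invariant", {
  # per-pixel (1x1 kernel) DOP of fully polarized data is exactly 1
  fx <- make_noiseless_raster()
  dop <- compute_dop(fx$tomo, recon_config(dop_kernel = c(1, 1)))
  expect_equal(as.numeric(dop), rep(1, length(dop)), tolerance = 1e-12)
  # kernel averaging over smoothly varying states stays close to 1
  expect_gt(min(compute_dop(fx$tomo, recon_config())), 0.99)

  # unitary invariance: a global system rotation leaves DOP unchanged
  fx2 <- make_noiseless_raster(system = "random", seed = 2)
  dop2 <- compute_dop(fx2$tomo, recon_config(dop_kernel = c(1, 1)))
  expect_equal(as.numeric(dop2), rep(1, length(dop2)), tolerance = 1e-12)

  # pure noise: DOP ~ O(1/sqrt(K)) for a K-sample kernel
  dark <- make_layered_phantom(
    data.frame(thickness = 300, dn = 0, theta = 0, reflectivity = 0),
    lateral_extent = c(400, 300)
  )
  geom <- small_raster(16, 1, 64)
  tomo <- synthesize_tomogram(dark, geom,
                              measurement_config(snr_db = 30, seed = 5))
  dop <- compute_dop(tomo, recon_config(dop_kernel = c(5, 5)))
  expect_lt(stats::median(dop), 0.3)
  expect_error(compute_dop(tomo, recon_config(dop_kernel = c(999, 5))),
               "larger")
})

test_that("mask thresholds behave at the extremes", {
  fx <- make_noiseless_raster()
  map <- peel_layers(fuse_spectral_bins(
    estimate_rotations(fx$tomo, exact_recon_config())
  ), 4.8, 1300, exact_recon_config())
  dop <- compute_dop(fx$tomo, recon_config())
  m0 <- apply_mask(map, dop, recon_config(dop_threshold = 0))
  expect_true(all(m0$mask))
  # an unreachable threshold masks everything and zeroes dn for display
  m1 <- apply_mask(map, dop * 0.5, recon_config(dop_threshold = 0.7))
  expect_false(any(m1$mask))
  expect_true(all(m1$dn == 0))
  expect_true(all(m1$dn_unmasked >= 0))
  expect_error(recon_config(dop_threshold = 1.5), "0, 1")
})

test_that("axis referencing applies offsets, sheath frames and flips", {
  map <- structure(
    list(
      dn = matrix(1e-3, 4, 10),
      theta = matrix(rep(seq(-0.6, 0.6, length.out = 10), each = 4), 4, 10),
      dn_unmasked = matrix(1e-3, 4, 10)
    ),
    class = "psoct_polmap"
  )
  # manual zero offset = identity
  out <- reference_axis(map, recon_config(
    axis_reference = list(mode = "manual", offset = 0)
  ))
  expect_equal(out$theta, map$theta)
  # manual offset shifts modulo pi
  out <- reference_axis(map, recon_config(
    axis_reference = list(mode = "manual", offset = 0.3)
  ))
  expect_equal(out$theta, wrap_axis_angle(map$theta - 0.3))

  # sheath: per-A-line offset removal; double application is idempotent
  sh <- map
  off <- c(0.1, -0.2, 0.3, 0)
  sh$theta <- wrap_axis_angle(sh$theta + off)
  cfg <- recon_config(axis_reference = list(mode = "sheath", known = 0))
  out <- reference_axis(sh, cfg, sheath_rows = 1:10)
  expect_equal(out$theta, wrap_axis_angle(map$theta + off - off),
               tolerance = 1e-10)
  twice <- reference_axis(out, cfg, sheath_rows = 1:10)
  expect_equal(twice$theta, out$theta, tolerance = 1e-10)
  expect_error(
    reference_axis(sh, recon_config(
      axis_reference = list(mode = "sheath")
    )),
    "sheath"
  )

  # mirror disambiguation picks the flipped hypothesis when it fits better
  flipped <- map
  flipped$theta <- wrap_axis_angle(-map$theta)
  out <- reference_axis(flipped, recon_config(
    axis_reference = list(
      mode = "manual", offset = 0,
      flip_check = list(rows = 1:10, known = map$theta)
    )
  ))
  expect_true(out$axis_flipped)
  expect_equal(out$theta, map$theta, tolerance = 1e-10)
})

test_that("growing the averaging kernel reduces the noisy dn error", {
  ph <- make_layered_phantom(
    data.frame(thickness = 400, dn = 1e-3, theta = 30 * pi / 180,
               reflectivity = 1),
    lateral_extent = c(40 * 25, 25)
  )
  geom <- small_raster(40, 1, 48)
  truth <- sample_ground_truth(ph, geom)
  tomo <- synthesize_tomogram(truth, config = measurement_config(
    snr_db = 30, speckle = TRUE, n_spectral_bins = 1, seed = 11
  ))
  meds <- vapply(c(1, 5, 9), function(k) {
    rc <- recon_config(stokes_kernel = c(k, k), local_kernel = c(k, k),
                       symmetrize = FALSE)
    est <- estimate_rotations(tomo, rc)
    map <- peel_layers(fuse_spectral_bins(est), 4.8, 1300, rc)
    stats::median(abs(map$dn - truth$dn))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("spectral-bin fusion recovers the truth through a dispersive system", {
  ph <- make_layered_phantom(two_layer_table(), lateral_extent = c(300, 300))
  geom <- small_raster(8, 2, 80)
  truth <- sample_ground_truth(ph, geom)
  cfg <- measurement_config(snr_db = Inf, speckle = FALSE,
                            n_spectral_bins = 3, system = "random",
                            system_bin_spread = 0.15, seed = 23)
  tomo <- synthesize_tomogram(truth, config = cfg)
  rc <- exact_recon_config()
  est <- symmetrize_system(estimate_rotations(tomo, rc), rc)
  fused <- fuse_spectral_bins(est)
  map <- peel_layers(fused, 4.8, 1300, rc)
  expect_lt(max(abs(map$dn - truth$dn)), 1e-6)
  # axes agree across the volume up to one global offset (modulo mirror)
  sel <- truth$dn > 1e-4
  d1 <- wrap_axis_angle(map$theta - truth$theta)[sel]
  d2 <- wrap_axis_angle(-map$theta - truth$theta)[sel]
  spread <- function(d) {
    off <- 0.5 * atan2(mean(sin(2 * d)), mean(cos(2 * d)))
    max(abs(wrap_axis_angle(d - off)))
  }
  expect_lt(min(spread(d1), spread(d2)), 1e-5)
})
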