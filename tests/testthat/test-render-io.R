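# Rendering, containers, configuration files and the CLI.

fake_map <- function(na = 24, nz = 30, geom = NULL) {
  structure(
    list(
      dn = matrix(1e-3, na, nz),
      theta = matrix(0.3, na, nz),
      dop = matrix(1, na, nz),
      mask = matrix(TRUE, na, nz),
      geometry = geom
    ),
    class = "psoct_polmap"
  )
}

test_that("composite map saturates, blanks and is axis-periodic", {
  m <- fake_map()
  m$dn[] <- 0
  expect_true(all(composite_map(m) == 0))

  m$dn[] <- 1.3e-3
  comp <- composite_map(m)  # default display range 0 - 1.3e-3
  expect_equal(max(comp), 1, tolerance = 1e-12)
  # brightness saturates: doubling dn changes nothing
  m2 <- m
  m2$dn[] <- 2.6e-3
  expect_equal(composite_map(m2), composite_map(m), ignore_attr = TRUE)

  # hue is periodic with period pi in the axis angle
  ma <- m
  ma$theta[] <- 0.4
  mb <- m
  mb$theta[] <- 0.4 - pi
  expect_equal(composite_map(ma), composite_map(mb), tolerance = 1e-12,
               ignore_attr = TRUE)

  # masked pixels are black
  m$mask[3, 5] <- FALSE
  comp <- composite_map(m)
  expect_equal(comp[3, 5, ], c(0, 0, 0))
  expect_error(composite_map(m, dn_max = 0), "positive")
})

test_that("view extraction projects over the stated extents", {
  geom <- small_raster(10, 8, 40)
  map <- fake_map(80, 40, geom)
  # depth-structured volume: value = depth index
  map$dn <- matrix(rep(seq_len(40), each = 80), 80, 40)
  vol <- as_volume(map)

  # single-pixel extent at a pixel center = plain slice
  v <- extract_view(vol, view_spec("enface", position = 9.5 * 4.8,
                                   extent = 4.8))
  expect_true(all(v == 10))
  # 30 um extent fully inside a uniform slab -> slab value
  map2 <- fake_map(80, 40, geom)
  map2$dn <- matrix(rep(ifelse(seq_len(40) > 20, 7, 1), each = 80), 80, 40)
  vol2 <- as_volume(map2)
  v <- extract_view(vol2, view_spec("enface", position = 30 * 4.8,
                                    extent = 30))
  expect_true(all(v == 7))
  # constant volume: any extent gives the constant
  vc <- as_volume(fake_map(80, 40, geom))
  for (ext in c(4.8, 30, 70)) {
    expect_true(all(abs(extract_view(
      vc, view_spec("cross_fast", position = 100, extent = ext)
    ) - 1e-3) < 1e-15))
  }
  expect_error(extract_view(vol, view_spec("enface", 1e9, 30)), "outside")
  expect_error(view_spec("enface", 10, 0), "positive")

  # projection width: a delta plane spreads exactly over the window
  map3 <- fake_map(80, 40, geom)
  map3$dn[] <- 0
  map3$dn[, 20] <- 1
  vol3 <- as_volume(map3)
  v <- extract_view(vol3, view_spec("enface", position = 19.5 * 4.8,
                                    extent = 5 * 4.8))
  expect_equal(unique(as.numeric(v)), 1 / 5, tolerance = 1e-12)

  # circular averaging of theta uses doubled angles
  mth <- fake_map(80, 40, geom)
  mth$theta <- matrix(rep(c(rep(80 * pi / 180, 20), rep(-80 * pi / 180, 20)),
                          each = 80), 80, 40)
  vth <- as_volume(mth)
  v <- extract_view(vth, view_spec("enface", position = 20 * 4.8,
                                   extent = 2 * 4.8), field = "theta")
  # mean of +80 and -80 degrees across the wrap is +/-90, not 0
  expect_equal(abs(unique(as.numeric(v))), pi / 2, tolerance = 1e-10)
})

test_that("helical views cover rotational, pullback, unwrapped, tangential", {
  geom <- small_helical(alines_per_rev = 36, n_rev = 4, depth = 30,
                        sheath = NULL)
  map <- fake_map(36 * 4, 30, geom)
  map$dn <- matrix(rep(seq_len(30), each = 36 * 4), 36 * 4, 30)
  vol <- as_volume(map)
  expect_identical(vol$coord$dims, c("angle", "pullback", "depth"))

  v <- extract_view(vol, view_spec("rot_cross", position = 40, extent = 60))
  expect_identical(dim(v), c(36L, 30L))
  v <- extract_view(vol, view_spec("pullback_cross", position = 100,
                                   extent = 2.5))
  expect_identical(dim(v), c(4L, 30L))
  v <- extract_view(vol, view_spec("unwrapped_enface",
                                   position = 10 * 4.8, extent = 30))
  expect_identical(dim(v), c(36L, 4L))
  # mean over the ~30 um depth window around index 10
  expect_equal(length(unique(as.numeric(v))), 1L)
  expect_true(v[1, 1] > 8 && v[1, 1] < 13)
  v <- extract_view(vol, view_spec("tangential",
                                   position = geom$r_start + 60,
                                   extent = 30))
  expect_identical(nrow(v), 4L)
  expect_true(any(is.finite(v)))
  # raster-only views refuse helical volumes
  expect_error(extract_view(vol, view_spec("cross_fast", 10, 70)), "raster")
})

test_that("containers and configs round-trip", {
  ph <- make_wmt_phantom(seed = 2, size = c(32, 32, 32), n_tracts = 2)
  path <- tempfile(fileext = ".psoct")
  write_container(ph, path)
  back <- read_container(path)
  expect_identical(back$dn, ph$dn)
  expect_identical(back$theta, ph$theta)
  expect_error(read_container(
    {
      p <- tempfile()
      saveRDS(list(container = "other"), p)
      p
    }
  ), "not a psoct container")

  cfg <- list(
    phantom = list(
      kind = "layered",
      layers = list(
        list(thickness = 250, dn = 5e-4, theta = 0.35, reflectivity = 1),
        list(thickness = 250, dn = 1.2e-3, theta = -1.05, reflectivity = 2)
      ),
      lateral_extent = c(200, 100)
    ),
    geometry = list(mode = "raster", n_fast = 8, n_slow = 4,
                    depth_pixels = 32),
    measurement = list(snr_db = 35, n_spectral_bins = 1, seed = 4),
    views = list(list(kind = "enface", position = 48, extent = 30))
  )
  yml <- tempfile(fileext = ".yaml")
  write_config(cfg, yml)
  got <- read_config(yml)
  expect_s3_class(got$phantom, "psoct_phantom")
  expect_identical(got$geometry$n_alines, 32L)
  expect_equal(got$measurement$snr_db, 35)
  expect_identical(got$views[[1]]$kind, "enface")
})

test_that("tiff and png exports write valid files with range metadata", {
  map <- fake_map()
  tif <- tempfile(fileext = ".tif")
  export_map_tiff(map, tif, intensity_db = matrix(20, 24, 30))
  expect_true(file.exists(tif))
  planes <- tiff::readTIFF(tif, all = TRUE)
  expect_length(planes, 4)  # dn, theta, dop, intensity
  meta <- jsonlite::read_json(paste0(tif, ".json"))
  expect_equal(unlist(meta$ranges$dn), c(0, 1.3e-3))
  # dn = 1e-3 over range [0, 1.3e-3]
  expect_equal(planes[[1]][1, 1], 1e-3 / 1.3e-3, tolerance = 1e-6)

  png_path <- tempfile(fileext = ".png")
  export_composite_png(composite_map(map), png_path)
  expect_true(file.exists(png_path))
  expect_identical(dim(png::readPNG(png_path)), c(24L, 30L, 3L))
})

test_that("cli runs the three-step pipeline deterministically", {
  wd <- tempfile("cli")
  dir.create(wd)
  yml <- file.path(wd, "demo.yaml")
  write_config(list(
    phantom = list(
      kind = "layered",
      layers = list(
        list(thickness = 200, dn = 1e-3, theta = 0.3, reflectivity = 1)
      ),
      lateral_extent = c(150, 100)
    ),
    geometry = list(mode = "raster", n_fast = 6, n_slow = 4,
                    depth_pixels = 32),
    measurement = list(snr_db = 30, n_spectral_bins = 1, seed = 1),
    reconstruction = list(symmetrize = FALSE, stokes_kernel = c(3, 3),
                          local_kernel = c(3, 3), dop_kernel = c(3, 3))
  ), yml)
  t1 <- file.path(wd, "t1.psoct")
  t2 <- file.path(wd, "t2.psoct")
  expect_identical(psoct_cli(c("simulate", "--config", yml, "--out", t1,
                               "--seed", "7", "--log-level", "quiet")), 0L)
  expect_identical(psoct_cli(c("simulate", "--config", yml, "--out", t2,
                               "--seed", "7", "--log-level", "quiet")), 0L)
  a <- read_container(t1)
  b <- read_container(t2)
  expect_identical(a$stokes, b$stokes)

  mp <- file.path(wd, "map.psoct")
  expect_identical(psoct_cli(c("reconstruct", "--in", t1, "--out", mp,
                               "--config", yml, "--log-level", "quiet")), 0L)
  map <- read_container(mp)
  expect_true(all(c("dn", "theta", "dop", "mask") %in% names(map)))

  expect_identical(psoct_cli(c("render", "--in", mp, "--out",
                               file.path(wd, "img"),
                               "--log-level", "quiet")), 0L)
  expect_true(file.exists(file.path(wd, "img_composite.png")))
  expect_true(file.exists(file.path(wd, "img_contrasts.tif")))

  # usage errors exit 2
  expect_identical(psoct_cli(character(0)), 2L)
  expect_identical(psoct_cli(c("explode")), 2L)
  expect_identical(psoct_cli(c("simulate", "--bogus", "x")), 2L)
  expect_identical(suppressMessages(
    psoct_cli(c("simulate", "--config", "missing.yaml", "--out", "x"))
  ), 1L)
})
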