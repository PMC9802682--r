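# Container and file I/O. Phantoms, geometries, tomograms and reconstructed
# maps are stored in a self-describing named-dataset container (a versioned R
# serialization that round-trips arrays bit-exactly), configurations in YAML,
# and rendered contrasts as normalized 32-bit TIFF planes (with JSON range
# sidecars) or 8-bit PNG composites.

CONTAINER_VERSION <- 1L

#' Write a container
#'
#' Serializes any of the package's objects (phantom, geometry, tomogram,
#' polarimetry map, volume) as a self-describing container with named
#' datasets and metadata attributes; arrays round-trip bit-exactly.
#'
#' @param x object to store
#' @param path output file path (conventional extension `.psoct`)
#' @return `path`, invisibly
#' @export
write_container <- function(x, path) {
  payload <- list(
    container = "psoct",
    version = CONTAINER_VERSION,
    class = class(x),
    data = x
  )
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' Read a container written by [write_container()]
#'
#' @param path file path
#' @return the stored object
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$container, "psoct")) {
    stop("not a psoct container")
  }
  if (payload$version > CONTAINER_VERSION) {
    stop("container written by a newer package version")
  }
  payload$data
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain top-level sections `phantom`, `geometry`,
#' `measurement`, `reconstruction`, `views`; each is translated into the
#' corresponding constructor call. See the package vignette for the schema.
#'
#' @param path YAML file
#' @return named list of constructed configuration objects
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  if (!is.null(cfg$phantom)) {
    p <- cfg$phantom
    out$phantom <- switch(p$kind %||% "layered",
      layered = {
        layers <- as.data.frame(do.call(rbind, lapply(p$layers, as.data.frame)))
        args <- p
        args$kind <- NULL
        args$layers <- NULL
        do.call(make_layered_phantom, c(list(layers = layers), args))
      },
      wmt = make_wmt_phantom(
        seed = p$seed %||% 1L,
        size = unlist(p$size %||% c(48, 48, 48)),
        n_tracts = p$n_tracts %||% 3L
      ),
      stop(sprintf("unknown phantom kind '%s'", p$kind))
    )
  }
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    mode <- g$mode %||% "raster"
    g$mode <- NULL
    out$geometry <- do.call(make_scan_geometry, c(list(mode = mode), g))
  }
  if (!is.null(cfg$measurement)) {
    out$measurement <- do.call(measurement_config, cfg$measurement)
  }
  if (!is.null(cfg$reconstruction)) {
    out$reconstruction <- do.call(recon_config, cfg$reconstruction)
  }
  if (!is.null(cfg$views)) {
    out$views <- lapply(cfg$views, function(v) do.call(view_spec, v))
  }
  out
}

#' Write a per-contrast TIFF stack
#'
#' Each scalar contrast (dn, theta, dop, intensity) is written as a 32-bit
#' TIFF plane normalized to [0, 1] over its display range (dn: 0 to
#' `dn_max`; theta: -pi/2 to pi/2; dop: 0 to 1; intensity: `clip` dB); the
#' ranges are recorded in a JSON sidecar `<path>.json` so the physical
#' values can be restored exactly.
#'
#' @param map `psoct_polmap`
#' @param path output TIFF path
#' @param fields which map fields to write
#' @param intensity_db optional intensity matrix appended as a plane
#' @param dn_max birefringence display maximum
#' @param clip intensity display range, dB
#' @return `path`, invisibly
#' @export
export_map_tiff <- function(map, path,
                            fields = c("dn", "theta", "dop"),
                            intensity_db = NULL,
                            dn_max = 1.3e-3, clip = c(0, 40)) {
  ranges <- list(
    dn = c(0, dn_max), theta = c(-pi / 2, pi / 2), dop = c(0, 1),
    intensity_db = clip, mask = c(0, 1)
  )
  planes <- list()
  meta <- list()
  for (f in fields) {
    m <- map[[f]]
    if (is.null(m)) stop(sprintf("map has no field '%s'", f))
    planes[[f]] <- m * 1
    meta[[f]] <- ranges[[f]] %||% range(m, na.rm = TRUE)
  }
  if (!is.null(intensity_db)) {
    planes$intensity_db <- intensity_db
    meta$intensity_db <- ranges$intensity_db
  }
  planes <- Map(function(m, rg) {
    m <- (m - rg[1L]) / (rg[2L] - rg[1L])
    m[is.na(m)] <- 0
    pmin(pmax(m, 0), 1)
  }, planes, meta)
  tiff::writeTIFF(unname(planes), path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(planes = names(planes), ranges = meta),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a composite image as PNG
#'
#' @param composite RGB array from [composite_map()] (values in [0, 1])
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
export_composite_png <- function(composite, path) {
  png::writePNG(composite, path)
  invisible(path)
}

#' Write a pipeline configuration to YAML
#'
#' Writes the raw configuration list (the `raw` field of [read_config()]'s
#' result, or any list following the same schema) so a phantom, geometry and
#' measurement can be regenerated from file.
#'
#' @param cfg named list (sections `phantom`, `geometry`, `measurement`,
#'   `reconstruction`, `views`)
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
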