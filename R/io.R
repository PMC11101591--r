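# File interfaces: binary geometry rasters (PNG/TIFF), composition
# snapshots (CSV / 32-bit float TIFF of Ca wt%), BMDD tables, YAML
# configurations and JSON run manifests. The spatial resolution lambda is
# always supplied via the configuration, never parsed from image metadata.

#' Read a binary trabecular geometry from a raster image
#'
#' Any nonzero pixel (first channel) is bone matrix.
#'
#' @param path PNG or TIFF file.
#' @param lambda Pixel side length, µm.
#' @return A [label_grid].
#' @export
read_geometry_image <- function(path, lambda) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  label_grid(img != 0, lambda)
}

#' Write a label grid as an 8-bit image (bone = 255, marrow = 0)
#'
#' @param grid A [label_grid].
#' @param path Output path; format chosen from the extension (.png/.tif).
#' @export
write_geometry_image <- function(grid, path) {
  stopifnot(inherits(grid, "label_grid"))
  img <- matrix(as.numeric(grid$labels), nrow(grid$labels),
                ncol(grid$labels))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("writing PNG requires the 'png' package")
      png::writePNG(img, path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(img, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Export a composition snapshot as long-format CSV
#'
#' One row per bone pixel: `x` (column), `y` (row), `alpha`, `ca_wt_pct`.
#'
#' @param field Ash-fraction matrix (`NA` on marrow).
#' @param grid A [label_grid].
#' @param path Output CSV path.
#' @param constants A [material_constants] list.
#' @export
write_composition_csv <- function(field, grid, path,
                                  constants = material_constants()) {
  stopifnot(inherits(grid, "label_grid"))
  idx <- which(grid$labels != 0)
  rc <- arrayInd(idx, dim(grid$labels))
  a <- field[idx]
  utils::write.csv(
    data.frame(x = rc[, 2], y = rc[, 1], alpha = a,
               ca_wt_pct = ca_from_ash(a, constants)),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Export a calcium map as a 32-bit float TIFF
#'
#' Stores `Ca wt% / 100` per pixel (TIFF float samples must lie in
#' \[0, 1\]). Marrow pixels carry the sentinel value 1.0, which no bone
#' pixel can reach (the calcium cap is ~0.30 on this scale).
#'
#' @inheritParams write_composition_csv
#' @param path Output TIFF path.
#' @export
write_composition_tiff <- function(field, grid, path,
                                   constants = material_constants()) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF requires the 'tiff' package")
  stopifnot(inherits(grid, "label_grid"))
  ca <- matrix(1, nrow(grid$labels), ncol(grid$labels))
  bone <- grid$labels != 0
  ca[bone] <- ca_from_ash(field[bone], constants) / 100
  tiff::writeTIFF(ca, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a BMDD as a two-column CSV
#'
#' Columns `bin_centre_ca_wt_pct` and `frequency`.
#'
#' @param bmdd A [compute_bmdd()] object.
#' @param path Output CSV path.
#' @export
write_bmdd_csv <- function(bmdd, path) {
  stopifnot(inherits(bmdd, "bmdd"))
  utils::write.csv(
    data.frame(bin_centre_ca_wt_pct = bmdd$bin_centres,
               frequency = bmdd$frequency),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file.
#' @return For `read_config`, a `sim_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$thickness_range))
    vals$thickness_range <- as.numeric(vals$thickness_range)
  do.call(simulation_config, vals)
}

#' @rdname read_config
#' @param config A [simulation_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  flat <- config[!vapply(config, is.null, logical(1))]
  extras <- c(flat$params_extra, flat$law_extra)
  flat$params_extra <- NULL
  flat$law_extra <- NULL
  yaml::write_yaml(c(flat, extras), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Every parameter and seed needed to re-run a result bit-identically,
#' plus the package version.
#'
#' @param result A `sim_result` or `sim_replicates`.
#' @param path Output JSON path.
#' @export
write_manifest <- function(result, path) {
  cfg <- result$config
  cfg$params_extra <- if (length(cfg$params_extra)) cfg$params_extra else NULL
  cfg$law_extra <- if (length(cfg$law_extra)) cfg$law_extra else NULL
  manifest <- list(
    package = "bmusim",
    version = as.character(utils::packageVersion("bmusim")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    n_reps = if (inherits(result, "sim_replicates")) result$n_reps else 1L
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
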