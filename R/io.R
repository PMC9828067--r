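# Shared I/O: hyperspectral stacks (multi-page TIFF + wavelength sidecar),
# portable MSI text format (long CSV + JSON metadata), run reports.
# Conventions: pixel coordinates 0-based, x right / y down; CSV is
# comma-separated UTF-8 with "." decimal separator and a mandatory header.

#' Write a hyperspectral image as a multi-page TIFF with sidecar
#'
#' Channels are written as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' scale factor, wavelength axis and pixel size go to a JSON sidecar so the
#' cube round-trips to within float-32 storage precision.
#'
#' @param image A [hyperspectral_image].
#' @param path Output TIFF path.
#' @param sidecar Sidecar JSON path (default `<path>.json`).
#' @return Invisibly, the sidecar path.
#' @export
write_hyperspectral <- function(image, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(image, "hyperspectral_image"))
  cube <- image$data
  scale <- max(cube, 1e-300)
  pages <- lapply(seq_len(dim(cube)[3]), function(ch) cube[, , ch] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(list(wavelength = image$wavelength,
                            pixel_size_nm = image$pixel_size_nm,
                            scale = scale),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a hyperspectral image from a multi-page TIFF with sidecar
#'
#' @param path TIFF path (channels as pages).
#' @param sidecar Sidecar JSON with `wavelength`, `pixel_size_nm`, `scale`;
#'   alternatively `wavelength` may be passed directly.
#' @param wavelength Optional wavelength axis overriding the sidecar.
#' @return A [hyperspectral_image]. Errors when the wavelength count does
#'   not match the page count; warns when the channel count is not 32.
#' @export
read_hyperspectral <- function(path, sidecar = paste0(path, ".json"),
                               wavelength = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  if (is.null(wavelength)) wavelength <- meta$wavelength
  if (is.null(wavelength)) stop("no wavelength axis: sidecar missing")
  if (length(wavelength) != length(pages))
    stop("wavelength count ", length(wavelength),
         " does not match page count ", length(pages))
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  cube <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (ch in seq_along(pages)) cube[, , ch] <- pages[[ch]] * scale
  hyperspectral_image(cube, wavelength,
                      pixel_size_nm = if (!is.null(meta$pixel_size_nm))
                        meta$pixel_size_nm else 300)
}

#' Write an MSI dataset to the portable text format
#'
#' Long-format CSV (`x,y,mz,intensity`, one row per centroid peak) plus a
#' JSON metadata file with the grid pitch and pixel count.
#'
#' @param dataset An [msi_dataset].
#' @param path CSV path.
#' @param meta Metadata JSON path (default `<path>.json`).
#' @return Invisibly, `path`.
#' @export
write_msi <- function(dataset, path, meta = paste0(path, ".json")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  n <- vapply(dataset$spectra, function(s) length(s$mz), 1L)
  tab <- data.frame(
    x = rep(dataset$coords$x, n),
    y = rep(dataset$coords$y, n),
    mz = unlist(lapply(dataset$spectra, `[[`, "mz")),
    intensity = unlist(lapply(dataset$spectra, `[[`, "intensity")))
  write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(pitch_um = dataset$pitch_um,
                            n_pixels = n_pixels(dataset)),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MSI dataset from the portable text format
#'
#' @param path CSV with columns `x,y,mz,intensity`.
#' @param meta Optional metadata JSON (grid pitch).
#' @return An [msi_dataset]. Unsorted m/z axes are sorted with a warning;
#'   an empty pixel list is an error.
#' @export
read_msi <- function(path, meta = paste0(path, ".json")) {
  tab <- read.csv(path)
  if (!all(c("x", "y", "mz", "intensity") %in% names(tab)))
    stop("malformed MSI file: need columns x,y,mz,intensity")
  if (nrow(tab) == 0) stop("empty pixel list")
  key <- paste(tab$x, tab$y)
  ord <- !duplicated(key)
  coords <- tab[ord, c("x", "y")]
  idx <- split(seq_len(nrow(tab)), factor(key, levels = key[ord]))
  spectra <- lapply(idx, function(i)
    list(mz = tab$mz[i], intensity = tab$intensity[i]))
  pitch <- 10
  if (file.exists(meta)) {
    m <- jsonlite::read_json(meta, simplifyVector = TRUE)
    if (!is.null(m$pitch_um)) pitch <- m$pitch_um
  }
  msi_dataset(coords, spectra, pitch_um = pitch)
}

#' Validate a run configuration list
#'
#' Checks a nested run configuration against the known schema before any
#' computation; unknown keys are rejected rather than silently ignored.
#'
#' @param config Named list; allowed keys: `lco`, `msi`, `lco_sim`,
#'   `msi_sim`, `seed`, `outdir`, `verbose`.
#' @return The validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  allowed <- c("lco", "msi", "lco_sim", "msi_sim", "seed", "outdir", "verbose")
  if (is.null(names(config)) || any(names(config) == ""))
    stop("run config must be a fully named list")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(config$seed) && (!is.numeric(config$seed) ||
                                config$seed != round(config$seed)))
    stop("seed must be an integer")
  invisible(config)
}

#' Write an analysis report: CSV tables and a JSON run manifest
#'
#' Each element of `results` that is a data frame or matrix is written as
#' `<name>.csv` (empty tables keep their headers); the manifest echoes the
#' seed and configuration and records row counts and the package version,
#' which is sufficient to re-run bit-identically.
#'
#' @param results Named list of data frames / matrices.
#' @param outdir Output directory (created if needed).
#' @param seed Seed to record.
#' @param config Configuration list to echo.
#' @return Invisibly, the manifest path.
#' @export
write_report <- function(results, outdir, seed = NULL, config = NULL) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  if (length(results) && (is.null(names(results)) || any(names(results) == "")))
    stop("results must be a named list")
  files <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) x <- as.data.frame(x)
    if (!is.data.frame(x)) next
    f <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(x, f, row.names = FALSE)
    files[[nm]] <- list(file = basename(f), rows = nrow(x))
  }
  manifest <- list(package = "vesselmap",
                   version = as.character(utils::packageVersion("vesselmap")),
                   seed = seed, config = config, tables = files)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mpath)
}
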