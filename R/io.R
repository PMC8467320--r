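#' Write / read a spectrum as two-column CSV
#'
#' Plain CSV with columns `wavenumber`, `intensity`, "." decimal, header
#' row.
#'
#' @param spec A [spectrum()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  utils::write.csv(data.frame(wavenumber = spec$wavenumbers,
                              intensity = spec$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param kind,meta Passed to [spectrum()] on read.
#' @export
read_spectrum_csv <- function(path, kind = "raman", meta = list()) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    stop("spectrum file ", path, " needs two columns (wavenumber, intensity)")
  spectrum(df[[1L]], df[[2L]], kind = kind, meta = meta)
}

#' Write a spectrum grid to disk
#'
#' One CSV per grid point (`spot_<row>_<col>.csv`) plus a JSON manifest
#' (`manifest.json`) carrying the layout, period and seed.
#'
#' @param grid A [spectrum_grid()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_spectrum_grid <- function(grid, dir) {
  stopifnot(inherits(grid, "ppdx_spectrum_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(grid$spectra))
  for (i in seq_along(grid$spectra)) {
    row <- (i - 1L) %/% grid$n_cols + 1L
    col <- (i - 1L) %% grid$n_cols + 1L
    files[i] <- sprintf("spot_%02d_%02d.csv", row, col)
    write_spectrum_csv(grid$spectra[[i]], file.path(dir, files[i]))
  }
  manifest <- list(n_rows = grid$n_rows, n_cols = grid$n_cols,
                   dx = grid$dx, dy = grid$dy,
                   week = grid$meta$week %||% NA,
                   seed = grid$meta$seed %||% NA,
                   files = files)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_grid
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_spectrum_grid()].
#' @export
read_spectrum_grid <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  spectra <- lapply(man$files, function(f)
    read_spectrum_csv(file.path(dir, f)))
  wk <- man$week
  spectrum_grid(spectra, man$n_rows, man$n_cols, man$dx, man$dy,
                meta = list(week = if (is.null(wk) || is.na(wk)) NULL else wk))
}

#' Write / read a binary mask
#'
#' Masks are stored as PGM (plain-text P2, 0 = background, 255 = crack) or
#' PNG, with a JSON sidecar (`<file>.json`) carrying the pixel size in
#' micrometers.
#'
#' @param mask A [binary_mask()].
#' @param path Output file; format chosen by extension (`.pgm` or `.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  px <- mask$pixels
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
    write(t(px) * 255L, con, ncolumns = ncol(px))
  } else if (ext == "png") {
    png::writePNG(matrix(as.numeric(px), nrow(px), ncol(px)), path)
  } else stop("unsupported mask format: .", ext)
  jsonlite::write_json(list(pixel_size = mask$pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_size Micrometers per pixel; when `NULL` (default), read from
#'   the JSON sidecar.
#' @export
read_mask <- function(path, pixel_size = NULL) {
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no pixel_size given and sidecar ", sidecar, " not found")
    pixel_size <- jsonlite::read_json(sidecar)$pixel_size
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (tok[1L] != "P2") stop("only plain-text (P2) PGM masks are supported")
    nc <- as.integer(tok[2L]); nr <- as.integer(tok[3L])
    vals <- as.integer(tok[-(1:4)])
    if (length(vals) != nr * nc) stop("corrupt PGM: wrong pixel count")
    px <- matrix(vals, nr, nc, byrow = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    px <- img
  } else stop("unsupported mask format: .", ext)
  binary_mask(px > max(px) / 2, pixel_size)
}

#' Write / read a thermogram as two-column CSV
#'
#' Columns `temperature`, `heat_flow`; a JSON sidecar stores the scan rate
#' and metadata.
#'
#' @param tg A [thermogram()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thermogram_csv <- function(tg, path) {
  stopifnot(inherits(tg, "ppdx_thermogram"))
  utils::write.csv(data.frame(temperature = tg$temperature,
                              heat_flow = tg$heat_flow),
                   path, row.names = FALSE)
  jsonlite::write_json(list(scan_rate = tg$scan_rate, endo_up = TRUE),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thermogram_csv
#' @param scan_rate Degrees C per minute; when `NULL`, read from the
#'   sidecar (default 5 if absent).
#' @export
read_thermogram_csv <- function(path, scan_rate = NULL) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    stop("thermogram file ", path,
         " needs two columns (temperature, heat_flow)")
  endo_up <- TRUE
  if (is.null(scan_rate)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      man <- jsonlite::read_json(sidecar)
      scan_rate <- man$scan_rate %||% 5
      endo_up <- man$endo_up %||% TRUE
    } else scan_rate <- 5
  }
  thermogram(df[[1L]], df[[2L]], scan_rate = scan_rate, endo_up = endo_up)
}
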