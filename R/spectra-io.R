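#' Construct a wavelength-indexed spectrum
#'
#' The package's basic data carrier: a series of a dimensionless optical
#' quantity on a strictly ascending wavelength grid (nm).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly ascending,
#'   at least 2 points.
#' @param value Numeric vector of the same length.
#' @param kind One of `"reflectance"`, `"transmittance"`, `"parameter"`,
#'   `"absorbance"`.
#' @param label Free-text label.
#' @param clip For reflectance/transmittance kinds, clip values outside
#'   \[0, 1\] into \[1e-6, 1 - 1e-6\] (with the count recorded in attribute
#'   `"n_clipped"`) instead of erroring.
#' @return An object of class `km_spectrum`.
#' @examples
#' spectrum_km(c(300, 500, 700), c(0.05, 0.2, 0.4), "reflectance")
#' @export
spectrum_km <- function(wavelength, value,
                        kind = c("reflectance", "transmittance",
                                 "parameter", "absorbance"),
                        label = "", clip = FALSE) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(value) != length(wavelength))
    stop("`wavelength` and `value` lengths differ", call. = FALSE)
  if (any(!is.finite(wavelength)) || any(diff(wavelength) <= 0))
    stop("wavelengths must be finite and strictly ascending", call. = FALSE)

  n_clipped <- 0L
  if (kind %in% c("reflectance", "transmittance")) {
    out <- !is.na(value) & (value < 0 | value > 1)
    if (any(out)) {
      if (!clip)
        stop(sprintf("%d %s value(s) outside [0, 1]; use clip = TRUE",
                     sum(out), kind), call. = FALSE)
      n_clipped <- sum(out)
      value <- pmin(pmax(value, 1e-6), 1 - 1e-6)
    }
  }
  structure(
    list(wavelength = wavelength, value = value, kind = kind,
         label = as.character(label)[1]),
    n_clipped = n_clipped,
    class = "km_spectrum"
  )
}

#' @export
print.km_spectrum <- function(x, ...) {
  cat(sprintf("<km_spectrum [%s]%s: %d points, %g-%g nm>\n", x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  rng <- range(x$value, na.rm = TRUE)
  cat(sprintf("  value range: %.4g .. %.4g\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.data.frame.km_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, value = x$value)
}

#' @export
plot.km_spectrum <- function(x, ..., xlab = "wavelength (nm)", ylab = x$kind,
                             type = "l") {
  graphics::plot(x$wavelength, x$value, type = type, xlab = xlab, ylab = ylab,
                 main = x$label, ...)
  invisible(x)
}

#' Read a spectrum from a two-column delimited text file
#'
#' Expects columns `wavelength_nm, value`, comma- or tab-delimited (sniffed
#' from the first data line), with an optional header row and optional
#' `# key=value` comment lines.  A `# kind=...` comment overrides the `kind`
#' argument.  Reflectance/transmittance values outside \[0, 1\] are clipped
#' into \[1e-6, 1 - 1e-6\] and the count is reported via a message and the
#' `"n_clipped"` attribute.
#'
#' @param path File path.
#' @param kind Spectrum kind (see [spectrum_km()]).
#' @param label Label; defaults to the file name.
#' @return A `km_spectrum`.
#' @export
read_spectrum <- function(path, kind = "reflectance", label = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  km <- regmatches(meta, regexec("^#\\s*kind\\s*=\\s*(\\S+)", meta))
  km <- Filter(function(m) length(m) == 2, km)
  if (length(km) > 0) kind <- km[[1]][2]
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0)
    stop(sprintf("%s: no data rows", path), call. = FALSE)

  delim <- if (grepl("\t", body[length(body)])) "\t" else ","
  parts <- strsplit(body, delim, fixed = TRUE)
  first <- suppressWarnings(as.numeric(parts[[1]][1]))
  if (is.na(first)) { parts <- parts[-1]; body <- body[-1] }  # header row
  if (length(parts) < 2)
    stop(sprintf("%s: fewer than 2 data points", path), call. = FALSE)

  wl <- val <- numeric(length(parts))
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]][1:2]))
    if (length(parts[[i]]) < 2 || any(is.na(p)))
      stop(sprintf("%s: unparseable row %d: '%s'", path, i, body[i]),
           call. = FALSE)
    wl[i] <- p[1]; val[i] <- p[2]
  }
  if (any(diff(wl) <= 0))
    stop(sprintf("%s: wavelengths not strictly ascending", path),
         call. = FALSE)
  sp <- spectrum_km(wl, val, kind = kind, label = label, clip = TRUE)
  if (attr(sp, "n_clipped") > 0)
    message(sprintf("read_spectrum: clipped %d out-of-range value(s) in %s",
                    attr(sp, "n_clipped"), path))
  sp
}

#' Write a spectrum to CSV
#'
#' Writes `# kind=...` and `# label=...` comment lines followed by a
#' `wavelength_nm,value` header and full-precision values, so that
#' [read_spectrum()] round-trips losslessly.
#'
#' @param spectrum A `km_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "km_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", spectrum$kind), con)
  if (nzchar(spectrum$label))
    writeLines(sprintf("# label=%s", spectrum$label), con)
  writeLines("wavelength_nm,value", con)
  writeLines(paste(format(spectrum$wavelength, digits = 17, trim = TRUE),
                   format(spectrum$value, digits = 17, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Resample spectra onto a common wavelength grid
#'
#' Linear interpolation; extrapolation is never performed — the grid must lie
#' within the wavelength range of every input spectrum.
#'
#' @param spectra A `km_spectrum` or list of them.
#' @param grid Numeric vector of target wavelengths (nm), ascending.
#' @return A list of resampled `km_spectrum` objects (a single object if a
#'   single spectrum was given).
#' @export
resample_spectra <- function(spectra, grid) {
  single <- inherits(spectra, "km_spectrum")
  if (single) spectra <- list(spectra)
  stopifnot(all(vapply(spectra, inherits, TRUE, "km_spectrum")))
  grid <- as.numeric(grid)
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("`grid` must be ascending with >= 2 points", call. = FALSE)
  lo <- max(vapply(spectra, function(s) min(s$wavelength), 0))
  hi <- min(vapply(spectra, function(s) max(s$wavelength), 0))
  if (min(grid) < lo - 1e-9 || max(grid) > hi + 1e-9)
    stop(sprintf(
      "grid [%g, %g] nm extends beyond the common range [%g, %g] nm",
      min(grid), max(grid), lo, hi), call. = FALSE)
  out <- lapply(spectra, function(s) {
    v <- stats::approx(s$wavelength, s$value, xout = grid, method = "linear",
                       rule = 1)$y
    spectrum_km(grid, v, kind = s$kind, label = s$label)
  })
  if (single) out[[1]] else out
}

#' Average spectra point-wise
#'
#' Arithmetic mean of replicate spectra of the same kind on a common grid
#' (resample first with [resample_spectra()] if the grids differ).
#'
#' @param spectra List of `km_spectrum` objects.
#' @param label Label for the averaged spectrum.
#' @return A `km_spectrum`.
#' @export
average_spectra <- function(spectra, label = "mean") {
  stopifnot(is.list(spectra), length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "km_spectrum")))
  kinds <- unique(vapply(spectra, function(s) s$kind, ""))
  if (length(kinds) != 1)
    stop("cannot average spectra of mixed kinds: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  wl <- spectra[[1]]$wavelength
  for (s in spectra[-1])
    if (length(s$wavelength) != length(wl) || any(s$wavelength != wl))
      stop("spectra are not on a common grid; resample first", call. = FALSE)
  m <- rowMeans(vapply(spectra, function(s) s$value, numeric(length(wl))))
  spectrum_km(wl, m, kind = kinds, label = label)
}

#' Default wavelength grid
#'
#' 300-700 nm at 1-nm steps: the ultraviolet-visible range over which petal
#' reflectance and transmittance are modelled.
#'
#' @param from,to,by Grid limits and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_grid <- function(from = 300, to = 700, by = 1) seq(from, to, by = by)
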