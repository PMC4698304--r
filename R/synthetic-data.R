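#' Pigment absorption template
#'
#' Describes a pigment's dimensionless absorption parameter spectrum
#' \eqn{K^*(\lambda)} as a sum of Gaussian bands.  The default emulates a
#' purple anthocyanin-like petal pigment: a green absorption band peaking at
#' 545 nm with \eqn{K^* = 1.4} at the peak, weak absorption in the violet,
#' and a much stronger ultraviolet band.
#'
#' @param bands Data frame (or coercible) with columns `center` (nm), `width`
#'   (Gaussian sigma, nm, > 0) and `amplitude` (dimensionless, >= 0); at
#'   least one band.
#' @return An object of class `pigment_template`.
#' @export
pigment_template <- function(bands = data.frame(
                               center = c(545, 310),
                               width = c(45, 35),
                               amplitude = c(1.4, 4.0))) {
  bands <- as.data.frame(bands)
  if (!all(c("center", "width", "amplitude") %in% names(bands)))
    stop("`bands` needs columns center, width, amplitude", call. = FALSE)
  if (nrow(bands) < 1 || any(bands$width <= 0) || any(bands$amplitude < 0))
    stop("invalid template: widths must be > 0, amplitudes >= 0",
         call. = FALSE)
  structure(list(bands = bands), class = "pigment_template")
}

#' @export
print.pigment_template <- function(x, ...) {
  cat("Pigment template (sum of Gaussian absorption bands):\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Generate a pigment absorption parameter spectrum
#'
#' Evaluates a [pigment_template()] on a wavelength grid:
#' \deqn{K^*(\lambda) = \sum_i a_i \exp\!\left(
#'   -\frac{(\lambda - c_i)^2}{2 w_i^2}\right).}
#'
#' @param template A [pigment_template()]; the default places the visible
#'   absorption peak at 545 nm with amplitude 1.4.
#' @param grid Wavelength grid in nm.
#' @return A `km_spectrum` of kind `"parameter"`.
#' @examples
#' k <- make_pigment_kstar(grid = default_grid())
#' k$value[k$wavelength == 545]  # 1.4 + UV band tail
#' @export
make_pigment_kstar <- function(template = pigment_template(),
                               grid = default_grid()) {
  stopifnot(inherits(template, "pigment_template"))
  b <- template$bands
  K <- rowSums(vapply(seq_len(nrow(b)), function(i)
    b$amplitude[i] * exp(-(grid - b$center[i])^2 / (2 * b$width[i]^2)),
    numeric(length(grid))))
  spectrum_km(grid, K, kind = "parameter", label = "K_p* (synthetic)")
}

#' Generate a scattering parameter spectrum
#'
#' Constant scattering parameter, optionally with troughs where absorption is
#' strong: with coupling \eqn{c}, \eqn{S^*(\lambda) = S_0 (1 - c\,
#' K^*(\lambda)/\max K^*)}.  Petal tissue shows such troughs in its derived
#' scattering spectra where the pigment absorbs severely; the long-wavelength
#' value always equals `base`.
#'
#' @param base Long-wavelength scattering parameter (default 0.5, typical of
#'   a pigmented petal layer).
#' @param grid Wavelength grid in nm.
#' @param trough_coupling Fraction in \[0, 1\] of the scattering removed at
#'   the absorption maximum (0 = flat spectrum).
#' @param K_star Absorption spectrum driving the troughs (`km_spectrum` or
#'   numeric); required when `trough_coupling > 0`.
#' @return A `km_spectrum` of kind `"parameter"`.
#' @export
make_scatter_sstar <- function(base = 0.5, grid = default_grid(),
                               trough_coupling = 0, K_star = NULL) {
  if (!is.numeric(base) || length(base) != 1 || base < 0)
    stop("`base` must be a single value >= 0", call. = FALSE)
  if (trough_coupling < 0 || trough_coupling > 1)
    stop("`trough_coupling` must lie in [0, 1]", call. = FALSE)
  S <- rep(base, length(grid))
  if (trough_coupling > 0) {
    if (is.null(K_star))
      stop("`K_star` required when trough_coupling > 0", call. = FALSE)
    K <- if (inherits(K_star, "km_spectrum")) K_star$value else K_star
    if (length(K) != length(grid))
      stop("`K_star` length must match the grid", call. = FALSE)
    if (max(K) > 0) S <- base * (1 - trough_coupling * K / max(K))
  }
  spectrum_km(grid, S, kind = "parameter", label = "S_p* (synthetic)")
}

#' Simulate integrating-sphere measurements of a layer stack
#'
#' Forward-computes the stack's diffuse observables for illumination of
#' either side and adds independent Gaussian measurement noise truncated to
#' \[0, 1\].  With `noise_sd = 0` the exact model output is returned, for
#' which the adaxial and abaxial transmittances are identical.
#'
#' @param stack List of [plate_rt] layers, top to bottom (e.g. from
#'   [build_flower_stack()] or [build_scenario()]).
#' @param noise_sd Standard deviation of the additive noise on the fraction
#'   scale (0 = noiseless).
#' @param seed Integer seed; required whenever `noise_sd > 0`.  No global
#'   random state is consumed or left behind.
#' @param wavelength Wavelength grid (nm) labelling the output spectra.
#' @return A list of four `km_spectrum` objects: `R_ad`, `T_ad`, `R_ab`,
#'   `T_ab`.
#' @export
simulate_measurement <- function(stack, noise_sd = 0, seed = NULL,
                                 wavelength) {
  stopifnot(is.numeric(noise_sd), noise_sd >= 0)
  s <- stack_spectra(stack)
  n <- length(s$T)
  if (missing(wavelength)) wavelength <- seq_len(n)
  if (length(wavelength) != n)
    stop("`wavelength` length does not match the stack", call. = FALSE)

  vals <- list(R_ad = s$R_ad, T_ad = s$T, R_ab = s$R_ab, T_ab = s$T)
  if (noise_sd > 0) {
    if (is.null(seed))
      stop("`seed` is required when noise_sd > 0", call. = FALSE)
    vals <- withr::with_seed(as.integer(seed), {
      lapply(vals, function(v)
        pmin(pmax(v + stats::rnorm(n, sd = noise_sd), 0), 1))
    })
  }
  kinds <- c(R_ad = "reflectance", T_ad = "transmittance",
             R_ab = "reflectance", T_ab = "transmittance")
  out <- lapply(names(vals), function(nm)
    spectrum_km(wavelength, vals[[nm]], kind = kinds[[nm]],
                label = paste0(nm, " (simulated)")))
  names(out) <- names(vals)
  out
}
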