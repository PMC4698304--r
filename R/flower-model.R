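#' Four-layer corolla model configuration
#'
#' The corolla is modelled as four layers, top to bottom: the upper surface
#' (a non-absorbing reflecting interface), a pigmented scattering layer, an
#' unpigmented scattering layer, and the lower surface.  This object carries
#' the assumed (not fitted) quantities: the surface reflectance, the
#' unpigmented layer's scattering parameter, and the effective thicknesses
#' used when converting dimensionless parameters to coefficients.
#'
#' @param r_surface Surface reflectance fraction (both surfaces); default
#'   0.03, the estimate for plant cell walls facing air.
#' @param S_u_star Dimensionless scattering parameter of the unpigmented
#'   layer; 0.1 is typical of petal tissue between veins, 0.2 of vein areas,
#'   and 0 collapses the interior to a single homogeneously pigmented layer.
#' @param d_pigmented,d_unpigmented Effective layer thicknesses in
#'   micrometres (used only for coefficient conversion; default 40).
#' @return An object of class `flower_config`.
#' @export
flower_config <- function(r_surface = 0.03, S_u_star = 0.1,
                          d_pigmented = 40, d_unpigmented = 40) {
  stopifnot(is.numeric(r_surface), is.numeric(S_u_star))
  if (any(r_surface < 0) || any(r_surface >= 1))
    stop("`r_surface` must lie in [0, 1)", call. = FALSE)
  if (length(S_u_star) != 1 || S_u_star < 0)
    stop("`S_u_star` must be a single value >= 0", call. = FALSE)
  if (d_pigmented <= 0 || d_unpigmented <= 0)
    stop("thicknesses must be > 0", call. = FALSE)
  structure(list(r_surface = r_surface, S_u_star = S_u_star,
                 d_pigmented = d_pigmented, d_unpigmented = d_unpigmented),
            class = "flower_config")
}

#' @export
print.flower_config <- function(x, ...) {
  cat("Four-layer corolla configuration\n")
  cat(sprintf("  surface reflectance r1 = r4 : %s\n",
              paste(format(unique(x$r_surface)), collapse = ", ")))
  cat(sprintf("  unpigmented layer S_u*      : %g\n", x$S_u_star))
  cat(sprintf("  thicknesses (pigmented/unpigmented) : %g / %g um\n",
              x$d_pigmented, x$d_unpigmented))
  invisible(x)
}

#' Build the four-layer corolla stack
#'
#' Assembles the ordered plate list \[surface, pigmented KM layer,
#' unpigmented KM layer, surface\] from a configuration and the pigmented
#' layer's parameter spectra.
#'
#' @param config A [flower_config()].
#' @param K_p_star,S_p_star Numeric vectors (per wavelength) of the pigmented
#'   layer's absorption and scattering parameters.
#' @return A list of four [plate_rt] objects, top to bottom.
#' @export
build_flower_stack <- function(config, K_p_star, S_p_star) {
  stopifnot(inherits(config, "flower_config"))
  list(
    surface_plate(config$r_surface),
    km_plate_rt(K_p_star, S_p_star),
    km_plate_rt(0, config$S_u_star),
    surface_plate(config$r_surface)
  )
}

# forward observables of a stack from both illumination sides
stack_spectra <- function(layers) {
  fwd <- combine_stack(layers)
  list(R_ad = fwd$r_top, T = fwd$t_down, R_ab = fwd$r_bottom)
}

#' Fit the pigmented layer of a corolla from adaxial spectra
#'
#' The central inverse computation.  Given measured (or simulated)
#' integrating-sphere reflectance and transmittance spectra of the adaxial
#' (upper) side of a corolla, and a four-layer configuration fixing the
#' surface reflectance and the unpigmented layer's scattering, recovers per
#' wavelength:
#' \enumerate{
#'   \item the upper surface is peeled off the measured stack observables
#'     ([peel_top()]);
#'   \item the pigmented layer's own reflectance \eqn{r_p} and transmittance
#'     \eqn{t_p} are solved against the known sub-stack of unpigmented layer
#'     plus lower surface ([solve_symmetric_middle()]);
#'   \item the layer's Kubelka-Munk parameters \eqn{K_p^*}, \eqn{S_p^*} are
#'     recovered by analytic inversion ([km_invert_rt()]);
#'   \item the pigment absorbance \eqn{D = 0.4343 K_p^*} is derived
#'     ([absorbance_from_kstar()]).
#' }
#' Wavelengths at which any step is degenerate or noise-inconsistent are
#' flagged invalid (`NA` parameters) rather than dropped; per-step failure
#' counts are kept in the returned object.
#'
#' @param reflectance,transmittance Adaxial spectra: a `km_spectrum`, a list
#'   of replicate `km_spectrum` objects (averaged after resampling), or a
#'   two-column `data.frame`/matrix of wavelength (nm) and fraction.
#' @param config A [flower_config()].
#' @param grid Optional wavelength grid (nm) to fit on; defaults to the
#'   spectra's common grid, or a 1-nm grid over their overlap when their
#'   grids differ.
#' @return An object of class `petal_fit` with per-wavelength components
#'   `r_p`, `t_p`, `K_p_star`, `S_p_star`, `D`, `valid`, the aligned input
#'   spectra, the configuration and step-failure counts.  Methods:
#'   [print.petal_fit()], [summary.petal_fit()], [coef.petal_fit()],
#'   [predict.petal_fit()], [residuals.petal_fit()], [plot.petal_fit()],
#'   [simulate.petal_fit()].
#' @examples
#' truth <- make_pigment_kstar(grid = default_grid(by = 10))
#' stack <- build_flower_stack(flower_config(), truth$value, 0.5)
#' m <- simulate_measurement(stack, wavelength = truth$wavelength)
#' fit <- fit_petal(m$R_ad, m$T_ad)
#' fit
#' @export
fit_petal <- function(reflectance, transmittance, config = flower_config(),
                      grid = NULL) {
  stopifnot(inherits(config, "flower_config"))
  R <- as_spectrum_input(reflectance, "reflectance")
  T <- as_spectrum_input(transmittance, "transmittance")

  if (is.null(grid)) {
    same <- length(R$wavelength) == length(T$wavelength) &&
      all(R$wavelength == T$wavelength)
    grid <- if (same) R$wavelength else {
      lo <- max(min(R$wavelength), min(T$wavelength))
      hi <- min(max(R$wavelength), max(T$wavelength))
      if (hi - lo < 1)
        stop("reflectance and transmittance wavelength ranges do not overlap",
             call. = FALSE)
      seq(ceiling(lo), floor(hi), by = 1)
    }
  }
  R <- resample_spectra(R, grid)
  T <- resample_spectra(T, grid)
  n <- length(grid)

  surface <- surface_plate(config$r_surface)
  bottom <- combine_two(km_plate_rt(0, config$S_u_star),
                        surface_plate(config$r_surface))

  peeled <- peel_top(R$value, T$value, surface)
  mid <- solve_symmetric_middle(peeled$R_rest, peeled$T_rest, bottom)
  inv <- km_invert_rt(mid$r, mid$t)

  valid <- peeled$valid & mid$valid & inv$valid
  counts <- c(peel = sum(!peeled$valid),
              solve = sum(peeled$valid & !mid$valid),
              invert = sum(peeled$valid & mid$valid & !inv$valid))
  if (!any(valid))
    stop(errorCondition(sprintf(
      "fit degenerate at every wavelength (failures: peel %d, solve %d, invert %d)",
      counts[["peel"]], counts[["solve"]], counts[["invert"]]),
      class = "petalkm_degenerate_fit"))

  D <- rep(NA_real_, n)
  D[valid] <- absorbance_from_kstar(inv$K_star[valid])

  structure(
    list(wavelength = grid,
         r_p = mid$r, t_p = mid$t,
         K_p_star = inv$K_star, S_p_star = inv$S_star, D = D,
         valid = valid, failure_counts = counts,
         R_ad = R, T_ad = T, config = config,
         call = match.call()),
    class = "petal_fit"
  )
}

# accept km_spectrum, list of replicates, data.frame or 2-col matrix
as_spectrum_input <- function(x, kind) {
  if (inherits(x, "km_spectrum")) return(x)
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "km_spectrum"))) {
    lo <- max(vapply(x, function(s) min(s$wavelength), 0))
    hi <- min(vapply(x, function(s) max(s$wavelength), 0))
    if (hi <= lo)
      stop("replicate spectra have no common wavelength range", call. = FALSE)
    g <- x[[1]]$wavelength
    g <- g[g >= lo & g <= hi]
    return(average_spectra(resample_spectra(x, g)))
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.data.frame(x) && ncol(x) >= 2)
    return(spectrum_km(x[[1]], x[[2]], kind = kind, clip = TRUE))
  stop(sprintf("cannot interpret %s input", kind), call. = FALSE)
}

#' @export
print.petal_fit <- function(x, ...) {
  cat("Four-layer Kubelka-Munk petal fit\n")
  cat(sprintf("  wavelengths : %d (%g-%g nm), %d valid\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              sum(x$valid)))
  cat(sprintf("  config      : r_surface = %g, S_u* = %g\n",
              x$config$r_surface[1], x$config$S_u_star))
  i <- which(x$valid)
  pk <- i[which.max(x$K_p_star[i])]
  cat(sprintf("  K_p* peak   : %.4g at %g nm (D = %.4g)\n",
              x$K_p_star[pk], x$wavelength[pk], x$D[pk]))
  invisible(x)
}

#' Summarise a petal fit
#'
#' Reports the absorption peak of the recovered pigmented layer, its
#' long-wavelength scattering asymptote, the derived absorption and
#' scattering coefficients at the configured thicknesses, and per-step
#' failure counts.
#'
#' @param object A `petal_fit`.
#' @param peak_window Wavelength window (nm) within which the visible
#'   absorption peak is sought (excludes the ultraviolet band).
#' @param ... Unused.
#' @return An object of class `summary.petal_fit`.
#' @export
summary.petal_fit <- function(object, peak_window = c(400, 700), ...) {
  i <- which(object$valid)
  wl <- object$wavelength
  vis <- i[wl[i] >= peak_window[1] & wl[i] <= peak_window[2]]
  pk <- if (length(vis)) vis[which.max(object$K_p_star[vis])] else
    i[which.max(object$K_p_star[i])]
  tail_i <- i[wl[i] >= max(wl[i]) - 20]
  co <- coefficients_from_parameters(object$K_p_star[pk],
                                     mean(object$S_p_star[tail_i]),
                                     d_um = object$config$d_pigmented)
  structure(
    list(fit = object,
         lambda_peak = wl[pk],
         K_peak = object$K_p_star[pk],
         D_peak = object$D[pk],
         S_tail = mean(object$S_p_star[tail_i]),
         K_mm = co$K_mm, S_mm = co$S_mm),
    class = "summary.petal_fit")
}

#' @export
print.summary.petal_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  visible absorption peak : K_p* = %.3g at %g nm  (absorbance D = %.3g)\n",
              x$K_peak, x$lambda_peak, x$D_peak))
  cat(sprintf("  S_p* long-wavelength asymptote : %.3g\n", x$S_tail))
  cat(sprintf("  at d = %g um : K = %.3g mm^-1, S_p = %.3g mm^-1\n",
              f$config$d_pigmented, x$K_mm, x$S_mm))
  fc <- f$failure_counts
  if (sum(fc) > 0)
    cat(sprintf("  invalid wavelengths : peel %d, solve %d, invert %d\n",
                fc[["peel"]], fc[["solve"]], fc[["invert"]]))
  invisible(x)
}

#' Extract fitted pigmented-layer parameters
#'
#' @param object A `petal_fit`.
#' @param ... Unused.
#' @return A matrix with one row per wavelength and columns `K_p_star`,
#'   `S_p_star`; row names are wavelengths in nm.
#' @export
coef.petal_fit <- function(object, ...) {
  m <- cbind(K_p_star = object$K_p_star, S_p_star = object$S_p_star)
  rownames(m) <- format(object$wavelength, trim = TRUE)
  m
}

#' Predict corolla spectra from a fitted pigmented layer
#'
#' Forward-combines the four-layer stack rebuilt from the fitted \eqn{r_p},
#' \eqn{t_p} and the configuration, for illumination of either side.  The
#' transmittance is identical from both sides (a stack theorem), so `T_ad`
#' and `T_ab` are equal by construction; with the configuration used for
#' fitting, `R_ad` and `T_ad` reproduce the input spectra at valid
#' wavelengths to round-off.
#'
#' @param object A `petal_fit`.
#' @param config Configuration for prediction; defaults to the one fitted
#'   with.  Supplying a different `S_u_star` predicts, e.g., vein versus
#'   inter-vein abaxial reflectance from one fit.
#' @param ... Unused.
#' @return A list of four `km_spectrum` objects: `R_ad`, `T_ad`, `R_ab`,
#'   `T_ab` (`NA` at invalid wavelengths).
#' @export
predict.petal_fit <- function(object, config = object$config, ...) {
  stopifnot(inherits(config, "flower_config"))
  wl <- object$wavelength
  n <- length(wl)
  v <- object$valid
  out <- list(R_ad = rep(NA_real_, n), T_ad = rep(NA_real_, n),
              R_ab = rep(NA_real_, n), T_ab = rep(NA_real_, n))
  if (any(v)) {
    layers <- list(
      surface_plate(config$r_surface),
      plate_rt(object$r_p[v], object$t_p[v]),
      km_plate_rt(0, config$S_u_star),
      surface_plate(config$r_surface)
    )
    s <- combine_stack(layers)
    out$R_ad[v] <- s$r_top
    out$T_ad[v] <- s$t_down
    out$R_ab[v] <- s$r_bottom
    out$T_ab[v] <- s$t_up
  }
  list(
    R_ad = spectrum_km(wl, out$R_ad, "reflectance", "predicted R_ad"),
    T_ad = spectrum_km(wl, out$T_ad, "transmittance", "predicted T_ad"),
    R_ab = spectrum_km(wl, out$R_ab, "reflectance", "predicted R_ab"),
    T_ab = spectrum_km(wl, out$T_ab, "transmittance", "predicted T_ab")
  )
}

#' Residuals of a petal fit
#'
#' Difference between the spectra reproduced by the fitted four-layer stack
#' and the (aligned, averaged) input spectra.  For noiseless synthetic input
#' these vanish to round-off; for measured spectra they are the part of the
#' data the four-layer model cannot represent at the given configuration.
#'
#' @param object A `petal_fit`.
#' @param ... Unused.
#' @return A data frame with columns `wavelength`, `reflectance`,
#'   `transmittance`.
#' @export
residuals.petal_fit <- function(object, ...) {
  p <- predict(object)
  data.frame(wavelength = object$wavelength,
             reflectance = p$R_ad$value - object$R_ad$value,
             transmittance = p$T_ad$value - object$T_ad$value)
}

#' @export
fitted.petal_fit <- function(object, ...) predict(object)[c("R_ad", "T_ad")]

#' Plot a petal fit
#'
#' Two panels: the input reflectance/transmittance spectra, and the recovered
#' pigmented-layer parameter spectra \eqn{K_p^*(\lambda)},
#' \eqn{S_p^*(\lambda)}.
#'
#' @param x A `petal_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.petal_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$wavelength, cbind(x$R_ad$value, x$T_ad$value),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "wavelength (nm)", ylab = "fraction",
                    main = "adaxial spectra", ...)
  graphics::legend("topleft", c("R_ad", "T_ad"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  graphics::matplot(x$wavelength, cbind(x$K_p_star, x$S_p_star),
                    type = "l", lty = 1, col = c("black", "grey50"),
                    xlab = "wavelength (nm)", ylab = "parameter",
                    main = "pigmented layer", ...)
  graphics::legend("topright", c("K_p*", "S_p*"), lty = 1,
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Simulate measurements from a fitted petal
#'
#' Rebuilds the fitted four-layer stack and generates simulated
#' integrating-sphere measurements with additive truncated-Gaussian noise
#' (see [simulate_measurement()]).
#'
#' @param object A `petal_fit`.
#' @param nsim Number of replicate simulated measurement sets.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param noise_sd Noise standard deviation on the fraction scale.
#' @param ... Unused.
#' @return A list of `nsim` measurement sets, each a list of four
#'   `km_spectrum` objects.
#' @export
simulate.petal_fit <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.005, ...) {
  v <- object$valid
  layers <- list(
    surface_plate(object$config$r_surface),
    plate_rt(object$r_p[v], object$t_p[v]),
    km_plate_rt(0, object$config$S_u_star),
    surface_plate(object$config$r_surface)
  )
  wl <- object$wavelength[v]
  if (!is.null(seed)) seeds <- seed + seq_len(nsim) - 1L
  else if (noise_sd > 0) stop("`seed` required when noise_sd > 0",
                              call. = FALSE)
  lapply(seq_len(nsim), function(i)
    simulate_measurement(layers, noise_sd = noise_sd,
                         seed = if (noise_sd > 0) seeds[i] else NULL,
                         wavelength = wl))
}

#' Build a pigment-distribution scenario stack
#'
#' Three model petals carrying the same total pigment and the same total
#' scattering, distributed differently:
#' \describe{
#'   \item{`asymmetric`}{pigment confined to the upper of two equally thick
#'     layers: \[surface, KM(K*, S_p*), KM(0, S_u*), surface\].}
#'   \item{`homogeneous`}{pigment and scattering pooled into one layer:
#'     \[surface, KM(K*, S_p* + S_u*), surface\].}
#'   \item{`symmetric`}{pigment split equally between an upper and a lower
#'     flank around the unpigmented layer: \[surface, KM(K*/2, S_p*/2),
#'     KM(0, S_u*), KM(K*/2, S_p*/2), surface\].}
#' }
#' Summed over interior layers, both \eqn{\sum K^*} and \eqn{\sum S^*} are
#' identical across the three.
#'
#' @param distribution `"asymmetric"`, `"homogeneous"` or `"symmetric"`.
#' @param K_star Pigment absorption parameter spectrum (numeric vector or
#'   `km_spectrum`).
#' @param S_p_star Scattering parameter of the pigmented layer (scalar or per
#'   wavelength); default 0.5, the long-wavelength asymptote of petal tissue.
#' @param S_u_star Scattering parameter of the unpigmented layer.
#' @param r_surface Surface reflectance.
#' @return A list of [plate_rt] layers (top to bottom) with attribute
#'   `"distribution"`.
#' @export
build_scenario <- function(distribution = c("asymmetric", "homogeneous",
                                            "symmetric"),
                           K_star, S_p_star = 0.5, S_u_star = 0.1,
                           r_surface = 0.03) {
  distribution <- match.arg(distribution)
  if (inherits(K_star, "km_spectrum")) K_star <- K_star$value
  surf <- surface_plate(r_surface)
  layers <- switch(distribution,
    asymmetric = list(surf, km_plate_rt(K_star, S_p_star),
                      km_plate_rt(0, S_u_star), surf),
    homogeneous = list(surf, km_plate_rt(K_star, S_p_star + S_u_star), surf),
    symmetric = list(surf, km_plate_rt(K_star / 2, S_p_star / 2),
                     km_plate_rt(0, S_u_star),
                     km_plate_rt(K_star / 2, S_p_star / 2), surf)
  )
  attr(layers, "distribution") <- distribution
  layers
}

#' Compute spectra for the three pigment-distribution scenarios
#'
#' Convenience wrapper: builds the asymmetric, homogeneous and symmetric
#' stacks from one pigment specification and returns, for each, the adaxial
#' reflectance, the (side-invariant) transmittance and the abaxial
#' reflectance.
#'
#' @inheritParams build_scenario
#' @param wavelength Wavelength grid (nm) matching `K_star`.
#' @return A named list (`asymmetric`, `homogeneous`, `symmetric`), each
#'   element a list of `km_spectrum` objects `R_ad`, `T`, `R_ab`.
#' @export
scenario_spectra <- function(K_star, wavelength, S_p_star = 0.5,
                             S_u_star = 0.1, r_surface = 0.03) {
  if (inherits(K_star, "km_spectrum")) {
    if (missing(wavelength)) wavelength <- K_star$wavelength
    K_star <- K_star$value
  }
  out <- lapply(c(asymmetric = "asymmetric", homogeneous = "homogeneous",
                  symmetric = "symmetric"), function(d) {
    s <- stack_spectra(build_scenario(d, K_star, S_p_star, S_u_star,
                                      r_surface))
    list(R_ad = spectrum_km(wavelength, s$R_ad, "reflectance",
                            paste0("R_ad [", d, "]")),
         T = spectrum_km(wavelength, s$T, "transmittance",
                         paste0("T [", d, "]")),
         R_ab = spectrum_km(wavelength, s$R_ab, "reflectance",
                            paste0("R_ab [", d, "]")))
  })
  out
}

#' Spectral saturation metric
#'
#' Depth of the reflectance trough at the pigment's absorption peak relative
#' to the reflectance plateau:
#' \deqn{1 - R(\lambda_{\max}) / \max_\lambda R(\lambda).}
#' 0 for a flat spectrum, approaching 1 when the trough is complete;
#' perceptually, the colour purity a pollinator would see.
#'
#' @param R A reflectance `km_spectrum`.
#' @param lambda_max Absorption peak wavelength in nm (default 545, the green
#'   absorption peak of a purple anthocyanin-like pigment).
#' @return A single value in \[0, 1\].
#' @export
saturation_metric <- function(R, lambda_max = 545) {
  stopifnot(inherits(R, "km_spectrum"))
  if (lambda_max < min(R$wavelength) || lambda_max > max(R$wavelength))
    stop("`lambda_max` outside the spectrum's wavelength range",
         call. = FALSE)
  ok <- !is.na(R$value)
  at <- stats::approx(R$wavelength[ok], R$value[ok], xout = lambda_max)$y
  mx <- max(R$value[ok])
  if (mx <= 0) return(0)
  1 - at / mx
}
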