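#' Diffuse reflectance and transmittance of a non-absorbing layer
#'
#' For a purely scattering (non-absorbing) homogeneous layer the two-flux
#' theory reduces to the closed forms
#' \deqn{r = S^*/(1 + S^*), \qquad t = 1/(1 + S^*),}
#' where \eqn{S^* = S d} is the dimensionless scattering parameter (scattering
#' coefficient times thickness).  Energy is conserved exactly: \eqn{r + t = 1}.
#'
#' @param S_star Numeric vector of dimensionless scattering parameters,
#'   \eqn{S^* \ge 0}.
#' @return A [plate_rt] object (symmetric plate), vectorised over `S_star`.
#' @seealso [km_plate_rt()] for the absorbing case.
#' @examples
#' km_nonabsorbing_rt(0.1)  # r = 0.0909..., t = 0.9090...
#' @export
km_nonabsorbing_rt <- function(S_star) {
  stopifnot(is.numeric(S_star))
  if (any(!is.finite(S_star)) || any(S_star < 0))
    stop("`S_star` must be finite and >= 0", call. = FALSE)
  r <- S_star / (1 + S_star)
  plate_rt(r_top = r, t_down = 1 - r)
}

#' Diffuse reflectance and transmittance of an absorbing, scattering layer
#'
#' Solves the two-flux (Kubelka-Munk) equations for a homogeneous layer with
#' dimensionless absorption parameter \eqn{K^* = K d} and scattering parameter
#' \eqn{S^* = S d}.  With \eqn{a = 1 + K^*/S^*}, \eqn{b = \sqrt{a^2 - 1}} and
#' \eqn{x = b S^*} the diffuse reflectance and transmittance are
#' \deqn{r = \frac{\sinh x}{a \sinh x + b \cosh x}, \qquad
#'       t = \frac{b}{a \sinh x + b \cosh x}.}
#' The limits are handled explicitly: \eqn{K^* = 0} reduces to
#' [km_nonabsorbing_rt()], \eqn{S^* = 0} gives the Bouguer absorber
#' \eqn{(r, t) = (0, e^{-K^*})}, and for very thick/opaque layers
#' (\eqn{x > 350}, where `sinh` would overflow) the asymptotes
#' \eqn{r = 1/(a + b)}, \eqn{t = 0} are used.
#'
#' @param K_star Numeric vector, dimensionless absorption parameter(s),
#'   \eqn{\ge 0}.
#' @param S_star Numeric vector, dimensionless scattering parameter(s),
#'   \eqn{\ge 0}.  Recycled against `K_star`.
#' @return A symmetric [plate_rt], vectorised over the parameters.
#' @examples
#' km_plate_rt(K_star = 1.4, S_star = 0.5)
#' @export
km_plate_rt <- function(K_star, S_star) {
  stopifnot(is.numeric(K_star), is.numeric(S_star))
  n <- max(length(K_star), length(S_star))
  K <- rep_len(K_star, n)
  S <- rep_len(S_star, n)
  if (any(!is.finite(K)) || any(!is.finite(S)) || any(K < 0) || any(S < 0))
    stop("`K_star` and `S_star` must be finite and >= 0", call. = FALSE)

  r <- numeric(n)
  t <- numeric(n)

  pure <- S == 0           # no scattering: exponential attenuation only
  r[pure] <- 0
  t[pure] <- exp(-K[pure])

  cons <- !pure & K == 0   # conservative scatterer
  if (any(cons)) {
    r[cons] <- S[cons] / (1 + S[cons])
    t[cons] <- 1 / (1 + S[cons])
  }

  gen <- !pure & !cons
  if (any(gen)) {
    a <- 1 + K[gen] / S[gen]
    b <- sqrt(a^2 - 1)
    x <- b * S[gen]
    thick <- x > 350       # sinh/cosh overflow guard; layer is effectively opaque
    sh <- sinh(pmin(x, 350))
    ch <- cosh(pmin(x, 350))
    den <- a * sh + b * ch
    rg <- ifelse(thick, 1 / (a + b), sh / den)
    tg <- ifelse(thick, 0, b / den)
    r[gen] <- rg
    t[gen] <- tg
  }

  plate_rt(r_top = r, t_down = t)
}

#' Recover Kubelka-Munk parameters from a layer's reflectance and transmittance
#'
#' Analytic inversion of [km_plate_rt()]: for a symmetric layer with diffuse
#' reflectance `r` and transmittance `t`,
#' \deqn{a = \frac{1 + r^2 - t^2}{2 r}, \quad b = \sqrt{a^2 - 1}, \quad
#'   S^* = \frac{1}{b}\,\mathrm{arccoth}\!\left(\frac{1 - a r}{b r}\right),
#'   \quad K^* = (a - 1)\,S^*,}
#' with \eqn{\mathrm{arccoth}(x) = \tfrac12 \ln\frac{x+1}{x-1}}.
#'
#' Degenerate and noisy inputs are handled per wavelength rather than by
#' aborting: `r = 0` gives the pure absorber \eqn{(K^*, S^*) = (-\ln t, 0)};
#' \eqn{a \le 1 + 10^{-9}} (non-absorbing within rounding) gives
#' \eqn{K^* = 0,\ S^* = r/t}; an arccoth argument \eqn{\le 1} — possible under
#' measurement noise — yields `NA` with `valid = FALSE`.  Recovered `K_star`
#' in \eqn{(-10^{-9}, 0)} is clamped to 0; more negative values are flagged
#' invalid.
#'
#' @param r,t Numeric vectors of diffuse reflectance and transmittance
#'   (fractions), or a [plate_rt] as `r` with `t` missing.
#' @return A data frame with columns `K_star`, `S_star` and logical `valid`.
#'   Invalid entries carry `NA` parameters.
#' @examples
#' km_invert_rt(0.0909090909, 0.9090909091)  # K* = 0, S* = 0.1
#' @export
km_invert_rt <- function(r, t) {
  if (missing(t) && inherits(r, "plate_rt")) {
    t <- r$t_down
    r <- r$r_top
  }
  stopifnot(is.numeric(r), is.numeric(t))
  n <- max(length(r), length(t))
  r <- rep_len(r, n)
  t <- rep_len(t, n)

  K <- rep(NA_real_, n)
  S <- rep(NA_real_, n)
  valid <- rep(FALSE, n)

  bad <- !is.finite(r) | !is.finite(t) | r < 0 | r >= 1 | t <= 0 | t > 1
  unphys <- !bad & (r + t > 1 + 1e-9)
  if (any(unphys))
    stop("unphysical input: r + t > 1", call. = FALSE)

  ok <- !bad & !unphys

  # pure absorber: no reflected flux at all
  pa <- ok & r == 0
  K[pa] <- -log(t[pa])
  S[pa] <- 0
  valid[pa] <- TRUE

  gen <- ok & !pa
  if (any(gen)) {
    rg <- r[gen]; tg <- t[gen]
    a <- (1 + rg^2 - tg^2) / (2 * rg)
    Kg <- rep(NA_real_, sum(gen))
    Sg <- rep(NA_real_, sum(gen))
    vg <- rep(FALSE, sum(gen))

    cons <- a <= 1 + 1e-9            # b -> 0 degeneracy: K = 0 limit
    Kg[cons] <- 0
    Sg[cons] <- rg[cons] / tg[cons]
    vg[cons] <- TRUE

    g2 <- !cons & a > 1
    if (any(g2)) {
      b <- sqrt(a[g2]^2 - 1)
      arg <- (1 - a[g2] * rg[g2]) / (b * rg[g2])
      dom <- arg > 1                  # arccoth domain; noise can push arg <= 1
      S2 <- ifelse(dom, 0.5 * log((arg + 1) / (arg - 1)) / b, NA_real_)
      K2 <- (a[g2] - 1) * S2
      # clamp rounding-level negatives, flag genuinely unphysical ones
      tiny <- dom & K2 < 0 & K2 > -1e-9
      K2[tiny] <- 0
      bad2 <- dom & (K2 < 0 | S2 < 0)
      K2[bad2] <- NA_real_
      S2[bad2] <- NA_real_
      Kg[g2] <- K2
      Sg[g2] <- S2
      vg[g2] <- dom & !bad2
    }
    K[gen] <- Kg
    S[gen] <- Sg
    valid[gen] <- vg
  }

  data.frame(K_star = K, S_star = S, valid = valid)
}

#' Convert an absorption parameter to decadic absorbance
#'
#' In a homogeneously pigmented, non-scattering medium the absorbance
#' (optical density) corresponding to the Kubelka-Munk absorption parameter is
#' \eqn{D = \log_{10}(e)\, K^* \approx 0.4343\, K^*}.
#'
#' @param K_star Numeric vector, \eqn{K^* \ge 0}.
#' @return Numeric vector of absorbances.
#' @examples
#' absorbance_from_kstar(1)  # 0.4343
#' @export
absorbance_from_kstar <- function(K_star) {
  stopifnot(is.numeric(K_star))
  if (any(!is.na(K_star) & K_star < 0))
    stop("`K_star` must be >= 0", call. = FALSE)
  log10(exp(1)) * K_star
}

#' Convert dimensionless parameters to absorption/scattering coefficients
#'
#' Divides the dimensionless parameters \eqn{K^* = K d}, \eqn{S^* = S d} by
#' the layer thickness to give coefficients in mm\eqn{^{-1}}.
#'
#' @param K_star,S_star Numeric vectors of dimensionless parameters (either
#'   may be `NULL` if only one is wanted).
#' @param d_um Layer thickness in micrometres, \eqn{> 0}.
#' @return A list with elements `K_mm` and `S_mm` (mm^-1; `NULL` where the
#'   corresponding input was `NULL`).
#' @examples
#' coefficients_from_parameters(K_star = 1.4, S_star = 0.1, d_um = 40)
#' # K = 35 mm^-1, S = 2.5 mm^-1
#' @export
coefficients_from_parameters <- function(K_star = NULL, S_star = NULL, d_um) {
  stopifnot(is.numeric(d_um), length(d_um) == 1)
  if (!is.finite(d_um) || d_um <= 0)
    stop("thickness `d_um` must be > 0", call. = FALSE)
  d_mm <- d_um / 1000
  list(
    K_mm = if (is.null(K_star)) NULL else K_star / d_mm,
    S_mm = if (is.null(S_star)) NULL else S_star / d_mm
  )
}
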