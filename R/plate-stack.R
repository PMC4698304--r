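#' Construct a diffuse plate
#'
#' A "plate" is anything with side-dependent diffuse observables: reflectance
#' `r_top` and transmittance `t_down` for illumination from above, `r_bottom`
#' and `t_up` for illumination from below.  Every single homogeneous layer is
#' symmetric (`r_top == r_bottom`, `t_down == t_up`); combined sub-stacks in
#' general are not, although their transmittance is always side-invariant.
#' All fields are vectorised (one element per wavelength) and recycled to a
#' common length.
#'
#' @param r_top,t_down Reflectance and transmittance for top illumination,
#'   fractions in \[0, 1\].
#' @param r_bottom,t_up Same for bottom illumination; default to the top-side
#'   values (symmetric plate).
#' @return An object of class `plate_rt`: a list of the four numeric vectors.
#' @examples
#' surface_plate(0.03)
#' plate_rt(0.2, 0.7)
#' @export
plate_rt <- function(r_top, t_down, r_bottom = r_top, t_up = t_down) {
  n <- max(length(r_top), length(t_down), length(r_bottom), length(t_up))
  p <- list(
    r_top = rep_len(as.numeric(r_top), n),
    t_down = rep_len(as.numeric(t_down), n),
    r_bottom = rep_len(as.numeric(r_bottom), n),
    t_up = rep_len(as.numeric(t_up), n)
  )
  for (f in names(p)) {
    v <- p[[f]]
    if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
      stop(sprintf("plate field `%s` must lie in [0, 1]", f), call. = FALSE)
    p[[f]] <- pmin(pmax(v, 0), 1)
  }
  if (any(p$r_top + p$t_down > 1 + 1e-9) || any(p$r_bottom + p$t_up > 1 + 1e-9))
    stop("energy violation: r + t > 1 on one side of the plate", call. = FALSE)
  structure(p, class = "plate_rt")
}

#' @export
print.plate_rt <- function(x, ...) {
  n <- length(x$r_top)
  cat(sprintf("<plate_rt: %d wavelength point%s>\n", n, if (n == 1) "" else "s"))
  sym <- isTRUE(all.equal(x$r_top, x$r_bottom)) &&
    isTRUE(all.equal(x$t_down, x$t_up))
  cat(if (sym) "  symmetric\n" else "  asymmetric (r_top != r_bottom)\n")
  show <- utils::head(data.frame(r_top = x$r_top, t_down = x$t_down,
                                 r_bottom = x$r_bottom, t_up = x$t_up), 6)
  print(show, row.names = FALSE)
  if (n > 6) cat(sprintf("  ... %d more\n", n - 6))
  invisible(x)
}

#' @export
length.plate_rt <- function(x) length(x$r_top)

#' Non-absorbing surface plate
#'
#' A petal surface modelled as a wavelength-independent reflecting interface:
#' reflectance `r`, transmittance `1 - r` (no absorption).
#'
#' @param r Surface reflectance fraction (scalar or per-wavelength vector).
#' @return A symmetric [plate_rt].
#' @export
surface_plate <- function(r) plate_rt(r_top = r, t_down = 1 - r)

#' Identity plate (perfectly transparent)
#' @param n Number of wavelength points.
#' @return A [plate_rt] with `r = 0`, `t = 1`.
#' @export
identity_plate <- function(n = 1) plate_rt(r_top = rep(0, n), t_down = rep(1, n))

# flip a plate upside down
reverse_plate <- function(p) {
  plate_rt(r_top = p$r_bottom, t_down = p$t_up,
           r_bottom = p$r_top, t_up = p$t_down)
}

#' Combine two plates with the adding equations
#'
#' Sums the infinite series of inter-plate reflections in closed form.  For a
#' top plate 1 above a bottom plate 2:
#' \deqn{T = \frac{t_1 t_2}{1 - r_1^b r_2^t}, \qquad
#'   R^t = r_1^t + \frac{t_1^\downarrow t_1^\uparrow r_2^t}{1 - r_1^b r_2^t},
#'   \qquad
#'   R^b = r_2^b + \frac{t_2^\uparrow t_2^\downarrow r_1^b}{1 - r_1^b r_2^t}.}
#' Intensities add (incoherent diffuse fluxes); interference is ignored.
#'
#' @param top,bottom [plate_rt] objects (recycled to a common length).
#' @return The combined [plate_rt]; in general asymmetric even when both
#'   inputs are symmetric.
#' @examples
#' a <- km_plate_rt(0.7, 0.25)
#' combine_two(a, a)  # equals km_plate_rt(1.4, 0.5)
#' @export
combine_two <- function(top, bottom) {
  stopifnot(inherits(top, "plate_rt"), inherits(bottom, "plate_rt"))
  n <- max(length(top), length(bottom))
  t1d <- rep_len(top$t_down, n);    t1u <- rep_len(top$t_up, n)
  r1t <- rep_len(top$r_top, n);     r1b <- rep_len(top$r_bottom, n)
  t2d <- rep_len(bottom$t_down, n); t2u <- rep_len(bottom$t_up, n)
  r2t <- rep_len(bottom$r_top, n);  r2b <- rep_len(bottom$r_bottom, n)

  den <- 1 - r1b * r2t
  if (any(den <= 0))
    stop("unphysical plate pair: 1 - r1_bottom * r2_top <= 0", call. = FALSE)

  plate_rt(
    r_top = r1t + t1d * t1u * r2t / den,
    t_down = t1d * t2d / den,
    r_bottom = r2b + t2u * t2d * r1b / den,
    t_up = t2u * t1u / den
  )
}

#' Combine an ordered stack of plates
#'
#' Left fold of [combine_two()] over a top-to-bottom list of plates.
#'
#' @param layers List of [plate_rt] objects, ordered top to bottom.
#' @return The combined [plate_rt].
#' @export
combine_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0)
    stop("`layers` must be a non-empty list of plates", call. = FALSE)
  Reduce(combine_two, layers)
}

#' Remove a known top plate from combined stack observables
#'
#' Inverts the adding equations for a known symmetric top plate: given the
#' full stack's top-illumination reflectance `total_R` and transmittance
#' `total_T`, returns the observables of everything below it,
#' \deqn{R_{\mathrm{rest}} = \frac{R - r_1}{t_1^2 + r_1 (R - r_1)}, \qquad
#'   T_{\mathrm{rest}} = \frac{T\,(1 - r_1 R_{\mathrm{rest}})}{t_1}.}
#'
#' @param total_R,total_T Numeric vectors, full-stack observables.
#' @param top Symmetric [plate_rt] with `t > 0`.
#' @return A data frame with columns `R_rest`, `T_rest` and `valid` (FALSE
#'   where the recovered `R_rest` falls outside \[0, 1)).
#' @export
peel_top <- function(total_R, total_T, top) {
  stopifnot(inherits(top, "plate_rt"))
  n <- max(length(total_R), length(total_T), length(top))
  R <- rep_len(as.numeric(total_R), n)
  T <- rep_len(as.numeric(total_T), n)
  r1 <- rep_len(top$r_top, n)
  t1 <- rep_len(top$t_down, n)
  if (any(t1 == 0))
    stop("singular top plate: t = 0 cannot be peeled", call. = FALSE)

  R_rest <- (R - r1) / (t1^2 + r1 * (R - r1))
  T_rest <- T * (1 - r1 * R_rest) / t1
  valid <- is.finite(R_rest) & is.finite(T_rest) & R_rest >= 0 & R_rest < 1 &
    T_rest >= 0 & T_rest <= 1
  R_rest[!valid] <- NA_real_
  T_rest[!valid] <- NA_real_
  data.frame(R_rest = R_rest, T_rest = T_rest, valid = valid)
}

#' Solve for an unknown symmetric plate above a known sub-stack
#'
#' Given the observables (`R_rest`, `T_rest`) of an unknown symmetric plate
#' stacked on a known bottom sub-stack with top-illumination observables
#' (`R_B`, `T_B`), recovers the plate's own reflectance and transmittance:
#' \deqn{r = \frac{R_{\mathrm{rest}} - (T_{\mathrm{rest}}/T_B)^2 R_B}
#'             {1 - (T_{\mathrm{rest}} R_B / T_B)^2}, \qquad
#'       t = \frac{T_{\mathrm{rest}} (1 - r R_B)}{T_B}.}
#'
#' @param R_rest,T_rest Numeric vectors: observables of plate + bottom stack.
#' @param bottom [plate_rt] of the known bottom sub-stack (its top side is
#'   used); `T_B > 0` required.
#' @return Data frame with columns `r`, `t`, `valid`; wavelengths where the
#'   recovered pair is unphysical (outside \[0,1\] or `r + t > 1`) are
#'   flagged invalid with `NA` values, as happens with noisy measurements.
#' @export
solve_symmetric_middle <- function(R_rest, T_rest, bottom) {
  stopifnot(inherits(bottom, "plate_rt"))
  n <- max(length(R_rest), length(T_rest), length(bottom))
  Rr <- rep_len(as.numeric(R_rest), n)
  Tr <- rep_len(as.numeric(T_rest), n)
  RB <- rep_len(bottom$r_top, n)
  TB <- rep_len(bottom$t_down, n)
  if (any(TB == 0))
    stop("singular bottom stack: T_B = 0", call. = FALSE)

  q <- Tr / TB
  r <- (Rr - q^2 * RB) / (1 - (q * RB)^2)
  t <- Tr * (1 - r * RB) / TB
  valid <- is.finite(r) & is.finite(t) &
    r >= -1e-12 & t >= -1e-12 & r <= 1 & t <= 1 & (r + t) <= 1 + 1e-9
  r <- ifelse(valid, pmin(pmax(r, 0), 1), NA_real_)
  t <- ifelse(valid, pmin(pmax(t, 0), 1), NA_real_)
  data.frame(r = r, t = t, valid = valid)
}

#' Bounce-series oracle for two-plate combination
#'
#' Independent check of [combine_two()]: sums the multiple-reflection
#' geometric series term by term (bounce by bounce) until every increment is
#' below `tol`.  Intended for testing, not production use.
#'
#' @param top,bottom [plate_rt] objects.
#' @param tol Convergence tolerance on series increments.
#' @param max_iter Iteration cap; exceeding it raises an error.
#' @return The combined [plate_rt].
#' @export
series_oracle <- function(top, bottom, tol = 1e-14, max_iter = 100000L) {
  stopifnot(inherits(top, "plate_rt"), inherits(bottom, "plate_rt"))
  n <- max(length(top), length(bottom))
  t1d <- rep_len(top$t_down, n);    t1u <- rep_len(top$t_up, n)
  r1t <- rep_len(top$r_top, n);     r1b <- rep_len(top$r_bottom, n)
  t2d <- rep_len(bottom$t_down, n); t2u <- rep_len(bottom$t_up, n)
  r2t <- rep_len(bottom$r_top, n);  r2b <- rep_len(bottom$r_bottom, n)

  g <- r1b * r2t                      # per-bounce gain of the inter-plate cavity
  if (any(g >= 1))
    stop("series does not converge: r1_bottom * r2_top >= 1", call. = FALSE)

  T_dn <- t1d * t2d
  R_tp <- r1t + t1d * r2t * t1u
  R_bt <- r2b + t2u * r1b * t2d
  T_up <- t2u * t1u
  term <- rep(1, n)
  for (i in seq_len(max_iter)) {
    term <- term * g
    if (all(abs(term) < tol)) break
    T_dn <- T_dn + t1d * t2d * term
    R_tp <- R_tp + t1d * r2t * t1u * term
    R_bt <- R_bt + t2u * r1b * t2d * term
    T_up <- T_up + t2u * t1u * term
    if (i == max_iter)
      stop("bounce series failed to converge within iteration cap",
           call. = FALSE)
  }
  plate_rt(r_top = R_tp, t_down = T_dn, r_bottom = R_bt, t_up = T_up)
}
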